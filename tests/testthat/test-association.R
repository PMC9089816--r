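test_that("equal-frequency discretization splits at empirical quantiles", {
  expect_equal(discretize(c(1, 2, 3, 4), 2), c(0, 0, 1, 1))
  expect_warning(z <- discretize(rep(3, 10), 5), "constant")
  expect_equal(z, rep(0L, 10))
  set.seed(11)
  bins <- discretize(rnorm(1000), 5)
  expect_true(all(abs(base::table(bins) - 200) <= 1))
  # ties share a bin
  v <- c(rep(1, 6), 2, 3)
  b <- discretize(v, 4)
  expect_equal(length(unique(b[v == 1])), 1)
})

test_that("mutual information matches the plug-in formula", {
  x <- rep(c(0, 1), each = 5)
  expect_equal(mutual_information(x, x), log(2), tolerance = 1e-12)
  # independent 2x2 product table (25 each cell)
  a <- rep(c(0, 0, 1, 1), each = 25)
  b <- rep(c(0, 1, 0, 1), each = 25)
  expect_equal(mutual_information(a, b), 0, tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "mismatch")
})

test_that("mutual information is symmetric, non-negative, and MI(x,x)=H(x)", {
  set.seed(21)
  for (i in 1:20) {
    x <- sample.int(4, 60, replace = TRUE)
    y <- sample.int(3, 60, replace = TRUE)
    mi <- mutual_information(x, y)
    expect_gte(mi, 0)
    expect_equal(mi, mutual_information(y, x), tolerance = 1e-12)
    px <- base::table(x) / 60
    expect_equal(mutual_information(x, x), -sum(px * log(px)),
                 tolerance = 1e-12)
  }
})

test_that("absolute Pearson correlation behaves at the extremes", {
  a <- c(1.2, 3.4, 2.2, 5.6, 0.1)
  expect_equal(pearson_abs(a, a), 1)
  expect_equal(pearson_abs(a, -a), 1)
  set.seed(31)
  expect_lt(pearson_abs(rnorm(10000), rnorm(10000)), 0.05)
  expect_warning(z <- pearson_abs(rep(1, 5), a), "constant")
  expect_equal(z, 0)
})

test_that("symmetrical uncertainty is a normalized association in [0,1]", {
  x <- rep(c(0, 1, 2), times = 10)
  expect_equal(symmetrical_uncertainty(x, x), 1)
  a <- rep(c(0, 0, 1, 1), each = 25)
  b <- rep(c(0, 1, 0, 1), each = 25)
  expect_equal(symmetrical_uncertainty(a, b), 0, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:20) {
    u <- sample.int(3, 50, replace = TRUE)
    v <- sample.int(5, 50, replace = TRUE)
    su <- symmetrical_uncertainty(u, v)
    expect_gte(su, 0); expect_lte(su, 1)
  }
  expect_equal(symmetrical_uncertainty(rep(1, 10), rep(2, 10)), 0)
})

test_that("the correlation cache applies the mode's measure per kind pair", {
  tab <- tiny_table()
  cache <- build_correlation_cache(tab)
  # identical discrete items: feature-feature MI equals the entropy
  tab2 <- feature_table(data.frame(a = tab$data$mirror, b = tab$data$mirror),
                        as.character(tab$labels))
  c2 <- build_correlation_cache(tab2)
  expect_equal(c2$feature_feature["a", "b"],
               mutual_information(tab2$data$a, tab2$data$a),
               tolerance = 1e-12)
  # continuous-continuous uses |Pearson| in fselector mode
  tab3 <- feature_table(data.frame(u = tab$data$cont, v = -tab$data$cont),
                        as.character(tab$labels))
  c3 <- build_correlation_cache(tab3, mode = "fselector")
  expect_equal(c3$feature_feature["u", "v"], 1)
  # ...and a bounded SU in scale-consistent mode
  c4 <- build_correlation_cache(tab3, mode = "symmetrical_uncertainty")
  expect_lte(c4$feature_feature["u", "v"], 1)
  expect_gt(c4$feature_feature["u", "v"], 0.9)
})

test_that("cache values are deterministic and row-permutation invariant", {
  g <- generate_assessment_data(synthetic_spec(n_subjects = 80, n_noise = 4,
                                               seed = 12))
  c1 <- build_correlation_cache(g$table)
  expect_identical(c1, build_correlation_cache(g$table))
  set.seed(5)
  perm <- sample.int(nrow(g$table$data))
  shuffled <- feature_table(g$table$data[perm, , drop = FALSE],
                            as.character(g$table$labels)[perm],
                            kinds = g$table$kinds)
  c2 <- build_correlation_cache(shuffled)
  expect_equal(c1$feature_class, c2$feature_class, tolerance = 1e-12)
  expect_equal(c1$feature_feature, c2$feature_feature, tolerance = 1e-12)
})

test_that("noise items show near-zero class association at large n", {
  g <- generate_assessment_data(synthetic_spec(n_subjects = 5000,
                                               n_noise = 6, seed = 13))
  cache <- build_correlation_cache(g$table)
  noise <- g$truth$item[g$truth$role == "noise"]
  expect_true(all(cache$feature_class[noise] < 0.01))
})

test_that("the cache serializes to a long-format CSV", {
  g <- generate_assessment_data(synthetic_spec(n_subjects = 60, n_noise = 2,
                                               seed = 14))
  cache <- build_correlation_cache(g$table)
  path <- withr::local_tempfile(fileext = ".csv")
  write_correlation_cache(cache, path)
  long <- utils::read.csv(path)
  p <- length(cache$items)
  expect_equal(nrow(long), p + p * (p - 1) / 2)
})
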