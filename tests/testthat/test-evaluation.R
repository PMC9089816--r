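test_that("binary AUC matches rank-statistic cases", {
  expect_equal(binary_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(binary_auc(c(0.5, 0.5), c(1, 0)), 0.5)
  # enumerate the 4 positive-negative pairs: all won by positives
  expect_equal(binary_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 1, 0)), 1)
  expect_equal(binary_auc(c(0.2, 0.9), c(1, 0)), 0)
  expect_error(binary_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("Hand-Till AUC equals brute-force pairwise enumeration", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(12:30, 1)
    labels <- sample(c("CN", "MCI", "AD"), n, replace = TRUE)
    while (length(unique(labels)) < 3)
      labels <- sample(c("CN", "MCI", "AD"), n, replace = TRUE)
    sm <- matrix(runif(3 * n), n, 3,
                 dimnames = list(NULL, c("AD", "CN", "MCI")))
    sm <- sm / rowSums(sm)
    expect_equal(hand_till_auc(sm, labels), brute_hand_till(sm, labels),
                 tolerance = 1e-12)
  }
})

test_that("Hand-Till agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  n <- 120
  labels <- sample(c("CN", "MCI", "AD"), n, replace = TRUE)
  sm <- matrix(runif(3 * n), n, 3,
               dimnames = list(NULL, c("CN", "MCI", "AD")))
  sm <- sm / rowSums(sm)
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::multiclass.roc(labels, as.data.frame(sm)))))
  expect_equal(hand_till_auc(sm, labels), ref, tolerance = 1e-9)
})

test_that("Hand-Till degenerates to binary AUC with two classes", {
  set.seed(63)
  labels <- sample(c("CN", "AD"), 40, replace = TRUE)
  s_ad <- runif(40)
  sm <- cbind(AD = s_ad, CN = 1 - s_ad)
  expect_equal(hand_till_auc(sm, labels), binary_auc(s_ad, labels == "AD"),
               tolerance = 1e-12)
})

test_that("perfectly separated scores give AUC 1; permuted labels give 0.5", {
  labels <- rep(c("CN", "MCI", "AD"), each = 5)
  sm <- matrix(0, 15, 3, dimnames = list(NULL, c("CN", "MCI", "AD")))
  sm[cbind(seq_len(15), rep(1:3, each = 5))] <- 1
  expect_equal(hand_till_auc(sm, labels), 1)

  set.seed(64)
  n <- 3000
  labs <- sample(c("CN", "MCI", "AD"), n, replace = TRUE)
  r <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, c("CN", "MCI", "AD")))
  expect_equal(hand_till_auc(r / rowSums(r), labs), 0.5, tolerance = 0.03)
})

test_that("AUC is invariant to monotone transforms of class scores", {
  set.seed(65)
  labels <- sample(c("CN", "MCI", "AD"), 60, replace = TRUE)
  sm <- matrix(runif(180), 60, 3, dimnames = list(NULL, c("CN", "MCI", "AD")))
  a1 <- hand_till_auc(sm, labels)
  a2 <- hand_till_auc(exp(3 * sm), labels)
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_error(hand_till_auc(sm[, 1:2], labels), "MCI|AD")
})

test_that("stratified folds partition subjects and balance classes", {
  labels <- sample(rep(c("CN", "MCI", "AD"), times = c(40, 35, 28)))
  folds <- stratified_folds(labels, k = 5, seed = 3)
  expect_equal(length(folds), length(labels))
  sizes <- base::table(folds)
  expect_lte(max(sizes) - min(sizes), 1)
  for (cl in c("CN", "MCI", "AD")) {
    per_fold <- base::table(folds[labels == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_identical(folds, stratified_folds(labels, k = 5, seed = 3))
})

test_that("standard CV scores a perfectly predictive item near 1", {
  labels <- rep(c("CN", "MCI", "AD"), each = 20)
  set.seed(71)
  tab <- feature_table(
    data.frame(perfect = rep(0:2, each = 20) + rnorm(60, sd = 0.05),
               junk = rnorm(60)),
    labels)
  cv <- standard_cv_auc(tab, "perfect", k = 5, backend = centroid_backend(),
                        seed = 2)
  expect_gt(cv$overall_mean_auc, 0.98)
  cv2 <- standard_cv_auc(tab, "perfect", k = 5, backend = centroid_backend(),
                         seed = 2)
  expect_identical(cv, cv2)
})

test_that("label-independent items score near chance", {
  g <- generate_assessment_data(synthetic_spec(
    n_subjects = 300, effect_size = 0, n_informative_continuous = 2,
    n_informative_discrete = 0, n_redundant = 0, n_noise = 2, seed = 41))
  cv <- standard_cv_auc(g$table, items_of(g$table), k = 5,
                        backend = centroid_backend(), seed = 7)
  expect_equal(cv$overall_mean_auc, 0.5, tolerance = 0.07)
})

test_that("selection-aware CV runs the selector once per fold", {
  g <- generate_assessment_data(synthetic_spec(n_subjects = 250, n_noise = 6,
                                               seed = 51))
  seen <- 0
  identity_selector <- function(tab) {
    seen <<- seen + 1
    items_of(tab)
  }
  cv <- fs_fold_cv(g$table, identity_selector, k = 5,
                   backend = centroid_backend(), seed = 4)
  expect_equal(seen, 5)
  expect_equal(nrow(cv$per_fold), 5)
  expect_true(all(vapply(cv$per_fold$items, identical, logical(1),
                         items_of(g$table))))
  expect_true(all(cv$per_fold$auc >= 0 & cv$per_fold$auc <= 1))
  # selector sees only its own fold's subjects
  sizes <- integer(0)
  size_probe <- function(tab) { sizes <<- c(sizes, nrow(tab$data)); items_of(tab) }
  fs_fold_cv(g$table, size_probe, k = 5, backend = centroid_backend(),
             seed = 4)
  expect_equal(sizes,
               as.integer(base::table(cv$fold_assignment)[as.character(1:5)]))
})

test_that("selection-aware CV separates signal from null tables", {
  g <- generate_assessment_data(synthetic_spec(n_subjects = 250, n_noise = 6,
                                               seed = 52))
  null_g <- generate_assessment_data(synthetic_spec(
    n_subjects = 250, effect_size = 0, n_noise = 6, seed = 52))
  sel <- function(tab) cfs_select(tab, mode = "symmetrical_uncertainty")
  cv_sig <- fs_fold_cv(g$table, sel, k = 5, backend = centroid_backend(),
                       seed = 6)
  suppressWarnings(
    cv_null <- fs_fold_cv(null_g$table, sel, k = 5,
                          backend = centroid_backend(), seed = 6))
  expect_gt(cv_sig$overall_mean_auc, 0.9)
  expect_lt(cv_null$overall_mean_auc, 0.65)
})
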