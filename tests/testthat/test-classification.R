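test_that("metrics follow their confusion-count definitions", {
  met <- compute_metrics(13, 1, 10, 2)
  expect_equal(met$accuracy, 23 / 26)
  expect_equal(met$sensitivity, 13 / 14)
  expect_equal(met$specificity_std, 10 / 12)
  expect_equal(met$npv, 10 / 11)
  expect_equal(met$ppv, 13 / 15)

  # zero denominators flag, not error
  met0 <- compute_metrics(0, 0, 5, 1)
  expect_true(is.na(met0$sensitivity))
  expect_error(compute_metrics(-1, 0, 0, 0), "non-negative")

  # accuracy decomposes over class prevalences for arbitrary counts
  set.seed(4)
  for (rep in 1:10) {
    cc <- as.list(sample(1:30, 4))
    names(cc) <- c("tp", "fn", "tn", "fp")
    m <- compute_metrics(cc$tp, cc$fn, cc$tn, cc$fp)
    P <- cc$tp + cc$fn
    N <- cc$tn + cc$fp
    expect_equal(m$accuracy,
                 (m$sensitivity * P + m$specificity_std * N) / (P + N))
  }
})

test_that("confusion counts treat PD as the positive class", {
  cc <- confusion_counts(c("PD", "PD", "HOG", "HOG"),
                         c("PD", "HOG", "HOG", "PD"))
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
})

test_that("features are leg-averaged per subject", {
  params <- data.frame(subject_id = c("a", "a"), leg = c("left", "right"),
                       step_time_s = c(0.54, 0.56), stride_time_s = c(1.1, 1.1),
                       step_length_m = c(0.3, 0.32),
                       stride_length_m = c(0.6, 0.64),
                       walking_speed_mps = c(0.55, 0.57))
  subjects <- data.frame(subject_id = "a", group = "PD")
  ft <- build_features(params, subjects)
  expect_equal(ft$step_time_s, 0.55)
  expect_equal(nrow(ft), 1L)

  co <- simulate_cohort(n_pd = 4, n_hog = 4, seed = 1)
  ft2 <- build_features(co$truth, co$subjects)
  expect_equal(nrow(ft2), 8L)
  expect_equal(ncol(ft2), 7L)  # id + five features + group

  empty <- build_features(co$truth[0, ], co$subjects[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("the stratified split reproduces the 62/26 cohort arithmetic", {
  ft <- shifted_features(n_pd = 48, n_hog = 40, shift_sd = 1)
  plan <- stratified_split(ft, ratio = 0.7, seed = 3)
  expect_length(plan$train_ids, 62L)
  expect_length(plan$eval_ids, 26L)
  ev_groups <- ft$group[ft$subject_id %in% plan$eval_ids]
  expect_equal(sum(ev_groups == "PD"), 14L)
  expect_equal(sum(ev_groups == "HOG"), 12L)
  expect_length(intersect(plan$train_ids, plan$eval_ids), 0L)

  plan2 <- stratified_split(ft, ratio = 0.7, seed = 3)
  expect_identical(plan, plan2)
  plan3 <- stratified_split(ft, ratio = 0.7, seed = 4)
  expect_false(identical(plan$eval_ids, plan3$eval_ids))
  expect_error(stratified_split(ft, ratio = 1.2), "parameter error")
})

test_that("each classifier solves its canonical easy problem", {
  # unanimous 5-NN vote
  tr <- shifted_features(n_pd = 10, n_hog = 10, shift_sd = 50, seed = 2)
  ev <- tr[tr$group == "PD", ][1:3, ]
  expect_true(all(fit_predict(tr, ev, "knn5") == "PD"))

  # one threshold separates the classes: a single split suffices
  expect_true(all(fit_predict(tr, tr, "decision_tree") == tr$group))

  # naive Bayes on two well-separated Gaussians (d' = 6)
  make_nb <- function(n, seed) {
    set.seed(seed)
    grp <- factor(rep(c("PD", "HOG"), each = n / 2), levels = c("PD", "HOG"))
    mu <- ifelse(grp == "PD", 0, 6)
    data.frame(subject_id = sprintf("N%03d", 1:n),
               step_time_s = rnorm(n, mu), stride_time_s = rnorm(n, mu),
               step_length_m = rnorm(n, mu), stride_length_m = rnorm(n, mu),
               walking_speed_mps = rnorm(n, mu), group = grp)
  }
  trn <- make_nb(200, 1)
  evl <- make_nb(200, 2)
  pred <- fit_predict(trn, evl, "gaussian_nb")
  expect_lt(mean(pred != evl$group), 0.01)

  one_class <- tr[tr$group == "PD", ]
  expect_error(fit_predict(one_class, ev, "svm_rbf"), "degenerate-model")
})

test_that("cross-validation separates a strongly shifted cohort", {
  ft <- shifted_features(n_pd = 44, n_hog = 44, shift_sd = 5, seed = 6)
  cv <- cross_validate(ft, n_splits = 5, seed = 2)
  expect_equal(nrow(cv), 20L)
  expect_true(all(cv$accuracy >= 0.95))
  expect_error(cross_validate(ft, n_splits = 1), "parameter error")
})

test_that("label permutation drives accuracy to chance", {
  co <- simulate_cohort(seed = 11)
  ft <- build_features(co$truth, co$subjects)
  set.seed(99)
  ft$group <- sample(ft$group)
  cv <- cross_validate(ft, seed = 7)
  expect_gt(mean(cv$accuracy), 0.3)
  expect_lt(mean(cv$accuracy), 0.7)
})

test_that("featureless cohorts fall back to the majority class", {
  ft <- shifted_features(n_pd = 18, n_hog = 12, shift_sd = 0, seed = 1)
  ft[gait_parameter_names()] <- lapply(
    list(0.5, 1, 0.3, 0.6, 0.6), function(v) rep(v, nrow(ft)))
  plan <- stratified_split(ft, seed = 2)
  tr <- ft[ft$subject_id %in% plan$train_ids, ]
  ev <- ft[ft$subject_id %in% plan$eval_ids, ]
  maj_frac <- mean(ev$group == "PD")  # PD is the majority class
  for (m in c("knn5", "svm_rbf", "gaussian_nb", "decision_tree")) {
    pred <- fit_predict(tr, ev, m, seed = 1)
    acc <- mean(pred == ev$group)
    expect_equal(acc, maj_frac)
  }
})
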