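#' Build the per-subject feature table
#'
#' Averages each of the five gait characteristics over the available legs of
#' each subject (both legs when present, the single available leg otherwise,
#' with a warning) and attaches the group label. The five leg-averaged
#' characteristics are the classifier features.
#'
#' @param params data.frame of per-leg estimates: columns `subject_id`,
#'   `leg` and the five parameter columns.
#' @param subjects subject table (see [read_subject_table()]) with
#'   `subject_id` and `group`.
#' @return Data.frame keyed by `subject_id` with the five feature columns
#'   and a `group` factor (levels `PD`, `HOG`). Subjects without any
#'   recording are dropped with a warning.
#' @export
build_features <- function(params, subjects) {
  pars <- gait_parameter_names()
  if (nrow(params) == 0L || nrow(subjects) == 0L) {
    out <- data.frame(subject_id = character(0))
    for (p in pars) out[[p]] <- numeric(0)
    out$group <- factor(character(0), levels = c("PD", "HOG"))
    return(out)
  }
  agg <- stats::aggregate(params[pars], by = list(subject_id = params$subject_id),
                          FUN = mean)
  single <- table(params$subject_id)
  if (any(single < 2L)) {
    warning(sum(single < 2L),
            " subject(s) have a single-leg recording; features use that leg",
            call. = FALSE)
  }
  missing <- setdiff(subjects$subject_id, agg$subject_id)
  if (length(missing) > 0L) {
    warning("dropping ", length(missing), " subject(s) without recordings",
            call. = FALSE)
  }
  out <- merge(agg, subjects[, c("subject_id", "group")], by = "subject_id")
  out$group <- factor(as.character(out$group), levels = c("PD", "HOG"))
  if (any(!stats::complete.cases(out[pars]))) {
    stop("validation error: missing feature values", call. = FALSE)
  }
  out[order(out$subject_id), , drop = FALSE]
}

#' Confusion counts with PD as the positive class
#'
#' @param truth,predicted factors or characters with values `PD`/`HOG`.
#' @return List of class `confusion_counts`: `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  structure(list(tp = sum(truth == "PD" & predicted == "PD"),
                 fn = sum(truth == "PD" & predicted == "HOG"),
                 tn = sum(truth == "HOG" & predicted == "HOG"),
                 fp = sum(truth == "HOG" & predicted == "PD")),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' With PD the positive class: accuracy `(tp+tn)/(tp+tn+fp+fn)`, sensitivity
#' `tp/(tp+fn)`, standard specificity `tn/(tn+fp)`, negative predictive
#' value `tn/(tn+fn)` and positive predictive value `tp/(tp+fp)`. Both the
#' standard specificity and the NPV are reported because clinical reports
#' sometimes label the latter "specificity". Zero denominators yield `NA`
#' (undefined-metric flag), never an error.
#'
#' @param counts a [confusion_counts()] object, or `tp` as a number when the
#'   four counts are given separately.
#' @param fn,tn,fp individual counts when `counts` is numeric.
#' @return List with `accuracy`, `sensitivity`, `specificity_std`, `npv`,
#'   `ppv`.
#' @examples
#' compute_metrics(13, 1, 10, 2)  # accuracy 0.8846, sensitivity 0.9286
#' @export
compute_metrics <- function(counts, fn = NULL, tn = NULL, fp = NULL) {
  if (inherits(counts, "confusion_counts")) {
    tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  } else {
    tp <- counts
  }
  if (any(c(tp, fn, tn, fp) < 0)) {
    stop("validation error: confusion counts must be non-negative",
         call. = FALSE)
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(accuracy = ratio(tp + tn, tp + tn + fp + fn),
       sensitivity = ratio(tp, tp + fn),
       specificity_std = ratio(tn, tn + fp),
       npv = ratio(tn, tn + fn),
       ppv = ratio(tp, tp + fp))
}

#' Stratified subject-wise train/evaluation split
#'
#' Draws a deterministic (seeded) random split of subjects into training and
#' evaluation sets, stratified by group so that each class contributes a
#' near-proportional share of the evaluation set: the evaluation set has
#' `round(n * (1 - ratio))` subjects, allocated per class by rounding and
#' adjusted on the largest class when the rounded shares disagree with the
#' total. An 88-subject cohort (48 PD + 40 HOG) at ratio 0.7 yields 62
#' training and 26 evaluation subjects (14 PD + 12 HOG).
#'
#' @param features feature table from [build_features()] (needs
#'   `subject_id` and `group`).
#' @param ratio training fraction in (0, 1); default 0.7.
#' @param seed integer seed making the split reproducible.
#' @return List of class `split_plan`: `train_ids`, `eval_ids`, `ratio`,
#'   `seed`.
#' @export
stratified_split <- function(features, ratio = 0.7, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) {
    stop("parameter error: ratio must lie strictly between 0 and 1",
         call. = FALSE)
  }
  tab <- table(features$group)
  if (any(tab < 2L)) {
    stop("parameter error: need at least 2 subjects per class", call. = FALSE)
  }
  n <- nrow(features)
  n_eval <- round(n * (1 - ratio))
  per_class <- round(tab * (1 - ratio))
  diffn <- n_eval - sum(per_class)
  if (diffn != 0L) {
    big <- names(tab)[which.max(tab)]
    per_class[big] <- per_class[big] + diffn
  }
  eval_ids <- local_seed(seed, {
    unlist(lapply(names(tab), function(g) {
      ids <- features$subject_id[features$group == g]
      sample(ids, per_class[[g]])
    }), use.names = FALSE)
  })
  structure(list(train_ids = sort(setdiff(features$subject_id, eval_ids)),
                 eval_ids = sort(eval_ids), ratio = ratio, seed = seed),
            class = "split_plan")
}

#' Fit one classifier and predict evaluation labels
#'
#' The four classifiers compared: 5-nearest-neighbour (`knn5`), support
#' vector machine with radial-basis kernel (`svm_rbf`, cost 1, gamma
#' `1 / (d * var)` of the standardized training features), Gaussian naive
#' Bayes (`gaussian_nb`), and a Gini decision tree with cost-complexity
#' pruning selected by internal 3-fold cross-validation (`decision_tree`).
#' Features are standardized with training-set statistics before the
#' distance/kernel methods (k-NN and SVM).
#'
#' @param train,eval data.frames with the five feature columns and (for
#'   `train`) a `group` factor.
#' @param model one of `"knn5"`, `"svm_rbf"`, `"gaussian_nb"`,
#'   `"decision_tree"`.
#' @param seed integer seed for the tree's internal cross-validation folds.
#' @return Factor of predicted labels (`PD`/`HOG`), one per evaluation row.
#' @export
fit_predict <- function(train, eval,
                        model = c("knn5", "svm_rbf", "gaussian_nb",
                                  "decision_tree"),
                        seed = 1L) {
  model <- match.arg(model)
  pars <- gait_parameter_names()
  y <- droplevels(factor(train$group, levels = c("PD", "HOG")))
  if (nlevels(y) < 2L) {
    stop("degenerate-model error: training set has a single class",
         call. = FALSE)
  }
  X <- as.matrix(train[pars])
  E <- as.matrix(eval[pars])
  zscore <- function() {
    mu <- colMeans(X)
    sig <- apply(X, 2, sd)
    sig[sig == 0] <- 1
    list(X = scale(X, mu, sig), E = scale(E, mu, sig))
  }
  pred <- switch(
    model,
    knn5 = {
      z <- zscore()
      local_seed(seed, class::knn(z$X, z$E, cl = y, k = 5))
    },
    svm_rbf = {
      z <- zscore()
      gam <- 1 / (ncol(z$X) * max(var(as.vector(z$X)), .Machine$double.eps))
      fit <- e1071::svm(z$X, y, kernel = "radial", cost = 1, gamma = gam,
                        scale = FALSE)
      predict(fit, z$E)
    },
    gaussian_nb = {
      fit <- e1071::naiveBayes(data.frame(X), y)
      predict(fit, data.frame(E))
    },
    decision_tree = {
      d <- data.frame(X, group = y)
      fit <- local_seed(seed, rpart::rpart(
        group ~ ., data = d, method = "class",
        parms = list(split = "gini"),
        control = rpart::rpart.control(xval = 3, minsplit = 10, cp = 0.001)))
      cp <- fit$cptable[which.min(fit$cptable[, "xerror"]), "CP"]
      pruned <- rpart::prune(fit, cp = cp)
      predict(pruned, data.frame(E), type = "class")
    })
  factor(as.character(pred), levels = c("PD", "HOG"))
}

#' Subject-wise stratified cross-validation of the four classifiers
#'
#' Performs `n_splits` independent seeded stratified resamples of the cohort
#' (each a fresh [stratified_split()] at the given ratio, i.e. repeated
#' 62/26-style subject draws rather than a partition), fits each classifier
#' on the training subjects of every split, and scores it on the held-out
#' subjects. No subject ever appears on both sides of one split.
#'
#' @param features feature table from [build_features()].
#' @param n_splits number of resamples (default 5); must be at least 2.
#' @param ratio training fraction (default 0.7).
#' @param seed integer base seed; split `s` uses `seed + s`.
#' @param models character vector of classifiers to run (default all four).
#' @return Data.frame with one row per model x split: the confusion counts
#'   and the metrics of [compute_metrics()] (accuracy as a fraction).
#' @export
cross_validate <- function(features, n_splits = 5L, ratio = 0.7, seed = 1L,
                           models = c("knn5", "svm_rbf", "gaussian_nb",
                                      "decision_tree")) {
  if (n_splits < 2L) {
    stop("parameter error: n_splits must be at least 2", call. = FALSE)
  }
  if (nlevels(droplevels(factor(features$group))) < 2L) {
    stop("degenerate-model error: cohort has a single class", call. = FALSE)
  }
  rows <- list()
  for (s in seq_len(n_splits)) {
    plan <- stratified_split(features, ratio = ratio, seed = seed + s)
    train <- features[features$subject_id %in% plan$train_ids, , drop = FALSE]
    eval <- features[features$subject_id %in% plan$eval_ids, , drop = FALSE]
    for (m in models) {
      pred <- fit_predict(train, eval, m, seed = seed + s)
      cc <- confusion_counts(eval$group, pred)
      met <- compute_metrics(cc)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, split = s, tp = cc$tp, fn = cc$fn, tn = cc$tn, fp = cc$fp,
        accuracy = met$accuracy, sensitivity = met$sensitivity,
        specificity_std = met$specificity_std, npv = met$npv, ppv = met$ppv)
    }
  }
  do.call(rbind, rows)
}
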