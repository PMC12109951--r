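#' Confusion matrix for gait-phase predictions
#'
#' @param y_true,y_pred factors/characters of equal length with labels in
#'   `levels`.
#' @param levels class labels; defaults to the 4 gait phases.
#' @return integer matrix (class `confusion_matrix`), rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(y_true, y_pred, levels = gait_phases()) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  t_ <- factor(as.character(y_true), levels = levels)
  p_ <- factor(as.character(y_pred), levels = levels)
  if (anyNA(t_) || anyNA(p_)) stop("labels outside the given levels")
  m <- as.matrix(table(true = t_, predicted = p_))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Classification metrics from a confusion matrix
#'
#' Per-class one-vs-rest reductions give TP/TN/FP/FN, from which precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean F1 are computed
#' per class and macro-averaged (micro-averaging available). Accuracy is the
#' overall fraction of correct predictions. Classes never predicted (or
#' absent) get precision/recall 0 with a warning rather than an error.
#'
#' @param cm a [confusion()] matrix.
#' @param times optional per-sample recognition times (ms); their mean is
#'   reported as `avg_time_ms`.
#' @param average `"macro"` (unweighted mean over classes) or `"micro"`
#'   (pooled counts).
#' @return list of class `metrics_report` with `accuracy`, `precision`,
#'   `recall`, `f1` (fractions in \[0, 1\]), `per_class` data frame,
#'   `avg_time_ms`, `n`.
#' @export
metrics <- function(cm, times = NULL, average = c("macro", "micro")) {
  average <- match.arg(average)
  stopifnot(inherits(cm, "confusion_matrix") || (is.matrix(cm) &&
              nrow(cm) == ncol(cm)))
  n <- sum(cm)
  if (n == 0L) stop("empty confusion matrix")
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning(what, " undefined for class(es) ",
              paste(rownames(cm)[bad], collapse = ", "), "; reported as 0")
    out <- ifelse(bad, 0, num / den)
    out
  }
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  per_class <- data.frame(class = rownames(cm), tp = tp, tn = tn, fp = fp,
                          fn = fn, precision = prec, recall = rec, f1 = f1,
                          row.names = NULL)
  if (average == "macro") {
    P <- mean(prec); R <- mean(rec); F1 <- mean(f1)
  } else {
    P <- sum(tp) / sum(tp + fp)
    R <- sum(tp) / sum(tp + fn)
    F1 <- ifelse(P + R == 0, 0, 2 * P * R / (P + R))
  }
  structure(list(accuracy = sum(tp) / n, precision = P, recall = R, f1 = F1,
                 per_class = per_class,
                 avg_time_ms = if (is.null(times)) NA_real_ else mean(times),
                 n = n, average = average, confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d  acc=%.4f  prec=%.4f (%s)  rec=%.4f  f1=%.4f",
    x$n, x$accuracy, x$precision, x$average, x$recall, x$f1))
  if (!is.na(x$avg_time_ms)) cat(sprintf("  t=%.2f ms", x$avg_time_ms))
  cat("\n")
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' @param labels factor of class labels.
#' @param k number of folds.
#' @param seed seed fixing the assignment.
#' @return integer vector of fold ids (1..k), stratified so every class is
#'   spread across folds to within one sample.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < k))
    stop("need at least k samples in every class for stratified ", k,
         "-fold splitting")
  folds <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Stratified k-fold cross-validation
#'
#' Generic harness: `trainer(features, labels)` fits a model on the
#' training portion of each fold and `predictor(model, features)` returns
#' predicted labels (or a list with `labels` and `times_ms`) on the held-out
#' portion.
#'
#' @param features array `n x height x width` or `feature_set`.
#' @param labels factor (taken from the feature set when omitted).
#' @param k number of folds.
#' @param trainer,predictor fitting/prediction functions (see above).
#' @param seed seed for the fold assignment.
#' @return list with `reports` (one [metrics()] per fold), `folds`, and
#'   `summary` (mean and sd of accuracy across folds).
#' @export
kfold_cv <- function(features, labels = NULL, k = 5L, trainer, predictor,
                     seed = 1L) {
  if (inherits(features, "feature_set") && is.null(labels))
    labels <- features$labels
  feats <- features_to_input(features)
  labels <- as.factor(labels)
  folds <- kfold_split(labels, k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- trainer(feats[tr, , , drop = FALSE], labels[tr])
    pred <- predictor(model, feats[!tr, , , drop = FALSE])
    times <- NULL
    if (is.list(pred)) {
      times <- pred$times_ms
      pred <- pred$labels
    }
    rep_ <- metrics(confusion(labels[!tr], pred,
                              levels = levels(labels)), times = times)
    rep_$fold <- f
    reports[[f]] <- rep_
  }
  accs <- vapply(reports, `[[`, 0, "accuracy")
  list(reports = reports, folds = folds,
       summary = data.frame(mean_accuracy = mean(accs),
                            sd_accuracy = stats::sd(accs)))
}

#' Ablation study: MCNN baseline vs attention / LSTM variants
#'
#' Trains each architecture variant on identical train/test splits across
#' paired seeds and tabulates accuracy, macro precision/recall/F1, average
#' recognition time and parameter count in the usual ablation-table
#' layout.
#'
#' @param features `feature_set` or array.
#' @param labels factor (from the feature set when omitted).
#' @param variants subset of `c("mcnn", "ema", "lstm", "full")`.
#' @param config base [model_config()].
#' @param train a [train_config()]; its `split` sets the train fraction.
#' @param seeds integer vector of seeds; each seed fixes one shared split
#'   and the weight initializations of all variants (paired comparison).
#' @return data frame with one row per variant (mean over seeds) and the
#'   per-seed accuracies as a `per_seed` attribute.
#' @export
ablation <- function(features, labels = NULL,
                     variants = c("mcnn", "ema", "lstm", "full"),
                     config = model_config(), train = train_config(),
                     seeds = 1:10) {
  variants <- match.arg(variants, several.ok = TRUE)
  if (length(variants) < 2L) stop("need at least 2 variants")
  if (inherits(features, "feature_set") && is.null(labels))
    labels <- features$labels
  feats <- features_to_input(features)
  labels <- phase_factor(labels)
  n <- length(labels)
  acc <- matrix(NA_real_, length(seeds), length(variants),
                dimnames = list(NULL, variants))
  rows <- list()
  for (v in variants) {
    cfg_v <- variant_config(config, v)
    reps <- list()
    for (si in seq_along(seeds)) {
      s <- seeds[si]
      set.seed(s)
      tr <- sort(sample.int(n, round(train$split * n)))
      tc <- train
      tc$seed <- s
      model <- train_emacnn(feats[tr, , , drop = FALSE], labels[tr],
                            config = cfg_v, train = tc)
      pred <- predict_emacnn(model, feats[-tr, , , drop = FALSE])
      rep_ <- metrics(confusion(labels[-tr], pred$labels),
                      times = pred$times_ms)
      acc[si, v] <- rep_$accuracy
      reps[[si]] <- rep_
    }
    rows[[v]] <- data.frame(
      variant = v,
      use_ema = cfg_v$use_ema, use_lstm = cfg_v$use_lstm,
      accuracy = mean(acc[, v]),
      precision = mean(vapply(reps, `[[`, 0, "precision")),
      recall = mean(vapply(reps, `[[`, 0, "recall")),
      f1 = mean(vapply(reps, `[[`, 0, "f1")),
      avg_time_ms = mean(vapply(reps, `[[`, 0, "avg_time_ms")),
      n_parameters = n_parameters(cfg_v))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_seed") <- acc
  out
}

#' Per-mode evaluation with an overall average
#'
#' Trains and evaluates one classifier per locomotion mode (holdout split)
#' and reports per-mode metrics plus their unweighted mean accuracy.
#'
#' @param mode_sets named list of `feature_set` objects, one per mode.
#' @param config a [model_config()].
#' @param train a [train_config()].
#' @return list with `per_mode` (named list of [metrics()] reports),
#'   `confusions` (named list) and `overall_accuracy` (unweighted mean).
#' @export
multi_scene_eval <- function(mode_sets, config = model_config(),
                             train = train_config()) {
  stopifnot(length(mode_sets) >= 1L)
  reports <- list()
  for (mode in names(mode_sets)) {
    fs <- mode_sets[[mode]]
    labels <- phase_factor(fs$labels)
    feats <- features_to_input(fs)
    n <- length(labels)
    set.seed(train$seed)
    tr <- sort(sample.int(n, round(train$split * n)))
    model <- train_emacnn(feats[tr, , , drop = FALSE], labels[tr],
                          config = config, train = train)
    pred <- predict_emacnn(model, feats[-tr, , , drop = FALSE])
    reports[[mode]] <- metrics(confusion(labels[-tr], pred$labels),
                               times = pred$times_ms)
  }
  list(per_mode = reports,
       confusions = lapply(reports, `[[`, "confusion"),
       overall_accuracy = mean(vapply(reports, `[[`, 0, "accuracy")))
}

#' Dataset bookkeeping at a given acquisition scale
#'
#' Computes the number of windowed samples implied by an acquisition plan:
#' `windows_per_subject_mode` windows for each of `n_subjects` subjects in
#' each of `n_modes` locomotion modes.
#'
#' @param windows_per_subject_mode windows per subject per mode.
#' @param n_subjects number of subjects.
#' @param n_modes number of locomotion modes.
#' @return list with `per_mode` (windows per mode over all subjects) and
#'   `total`.
#' @export
dataset_plan <- function(windows_per_subject_mode = 3200L, n_subjects = 12L,
                         n_modes = 5L) {
  per_mode <- windows_per_subject_mode * n_subjects
  list(windows_per_subject_mode = windows_per_subject_mode,
       n_subjects = n_subjects, n_modes = n_modes,
       per_mode = per_mode, total = per_mode * n_modes)
}
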