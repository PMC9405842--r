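# Cross-validated dyslexia classification: feature assembly over painting
# grouping schemes, stratified 5-fold CV with train-statistic normalization,
# pinned SVM-RBF / ridge-logistic models, Mann-Whitney group statistics and
# permutation feature importance.

#' Per-recording DGI feature table
#'
#' @param recordings list of [binocular_recording()] objects.
#' @param min_samples dwell filter passed to [compute_dgi()].
#' @return data.frame with columns `dgi`, `mean_duration_ms`,
#'   `mean_amplitude_deg`, one row per recording.
#' @export
dgi_features <- function(recordings, min_samples = 3L) {
  rows <- lapply(recordings, function(r) {
    g <- compute_dgi(r, min_samples)
    data.frame(dgi = g$dgi, mean_duration_ms = g$mean_duration_ms,
               mean_amplitude_deg = g$mean_amplitude_deg)
  })
  do.call(rbind, rows)
}

#' Per-recording oculomotor (saccade/fixation) feature table
#'
#' @param recordings list of [binocular_recording()] objects.
#' @return data.frame with the 32 `<descriptor>_<stat>` columns of
#'   [extract_features()], one row per recording.
#' @export
aideal_features <- function(recordings) {
  rows <- lapply(recordings, function(r)
    as.data.frame(t(unclass(extract_features(r)))))
  do.call(rbind, rows)
}

#' Assemble labelled feature matrices under a painting grouping scheme
#'
#' The three analyses differ only in how recordings are pooled across the
#' seven paintings: separately per painting, as the Op-Art group (paintings
#' 1-3) vs the complex-composition group (paintings 4-7), or all seven
#' combined. The painting identity itself is never a feature.
#'
#' @param manifest data.frame with `subject`, `label` (0/1), `painting`.
#' @param features data.frame of numeric features, rows aligned with
#'   `manifest`.
#' @param scheme `"per_painting"`, `"groups"` or `"combined"`.
#' @return Named list of datasets, each a list with `x` (numeric matrix),
#'   `y` (0/1 integer), `painting` (integer vector).
#' @export
assemble <- function(manifest, features,
                     scheme = c("combined", "groups", "per_painting")) {
  scheme <- match.arg(scheme)
  features <- as.data.frame(features)
  if (nrow(features) != nrow(manifest))
    stop("assembly error: ", nrow(manifest), " manifest rows but ",
         nrow(features), " feature rows", call. = FALSE)
  if (anyNA(features))
    stop("assembly error: missing feature values (recording row ",
         paste(which(rowSums(is.na(features)) > 0), collapse = ", "), ")",
         call. = FALSE)
  parts <- switch(scheme,
    per_painting = split(seq_len(nrow(manifest)), manifest$painting),
    groups = list(paintings_1_3 = which(manifest$painting %in% 1:3),
                  paintings_4_7 = which(manifest$painting %in% 4:7)),
    combined = list(combined = seq_len(nrow(manifest))))
  if (scheme == "per_painting")
    names(parts) <- paste0("painting_", names(parts))
  lapply(parts, function(i)
    list(x = as.matrix(features[i, , drop = FALSE]),
         y = as.integer(manifest$label[i]),
         painting = as.integer(manifest$painting[i])))
}

#' Classification metrics in percent
#'
#' Sensitivity is recall on the dyslexic (positive, 1) class; specificity is
#' recall on the control (0) class. A metric whose class is absent from the
#' truth is `NA`.
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return named numeric: `accuracy`, `sensitivity`, `specificity` (0-100).
#' @export
classification_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  c(accuracy = 100 * mean(truth == predicted),
    sensitivity = if (any(truth == 1))
      100 * mean(predicted[truth == 1] == 1) else NA_real_,
    specificity = if (any(truth == 0))
      100 * mean(predicted[truth == 0] == 0) else NA_real_)
}

scale_train_test <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sd <- sqrt(colMeans(sweep(xtr, 2, mu)^2))   # population sd of the train set
  sd[sd == 0] <- 1                             # inert feature stays inert
  list(tr = sweep(sweep(xtr, 2, mu), 2, sd, "/"),
       te = sweep(sweep(xte, 2, mu), 2, sd, "/"))
}

fit_model <- function(xtr, ytr, model) {
  if (model == "svm_rbf") {
    p <- ncol(xtr)
    g <- 1 / (p * mean(colMeans(sweep(xtr, 2, colMeans(xtr))^2)))
    e1071::svm(xtr, factor(ytr, levels = c(0, 1)), type = "C-classification",
               kernel = "radial", cost = 1, gamma = g, scale = FALSE)
  } else {
    x <- if (ncol(xtr) == 1L) cbind(xtr, 0) else xtr  # glmnet needs >= 2 cols
    glmnet::glmnet(x, ytr, family = "binomial", alpha = 0,
                   lambda = 1 / nrow(x), standardize = FALSE)
  }
}

predict_model <- function(fit, xte, model) {
  if (model == "svm_rbf")
    as.integer(as.character(predict(fit, xte)))
  else {
    x <- if (ncol(xte) == 1L) cbind(xte, 0) else xte
    as.integer(predict(fit, x, type = "class"))
  }
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      if (length(idx) < k)
        stop("stratification error: class ", cl, " has fewer than ", k,
             " rows", call. = FALSE)
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  fold
}

#' Stratified five-fold cross-validated classification
#'
#' At each fold the train and test sets are z-normalized by the training
#' set's mean and standard deviation (never the test set's), then one of two
#' pinned models is fitted: an RBF-kernel SVM (soft margin constant 1, kernel
#' width 1/(n_features x mean train-feature variance)) or an L2-regularized
#' logistic regression (unit penalty strength). No hyperparameter tuning is
#' performed.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels (1 = dyslexic).
#' @param model `"svm_rbf"` or `"logistic"`.
#' @param seed fold-assignment seed.
#' @param folds number of folds (default 5).
#' @param keep_fits keep per-fold fitted models and scalers (used by
#'   [feature_importance()]).
#' @return Object of class `cv_report`: list with `model`, `n`, `per_fold`
#'   (data.frame of fold metrics), `mean` (named metric means), `fold`
#'   (row assignments), and optionally `fits`.
#' @export
crossvalidate <- function(x, y, model = c("svm_rbf", "logistic"), seed = 42,
                          folds = 5L, keep_fits = FALSE) {
  model <- match.arg(model)
  x <- as.matrix(x); y <- as.integer(y)
  if (nrow(x) < 10) stop("need at least 10 rows", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  fold <- stratified_folds(y, folds, seed)
  per <- vector("list", folds)
  fits <- vector("list", folds)
  for (k in seq_len(folds)) {
    te <- which(fold == k); tr <- which(fold != k)
    sc <- scale_train_test(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    fit <- fit_model(sc$tr, y[tr], model)
    pred <- predict_model(fit, sc$te, model)
    per[[k]] <- c(fold = k, classification_metrics(y[te], pred))
    if (keep_fits) fits[[k]] <- list(fit = fit, test = te,
                                     mu = colMeans(x[tr, , drop = FALSE]),
                                     sd = {
                                       s <- sqrt(colMeans(sweep(x[tr, , drop = FALSE], 2,
                                                                colMeans(x[tr, , drop = FALSE]))^2))
                                       s[s == 0] <- 1; s
                                     })
  }
  per <- as.data.frame(do.call(rbind, per))
  structure(list(model = model, n = nrow(x), per_fold = per,
                 mean = colMeans(per[-1]), fold = fold,
                 fits = if (keep_fits) fits), class = "cv_report")
}

#' @method print cv_report
#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, n = %d, %d folds\n", x$model, x$n,
              nrow(x$per_fold)))
  cat(sprintf("  mean accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              x$mean["accuracy"], x$mean["sensitivity"],
              x$mean["specificity"]))
  invisible(x)
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Two-sided test of stochastic equality of two samples. `U` counts pairs
#' where an `x` value exceeds a `y` value (ties half-counted); `z` is signed
#' by the x-vs-y rank tendency, with the variance corrected for ties. No
#' continuity correction is applied.
#'
#' @param x,y numeric samples for the two groups.
#' @return list with `U`, `z`, `p`, and `degenerate` (TRUE when all pooled
#'   values are identical).
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  s2 <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (s2 <= 0)
    return(list(U = U, z = 0, p = 1, degenerate = TRUE))
  z <- (U - nx * ny / 2) / sqrt(s2)
  list(U = U, z = z, p = min(1, 2 * stats::pnorm(-abs(z))),
       degenerate = FALSE)
}

#' Permutation feature importance
#'
#' For each feature, its test-fold column is shuffled `n_shuffles` times and
#' the mean drop in held-out accuracy (percentage points, averaged over
#' folds and shuffles) is reported. Shared information between correlated
#' features lowers both their importances.
#'
#' @param x,y,model,seed as in [crossvalidate()].
#' @param n_shuffles permutations per feature.
#' @return named numeric vector of importances.
#' @export
feature_importance <- function(x, y, model = c("svm_rbf", "logistic"),
                               seed = 42, n_shuffles = 10L) {
  model <- match.arg(model)
  x <- as.matrix(x)
  cv <- crossvalidate(x, y, model, seed, keep_fits = TRUE)
  base <- cv$per_fold$accuracy
  imp <- numeric(ncol(x))
  with_seed(seed + 1L, {
    for (j in seq_len(ncol(x))) {
      drops <- numeric(0)
      for (k in seq_along(cv$fits)) {
        fk <- cv$fits[[k]]
        xte <- x[fk$test, , drop = FALSE]
        for (s in seq_len(n_shuffles)) {
          xp <- xte
          xp[, j] <- xp[sample.int(nrow(xp)), j]
          xs <- sweep(sweep(xp, 2, fk$mu), 2, fk$sd, "/")
          pred <- predict_model(fk$fit, xs, model)
          drops <- c(drops,
                     base[k] - classification_metrics(y[fk$test], pred)["accuracy"])
        }
      }
      imp[j] <- mean(drops)
    }
  })
  names(imp) <- colnames(x)
  imp
}

#' Fuse oculomotor and DGI feature sets and classify
#'
#' Column-concatenates the saccade/fixation descriptor summary and the DGI
#' feature table, assembles the combined (all paintings) dataset and runs
#' [crossvalidate()].
#'
#' @param manifest cohort manifest (see [assemble()]).
#' @param aideal data.frame of 32 descriptor summaries per recording.
#' @param dgi data.frame of DGI features per recording.
#' @param model,seed as in [crossvalidate()].
#' @return a `cv_report`.
#' @export
fuse_and_classify <- function(manifest, aideal, dgi,
                              model = c("svm_rbf", "logistic"), seed = 42) {
  model <- match.arg(model)
  fused <- cbind(as.data.frame(aideal), as.data.frame(dgi))
  ds <- assemble(manifest, fused, "combined")$combined
  crossvalidate(ds$x, ds$y, model, seed)
}
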