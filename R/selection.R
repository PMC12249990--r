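# Biomarker selection and evaluation: repeated-subsampling gradient-boosting
# importance ranking, cross-maneuver overlap, and leave-one-out
# cross-validated association models.

#' Configuration of the selection / evaluation procedure
#'
#' @param n_iterations Number of resampling iterations (study default
#'   1000).
#' @param subsample_fraction Fraction of subjects drawn (without
#'   replacement) per iteration.
#' @param top_k Number of top-ranked features retained per maneuver before
#'   the cross-maneuver overlap.
#' @param seed Base seed; iteration seeds are derived from it.
#' @param nrounds,max_depth,eta Gradient-boosting hyperparameters (trees,
#'   tree depth, learning rate).
#' @param min_mz Exclusion threshold: features with m/z below this value
#'   are never modelled.
#' @param max_redraws Maximum redraw attempts for degenerate (single-class)
#'   subsamples.
#' @param impute_max_iter,impute_ridge Chained-imputation rounds and ridge
#'   penalty (per-observation scale).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_iterations = 1000L,
                             subsample_fraction = 2 / 3,
                             top_k = 30L, seed = 1L,
                             nrounds = 200L, max_depth = 3L, eta = 0.1,
                             min_mz = 42, max_redraws = 100L,
                             impute_max_iter = 10L, impute_ridge = 1e-2) {
  stopifnot(n_iterations >= 1L, top_k >= 1L,
            subsample_fraction > 0, subsample_fraction < 1)
  structure(
    list(n_iterations = as.integer(n_iterations),
         subsample_fraction = subsample_fraction,
         top_k = as.integer(top_k), seed = as.integer(seed),
         nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
         eta = eta, min_mz = min_mz, max_redraws = as.integer(max_redraws),
         impute_max_iter = as.integer(impute_max_iter),
         impute_ridge = impute_ridge),
    class = "selection_config"
  )
}

#' Predictor exclusion rules
#'
#' Drops calibrant ions (within the extraction tolerance of each calibrant
#' m/z), the water-adduct phase tracer, the normalization reference ion,
#' and every feature with m/z below `min_mz` (default 42; the boundary
#' feature at 42.03 is retained).
#'
#' @param mz Numeric vector of feature m/z.
#' @param calibrants A [calibrant_set()].
#' @param water_adduct,reference_mz Tracer/reference ions to drop.
#' @param min_mz Lower m/z bound for predictors.
#' @return Logical vector: `TRUE` where the feature is kept.
#' @export
exclusion_filter <- function(mz, calibrants = calibrant_set(),
                             water_adduct = tracer_set()$water_adduct,
                             reference_mz = REFERENCE_ION_MZ,
                             min_mz = 42) {
  keep <- mz >= min_mz
  for (ion in c(calibrants, water_adduct, reference_mz)) {
    keep <- keep & abs(mz - ion) > extraction_half_width(ion)
  }
  keep
}

# Restrict a feature matrix to the allowed predictor set.
apply_exclusion <- function(fm, config = selection_config()) {
  keep <- exclusion_filter(fm$mz, min_mz = config$min_mz)
  feature_matrix(fm$values[, keep, drop = FALSE], fm$mz[keep], fm$maneuver,
                 subjects = fm$subjects, group = fm$group)
}

# Per-feature z-scoring fitted on (training) rows only.
zscore_fit <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  sd <- apply(X, 2L, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- 1
  mu[!is.finite(mu)] <- 0
  list(mu = mu, sd = sd)
}

zscore_apply <- function(X, fit) {
  sweep(sweep(X, 2L, fit$mu, "-"), 2L, fit$sd, "/")
}

#' Round-robin chained ridge imputation
#'
#' Missing entries are initialised at the column mean, then each incomplete
#' feature is regressed on all others with a ridge-penalised linear model
#' and its missing entries replaced by the predictions, cycling over
#' features until the imputed values move less than `tol` (in units of the
#' overall standard deviation) or `max_iter` rounds have run. Intended for
#' z-scored matrices inside a resampling iteration or training fold.
#'
#' @param X Numeric matrix with `NA` for missing entries.
#' @param max_iter Maximum rounds over all incomplete features.
#' @param ridge Ridge penalty per observation.
#' @param tol Convergence tolerance.
#' @return The completed matrix (unchanged when nothing is missing).
#' @export
impute_iterative <- function(X, max_iter = 10L, ridge = 1e-2, tol = 1e-3) {
  miss <- is.na(X)
  if (!any(miss)) return(X)
  if (any(colSums(!miss) == 0L)) {
    stop("cannot impute an all-missing column", call. = FALSE)
  }
  scale_ref <- stats::sd(X[!miss])
  if (!is.finite(scale_ref) || scale_ref == 0) scale_ref <- 1
  mu <- colMeans(X, na.rm = TRUE)
  filled <- X
  for (j in seq_len(ncol(X))) filled[miss[, j], j] <- mu[j]
  incomplete <- which(colSums(miss) > 0L)
  if (ncol(X) < 2L) return(filled)
  n <- nrow(X)
  for (round in seq_len(max_iter)) {
    delta <- 0
    for (j in incomplete) {
      obs <- !miss[, j]
      A <- cbind(1, filled[, -j, drop = FALSE])
      pen <- diag(c(0, rep(ridge * n, ncol(A) - 1L)))
      coef <- tryCatch(
        solve(crossprod(A[obs, , drop = FALSE]) + pen,
              crossprod(A[obs, , drop = FALSE], filled[obs, j])),
        error = function(e) NULL
      )
      if (is.null(coef)) next
      pred <- A[!obs, , drop = FALSE] %*% coef
      delta <- max(delta, max(abs(pred - filled[!obs, j])) / scale_ref)
      filled[!obs, j] <- pred
    }
    if (delta < tol) break
  }
  filled
}

# Gradient-boosted ensemble fit; objective chosen by endpoint type.
fit_gbm <- function(X, y, binary, config) {
  obj <- if (binary) "binary:logistic" else "reg:squarederror"
  d <- xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = 1)
  xgboost::xgb.train(
    params = list(objective = obj, max_depth = config$max_depth,
                  eta = config$eta, nthread = 1,
                  # exact greedy splits (midpoints between sorted values):
                  # cohorts are small, and histogram bin edges would place
                  # thresholds on observed class-edge values
                  tree_method = "exact"),
    data = d, nrounds = config$nrounds, verbose = 0
  )
}

# Total-gain importance as a full-length named vector (0 for unused
# features).
gain_importance <- function(model, feature_names) {
  out <- stats::setNames(numeric(length(feature_names)), feature_names)
  if (length(feature_names) == 1L) {
    # the gain share of a single-feature model is 1 by definition (and the
    # importance extractor chokes on one-feature models)
    out[1L] <- 1
    return(out)
  }
  imp <- xgboost::xgb.importance(model = model)
  if (!is.null(imp) && nrow(imp)) out[imp$Feature] <- imp$Gain
  out
}

# Coerce an endpoint vector: logical/2-level factor -> binary 0/1.
endpoint_type <- function(endpoint) {
  if (is.logical(endpoint)) {
    list(binary = TRUE, y = as.numeric(endpoint))
  } else if (is.character(endpoint) || is.factor(endpoint)) {
    f <- droplevels(factor(endpoint))
    if (nlevels(f) != 2L) stop("binary endpoint needs 2 levels", call. = FALSE)
    list(binary = TRUE, y = as.numeric(f) - 1, levels = levels(f))
  } else {
    list(binary = FALSE, y = as.numeric(endpoint))
  }
}

#' Resampled gradient-boosting importance ranking
#'
#' Repeats `n_iterations` times: draw `subsample_fraction` of the subjects
#' without replacement (redrawing degenerate single-class subsamples),
#' z-score and chained-ridge-impute the subsample, fit a gradient-boosted
#' ensemble (classifier for binary endpoints, regressor for quantitative
#' ones), and record per-feature total-gain importance. The final score per
#' feature is the median importance across iterations, ranked in descending
#' order; ties break by m/z. Fully reproducible from `config$seed`.
#'
#' @param fm A [feature_matrix()] (exclusion rules are applied internally).
#' @param endpoint Endpoint vector aligned with `fm$subjects` (logical or
#'   2-level factor for classification, numeric for regression).
#' @param config A [selection_config()].
#' @return A `selection_result` data frame with columns `mz`,
#'   `median_importance`, `rank`, `top_k`; the maneuver and number of
#'   redraws are carried as attributes.
#' @export
resample_importance <- function(fm, endpoint, config = selection_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  fm <- apply_exclusion(fm, config)
  et <- endpoint_type(endpoint)
  X <- fm$values
  n <- nrow(X)
  feat <- colnames(X)
  if (et$binary && length(unique(et$y)) < 2L) {
    stop("binary endpoint has a single class", call. = FALSE)
  }
  if (!et$binary && stats::sd(et$y) == 0) {
    stop("quantitative endpoint has zero variance", call. = FALSE)
  }
  m <- max(2L, floor(n * config$subsample_fraction))
  imp <- matrix(NA_real_, config$n_iterations, ncol(X),
                dimnames = list(NULL, feat))
  redraws <- 0L
  for (it in seq_len(config$n_iterations)) {
    idx <- NULL
    for (attempt in 0:config$max_redraws) {
      idx_try <- with_seed(config$seed + it + 100000L * attempt,
                           sample(n, m))
      if (!et$binary || length(unique(et$y[idx_try])) == 2L) {
        idx <- idx_try
        if (attempt > 0L) redraws <- redraws + attempt
        break
      }
    }
    if (is.null(idx)) stop("could not draw a two-class subsample",
                           call. = FALSE)
    Xs <- X[idx, , drop = FALSE]
    zf <- zscore_fit(Xs)
    Xs <- zscore_apply(Xs, zf)
    Xs <- impute_iterative(Xs, config$impute_max_iter, config$impute_ridge)
    model <- fit_gbm(Xs, et$y[idx], et$binary, config)
    imp[it, ] <- gain_importance(model, feat)
  }
  med <- apply(imp, 2L, stats::median)
  ord <- order(-med, fm$mz)
  res <- data.frame(mz = fm$mz, median_importance = unname(med))
  res$rank <- match(seq_len(ncol(X)), ord)
  res$top_k <- res$rank <= config$top_k
  res <- res[order(res$rank), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "maneuver") <- fm$maneuver
  attr(res, "redraws") <- redraws
  class(res) <- c("selection_result", "data.frame")
  res
}

#' Cross-maneuver overlap of top-ranked features
#'
#' Intersection of the two per-maneuver top-k lists, ordered by mean rank.
#' An empty intersection returns an empty set with a warning (the endpoint
#' is then unmodellable).
#'
#' @param ranking_quiet,ranking_forced `selection_result` objects over the
#'   same feature universe.
#' @param top_k Number of top features per maneuver to intersect.
#' @return Numeric vector of overlapping m/z, ordered by mean rank.
#' @export
select_overlap <- function(ranking_quiet, ranking_forced, top_k = 30L) {
  key <- function(r) sprintf("%.4f", r$mz[r$rank <= top_k])
  kq <- key(ranking_quiet); kf <- key(ranking_forced)
  common <- intersect(kq, kf)
  if (!length(common)) {
    warning("no overlapping features between maneuvers", call. = FALSE)
    return(numeric(0))
  }
  mean_rank <- vapply(common, function(k) {
    (ranking_quiet$rank[sprintf("%.4f", ranking_quiet$mz) == k] +
       ranking_forced$rank[sprintf("%.4f", ranking_forced$mz) == k]) / 2
  }, numeric(1))
  as.numeric(common[order(mean_rank, as.numeric(common))])
}

# Rank-statistic AUC over out-of-fold probabilities; ties share ranks.
auc_rank <- function(labels, scores) {
  ok <- !is.na(scores)
  labels <- labels[ok]; scores <- scores[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validated association model
#'
#' For each subject, the gradient-boosted model is trained on all other
#' subjects (z-scoring and chained imputation fitted inside the training
#' fold only; the held-out row is transformed with the training parameters
#' and its missing entries filled at the training mean) and the held-out
#' subject is predicted. Classifier performance is summarised by the AUC
#' over out-of-fold probabilities and by sensitivity, specificity, PPV and
#' NPV at a probability threshold of 0.5; regressors report the coefficient
#' of determination, maximal error, explained variance and RMSE.
#' Importances are finally recomputed on the full data restricted to the
#' overlap features.
#'
#' @param fm A [feature_matrix()].
#' @param endpoint Endpoint vector aligned with `fm$subjects`.
#' @param overlap_mz Features (m/z) to model, e.g. from
#'   [select_overlap()].
#' @param config A [selection_config()].
#' @param threshold Probability threshold for the confusion matrix.
#' @return An `eval_result` list: `out_of_fold` (one prediction per
#'   subject), `metrics`, `refit_importance`, `maneuver`,
#'   `skipped_folds`.
#' @export
loocv_evaluate <- function(fm, endpoint, overlap_mz,
                           config = selection_config(), threshold = 0.5) {
  stopifnot(inherits(fm, "feature_matrix"), length(overlap_mz) >= 1L)
  cols <- match(sprintf("%.4f", overlap_mz), colnames(fm$values))
  if (anyNA(cols)) stop("overlap features absent from matrix", call. = FALSE)
  X <- fm$values[, cols, drop = FALSE]
  et <- endpoint_type(endpoint)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 subjects for LOO-CV", call. = FALSE)
  pred <- rep(NA_real_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    ytr <- et$y[-i]
    if (et$binary && length(unique(ytr)) < 2L) {
      skipped <- c(skipped, i)
      next
    }
    Xtr <- X[-i, , drop = FALSE]
    zf <- zscore_fit(Xtr)
    Xtr <- impute_iterative(zscore_apply(Xtr, zf),
                            config$impute_max_iter, config$impute_ridge)
    model <- fit_gbm(Xtr, ytr, et$binary, config)
    xte <- zscore_apply(X[i, , drop = FALSE], zf)
    xte[is.na(xte)] <- 0  # training mean on the z scale
    pred[i] <- stats::predict(
      model, xgboost::xgb.DMatrix(xte, nthread = 1))
  }

  if (et$binary) {
    y <- et$y
    cls <- as.integer(pred >= threshold)
    tp <- sum(cls == 1 & y == 1, na.rm = TRUE)
    tn <- sum(cls == 0 & y == 0, na.rm = TRUE)
    fp <- sum(cls == 1 & y == 0, na.rm = TRUE)
    fn <- sum(cls == 0 & y == 1, na.rm = TRUE)
    metrics <- list(
      auc = auc_rank(y, pred),
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
      accuracy = (tp + tn) / sum(!is.na(pred))
    )
  } else {
    ok <- !is.na(pred)
    y <- et$y[ok]; p <- pred[ok]
    metrics <- list(
      r_squared = 1 - sum((y - p)^2) / sum((y - mean(y))^2),
      max_error = max(abs(y - p)),
      explained_variance = 1 - stats::var(y - p) / stats::var(y),
      rmse = sqrt(mean((y - p)^2))
    )
  }

  zf <- zscore_fit(X)
  Xfull <- impute_iterative(zscore_apply(X, zf),
                            config$impute_max_iter, config$impute_ridge)
  refit <- fit_gbm(Xfull, et$y, et$binary, config)
  structure(
    list(out_of_fold = pred, metrics = metrics,
         refit_importance = gain_importance(refit, colnames(X)),
         maneuver = fm$maneuver, skipped_folds = skipped,
         binary = et$binary),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  m <- x$metrics
  if (x$binary) {
    cat(sprintf(paste0("<eval_result> %s: AUC %.3f, sens %.3f, spec %.3f, ",
                       "PPV %.3f, NPV %.3f\n"),
                x$maneuver, m$auc, m$sensitivity, m$specificity, m$ppv,
                m$npv))
  } else {
    cat(sprintf("<eval_result> %s: R2 %.3f, RMSE %.3f, max err %.3f\n",
                x$maneuver, m$r_squared, m$rmse, m$max_error))
  }
  invisible(x)
}

#' End-to-end biomarker discovery for one endpoint
#'
#' Runs the resampled importance ranking independently on the quiet and
#' forced matrices, intersects the two top-k lists, and evaluates the
#' overlap set by leave-one-out cross-validation on each maneuver.
#'
#' @param quiet_fm,forced_fm [feature_matrix()] objects over the same
#'   consensus axis.
#' @param endpoint Endpoint vector aligned with the matrices' subjects
#'   (which must match).
#' @param config A [selection_config()].
#' @return A list with `ranking_quiet`, `ranking_forced`, `overlap`,
#'   `eval_quiet`, `eval_forced`.
#' @export
discover_biomarkers <- function(quiet_fm, forced_fm, endpoint,
                                config = selection_config()) {
  stopifnot(identical(quiet_fm$subjects, forced_fm$subjects))
  rq <- resample_importance(quiet_fm, endpoint, config)
  rf <- resample_importance(forced_fm, endpoint, config)
  overlap <- select_overlap(rq, rf, config$top_k)
  ev_q <- ev_f <- NULL
  if (length(overlap)) {
    ev_q <- loocv_evaluate(quiet_fm, endpoint, overlap, config)
    ev_f <- loocv_evaluate(forced_fm, endpoint, overlap, config)
  }
  list(ranking_quiet = rq, ranking_forced = rf, overlap = overlap,
       eval_quiet = ev_q, eval_forced = ev_f)
}
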