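#' Classification metrics from a confusion matrix
#' @param tp,tn,fp,fn non-negative integer counts (sum > 0).
#' @return list with `tp`, `tn`, `fp`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity` (the latter two `NA` when their denominator is 0).
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("all counts are zero; metrics undefined", call. = FALSE)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = (tp + tn) / sum(counts),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Fit an empirical per-parameter range filter
#'
#' For every parameter in `params` observed in the positive training
#' examples, the closed interval between the `limits[1]` and `limits[2]`
#' empirical quantiles (linear interpolation between order statistics, i.e.
#' `stats::quantile` type 7) becomes its admissible window. `overrides`
#' replace the window for named parameters with a strict upper bound
#' (value < bound); the default constrains the ppri-miRNA folding energy to
#' below -20 kcal/mol, removing unstable structures.
#'
#' By default windows cover the SVM-eligible parameters: ppri-miRNA-scoped
#' parameters (other than the MFE override) depend on how much flanking
#' sequence a record happens to carry, not on the candidate, and are removed
#' before both filtering and classification.
#'
#' @param positives data.frame of positive feature rows.
#' @param params parameters to window (default: SVM-eligible catalog
#'   parameters present in `positives`).
#' @param limits lower/upper quantile probabilities (default 0.1%/99.9%).
#' @param overrides named list: parameter -> strict upper bound.
#' @param catalog parameter catalog.
#' @return object of class `range_filter`: list with `windows` (data.frame
#'   `param`, `lo`, `hi`), `overrides`, `limits`.
#' @export
fit_range_filter <- function(positives, params = NULL,
                             limits = c(0.001, 0.999),
                             overrides = list(ppri_mfe = -20),
                             catalog = default_catalog()) {
  if (is.null(params))
    params <- intersect(svm_eligible_params(catalog), names(positives))
  params <- setdiff(params, names(overrides))
  wins <- lapply(params, function(p) {
    x <- positives[[p]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NULL)
    q <- stats::quantile(x, probs = limits, type = 7, names = FALSE)
    data.frame(param = p, lo = q[1], hi = q[2], stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, wins)
  rownames(windows) <- NULL
  structure(list(windows = windows, overrides = overrides, limits = limits),
            class = "range_filter")
}

#' @export
print.range_filter <- function(x, ...) {
  cat(sprintf("range_filter: %d windows at %.3g%%/%.3g%% + %d override(s)\n",
              nrow(x$windows), 100 * x$limits[1], 100 * x$limits[2],
              length(x$overrides)))
  invisible(x)
}

#' Apply a range filter to feature rows
#'
#' A row passes iff every windowed parameter lies inside its closed interval
#' and every override satisfies its strict upper bound. Undefined-feature
#' markers (`NA`, absent components) always pass: absence is legal.
#'
#' @param rf a [fit_range_filter()] result.
#' @param features data.frame of feature rows (or a single named list).
#' @return data.frame with logical `pass` and character `violations`
#'   (comma-separated parameter names, "" if none), one row per input row.
#' @export
apply_range_filter <- function(rf, features) {
  if (!is.data.frame(features)) features <- as.data.frame(features[
    sapply(features, function(v) length(v) == 1L)], stringsAsFactors = FALSE)
  n <- nrow(features)
  viol <- vector("list", n)
  for (k in seq_len(nrow(rf$windows))) {
    p <- rf$windows$param[k]
    if (!p %in% names(features)) next
    x <- features[[p]]
    bad <- !is.na(x) & (x < rf$windows$lo[k] | x > rf$windows$hi[k])
    for (i in which(bad)) viol[[i]] <- c(viol[[i]], p)
  }
  for (p in names(rf$overrides)) {
    if (!p %in% names(features)) next
    x <- features[[p]]
    bad <- !is.na(x) & x >= rf$overrides[[p]]
    for (i in which(bad)) viol[[i]] <- c(viol[[i]], p)
  }
  data.frame(pass = lengths(viol) == 0L,
             violations = vapply(viol, function(v)
               paste(v, collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}

#' Fit / apply a min-max feature scaler
#'
#' Training features are mapped linearly to `[-1, 1]` by their training
#' min/max (the standard preparation for RBF-SVM input). Undefined-feature
#' markers (`NA`) map to the component-absent value -1; constant parameters
#' map to 0. At prediction time out-of-range values are clipped to `[-1, 1]`
#' when `clip = TRUE` (gross outliers are already handled by the range
#' filter).
#'
#' @param data data.frame of training feature rows.
#' @param params parameters to scale.
#' @return `fit_scaler()`: object of class `feature_scaler`.
#' @export
fit_scaler <- function(data, params) {
  rng <- t(vapply(params, function(p) {
    x <- data[[p]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) c(0, 0) else range(x)
  }, numeric(2)))
  structure(list(params = params, min = rng[, 1], max = rng[, 2]),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a `feature_scaler`.
#' @param clip clip scaled values into `[-1, 1]`.
#' @return `apply_scaler()`: numeric matrix, one column per parameter.
#' @export
apply_scaler <- function(scaler, data, clip = FALSE) {
  out <- matrix(0, nrow(data), length(scaler$params),
                dimnames = list(NULL, scaler$params))
  for (k in seq_along(scaler$params)) {
    p <- scaler$params[k]
    x <- data[[p]]
    lo <- scaler$min[k]; hi <- scaler$max[k]
    y <- if (hi > lo) 2 * (x - lo) / (hi - lo) - 1 else rep(0, length(x))
    y[is.na(x)] <- -1
    if (clip) y <- pmin(1, pmax(-1, y))
    out[, k] <- y
  }
  out
}

#' @rdname fit_scaler
#' @param scaled numeric matrix produced by `apply_scaler()`.
#' @return `invert_scaler()`: data.frame of unscaled values (markers and
#'   constant parameters are not recoverable and come back as stored).
#' @export
invert_scaler <- function(scaler, scaled) {
  out <- as.data.frame(scaled)
  for (k in seq_along(scaler$params)) {
    lo <- scaler$min[k]; hi <- scaler$max[k]
    if (hi > lo) out[[k]] <- (scaled[, k] + 1) / 2 * (hi - lo) + lo
    else out[[k]] <- rep(lo, nrow(scaled))
  }
  names(out) <- scaler$params
  out
}

## ---- SVM internals --------------------------------------------------------

## Fit a libsvm RBF classifier and extract a self-contained representation:
## decision value f(x) = sign * (sum_i coef_i K(sv_i, x) - rho), arranged so
## that f > 0 predicts the positive class.
.svm_fit <- function(X, y, cost, gamma) {
  fit <- e1071::svm(x = X, y = y, scale = FALSE, kernel = "radial",
                    cost = cost, gamma = gamma)
  sv <- as.matrix(fit$SV)
  coefs <- as.numeric(fit$coefs)
  rho <- as.numeric(fit$rho)
  raw <- .rbf_decision(list(sv = sv, coefs = coefs, rho = rho,
                            gamma = gamma, sign = 1), X)
  pred <- fit$fitted
  agree <- mean((raw > 0) == (pred == "positive"))
  sgn <- if (agree >= 0.5) 1 else -1
  list(sv = sv, coefs = coefs, rho = rho, gamma = gamma, cost = cost,
       sign = sgn)
}

.rbf_decision <- function(model, X) {
  X <- as.matrix(X)
  sv <- model$sv
  d2 <- outer(rowSums(X^2), rowSums(sv^2), "+") - 2 * X %*% t(sv)
  d2[d2 < 0] <- 0
  K <- exp(-model$gamma * d2)
  model$sign * (as.vector(K %*% model$coefs) - model$rho)
}

.stratified_folds <- function(y, k) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > min(table(y)))
    stop("k exceeds the size of the smallest class", call. = FALSE)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.cv_accuracy <- function(X, y, k, cost, gamma, fold = NULL) {
  if (is.null(fold)) fold <- .stratified_folds(y, k)
  correct <- 0L
  for (f in seq_len(k)) {
    te <- fold == f
    m <- .svm_fit(X[!te, , drop = FALSE], y[!te], cost, gamma)
    dv <- .rbf_decision(m, X[te, , drop = FALSE])
    correct <- correct + sum((dv > 0) == (y[te] == "positive"))
  }
  correct / length(y)
}

#' Stratified k-fold cross-validation of the RBF classifier
#'
#' @param dataset a [assemble_level()] result or a data.frame with a `label`
#'   factor column.
#' @param params parameter names used as SVM input.
#' @param k number of folds (>= 2, at most the smallest class size).
#' @param cost,gamma RBF-SVM hyperparameters (`NULL` gamma = 1/#params, the
#'   libsvm default).
#' @return list with `folds` (data.frame of per-fold metrics), `mean_accuracy`
#'   and `pooled` metrics recomputed from summed confusion counts.
#' @export
cross_validate <- function(dataset, params, k = 5L, cost = 1, gamma = NULL) {
  dat <- if (inherits(dataset, "level_dataset")) dataset$data else dataset
  y <- dat$label
  if (nlevels(droplevels(y)) < 2L)
    stop("dataset must contain both classes", call. = FALSE)
  scaler <- fit_scaler(dat, params)
  X <- apply_scaler(scaler, dat)
  if (is.null(gamma)) gamma <- 1 / length(params)
  fold <- .stratified_folds(y, k)
  rows <- list()
  tot <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (f in seq_len(k)) {
    te <- fold == f
    m <- .svm_fit(X[!te, , drop = FALSE], y[!te], cost, gamma)
    dv <- .rbf_decision(m, X[te, , drop = FALSE])
    pos <- y[te] == "positive"
    tp <- sum(dv > 0 & pos); fn <- sum(dv <= 0 & pos)
    tn <- sum(dv <= 0 & !pos); fp <- sum(dv > 0 & !pos)
    mt <- compute_metrics(tp, tn, fp, fn)
    rows[[f]] <- data.frame(fold = f, tp = tp, tn = tn, fp = fp, fn = fn,
                            accuracy = mt$accuracy,
                            sensitivity = mt$sensitivity,
                            specificity = mt$specificity)
    tot <- tot + c(tp = tp, tn = tn, fp = fp, fn = fn)
  }
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean_accuracy = mean(folds$accuracy),
       pooled = compute_metrics(unname(tot["tp"]), unname(tot["tn"]),
                                unname(tot["fp"]), unname(tot["fn"])))
}

#' Train an RBF-SVM model bundle with grid search
#'
#' Features are scaled to `[-1, 1]` by training min/max, then `(C, gamma)`
#' are chosen by stratified `cv_folds`-fold cross-validated accuracy over the
#' libsvm-recommended grid `C in 2^(-5,-3,...,15)`, `gamma in
#' 2^(-15,-13,...,3)`; ties break to the smaller `C`, then smaller `gamma`.
#' The classifier is refit on the full dataset at the chosen point and stored
#' as a self-contained bundle (support vectors, coefficients, scaler, range
#' filter, backend id) so prediction needs no training data.
#'
#' @param dataset a [assemble_level()] result.
#' @param params selected parameter names (SVM-eligible catalog subset).
#' @param range_filter a fitted [fit_range_filter()] (stored in the bundle).
#' @param grid list with numeric vectors `cost` and `gamma`.
#' @param cv_folds folds for the grid search.
#' @param group group label stored in the bundle.
#' @param backend folding backend id pinned by the bundle.
#' @param catalog parameter catalog (version recorded).
#' @return object of class `model_bundle`.
#' @export
train_svm <- function(dataset, params, range_filter = NULL,
                      grid = list(cost = 2^seq(-5, 15, 2),
                                  gamma = 2^seq(-15, 3, 2)),
                      cv_folds = 5L, group = "overall", backend = "rnafold",
                      catalog = default_catalog()) {
  dat <- if (inherits(dataset, "level_dataset")) dataset$data else dataset
  y <- droplevels(dat$label)
  if (nlevels(y) < 2L)
    stop("dataset must contain both classes", call. = FALSE)
  y <- factor(as.character(y), levels = c("negative", "positive"))
  scaler <- fit_scaler(dat, params)
  X <- apply_scaler(scaler, dat)
  best <- list(acc = -Inf, cost = NA, gamma = NA)
  fold <- .stratified_folds(y, cv_folds)
  for (cost in sort(grid$cost)) {
    for (gamma in sort(grid$gamma)) {
      acc <- .cv_accuracy(X, y, cv_folds, cost, gamma, fold = fold)
      if (acc > best$acc + 1e-12) best <- list(acc = acc, cost = cost,
                                               gamma = gamma)
    }
  }
  svm <- .svm_fit(X, y, best$cost, best$gamma)
  structure(list(group = group,
                 level = if (inherits(dataset, "level_dataset"))
                   dataset$level else NA_integer_,
                 params = params, scaler = scaler,
                 range_filter = range_filter, svm = svm,
                 cv_accuracy = best$acc, cv_folds = cv_folds,
                 backend = backend,
                 catalog_version = attr(catalog, "version") %||% "custom"),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(
    "model_bundle: group=%s level=%s, %d params, C=%g gamma=%g (CV acc %.3f)\n",
    x$group, x$level, length(x$params), x$svm$cost, x$svm$gamma,
    x$cv_accuracy))
  cat("backend:", x$backend, " catalog:", x$catalog_version, "\n")
  invisible(x)
}

#' Decision values of a model bundle for feature rows
#' @param bundle a `model_bundle`.
#' @param features data.frame of feature rows.
#' @return numeric decision values; > 0 predicts a true miRNA placement.
#' @export
decision_values <- function(bundle, features) {
  X <- apply_scaler(bundle$scaler, features, clip = TRUE)
  .rbf_decision(bundle$svm, X)
}

#' Serialize / deserialize a model bundle
#'
#' Bundles are written as lossless JSON text (no binary artifacts), so a
#' bundle file is a portable, self-contained classifier.
#'
#' @param bundle a `model_bundle`.
#' @param path file path.
#' @return `read_model_bundle()` returns the bundle.
#' @export
write_model_bundle <- function(bundle, path) {
  writeLines(jsonlite::serializeJSON(unclass(bundle), digits = I(17)), path)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  class(obj$scaler) <- "feature_scaler"
  if (!is.null(obj$range_filter)) class(obj$range_filter) <- "range_filter"
  structure(obj, class = "model_bundle")
}

#' Greedy beam-search selection of a discriminative parameter chain
#'
#' Stage 1 scores every single parameter by the mean cross-validated SVM
#' accuracy over three positive/negative dataset pairings and keeps the
#' `beam` best as seeds. Each following stage extends every kept chain by
#' every unused parameter, rescores, and keeps the `beam` best chains of the
#' new length, until the pool is exhausted (or `max_len` is reached). The
#' accuracy-versus-length curve is returned together with the chain at the
#' argmax length; the curve is reported, never assumed monotone. Ties at the
#' beam boundary break lexicographically, making the search deterministic
#' under a fixed RNG state.
#'
#' @param pos_sets,neg_sets lists of (ideally 3) data.frames of positive and
#'   negative feature rows; pairing `i` uses `pos_sets[[i]]` with
#'   `neg_sets[[i]]`.
#' @param pool candidate parameter names (SVM-eligible).
#' @param beam beam width (default 10).
#' @param max_len optional cap on chain length (default: pool size).
#' @param cv_folds folds used for chain scoring.
#' @param cost fixed SVM cost during the search (the final model is
#'   re-grid-searched separately).
#' @return list with `curve` (data.frame `length`, `accuracy`), `best_chain`,
#'   `best_length`, and `chains` (kept chains per length).
#' @export
greedy_parameter_selection <- function(pos_sets, neg_sets, pool, beam = 10L,
                                       max_len = NULL, cv_folds = 5L,
                                       cost = 1) {
  stopifnot(length(pos_sets) == length(neg_sets), length(pool) >= 2L)
  max_len <- min(max_len %||% length(pool), length(pool))
  pairings <- lapply(seq_along(pos_sets), function(i) {
    pos <- pos_sets[[i]]; neg <- neg_sets[[i]]
    pos$label <- "positive"; neg$label <- "negative"
    keep <- c(pool, "label")
    dat <- rbind(pos[, keep, drop = FALSE], neg[, keep, drop = FALSE])
    dat$label <- factor(dat$label, levels = c("negative", "positive"))
    dat
  })
  ## fix fold assignments once per pairing so chain scores are comparable
  folds <- lapply(pairings, function(d) .stratified_folds(d$label, cv_folds))
  score_chain <- function(chain) {
    mean(vapply(seq_along(pairings), function(i) {
      dat <- pairings[[i]]
      scaler <- fit_scaler(dat, chain)
      X <- apply_scaler(scaler, dat)
      y <- dat$label
      gamma <- 1 / length(chain)
      correct <- 0L
      for (f in seq_len(cv_folds)) {
        te <- folds[[i]] == f
        m <- .svm_fit(X[!te, , drop = FALSE], y[!te], cost, gamma)
        dv <- .rbf_decision(m, X[te, , drop = FALSE])
        correct <- correct + sum((dv > 0) == (y[te] == "positive"))
      }
      correct / length(y)
    }, numeric(1)))
  }
  order_beam <- function(chains, scores) {
    key <- vapply(chains, paste, character(1), collapse = "\r")
    ord <- order(-scores, key)
    ord[seq_len(min(beam, length(ord)))]
  }
  chains <- as.list(pool)
  scores <- vapply(chains, score_chain, numeric(1))
  keep <- order_beam(chains, scores)
  chains <- chains[keep]; scores <- scores[keep]
  curve <- data.frame(length = 1L, accuracy = max(scores))
  kept_by_len <- list(list(chains = chains, scores = scores))
  len <- 1L
  while (len < max_len) {
    cand_chains <- list()
    for (ch in chains) {
      for (p in setdiff(pool, ch))
        cand_chains[[length(cand_chains) + 1L]] <- c(ch, p)
    }
    ## drop duplicate parameter sets that arise from different orders? No:
    ## chains are ordered objects; score depends only on the set, so cache.
    set_key <- vapply(cand_chains, function(ch)
      paste(sort(ch), collapse = "\r"), character(1))
    uniq <- !duplicated(set_key)
    uniq_scores <- vapply(cand_chains[uniq], score_chain, numeric(1))
    cand_scores <- uniq_scores[match(set_key, set_key[uniq])]
    keep <- order_beam(cand_chains, cand_scores)
    chains <- cand_chains[keep]; scores <- cand_scores[keep]
    len <- len + 1L
    curve <- rbind(curve, data.frame(length = len, accuracy = max(scores)))
    kept_by_len[[len]] <- list(chains = chains, scores = scores)
  }
  best_len <- curve$length[which.max(curve$accuracy)]
  best <- kept_by_len[[best_len]]
  list(curve = curve,
       best_chain = best$chains[[which.max(best$scores)]],
       best_length = best_len,
       chains = kept_by_len)
}
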