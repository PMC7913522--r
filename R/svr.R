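# Quality model: epsilon-SVR with RBF kernel on the concatenated pooled
# features ("training B"). The dual problem is solved by libsvm via e1071
# with a tight KKT tolerance; prediction evaluates the kernel expansion
# f(x) = sum_n t_n c(x_n, x) + b directly from the stored coefficients.

#' Extract concatenated pooled features from a fusion network
#'
#' Runs every image of a dataset through the fusion and collects the
#' concatenated global-average-pooled feature vectors, one row per image.
#' A per-dimension min--max scaler is fitted on these rows (train time) or
#' reused (test time, by passing the training scaler): RBF-SVR needs
#' comparable feature scales, and freezing the scaler at train time avoids
#' test-set leakage.
#'
#' @param net A `fusion_network`.
#' @param ds An `mriqa_dataset`.
#' @param scaler A scaler from a previous (training) call, or `NULL` to fit
#'   one on these rows.
#' @return A `feature_matrix`: list with `rows` (raw features), `ids`, and
#'   `scaler` (`min`, `range` per dimension).
#' @export
extract_features <- function(net, ds, scaler = NULL) {
  out <- forward(net, ds)
  rows <- out$features
  if (any(!is.finite(rows))) stop_mriqa("non-finite features extracted")
  if (is.null(scaler)) scaler <- fit_minmax_scaler(rows)
  structure(list(rows = rows, ids = rownames(rows), scaler = scaler),
            class = "feature_matrix")
}

fit_minmax_scaler <- function(rows) {
  mn <- apply(rows, 2L, min)
  rg <- apply(rows, 2L, max) - mn
  rg[rg == 0] <- 1  # constant columns map to 0
  list(min = mn, range = rg)
}

apply_minmax_scaler <- function(scaler, rows) {
  sweep(sweep(rows, 2L, scaler$min, "-"), 2L, scaler$range, "/")
}

scaled_rows <- function(x) {
  if (inherits(x, "feature_matrix")) apply_minmax_scaler(x$scaler, x$rows)
  else stop_mriqa("expected a feature_matrix")
}

#' Radial basis function kernel
#'
#' `c(a, b) = exp(-gamma * ||a - b||^2)` with the Euclidean norm; the value
#' lies in (0, 1] and equals 1 iff `a == b`. `gamma` is the precision
#' parameter of the kernel.
#'
#' @param a,b Numeric vectors of equal length.
#' @param gamma Positive precision parameter.
#' @return Kernel value.
#' @export
rbf_kernel <- function(a, b, gamma) {
  if (length(a) != length(b)) stop_mriqa("`a` and `b` must have equal length")
  if (gamma <= 0) stop_mriqa("`gamma` must be > 0")
  exp(-gamma * sum((a - b)^2))
}

# Cross-kernel matrix between row sets (n x d, m x d) -> n x m.
rbf_cross <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit an epsilon-SVR quality model
#'
#' Solves the epsilon-insensitive support vector regression with RBF kernel
#' for the given features and subjective scores. The dual solution
#' satisfies \eqn{\sum_n t_n = 0} and \eqn{|t_n| \le C}; training points
#' strictly inside the epsilon tube have \eqn{t_n = 0}.
#'
#' @param X A `feature_matrix` (its stored min--max scaler is applied and
#'   kept in the model) or a plain numeric matrix (`scale = TRUE` fits a
#'   scaler on it; `scale = FALSE` uses the rows as given).
#' @param qs Subjective scores, one per row.
#' @param C Box constraint (> 0).
#' @param gamma RBF precision parameter (> 0).
#' @param epsilon Insensitive-tube half width (>= 0).
#' @param scale For plain-matrix `X`: min--max scale the rows first?
#' @param tolerance KKT termination tolerance of the dual solver.
#' @return An `svr_model` with coefficients `t_n` (full length, zeros off
#'   the support), support vectors, bias `b`, hyperparameters, and the
#'   scaler.
#' @export
svr_fit <- function(X, qs, C = 1, gamma = NULL, epsilon = 0.1,
                    scale = TRUE, tolerance = 1e-7) {
  if (C <= 0 || epsilon < 0) stop_mriqa("need C > 0 and epsilon >= 0")
  if (inherits(X, "feature_matrix")) {
    scaler <- X$scaler
    rows <- apply_minmax_scaler(scaler, X$rows)
  } else {
    rows <- as.matrix(X)
    scaler <- if (scale) fit_minmax_scaler(rows) else NULL
    if (scale) rows <- apply_minmax_scaler(scaler, rows)
  }
  if (nrow(rows) < 2L) stop_mriqa("need at least 2 training rows")
  if (length(qs) != nrow(rows)) stop_mriqa("`qs` length must match rows of `X`")
  if (is.null(gamma)) gamma <- 1 / ncol(rows)
  if (gamma <= 0) stop_mriqa("`gamma` must be > 0")
  fit <- e1071::svm(rows, qs, type = "eps-regression", kernel = "radial",
                    cost = C, gamma = gamma, epsilon = epsilon,
                    scale = FALSE, tolerance = tolerance, fitted = FALSE)
  coef_full <- numeric(nrow(rows))
  coef_full[fit$index] <- fit$coefs
  structure(list(C = C, gamma = gamma, epsilon = epsilon,
                 coefficients = coef_full,
                 support_index = fit$index,
                 support_vectors = rows[fit$index, , drop = FALSE],
                 bias = -fit$rho, scaler = scaler,
                 n_train = nrow(rows)),
            class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("<svr_model> C=%g gamma=%g epsilon=%g; %d/%d support vectors, bias %.4g\n",
              x$C, x$gamma, x$epsilon, length(x$support_index), x$n_train, x$bias))
  invisible(x)
}

#' Predict quality with an epsilon-SVR model
#'
#' Evaluates the kernel expansion
#' \eqn{f(x) = \sum_n t_n c(x_n, x) + b} row-wise.
#'
#' @param model An `svr_model`.
#' @param x A `feature_matrix`, a numeric matrix (rows are observations on
#'   the raw feature scale if the model holds a scaler), or a single
#'   vector.
#' @return Numeric prediction(s).
#' @export
svr_predict <- function(model, x) {
  if (inherits(x, "feature_matrix")) x <- x$rows
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$support_vectors) &&
      nrow(model$support_vectors) > 0L)
    stop_mriqa("feature dimension mismatch: model expects ",
               ncol(model$support_vectors), ", got ", ncol(x))
  if (!is.null(model$scaler)) x <- apply_minmax_scaler(model$scaler, x)
  if (!nrow(model$support_vectors))
    return(rep(model$bias, nrow(x)))
  K <- rbf_cross(x, model$support_vectors, model$gamma)
  as.numeric(K %*% model$coefficients[model$support_index] + model$bias)
}

# Dual objective of the epsilon-SVR at coefficient vector t (maximized):
#   -1/2 t'Kt - epsilon * sum|t| + q't .
# Exposed for solver-equivalence checks.
svr_dual_objective <- function(K, qs, t, epsilon) {
  -0.5 * as.numeric(t %*% K %*% t) - epsilon * sum(abs(t)) + sum(qs * t)
}

#' Save or load an SVR quality model
#'
#' Single-file JSON archive with a versioned schema holding the scaler,
#' hyperparameters, support vectors, coefficients, and bias.
#'
#' @param model An `svr_model`.
#' @param path Path to the `.json` archive.
#' @return `save_svr_model` returns `path` invisibly; `load_svr_model` the
#'   restored `svr_model`.
#' @export
save_svr_model <- function(model, path) {
  obj <- unclass(model)
  obj$schema <- "mriqa-svr-1"
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_svr_model
#' @export
load_svr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "mriqa-svr-1"))
    stop_mriqa("not an mriqa SVR archive: ", path)
  obj$schema <- NULL
  obj$support_vectors <- as.matrix(obj$support_vectors)
  if (!is.null(obj$scaler))
    obj$scaler <- list(min = as.numeric(obj$scaler$min),
                       range = as.numeric(obj$scaler$range))
  structure(obj, class = "svr_model")
}

#' Hyperparameter grids for the SVR quality model
#'
#' `"full"` is a wide log-spaced search grid (C in 2^(-3..9), gamma in
#' 2^(-15..3), epsilon in {0.01, 0.1, 0.5}); `"compact"` is the reduced
#' grid used by the desk-scale evaluation protocol.
#'
#' @param kind `"compact"` or `"full"`.
#' @return List with numeric vectors `C`, `gamma`, `epsilon`.
#' @export
svr_grid <- function(kind = c("compact", "full")) {
  kind <- match.arg(kind)
  if (kind == "full")
    list(C = 2^seq(-3, 9, by = 2), gamma = 2^seq(-15, 3, by = 2),
         epsilon = c(0.01, 0.1, 0.5))
  else
    list(C = 2^c(-1, 1, 3, 5), gamma = 2^c(-9, -7, -5, -3, -1),
         epsilon = c(0.01, 0.1))
}

#' Select SVR hyperparameters by cross-validated rank correlation
#'
#' Grid search maximizing the mean Spearman correlation between
#' cross-validation predictions and subjective scores on the training data
#' only. Ties are broken towards smaller `C`, then smaller `gamma`, then
#' smaller `epsilon`.
#'
#' @param X A `feature_matrix` or numeric matrix (training rows).
#' @param qs Subjective scores.
#' @param grid List with vectors `C`, `gamma`, `epsilon` (see [svr_grid()]).
#' @param folds Number of CV folds (`>= 2`, `<=` number of rows).
#' @param seed Seed for the fold assignment.
#' @return List with the selected `C`, `gamma`, `epsilon`, and the CV table.
#' @export
select_hyperparams <- function(X, qs, grid = svr_grid(), folds = 5L, seed = 1L) {
  rows <- if (inherits(X, "feature_matrix")) X$rows else as.matrix(X)
  n <- nrow(rows)
  if (folds < 2L) stop_mriqa("`folds` must be >= 2")
  if (n < folds) stop_mriqa("need at least as many rows as folds")
  if (!length(grid$C) || !length(grid$gamma) || !length(grid$epsilon))
    stop_mriqa("`grid` must be non-empty")
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  cand <- expand.grid(C = grid$C, gamma = grid$gamma, epsilon = grid$epsilon,
                      KEEP.OUT.ATTRS = FALSE)
  score <- numeric(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    rho <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- svr_fit(rows[tr, , drop = FALSE], qs[tr], C = cand$C[k],
                   gamma = cand$gamma[k], epsilon = cand$epsilon[k],
                   scale = TRUE, tolerance = 1e-3)
      pr <- svr_predict(m, rows[!tr, , drop = FALSE])
      rho[f] <- tryCatch(srcc(pr, qs[!tr]), error = function(e) 0)
    }
    score[k] <- mean(rho)
  }
  ord <- order(-score, cand$C, cand$gamma, cand$epsilon)
  best <- ord[1L]
  list(C = cand$C[best], gamma = cand$gamma[best], epsilon = cand$epsilon[best],
       cv = cbind(cand, srcc = score))
}
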