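# The four IQA performance criteria. SRCC and KRCC operate on raw
# objective scores; PLCC and RMSE are computed after the five-parameter
# logistic mapping between objective and subjective scores.

check_pair <- function(x, y, min_len = 2L) {
  if (length(x) != length(y)) stop_mriqa("score vectors must have equal length")
  if (length(x) < min_len)
    stop_mriqa("need at least ", min_len, " score pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_mriqa("scores must be finite")
}

#' Spearman rank-order correlation coefficient
#'
#' Tie-free data uses the classical formula
#' \eqn{1 - 6\sum_i d_i^2 / (m(m^2-1))} on rank differences `d_i`; with
#' ties it falls back to the Pearson correlation of average ranks (the
#' standard generalization).
#'
#' @param qo,qs Equal-length score vectors (`m >= 3`).
#' @return Value in `[-1, 1]`.
#' @export
srcc <- function(qo, qs) {
  check_pair(qo, qs, 3L)
  rx <- rank(qo); ry <- rank(qs)
  if (anyDuplicated(qo) || anyDuplicated(qs)) {
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
      stop_mriqa("SRCC undefined for constant scores")
    return(stats::cor(rx, ry))
  }
  m <- length(qo)
  1 - 6 * sum((rx - ry)^2) / (m * (m^2 - 1))
}

#' Kendall rank-order correlation coefficient
#'
#' Exhaustive pair enumeration:
#' \eqn{(m_c - m_d) / (0.5\,m(m-1))} with `m_c` concordant and `m_d`
#' discordant pairs; tied pairs count as neither while the denominator
#' keeps all pairs (the tau-a convention; note this differs from tau-b on
#' tied data).
#'
#' @param qo,qs Equal-length score vectors (`m >= 2`).
#' @return Value in `[-1, 1]`.
#' @export
krcc <- function(qo, qs) {
  check_pair(qo, qs, 2L)
  s1 <- sign(outer(qo, qo, "-"))
  s2 <- sign(outer(qs, qs, "-"))
  prod_sign <- s1 * s2
  m <- length(qo)
  mc <- sum(prod_sign[upper.tri(prod_sign)] > 0)
  md <- sum(prod_sign[upper.tri(prod_sign)] < 0)
  (mc - md) / (0.5 * m * (m - 1))
}

#' Pearson linear correlation coefficient
#'
#' Computed on mean-removed vectors:
#' \eqn{\bar{Q}_o^T \bar{Q}_s / \sqrt{(\bar{Q}_o^T\bar{Q}_o)(\bar{Q}_s^T\bar{Q}_s)}}.
#' Conventionally applied to logistically mapped objective scores; errors
#' on constant input, for which the correlation is undefined.
#'
#' @param qo_mapped,qs Equal-length score vectors (`m >= 3`).
#' @return Value in `[-1, 1]`.
#' @export
plcc <- function(qo_mapped, qs) {
  check_pair(qo_mapped, qs, 3L)
  a <- qo_mapped - mean(qo_mapped)
  b <- qs - mean(qs)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) stop_mriqa("PLCC undefined for constant scores")
  sum(a * b) / den
}

#' Root mean square error
#'
#' \eqn{\sqrt{(Q_o - Q_s)^T(Q_o - Q_s)/m}}, conventionally applied to
#' logistically mapped objective scores.
#'
#' @param qo_mapped,qs Equal-length score vectors (`m >= 1`).
#' @return Non-negative scalar.
#' @export
rmse <- function(qo_mapped, qs) {
  check_pair(qo_mapped, qs, 1L)
  sqrt(mean((qo_mapped - qs)^2))
}

logistic5 <- function(beta, qo) {
  beta[1] * (0.5 - 1 / (1 + exp(beta[2] * (qo - beta[3])))) +
    beta[4] * qo + beta[5]
}

#' Fit the five-parameter logistic mapping
#'
#' Fits \eqn{Q_o' = \beta_1(\tfrac12 - 1/(1+\exp(\beta_2(Q_o-\beta_3)))) +
#' \beta_4 Q_o + \beta_5} to the (objective, subjective) score pairs by
#' Levenberg--Marquardt nonlinear least squares, initialized at
#' `beta = (range(qs), 1/sd(qo), mean(qo), 1, 0)`. The family contains the
#' identity (`beta = (0, 1, mean(qo), 1, 0)`), which is returned whenever
#' the optimizer fails or does not improve on it, so the mapping never
#' degrades the raw scores.
#'
#' @param qo Objective scores (length `>= 5`, not constant).
#' @param qs Subjective scores.
#' @return A `logistic_fit`: list with `beta` (length 5) and `converged`
#'   (`FALSE` when the identity fallback was used).
#' @export
fit_logistic_mapping <- function(qo, qs) {
  check_pair(qo, qs, 5L)
  if (stats::sd(qo) == 0)
    stop_mriqa("logistic mapping undefined for constant objective scores")
  identity_beta <- c(0, 1, mean(qo), 1, 0)
  ss_id <- sum((qo - qs)^2)
  if (ss_id < 1e-12)  # already a perfect identity fit; nothing to optimize
    return(structure(list(beta = identity_beta, converged = TRUE),
                     class = "logistic_fit"))
  start <- list(b1 = diff(range(qs)), b2 = 1 / stats::sd(qo),
                b3 = mean(qo), b4 = 1, b5 = 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      qs ~ b1 * (0.5 - 1 / (1 + exp(b2 * (qo - b3)))) + b4 * qo + b5,
      start = start, data = data.frame(qo = qo, qs = qs),
      control = minpack.lm::nls.lm.control(maxiter = 1000)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    warning("logistic mapping did not converge; using identity mapping",
            call. = FALSE)
    return(structure(list(beta = identity_beta, converged = FALSE),
                     class = "logistic_fit"))
  }
  beta <- unname(stats::coef(fit))
  ss_fit <- sum((logistic5(beta, qo) - qs)^2)
  if (!all(is.finite(beta)) || ss_fit > ss_id)
    return(structure(list(beta = identity_beta, converged = FALSE),
                     class = "logistic_fit"))
  structure(list(beta = beta, converged = TRUE), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> beta = (%s)%s\n",
              paste(signif(x$beta, 4), collapse = ", "),
              if (x$converged) "" else " [identity fallback]"))
  invisible(x)
}

#' Apply a fitted logistic mapping
#'
#' Element-wise evaluation of the five-parameter function at the given
#' objective scores.
#'
#' @param fit A `logistic_fit` (or a numeric vector of five betas).
#' @param qo Objective scores.
#' @return Mapped scores, same length as `qo`.
#' @export
apply_mapping <- function(fit, qo) {
  beta <- if (inherits(fit, "logistic_fit")) fit$beta else fit
  if (length(beta) != 5L || any(!is.finite(beta)))
    stop_mriqa("`fit` must hold five finite parameters")
  logistic5(beta, qo)
}
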