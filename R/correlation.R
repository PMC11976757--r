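#' Quantile by linear interpolation at (n-1)q
#'
#' The quantile convention used throughout the cohort summaries: sort the
#' values and linearly interpolate at position `(n-1)*q` (0-based), i.e.
#' type 7 in [stats::quantile()]. This is the convention under which the
#' cohort medians and interquartile ranges of the packaged reference table
#' reproduce their published roundings.
#'
#' @param x Nonempty numeric vector (NA not allowed).
#' @param q Probabilities in `[0, 1]`.
#' @return Quantile value(s), unnamed.
#' @export
cohort_quantile <- function(x, q) {
  if (length(x) == 0 || anyNA(x))
    stop("quantile needs a nonempty vector without missing values",
         call. = FALSE)
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  unname(stats::quantile(x, q, type = 7))
}

mid_ranks <- function(x) rank(x, ties.method = "average")

new_correlation_result <- function(rho, p, n, covariates = character(0),
                                   method = "spearman") {
  structure(list(rho = rho, p_value = p, n = n, covariates = covariates,
                 method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  adj <- if (length(x$covariates))
    paste0(" adjusted for ", paste(x$covariates, collapse = ", ")) else ""
  cat(sprintf("Spearman rho = %s (n = %d, p = %s)%s\n",
              if (is.na(x$rho)) "undefined" else sprintf("%.4f", x$rho),
              x$n,
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 3),
              adj))
  invisible(x)
}

t_approx_p <- function(rho, df) {
  if (is.na(rho) || df < 1) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(-abs(tval), df)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midrank-transformed data, with a p-value from the
#' t approximation on `n - 2` degrees of freedom. Ties receive average
#' ranks. If either variable has zero rank variance the correlation is
#' undefined and returned as `NA`.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return A `correlation_result` with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  rx <- mid_ranks(x)
  ry <- mid_ranks(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(new_correlation_result(NA_real_, NA_real_, n))
  rho <- stats::cor(rx, ry)
  new_correlation_result(rho, t_approx_p(rho, n - 2), n)
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms every variable (midranks), residualizes the ranked `x`
#' and ranked `y` on the ranked covariates by least squares with an
#' intercept, and returns the Pearson correlation of the residuals. The
#' p-value uses the t approximation on `n - k - 2` degrees of freedom for
#' `k` covariates. With no covariates this is exactly [spearman_cor()].
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates `NULL`, a numeric vector, or a matrix/data frame of
#'   covariate columns (same length as `x`).
#' @return A `correlation_result` carrying the covariate names.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      (is.data.frame(covariates) && ncol(covariates) == 0))
    return(spearman_cor(x, y))
  Z <- as.matrix(covariates)
  n <- length(x)
  if (length(y) != n || nrow(Z) != n)
    stop("x, y and covariates must have equal length", call. = FALSE)
  k <- ncol(Z)
  if (n < k + 3)
    stop("need at least covariates + 3 observations", call. = FALSE)
  cn <- colnames(Z)
  if (is.null(cn)) cn <- paste0("z", seq_len(k))
  RZ <- cbind(1, apply(Z, 2, mid_ranks))
  qrz <- qr(RZ)
  if (qrz$rank < ncol(RZ))
    stop("rank-deficiency error: covariates are collinear after ranking",
         call. = FALSE)
  rx <- qr.resid(qrz, mid_ranks(x))
  ry <- qr.resid(qrz, mid_ranks(y))
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(new_correlation_result(NA_real_, NA_real_, n, cn))
  rho <- stats::cor(rx, ry)
  new_correlation_result(rho, t_approx_p(rho, n - k - 2), n, cn)
}
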