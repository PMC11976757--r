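#' Cohort-level summary of lesion and steal volumetrics
#'
#' Computes the statistics the cohort stage reports from a per-subject
#' table: median and interquartile range of the infarct lesion volume and
#' of the affected-territory steal volume; per-subject coverage percentages
#' (percent of the lesion covered by steal and percent of steal volume
#' inside the lesion) with their medians and IQRs; mean and SD of the
#' in-lesion CVR; the Spearman correlation between lesion volume and
#' extra-lesional steal volume, both unadjusted and (when
#' `groin_to_mr_hours` and `nihss_admission` are available) adjusted for
#' those covariates; and, when `nihss_discharge` is present, a
#' proportional-odds model of discharge NIHSS on extra-lesional steal,
#' unadjusted and adjusted for lesion volume, age and admission NIHSS,
#' with a Brant-Wald check where the outcome has at least three categories.
#'
#' All quantiles use [cohort_quantile()] (linear interpolation at
#' `(n-1)q`). Percentages with a zero denominator are undefined and are
#' dropped from their summaries.
#'
#' @param records Cohort data frame, as from [load_cohort_table()] or
#'   [synthesize_cohort()].
#' @return Object of class `cohort_summary`.
#' @export
cohort_summary <- function(records) {
  if (nrow(records) == 0) stop("empty cohort", call. = FALSE)
  q3 <- function(x) {
    x <- x[!is.na(x)]
    stats::setNames(cohort_quantile(x, c(0.5, 0.25, 0.75)),
                    c("median", "q1", "q3"))
  }
  pct_in <- ifelse(records$steal_aca_mca_ml > 0,
                   100 * records$steal_in_lesion_ml /
                     records$steal_aca_mca_ml, NA_real_)
  pct_cov <- ifelse(records$lesion_ml > 0,
                    100 * records$steal_in_lesion_ml / records$lesion_ml,
                    NA_real_)
  out <- list(
    n = nrow(records),
    lesion_ml = q3(records$lesion_ml),
    steal_aca_mca_ml = q3(records$steal_aca_mca_ml),
    pct_steal_in_lesion = q3(pct_in),
    pct_lesion_covered = q3(pct_cov),
    cvr_in_lesion = if ("cvr_lesion_mean" %in% names(records))
      c(mean = mean(records$cvr_lesion_mean),
        sd = stats::sd(records$cvr_lesion_mean)) else NULL,
    spearman_unadjusted = spearman_cor(records$lesion_ml,
                                       records$steal_outside_ml))
  maybe <- function(expr) tryCatch(expr, error = function(e) NULL)
  if (all(c("groin_to_mr_hours", "nihss_admission") %in% names(records)))
    out$spearman_adjusted <- maybe(partial_spearman(
      records$lesion_ml, records$steal_outside_ml,
      records[, c("groin_to_mr_hours", "nihss_admission")]))
  if ("nihss_discharge" %in% names(records) &&
      length(unique(records$nihss_discharge)) >= 2) {
    out$ordinal_unadjusted <- maybe(fit_ordinal(
      records$nihss_discharge,
      records[, "steal_outside_ml", drop = FALSE]))
    adj <- intersect(c("lesion_ml", "age", "nihss_admission"),
                     names(records))
    out$ordinal_adjusted <- maybe(fit_ordinal(
      records$nihss_discharge,
      records[, c("steal_outside_ml", adj), drop = FALSE]))
    if (length(unique(records$nihss_discharge)) >= 3 &&
        inherits(out$ordinal_adjusted, "ordinal_fit"))
      out$brant <- tryCatch(
        suppressWarnings(brant_test(out$ordinal_adjusted)),
        error = function(e) conditionMessage(e))
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  med <- function(v) sprintf("%.2f [IQR %.2f-%.2f]", v["median"], v["q1"],
                             v["q3"])
  cat(sprintf("Cohort of %d subjects\n", x$n))
  cat("  DWI lesion volume (mL):        ", med(x$lesion_ml), "\n")
  cat("  steal volume, ACA+MCA (mL):    ", med(x$steal_aca_mca_ml), "\n")
  cat("  % of steal inside lesion:      ", med(x$pct_steal_in_lesion), "\n")
  cat("  % of lesion covered by steal:  ", med(x$pct_lesion_covered), "\n")
  if (!is.null(x$cvr_in_lesion))
    cat(sprintf("  in-lesion CVR (%%/mmHg):         %.3f +/- %.3f\n",
                x$cvr_in_lesion["mean"], x$cvr_in_lesion["sd"]))
  cat("  lesion vs extra-lesional steal: ")
  print(x$spearman_unadjusted)
  if (!is.null(x$spearman_adjusted)) {
    cat("  adjusted:                       ")
    print(x$spearman_adjusted)
  }
  if (!is.null(x$ordinal_unadjusted)) {
    cat("  discharge-NIHSS model (unadjusted):\n")
    print(x$ordinal_unadjusted)
    if (!is.null(x$ordinal_adjusted)) {
      cat("  discharge-NIHSS model (adjusted):\n")
      print(x$ordinal_adjusted)
    }
    if (!is.null(x$brant) && inherits(x$brant, "brant_result")) print(x$brant)
  }
  invisible(x)
}

#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  row <- c(n = x$n,
           stats::setNames(as.list(x$lesion_ml),
                           paste0("lesion_ml_", names(x$lesion_ml))),
           stats::setNames(as.list(x$steal_aca_mca_ml),
                           paste0("steal_ml_", names(x$steal_aca_mca_ml))),
           stats::setNames(as.list(x$pct_steal_in_lesion),
                           paste0("pct_steal_in_lesion_",
                                  names(x$pct_steal_in_lesion))),
           stats::setNames(as.list(x$pct_lesion_covered),
                           paste0("pct_lesion_covered_",
                                  names(x$pct_lesion_covered))),
           list(cvr_in_lesion_mean = unname(x$cvr_in_lesion["mean"]),
                cvr_in_lesion_sd = unname(x$cvr_in_lesion["sd"]),
                spearman_rho = x$spearman_unadjusted$rho,
                spearman_p = x$spearman_unadjusted$p_value,
                spearman_adj_rho = if (!is.null(x$spearman_adjusted))
                  x$spearman_adjusted$rho else NA_real_,
                spearman_adj_p = if (!is.null(x$spearman_adjusted))
                  x$spearman_adjusted$p_value else NA_real_))
  as.data.frame(row, check.names = TRUE)
}
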