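#' Volume of a binary mask in mL
#'
#' @param mask Logical (or 0/1) 3D array, or a `steal_mask`.
#' @param grid The [volume_grid()].
#' @return Volume in millilitres: `count * voxel volume (mm^3) / 1000`.
#' @export
mask_volume <- function(mask, grid) {
  if (inherits(mask, "steal_mask")) mask <- mask$values
  sum(mask != 0) * voxel_volume_ml(grid)
}

#' Partition tissue by lesion and steal status
#'
#' Decomposes the steal mask against the infarct lesion mask into
#' lesion-positive/steal-positive and lesion-negative/steal-positive
#' compartments, in mL, together with the two coverage percentages the
#' cohort stage summarizes: the percentage of the lesion covered by steal
#' and the percentage of steal volume lying inside the lesion. A percentage
#' whose denominator volume is zero is flagged undefined (`NA`) rather than
#' forced to a number.
#'
#' @param steal A `steal_mask` or logical array.
#' @param lesion Logical (or 0/1) 3D lesion mask.
#' @param grid The shared [volume_grid()].
#' @return Object of class `overlap_partition` with fields
#'   `steal_total_ml`, `steal_in_lesion_ml`, `steal_outside_lesion_ml`,
#'   `lesion_ml`, `pct_lesion_covered_by_steal`, `pct_steal_inside_lesion`.
#' @export
partition_overlap <- function(steal, lesion, grid) {
  sv <- if (inherits(steal, "steal_mask")) steal$values else steal != 0
  lv <- lesion != 0
  if (!identical(dim(sv), grid$shape) || !identical(dim(lv), grid$shape))
    stop("grid mismatch: masks do not share the declared grid", call. = FALSE)
  vml <- voxel_volume_ml(grid)
  n_in <- sum(sv & lv)
  n_out <- sum(sv & !lv)
  n_les <- sum(lv)
  structure(list(
    steal_total_ml = (n_in + n_out) * vml,
    steal_in_lesion_ml = n_in * vml,
    steal_outside_lesion_ml = n_out * vml,
    lesion_ml = n_les * vml,
    pct_lesion_covered_by_steal = if (n_les > 0) 100 * n_in / n_les
                                  else NA_real_,
    pct_steal_inside_lesion = if (n_in + n_out > 0)
      100 * n_in / (n_in + n_out) else NA_real_),
    class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf(
    "overlap: lesion %.2f mL, steal %.2f mL (%.2f in / %.2f outside lesion)\n",
    x$lesion_ml, x$steal_total_ml, x$steal_in_lesion_ml,
    x$steal_outside_lesion_ml))
  cat(sprintf("  %% lesion covered by steal: %s; %% steal inside lesion: %s\n",
              fmt_pct(x$pct_lesion_covered_by_steal),
              fmt_pct(x$pct_steal_inside_lesion)))
  invisible(x)
}

fmt_pct <- function(p) if (is.na(p)) "undefined" else sprintf("%.1f", p)

#' Region-of-interest statistics for one subject
#'
#' Extracts the per-subject row of the cohort table: mean CVR in the
#' affected-side ACA and MCA territories, mean and SD of CVR inside the
#' lesion, hemispheric means, the lesion volume, and the steal volume
#' clipped to the affected ACA+MCA territory partitioned by lesion
#' membership. Undefined CVR voxels are skipped in every mean.
#'
#' @param cvr A [compute_cvr()] result.
#' @param territories Labelled territory volume (labels per
#'   [territory_labels()]).
#' @param lesion Logical lesion mask.
#' @param steal A `steal_mask` or logical array.
#' @param affected_side `"left"` or `"right"`.
#' @param clip_steal_to_territory Restrict steal volumetrics to the affected
#'   ACA+MCA labels (default), mirroring a steal volume reported "in ACA +
#'   MCA territory" of the stroke side.
#' @return One-row data frame with columns `cvr_mca`, `cvr_aca`,
#'   `cvr_lesion_mean`, `cvr_lesion_sd`, `cvr_ipsi`, `cvr_contra`,
#'   `lesion_ml`, `steal_aca_mca_ml`, `steal_in_lesion_ml`,
#'   `steal_outside_ml`.
#' @export
roi_statistics <- function(cvr, territories, lesion, steal,
                           affected_side = c("right", "left"),
                           clip_steal_to_territory = TRUE) {
  affected_side <- match.arg(affected_side)
  stopifnot(inherits(cvr, "cvr_map"))
  sv <- if (inherits(steal, "steal_mask")) steal$values else steal != 0
  if (!identical(dim(territories), cvr$grid$shape))
    stop("grid mismatch: atlas does not share the CVR grid", call. = FALSE)
  labs <- territory_labels()
  lab_of <- function(terr, hemi)
    labs$label[labs$territory == terr & labs$hemisphere == hemi]
  need <- c(lab_of("ACA", affected_side), lab_of("MCA", affected_side))
  if (!all(need %in% territories))
    stop("atlas error: affected-side ACA/MCA labels missing from atlas",
         call. = FALSE)
  mean_in <- function(sel) {
    v <- cvr$values[sel & cvr$brain_mask]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  ipsi <- territories %in% labs$label[labs$hemisphere == affected_side]
  dim(ipsi) <- dim(territories)
  contra <- territories %in% labs$label[labs$hemisphere != affected_side]
  dim(contra) <- dim(territories)
  aca_mca <- array(territories %in% need, dim(territories))
  sv_terr <- if (clip_steal_to_territory) sv & aca_mca else sv
  vml <- voxel_volume_ml(cvr$grid)
  lesion <- lesion != 0
  lesion_cvr <- cvr$values[lesion & cvr$brain_mask]
  data.frame(
    cvr_mca = mean_in(array(territories %in% lab_of("MCA", affected_side),
                            dim(territories))),
    cvr_aca = mean_in(array(territories %in% lab_of("ACA", affected_side),
                            dim(territories))),
    cvr_lesion_mean = if (length(lesion_cvr)) mean(lesion_cvr) else NA_real_,
    cvr_lesion_sd = if (length(lesion_cvr) > 1) stats::sd(lesion_cvr)
                    else NA_real_,
    cvr_ipsi = mean_in(ipsi),
    cvr_contra = mean_in(contra),
    lesion_ml = sum(lesion) * vml,
    steal_aca_mca_ml = sum(sv_terr) * vml,
    steal_in_lesion_ml = sum(sv_terr & lesion) * vml,
    steal_outside_ml = sum(sv_terr & !lesion) * vml)
}
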