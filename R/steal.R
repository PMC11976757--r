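#' Classify steal-phenomenon voxels
#'
#' A voxel is classified as exhibiting vascular steal when its reactivity is
#' paradoxically negative (`CVR < 0` %/mmHg) and it deviates below the
#' healthy reference atlas by at least `z_threshold` standard deviations
#' (`Z <= -z_threshold`). The second gate keeps only negative voxels that
#' differ significantly from the healthy cohort, suppressing voxels that are
#' negative by noise alone.
#'
#' @param cvr A [compute_cvr()] result.
#' @param zmap The matching [zscore_map()] result.
#' @param z_threshold Positive number of atlas SDs; default 2.
#' @return Object of class `steal_mask`: `values` (logical 3D array, `TRUE`
#'   only where CVR is defined), `grid`, `criterion`.
#' @export
detect_steal <- function(cvr, zmap, z_threshold = 2) {
  stopifnot(inherits(cvr, "cvr_map"), inherits(zmap, "z_map"))
  if (!is.numeric(z_threshold) || z_threshold <= 0)
    stop("z_threshold must be > 0", call. = FALSE)
  check_same_grid(cvr$grid, zmap$grid, "CVR and Z maps")
  sel <- !is.na(cvr$values) & !is.na(zmap$values) &
    cvr$values < 0 & zmap$values <= -z_threshold
  structure(list(values = sel, grid = cvr$grid,
                 criterion = list(cvr_below = 0, z_threshold = z_threshold)),
            class = "steal_mask")
}

#' @export
print.steal_mask <- function(x, ...) {
  cat(sprintf("steal mask: %d voxels (%.2f mL), criterion CVR < %g & Z <= -%g\n",
              sum(x$values), mask_volume(x$values, x$grid),
              x$criterion$cvr_below, x$criterion$z_threshold))
  invisible(x)
}

# 26-connected component labelling by breadth-first frontier expansion.
label_components <- function(mask) {
  shp <- dim(mask)
  lab <- array(0L, shp)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  nxt <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    nxt <- nxt + 1L
    lab[seed] <- nxt
    frontier <- seed
    while (length(frontier)) {
      ai <- arrayInd(frontier, shp)
      cand <- ai[rep(seq_len(nrow(ai)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(ai)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= shp[1] &
            cand[, 2] >= 1 & cand[, 2] <= shp[2] &
            cand[, 3] >= 1 & cand[, 3] <= shp[3]
      ci <- unique(cand[ok, 1] + (cand[ok, 2] - 1L) * shp[1] +
                     (cand[ok, 3] - 1L) * shp[1] * shp[2])
      ci <- ci[mask[ci] & lab[ci] == 0L]
      lab[ci] <- nxt
      frontier <- ci
    }
  }
  lab
}

#' Remove small clusters from a steal mask
#'
#' Drops 26-connected components smaller than `min_cluster_voxels`. The
#' default of 0 disables the filter, keeping the voxel-level steal
#' definition intact.
#'
#' @param mask A [detect_steal()] result.
#' @param min_cluster_voxels Minimum component size to retain.
#' @return A `steal_mask` with small components removed.
#' @export
clean_mask <- function(mask, min_cluster_voxels = 0) {
  stopifnot(inherits(mask, "steal_mask"), min_cluster_voxels >= 0)
  if (min_cluster_voxels == 0) return(mask)
  lab <- label_components(mask$values)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_cluster_voxels)
  out <- mask
  out$values <- array(lab %in% keep, dim(mask$values))
  out$criterion$min_cluster_voxels <- min_cluster_voxels
  out
}
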