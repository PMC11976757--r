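#' Voxel grid of a volume
#'
#' Records the array shape and voxel size shared by all volumes of one
#' subject. All co-analyzed volumes (BOLD, masks, atlases) must live on an
#' identical grid; the pipeline performs no world-space registration.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param voxel_size Numeric vector of length 3, mm per axis (all > 0).
#' @return Object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(3, 3, 3)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("grid shape must be three positive integers", call. = FALSE)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel sizes must be three positive numbers (mm)", call. = FALSE)
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume grid: %s voxels at %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

voxel_volume_ml <- function(grid) prod(grid$voxel_size) / 1000

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && all(abs(a$voxel_size - b$voxel_size) < tol)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b))
    stop("grid mismatch: ", what, " are not on the same voxel grid",
         call. = FALSE)
  invisible(TRUE)
}

# Solid ellipsoid on a voxel grid; center and radii in (1-based) voxel units.
ellipsoid_mask <- function(shape, center, radii) {
  stopifnot(length(center) == 3, length(radii) == 3, all(radii > 0))
  if (any(center < 1) || any(center > shape))
    stop("geometry outside grid: ellipsoid center not within the volume",
         call. = FALSE)
  a <- array(0, shape)
  d2 <- ((slice.index(a, 1) - center[1]) / radii[1])^2 +
        ((slice.index(a, 2) - center[2]) / radii[2])^2 +
        ((slice.index(a, 3) - center[3]) / radii[3])^2
  d2 <= 1
}

# Restore the caller's RNG state after running a seeded computation.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
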