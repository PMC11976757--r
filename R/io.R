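nifti_of <- function(arr, grid, datatype = "double") {
  nd <- length(dim(arr))
  pd <- if (nd == 4L) c(grid$voxel_size, 1) else grid$voxel_size
  RNifti::asNifti(structure(arr * 1, pixdim = pd), datatype = datatype)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  grid <- volume_grid(dm[1:3], RNifti::pixdim(img)[1:3])
  list(data = array(as.numeric(img), dm), grid = grid)
}

#' Write a subject bundle to disk
#'
#' Serializes every component of a subject in the pipeline's on-disk layout:
#' NIfTI-1 volumes (`bold.nii`, `lesion_mask.nii`, `territories.nii`,
#' `brain_mask.nii`, `cvr_truth.nii`, `steal_truth.nii`, `atlas_mean.nii`,
#' `atlas_sd.nii`; masks and atlas as unsigned 8-bit), a one-column PetCO2
#' trace with header line `mmHg`, a six-column motion trace (translations
#' mm, rotations radians), the protocol as YAML and, when present, the
#' clinical record as CSV.
#'
#' @param bundle A `subject_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_subject <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- bundle$grid
  p <- function(f) file.path(dir, f)
  RNifti::writeNifti(nifti_of(bundle$bold, g), p("bold.nii"))
  RNifti::writeNifti(nifti_of(bundle$lesion_mask, g, "uint8"),
                     p("lesion_mask.nii"))
  RNifti::writeNifti(nifti_of(bundle$brain_mask, g, "uint8"),
                     p("brain_mask.nii"))
  RNifti::writeNifti(nifti_of(bundle$steal_truth, g, "uint8"),
                     p("steal_truth.nii"))
  RNifti::writeNifti(nifti_of(bundle$territories, g, "uint8"),
                     p("territories.nii"))
  cvrt <- bundle$cvr_truth
  cvrt[is.na(cvrt)] <- 0  # NIfTI carries no NA; mask marks validity
  RNifti::writeNifti(nifti_of(cvrt, g), p("cvr_truth.nii"))
  am <- bundle$atlas_ref$mean; am[is.na(am)] <- 0
  as_ <- bundle$atlas_ref$sd; as_[is.na(as_)] <- 0
  RNifti::writeNifti(nifti_of(am, g), p("atlas_mean.nii"))
  RNifti::writeNifti(nifti_of(as_, g), p("atlas_sd.nii"))
  writeLines(c("mmHg", format(bundle$petco2, digits = 17)), p("petco2.txt"))
  utils::write.table(format(bundle$motion, digits = 17), p("motion.txt"),
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(c(bundle$protocol,
                     list(affected_side = bundle$affected_side,
                          subject_id = bundle$subject_id)),
                   p("protocol.yaml"))
  if (!is.null(bundle$clinical))
    utils::write.csv(bundle$clinical, p("clinical.csv"), row.names = FALSE)
  invisible(vapply(c("bold.nii", "lesion_mask.nii", "brain_mask.nii",
                     "steal_truth.nii", "territories.nii", "cvr_truth.nii",
                     "atlas_mean.nii", "atlas_sd.nii", "petco2.txt",
                     "motion.txt", "protocol.yaml"), p, character(1)))
}

resample_nearest <- function(data, from, to) {
  map <- lapply(1:3, function(ax) {
    pos <- ((seq_len(to$shape[ax]) - 0.5) * to$voxel_size[ax]) /
      from$voxel_size[ax] + 0.5
    pmin(pmax(round(pos), 1L), from$shape[ax])
  })
  array(data[map[[1]], map[[2]], map[[3]]], to$shape)
}

#' Load a subject bundle from disk
#'
#' Reads the layout written by [write_subject()], validating that every
#' volume shares one voxel grid and that BOLD frame count, PetCO2 trace and
#' motion trace agree. Under `grid_policy = "strict"` any grid mismatch is
#' an error; under `"resample-nearest"` the masks and label atlas (only)
#' are resampled to the BOLD grid by nearest neighbour.
#'
#' @param dir Directory containing the subject files.
#' @param grid_policy `"strict"` or `"resample-nearest"`.
#' @return A `subject_bundle`.
#' @export
load_subject <- function(dir, grid_policy = c("strict", "resample-nearest")) {
  grid_policy <- match.arg(grid_policy)
  p <- function(f) file.path(dir, f)
  for (f in c("bold.nii", "lesion_mask.nii", "territories.nii",
              "petco2.txt", "motion.txt", "protocol.yaml"))
    if (!file.exists(p(f)))
      stop("missing subject file: ", p(f), call. = FALSE)
  bold <- read_volume(p("bold.nii"))
  grid <- bold$grid
  n <- dim(bold$data)[4]
  pet <- as.numeric(readLines(p("petco2.txt"))[-1])
  motion <- as.matrix(utils::read.table(p("motion.txt"), header = TRUE))
  if (length(pet) != n)
    stop("alignment error: ", n, " BOLD frames but ", length(pet),
         " PetCO2 samples", call. = FALSE)
  if (nrow(motion) != n)
    stop("alignment error: ", n, " BOLD frames but ", nrow(motion),
         " motion rows", call. = FALSE)
  py <- yaml::read_yaml(p("protocol.yaml"))
  protocol <- co2_protocol(py$resting_petco2, py$step_amplitude,
                           py$baseline_s, py$step_s, py$recovery_s, py$tr)

  get_vol <- function(f, resample_ok = FALSE, required = TRUE) {
    if (!file.exists(p(f))) {
      if (required) stop("missing subject file: ", p(f), call. = FALSE)
      return(NULL)
    }
    v <- read_volume(p(f))
    if (!grids_equal(v$grid, grid)) {
      if (grid_policy == "resample-nearest" && resample_ok)
        v$data <- resample_nearest(v$data, v$grid, grid)
      else stop("grid mismatch: ", f, " is not on the BOLD grid",
                call. = FALSE)
    }
    v$data
  }
  lesion <- get_vol("lesion_mask.nii", resample_ok = TRUE)
  if (!all(lesion %in% c(0, 1)))
    stop("mask error: lesion mask contains values other than 0/1",
         call. = FALSE)
  territories <- get_vol("territories.nii", resample_ok = TRUE)
  brain <- get_vol("brain_mask.nii", resample_ok = TRUE, required = FALSE)
  steal <- get_vol("steal_truth.nii", resample_ok = TRUE, required = FALSE)
  cvrt <- get_vol("cvr_truth.nii", required = FALSE)
  am <- get_vol("atlas_mean.nii", required = FALSE)
  asd <- get_vol("atlas_sd.nii", required = FALSE)
  atlas_ref <- if (!is.null(am) && !is.null(asd)) {
    asd[asd == 0] <- NA
    atlas_reference(am, asd, grid)
  }
  clinical <- if (file.exists(p("clinical.csv")))
    utils::read.csv(p("clinical.csv"))
  structure(list(bold = bold$data, petco2 = pet, motion = motion,
                 protocol = protocol, grid = grid,
                 brain_mask = if (!is.null(brain)) brain > 0,
                 lesion_mask = lesion > 0,
                 steal_truth = if (!is.null(steal)) steal > 0,
                 cvr_truth = cvrt, territories = territories,
                 atlas_ref = atlas_ref,
                 affected_side = py$affected_side %||% "right",
                 clinical = clinical,
                 subject_id = py$subject_id %||% basename(dir)),
            class = "subject_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cohort_table_schema <- c("subject_id", "cvr_mca", "cvr_aca",
                         "cvr_lesion_mean", "cvr_lesion_sd", "lesion_ml",
                         "steal_aca_mca_ml", "steal_in_lesion_ml",
                         "steal_outside_ml")

#' Load a cohort table
#'
#' Reads a per-subject cohort CSV. The required columns are the volumetric
#' and CVR summaries (`subject_id`, `cvr_mca`, `cvr_aca`, `cvr_lesion_mean`,
#' `cvr_lesion_sd`, `lesion_ml`, `steal_aca_mca_ml`, `steal_in_lesion_ml`,
#' `steal_outside_ml`); clinical columns (`age`, `nihss_admission`, `nihss_discharge`,
#' `groin_to_mr_hours`, ...) are optional. Volumes are mL, CVR values
#' %/mmHg.
#'
#' @param path CSV file path. Defaults to the packaged transcription of the
#'   published 21-subject steal-distribution table.
#' @return Data frame with one validated row per subject.
#' @export
load_cohort_table <- function(path = steal_table_path()) {
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("schema error: cannot parse cohort table: ",
                         conditionMessage(e), call. = FALSE))
  missing <- setdiff(cohort_table_schema, names(tab))
  if (length(missing))
    stop("schema error: cohort table lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  vols <- c("lesion_ml", "steal_aca_mca_ml", "steal_in_lesion_ml",
            "steal_outside_ml")
  for (v in vols) {
    if (!is.numeric(tab[[v]]) || anyNA(tab[[v]]) || any(tab[[v]] < 0))
      stop("schema error: column ", v, " must be non-negative numeric",
           call. = FALSE)
  }
  for (v in c("nihss_admission", "nihss_discharge"))
    if (v %in% names(tab) && any(tab[[v]] < 0 | tab[[v]] > 42, na.rm = TRUE))
      stop("schema error: ", v, " outside 0-42", call. = FALSE)
  tab
}

#' Path to the packaged cohort reference table
#'
#' Transcription (verbatim two-decimal values) of the published per-subject
#' distribution of steal volumes and CVR in the affected hemisphere of 21
#' thrombectomy patients.
#'
#' @return File path of the CSV.
#' @export
steal_table_path <- function()
  system.file("extdata", "steal_distribution_cohort.csv",
              package = "cvrsteal", mustWork = TRUE)
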