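# File formats: NIfTI-1 volumes via RNifti, FSL-dialect bval/bvec text
# files, cohort CSV, JSON manifest. A fixture bundle is a directory holding
# a simulated acquisition plus a cohort table, regenerable from the seeds
# recorded in its manifest.

#' Write a diffusion volume as NIfTI + bval/bvec
#'
#' The 4D signal is written as double-precision NIfTI-1 (so values
#' round-trip bit-exactly) alongside FSL-dialect `.bval` (one row) and
#' `.bvec` (three rows) text files.
#'
#' @param dwi a `dwi_volume` from [generate_dwi()] or [read_dwi()].
#' @param path output path without extension; `.nii.gz`, `.bval`, `.bvec`
#'   are appended.
#' @return Invisibly, the three file paths.
#' @export
write_dwi <- function(dwi, path) {
  stopifnot(inherits(dwi, "dwi_volume"))
  nii <- paste0(path, ".nii.gz")
  img <- structure(dwi$signal, pixdim = c(dwi$voxel_size_mm, 1))
  RNifti::writeNifti(RNifti::asNifti(img), nii, datatype = "double")
  bval <- paste0(path, ".bval")
  bvec <- paste0(path, ".bvec")
  writeLines(paste(format(dwi$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval)
  writeLines(apply(t(dwi$bvecs), 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), bvec)
  invisible(c(nifti = nii, bval = bval, bvec = bvec))
}

#' Read a diffusion volume from NIfTI + bval/bvec
#'
#' @param nifti path to the 4D NIfTI file.
#' @param bval,bvec paths to FSL-dialect gradient files; default to the
#'   NIfTI path with swapped extensions.
#' @param axes anatomical meaning of the three array axes; the package
#'   convention (x = left-right, y = anterior-posterior, z = cranio-caudal)
#'   is assumed for phantom data.
#' @return A `dwi_volume`.
#' @export
read_dwi <- function(nifti, bval = NULL, bvec = NULL,
                     axes = AXIS_CONVENTION) {
  base <- sub("\\.nii(\\.gz)?$", "", nifti)
  bval <- bval %||% paste0(base, ".bval")
  bvec <- bvec %||% paste0(base, ".bvec")
  for (f in c(nifti, bval, bvec))
    if (!file.exists(f)) stop_("file not found: %s", f)
  img <- RNifti::readNifti(nifti)
  sig <- unclass(as.array(img))
  attributes(sig) <- list(dim = dim(sig))
  if (length(dim(sig)) != 4L) stop_("%s is not a 4D volume", nifti)
  bvals <- scan(bval, quiet = TRUE)
  bv <- as.matrix(read.table(bvec))
  if (nrow(bv) != 3L || ncol(bv) != length(bvals))
    stop_("bvec file %s is not 3 x n matching %s", bvec, bval)
  vox <- RNifti::pixdim(img)[1:3]
  structure(list(signal = sig, bvals = bvals, bvecs = unname(t(bv)),
                 voxel_size_mm = vox, axes = axes),
            class = "dwi_volume")
}

# CSV writer that preserves doubles bit-exactly through the text round trip
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                          sprintf("%.17g", out[[nm]]))
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Restores the column types written by [write_fixture_bundle()]: the
#' `group` column becomes a factor with the four study-group levels and
#' `gender` a factor with levels F/M.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("group" %in% names(df))
    df$group <- factor(df$group, levels = GROUP_LEVELS)
  if ("gender" %in% names(df))
    df$gender <- factor(df$gender, levels = c("F", "M"))
  df
}

#' Write a self-describing fixture bundle
#'
#' Generates (deterministically, from the seeds inside the specs) and
#' writes: the phantom DWI as `dwi.nii.gz` + `dwi.bval`/`dwi.bvec`, the
#' cohort as `cohort.csv`, and `manifest.json` recording the generator
#' parameters and seeds. Omitting `phantom` writes a cohort-only bundle;
#' downstream imaging stages are then skipped.
#'
#' @param out_dir writable output directory (created if missing).
#' @param phantom a [phantom_spec()] or `NULL`.
#' @param cohort a [cohort_spec()] or `NULL`.
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_bundle <- function(out_dir, phantom = NULL, cohort = NULL) {
  if (is.null(phantom) && is.null(cohort))
    stop_("nothing to write: supply a phantom spec, a cohort spec, or both")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_("cannot create directory %s", out_dir)
  manifest <- list(bundle = "alpskit-fixture", version = 1L,
                   files = list())
  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "phantom_spec"))
    tf <- generate_tensor_field(phantom)
    dwi <- generate_dwi(tf, noise_sigma = phantom$noise_sigma,
                        seed = phantom$seed)
    write_dwi(dwi, file.path(out_dir, "dwi"))
    manifest$files$dwi <- c("dwi.nii.gz", "dwi.bval", "dwi.bvec")
    manifest$phantom <- phantom_spec_manifest(phantom)
  }
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_spec"))
    tab <- generate_cohort(cohort)
    write_cohort_csv(tab, file.path(out_dir, "cohort.csv"))
    manifest$files$cohort <- "cohort.csv"
    manifest$cohort <- unclass(cohort)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "columnmajor")
  invisible(manifest)
}

# phantom spec serialized without the bulky region map; the map is
# regenerable from grid_shape for the default geometry
phantom_spec_manifest <- function(spec) {
  s <- unclass(spec)
  s$region_map <- NULL
  s$base_tensors <- lapply(s$base_tensors, function(m) as.vector(m))
  s
}

#' Read a fixture bundle
#'
#' @param dir bundle directory written by [write_fixture_bundle()].
#' @return List with `dwi` (a `dwi_volume` or `NULL`), `cohort` (data frame
#'   or `NULL`) and `manifest`.
#' @export
read_fixture_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_("no manifest.json in %s", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  dwi <- NULL
  if (!is.null(manifest$files$dwi))
    dwi <- read_dwi(file.path(dir, "dwi.nii.gz"))
  cohort <- NULL
  if (!is.null(manifest$files$cohort))
    cohort <- read_cohort_csv(file.path(dir, "cohort.csv"))
  list(dwi = dwi, cohort = cohort, manifest = manifest)
}
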