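#' @include AllClasses.R AllGenerics.R fitting.R
NULL

#' Write an image stack to NIfTI
#'
#' Stores a 2D image or a 2D+weighting stack with explicit pixel-size
#' metadata (default 1 mm slice thickness, isotropic in-plane spacing).
#'
#' @param img Matrix or 3D array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param pixdim In-plane pixel size and slice thickness (mm).
#' @return `path`, invisibly.
#' @export
writeImageNifti <- function(img, path, pixdim = c(0.078, 0.078, 1)) {
  nii <- RNifti::asNifti(img, pixdim = pixdim[seq_len(min(3, length(dim(img))))])
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read an image stack from NIfTI
#'
#' @param path NIfTI file path.
#' @return Numeric array (attributes dropped).
#' @export
readImageNifti <- function(path) {
  if (!file.exists(path))
    stop("NIfTI file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Write the weighting time sidecar
#'
#' Tab-separated sidecar with columns `weighting_index` and `duration_s`,
#' giving the preparation duration of each image in a weighted series.
#'
#' @param times Durations (s).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeTimesTsv <- function(times, path) {
  utils::write.table(
    data.frame(weighting_index = seq_along(times) - 1L, duration_s = times),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the weighting time sidecar
#'
#' @param path TSV path written by [writeTimesTsv()].
#' @return Durations in seconds.
#' @export
readTimesTsv <- function(path) {
  if (!file.exists(path))
    stop("times sidecar not found: ", path,
         " (expected TSV with columns weighting_index, duration_s)",
         call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("weighting_index", "duration_s") %in% names(df)))
    stop("times sidecar must carry columns weighting_index and duration_s",
         call. = FALSE)
  df$duration_s[order(df$weighting_index)]
}

#' Write fitted maps to a directory
#'
#' Writes `t_map.nii.gz` (seconds), `ss_map.nii.gz`, `rsq_map.nii.gz` and
#' `mask.nii.gz` under `dir`.
#'
#' @param maps A [RegionMaps-class].
#' @param dir Output directory (created if needed).
#' @param pixdim Pixel size metadata (mm).
#' @return `dir`, invisibly.
#' @export
writeMaps <- function(maps, dir, pixdim = c(0.078, 0.078, 1)) {
  stopifnot(is(maps, "RegionMaps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeImageNifti(maps@tMap, file.path(dir, "t_map.nii.gz"), pixdim)
  writeImageNifti(maps@ssMap, file.path(dir, "ss_map.nii.gz"), pixdim)
  writeImageNifti(maps@rsqMap, file.path(dir, "rsq_map.nii.gz"), pixdim)
  writeImageNifti(maps@mask * 1, file.path(dir, "mask.nii.gz"), pixdim)
  invisible(dir)
}

#' Read fitted maps from a directory
#'
#' @param dir Directory written by [writeMaps()].
#' @return A [RegionMaps-class].
#' @export
readMaps <- function(dir) {
  tM <- readImageNifti(file.path(dir, "t_map.nii.gz"))
  sM <- readImageNifti(file.path(dir, "ss_map.nii.gz"))
  rM <- readImageNifti(file.path(dir, "rsq_map.nii.gz"))
  mk <- readImageNifti(file.path(dir, "mask.nii.gz")) > 0.5
  tM[!mk] <- NA_real_
  new("RegionMaps", tMap = tM, ssMap = sM, rsqMap = rM, mask = mk)
}
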