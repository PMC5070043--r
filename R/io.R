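#' @importFrom utils read.delim write.table
NULL

#' Write a volume to NIfTI-1
#'
#' @param x a [BrainVolume], [LabelAtlas] or 3D array.
#' @param path output path (.nii or .nii.gz).
#' @param voxelSize voxel size in mm (taken from the object when given a
#'   volume class).
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path, voxelSize = c(2, 2, 2)) {
  if (is(x, "BrainVolume")) {
    voxelSize <- voxelSize(x)
    x <- voxelData(x)
  }
  img <- RNifti::asNifti(x, internal = FALSE)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path file path.
#' @param atlas read as a [LabelAtlas] (integer labels) instead of a
#'   [BrainVolume].
#' @return a [BrainVolume] or [LabelAtlas].
#' @export
readVolume <- function(path, atlas = FALSE) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  a <- array(as.numeric(img), dim(img)[1:3])
  if (atlas) labelAtlas(array(as.integer(round(a)), dim(a)), vox)
  else brainVolume(a, vox)
}

#' Write a per-subject volume stack as one NIfTI file per subject
#'
#' @param stack a [GmvStack].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
writeStack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- voxelData(stack)
  ids <- subjectIds(stack)
  paths <- file.path(dir, paste0(ids, "_gmv.nii.gz"))
  for (i in seq_along(ids))
    writeVolume(v[, , , i], paths[i], voxelSize(stack))
  setNames(paths, ids)
}

#' Read per-subject NIfTI volumes into a stack
#'
#' All volumes must share grid shape and voxel size.
#'
#' @param paths named character vector (names are subject ids; when
#'   unnamed, ids are derived from file names).
#' @return a [GmvStack].
#' @export
readStack <- function(paths) {
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("(_gmv)?\\.nii(\\.gz)?$", "", basename(paths))
  vols <- lapply(paths, readVolume)
  d <- dim(vols[[1]])
  vox <- voxelSize(vols[[1]])
  for (v in vols[-1]) {
    if (!identical(dim(v), d) ||
        max(abs(voxelSize(v) - vox)) > 1e-6)
      stop("geometry error: volumes differ in grid shape or voxel size")
  }
  arr <- array(0, c(d, length(vols)))
  for (i in seq_along(vols)) arr[, , , i] <- voxelData(vols[[i]])
  gmvStack(arr, vox, ids)
}

#' Read a TSV table
#'
#' Tab-separated, dot decimal separator, explicit header: the only table
#' dialect accepted. Numeric-looking columns containing comma decimals
#' raise an explicit parse error rather than being silently read as text.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.character(col) &&
        any(grepl("^-?[0-9]+,[0-9]+$", col))) {
      stop("parse error in ", basename(path), ", column '", nm,
           "': comma decimal separator; use '.'")
    }
  }
  df
}

#' Write a TSV table
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a StatMap as NIfTI maps plus a JSON sidecar
#'
#' Writes the t-map, one beta map per regressor, and a sidecar recording
#' contrast, df and model columns.
#'
#' @param statMap a [StatMap].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return sidecar path, invisibly.
#' @export
writeStatMap <- function(statMap, dir, prefix = "stat") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeVolume(statMap@tValues, file.path(dir, paste0(prefix, "_tmap.nii.gz")),
              voxelSize(statMap))
  for (nm in names(statMap@betas))
    writeVolume(statMap@betas[[nm]],
                file.path(dir, paste0(prefix, "_beta_", nm, ".nii.gz")),
                voxelSize(statMap))
  side <- file.path(dir, paste0(prefix, "_glm.json"))
  jsonlite::write_json(list(contrast = statMap@contrast, df = statMap@df,
                            columns = statMap@columns),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Write a ThresholdMap as TSV (and optionally a NIfTI threshold volume)
#'
#' @param thresholdMap a [ThresholdMap].
#' @param path TSV output path.
#' @param atlas optional [LabelAtlas]; when given, a per-voxel threshold
#'   volume is written next to the TSV.
#' @return the TSV path, invisibly.
#' @export
writeThresholdMap <- function(thresholdMap, path, atlas = NULL) {
  tab <- thresholdTable(thresholdMap)
  names(tab)[names(tab) == "combined"] <- "combined_expression"
  writeTsv(tab, path)
  if (!is.null(atlas))
    writeVolume(thresholdVolume(thresholdMap, atlas),
                sub("\\.tsv$", "_pthresh.nii.gz", path))
  invisible(path)
}
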