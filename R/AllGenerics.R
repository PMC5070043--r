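#' Voxel data of a volume-like object
#' @param x a [BrainVolume], [GmvStack] or [StatMap].
#' @return the underlying array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel size in mm
#' @param x a volume-like object.
#' @return numeric(3).
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Region labels present in an atlas
#' @param x a [LabelAtlas].
#' @return sorted non-background integer labels.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' Subject identifiers of a stack
#' @param x a [GmvStack].
#' @return character vector.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Number of subjects in a stack
#' @param x a [GmvStack].
#' @return integer.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Threshold table of a ThresholdMap
#' @param x a [ThresholdMap].
#' @return data.frame with region_label, expression means, rank and
#'   p_threshold.
#' @export
setGeneric("thresholdTable", function(x) standardGeneric("thresholdTable"))

setMethod("voxelData", "BrainVolume", function(x) x@values)
setMethod("voxelData", "GmvStack", function(x) x@values)
setMethod("voxelData", "StatMap", function(x) x@tValues)
setMethod("voxelSize", "BrainVolume", function(x) x@voxelSize)
setMethod("voxelSize", "GmvStack", function(x) x@voxelSize)
setMethod("voxelSize", "StatMap", function(x) x@voxelSize)
setMethod("regionLabels", "LabelAtlas", function(x) {
  u <- sort(unique(as.vector(x@values)))
  u[u != 0]
})
setMethod("subjectIds", "GmvStack", function(x) x@subjectIds)
setMethod("nSubjects", "GmvStack", function(x) dim(x@values)[4])
setMethod("thresholdTable", "ThresholdMap", function(x) x@scores)

#' @describeIn voxelData dimensions of the grid
#' @export
setMethod("dim", "BrainVolume", function(x) dim(x@values))

#' Construct a BrainVolume
#' @param values 3D numeric array.
#' @param voxelSize numeric voxel edge lengths in mm (recycled to 3).
#' @return a [BrainVolume].
#' @export
brainVolume <- function(values, voxelSize = c(2, 2, 2)) {
  new("BrainVolume", values = values,
      voxelSize = rep_len(as.numeric(voxelSize), 3L))
}

#' Construct a LabelAtlas
#' @inheritParams brainVolume
#' @return a [LabelAtlas].
#' @export
labelAtlas <- function(values, voxelSize = c(2, 2, 2)) {
  storage.mode(values) <- "integer"
  new("LabelAtlas", values = values,
      voxelSize = rep_len(as.numeric(voxelSize), 3L))
}

#' Construct a GmvStack
#' @param values 4D array (x, y, z, subject).
#' @param voxelSize numeric voxel edge lengths in mm (recycled to 3).
#' @param subjectIds character ids, 4th-dimension order.
#' @return a [GmvStack].
#' @export
gmvStack <- function(values, voxelSize = c(2, 2, 2),
                     subjectIds = sprintf("S%03d", seq_len(dim(values)[4]))) {
  new("GmvStack", values = values,
      voxelSize = rep_len(as.numeric(voxelSize), 3L),
      subjectIds = as.character(subjectIds))
}
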