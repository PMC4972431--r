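#' @import methods
#' @importFrom stats rnorm runif lm.fit pt approx filter coef lm resid
#'   fitted cor pf qt sd var
#' @importFrom utils head tail
NULL

#' Labelled tissue volume
#'
#' A 3D integer label array together with a voxel-to-world affine and a
#' named mapping from tissue role (\code{"WM"}, \code{"GM"}, \code{"CSF"},
#' \code{"background"}) to label value.  Voxel indices are 0-based when
#' passed through the affine (NIfTI convention, voxel-centre sampling);
#' the R array itself is of course 1-based.
#'
#' @slot voxels 3D integer array of tissue labels.
#' @slot affine 4x4 voxel-index (0-based) to world-mm transform.
#' @slot labels named integer vector mapping role to label value.
#' @export
setClass("LabelVolume",
  representation(voxels = "array", affine = "matrix", labels = "integer"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
    if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
    if (abs(det(object@affine)) < 1e-12) return("affine must be invertible")
    if (is.null(names(object@labels))) return("labels must be named")
    TRUE
  })

#' Triangulated surface mesh
#'
#' A triangle mesh in world millimetre coordinates.  Triangles are
#' 1-based vertex index triples wound so that the right-hand-rule normal
#' points outward (from white matter into grey matter for interface
#' meshes).  Normals are derived, not stored: see [vertexNormals()].
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @slot triangles integer matrix, one row per triangle, 1-based indices.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix"),
  validity = function(object) {
    if (ncol(object@vertices) != 3L) return("vertices must have 3 columns")
    if (nrow(object@triangles) > 0L) {
      if (ncol(object@triangles) != 3L) return("triangles must have 3 columns")
      idx <- range(object@triangles)
      if (idx[1] < 1L || idx[2] > nrow(object@vertices))
        return("triangle indices out of range")
    }
    TRUE
  })

#' Rigid head-motion trace
#'
#' Per-frame rigid-body realignment parameters: three translations (mm)
#' and three rotations (radians), with the acquisition time of each frame.
#'
#' @slot translations numeric frames x 3 matrix (mm).
#' @slot rotations numeric frames x 3 matrix (radians).
#' @slot frameTimes numeric vector of frame times (s).
#' @export
setClass("MotionTrace",
  representation(translations = "matrix", rotations = "matrix",
                 frameTimes = "numeric"),
  validity = function(object) {
    n <- nrow(object@translations)
    if (nrow(object@rotations) != n) return("translations/rotations mismatch")
    if (length(object@frameTimes) != n) return("frameTimes length mismatch")
    if (!all(is.finite(object@translations)) ||
        !all(is.finite(object@rotations)))
      return("non-finite motion parameters")
    TRUE
  })

#' Per-vertex EPI time series
#'
#' EPI intensities projected onto mesh vertices: a frames x vertices
#' matrix, frame times, and a per-frame kept mask from motion censoring.
#'
#' @slot data numeric frames x vertices matrix (NA where a vertex mapped
#'   outside the EPI field of view).
#' @slot frameTimes numeric frame times (s).
#' @slot keptMask logical per-frame mask (TRUE = frame retained).
#' @slot mesh the [SurfaceMesh-class] the columns refer to.
#' @export
setClass("VertexSeries",
  representation(data = "matrix", frameTimes = "numeric",
                 keptMask = "logical", mesh = "SurfaceMesh"),
  validity = function(object) {
    if (length(object@frameTimes) != nrow(object@data))
      return("frameTimes length must equal frame count")
    if (length(object@keptMask) != nrow(object@data))
      return("keptMask length must equal frame count")
    if (ncol(object@data) != nrow(object@mesh@vertices))
      return("columns must align with mesh vertices")
    TRUE
  })

#' Block-design specification
#'
#' Onsets and durations (s) of the 'move' blocks of an alternating
#' move/stop block design, the repetition time, and the high-pass cutoff.
#'
#' @slot moveOnsets numeric onsets (s) of move blocks.
#' @slot blockDuration numeric block duration (s).
#' @slot TR numeric repetition time (s).
#' @slot highpass numeric high-pass cutoff (s), default 120.
#' @export
setClass("DesignSpec",
  representation(moveOnsets = "numeric", blockDuration = "numeric",
                 TR = "numeric", highpass = "numeric"),
  validity = function(object) {
    if (any(diff(sort(object@moveOnsets)) < object@blockDuration))
      return("move blocks overlap")
    if (object@TR <= 0) return("TR must be positive")
    TRUE
  })

#' Vertex-wise GLM statistics
#'
#' Per-vertex contrast estimate and t statistic from the surface GLM,
#' with residual degrees of freedom.
#'
#' @slot beta numeric per-vertex contrast (move - stop) estimate.
#' @slot tstat numeric per-vertex t statistic (NA where unestimable).
#' @slot df numeric residual degrees of freedom.
#' @slot arCoef numeric pooled AR(1) coefficient used for prewhitening.
#' @export
setClass("VertexStatMap",
  representation(beta = "numeric", tstat = "numeric", df = "numeric",
                 arCoef = "numeric"),
  validity = function(object) {
    if (length(object@beta) != length(object@tstat))
      return("beta/tstat length mismatch")
    TRUE
  })

#' Planar (single-slice) region of interest
#'
#' A 2D ROI drawn on one slice of a reference grid: thalamus, posterior
#' limb of the internal capsule (PLIC), brainstem, or corpus callosum.
#' Voxel indices are 0-based.
#'
#' @slot affine 4x4 voxel-to-world transform of the reference grid.
#' @slot dim integer grid shape.
#' @slot axis integer slice axis (1 = x, 2 = y, 3 = z).
#' @slot sliceIndex integer 0-based slice index along \code{axis}.
#' @slot voxels integer K x 3 matrix of 0-based in-plane voxel indices.
#' @slot role character: "thalamus", "plic", "brainstem" or "cc".
#' @export
setClass("PlanarROI",
  representation(affine = "matrix", dim = "integer", axis = "integer",
                 sliceIndex = "integer", voxels = "matrix",
                 role = "character"),
  validity = function(object) {
    if (nrow(object@voxels) == 0L) return("ROI is empty")
    if (any(object@voxels[, object@axis] != object@sliceIndex))
      return("all ROI voxels must lie on the stated slice")
    TRUE
  })

#' Streamline collection
#'
#' An ordered list of streamlines (each a nodes x 3 matrix of world-mm
#' points) with per-track metadata and provenance counts.
#'
#' @slot streamlines list of numeric matrices, one per track.
#' @slot metadata data.frame with one row per track (seed triangle,
#'   termination reason, labels as they are assigned).
#' @slot space character tag naming the coordinate space.
#' @slot provenance list of counts (requested, attempted, accepted).
#' @export
setClass("Tractogram",
  representation(streamlines = "list", metadata = "data.frame",
                 space = "character", provenance = "list"),
  validity = function(object) {
    if (nrow(object@metadata) > 0L &&
        nrow(object@metadata) != length(object@streamlines))
      return("metadata rows must match streamline count")
    TRUE
  })

#' Weighted k-means result
#'
#' @slot labels integer per-track cluster label (1..k).
#' @slot centers numeric k x features matrix of cluster means.
#' @slot cost numeric global cost of the returned partition.
#' @slot attempts integer number of restarts run.
#' @slot converged logical whether the best attempt converged.
#' @slot iterations integer iterations used by the best attempt.
#' @export
setClass("ClusterResult",
  representation(labels = "integer", centers = "matrix", cost = "numeric",
                 attempts = "integer", converged = "logical",
                 iterations = "integer"))
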