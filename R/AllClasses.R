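#' @import methods
NULL

#' Label scheme for maxillary scan segmentation
#'
#' Maps integer class ids to class names, anatomical roles and unique RGB
#' palette colors. The canonical scheme has 28 entries: 16 permanent teeth
#' (including third molars), 10 primary teeth, the palatal rugae patch, and a
#' void class (gingiva plus background, colored black).
#'
#' @slot entries a \code{data.frame} with columns \code{id} (integer),
#'   \code{name} (character), \code{role} (one of \code{"permanent-tooth"},
#'   \code{"third-molar"}, \code{"primary-tooth"}, \code{"rugae"},
#'   \code{"void"}), and \code{r}, \code{g}, \code{b} (integer, 0--255).
#' @seealso [defaultLabelScheme()]
#' @export
setClass("LabelScheme", representation(entries = "data.frame"))

setValidity("LabelScheme", function(object) {
  e <- object@entries
  need <- c("id", "name", "role", "r", "g", "b")
  if (!all(need %in% names(e))) {
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(e$id)) return("label ids must be unique")
  key <- paste(e$r, e$g, e$b)
  if (anyDuplicated(key)) return("palette colors must be unique")
  if (any(e$r < 0 | e$r > 255 | e$g < 0 | e$g > 255 | e$b < 0 | e$b > 255)) {
    return("palette colors must lie in [0, 255]")
  }
  v <- e[e$role == "void", , drop = FALSE]
  if (nrow(v) == 1L && (v$r != 0 || v$g != 0 || v$b != 0)) {
    return("the void class must be black [0,0,0]")
  }
  TRUE
})

#' Labeled triangle mesh
#'
#' A triangle mesh in millimetres with per-vertex texture color and a
#' per-vertex class label drawn from an attached [LabelScheme-class].
#'
#' @slot vertices numeric N x 3 matrix of vertex positions (mm).
#' @slot faces integer M x 3 matrix of 1-based vertex indices.
#' @slot color numeric N x 3 matrix of RGB texture colors in [0, 255].
#' @slot label integer vector of length N of class ids.
#' @slot scheme the [LabelScheme-class] the labels refer to.
#' @export
setClass("LabeledMesh", representation(
  vertices = "matrix", faces = "matrix", color = "matrix",
  label = "integer", scheme = "LabelScheme"
))

setValidity("LabeledMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must be N x 3")
  if (!all(is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(f) > 0L) {
    if (ncol(f) != 3L) return("faces must be M x 3 (triangles only)")
    if (min(f) < 1L || max(f) > nrow(v)) {
      return("face indices must reference existing vertices")
    }
  }
  if (nrow(object@color) != nrow(v) || ncol(object@color) != 3L) {
    return("color must be N x 3")
  }
  if (length(object@label) != nrow(v)) return("label must have length N")
  if (!all(object@label %in% object@scheme@entries$id)) {
    return("every label id must exist in the attached scheme")
  }
  TRUE
})

#' Camera pose for simulated projection
#'
#' A pinhole camera on a hemisphere above the scan, looking at a target
#' point, with a roll angle about the optical axis and simple intrinsics.
#'
#' @slot position numeric length-3 camera center (mm).
#' @slot lookAt numeric length-3 target point (mm).
#' @slot roll rotation about the optical axis (radians).
#' @slot focal focal length in pixels (after any perspective jitter).
#' @slot center numeric length-2 principal point (pixels).
#' @slot width,height image size in pixels.
#' @export
setClass("CameraPose", representation(
  position = "numeric", lookAt = "numeric", roll = "numeric",
  focal = "numeric", center = "numeric", width = "integer", height = "integer"
))

setValidity("CameraPose", function(object) {
  if (length(object@position) != 3L || length(object@lookAt) != 3L) {
    return("position and lookAt must be length-3")
  }
  if (sum((object@lookAt - object@position)^2) <= 0) {
    return("camera position must differ from the look-at target")
  }
  if (object@focal <= 0) return("focal length must be positive")
  TRUE
})

#' One camera view of a mesh
#'
#' Holds the texture render, the flat (unlit, non-anti-aliased) label render,
#' the depth buffer and the pixel-to-face map produced by a single camera.
#' \code{pix2face} is 0 at background pixels; \code{depth} is \code{Inf}
#' there and finite exactly where a face covers the pixel.
#'
#' @slot texture H x W x 3 array, RGB in [0, 1].
#' @slot label H x W x 3 array of palette colors in [0, 1] (black background).
#' @slot depth H x W matrix of camera-space depth (mm; Inf at background).
#' @slot pix2face H x W integer matrix of 1-based face ids (0 = background).
#' @slot pose the [CameraPose-class] used.
#' @export
setClass("ViewRender", representation(
  texture = "array", label = "array", depth = "matrix",
  pix2face = "matrix", pose = "CameraPose"
))

#' Rigid body transform
#'
#' A 4 x 4 homogeneous matrix whose rotation block is orthonormal with
#' determinant +1 and whose last row is (0, 0, 0, 1).
#'
#' @slot H numeric 4 x 4 matrix.
#' @seealso [composeTransform()], [decomposeTransform()]
#' @export
setClass("RigidTransform", representation(H = "matrix"))

setValidity("RigidTransform", function(object) {
  H <- object@H
  if (!all(dim(H) == c(4L, 4L))) return("H must be 4 x 4")
  if (max(abs(H[4, ] - c(0, 0, 0, 1))) > 1e-9) {
    return("last row must be (0, 0, 0, 1)")
  }
  R <- H[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) {
    return("rotation block must be orthonormal")
  }
  if (abs(det(R) - 1) > 1e-6) return("rotation block must have det +1")
  TRUE
})

#' Anatomical coordinate frame
#'
#' Right-handed orthonormal frame built from the six landmark spheres: the
#' occlusal plane through the two molar cusps and the incisor edge, the
#' sagittal plane through the median raphae points, origin at the normal
#' projection of the incisive papilla onto the occlusal plane.
#'
#' @slot origin numeric length-3 (mm).
#' @slot axes 3 x 3 orthonormal matrix, rows are the x, y, z axes in world
#'   coordinates.
#' @export
setClass("CoordinateFrame", representation(origin = "numeric", axes = "matrix"))

setValidity("CoordinateFrame", function(object) {
  A <- object@axes
  if (!all(dim(A) == c(3L, 3L))) return("axes must be 3 x 3")
  if (max(abs(A %*% t(A) - diag(3))) > 1e-9) return("axes must be orthonormal")
  if (abs(det(A) - 1) > 1e-9) return("axes must be right-handed (det +1)")
  TRUE
})
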