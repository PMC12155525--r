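#' Construct a LabeledMesh
#'
#' @param vertices numeric N x 3 matrix of positions (mm).
#' @param faces integer M x 3 matrix of 1-based triangle indices.
#' @param color numeric N x 3 matrix of RGB in [0, 255]; defaults to grey.
#' @param label integer vector of per-vertex class ids; defaults to all-void.
#' @param scheme a [LabelScheme-class]; defaults to [defaultLabelScheme()].
#' @return a [LabeledMesh-class].
#' @export
LabeledMesh <- function(vertices, faces, color = NULL, label = NULL,
                        scheme = defaultLabelScheme()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (is.null(color)) {
    color <- matrix(200, nrow(vertices), 3)
  }
  color <- as.matrix(color)
  storage.mode(color) <- "double"
  dimnames(color) <- NULL
  if (is.null(label)) label <- rep(voidLabel(scheme), nrow(vertices))
  new("LabeledMesh", vertices = vertices, faces = faces, color = color,
      label = as.integer(label), scheme = scheme)
}

#' @describeIn LabeledMesh-class vertex position matrix (N x 3, mm).
#' @param mesh a [LabeledMesh-class].
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @describeIn LabeledMesh-class triangle index matrix (M x 3, 1-based).
#' @export
meshFaces <- function(mesh) mesh@faces

#' @describeIn LabeledMesh-class per-vertex texture color (N x 3, 0-255).
#' @export
meshColors <- function(mesh) mesh@color

#' @describeIn LabeledMesh-class per-vertex label ids (length N).
#' @export
meshLabels <- function(mesh) mesh@label

#' @describeIn LabeledMesh-class the attached [LabelScheme-class].
#' @export
meshScheme <- function(mesh) mesh@scheme

#' Replace the label channel of a mesh
#' @param mesh a [LabeledMesh-class].
#' @param label integer vector of class ids, length N.
#' @export
setMeshLabels <- function(mesh, label) {
  mesh@label <- as.integer(label)
  validObject(mesh)
  mesh
}

setMethod("show", "LabeledMesh", function(object) {
  present <- sort(unique(object@label))
  cat("LabeledMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces,", length(present), "label classes\n")
})

#' Area-weighted per-vertex normals
#'
#' Face normals (weighted by twice the triangle area) accumulated on the
#' three corner vertices and normalized. Isolated vertices get (0, 0, 1).
#'
#' @param mesh a [LabeledMesh-class].
#' @return numeric N x 3 matrix of unit normals.
#' @export
vertexNormals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  n <- matrix(0, nrow(v), 3)
  if (nrow(f) > 0) {
    a <- v[f[, 1], , drop = FALSE]
    e1 <- v[f[, 2], , drop = FALSE] - a
    e2 <- v[f[, 3], , drop = FALSE] - a
    fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    g <- c(f[, 1], f[, 2], f[, 3])
    for (d in 1:3) {
      acc <- rowsum(rep(fn[, d], 3), g)
      idx <- as.integer(rownames(acc))
      n[idx, d] <- n[idx, d] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  zero <- len < 1e-12
  n[zero, ] <- rep(c(0, 0, 1), each = sum(zero))
  len[zero] <- 1
  n / len
}

#' Center and bounding-sphere radius of a mesh
#' @param mesh a [LabeledMesh-class].
#' @return list with \code{center} (length-3) and \code{radius} (mm).
#' @export
boundingSphere <- function(mesh) {
  v <- mesh@vertices
  ctr <- colMeans(v)
  list(center = ctr,
       radius = sqrt(max(rowSums(sweep(v, 2, ctr)^2))))
}
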