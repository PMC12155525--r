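# Software rendering of labeled textured meshes.
#
# A deliberate software rasterizer (barycentric coverage + z-buffer in C++)
# rather than an OpenGL dependency: renders are bit-reproducible across
# machines and CI. Texture and label images share one rasterization pass,
# so their coverage masks and pixel-to-face maps are identical by
# construction. Label images are flat and unlit with no anti-aliasing:
# each covered pixel takes the palette color of the label of the nearest
# vertex (largest barycentric weight) of its front face, so only exact
# palette colors ever appear.

#' Lighting configuration for texture renders
#'
#' Three modes: \code{glow} (raw vertex colors, shadow-free),
#' \code{ambient} (Lambertian with one directional light at infinity,
#' consistent parallel shading), and \code{spot} (Lambertian with
#' inverse-square falloff from two fixed spot positions whose intensity is
#' randomized per render).
#'
#' @param mode one of \code{"glow"}, \code{"ambient"}, \code{"spot"}.
#' @param direction directional-light unit vector (ambient mode).
#' @param spotPositions 2 x 3 matrix of spot light positions (mm).
#' @param spotIntensity length-2 intensities (spot mode).
#' @param floorLight ambient floor in [0, 1] so unlit faces stay visible.
#' @export
lightingConfig <- function(mode = c("glow", "ambient", "spot"),
                           direction = c(0.35, 0.25, 0.9),
                           spotPositions = rbind(c(-60, -60, 120),
                                                 c(60, 60, 120)),
                           spotIntensity = c(1, 1),
                           floorLight = 0.2) {
  mode <- match.arg(mode)
  list(mode = mode, direction = .unit(direction),
       spotPositions = spotPositions, spotIntensity = spotIntensity,
       floorLight = floorLight)
}

# per-vertex scalar shading factor in [0, 1]
.vertexShade <- function(mesh, lighting, normals = NULL) {
  if (lighting$mode == "glow") return(rep(1, nrow(mesh@vertices)))
  n <- if (is.null(normals)) vertexNormals(mesh) else normals
  if (lighting$mode == "ambient") {
    lam <- pmax(0, n %*% lighting$direction)
    pmin(1, lighting$floorLight + (1 - lighting$floorLight) * lam)
  } else {
    v <- mesh@vertices
    acc <- rep(0, nrow(v))
    att <- 100^2          # inverse-square falloff scale (mm^2)
    for (k in seq_len(nrow(lighting$spotPositions))) {
      dv <- t(lighting$spotPositions[k, ] - t(v))
      dist2 <- rowSums(dv^2)
      lam <- pmax(0, rowSums(n * dv / sqrt(dist2)))
      acc <- acc + lighting$spotIntensity[k] * lam * att / (att + dist2)
    }
    pmin(1, lighting$floorLight + (1 - lighting$floorLight) * acc)
  }
}

.renderCore <- function(mesh, pose) {
  pr <- projectPoints(pose, mesh@vertices)
  cpp_rasterize(pr$px, pr$py, pr$z, mesh@faces, pose@width, pose@height)
}

# assemble an H x W x 3 image from rasterizer output and per-vertex RGB
.composeImage <- function(ras, faces, rgb, interpolate) {
  H <- nrow(ras$face); W <- ncol(ras$face)
  img <- array(0, c(H, W, 3))
  hit <- which(ras$face > 0)
  if (length(hit)) {
    f <- ras$face[hit]
    i1 <- faces[f, 1]; i2 <- faces[f, 2]; i3 <- faces[f, 3]
    if (interpolate) {
      w1 <- ras$b1[hit]; w2 <- ras$b2[hit]; w3 <- 1 - w1 - w2
      for (ch in 1:3) {
        plane <- matrix(0, H, W)
        plane[hit] <- w1 * rgb[i1, ch] + w2 * rgb[i2, ch] + w3 * rgb[i3, ch]
        img[, , ch] <- plane
      }
    } else {
      # nearest vertex of the face in barycentric terms (no color mixing)
      w <- cbind(ras$b1[hit], ras$b2[hit], 1 - ras$b1[hit] - ras$b2[hit])
      pickCol <- max.col(w, ties.method = "first")
      near <- cbind(i1, i2, i3)[cbind(seq_along(hit), pickCol)]
      for (ch in 1:3) {
        plane <- matrix(0, H, W)
        plane[hit] <- rgb[near, ch]
        img[, , ch] <- plane
      }
    }
  }
  img
}

#' Render the texture view of a mesh
#'
#' Pinhole perspective projection with z-buffer hidden-surface removal and
#' per-vertex Gouraud shading under the given lighting mode. Returns a
#' [ViewRender-class] whose label plane is also filled (flat, unlit) so
#' that texture and label share the same rasterization.
#'
#' @param mesh a [LabeledMesh-class].
#' @param pose a [CameraPose-class].
#' @param lighting a [lightingConfig()]; default glow.
#' @param normals optional precomputed [vertexNormals()] matrix (an
#'   optimization for rendering many views of one mesh).
#' @return a [ViewRender-class].
#' @export
renderView <- function(mesh, pose, lighting = lightingConfig("glow"),
                       normals = NULL) {
  ras <- .renderCore(mesh, pose)
  shade <- .vertexShade(mesh, lighting, normals)
  tex <- .composeImage(ras, mesh@faces, (mesh@color / 255) * shade,
                       interpolate = TRUE)
  pal <- schemePalette(mesh@scheme) / 255
  lrgb <- pal[match(mesh@label, as.integer(rownames(pal))), , drop = FALSE]
  lab <- .composeImage(ras, mesh@faces, lrgb, interpolate = FALSE)
  depth <- ras$depth
  new("ViewRender", texture = tex, label = lab, depth = depth,
      pix2face = ras$face, pose = pose)
}

#' Render the label image of a mesh
#'
#' Same projection and depth buffer as [renderView()], but only the label
#' plane is meaningful: flat palette colors of the nearest vertex of each
#' covered face, no lighting, no anti-aliasing, black background.
#' @param mesh a [LabeledMesh-class].
#' @param pose a [CameraPose-class].
#' @return a [ViewRender-class].
#' @export
renderLabelImage <- function(mesh, pose) {
  renderView(mesh, pose, lightingConfig("glow"))
}

setMethod("show", "ViewRender", function(object) {
  cat(sprintf("ViewRender %dx%d, %.1f%% covered\n",
              object@pose@height, object@pose@width,
              100 * mean(object@pix2face > 0)))
})

#' @describeIn ViewRender-class the texture raster (H x W x 3, [0,1]).
#' @param view a [ViewRender-class].
#' @export
textureImage <- function(view) view@texture

#' @describeIn ViewRender-class the label raster (H x W x 3, [0,1]).
#' @export
labelImage <- function(view) view@label

#' @describeIn ViewRender-class the depth buffer (Inf = background).
#' @export
depthBuffer <- function(view) view@depth

#' @describeIn ViewRender-class per-pixel 1-based face ids (0 = background).
#' @export
pixelFaceMap <- function(view) view@pix2face

#' Decode a label raster into a class-id matrix
#'
#' @param img H x W x 3 array in [0,1] (as stored in a [ViewRender-class]
#'   or read from a label PNG).
#' @param scheme a [LabelScheme-class].
#' @return integer H x W matrix of class ids; background decodes to void.
#' @export
decodeLabelImage <- function(img, scheme) {
  cols <- round(cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                      as.vector(img[, , 3])) * 255)
  ids <- labelsFromColors(cols, scheme)
  matrix(ids, nrow = dim(img)[1])
}
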