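# Paired texture/label 2D dataset generation and label statistics.

.deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647)
}

#' Rebuild a CameraPose from a manifest row
#' @param row one row of a dataset manifest.
#' @export
poseFromManifestRow <- function(row) {
  cameraPose(position = c(row$pos_x, row$pos_y, row$pos_z),
             lookAt = c(row$look_x, row$look_y, row$look_z),
             roll = row$roll, focal = row$focal,
             width = row$width, height = row$height)
}

#' Generate a paired 2D texture/label dataset from labeled meshes
#'
#' For every mesh, \code{nViewsPerMesh} camera poses are sampled on the
#' hemisphere above it (radius = \code{radiusFactor} times the bounding
#' sphere radius) and a paired texture and label image is rendered for
#' each: lighting mode drawn from \code{lightingModes} with randomized spot
#' intensity, perspective randomized via \code{fovJitter}. Images are
#' written as lossless PNG (palette colors survive exactly) and every pair
#' is recorded in \code{manifest.csv} with its full pose.
#'
#' @param meshes named list of [LabeledMesh-class] (names become scan ids).
#' @param nViewsPerMesh views per mesh.
#' @param outDir output directory (created if needed).
#' @param lightingModes subset of glow/ambient/spot to randomize over.
#' @param seed global RNG seed; per-scan seeds are derived from it.
#' @param width,height image size in pixels.
#' @param focal nominal focal length in pixels (before jitter); default
#'   0.85 * width, see [sampleCameraPoses()].
#' @param fovJitter perspective-distortion amplitude.
#' @param radiusFactor hemisphere radius in bounding-sphere radii.
#' @param minElevation minimum camera elevation (degrees).
#' @param elevationRange,azimuthRange,rollRange optional pose restrictions,
#'   see [sampleCameraPoses()].
#' @return the manifest \code{data.frame} (one row per image pair).
#' @export
generateDataset <- function(meshes, nViewsPerMesh, outDir,
                            lightingModes = c("glow", "ambient", "spot"),
                            seed = 1L, width = 256L, height = 256L,
                            focal = NULL, fovJitter = 0.15, radiusFactor = 2.5,
                            minElevation = 15, elevationRange = NULL,
                            azimuthRange = c(0, 360),
                            rollRange = c(0, 360)) {
  if (length(meshes) < 1L) stop("need at least one mesh")
  if (is.null(names(meshes))) {
    names(meshes) <- sprintf("scan%03d", seq_along(meshes))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)

  rows <- vector("list", length(meshes) * nViewsPerMesh)
  r <- 0L
  for (i in seq_along(meshes)) {
    mesh <- meshes[[i]]
    id <- names(meshes)[i]
    bs <- boundingSphere(mesh)
    sd_i <- .deriveSeed(seed, i)
    poses <- sampleCameraPoses(nViewsPerMesh, seed = sd_i,
                               radius = radiusFactor * bs$radius,
                               center = bs$center, width = width,
                               height = height, focal = focal,
                               minElevation = minElevation,
                               elevationRange = elevationRange,
                               azimuthRange = azimuthRange,
                               rollRange = rollRange, fovJitter = fovJitter)
    light <- .withSeed(.deriveSeed(seed, i + 100000L), list(
      mode = sample(lightingModes, nViewsPerMesh, replace = TRUE),
      spot = matrix(stats::runif(2 * nViewsPerMesh, 0.5, 1.5), ncol = 2)
    ))
    normals <- vertexNormals(mesh)
    for (v in seq_len(nViewsPerMesh)) {
      lc <- lightingConfig(light$mode[v], spotIntensity = light$spot[v, ])
      view <- renderView(mesh, poses[[v]], lc, normals = normals)
      texPath <- file.path(outDir, sprintf("%s_v%03d_tex.png", id, v))
      labPath <- file.path(outDir, sprintf("%s_v%03d_lab.png", id, v))
      png::writePNG(view@texture, texPath)
      png::writePNG(view@label, labPath)
      p <- poses[[v]]
      r <- r + 1L
      rows[[r]] <- data.frame(
        mesh = id, view = v, texture = texPath, label = labPath,
        lighting = light$mode[v],
        spot1 = light$spot[v, 1], spot2 = light$spot[v, 2],
        pos_x = p@position[1], pos_y = p@position[2], pos_z = p@position[3],
        look_x = p@lookAt[1], look_y = p@lookAt[2], look_z = p@lookAt[3],
        roll = p@roll, focal = p@focal, width = p@width, height = p@height,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a dataset manifest written by [generateDataset()]
#' @param path the manifest CSV (or the dataset directory containing it).
#' @export
readManifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pixel-per-vertex statistics of a rendered dataset
#'
#' For every label: total pixels over all label images of the manifest,
#' total vertices over all meshes, and their ratio. Projection sampling is
#' unbiased when the ratios are nearly constant across labels, so the
#' summary reports the mean and SD of the ratios over labels that appear
#' in both counts; labels rendered nowhere are reported with zero counts
#' and excluded from the summary.
#'
#' @param manifest a dataset manifest (see [generateDataset()]).
#' @param meshes the named list of meshes the dataset was generated from.
#' @param scheme a [LabelScheme-class].
#' @return list with \code{table} (per-label counts and ratio),
#'   \code{meanRatio} and \code{sdRatio}.
#' @export
labelPixelStats <- function(manifest, meshes, scheme = defaultLabelScheme()) {
  ids <- scheme@entries$id
  pix <- stats::setNames(numeric(length(ids)), ids)
  for (k in seq_len(nrow(manifest))) {
    img <- png::readPNG(manifest$label[k])
    lab <- decodeLabelImage(img, scheme)
    tab <- table(lab)
    pix[names(tab)] <- pix[names(tab)] + as.numeric(tab)
  }
  vert <- stats::setNames(numeric(length(ids)), ids)
  for (m in meshes) {
    tab <- table(m@label)
    vert[names(tab)] <- vert[names(tab)] + as.numeric(tab)
  }
  # background pixels are not vertex-backed; the void row reports mesh
  # void vertices against rendered void+background pixels and is kept in
  # the table but judged like any other zero-guarded label
  ratio <- ifelse(vert > 0, pix / vert, NA_real_)
  ok <- vert > 0 & pix > 0
  tab <- data.frame(id = ids, name = scheme@entries$name,
                    pixels = as.numeric(pix), vertices = as.numeric(vert),
                    ratio = ratio, included = ok,
                    stringsAsFactors = FALSE)
  list(table = tab,
       meanRatio = mean(ratio[ok]),
       sdRatio = stats::sd(ratio[ok]))
}
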