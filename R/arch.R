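# Synthetic maxillary arch generator.
#
# Stands in for clinical intraoral scans: a palatal dome (polar grid bowl)
# with a ridged rugae patch on the anterior midline, and one superellipsoid
# crown per tooth class arranged on a parabolic arch curve. Axes: +x
# anterior, +y patient-left, +z occlusal (up, toward the cameras). No
# anatomical realism is claimed; the generator provides separable labeled
# blobs with texture contrast, known landmarks, and exact ground truth for
# motion experiments.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Parameters of the synthetic arch generator
#'
#' @param nTeeth number of teeth, 0 to 16. The 16 permanent classes are laid
#'   out along the arch (right third molar through left third molar); the
#'   middle \code{nTeeth} slots are populated, so the default 14 is the full
#'   permanent dentition excluding third molars.
#' @param archWidth intermolar width (mm).
#' @param archDepth anterior-posterior arch depth (mm).
#' @param toothScale global scale factor on the per-class crown presets.
#' @param rugaeRidgeCount number of transverse rugae ridges.
#' @param rugaeAmplitude ridge amplitude (mm).
#' @param meshResolution approximate total vertex count.
#' @param colorNoise texture color jitter SD (0-255 scale).
#' @param seed integer RNG seed.
#' @return a list of class parameters for [generateArch()].
#' @export
archParams <- function(nTeeth = 14L, archWidth = 34, archDepth = 30,
                       toothScale = 1, rugaeRidgeCount = 4L,
                       rugaeAmplitude = 0.5, meshResolution = 4000L,
                       colorNoise = 6, seed = 1L) {
  if (nTeeth < 0L || nTeeth > 16L) stop("nTeeth must be in [0, 16]")
  if (archWidth <= 0 || archDepth <= 0 || toothScale <= 0) {
    stop("length parameters must be positive")
  }
  if (meshResolution <= 0) stop("meshResolution must be positive")
  list(nTeeth = as.integer(nTeeth), archWidth = archWidth,
       archDepth = archDepth, toothScale = toothScale,
       rugaeRidgeCount = as.integer(rugaeRidgeCount),
       rugaeAmplitude = rugaeAmplitude,
       meshResolution = as.integer(meshResolution),
       colorNoise = colorNoise, seed = as.integer(seed))
}

# crown semi-axes (mm): thickness (x'), width along arch (y'), height (z)
.crownPreset <- function(name) {
  if (grepl("third molar", name))            c(3.0, 3.4, 4.2)
  else if (grepl("molar", name))             c(3.4, 3.8, 4.8)
  else if (grepl("bicuspid", name))          c(2.8, 3.0, 5.0)
  else if (grepl("canine", name))            c(2.2, 2.6, 5.5)
  else if (grepl("central incisor", name))   c(1.7, 3.4, 5.2)
  else                                       c(1.6, 2.8, 4.8)  # lateral incisor
}

# superellipsoid crown grid with an apex vertex closing the top; a buccal
# bulge (egg-shaped cross-section) and an offset apex break the 180-degree
# symmetry a plain superellipsoid would have, as real crowns do -- without
# this, per-tooth rigid registration would be ambiguous up to a half turn
.superellipsoid <- function(center, semi, zrot, nu, nv, e1 = 0.9, e2 = 0.7) {
  spow <- function(w, e) sign(w) * abs(w)^e
  u <- seq(-1.15, 1.38, length.out = nu)
  v <- seq(0, 2 * pi, length.out = nv + 1L)[seq_len(nv)]
  cu <- spow(cos(u), e1); su <- spow(sin(u), e1)
  cv <- spow(cos(v), e2); sv <- spow(sin(v), e2)
  bulge <- 1 + 0.15 * cos(v)
  x <- semi[1] * outer(cu, cv * bulge)
  y <- semi[2] * outer(cu, sv * bulge)
  z <- semi[3] * matrix(su, nu, nv)
  verts <- cbind(as.vector(x), as.vector(y), as.vector(z))
  verts <- rbind(verts, c(0.15 * semi[1], 0, semi[3]))   # offset apex
  cz <- cos(zrot); sz <- sin(zrot)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  verts <- sweep(verts %*% t(Rz), 2, center, "+")

  idx <- function(j, k) (k - 1L) * nu + j        # column-major grid index
  faces <- list()
  for (k in seq_len(nv)) {
    k2 <- if (k == nv) 1L else k + 1L
    j <- seq_len(nu - 1L)
    faces[[length(faces) + 1L]] <- cbind(idx(j, k), idx(j + 1L, k), idx(j + 1L, k2))
    faces[[length(faces) + 1L]] <- cbind(idx(j, k), idx(j + 1L, k2), idx(j, k2))
  }
  apex <- nu * nv + 1L
  ktop <- seq_len(nv)
  k2top <- c(seq_len(nv)[-1], 1L)
  faces[[length(faces) + 1L]] <- cbind(idx(nu, ktop), rep(apex, nv), idx(nu, k2top))
  list(vertices = verts, faces = do.call(rbind, faces))
}

# polar-grid palatal bowl; returns vertices, faces, and the grid's (x, y)
.palateDome <- function(cx, sx, sy, depth, nr, nth) {
  r <- seq(0, 1, length.out = nr + 1L)[-1]
  th <- seq(0, 2 * pi, length.out = nth + 1L)[seq_len(nth)]
  x <- cx + sx * outer(r, cos(th))
  y <- sy * outer(r, sin(th))
  z <- -depth * (1 - outer(r, rep(1, nth))^2)
  verts <- rbind(c(cx, 0, -depth),
                 cbind(as.vector(x), as.vector(y), as.vector(z)))
  idx <- function(i, k) 1L + (k - 1L) * nr + i     # ring i of nr, spoke k
  faces <- list()
  for (k in seq_len(nth)) {
    k2 <- if (k == nth) 1L else k + 1L
    faces[[length(faces) + 1L]] <- cbind(1L, idx(1L, k), idx(1L, k2))
    i <- seq_len(nr - 1L)
    faces[[length(faces) + 1L]] <- cbind(idx(i, k), idx(i + 1L, k), idx(i + 1L, k2))
    faces[[length(faces) + 1L]] <- cbind(idx(i, k), idx(i + 1L, k2), idx(i, k2))
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

# the 16 permanent classes in arch order, right third molar -> left third molar
.archSequence <- function(scheme) {
  perm <- c("third molar", "second molar", "first molar", "second bicuspid",
            "first bicuspid", "canine", "lateral incisor", "central incisor")
  labelId(scheme, c(paste("right", perm), paste("left", rev(perm))))
}

#' Generate a labeled synthetic maxillary arch with landmarks
#'
#' @param params an [archParams()] list.
#' @param scheme a [LabelScheme-class].
#' @return list with \code{mesh} (a [LabeledMesh-class]) and
#'   \code{landmarks} (named list of six on-surface points: two molar
#'   cusps, the incisor edge, and three median-raphae points of which the
#'   most anterior is the incisive papilla).
#' @examples
#' arch <- generateArch(archParams(nTeeth = 4, meshResolution = 1200))
#' arch$mesh
#' @export
generateArch <- function(params = archParams(), scheme = defaultLabelScheme()) {
  .withSeed(params$seed, {
    W <- params$archWidth; D <- params$archDepth
    A <- D / 2; B <- D          # arch parabola x = A - B t^2, t in [-1, 1]
    n <- params$nTeeth

    # palate sizing: interior of the arch, inset from the tooth row
    cxp <- A - B / 2 - 1
    sxp <- B / 2 + 2
    syp <- W / 2 - 3
    vPalate <- max(200L, as.integer(params$meshResolution * 0.45))
    nth <- max(16L, as.integer(round(sqrt(vPalate * 2.2))))
    nr <- max(8L, as.integer(round(vPalate / nth)))
    dome <- .palateDome(cxp, sxp, syp, depth = 9, nr = nr, nth = nth)

    # rugae patch: anterior midline of the palate, transverse sine ridges
    pv <- dome$vertices
    xr0 <- cxp + 0.25 * sxp
    xr1 <- cxp + 0.95 * sxp
    yr <- 0.55 * syp
    inRugae <- pv[, 1] > xr0 & pv[, 1] < xr1 & abs(pv[, 2]) < yr
    phase <- (pv[, 1] - xr0) / (xr1 - xr0)
    edge <- pmin(1, 3 * pmin(phase, 1 - phase, na.rm = TRUE)) *
            pmin(1, 3 * (1 - abs(pv[, 2]) / yr))
    ridge <- params$rugaeAmplitude *
             sin(2 * pi * params$rugaeRidgeCount * phase) * pmax(0, edge)
    pv[inRugae, 3] <- pv[inRugae, 3] + ridge[inRugae]
    dome$vertices <- pv

    verts <- dome$vertices
    faces <- dome$faces
    labels <- ifelse(inRugae, rugaeLabel(scheme), voidLabel(scheme))

    # teeth on the arch curve: middle n of the 16 class slots, placed by
    # arc length with width-proportional slots so neighboring crowns do
    # not interpenetrate
    seqIds <- .archSequence(scheme)
    slots <- seq_len(16L)
    used <- if (n > 0L) slots[(16L - n) %/% 2L + seq_len(n)] else integer()
    tt <- seq(-1, 1, length.out = 801L)
    xc <- A - B * tt^2
    yc <- (W / 2) * tt
    seg <- sqrt(diff(xc)^2 + diff(yc)^2)
    arc <- c(0, cumsum(seg))
    L <- arc[length(arc)]
    presets <- t(vapply(seqIds, function(id)
      .crownPreset(labelName(scheme, id)), numeric(3))) * params$toothScale
    wSlot <- 2 * presets[, 2]
    f <- min(1, 0.8 * L / sum(wSlot))          # shrink crowns to fit the arch
    presets[, 1:2] <- presets[, 1:2] * f
    wSlot <- wSlot * f
    gap <- (L - sum(wSlot)) / 17
    sCenter <- gap * slots + cumsum(wSlot) - wSlot / 2
    tSlot <- stats::approx(arc, tt, xout = sCenter)$y

    vTooth <- max(60L, as.integer(params$meshResolution * 0.55 / max(1L, n)))
    nv <- max(8L, as.integer(round(sqrt(vTooth * 2))))
    nu <- max(6L, as.integer(round(vTooth / nv)))

    for (s in used) {
      id <- seqIds[s]
      t <- tSlot[s]
      ctr <- c(A - B * t^2, (W / 2) * t, 1.2)
      tangent <- atan2(W / 2, -2 * B * t)           # (dy/dt, dx/dt)
      semi <- presets[s, ]
      se <- .superellipsoid(ctr, semi, tangent - pi / 2, nu, nv)
      faces <- rbind(faces, se$faces + nrow(verts))
      verts <- rbind(verts, se$vertices)
      labels <- c(labels, rep(id, nrow(se$vertices)))
    }

    # texture: pink mucosa, whitish enamel, per-vertex noise
    isTooth <- labels %in% toothLabels(scheme)
    base <- matrix(0, nrow(verts), 3)
    base[!isTooth, ] <- rep(c(225, 130, 120), each = sum(!isTooth))
    base[isTooth, ] <- rep(c(235, 228, 210), each = sum(isTooth))
    col <- base + matrix(stats::rnorm(3 * nrow(verts), 0, params$colorNoise),
                         ncol = 3)
    col[col < 0] <- 0
    col[col > 255] <- 255

    mesh <- LabeledMesh(verts, faces, color = col, label = labels,
                        scheme = scheme)

    # landmarks on generated geometry
    lm <- list()
    vt <- verts
    if (length(used) >= 2L) {
      rightIds <- seqIds[used[used <= 8L]]
      leftIds <- seqIds[used[used > 8L]]
      pickTop <- function(ids) {
        sel <- which(labels %in% ids)
        sel[which.max(vt[sel, 3])]
      }
      lm$molar_cusp_right <- vt[pickTop(rightIds[1]), ]
      lm$molar_cusp_left <- vt[pickTop(leftIds[length(leftIds)]), ]
      frontSlot <- used[which.min(abs(tSlot[used]))]
      lm$incisor_edge <- vt[pickTop(seqIds[frontSlot]), ]
    } else {
      # toothless arch: use palate rim points so the frame stays defined
      rim <- which(abs(pv[, 3]) < 1e-6)
      lm$molar_cusp_right <- vt[rim[which.min(pv[rim, 2])], ]
      lm$molar_cusp_left <- vt[rim[which.max(pv[rim, 2])], ]
      lm$incisor_edge <- vt[rim[which.max(pv[rim, 1])], ]
    }
    rugIdx <- which(inRugae & abs(pv[, 2]) < 1.5)
    ord <- rugIdx[order(pv[rugIdx, 1], decreasing = TRUE)]
    pickAt <- c(1L, as.integer(length(ord) / 2), length(ord))
    lm$incisive_papilla <- vt[ord[pickAt[1]], ]
    lm$raphae_mid <- vt[ord[pickAt[2]], ]
    lm$raphae_posterior <- vt[ord[pickAt[3]], ]

    list(mesh = mesh, landmarks = lm)
  })
}

#' Apply known per-tooth rigid motions to a labeled mesh
#'
#' Vertices of each listed tooth are transformed by its matrix; rugae
#' vertices are never moved (they are the stable reference). Void (mucosa)
#' vertices can optionally be displaced by a smooth low-amplitude
#' radial-basis deformation that vanishes on the rugae patch, emulating
#' soft-tissue change between scans.
#'
#' @param mesh a [LabeledMesh-class].
#' @param motions named list of [RigidTransform-class] (or 4 x 4 matrices);
#'   names are tooth class names or label ids present in the mesh.
#' @param mucosaWobble deformation amplitude for void vertices (mm).
#' @param seed RNG seed for the wobble field.
#' @return the deformed [LabeledMesh-class].
#' @export
applyToothMotion <- function(mesh, motions, mucosaWobble = 0, seed = 1L) {
  scheme <- mesh@scheme
  teeth <- toothLabels(scheme)
  v <- mesh@vertices
  for (key in names(motions)) {
    id <- suppressWarnings(as.integer(key))
    if (is.na(id)) id <- labelId(scheme, key)
    if (!id %in% teeth) {
      stop("'", key, "' is not a tooth class (rugae and void cannot move)")
    }
    sel <- mesh@label == id
    if (!any(sel)) stop("tooth '", key, "' is not present in the mesh")
    v[sel, ] <- transformPoints(motions[[key]], v[sel, , drop = FALSE])
  }
  if (mucosaWobble > 0) {
    .withSeed(seed, {
      void <- mesh@label == voidLabel(scheme)
      if (any(void)) {
        ctr <- v[sample(which(void), min(6L, sum(void))), , drop = FALSE]
        amp <- matrix(stats::rnorm(3 * nrow(ctr), 0, mucosaWobble), ncol = 3)
        sigma <- 6
        disp <- matrix(0, sum(void), 3)
        for (k in seq_len(nrow(ctr))) {
          w <- exp(-rowSums(sweep(v[void, , drop = FALSE], 2, ctr[k, ])^2) /
                     (2 * sigma^2))
          disp <- disp + outer(w, amp[k, ])
        }
        v[void, ] <- v[void, ] + disp
      }
    })
  }
  mesh@vertices <- v
  mesh
}

#' Add scanner-like noise along vertex normals
#'
#' I.i.d. Gaussian displacement of every vertex along its normal; labels,
#' faces and colors are untouched.
#' @param mesh a [LabeledMesh-class].
#' @param sigma noise SD (mm), >= 0.
#' @param seed RNG seed.
#' @export
addScanNoise <- function(mesh, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(mesh)
  .withSeed(seed, {
    n <- vertexNormals(mesh)
    mesh@vertices <- mesh@vertices +
      n * stats::rnorm(nrow(mesh@vertices), 0, sigma)
    mesh
  })
}
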