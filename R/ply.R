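# PLY I/O for textured, labeled triangle meshes.
# Supports the two dialects intraoral-scan tooling emits: ascii 1.0 and
# binary_little_endian 1.0, with per-vertex x/y/z + uchar red/green/blue and
# triangle faces. Coordinates are written at full double precision (ascii
# %.17g, binary float64) so write/read roundtrips are exact.

# write lines with "\n" endings regardless of platform
.writeTextLines <- function(con, lines) {
  writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL)
}

.plyTypeSize <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                  float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.plyReadWhat <- function(type) {
  if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
}

.parsePlyHeader <- function(lines) {
  if (length(lines) < 2L || lines[1] != "ply") stop("not a PLY file")
  fmt <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (fmt[1] != "format" || !fmt[2] %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", paste(fmt[-1], collapse = " "))
  }
  elements <- list()
  cur <- NULL
  for (ln in lines[-(1:2)]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property outside an element")
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, countType = tok[3], type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") break
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  list(format = fmt[2], elements = elements)
}

#' Read a textured mesh from a PLY file
#'
#' Reads ascii or binary_little_endian PLY with per-vertex positions and RGB
#' colors and triangular faces. When \code{scheme} is supplied the label
#' channel is decoded from the vertex colors via [labelsFromColors()]
#' (exact palette match); otherwise all vertices are labeled void.
#'
#' @param path path to a .ply file.
#' @param scheme optional [LabelScheme-class] used to decode label colors.
#' @return a [LabeledMesh-class].
#' @export
readPLY <- function(path, scheme = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("PLY header has no end_header")
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  hd <- .parsePlyHeader(header)
  ve <- hd$elements[["vertex"]]
  fe <- hd$elements[["face"]]
  if (is.null(ve)) stop("PLY has no vertex element")
  need <- c("x", "y", "z", "red", "green", "blue")
  if (!all(need %in% names(ve$props))) {
    stop("PLY vertex element lacks required properties: ",
         paste(setdiff(need, names(ve$props)), collapse = ", "))
  }

  if (hd$format == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    vlines <- body[seq_len(ve$count)]
    vtok <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                   nrow = ve$count, byrow = TRUE)
    colnames(vtok) <- names(ve$props)
    nf <- if (is.null(fe)) 0L else fe$count
    faces <- matrix(integer(), 0L, 3L)
    if (nf > 0L) {
      flines <- body[ve$count + seq_len(nf)]
      ftok <- strsplit(trimws(flines), "\\s+")
      cnt <- vapply(ftok, function(t) as.integer(t[1]), 1L)
      if (any(cnt != 3L)) stop("non-triangle faces are not supported")
      faces <- t(vapply(ftok, function(t) as.integer(t[2:4]), integer(3))) + 1L
    }
  } else {
    # binary little-endian: vertices are fixed-size records
    sizes <- vapply(ve$props, function(p) .plyTypeSize[[p$type]], 1L)
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = rec * ve$count)
    rmat <- matrix(raw, nrow = rec)
    off <- cumsum(c(0L, sizes[-length(sizes)]))
    names(off) <- names(ve$props)
    vals <- lapply(names(ve$props), function(p) {
      s <- sizes[[p]]
      bytes <- as.vector(rmat[off[[p]] + seq_len(s), , drop = FALSE])
      readBin(bytes, .plyReadWhat(ve$props[[p]]$type), n = ve$count,
              size = s, endian = "little",
              signed = !(ve$props[[p]]$type %in% c("uchar", "uint8", "ushort", "uint16")))
    })
    vtok <- do.call(cbind, vals)
    colnames(vtok) <- names(ve$props)
    faces <- matrix(integer(), 0L, 3L)
    if (!is.null(fe) && fe$count > 0L) {
      lp <- fe$props[[1]]
      cs <- .plyTypeSize[[lp$countType]]
      is <- .plyTypeSize[[lp$type]]
      frec <- cs + 3L * is
      fraw <- readBin(con, "raw", n = frec * fe$count)
      if (length(fraw) < frec * fe$count) stop("truncated PLY face data")
      fmat <- matrix(fraw, nrow = frec)
      cnt <- readBin(as.vector(fmat[seq_len(cs), , drop = FALSE]), "integer",
                     n = fe$count, size = cs, endian = "little", signed = FALSE)
      if (any(cnt != 3L)) stop("non-triangle faces are not supported")
      idx <- readBin(as.vector(fmat[cs + seq_len(3L * is), , drop = FALSE]),
                     "integer", n = 3L * fe$count, size = is, endian = "little")
      faces <- matrix(idx, ncol = 3L, byrow = TRUE) + 1L
    }
  }

  verts <- vtok[, c("x", "y", "z"), drop = FALSE]
  cols <- vtok[, c("red", "green", "blue"), drop = FALSE]
  if (is.null(scheme)) {
    mesh <- LabeledMesh(verts, faces, color = cols)
  } else {
    mesh <- LabeledMesh(verts, faces, color = cols, scheme = scheme,
                        label = labelsFromColors(cols, scheme))
  }
  mesh
}

#' Write a mesh to a PLY file
#'
#' @param mesh a [LabeledMesh-class].
#' @param path output path.
#' @param binary write binary_little_endian (default ascii).
#' @param encodeLabels if \code{TRUE}, vertex colors are the scheme palette
#'   colors of the labels instead of the texture colors, so the label
#'   channel survives the file format.
#' @return \code{path}, invisibly.
#' @export
writePLY <- function(mesh, path, binary = FALSE, encodeLabels = FALSE) {
  v <- mesh@vertices
  f <- mesh@faces
  cols <- if (encodeLabels) {
    pal <- schemePalette(mesh@scheme)
    pal[match(mesh@label, as.integer(rownames(pal))), , drop = FALSE]
  } else {
    round(mesh@color)
  }
  storage.mode(cols) <- "integer"
  if (any(cols < 0L | cols > 255L)) stop("colors must be in [0, 255]")
  header <- c(
    "ply",
    paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
    paste("element vertex", nrow(v)),
    paste("property double", c("x", "y", "z")),
    paste("property uchar", c("red", "green", "blue")),
    paste("element face", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  .writeTextLines(con, header)
  if (binary) {
    if (nrow(v) > 0L) {
      dbytes <- matrix(writeBin(as.double(t(v)), raw(), size = 8,
                                endian = "little"), nrow = 24L)
      cbytes <- matrix(as.raw(t(cols)), nrow = 3L)
      writeBin(as.vector(rbind(dbytes, cbytes)), con)
    }
    if (nrow(f) > 0L) {
      ibytes <- matrix(writeBin(as.integer(t(f) - 1L), raw(), size = 4,
                                endian = "little"), nrow = 12L)
      cnt <- matrix(rep(as.raw(3L), nrow(f)), nrow = 1L)
      writeBin(as.vector(rbind(cnt, ibytes)), con)
    }
  } else {
    vl <- paste(formatC(v[, 1], digits = 17, format = "g"),
                formatC(v[, 2], digits = 17, format = "g"),
                formatC(v[, 3], digits = 17, format = "g"),
                cols[, 1], cols[, 2], cols[, 3])
    .writeTextLines(con, vl)
    if (nrow(f) > 0L) {
      .writeTextLines(con, paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
    }
  }
  invisible(path)
}

#' Write landmark points as a small text file
#'
#' One line per landmark: \code{name x y z}, whitespace separated.
#' @param landmarks a named list of length-3 numeric points.
#' @param path output path.
#' @export
writeLandmarks <- function(landmarks, path) {
  ln <- vapply(names(landmarks), function(nm) {
    p <- landmarks[[nm]]
    paste(nm, formatC(p[1], digits = 17, format = "g"),
          formatC(p[2], digits = 17, format = "g"),
          formatC(p[3], digits = 17, format = "g"))
  }, "")
  writeLines(ln, path)
  invisible(path)
}

#' Read a landmark file written by [writeLandmarks()]
#' @param path path to the landmark text file.
#' @return named list of length-3 numeric points.
#' @export
readLandmarks <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  out <- list()
  for (l in ln) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    out[[tok[1]]] <- as.numeric(tok[2:4])
  }
  out
}
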