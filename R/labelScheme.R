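#' The canonical 28-class label scheme
#'
#' Builds the fixed labeling scheme used throughout the package: 26 tooth
#' classes (16 permanent including third molars, 10 primary), one rugae
#' class and one void class covering gingiva and background. The right
#' central incisor is colored RGB \code{[85,85,0]} and void is black
#' \code{[0,0,0]}. The remaining 26 palette colors are assigned
#' deterministically from the 4-level lattice \code{{0,85,170,255}^3},
#' taking every other lattice point so consecutive classes are well
#' separated in RGB; the exact values are a package convention, chosen once
#' and stable across versions.
#'
#' @return a [LabelScheme-class] with 28 entries.
#' @examples
#' sch <- defaultLabelScheme()
#' nrow(schemeEntries(sch))   # 28
#' @export
defaultLabelScheme <- function() {
  sides <- c("left", "right")
  perm <- c("central incisor", "lateral incisor", "canine",
            "first bicuspid", "second bicuspid", "first molar",
            "second molar", "third molar")
  prim <- c("primary central incisor", "primary lateral incisor",
            "primary canine", "first primary molar", "second primary molar")
  names <- c(
    paste("left", perm), paste("right", perm),
    paste("left", prim), paste("right", prim),
    "rugae", "background"
  )
  roles <- c(
    rep("permanent-tooth", 7), "third-molar",
    rep("permanent-tooth", 7), "third-molar",
    rep("primary-tooth", 10), "rugae", "void"
  )
  ids <- c(1:27, 0L)

  # palette: 4-level lattice, stride-2 walk, reserved colors pinned
  lv <- c(0L, 85L, 170L, 255L)
  lattice <- as.matrix(expand.grid(r = lv, g = lv, b = lv))
  reserved <- c("0 0 0", "85 85 0")
  key <- paste(lattice[, 1], lattice[, 2], lattice[, 3])
  pool <- lattice[!(key %in% reserved), , drop = FALSE]
  pick <- pool[seq(1L, nrow(pool), by = 2L)[1:26], , drop = FALSE]

  cols <- matrix(0L, nrow = 28, ncol = 3)
  free <- setdiff(seq_len(27), 9L)       # entry 9 = right central incisor
  cols[free, ] <- pick
  cols[9, ] <- c(85L, 85L, 0L)
  cols[28, ] <- c(0L, 0L, 0L)

  new("LabelScheme", entries = data.frame(
    id = ids, name = names, role = roles,
    r = cols[, 1], g = cols[, 2], b = cols[, 3],
    stringsAsFactors = FALSE
  ))
}

#' @describeIn LabelScheme-class the entry table (id, name, role, r, g, b).
#' @param scheme a [LabelScheme-class].
#' @export
schemeEntries <- function(scheme) scheme@entries

#' Palette matrix of a scheme
#'
#' @param scheme a [LabelScheme-class].
#' @return integer matrix with one RGB row per entry, rownames = label ids.
#' @export
schemePalette <- function(scheme) {
  e <- scheme@entries
  m <- cbind(e$r, e$g, e$b)
  rownames(m) <- e$id
  m
}

#' Label ids with a given anatomical role
#'
#' @param scheme a [LabelScheme-class].
#' @param roles character vector of roles, e.g. \code{"permanent-tooth"}.
#' @return integer vector of label ids.
#' @export
labelsWithRole <- function(scheme, roles) {
  as.integer(scheme@entries$id[scheme@entries$role %in% roles])
}

#' Ids of all tooth classes (permanent, third molar and primary)
#' @param scheme a [LabelScheme-class].
#' @export
toothLabels <- function(scheme) {
  labelsWithRole(scheme, c("permanent-tooth", "third-molar", "primary-tooth"))
}

#' The void (background + gingiva) label id
#' @param scheme a [LabelScheme-class].
#' @export
voidLabel <- function(scheme) labelsWithRole(scheme, "void")

#' The rugae label id
#' @param scheme a [LabelScheme-class].
#' @export
rugaeLabel <- function(scheme) labelsWithRole(scheme, "rugae")

#' Look up label ids by class name
#' @param scheme a [LabelScheme-class].
#' @param names character vector of class names.
#' @export
labelId <- function(scheme, names) {
  i <- match(names, scheme@entries$name)
  if (anyNA(i)) stop("unknown class name(s): ",
                     paste(names[is.na(i)], collapse = ", "))
  as.integer(scheme@entries$id[i])
}

#' Look up class names by label id
#' @param scheme a [LabelScheme-class].
#' @param ids integer vector of label ids.
#' @export
labelName <- function(scheme, ids) {
  i <- match(ids, scheme@entries$id)
  if (anyNA(i)) stop("unknown label id(s): ", paste(ids[is.na(i)], collapse = ", "))
  scheme@entries$name[i]
}

#' Decode per-vertex labels from palette colors
#'
#' Inverts the label-as-color encoding: each vertex color must match a
#' palette color of the scheme exactly (label renders are produced without
#' anti-aliasing, so any off-palette color indicates a bug and is an error,
#' never snapped to the nearest palette entry). Black decodes to void.
#'
#' @param x a [LabeledMesh-class], or an N x 3 color matrix in [0, 255].
#' @param scheme a [LabelScheme-class].
#' @return integer vector of label ids, one per vertex.
#' @export
labelsFromColors <- function(x, scheme) {
  cols <- if (is(x, "LabeledMesh")) x@color else x
  cols <- round(cols)
  pal <- schemePalette(scheme)
  key <- paste(cols[, 1], cols[, 2], cols[, 3])
  pkey <- paste(pal[, 1], pal[, 2], pal[, 3])
  i <- match(key, pkey)
  if (anyNA(i)) {
    bad <- unique(key[is.na(i)])
    stop("color(s) not in the scheme palette: [",
         paste(utils::head(bad, 5), collapse = "], ["), "]")
  }
  scheme@entries$id[i]
}

setMethod("show", "LabelScheme", function(object) {
  e <- object@entries
  cat("LabelScheme with", nrow(e), "classes:",
      sum(e$role %in% c("permanent-tooth", "third-molar")), "permanent,",
      sum(e$role == "primary-tooth"), "primary,",
      sum(e$role == "rugae"), "rugae,",
      sum(e$role == "void"), "void\n")
})
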