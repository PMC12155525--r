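test_that("default label scheme has the canonical 28 classes and colors", {
  e <- schemeEntries(scheme)
  expect_equal(nrow(e), 28L)
  expect_equal(sum(e$role %in% c("permanent-tooth", "third-molar")), 16L)
  expect_equal(sum(e$role == "primary-tooth"), 10L)
  expect_equal(unname(unlist(
    e[e$name == "right central incisor", c("r", "g", "b")])), c(85, 85, 0))
  expect_equal(unname(unlist(
    e[e$role == "void", c("r", "g", "b")])), c(0, 0, 0))
  # injective palette
  expect_false(anyDuplicated(paste(e$r, e$g, e$b)) > 0)
})

test_that("labels decode from palette colors exactly, with errors on off-palette", {
  n <- 5L
  cols <- matrix(rep(c(85, 85, 0), each = n), n, 3)
  expect_equal(labelsFromColors(cols, scheme),
               rep(labelId(scheme, "right central incisor"), n))
  expect_equal(labelsFromColors(matrix(0, n, 3), scheme),
               rep(voidLabel(scheme), n))
  cols[2, ] <- c(1, 2, 3)
  expect_error(labelsFromColors(cols, scheme), "1 2 3")
})

test_that("hand-written ascii PLY reads back field by field", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 3",
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "element face 1",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0 10 20 30",
    "1.5 0 0 40 50 60",
    "0 2.25 0.5 70 80 90",
    "3 0 1 2"
  ), path)
  m <- readPLY(path)
  expect_equal(meshVertices(m),
               rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 2.25, 0.5)))
  expect_equal(meshColors(m), rbind(c(10, 20, 30), c(40, 50, 60), c(70, 80, 90)))
  expect_equal(meshFaces(m), rbind(c(1L, 2L, 3L)))
})

test_that("PLY without a blue property is a format error", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 1",
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green",
    "end_header", "0 0 0 1 2"
  ), path)
  expect_error(readPLY(path), "blue")
})

test_that("PLY write/read roundtrips both dialects bit-exactly", {
  m <- smallArch()$mesh
  fa <- withr::local_tempfile(fileext = ".ply")
  fb <- withr::local_tempfile(fileext = ".ply")
  writePLY(m, fa, binary = FALSE, encodeLabels = TRUE)
  writePLY(m, fb, binary = TRUE, encodeLabels = TRUE)
  ma <- readPLY(fa, scheme)
  mb <- readPLY(fb, scheme)
  expect_identical(meshVertices(ma), meshVertices(m))
  expect_identical(meshVertices(mb), meshVertices(m))
  expect_identical(meshFaces(ma), meshFaces(m))
  expect_identical(meshLabels(ma), meshLabels(m))   # label channel survives
  expect_identical(meshLabels(mb), meshLabels(m))
  expect_identical(meshColors(ma), meshColors(mb))
})

test_that("writing labels as colors uses the palette", {
  m <- triangleMesh(label = rugaeLabel(scheme))
  f <- withr::local_tempfile(fileext = ".ply")
  writePLY(m, f, encodeLabels = TRUE)
  m2 <- readPLY(f)
  pal <- schemePalette(scheme)
  rug <- pal[rownames(pal) == as.character(rugaeLabel(scheme)), ]
  expect_true(all(t(meshColors(m2)) == rug))
})

test_that("invalid meshes are rejected by the class validity", {
  expect_error(LabeledMesh(rbind(c(0, 0, NA)), matrix(integer(), 0, 3)),
               "finite")
  expect_error(LabeledMesh(rbind(c(0, 0, 0)), rbind(c(1L, 2L, 3L))),
               "face indices")
  expect_error(LabeledMesh(rbind(c(0, 0, 0)), matrix(integer(), 0, 3),
                           label = 999L), "scheme")
})

test_that("an independent PLY reader agrees with ours on both dialects", {
  m <- smallArch()$mesh
  fa <- withr::local_tempfile(fileext = ".ply")
  fb <- withr::local_tempfile(fileext = ".ply")
  writePLY(m, fa, binary = FALSE)
  writePLY(m, fb, binary = TRUE)
  script <- paste(
    "import trimesh, sys, json",
    "out = []",
    "for p in sys.argv[1:]:",
    "    t = trimesh.load(p, process=False)",
    "    out.append([len(t.vertices), len(t.faces),",
    "                float(t.vertices.sum()), int(t.faces.sum())])",
    "print(json.dumps(out))", sep = "\n")
  res <- suppressWarnings(system2("python", c("-", fa, fb),
                                  input = script, stdout = TRUE,
                                  stderr = FALSE))
  parsed <- jsonlite::fromJSON(res[length(res)])
  for (k in 1:2) {
    expect_equal(parsed[k, 1], nrow(meshVertices(m)))
    expect_equal(parsed[k, 2], nrow(meshFaces(m)))
    expect_equal(parsed[k, 3], sum(meshVertices(m)), tolerance = 1e-9)
    expect_equal(parsed[k, 4], sum(meshFaces(m) - 1L))
  }
})
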