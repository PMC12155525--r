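# Pipeline orchestration: staged commands over a single YAML-style config,
# with derived per-stage seeds and a hash-stamped run manifest, so every
# stage is reproducible from the config alone.

#' Pipeline configuration
#'
#' Builds the full stage configuration from defaults, an optional YAML
#' file, and optional overrides (a nested list merged last). Every stage
#' seed is derived deterministically from the single global seed.
#'
#' @param path optional YAML config file.
#' @param overrides optional nested list merged over the file values.
#' @return nested config list.
#' @export
pipelineConfig <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    workDir = "palateseg-run",
    seed = 1L,
    generate = list(nScans = 3L, nTeeth = 14L, meshResolution = 4000L,
                    colorNoise = 6),
    render = list(nViews = 10L, width = 128L, height = 128L,
                  lightingModes = c("glow", "ambient", "spot"),
                  fovJitter = 0.15, minElevation = 15,
                  elevationRange = NULL, azimuthRange = c(0, 360),
                  rollRange = c(0, 360)),
    model = list(inputSize = 128L, nClasses = 28L,
                 channels = c(12L, 24L, 48L), attention = "end"),
    train = list(epochs = 20L, batchSize = 1L, learningRate = 1e-4,
                 decay = 0.995, fractions = c(0.8, 0.1, 0.1)),
    icp = list(maxIter = 100L, tol = 1e-10, trimFraction = 0)
  )
  .mergeList <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        .mergeList(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  if (!is.null(path)) cfg <- .mergeList(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- .mergeList(cfg, overrides)
  cfg
}

.stageSeed <- function(cfg, stage) {
  .deriveSeed(cfg$seed, match(stage, c("generate", "render", "train",
                                       "predict", "bake", "evaluate",
                                       "motion")))
}

.logStage <- function(stage, cfg, ...) {
  message(sprintf("[%s] seed=%d config=%s %s", stage, cfg$seed,
                  substr(digestConfig(cfg), 1, 8), paste(..., collapse = " ")))
}

#' Short stable hash of a config list
#' @param cfg a config list.
#' @export
digestConfig <- function(cfg) {
  raw <- serialize(cfg, NULL, version = 2)
  # small polynomial rolling hash, enough to stamp logs and manifests
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.appendRunManifest <- function(cfg, stage, files) {
  files <- files[file.exists(files)]
  rows <- data.frame(stage = stage, file = files,
                     md5 = as.character(tools::md5sum(files)),
                     config = digestConfig(cfg), stringsAsFactors = FALSE)
  path <- file.path(cfg$workDir, "run_manifest.csv")
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(rows)
}

#' Generate the synthetic scan set
#'
#' Writes one labeled PLY and one landmark file per synthetic scan, plus a
#' scan manifest, under \code{workDir/meshes}.
#' @param cfg a [pipelineConfig()].
#' @return the scan manifest data.frame.
#' @export
cmdGenerate <- function(cfg) {
  if (cfg$generate$nScans < 1) stop("config generate$nScans must be >= 1")
  .logStage("generate", cfg, cfg$generate$nScans, "scans")
  dir <- file.path(cfg$workDir, "meshes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(cfg$generate$nScans)) {
    ap <- archParams(nTeeth = cfg$generate$nTeeth,
                     meshResolution = cfg$generate$meshResolution,
                     colorNoise = cfg$generate$colorNoise,
                     seed = .deriveSeed(.stageSeed(cfg, "generate"), i))
    arch <- generateArch(ap)
    id <- sprintf("scan%03d", i)
    ply <- file.path(dir, paste0(id, ".ply"))
    lmk <- file.path(dir, paste0(id, "_landmarks.txt"))
    writePLY(arch$mesh, ply, encodeLabels = TRUE)
    writeLandmarks(arch$landmarks, lmk)
    rows[[i]] <- data.frame(mesh = id, ply = ply, landmarks = lmk,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "scans.csv"), row.names = FALSE)
  .appendRunManifest(cfg, "generate", c(manifest$ply, manifest$landmarks))
  manifest
}

.loadScans <- function(cfg) {
  path <- file.path(cfg$workDir, "meshes", "scans.csv")
  if (!file.exists(path)) {
    stop("missing scan manifest ", path, "; run cmdGenerate first")
  }
  scans <- utils::read.csv(path, stringsAsFactors = FALSE)
  sch <- defaultLabelScheme()
  meshes <- lapply(scans$ply, readPLY, scheme = sch)
  names(meshes) <- scans$mesh
  list(scans = scans, meshes = meshes)
}

#' Render the paired 2D dataset for all generated scans
#' @param cfg a [pipelineConfig()].
#' @return the dataset manifest.
#' @export
cmdRender <- function(cfg) {
  sc <- .loadScans(cfg)
  .logStage("render", cfg, length(sc$meshes), "scans x", cfg$render$nViews,
            "views")
  manifest <- generateDataset(
    sc$meshes, cfg$render$nViews, file.path(cfg$workDir, "images"),
    lightingModes = cfg$render$lightingModes,
    seed = .stageSeed(cfg, "render"),
    width = cfg$render$width, height = cfg$render$height,
    fovJitter = cfg$render$fovJitter,
    minElevation = cfg$render$minElevation,
    elevationRange = cfg$render$elevationRange,
    azimuthRange = cfg$render$azimuthRange,
    rollRange = cfg$render$rollRange)
  .appendRunManifest(cfg, "render",
                     file.path(cfg$workDir, "images", "manifest.csv"))
  manifest
}

#' Train the segmentation network on the rendered dataset
#' @param cfg a [pipelineConfig()].
#' @return list(model, history); the checkpoint goes to
#'   \code{workDir/model.rds}.
#' @export
cmdTrain <- function(cfg) {
  manPath <- file.path(cfg$workDir, "images", "manifest.csv")
  if (!file.exists(manPath)) {
    stop("missing dataset manifest ", manPath, "; run cmdRender first")
  }
  manifest <- readManifest(manPath)
  .logStage("train", cfg, nrow(manifest), "images")
  manifest <- splitByScan(manifest, cfg$train$fractions,
                          seed = .stageSeed(cfg, "train"))
  mcfg <- segnetConfig(inputSize = cfg$model$inputSize,
                       nClasses = cfg$model$nClasses,
                       channels = cfg$model$channels,
                       attention = cfg$model$attention)
  model <- buildSegNet(mcfg, seed = .stageSeed(cfg, "train"))
  samples <- samplesFromManifest(manifest, model)
  for (i in seq_along(samples)) samples[[i]]$split <- manifest$split[i]
  fit <- trainSegNet(model, samples,
                     trainConfig(epochs = cfg$train$epochs,
                                 batchSize = cfg$train$batchSize,
                                 learningRate = cfg$train$learningRate,
                                 decay = cfg$train$decay,
                                 seed = .stageSeed(cfg, "train")))
  saveSegNet(fit$model, file.path(cfg$workDir, "model.rds"))
  utils::write.csv(fit$history, file.path(cfg$workDir, "history.csv"),
                   row.names = FALSE)
  .appendRunManifest(cfg, "train", file.path(cfg$workDir, "history.csv"))
  fit
}

#' Predict label images for the test split
#' @param cfg a [pipelineConfig()].
#' @return prediction manifest (test rows with a \code{prediction} column).
#' @export
cmdPredict <- function(cfg) {
  model <- loadSegNet(file.path(cfg$workDir, "model.rds"))
  manifest <- splitByScan(readManifest(file.path(cfg$workDir, "images")),
                          cfg$train$fractions,
                          seed = .stageSeed(cfg, "train"))
  test <- manifest[manifest$split == "test", , drop = FALSE]
  .logStage("predict", cfg, nrow(test), "test images")
  dir <- file.path(cfg$workDir, "predictions")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  test$prediction <- vapply(seq_len(nrow(test)), function(k) {
    img <- png::readPNG(test$texture[k])
    pred <- predictSegNet(model, img)
    out <- file.path(dir, basename(sub("_tex", "_pred", test$texture[k])))
    png::writePNG(pred$image, out)
    out
  }, "")
  utils::write.csv(test, file.path(dir, "predictions.csv"), row.names = FALSE)
  .appendRunManifest(cfg, "predict", file.path(dir, "predictions.csv"))
  test
}

#' Bake predictions (or ground-truth renders) onto the test meshes
#'
#' For every test scan, back-projects the per-view label images onto the
#' mesh vertices, majority-votes, and writes the finalized labeled PLY
#' plus a per-class vertex IoU CSV against the ground truth. With
#' \code{oracle = TRUE} the ground-truth label renders stand in for
#' predictions, exercising the geometric pipeline independently of
#' training.
#'
#' @param cfg a [pipelineConfig()].
#' @param oracle use ground-truth label renders as predictions.
#' @return named list of per-scan results (labels, metrics).
#' @export
cmdBake <- function(cfg, oracle = FALSE) {
  sc <- .loadScans(cfg)
  predPath <- file.path(cfg$workDir, "predictions", "predictions.csv")
  if (oracle) {
    manifest <- readManifest(file.path(cfg$workDir, "images"))
    manifest$prediction <- manifest$label
  } else {
    if (!file.exists(predPath)) {
      stop("missing predictions ", predPath, "; run cmdPredict first")
    }
    manifest <- utils::read.csv(predPath, stringsAsFactors = FALSE)
  }
  .logStage("bake", cfg, if (oracle) "oracle" else "predicted",
            nrow(manifest), "views")
  dir <- file.path(cfg$workDir, "baked")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sch <- defaultLabelScheme()
  out <- list()
  for (id in unique(manifest$mesh)) {
    mesh <- sc$meshes[[id]]
    if (is.null(mesh)) stop("mesh ", id, " missing from the scan set")
    rows <- manifest[manifest$mesh == id, , drop = FALSE]
    obs <- lapply(seq_len(nrow(rows)), function(k) {
      pose <- poseFromManifestRow(rows[k, ])
      pred <- png::readPNG(rows$prediction[k])
      bakeView(mesh, pose, pred)
    })
    tally <- accumulateVotes(obs, sch)
    labels <- finalizeLabels(tally, sch)
    baked <- setMeshLabels(mesh, labels)
    ply <- file.path(dir, paste0(id, "_baked.ply"))
    writePLY(baked, ply, encodeLabels = TRUE)
    # never-observed vertices default to void; they are excluded from the
    # score, which covers vertices observed in at least one view
    m3 <- metrics3D(labels, mesh@label, sch, subset = tally$visibility > 0)
    writeMetrics3D(m3, file.path(dir, paste0(id, "_iou.csv")))
    out[[id]] <- list(labels = labels, visibility = tally$visibility,
                      metrics = m3)
  }
  .appendRunManifest(cfg, "bake", file.path(dir, paste0(unique(manifest$mesh),
                                                        "_baked.ply")))
  out
}

#' Evaluate test-split predictions against ground truth
#' @param cfg a [pipelineConfig()].
#' @return [datasetMetrics()] result; the per-class table goes to
#'   \code{workDir/metrics2d.csv}.
#' @export
cmdEvaluate <- function(cfg) {
  predPath <- file.path(cfg$workDir, "predictions", "predictions.csv")
  if (!file.exists(predPath)) {
    stop("missing predictions ", predPath, "; run cmdPredict first")
  }
  test <- utils::read.csv(predPath, stringsAsFactors = FALSE)
  .logStage("evaluate", cfg, nrow(test), "pairs")
  pairs <- lapply(seq_len(nrow(test)), function(k) {
    list(pred = png::readPNG(test$prediction[k]),
         truth = png::readPNG(test$label[k]))
  })
  dm <- datasetMetrics(pairs)
  writeMetricsCSV(dm, file.path(cfg$workDir, "metrics2d.csv"))
  .appendRunManifest(cfg, "evaluate", file.path(cfg$workDir, "metrics2d.csv"))
  dm
}

#' Estimate per-tooth motion between two segmented scans
#'
#' @param cfg a [pipelineConfig()].
#' @param prePly,postPly labeled PLY paths (labels encoded as colors).
#' @param preLandmarks,postLandmarks landmark file paths (optional).
#' @return a [ToothMotionReport-class]; the CSV goes to
#'   \code{workDir/motion.csv}.
#' @export
cmdMotion <- function(cfg, prePly, postPly,
                      preLandmarks = NULL, postLandmarks = NULL) {
  for (p in c(prePly, postPly)) {
    if (!file.exists(p)) stop("missing input mesh ", p)
  }
  sch <- defaultLabelScheme()
  pre <- readPLY(prePly, sch)
  post <- readPLY(postPly, sch)
  lmPre <- if (!is.null(preLandmarks)) readLandmarks(preLandmarks)
  lmPost <- if (!is.null(postLandmarks)) readLandmarks(postLandmarks)
  .logStage("motion", cfg, basename(prePly), "->", basename(postPly))
  report <- estimateToothMotions(pre, post, lmPre, lmPost,
                                 maxIter = cfg$icp$maxIter,
                                 tol = cfg$icp$tol,
                                 trimFraction = cfg$icp$trimFraction)
  dir.create(cfg$workDir, recursive = TRUE, showWarnings = FALSE)
  writeMotionReport(report, file.path(cfg$workDir, "motion.csv"),
                    file.path(cfg$workDir, "motion_transforms.json"))
  .appendRunManifest(cfg, "motion", file.path(cfg$workDir, "motion.csv"))
  report
}
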