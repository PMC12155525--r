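# SegNet-style encoder-decoder: construction, forward/backward, training.

#' Network configuration
#'
#' The encoder is a chain of conv(3x3) + batch-norm + ReLU blocks, each
#' followed by 2x2 stride-2 max pooling; the decoder mirrors it with
#' transposed-convolution upsampling, batch norm and additive skip
#' connections from the encoder at matching scales, ending in a 1x1
#' convolution and per-pixel softmax. \code{attention} places a channel
#' and a spatial attention layer either just before the softmax head
#' (\code{"end"}) or at the encoder-decoder transition (\code{"center"});
#' \code{"none"} is the plain architecture. The default is a desk-scale
#' model (3 blocks); \code{fullScale = TRUE} selects the 13-convolution
#' VGG-style encoder (2+2+3+3+3 convolutions over 5 blocks) for GPU-class
#' budgets.
#'
#' @param inputSize input image side in pixels (must be divisible by
#'   2^blocks).
#' @param nClasses number of classes including void/background.
#' @param channels encoder channel widths, one per block.
#' @param convsPerBlock convolution count per encoder block.
#' @param attention one of \code{"none"}, \code{"end"}, \code{"center"}.
#' @param attentionReduction channel-attention squeeze ratio.
#' @param classWeights optional per-class loss weights (length nClasses);
#'   \code{NULL} = unweighted cross-entropy.
#' @param coordChannels append two normalized pixel-coordinate planes to
#'   the RGB input (CoordConv-style). Tooth identity is largely a
#'   positional property under constrained-pose protocols, and the
#'   coordinate planes give a small network direct access to position
#'   instead of forcing it to infer position from its receptive field.
#' @param fullScale use the 13-layer encoder preset.
#' @return a config list for [buildSegNet()].
#' @export
segnetConfig <- function(inputSize = 64L, nClasses = 28L,
                         channels = c(12L, 24L, 48L),
                         convsPerBlock = rep(1L, length(channels)),
                         attention = c("none", "end", "center"),
                         attentionReduction = 8L,
                         classWeights = NULL, coordChannels = FALSE,
                         fullScale = FALSE) {
  attention <- match.arg(attention)
  if (fullScale) {
    channels <- c(64L, 128L, 256L, 512L, 512L)
    convsPerBlock <- c(2L, 2L, 3L, 3L, 3L)
    if (inputSize < 2^5) inputSize <- 256L
  }
  if (nClasses < 2L) stop("nClasses must be >= 2")
  if (length(convsPerBlock) != length(channels)) {
    stop("convsPerBlock must match channels in length")
  }
  if (inputSize %% 2^length(channels) != 0L) {
    stop("inputSize must be divisible by the total downsampling factor 2^",
         length(channels))
  }
  list(inputSize = as.integer(inputSize), nClasses = as.integer(nClasses),
       channels = as.integer(channels),
       convsPerBlock = as.integer(convsPerBlock),
       attention = attention,
       attentionReduction = as.integer(attentionReduction),
       classWeights = classWeights,
       coordChannels = isTRUE(coordChannels))
}

.heConv <- function(k, cin, cout) {
  matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

.newBn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       run = list(mean = rep(0, c), var = rep(1, c)))
}

#' Build a SegNet-style model
#'
#' Initializes all parameters (He-scaled convolution weights, unit batch
#' norms, zero biases) for the architecture described in [segnetConfig()].
#'
#' @param config a [segnetConfig()] list.
#' @param seed RNG seed for the initialization.
#' @param classIds integer label ids corresponding to the output channels;
#'   defaults to the ids of [defaultLabelScheme()] (first
#'   \code{nClasses}).
#' @return a model list with elements \code{config}, \code{params},
#'   \code{classIds}.
#' @export
buildSegNet <- function(config = segnetConfig(), seed = 1L, classIds = NULL) {
  if (is.null(classIds)) {
    sch <- defaultLabelScheme()
    classIds <- sch@entries$id[seq_len(config$nClasses)]
  }
  if (length(classIds) != config$nClasses) {
    stop("classIds must have length nClasses")
  }
  .withSeed(seed, {
    ch <- config$channels
    B <- length(ch)
    enc <- vector("list", B)
    cin <- if (isTRUE(config$coordChannels)) 5L else 3L
    for (b in seq_len(B)) {
      blk <- vector("list", config$convsPerBlock[b])
      for (j in seq_len(config$convsPerBlock[b])) {
        cout <- ch[b]
        blk[[j]] <- c(list(W = .heConv(3L, cin, cout), b = rep(0, cout)),
                      .newBn(cout))
        cin <- cout
      }
      enc[[b]] <- blk
    }
    dec <- vector("list", B)
    for (b in rev(seq_len(B))) {
      up <- c(list(W = array(stats::rnorm(ch[b] * ch[b] * 4, 0,
                                          sqrt(2 / ch[b])),
                             c(ch[b], ch[b], 4L)),
                   b = rep(0, ch[b])), .newBn(ch[b]))
      conv <- NULL
      if (b > 1L) {
        conv <- c(list(W = .heConv(3L, ch[b], ch[b - 1L]),
                       b = rep(0, ch[b - 1L])), .newBn(ch[b - 1L]))
      }
      dec[[b]] <- list(up = up, conv = conv)
    }
    att <- NULL
    if (config$attention != "none") {
      cAtt <- if (config$attention == "end") ch[1] else ch[B]
      hid <- max(1L, cAtt %/% config$attentionReduction)
      att <- list(
        ch = list(W1 = matrix(stats::rnorm(cAtt * hid, 0, sqrt(2 / cAtt)),
                              cAtt, hid),
                  W2 = matrix(stats::rnorm(hid * cAtt, 0, sqrt(2 / hid)),
                              hid, cAtt)),
        sp = list(W = .heConv(7L, 2L, 1L), b = 0)
      )
    }
    head <- list(W = .heConv(1L, ch[1], config$nClasses),
                 b = rep(0, config$nClasses))
    list(config = config,
         params = list(enc = enc, dec = dec, att = att, head = head),
         classIds = as.integer(classIds))
  })
}

# conv + bn + relu with cache; p is a layer param list, k the kernel size
.cbrForward <- function(x, p, k, train) {
  cv <- convForward(x, p$W, p$b, k)
  bn <- bnForward(cv$y, p$gamma, p$beta, p$run, train)
  rl <- reluForward(bn$y)
  list(y = rl$y, run = bn$running,
       cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache))
}

.cbrBackward <- function(dy, p, cache) {
  dy <- reluBackward(dy, cache$relu)
  bn <- bnBackward(dy, p$gamma, cache$bn)
  cv <- convBackward(bn$dx, p$W, cache$conv)
  list(dx = cv$dx,
       grad = list(W = cv$dW, b = cv$db, gamma = bn$dgamma, beta = bn$dbeta))
}

# full forward pass; returns logits, per-layer caches, and the model with
# refreshed batch-norm running stats when train = TRUE
.segnetForward <- function(model, x, train = FALSE) {
  cfg <- model$config
  P <- model$params
  if (isTRUE(cfg$coordChannels)) {
    d <- dim(x)
    cx <- matrix(rep(seq(-1, 1, length.out = d[2]), each = d[1]), d[1])
    cy <- matrix(rep(seq(-1, 1, length.out = d[1]), times = d[2]), d[1])
    x <- array(c(x, cx, cy), c(d[1], d[2], d[3] + 2L))
  }
  B <- length(cfg$channels)
  caches <- list(enc = vector("list", B), dec = vector("list", B))
  skips <- vector("list", B)
  for (b in seq_len(B)) {
    blkCache <- vector("list", length(P$enc[[b]]))
    for (j in seq_along(P$enc[[b]])) {
      st <- .cbrForward(x, P$enc[[b]][[j]], 3L, train)
      if (train) P$enc[[b]][[j]]$run <- st$run
      blkCache[[j]] <- st$cache
      x <- st$y
    }
    skips[[b]] <- x
    pl <- poolForward(x)
    x <- pl$y
    caches$enc[[b]] <- list(convs = blkCache, pool = pl$cache)
  }
  if (cfg$attention == "center") {
    ca <- channelAttentionForward(x, P$att$ch)
    sa <- spatialAttentionForward(ca$y, P$att$sp)
    caches$att <- list(ch = ca$cache, sp = sa$cache)
    x <- sa$y
  }
  for (b in rev(seq_len(B))) {
    up <- upconvForward(x, P$dec[[b]]$up$W, P$dec[[b]]$up$b)
    bn <- bnForward(up$y, P$dec[[b]]$up$gamma, P$dec[[b]]$up$beta,
                    P$dec[[b]]$up$run, train)
    if (train) P$dec[[b]]$up$run <- bn$running
    rl <- reluForward(bn$y)
    x <- rl$y + skips[[b]]
    cc <- NULL
    if (b > 1L) {
      st <- .cbrForward(x, P$dec[[b]]$conv, 3L, train)
      if (train) P$dec[[b]]$conv$run <- st$run
      cc <- st$cache
      x <- st$y
    }
    caches$dec[[b]] <- list(up = up$cache, bn = bn$cache, relu = rl$cache,
                            conv = cc)
  }
  if (cfg$attention == "end") {
    ca <- channelAttentionForward(x, P$att$ch)
    sa <- spatialAttentionForward(ca$y, P$att$sp)
    caches$att <- list(ch = ca$cache, sp = sa$cache)
    x <- sa$y
  }
  hd <- convForward(x, P$head$W, P$head$b, 1L)
  caches$head <- hd$cache
  model$params <- P
  list(logits = hd$y, caches = caches, model = model)
}

.segnetBackward <- function(model, caches, dlogits) {
  cfg <- model$config
  P <- model$params
  B <- length(cfg$channels)
  g <- list(enc = vector("list", B), dec = vector("list", B),
            att = NULL, head = NULL)
  hb <- convBackward(dlogits, P$head$W, caches$head)
  g$head <- list(W = hb$dW, b = hb$db)
  dy <- hb$dx
  if (cfg$attention == "end") {
    sb <- spatialAttentionBackward(dy, P$att$sp, caches$att$sp)
    cb <- channelAttentionBackward(sb$dx, P$att$ch, caches$att$ch)
    g$att <- list(ch = list(W1 = cb$dW1, W2 = cb$dW2),
                  sp = list(W = sb$dW, b = sb$db))
    dy <- cb$dx
  }
  dskips <- vector("list", B)
  for (b in seq_len(B)) {
    cc <- caches$dec[[b]]
    gd <- list(up = NULL, conv = NULL)
    if (b > 1L) {
      st <- .cbrBackward(dy, P$dec[[b]]$conv, cc$conv)
      gd$conv <- st$grad
      dy <- st$dx
    }
    dskips[[b]] <- dy                      # additive skip: gradient forks
    dy2 <- reluBackward(dy, cc$relu)
    bn <- bnBackward(dy2, P$dec[[b]]$up$gamma, cc$bn)
    up <- upconvBackward(bn$dx, P$dec[[b]]$up$W, cc$up)
    gd$up <- list(W = up$dW, b = up$db, gamma = bn$dgamma, beta = bn$dbeta)
    g$dec[[b]] <- gd
    dy <- up$dx
  }
  if (cfg$attention == "center") {
    sb <- spatialAttentionBackward(dy, P$att$sp, caches$att$sp)
    cb <- channelAttentionBackward(sb$dx, P$att$ch, caches$att$ch)
    g$att <- list(ch = list(W1 = cb$dW1, W2 = cb$dW2),
                  sp = list(W = sb$dW, b = sb$db))
    dy <- cb$dx
  }
  for (b in rev(seq_len(B))) {
    cc <- caches$enc[[b]]
    dy <- poolBackward(dy, cc$pool)
    dy <- dy + dskips[[b]]
    gb <- vector("list", length(P$enc[[b]]))
    for (j in rev(seq_along(P$enc[[b]]))) {
      st <- .cbrBackward(dy, P$enc[[b]][[j]], cc$convs[[j]])
      gb[[j]] <- st$grad
      dy <- st$dx
    }
    g$enc[[b]] <- gb
  }
  g
}

# ---- parameter-tree utilities (leaves = numeric arrays; "run" skipped) ----

.treeWalk <- function(p, g, f, path = "") {
  if (is.numeric(p)) return(f(p, g, path))
  out <- p
  for (nm in names(p)) {
    if (nm == "run" || is.null(p[[nm]])) next
    out[[nm]] <- .treeWalk(p[[nm]], g[[nm]], f, paste(path, nm))
  }
  if (is.null(names(p))) {
    for (i in seq_along(p)) {
      if (is.null(p[[i]])) next
      out[[i]] <- .treeWalk(p[[i]], g[[i]], f, paste(path, i))
    }
  }
  out
}

.adamInit <- function(params) {
  .treeWalk(params, params, function(p, g, path) array(0, dim(p) %||% length(p)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamStep <- function(params, grads, m, v, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  mNew <- .treeWalk(m, grads, function(mm, gg, path) beta1 * mm + (1 - beta1) * gg)
  vNew <- .treeWalk(v, grads, function(vv, gg, path) beta2 * vv + (1 - beta2) * gg^2)
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  pNew <- .treeWalk(params, .treeZip(mNew, vNew), function(pp, mv, path) {
    pp - lr * (mv$m / corr1) / (sqrt(mv$v / corr2) + eps)
  })
  list(params = pNew, m = mNew, v = vNew)
}

# zip two parallel trees into leaves list(m =, v =)
.treeZip <- function(a, b) {
  if (is.numeric(a)) return(list(m = a, v = b))
  out <- a
  if (!is.null(names(a))) {
    for (nm in names(a)) {
      if (nm == "run" || is.null(a[[nm]])) next
      out[[nm]] <- .treeZip(a[[nm]], b[[nm]])
    }
  } else {
    for (i in seq_along(a)) {
      if (is.null(a[[i]])) next
      out[[i]] <- .treeZip(a[[i]], b[[i]])
    }
  }
  out
}

#' Training configuration
#'
#' @param epochs number of passes over the training set.
#' @param batchSize images per gradient step (the reference protocol is 1).
#' @param learningRate Adam learning rate.
#' @param decay multiplicative per-epoch learning-rate factor in (0, 1].
#' @param seed RNG seed controlling data order.
#' @export
trainConfig <- function(epochs = 50L, batchSize = 1L,
                        learningRate = 1e-4, decay = 0.995, seed = 1L) {
  if (learningRate <= 0) stop("learningRate must be positive")
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]")
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       learningRate = learningRate, decay = decay, seed = as.integer(seed))
}

# one labeled sample: x [S,S,3] in [0,1], y integer [S,S] of class INDICES
.toSample <- function(textureImg, labelImg, classIds, scheme) {
  y <- if (length(dim(labelImg)) == 3L) decodeLabelImage(labelImg, scheme)
       else labelImg
  idx <- match(y, classIds)
  if (anyNA(idx)) stop("label image contains ids outside the model's classes")
  list(x = textureImg, y = matrix(idx, nrow(y)))
}

#' Assemble training samples from a dataset manifest
#'
#' Reads the texture/label PNG pairs of a manifest into in-memory samples
#' for [trainSegNet()], tagging each with its scan id for split hygiene.
#' @param manifest a dataset manifest (see [generateDataset()]).
#' @param model the model the samples are for (class-id mapping).
#' @param scheme a [LabelScheme-class].
#' @export
samplesFromManifest <- function(manifest, model,
                                scheme = defaultLabelScheme()) {
  lapply(seq_len(nrow(manifest)), function(k) {
    s <- .toSample(png::readPNG(manifest$texture[k]),
                   png::readPNG(manifest$label[k]),
                   model$classIds, scheme)
    s$scan <- manifest$mesh[k]
    s
  })
}

#' Scan-level train/validation/test split
#'
#' Splits a manifest by scan id, never by image, so no scan contributes
#' images to more than one split.
#' @param manifest a dataset manifest.
#' @param fractions length-3 split fractions (train, val, test), summing
#'   to 1.
#' @param seed RNG seed for the scan shuffle.
#' @return the manifest with a \code{split} column.
#' @export
splitByScan <- function(manifest, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  scans <- unique(manifest$mesh)
  .withSeed(seed, {
    scans <- sample(scans)
    n <- length(scans)
    nTrain <- round(fractions[1] * n)
    nVal <- round(fractions[2] * n)
    split <- rep("test", n)
    split[seq_len(nTrain)] <- "train"
    if (nVal > 0) split[nTrain + seq_len(min(nVal, n - nTrain))] <- "val"
    manifest$split <- split[match(manifest$mesh, scans)]
    manifest
  })
}

.checkSplits <- function(samples) {
  splits <- vapply(samples, function(s) s$split %||% "train", "")
  scans <- vapply(samples, function(s) as.character(s$scan %||% "scan"), "")
  tab <- unique(data.frame(scan = scans, split = splits))
  if (anyDuplicated(tab$scan)) {
    stop("scan(s) appear in more than one split: ",
         paste(tab$scan[duplicated(tab$scan)], collapse = ", "))
  }
  invisible(TRUE)
}

#' Train a SegNet model
#'
#' Per-pixel cross-entropy with Adam, batch size 1 (gradient steps per
#' image) and a multiplicative per-epoch learning-rate decay. Samples must
#' be grouped by scan; a scan contributing images to more than one split
#' is an error. History records the mean training loss per epoch and, if
#' validation samples are given, validation loss and mean IoU.
#'
#' @param model a model from [buildSegNet()].
#' @param samples list of samples (see [samplesFromManifest()]); samples
#'   with \code{split} set are filtered to \code{"train"} /\code{"val"},
#'   untagged samples all train.
#' @param config a [trainConfig()].
#' @param scheme a [LabelScheme-class] (for validation mIoU).
#' @param verbose print one line per epoch.
#' @return list with the trained \code{model} and \code{history}
#'   (data.frame: epoch, lr, trainLoss, valLoss, valMeanIoU).
#' @export
trainSegNet <- function(model, samples, config = trainConfig(),
                        scheme = defaultLabelScheme(), verbose = FALSE) {
  .checkSplits(samples)
  splits <- vapply(samples, function(s) s$split %||% "train", "")
  trainSet <- samples[splits == "train"]
  valSet <- samples[splits == "val"]
  if (length(trainSet) == 0L) stop("no training samples")
  if (config$epochs == 0L) {
    return(list(model = model, history = data.frame()))
  }
  m <- .adamInit(model$params)
  v <- .adamInit(model$params)
  lr <- config$learningRate
  t <- 0L
  history <- vector("list", config$epochs)
  cw <- model$config$classWeights
  .withSeed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(seq_along(trainSet))
      losses <- numeric(length(ord))
      for (i in seq_along(ord)) {
        s <- trainSet[[ord[i]]]
        fw <- .segnetForward(model, s$x, train = TRUE)
        model <- fw$model
        sl <- softmaxLoss(fw$logits, s$y)
        dlog <- sl$dlogits
        loss <- sl$loss
        if (!is.null(cw)) {
          wpix <- matrix(cw[s$y], nrow(s$y))
          d <- dim(dlog)
          dlog <- dlog * array(rep(wpix, d[3]), d)
          loss <- loss * mean(wpix)   # reporting scale only
        }
        g <- .segnetBackward(model, fw$caches, dlog)
        t <- t + 1L
        st <- .adamStep(model$params, g, m, v, lr, t)
        model$params <- st$params
        m <- st$m
        v <- st$v
        losses[i] <- loss
      }
      valLoss <- NA_real_
      valIoU <- NA_real_
      if (length(valSet)) {
        vl <- vapply(valSet, function(s) {
          fw <- .segnetForward(model, s$x, train = FALSE)
          softmaxLoss(fw$logits, s$y)$loss
        }, 0)
        valLoss <- mean(vl)
        vi <- vapply(valSet, function(s) {
          pr <- .segnetForward(model, s$x, train = FALSE)
          cls <- apply(pr$logits, c(1, 2), which.max)
          m2 <- metrics2D(matrix(model$classIds[cls], nrow(cls)),
                          matrix(model$classIds[s$y], nrow(s$y)), scheme)
          m2$meanIoU
        }, 0)
        valIoU <- mean(vi)
      }
      history[[ep]] <- data.frame(epoch = ep, lr = lr,
                                  trainLoss = mean(losses),
                                  valLoss = valLoss, valMeanIoU = valIoU)
      if (verbose) {
        message(sprintf("epoch %d lr %.3g loss %.4f val %.4f mIoU %.3f",
                        ep, lr, mean(losses), valLoss, valIoU))
      }
      lr <- lr * config$decay
    }
  })
  list(model = model, history = do.call(rbind, history))
}

#' Predict a label image for one texture image
#'
#' Runs the network in evaluation mode (batch-norm running statistics,
#' no randomness) and renders the per-pixel argmax class in palette
#' colors.
#'
#' @param model a trained model.
#' @param image H x W x 3 array in [0, 1]; H = W = the model's input size.
#' @param scheme a [LabelScheme-class] for the palette.
#' @return list with \code{classes} (integer id matrix), \code{image}
#'   (H x W x 3 palette raster) and \code{probs} (H x W x K softmax).
#' @export
predictSegNet <- function(model, image, scheme = defaultLabelScheme()) {
  d <- dim(image)
  if (d[1] != model$config$inputSize || d[2] != model$config$inputSize) {
    stop("image size ", d[1], "x", d[2], " does not match the model input ",
         model$config$inputSize)
  }
  fw <- .segnetForward(model, image, train = FALSE)
  probs <- softmaxProbs(fw$logits)
  cls <- apply(probs, c(1, 2), which.max)
  ids <- matrix(model$classIds[cls], nrow(cls))
  pal <- schemePalette(scheme) / 255
  pi <- match(ids, as.integer(rownames(pal)))
  img <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal[pi, ch], d[1])
  list(classes = ids, image = img, probs = probs)
}

#' Apply channel attention to a feature map
#'
#' Squeeze-and-excite gating: a global average pool over each channel is
#' passed through a small two-layer MLP and a sigmoid to produce one
#' weight per channel, which rescales that channel. With \code{weights}
#' supplied the learned gate is bypassed and the given per-channel
#' weights applied directly.
#'
#' @param featureMap H x W x C array.
#' @param params list(W1, W2) MLP weights (see [buildSegNet()]); ignored
#'   when \code{weights} is given.
#' @param weights optional length-C numeric gate.
#' @return gated H x W x C array.
#' @export
channelAttention <- function(featureMap, params = NULL, weights = NULL) {
  d <- dim(featureMap)
  if (!is.null(weights)) {
    M <- sweep(matrix(featureMap, ncol = d[3]), 2, weights, "*")
    return(array(M, d))
  }
  channelAttentionForward(featureMap, params)$y
}

#' Apply spatial attention to a feature map
#'
#' Position gating: channel mean- and max-pooled planes are convolved
#' (7x7) and squashed to a per-position sigmoid weight map that rescales
#' every channel. With \code{weights} supplied (an H x W matrix) the
#' learned map is bypassed.
#'
#' @param featureMap H x W x C array.
#' @param params list(W, b) convolution parameters; ignored when
#'   \code{weights} is given.
#' @param weights optional H x W weight matrix.
#' @return gated H x W x C array.
#' @export
spatialAttention <- function(featureMap, params = NULL, weights = NULL) {
  d <- dim(featureMap)
  if (!is.null(weights)) {
    return(featureMap * array(rep(weights, d[3]), d))
  }
  spatialAttentionForward(featureMap, params)$y
}

#' Count trainable parameters of a model
#' @param model a model from [buildSegNet()].
#' @export
countParameters <- function(model) {
  n <- 0
  .treeWalk(model$params, model$params, function(p, g, path) {
    n <<- n + length(p)
    p
  })
  n
}

#' Save / load a model checkpoint
#'
#' The parameters go into R's native serialization; a JSON sidecar records
#' the architecture config and class ids so a checkpoint is
#' self-describing.
#' @param model a model list.
#' @param path checkpoint path (.rds); the sidecar is \code{path.json}.
#' @export
saveSegNet <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(config = model$config[setdiff(names(model$config), "classWeights")],
         classIds = model$classIds),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveSegNet
#' @export
loadSegNet <- function(path) readRDS(path)
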