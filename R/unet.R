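# The 3D U-Net: architecture plan, seeded initialization, forward pass,
# backpropagation, Dice loss, Adam training loop, and Expansion Transfer
# Learning (ETL) between the two pipeline stages.
#
# Feature maps are held as N x C matrices (N = prod(grid dims), voxel
# index fastest along axis 1); the compiled kernels in src/ do the heavy
# lifting. Convolutions are 3x3x3, same padding, followed by ReLU
# (except the output layer, which is sigmoid). Pooling is 2x2x2 max;
# upsampling repeats elements by 2 per axis; skip connections
# concatenate channels. The network is fully convolutional, so trained
# weights run at any resolution divisible by 2^depth -- the property ETL
# exploits when expanding second-step weights to the first step's wider
# field of view.

#' Construct a U-Net architecture specification
#'
#' @param depth number of pooling steps (default 4).
#' @param baseChannels feature maps after the first convolution
#'   (default 16; the deepest layer then has `baseChannels * 2^(depth+1)`
#'   feature maps, 512 for the defaults).
#' @param inChannels input channels (1 for CT).
#' @param norm `"none"` (plain convolutions, the reference behaviour) or
#'   `"instance"`: per-channel instance normalization with learned scale
#'   and shift after every convolution except the output layer.
#'   Normalization keeps activations in a sane range regardless of
#'   depth/width, which prevents the wholesale ReLU death and sigmoid
#'   saturation that unnormalized small networks exhibit under the pure
#'   Dice loss.
#' @return a [UNetSpec-class].
#' @examples
#' unetSpec()                   # full-size: 10 encoder convs, 512 deep
#' unetSpec(depth = 2, baseChannels = 4)  # reduced, for desk-scale runs
#' @export
unetSpec <- function(depth = 4L, baseChannels = 16L, inChannels = 1L,
                     norm = c("none", "instance")) {
  norm <- match.arg(norm)
  new("UNetSpec", depth = as.integer(depth),
      baseChannels = as.integer(baseChannels),
      inChannels = as.integer(inChannels), norm = norm)
}

#' Layer inventory of a U-Net specification
#'
#' One row per convolution layer with its input/output channel counts and
#' whether it sits on the encoding or decoding path. The encoder has
#' `2 * depth + 2` convolutions with `depth` max-pooling steps between
#' them, doubling the feature maps at every pooling step.
#'
#' @param spec a [UNetSpec-class].
#' @return `data.frame` with columns `name`, `cin`, `cout`, `path`.
#' @export
unetLayers <- function(spec) {
  d <- spec@depth; c0 <- spec@baseChannels
  rows <- list(data.frame(name = "enc_in", cin = spec@inChannels, cout = c0,
                          path = "encoder"))
  for (k in seq_len(d)) {
    ch <- c0 * 2^(k - 1)
    rows[[length(rows) + 1]] <- data.frame(
      name = c(sprintf("enc%da", k), sprintf("enc%db", k)),
      cin = c(ch, ch), cout = c(ch, 2 * ch), path = "encoder")
  }
  deep <- c0 * 2^(d + 1)
  rows[[length(rows) + 1]] <- data.frame(
    name = c("enc_bottom", "dec_bottom"), cin = c(deep / 2, deep),
    cout = c(deep, deep), path = c("encoder", "decoder"))
  cur <- deep
  for (j in seq_len(d)) {
    skip <- c0 * 2^(d - j)
    rows[[length(rows) + 1]] <- data.frame(
      name = c(sprintf("dec%da", j), sprintf("dec%db", j)),
      cin = c(cur, cur / 2 + skip), cout = c(cur / 2, cur / 2),
      path = "decoder")
    cur <- cur / 2
  }
  rows[[length(rows) + 1]] <- data.frame(name = "dec_out", cin = cur,
                                         cout = 1, path = "decoder")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Initialize U-Net weights
#'
#' He-normal initialization (sd `sqrt(2 / fan_in)`), deterministic for a
#' fixed seed; biases start at zero.
#'
#' @param spec a [UNetSpec-class].
#' @param seed RNG seed.
#' @return a [UNetWeights-class] with provenance `stage = NULL` (untrained).
#' @export
buildUNet <- function(spec, seed = 1L) {
  plan <- unetLayers(spec)
  params <- .withLocalSeed(seed, {
    ps <- list()
    for (i in seq_len(nrow(plan))) {
      fanIn <- 27 * plan$cin[i]
      ps[[plan$name[i]]] <- list(
        W = matrix(rnorm(fanIn * plan$cout[i], 0, sqrt(2 / fanIn)),
                   fanIn, plan$cout[i]),
        b = numeric(plan$cout[i]))
      if (spec@norm == "instance" && plan$name[i] != "dec_out") {
        ps[[plan$name[i]]]$g <- rep(1, plan$cout[i])
        ps[[plan$name[i]]]$be <- numeric(plan$cout[i])
      }
    }
    ps
  })
  new("UNetWeights", spec = spec, params = params,
      provenance = list(seed = as.integer(seed), epochs = 0L))
}

.checkDivisible <- function(dims, depth) {
  f <- 2^depth
  bad <- which(dims %% f != 0)
  if (length(bad))
    .fibsegError("fibseg_shape_error",
                 sprintf("axis %d extent %d is not divisible by %d (2^depth)",
                         bad[1], dims[bad[1]], f))
}

.relu <- function(h) { h[h < 0] <- 0; h }
.sigmoid <- function(h) 1 / (1 + exp(-h))
.LOGIT_BOUND <- 12

# internal: full forward pass; with cache = TRUE also returns everything
# backpropagation needs.
.unetRun <- function(weights, x, cache = FALSE) {
  spec <- weights@spec; P <- weights@params
  d <- spec@depth
  dims <- dim(x)
  .checkDivisible(dims, d)
  useNorm <- spec@norm == "instance"
  st <- if (cache) new.env(parent = emptyenv()) else NULL
  keep <- function(key, val) if (cache) assign(key, val, st)
  cv <- function(h, dm, layer) {
    z <- .cv_fwd(h, as.integer(dm), P[[layer]]$W, P[[layer]]$b)
    if (useNorm && layer != "dec_out") {
      mu <- colMeans(z)
      zc <- sweep(z, 2, mu)
      sdv <- sqrt(colMeans(zc^2) + 1e-5)
      hn <- sweep(zc, 2, sdv, "/")
      keep(paste0("in_hn_", layer), hn)
      keep(paste0("in_sd_", layer), sdv)
      z <- sweep(sweep(hn, 2, P[[layer]]$g, "*"), 2, P[[layer]]$be, "+")
    }
    z
  }

  h <- matrix(as.numeric(x), ncol = 1)
  keep("x_enc_in", h); keep("dims_enc_in", dims)
  h <- .relu(cv(h, dims, "enc_in")); keep("m_enc_in", h > 0)
  skips <- list(); skipDims <- list()
  for (k in seq_len(d)) {
    la <- sprintf("enc%da", k); lb <- sprintf("enc%db", k)
    keep(paste0("x_", la), h); keep(paste0("dims_", la), dims)
    h <- .relu(cv(h, dims, la)); keep(paste0("m_", la), h > 0)
    skips[[k]] <- h; skipDims[[k]] <- dims
    mp <- .mp_fwd(h, as.integer(dims)); keep(paste0("pool_idx_", k), mp$idx)
    keep(paste0("pool_nin_", k), nrow(h))
    h <- mp$y; dims <- dims / 2
    keep(paste0("x_", lb), h); keep(paste0("dims_", lb), dims)
    h <- .relu(cv(h, dims, lb)); keep(paste0("m_", lb), h > 0)
  }
  keep("x_enc_bottom", h); keep("dims_enc_bottom", dims)
  h <- .relu(cv(h, dims, "enc_bottom")); keep("m_enc_bottom", h > 0)
  keep("x_dec_bottom", h); keep("dims_dec_bottom", dims)
  h <- .relu(cv(h, dims, "dec_bottom")); keep("m_dec_bottom", h > 0)
  for (j in seq_len(d)) {
    la <- sprintf("dec%da", j); lb <- sprintf("dec%db", j)
    keep(paste0("x_", la), h); keep(paste0("dims_", la), dims)
    h <- .relu(cv(h, dims, la)); keep(paste0("m_", la), h > 0)
    keep(paste0("up_dims_", j), dims)
    h <- .up_fwd(h, as.integer(dims)); dims <- dims * 2
    sk <- skips[[d + 1 - j]]
    keep(paste0("cat_main_", j), ncol(h))
    h <- cbind(h, sk)
    keep(paste0("x_", lb), h); keep(paste0("dims_", lb), dims)
    h <- .relu(cv(h, dims, lb)); keep(paste0("m_", lb), h > 0)
  }
  keep("x_dec_out", h); keep("dims_dec_out", dims)
  logits <- cv(h, dims, "dec_out")
  # bounded-logit sigmoid: z' = a tanh(z/a). Indistinguishable from the
  # plain sigmoid at working logits (|z| < 6) but keeps a usable
  # gradient at extreme confidence, where the pure Dice loss otherwise
  # dies of sigmoid saturation.
  zb <- .LOGIT_BOUND * tanh(logits / .LOGIT_BOUND)
  p <- .sigmoid(zb)
  keep("tanh_d", 1 - (zb / .LOGIT_BOUND)^2)
  keep("p", p)
  prob <- array(as.numeric(p), dims)
  if (cache) list(prob = prob, cache = st) else prob
}

# internal: backpropagation. gp is dLoss/dProb as a vector; returns a
# named list of list(gW, gb) per layer.
.unetBackprop <- function(weights, gp) {
  spec <- weights@spec; P <- weights@params
  d <- spec@depth
  st <- attr(gp, "cache")
  useNorm <- spec@norm == "instance"
  grads <- list()
  bwd <- function(g, layer) {
    extra <- NULL
    if (useNorm && layer != "dec_out") {
      hn <- get(paste0("in_hn_", layer), st)
      sdv <- get(paste0("in_sd_", layer), st)
      extra <- list(gg = colSums(g * hn), gbe = colSums(g))
      ghn <- sweep(g, 2, P[[layer]]$g, "*")
      g <- sweep(ghn, 2, colMeans(ghn)) -
        sweep(hn, 2, colMeans(ghn * hn), "*")
      g <- sweep(g, 2, sdv, "/")
    }
    x <- get(paste0("x_", layer), st)
    dm <- get(paste0("dims_", layer), st)
    r <- .cv_bwd(x, as.integer(dm), P[[layer]]$W, g)
    grads[[layer]] <<- c(list(gW = r$gW, gb = r$gb),
                         if (!is.null(extra)) list(gg = extra$gg, gbe = extra$gbe))
    r$gx
  }
  p <- get("p", st)
  g <- matrix(as.numeric(gp) * p * (1 - p) * get("tanh_d", st),
              ncol = 1)                    # through bounded-logit sigmoid
  g <- bwd(g, "dec_out")
  skipGrads <- vector("list", d)
  for (j in rev(seq_len(d))) {
    la <- sprintf("dec%da", j); lb <- sprintf("dec%db", j)
    g <- g * get(paste0("m_", lb), st)
    g <- bwd(g, lb)
    nMain <- get(paste0("cat_main_", j), st)
    skipGrads[[d + 1 - j]] <- g[, (nMain + 1):ncol(g), drop = FALSE]
    g <- g[, seq_len(nMain), drop = FALSE]
    g <- .up_bwd(g, as.integer(2 * get(paste0("up_dims_", j), st)))
    g <- g * get(paste0("m_", la), st)
    g <- bwd(g, la)
  }
  g <- g * get("m_dec_bottom", st); g <- bwd(g, "dec_bottom")
  g <- g * get("m_enc_bottom", st); g <- bwd(g, "enc_bottom")
  for (k in rev(seq_len(d))) {
    la <- sprintf("enc%da", k); lb <- sprintf("enc%db", k)
    g <- g * get(paste0("m_", lb), st)
    g <- bwd(g, lb)
    g <- .mp_bwd(g, get(paste0("pool_idx_", k), st), get(paste0("pool_nin_", k), st))
    g <- g + skipGrads[[k]]
    g <- g * get(paste0("m_", la), st)
    g <- bwd(g, la)
  }
  g <- g * get("m_enc_in", st)
  bwd(g, "enc_in")
  grads
}

#' Forward pass of the U-Net
#'
#' Applies the network to a normalized volume. Every grid axis must be
#' divisible by `2^depth`; the output probability grid has exactly the
#' input shape (same-padding convolutions, symmetric pool/upsample).
#'
#' @param weights a [UNetWeights-class].
#' @param x a [CTVolume-class] or 3D array with intensities in `[0, 1]`.
#' @return 3D array of probabilities in `[0, 1]`, same shape as `x`
#'   (a [CTVolume-class] in, a [CTVolume-class] out).
#' @export
unetForward <- function(weights, x) {
  isVol <- is(x, "CTVolume")
  arr <- if (isVol) voxels(x) else x
  prob <- .unetRun(weights, arr, cache = FALSE)
  if (isVol) ctVolume(prob, spacing(x), origin(x)) else prob
}

#' Soft Dice loss
#'
#' \eqn{L = 1 - (2 \Sigma p t + \epsilon) / (\Sigma p + \Sigma t + \epsilon)},
#' the overlap-based training loss; 0 for a perfect prediction, close to
#' 1 for disjoint non-empty prediction and target. The smoothing term
#' avoids 0/0 on empty targets.
#'
#' @param prediction array/vector of probabilities in `[0, 1]`.
#' @param target binary array/vector of the same shape.
#' @param eps smoothing constant (default 1e-6).
#' @return scalar loss in `[0, 1]`.
#' @export
diceLoss <- function(prediction, target, eps = 1e-6) {
  if (!identical(dim(prediction), dim(target)) ||
      length(prediction) != length(target))
    .fibsegError("fibseg_shape_error", "prediction and target differ in shape")
  1 - (2 * sum(prediction * target) + eps) /
    (sum(prediction) + sum(target) + eps)
}

# internal: dLoss/dprediction of the soft Dice loss
.diceLossGrad <- function(prediction, target, eps = 1e-6) {
  s <- sum(prediction) + sum(target) + eps
  num <- 2 * sum(prediction * target) + eps
  -(2 * target * s - num) / s^2
}

# Saturation guard for warm starts. A network transferred from another
# stage can be confidently wrong on the new input distribution: logits
# far outside [-10, 10] drive the sigmoid to exactly 0/1, where the
# Dice-loss gradient vanishes and training never escapes (observed as a
# loss pinned at 1). If, on the first training sample, the start is both
# saturated and performing badly, the output layer is rescaled (a
# temperature recalibration of its kernel and bias) so the 90th
# percentile of |logit| is 4. A healthy initialization -- fresh He init,
# or a warm start that already fits -- is left untouched.
.desaturateOutput <- function(w, sample) {
  # probabilities of exactly 0/1 clamp the measurable |logit| at ~27.6,
  # so rescale iteratively until the measured saturation clears
  for (it in 1:6) {
    prob <- .unetRun(w, sample$x, cache = FALSE)
    z <- abs(stats::qlogis(pmin(pmax(prob, 1e-12), 1 - 1e-12)))
    q90 <- quantile(z, 0.9, names = FALSE)
    if (it == 1 && diceLoss(prob, sample$y) <= 0.5) return(w)
    if (q90 <= 8) return(w)
    scale <- 4 / q90
    w@params$dec_out$W <- w@params$dec_out$W * scale
    w@params$dec_out$b <- w@params$dec_out$b * scale
    w@provenance$output_rescaled <- scale *
      (if (is.null(w@provenance$output_rescaled)) 1
       else w@provenance$output_rescaled)
  }
  w
}

#' Training configuration for [trainUNet()]
#'
#' The optimizer is Adam on the soft Dice loss, batch size 1 (whole
#' volumes at a fixed per-stage resolution, no patches, no data
#' augmentation). Learning rate and epoch count are package defaults
#' chosen for the desk-scale phantom experiments.
#'
#' @param lr Adam learning rate.
#' @param beta1,beta2,epsAdam Adam moment decays and stabilizer.
#' @param epochs training epochs (each sees every sample once).
#' @param weightDecay decoupled (AdamW-style) weight decay; keeps the
#'   network's confidence moderate, which preserves usable Dice-loss
#'   gradients (default 0).
#' @param clipNorm global gradient-norm clipping threshold; caps the
#'   occasional huge Dice-loss gradient step that would otherwise drive
#'   the sigmoid into saturation, where training dies.
#' @param seed seed for weight init order and per-epoch shuffling.
#' @return a list of class `fibsegTrainConfig`.
#' @export
unetTrainConfig <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                            epsAdam = 1e-8, epochs = 20L, clipNorm = 1,
                            weightDecay = 0, seed = 1L) {
  stopifnot(lr > 0, epochs >= 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, epsAdam = epsAdam,
                 epochs = as.integer(epochs), clipNorm = clipNorm,
                 weightDecay = weightDecay, seed = as.integer(seed)),
            class = "fibsegTrainConfig")
}

#' Train a U-Net on prepared samples
#'
#' Full-volume, batch-size-1 training with Adam on the soft Dice loss.
#' Samples must already be resampled to the stage resolution and
#' intensity-normalized. After every epoch the mean validation loss is
#' computed and the best-validation weights are kept (checkpoint
#' selection). Fully deterministic for a fixed seed under single-threaded
#' execution.
#'
#' @param samples `list(train = , val = )`, each a list of
#'   `list(x = normalized 3D array, y = binary 3D array)`.
#' @param config a [unetTrainConfig()].
#' @param initWeights optional [UNetWeights-class] to start from (used by
#'   Expansion Transfer Learning); defaults to a fresh seeded
#'   initialization of `spec`.
#' @param spec [UNetSpec-class] used when `initWeights` is absent.
#' @param stage provenance tag (`"step1"` / `"step2"` / free text).
#' @param verbose print per-epoch losses.
#' @return `list(weights = UNetWeights at the best validation epoch,
#'   history = data.frame(epoch, train_loss, val_loss))`.
#' @export
trainUNet <- function(samples, config = unetTrainConfig(),
                      initWeights = NULL, spec = unetSpec(),
                      stage = "unspecified", verbose = FALSE) {
  if (length(samples$train) < 1 || length(samples$val) < 1)
    .fibsegError("fibseg_data_error",
                 "need at least one training and one validation sample")
  w <- if (is.null(initWeights)) buildUNet(spec, config$seed) else initWeights
  w <- .desaturateOutput(w, samples$train[[1]])
  P <- w@params
  mState <- lapply(P, function(p) lapply(p, function(q) 0 * q))
  vState <- lapply(P, function(p) lapply(p, function(q) 0 * q))
  tStep <- 0
  evalLoss <- function(params, ss) {
    wEval <- w; wEval@params <- params
    mean(vapply(ss, function(s)
      diceLoss(.unetRun(wEval, s$x, cache = FALSE), s$y), 0))
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = P, epoch = 0L)
  .withLocalSeed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(samples$train))
      epochLosses <- numeric(length(ord))
      for (si in seq_along(ord)) {
        s <- samples$train[[ord[si]]]
        wCur <- w; wCur@params <- P
        run <- .unetRun(wCur, s$x, cache = TRUE)
        epochLosses[si] <- diceLoss(run$prob, s$y)
        gp <- .diceLossGrad(as.numeric(run$prob), as.numeric(s$y))
        attr(gp, "cache") <- run$cache
        grads <- .unetBackprop(wCur, gp)
        if (!is.null(config$clipNorm) && config$clipNorm > 0) {
          gn <- sqrt(sum(vapply(grads, function(g)
            sum(vapply(g, function(q) sum(q^2), 0)), 0)))
          if (gn > config$clipNorm) {
            sc <- config$clipNorm / gn
            grads <- lapply(grads, function(g) lapply(g, function(q) q * sc))
          }
        }
        tStep <- tStep + 1
        corr1 <- 1 - config$beta1^tStep
        corr2 <- 1 - config$beta2^tStep
        for (ln in names(P)) {
          for (part in names(P[[ln]])) {
            g <- grads[[ln]][[paste0("g", part)]]
            if (is.null(g)) next
            mState[[ln]][[part]] <- config$beta1 * mState[[ln]][[part]] +
              (1 - config$beta1) * g
            vState[[ln]][[part]] <- config$beta2 * vState[[ln]][[part]] +
              (1 - config$beta2) * g^2
            P[[ln]][[part]] <- P[[ln]][[part]] - config$lr *
              (mState[[ln]][[part]] / corr1) /
              (sqrt(vState[[ln]][[part]] / corr2) + config$epsAdam)
            if (!is.null(config$weightDecay) && config$weightDecay > 0)
              P[[ln]][[part]] <- P[[ln]][[part]] *
                (1 - config$lr * config$weightDecay)
          }
        }
      }
      valLoss <- evalLoss(P, samples$val)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(epochLosses), val_loss = valLoss))
      if (valLoss < best$loss)
        best <- list(loss = valLoss, params = P, epoch = epoch)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        mean(epochLosses), valLoss))
    }
  })
  w@params <- best$params
  w@provenance <- list(stage = stage, seed = config$seed,
                       epochs = config$epochs, best_epoch = best$epoch,
                       best_val_loss = best$loss,
                       transferredFrom = w@provenance$transferredFrom,
                       output_rescaled = w@provenance$output_rescaled)
  list(weights = w, history = history)
}

#' Expansion Transfer Learning: seed step 1 from step 2
#'
#' The second-step (refinement) network is trained first on the easier,
#' cropped high-resolution task; because the architecture is fully
#' convolutional and therefore resolution-agnostic, *all* of its
#' convolutional parameters transfer verbatim to initialize the
#' first-step (localization) network at a different input resolution --
#' expanding the detailed second-step training result to the whole field
#' of view.
#'
#' @param secondStepWeights a trained [UNetWeights-class].
#' @param targetSpec the first step's [UNetSpec-class]; must equal the
#'   source spec (checked layer by layer).
#' @return a [UNetWeights-class] with copied parameters and provenance
#'   recording the transfer source.
#' @export
expansionTransfer <- function(secondStepWeights, targetSpec = NULL) {
  spec <- secondStepWeights@spec
  if (!is.null(targetSpec)) {
    if (!identical(spec@norm, targetSpec@norm))
      .fibsegError("fibseg_transfer_error",
                   "network specifications differ in normalization")
    src <- unetLayers(spec); dst <- unetLayers(targetSpec)
    if (!identical(src, dst)) {
      bad <- union(setdiff(dst$name, src$name),
                   dst$name[!(dst$name %in% src$name) |
                              (dst$name %in% src$name &
                                 (dst$cin != src$cin[match(dst$name, src$name)] |
                                    dst$cout != src$cout[match(dst$name, src$name)]))])
      .fibsegError("fibseg_transfer_error",
                   sprintf("network specifications differ; incompatible layers: %s",
                           paste(unique(bad), collapse = ", ")))
    }
  }
  out <- secondStepWeights
  out@provenance <- list(
    stage = "step1_init",
    transferredFrom = secondStepWeights@provenance$stage,
    source_seed = secondStepWeights@provenance$seed)
  out
}

#' Save / load U-Net weights
#'
#' Weights are serialized with `saveRDS()`; a human-readable JSON sidecar
#' (`<path>.json`) records the architecture and provenance (stage, seed,
#' epochs) for auditability.
#'
#' @param weights a [UNetWeights-class].
#' @param path destination `.rds` path.
#' @return `path` invisibly ([saveWeights()]); a [UNetWeights-class]
#'   ([loadWeights()]).
#' @export
saveWeights <- function(weights, path) {
  saveRDS(weights, path)
  sidecar <- list(
    spec = list(depth = weights@spec@depth,
                baseChannels = weights@spec@baseChannels,
                inChannels = weights@spec@inChannels),
    provenance = weights@provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname saveWeights
#' @export
loadWeights <- function(path) {
  if (!file.exists(path))
    .fibsegError("fibseg_io_error", sprintf("checkpoint does not exist: %s", path))
  w <- readRDS(path)
  if (!is(w, "UNetWeights"))
    .fibsegError("fibseg_format_error", "file does not contain UNetWeights")
  w
}
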