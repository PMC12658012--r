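# Architecture contract, forward-pass shape behaviour, Dice loss,
# gradient correctness, training-loop determinism and Expansion
# Transfer Learning.

test_that("the full-size architecture matches the published layer inventory", {
  spec <- unetSpec()                       # depth 4, base 16
  plan <- unetLayers(spec)
  expect_equal(sum(plan$path == "encoder"), 10)   # ten encoder convolutions
  expect_equal(spec@depth, 4L)                    # four pooling steps
  expect_equal(max(plan$cout), 512)               # deepest feature maps
  expect_equal(plan$cout[plan$name == "enc_in"], 16)
  expect_equal(plan$cout[nrow(plan)], 1)          # single-channel output
  # feature maps double at every pooling step
  encB <- plan[grepl("^enc\\db$", plan$name), ]
  expect_equal(encB$cout, 16 * 2^(1:4))
  # all published stage resolutions are divisible by 2^4
  for (res in list(c(144, 144, 288), c(80, 80, 960), c(96, 192, 320)))
    expect_true(all(res %% 2^spec@depth == 0))
})

test_that("weight initialization is seed-deterministic", {
  spec <- testSpec()
  w1 <- buildUNet(spec, seed = 9)
  w2 <- buildUNet(spec, seed = 9)
  expect_identical(w1@params, w2@params)
  w3 <- buildUNet(spec, seed = 10)
  expect_false(identical(w1@params, w3@params))
  # parameter shapes follow the plan
  plan <- unetLayers(spec)
  for (i in seq_len(nrow(plan))) {
    expect_equal(dim(w1@params[[plan$name[i]]]$W),
                 c(27 * plan$cin[i], plan$cout[i]))
  }
})

test_that("forward preserves shape, bounds output, and validates divisibility", {
  w <- buildUNet(unetSpec(), seed = 1)     # full-size network
  x <- array(runif(32 * 32 * 64), c(32, 32, 64))
  p <- unetForward(w, x)
  expect_equal(dim(p), c(32, 32, 64))
  expect_true(all(p >= 0 & p <= 1))
  # the offending axis is named in the error
  expect_error(unetForward(w, array(0.5, c(30, 32, 64))),
               "axis 1", class = "fibseg_shape_error")
  expect_error(unetForward(w, array(0.5, c(32, 32, 60))),
               "axis 3", class = "fibseg_shape_error")
  # constant input gives a spatially constant response away from the
  # borders (interior chosen beyond the receptive-field radius)
  wc <- buildUNet(unetSpec(depth = 1L, baseChannels = 2L), seed = 2)
  pc <- unetForward(wc, array(0.5, c(32, 32, 32)))
  inner <- pc[14:19, 14:19, 14:19]
  expect_lt(max(inner) - min(inner), 1e-9)
})

test_that("the soft Dice loss matches hand arithmetic and is symmetric", {
  t <- array(1, c(2, 2, 2))
  expect_lt(diceLoss(t, t), 1e-6)                     # perfect overlap
  p0 <- array(0, c(2, 2, 2)); t0 <- array(1, c(2, 2, 2))
  expect_gt(diceLoss(p0, t0), 1 - 1e-6)               # disjoint
  # p = 0.5 everywhere, t = all ones on 8 voxels: 1 - 8/12 = 1/3
  expect_equal(diceLoss(array(0.5, c(2, 2, 2)), t), 1 / 3, tolerance = 1e-5)
  # symmetric in its arguments for binary inputs
  set.seed(4)
  a <- array(as.numeric(runif(27) > 0.5), c(3, 3, 3))
  b <- array(as.numeric(runif(27) > 0.5), c(3, 3, 3))
  expect_equal(diceLoss(a, b), diceLoss(b, a))
  expect_error(diceLoss(array(0.5, c(2, 2, 2)), array(1, c(4, 2, 1))),
               class = "fibseg_shape_error")
})

test_that("backpropagation agrees with finite differences", {
  set.seed(42)
  spec <- unetSpec(depth = 1L, baseChannels = 2L)
  w <- buildUNet(spec, seed = 3)
  x <- array(runif(4 * 4 * 4), c(4, 4, 4))
  y <- array(as.integer(runif(4 * 4 * 4) > 0.6), c(4, 4, 4))
  run <- fibseg:::.unetRun(w, x, cache = TRUE)
  gp <- fibseg:::.diceLossGrad(as.numeric(run$prob), as.numeric(y))
  attr(gp, "cache") <- run$cache
  grads <- fibseg:::.unetBackprop(w, gp)
  L0 <- diceLoss(run$prob, y)
  eps <- 1e-6
  for (ln in names(w@params)) {
    for (rep in 1:2) {
      i <- sample(length(w@params[[ln]]$W), 1)
      w2 <- w; w2@params[[ln]]$W[i] <- w2@params[[ln]]$W[i] + eps
      num <- (diceLoss(fibseg:::.unetRun(w2, x), y) - L0) / eps
      ana <- grads[[ln]]$gW[i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("one small gradient step decreases the Dice loss", {
  set.seed(5)
  spec <- unetSpec(depth = 1L, baseChannels = 2L)
  w <- buildUNet(spec, seed = 7)
  x <- array(runif(8 * 8 * 8), c(8, 8, 8))
  y <- array(0L, c(8, 8, 8)); y[3:6, 3:6, 3:6] <- 1L
  run <- fibseg:::.unetRun(w, x, cache = TRUE)
  L0 <- diceLoss(run$prob, y)
  gp <- fibseg:::.diceLossGrad(as.numeric(run$prob), as.numeric(y))
  attr(gp, "cache") <- run$cache
  grads <- fibseg:::.unetBackprop(w, gp)
  lr <- 1e-3
  for (ln in names(w@params)) {
    w@params[[ln]]$W <- w@params[[ln]]$W - lr * grads[[ln]]$gW
    w@params[[ln]]$b <- w@params[[ln]]$b - lr * grads[[ln]]$gb
  }
  expect_lt(diceLoss(fibseg:::.unetRun(w, x), y), L0)
})

makeBlobSamples <- function(n, d = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cx <- sample(3:6, 3, replace = TRUE)
    y <- array(0L, d)
    y[(cx[1] - 1):(cx[1] + 1), (cx[2] - 1):(cx[2] + 1), (cx[3] - 1):(cx[3] + 1)] <- 1L
    x <- y + array(rnorm(prod(d), 0, 0.1), d)
    list(x = pmin(pmax(x, 0), 1), y = y)
  })
}

test_that("training converges on a toy task, deterministically, with checkpointing", {
  spec <- unetSpec(depth = 1L, baseChannels = 2L)
  ss <- makeBlobSamples(6, seed = 2)
  samples <- list(train = ss[1:5], val = ss[6])
  cfg <- unetTrainConfig(lr = 5e-3, epochs = 30, seed = 8)
  r1 <- trainUNet(samples, cfg, spec = spec, stage = "toy")
  expect_true(all(is.finite(r1$history$train_loss)))
  # checkpoint selection: returned weights achieve the minimum val loss
  expect_equal(min(r1$history$val_loss), r1$weights@provenance$best_val_loss)
  expect_lte(r1$weights@provenance$best_val_loss, r1$history$val_loss[1])
  # the toy task is learned
  expect_lt(min(r1$history$val_loss), 0.3)
  # full seed determinism of the history
  r2 <- trainUNet(samples, cfg, spec = spec, stage = "toy")
  expect_identical(r1$history, r2$history)
  # warm-starting from the converged weights does not hurt
  r3 <- trainUNet(samples, unetTrainConfig(lr = 1e-4, epochs = 3, seed = 8),
                  initWeights = r1$weights, stage = "toy2")
  expect_lte(r3$weights@provenance$best_val_loss,
             r1$weights@provenance$best_val_loss + 0.05)
  expect_error(trainUNet(list(train = list(), val = ss[6]), cfg, spec = spec),
               class = "fibseg_data_error")
})

test_that("expansion transfer copies every parameter and survives resolution changes", {
  spec <- testSpec()
  ss <- makeBlobSamples(3, d = c(8, 8, 8), seed = 3)
  r <- trainUNet(list(train = ss[1:2], val = ss[3]),
                 unetTrainConfig(epochs = 2, seed = 1), spec = spec,
                 stage = "step2")
  w1 <- expansionTransfer(r$weights, spec)
  # identity on parameters
  expect_identical(w1@params, r$weights@params)
  expect_equal(w1@provenance$stage, "step1_init")
  expect_equal(w1@provenance$transferredFrom, "step2")
  # inference at a different input resolution succeeds after transfer
  p <- unetForward(w1, array(runif(16 * 24 * 32), c(16, 24, 32)))
  expect_equal(dim(p), c(16, 24, 32))
  # incompatible channel progressions are rejected with layer names
  expect_error(expansionTransfer(r$weights, unetSpec(depth = 2L, baseChannels = 8L)),
               class = "fibseg_transfer_error")
  expect_error(expansionTransfer(r$weights, unetSpec(depth = 3L, baseChannels = 4L)),
               class = "fibseg_transfer_error")
})

test_that("weight checkpoints round-trip with a JSON sidecar", {
  w <- buildUNet(testSpec(), seed = 4)
  f <- withr::local_tempfile(fileext = ".rds")
  saveWeights(w, f)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$spec$depth, 2)
  r <- loadWeights(f)
  expect_identical(r@params, w@params)
  expect_error(loadWeights("nope.rds"), class = "fibseg_io_error")
})
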