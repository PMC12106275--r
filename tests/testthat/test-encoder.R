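tiny_cfg <- function(op = "dwt", seed = 5)
  encoder_config("tiny", input_shape = c(16L, 16L, 16L), stem_channels = 3L,
                 stem_downsample = 1L, stage_widths = c(4L, 6L),
                 stage_downsample = c(1L, 1L), blocks_per_stage = c(1L, 1L),
                 feature_dim = 6L, downsample_op = op, seed = seed)

test_that("initialisation is deterministic in the seed", {
  a <- init_encoder(tiny_cfg(seed = 9))
  b <- init_encoder(tiny_cfg(seed = 9))
  expect_identical(a, b)
  c <- init_encoder(tiny_cfg(seed = 10))
  expect_gt(max(abs(a$stem$W - c$stem$W)), 0)
})

test_that("the default preset emits a length-512 feature vector from 32^3", {
  st <- init_encoder(encoder_config("default", seed = 1))
  z <- encode(array(rnorm(32^3), c(32, 32, 32)), st)
  expect_equal(dim(z), c(1L, 512L))
  expect_true(all(is.finite(z)))
})

test_that("invalid configurations are rejected", {
  expect_error(encoder_config("tiny", input_shape = c(8L, 8L, 8L),
                              stem_downsample = 2L,
                              stage_downsample = c(2L, 2L)),
               "invalid config")
  expect_error(encoder_config("tiny", feature_dim = 7L), "feature_dim")
  expect_error(encoder_config("tiny", stage_downsample = c(3L, 0L)),
               "downsample steps")
})

test_that("wavelet blocks contract shapes by 2^downsample_steps", {
  set.seed(2)
  blk <- cryowave:::block_init(2L, 4L, 1L)
  x <- array(rnorm(16^3 * 3 * 2), c(16^3, 3, 2))
  r <- wavelet_block_forward(x, c(16L, 16L, 16L), blk)
  expect_equal(r$d3, c(8L, 8L, 8L))
  expect_equal(dim(r$out), c(512L, 3L, 4L))
  blk2 <- cryowave:::block_init(2L, 4L, 2L)
  r2 <- wavelet_block_forward(x, c(16L, 16L, 16L), blk2)
  expect_equal(r2$d3, c(4L, 4L, 4L))
  expect_error(wavelet_block_forward(x, c(15L, 15L, 15L), blk),
               "invalid shape")
})

test_that("a zeroed block is the identity on its residual path", {
  set.seed(3)
  blk <- cryowave:::block_init(3L, 3L, 0L)
  blk$W1[] <- 0; blk$W2[] <- 0
  x <- array(abs(rnorm(8^3 * 2 * 3)), c(8^3, 2, 3))  # nonnegative input
  r <- wavelet_block_forward(x, c(8L, 8L, 8L), blk, training = FALSE)
  expect_equal(r$out, x)
})

test_that("zero input produces zero pre-normalisation activations", {
  set.seed(4)
  blk <- cryowave:::block_init(2L, 4L, 1L)
  x <- array(0, c(8^3, 2, 2))
  lo <- cryowave:::nn_dwt_low(x, c(8L, 8L, 8L), "ch3.3")
  cv <- cryowave:::conv3_forward(lo$out, lo$d3, blk$W1)
  expect_equal(max(abs(cv$out)), 0)
})

test_that("encoding is deterministic and batch-consistent", {
  st <- init_encoder(tiny_cfg())
  v <- array(rnorm(16^3), c(16, 16, 16))
  z1 <- encode(list(v, v, v), st)
  expect_equal(dim(z1), c(3L, 6L))
  expect_equal(z1[1, ], z1[2, ])
  expect_equal(encode(v, st), z1[1, , drop = FALSE], tolerance = 1e-6)
  expect_error(encode(array(0, c(8, 8, 8)), st), "invalid shape")
})

test_that("different banks give different features", {
  v <- array(rnorm(16^3), c(16, 16, 16))
  z_haar <- encode(v, init_encoder(tiny_cfg()))
  cfg2 <- tiny_cfg(); cfg2$bank_name <- "haar"
  z_ch <- encode(v, init_encoder(cfg2))
  expect_gt(max(abs(z_haar - z_ch)), 0)
})

test_that("intermediate resolutions follow the downsampling schedule", {
  cfg <- tiny_cfg()
  st <- init_encoder(cfg)
  X <- array(rnorm(16^3 * 2), c(16^3, 2, 1))
  fw <- cryowave:::encoder_forward(st, X, training = FALSE)
  d3s <- lapply(fw$caches$blocks, function(b) b$d3_in)
  expect_equal(d3s[[1]], c(8L, 8L, 8L))   # after stem downsample
  expect_equal(d3s[[2]], c(4L, 4L, 4L))   # after stage 1
  expect_equal(prod(fw$caches$final_v), 2L^3L)  # after stage 2
})

test_that("encoder gradients match finite differences", {
  set.seed(9)
  cfg <- encoder_config("tiny", input_shape = c(8L, 8L, 8L),
                        stem_channels = 3L, stem_downsample = 1L,
                        stage_widths = c(4L, 6L), stage_downsample = c(1L, 0L),
                        blocks_per_stage = c(1L, 1L), feature_dim = 6L,
                        seed = 5)
  st <- init_encoder(cfg)
  w <- init_classifier(6, 2, "tvmf", tau = 8, seed = 2)
  X <- array(rnorm(512 * 3), c(512, 3, 1)); lab <- c(1, 2, 1)
  loss_of <- function(s) {
    fw <- cryowave:::encoder_forward(s, X, training = TRUE)
    cryowave:::classifier_grad(fw$z, w, lab)$loss
  }
  fw <- cryowave:::encoder_forward(st, X, training = TRUE)
  cg <- cryowave:::classifier_grad(fw$z, w, lab)
  ge <- cryowave:::encoder_backward(fw$state, fw$caches, cg$dZ)
  eps <- 1e-5
  probe <- list(
    list(get = function(s) s$stem$W, set = function(s, p) { s$stem$W[] <- p; s },
         g = ge$stem$W),
    list(get = function(s) s$blocks[[1]]$W1,
         set = function(s, p) { s$blocks[[1]]$W1[] <- p; s },
         g = ge$blocks[[1]]$W1),
    list(get = function(s) s$blocks[[1]]$Wp,
         set = function(s, p) { s$blocks[[1]]$Wp[] <- p; s },
         g = ge$blocks[[1]]$Wp),
    list(get = function(s) s$blocks[[2]]$W2,
         set = function(s, p) { s$blocks[[2]]$W2[] <- p; s },
         g = ge$blocks[[2]]$W2),
    list(get = function(s) s$blocks[[1]]$bn1$gamma,
         set = function(s, p) { s$blocks[[1]]$bn1$gamma <- p; s },
         g = ge$blocks[[1]]$bn1$gamma),
    list(get = function(s) s$stem$bn$beta,
         set = function(s, p) { s$stem$bn$beta <- p; s },
         g = ge$stem$bn$beta))
  for (pr in probe) {
    for (k in 1:3) {
      i <- sample(length(pr$get(st)), 1)
      sp <- st; p <- pr$get(sp); p[i] <- p[i] + eps; sp <- pr$set(sp, p)
      sm <- st; p <- pr$get(sm); p[i] <- p[i] - eps; sm <- pr$set(sm, p)
      fd <- (loss_of(sp) - loss_of(sm)) / (2 * eps)
      expect_equal(pr$g[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("the strided-convolution control produces matching shapes", {
  st <- init_encoder(tiny_cfg(op = "conv"))
  v <- array(rnorm(16^3), c(16, 16, 16))
  z <- encode(v, st)
  expect_equal(dim(z), c(1L, 6L))
  expect_true(all(is.finite(z)))
})
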