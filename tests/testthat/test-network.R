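# Dual-encoder U-Net: aux input preparation, the frozen mock encoder,
# embedding resizing, fusion strategies, model construction and gradients.

test_that("prepare_aux_input preserves constants, identity size and linear ramps", {
  const <- matrix(0.37, 256, 256)
  up <- prepare_aux_input(const)
  expect_equal(dim(up), c(1024, 1024))
  expect_true(all(abs(up - 0.37) < 1e-12))
  id <- matrix(runif(1024 * 1024), 1024, 1024)
  expect_equal(prepare_aux_input(id), id)
  ramp <- matrix(rep(seq(0, 1, length.out = 64), 64), 64, 64)
  upr <- prepare_aux_input(ramp)
  # bilinear interpolation keeps a plane linear: second differences vanish
  expect_lt(max(abs(diff(upr[, 1], differences = 2))), 1e-6)
  expect_lt(max(abs(upr[, 1] - upr[, 512])), 1e-12)
  expect_error(prepare_aux_input(matrix(0, 4, 4)), "8 x 8")
})

test_that("mock auxiliary encoder is deterministic, seed-sensitive and frozen", {
  enc <- mock_auxiliary_encoder(seed = 21, channels = 6)
  img <- matrix(runif(64 * 64), 64, 64)
  e1 <- enc$encode(img)
  e2 <- enc$encode(img)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(64, 64, 6))
  enc2 <- mock_auxiliary_encoder(seed = 22, channels = 6)
  expect_false(isTRUE(all.equal(enc2$encode(img), e1)))
  expect_true(enc$frozen)
  expect_identical(enc$fingerprint, mock_auxiliary_encoder(21, 6)$fingerprint)
})

test_that("resize_embedding keeps channels, constants and block means", {
  e <- array(rnorm(64 * 64 * 5), c(64, 64, 5))
  expect_identical(resize_embedding(e, c(64, 64)), e)
  const <- array(2.5, c(16, 16, 3))
  expect_true(all(abs(resize_embedding(const, c(40, 40)) - 2.5) < 1e-12))
  down <- resize_embedding(e, c(16, 16))
  expect_equal(dim(down), c(16, 16, 5))
  for (k in 1:5) {
    # area resampling at an integer factor is an exact block mean
    bm <- matrix(0, 16, 16)
    for (i in 1:16) for (j in 1:16)
      bm[i, j] <- mean(e[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j), k])
    expect_equal(down[, , k], bm, tolerance = 1e-3)
    expect_equal(mean(down[, , k]), mean(e[, , k]), tolerance = 1e-3)
  }
})

test_that("fusion strategies obey their shape and identity contracts", {
  main <- array(rnorm(16 * 16 * 32), c(16, 16, 32))
  aux <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  cc <- fuse_embeddings(main, aux, "concatenate")
  expect_equal(dim(cc), c(16, 16, 40))
  expect_equal(cc[, , 1:32], main)
  same <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  expect_equal(fuse_embeddings(same, same * 0, "addition"), same)
  expect_equal(fuse_embeddings(same, same * 0 + 1, "multiplication"), same)
  ag <- fuse_embeddings(main, aux, "attention_gate")
  expect_equal(dim(ag), dim(main))
  bad <- array(0, c(8, 8, 8))
  expect_error(fuse_embeddings(main, bad, "concatenate"), "spatial")
})

test_that("build_model enforces config invariants and produces normalized heads", {
  expect_error(arch_config(seg_head_enabled = FALSE, reg_head_enabled = FALSE),
               "head")
  expect_error(arch_config(input_size = c(100, 100), depth = 4), "divisible")
  cfg <- arch_config(input_size = c(64, 64), depth = 3, base_channels = 4,
                     aux_enabled = TRUE, aux_channels = 3)
  model <- build_model(cfg, seed = 2)
  img <- matrix(runif(64 * 64), 64, 64)
  out <- model_forward(model, img)
  expect_equal(dim(out$prob), c(64, 64, 2))
  expect_equal(dim(out$phi), c(64, 64, 2))
  sums <- out$prob[, , 1] + out$prob[, , 2]
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("disabling the aux branch makes the forward pass encoder-independent", {
  cfg <- arch_config(input_size = c(32, 32), depth = 2, base_channels = 4,
                     aux_enabled = FALSE)
  model <- build_model(cfg, seed = 3)
  expect_null(model$aux)
  img <- matrix(runif(1024), 32, 32)
  o1 <- model_forward(model, img)
  o2 <- model_forward(model, img,
                      aux_embedding = array(rnorm(64 * 64 * 8), c(64, 64, 8)))
  expect_identical(o1$prob, o2$prob)
})

test_that("concatenate fusion carries more parameters than addition", {
  base <- function(fusion) n_parameters(build_model(
    arch_config(input_size = c(32, 32), depth = 2, base_channels = 8,
                aux_enabled = TRUE, fusion = fusion), seed = 1))
  expect_gt(base("concatenate"), base("addition"))
})

test_that("model gradients match directional finite differences", {
  set.seed(31)
  for (setup in list(list(norm = "batch", fusion = "attention_gate"),
                     list(norm = "none", fusion = "concatenate"),
                     list(norm = "batch", fusion = "multiplication"))) {
    cfg <- arch_config(input_size = c(16, 16), num_classes = 2, depth = 2,
                       base_channels = 4, aux_enabled = TRUE, aux_channels = 3,
                       fusion = setup$fusion, norm = setup$norm)
    model <- build_model(cfg, seed = 5)
    img <- matrix(runif(256), 16, 16)
    lab <- (img > 0.5) * 1L
    y <- shapeprior:::one_hot(lab, 2)
    phi_t <- unclass(labels_to_levelset(label_mask(lab, 2)))
    emb <- model$aux$encode(img)
    lossfn <- function(params) {
      m2 <- model; m2$params <- params
      out <- model_forward(m2, img, aux_embedding = emb, training = TRUE)
      segmentation_loss(out$prob, y) + 0.1 * levelset_mse(out$phi, phi_t)
    }
    out <- model_forward(model, img, aux_embedding = emb, keep_cache = TRUE,
                         training = TRUE)
    dlog <- shapeprior:::seg_loss_grad_logits(out$prob, y)
    dphi <- 0.1 * shapeprior:::levelset_mse_grad(out$phi, phi_t)
    g <- shapeprior:::model_backward(model, out$cache, dlog, dphi)
    # random direction over all parameters: high signal-to-noise even with
    # single-precision convolution kernels
    dirs <- lapply(model$params, function(p) {
      d <- rnorm(length(p))
      if (!is.null(dim(p))) dim(d) <- dim(p)
      d
    })
    h <- 1e-3
    pp <- model$params; pm <- model$params
    for (nm in names(pp)) {
      pp[[nm]] <- pp[[nm]] + h * dirs[[nm]]
      pm[[nm]] <- pm[[nm]] - h * dirs[[nm]]
    }
    fd <- (lossfn(pp) - lossfn(pm)) / (2 * h)
    an <- sum(vapply(names(g), function(nm) sum(g[[nm]] * dirs[[nm]]), 0))
    # single-precision convolution kernels and ReLU kinks crossed by the
    # full-parameter perturbation bound the achievable agreement
    expect_equal(an, fd, tolerance = 8e-2)
  }
})

test_that("all four fusion strategies train end-to-end and halve the loss", {
  for (fusion in c("concatenate", "addition", "multiplication",
                   "attention_gate")) {
    cfg <- run_config(
      architecture = arch_config(input_size = c(48, 48), depth = 2,
                                 base_channels = 4, aux_enabled = TRUE,
                                 aux_channels = 4, fusion = fusion),
      data = circle_dataset_spec(n_images = 10, image_size = c(48, 48),
                                 radius_range = c(5, 12), seed = 17),
      seed = 17, steps = 200, batch_size = 2)
    fit <- train(cfg)
    first <- mean(fit$log$total[1:5])
    last <- mean(fit$log$total[196:200])
    expect_lt(last, 0.5 * first)
    expect_identical(fit$aux_fingerprint_before, fit$aux_fingerprint_after)
  }
})

test_that("predict_mask falls back to the level-set sign rule without a seg head", {
  cfg <- arch_config(input_size = c(32, 32), depth = 2, base_channels = 4,
                     aux_enabled = FALSE, seg_head_enabled = FALSE)
  model <- build_model(cfg, seed = 9)
  img <- matrix(runif(1024), 32, 32)
  out <- model_forward(model, img)
  expect_null(out$prob)
  lab <- predict_mask(model, img)
  expect_identical(sort(unique(as.vector(lab))),
                   sort(unique(as.vector((out$phi[, , 2] < 0) * 1L))))
  expect_identical(lab, matrix((out$phi[, , 2] < 0) * 1L, 32, 32))
})
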