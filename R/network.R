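# Dual-encoder U-Net with a frozen auxiliary embedding provider, four
# embedding-fusion strategies and a two-head decoder (segmentation
# probabilities + level-set regression). The trainable encoder/decoder is a
# plain U-Net; the auxiliary encoder is any frozen provider honoring the
# `auxiliary_encoder` contract (a seeded mock is included so everything runs
# offline). The auxiliary embedding joins the network at the deepest decoder
# input only.

#' Architecture configuration
#'
#' Explicit configuration of the segmentation network: a U-Net with `depth`
#' resolution levels (channels doubling from `base_channels`, capped at
#' `max_channels`), an optional frozen auxiliary encoder whose embedding is
#' fused into the deepest decoder input, and up to two output heads.
#'
#' @param input_size Spatial input size `c(H, W)`; must be divisible by
#'   `2^(depth - 1)`.
#' @param num_classes Number of segmentation classes `C` (>= 2).
#' @param depth Number of resolution levels (>= 2).
#' @param base_channels Channels at the finest level.
#' @param max_channels Channel cap at deep levels.
#' @param fusion One of `"concatenate"`, `"addition"`, `"multiplication"`,
#'   `"attention_gate"`.
#' @param aux_enabled Use the auxiliary encoder branch.
#' @param aux_channels Channels of the auxiliary embedding.
#' @param reg_head_enabled Include the level-set regression head.
#' @param seg_head_enabled Include the segmentation (softmax) head.
#' @param norm Normalization inside conv blocks: `"none"` (conv-ReLU, the
#'   original U-Net block; the default, which also lets the level-set
#'   regression head reach its large raw-distance targets quickly) or
#'   `"batch"` (conv-BN-ReLU with running statistics for inference).
#' @return An `arch_config` list.
#' @export
arch_config <- function(input_size = c(128, 128), num_classes = 2,
                        depth = 5, base_channels = 32, max_channels = 256,
                        fusion = c("concatenate", "addition",
                                   "multiplication", "attention_gate"),
                        aux_enabled = TRUE, aux_channels = 8,
                        reg_head_enabled = TRUE, seg_head_enabled = TRUE,
                        norm = c("none", "batch")) {
  fusion <- match.arg(fusion)
  norm <- match.arg(norm)
  if (depth < 2) stop("depth must be >= 2", call. = FALSE)
  if (!seg_head_enabled && !reg_head_enabled)
    stop("at least one output head must be enabled", call. = FALSE)
  if (num_classes < 2) stop("num_classes must be >= 2", call. = FALSE)
  div <- 2^(depth - 1)
  if (any(input_size %% div != 0))
    stop(sprintf("input_size must be divisible by %d for depth %d",
                 div, depth), call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 fusion = fusion, aux_enabled = isTRUE(aux_enabled),
                 aux_channels = as.integer(aux_channels),
                 reg_head_enabled = isTRUE(reg_head_enabled),
                 seg_head_enabled = isTRUE(seg_head_enabled),
                 norm = norm),
            class = "arch_config")
}

level_channels <- function(cfg) {
  pmin(cfg$base_channels * 2^(0:(cfg$depth - 1)), cfg$max_channels)
}

#' Resize an image for the auxiliary encoder
#'
#' Bilinear resize of a grayscale image to the auxiliary encoder's fixed
#' 1024 x 1024 input size. The intensity range is preserved (bilinear
#' interpolation of a constant is the constant; linear ramps stay linear),
#' and a 1024 x 1024 input passes through unchanged.
#'
#' @param image Numeric matrix (H, W >= 8).
#' @param size Target side length.
#' @return `size` x `size` numeric matrix.
#' @export
prepare_aux_input <- function(image, size = 1024) {
  stop_if_not_matrix(image, "image")
  if (nrow(image) < 8 || ncol(image) < 8)
    stop("image must be at least 8 x 8", call. = FALSE)
  x <- as_chw_array(image)
  out <- cpp_resize_bilinear(x, nrow(image), ncol(image), 1L, size, size)
  out[, , 1]
}

#' Resize an embedding grid spatially
#'
#' Channel count is unchanged. Downscaling uses area-weighted averaging
#' (exact block means for integer factors, so per-channel means are
#' conserved); upscaling uses bilinear interpolation. Resizing to the
#' current size returns the input unchanged.
#'
#' @param e `h x w x c` embedding array.
#' @param target_hw Target spatial size `c(h, w)`.
#' @return Resized `target_h x target_w x c` array.
#' @export
resize_embedding <- function(e, target_hw) {
  e <- as_chw_array(e)
  d <- dim(e)
  th <- as.integer(target_hw[1]); tw <- as.integer(target_hw[2])
  if (th < 1 || tw < 1) stop("target dims must be >= 1", call. = FALSE)
  if (th == d[1] && tw == d[2]) return(e)
  if (th <= d[1] && tw <= d[2]) cpp_resize_area(e, d[1], d[2], d[3], th, tw)
  else cpp_resize_bilinear(e, d[1], d[2], d[3], th, tw)
}

#' Seeded mock auxiliary encoder
#'
#' A frozen, deterministic stand-in for a pretrained foundation-model image
#' encoder, for offline runs and tests. It is synthetic: a fixed random
#' two-layer convolutional projection whose weights are drawn once from
#' `seed`. `encode()` resizes the input to 1024 x 1024
#' ([prepare_aux_input()]), reduces it to the fixed 64 x 64 embedding grid
#' by area averaging, and applies the frozen tanh convolutions. Identical
#' (seed, input) pairs give bitwise-identical embeddings; the parameters
#' are never updated by training.
#'
#' @param seed Integer seed for the frozen weights.
#' @param channels Embedding channels.
#' @return An object of class `auxiliary_encoder` with fields `encode`
#'   (function image -> 64 x 64 x channels array), `channels`, `frozen`,
#'   `fingerprint` and `spec` (enough to reconstruct it).
#' @export
mock_auxiliary_encoder <- function(seed = 1, channels = 8) {
  hidden <- 16L
  w <- with_local_seed(seed, list(
    l1 = init_conv(3, 1, hidden),
    l2 = init_conv(3, hidden, channels)
  ))
  encode <- function(image) {
    x1024 <- prepare_aux_input(image)
    x64 <- cpp_resize_area(as_chw_array(x1024), 1024L, 1024L, 1L, 64L, 64L)
    h <- tanh(conv_layer_forward(x64, w$l1$W, w$l1$b, 3L))
    tanh(conv_layer_forward(h, w$l2$W, w$l2$b, 3L))
  }
  structure(list(encode = encode, channels = as.integer(channels),
                 frozen = TRUE, weights = w, fingerprint = fingerprint(w),
                 spec = list(type = "mock", seed = seed,
                             channels = as.integer(channels))),
            class = "auxiliary_encoder")
}

#' @export
print.auxiliary_encoder <- function(x, ...) {
  cat(sprintf("<auxiliary_encoder: %d-channel 64x64 embedding, frozen, %s>\n",
              x$channels, substr(x$fingerprint, 1, 8)))
  invisible(x)
}

make_fusion_params <- function(fusion, main_ch, aux_ch) {
  # Draws from the caller's RNG stream.
  switch(fusion,
    concatenate = list(),
    addition = ,
    multiplication = list(fuse_proj = init_conv(1, aux_ch, main_ch)),
    attention_gate = {
      ci <- max(4L, main_ch %/% 2L)
      list(att_m = init_conv(1, main_ch, ci),
           att_a = init_conv(1, aux_ch, ci),
           att_psi = init_conv(1, ci, 1L, gain = 1))
    })
}

#' Fuse main and auxiliary embedding grids
#'
#' Combines two spatially aligned feature grids. `"concatenate"` stacks
#' channels; `"addition"` / `"multiplication"` combine elementwise (the
#' auxiliary grid is first passed through a learned 1x1 projection to match
#' channels, or used raw if channel counts already agree and no params are
#' given); `"attention_gate"` modulates the main grid by a learned sigmoid
#' gate computed from both inputs (output channels = main channels).
#'
#' @param main,aux `h x w x c` arrays with equal spatial dims.
#' @param strategy A fusion strategy name.
#' @param params Learned fusion parameters from the model (created with
#'   seeded defaults when `NULL` and required).
#' @return Fused embedding array.
#' @export
fuse_embeddings <- function(main, aux,
                            strategy = c("concatenate", "addition",
                                         "multiplication", "attention_gate"),
                            params = NULL) {
  strategy <- match.arg(strategy)
  main <- as_chw_array(main); aux <- as_chw_array(aux)
  if (!all(dim(main)[1:2] == dim(aux)[1:2]))
    stop("spatial dims of main and aux must match", call. = FALSE)
  if (is.null(params) && strategy != "concatenate" &&
      !(strategy %in% c("addition", "multiplication") &&
        dim(main)[3] == dim(aux)[3])) {
    params <- with_local_seed(1, make_fusion_params(strategy, dim(main)[3],
                                                    dim(aux)[3]))
  }
  fuse_forward(main, aux, strategy, params)$out
}

fuse_forward <- function(main, aux, strategy, params) {
  switch(strategy,
    concatenate = list(out = concat_ch(main, aux)),
    addition = {
      pa <- if (!is.null(params$fuse_proj))
        conv_layer_forward(aux, params$fuse_proj$W, params$fuse_proj$b, 1L)
      else aux
      if (dim(pa)[3] != dim(main)[3])
        stop("addition fusion requires equal channel counts", call. = FALSE)
      list(out = main + pa, pa = pa)
    },
    multiplication = {
      pa <- if (!is.null(params$fuse_proj))
        conv_layer_forward(aux, params$fuse_proj$W, params$fuse_proj$b, 1L)
      else aux
      if (dim(pa)[3] != dim(main)[3])
        stop("multiplication fusion requires equal channel counts",
             call. = FALSE)
      list(out = main * pa, pa = pa)
    },
    attention_gate = {
      m <- conv_layer_forward(main, params$att_m$W, params$att_m$b, 1L)
      a <- conv_layer_forward(aux, params$att_a$W, params$att_a$b, 1L)
      q <- relu(m + a)
      zg <- conv_layer_forward(q, params$att_psi$W, params$att_psi$b, 1L)
      g <- 1 / (1 + exp(-zg))
      C <- dim(main)[3]
      gate <- array(rep(g[, , 1], C), dim(main))
      list(out = main * gate, q = q, zq = m + a, g = g, gate = gate)
    })
}

# Backward through fusion; returns grads for main and fusion params
# (the frozen aux branch receives no parameter updates).
fuse_backward <- function(dfused, main, aux, strategy, params, cache) {
  grads <- list()
  switch(strategy,
    concatenate = {
      cm <- dim(main)[3]
      list(dmain = dfused[, , seq_len(cm), drop = FALSE], grads = grads)
    },
    addition = {
      if (!is.null(params$fuse_proj)) {
        bw <- conv_layer_backward(aux, params$fuse_proj$W, dfused, 1L)
        grads[["fuse_proj.W"]] <- bw$dw
        grads[["fuse_proj.b"]] <- bw$db
      }
      list(dmain = dfused, grads = grads)
    },
    multiplication = {
      dmain <- dfused * cache$pa
      dpa <- dfused * main
      if (!is.null(params$fuse_proj)) {
        bw <- conv_layer_backward(aux, params$fuse_proj$W, dpa, 1L)
        grads[["fuse_proj.W"]] <- bw$dw
        grads[["fuse_proj.b"]] <- bw$db
      }
      list(dmain = dmain, grads = grads)
    },
    attention_gate = {
      dmain <- dfused * cache$gate
      dg <- dfused * main
      dg1 <- dg[, , 1]
      C <- dim(main)[3]
      if (C > 1) for (k in 2:C) dg1 <- dg1 + dg[, , k]
      dzg <- array(dg1, c(dim(main)[1], dim(main)[2], 1L)) *
        cache$g * (1 - cache$g)
      bw_psi <- conv_layer_backward(cache$q, params$att_psi$W, dzg, 1L)
      grads[["att_psi.W"]] <- bw_psi$dw
      grads[["att_psi.b"]] <- bw_psi$db
      dq <- bw_psi$dx
      dq[cache$zq <= 0] <- 0
      bw_m <- conv_layer_backward(main, params$att_m$W, dq, 1L)
      grads[["att_m.W"]] <- bw_m$dw
      grads[["att_m.b"]] <- bw_m$db
      bw_a <- conv_layer_backward(aux, params$att_a$W, dq, 1L)
      grads[["att_a.W"]] <- bw_a$dw
      grads[["att_a.b"]] <- bw_a$db
      list(dmain = dmain + bw_m$dx, grads = grads)
    })
}

#' Build a segmentation model
#'
#' Constructs the U-Net encoder-decoder with skip connections, the optional
#' frozen auxiliary branch (fused at the deepest decoder input), and the
#' enabled output heads: a softmax segmentation head producing per-pixel
#' class probabilities and/or a linear regression head producing a
#' per-class level-set prediction. Weights are He-initialized from `seed`.
#'
#' @param cfg An [arch_config].
#' @param aux_encoder An `auxiliary_encoder`; when `NULL` and the auxiliary
#'   branch is enabled, a [mock_auxiliary_encoder()] derived from `seed` is
#'   attached.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `segmentation_model`.
#' @export
build_model <- function(cfg, aux_encoder = NULL, seed = 1) {
  stopifnot(inherits(cfg, "arch_config"))
  ch <- level_channels(cfg)
  d <- cfg$depth
  if (cfg$aux_enabled && is.null(aux_encoder))
    aux_encoder <- mock_auxiliary_encoder(seed = seed + 1000L,
                                          channels = cfg$aux_channels)
  if (cfg$aux_enabled && aux_encoder$channels != cfg$aux_channels)
    stop("aux encoder channels disagree with config", call. = FALSE)

  params <- with_local_seed(seed, {
    p <- list()
    for (k in 0:(d - 1)) {
      cin <- if (k == 0) 1L else ch[k]
      p[[sprintf("enc%d_1", k)]] <- init_conv(3, cin, ch[k + 1])
      p[[sprintf("enc%d_2", k)]] <- init_conv(3, ch[k + 1], ch[k + 1])
    }
    bott_out <- ch[d]
    if (cfg$aux_enabled) {
      fp <- make_fusion_params(cfg$fusion, ch[d], cfg$aux_channels)
      p <- c(p, fp)
      if (cfg$fusion == "concatenate") bott_out <- ch[d] + cfg$aux_channels
    }
    for (k in (d - 2):0) {
      cin <- (if (k == d - 2) bott_out else ch[k + 2]) + ch[k + 1]
      p[[sprintf("dec%d_1", k)]] <- init_conv(3, cin, ch[k + 1])
      p[[sprintf("dec%d_2", k)]] <- init_conv(3, ch[k + 1], ch[k + 1])
    }
    if (cfg$seg_head_enabled)
      p[["head_seg"]] <- init_conv(1, ch[1], cfg$num_classes, gain = 1)
    if (cfg$reg_head_enabled)
      p[["head_reg"]] <- init_conv(1, ch[1], cfg$num_classes, gain = 1)
    p
  })
  # flatten to named arrays for the optimizer
  flat <- list()
  for (nm in names(params)) {
    flat[[paste0(nm, ".W")]] <- params[[nm]]$W
    flat[[paste0(nm, ".b")]] <- params[[nm]]$b
  }
  buffers <- list()
  if (cfg$norm == "batch") {
    for (nm in conv_block_names(cfg)) {
      cout <- ncol(params[[nm]]$W)
      flat[[paste0(nm, ".bn.g")]] <- rep(1, cout)
      flat[[paste0(nm, ".bn.b")]] <- rep(0, cout)
      buffers[[nm]] <- list(rmean = rep(0, cout), rvar = rep(1, cout))
    }
  }
  structure(list(cfg = cfg, params = flat, buffers = buffers,
                 aux = aux_encoder, seed = seed),
            class = "segmentation_model")
}

#' @export
print.segmentation_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(paste0("<segmentation_model: depth %d, base %d, fusion %s, ",
                     "aux %s, heads [%s], %d parameters>\n"),
              x$cfg$depth, x$cfg$base_channels, x$cfg$fusion,
              if (x$cfg$aux_enabled) "on" else "off",
              paste(c(if (x$cfg$seg_head_enabled) "seg",
                      if (x$cfg$reg_head_enabled) "reg"), collapse = ", "),
              np),
      ...)
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A `segmentation_model`.
#' @return Integer count of trainable scalar parameters (the frozen
#'   auxiliary encoder is excluded).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

pget <- function(params, nm) list(W = params[[paste0(nm, ".W")]],
                                  b = params[[paste0(nm, ".b")]])

conv_block_names <- function(cfg) {
  d <- cfg$depth
  c(sprintf("enc%d_1", 0:(d - 1)), sprintf("enc%d_2", 0:(d - 1)),
    sprintf("dec%d_1", 0:(d - 2)), sprintf("dec%d_2", 0:(d - 2)))
}

# One conv block: conv 3x3 -> (batch norm) -> ReLU. Returns the activation,
# a cache for the backward pass, and updated running buffers.
conv_block_forward <- function(x, params, buffers, nm, norm, training) {
  w <- pget(params, nm)
  z <- conv_layer_forward(x, w$W, w$b, 3L)
  if (norm == "batch") {
    bn <- bn_relu_forward(z, params[[paste0(nm, ".bn.g")]],
                          params[[paste0(nm, ".bn.b")]],
                          buffers[[nm]], training)
    buffers[[nm]] <- list(rmean = bn$rmean, rvar = bn$rvar)
    list(a = bn$a, buffers = buffers,
         cache = list(input = x, a = bn$a, xhat = bn$xhat,
                      inv_sd = bn$inv_sd))
  } else {
    list(a = relu(z), buffers = buffers,
         cache = list(input = x, pre = z))
  }
}

# Backward through one conv block; da is the gradient at the block output.
conv_block_backward <- function(da, params, nm, bc, norm, training, grads) {
  if (norm == "batch") {
    bnb <- bn_relu_backward(da, bc$a, bc$xhat, bc$inv_sd,
                            params[[paste0(nm, ".bn.g")]], training)
    grads[[paste0(nm, ".bn.g")]] <- bnb$dgamma
    grads[[paste0(nm, ".bn.b")]] <- bnb$dbeta
    dpre <- bnb$dz
  } else {
    dpre <- da
    dpre[bc$pre <= 0] <- 0
  }
  w <- pget(params, nm)
  bw <- conv_layer_backward(bc$input, w$W, dpre, 3L)
  grads[[paste0(nm, ".W")]] <- bw$dw
  grads[[paste0(nm, ".b")]] <- bw$db
  list(dx = bw$dx, grads = grads)
}

fusion_param_list <- function(params, fusion) {
  switch(fusion,
    concatenate = list(),
    addition = ,
    multiplication = list(fuse_proj = pget(params, "fuse_proj")),
    attention_gate = list(att_m = pget(params, "att_m"),
                          att_a = pget(params, "att_a"),
                          att_psi = pget(params, "att_psi")))
}

#' Forward pass
#'
#' Runs the network on one grayscale image. Returns per-pixel class
#' probabilities (`prob`, softmax over channels) and/or the predicted
#' level-set map (`phi`), depending on which heads are enabled.
#'
#' @param model A `segmentation_model`.
#' @param image Numeric `H x W` matrix matching `cfg$input_size`.
#' @param aux_embedding Optional precomputed auxiliary embedding (the frozen
#'   encoder output is constant per image, so callers may cache it).
#' @param keep_cache Keep intermediate activations for a backward pass.
#' @param training Use batch statistics (and update the running buffers
#'   returned in `cache$buffers`) instead of the stored running statistics.
#' @return List with `prob`, `logits`, `phi` (those enabled) and `cache`.
#' @export
model_forward <- function(model, image, aux_embedding = NULL,
                          keep_cache = FALSE, training = FALSE) {
  cfg <- model$cfg
  pr <- model$params
  d <- cfg$depth
  ch <- level_channels(cfg)
  if (!all(dim(image) == cfg$input_size))
    stop("image size disagrees with config input_size", call. = FALSE)

  cache <- list(enc = vector("list", d), dec = vector("list", d - 1))
  buffers <- model$buffers
  x <- as_chw_array(image)
  skips <- vector("list", d)
  for (k in 0:(d - 1)) {
    b1 <- conv_block_forward(x, pr, buffers, sprintf("enc%d_1", k),
                             cfg$norm, training)
    buffers <- b1$buffers
    b2 <- conv_block_forward(b1$a, pr, buffers, sprintf("enc%d_2", k),
                             cfg$norm, training)
    buffers <- b2$buffers
    a2 <- b2$a
    skips[[k + 1]] <- a2
    st <- list(b1 = b1$cache, a1 = b1$a, b2 = b2$cache, a2 = a2)
    if (k < d - 1) {
      mp <- maxpool2(a2)
      st$idx <- mp$idx
      x <- mp$y
    }
    cache$enc[[k + 1]] <- st
  }
  bott <- skips[[d]]

  fused <- bott
  if (cfg$aux_enabled) {
    emb <- aux_embedding %||% model$aux$encode(image)
    aux_r <- resize_embedding(emb, dim(bott)[1:2])
    fparams <- fusion_param_list(pr, cfg$fusion)
    ff <- fuse_forward(bott, aux_r, cfg$fusion, fparams)
    fused <- ff$out
    cache$aux_r <- aux_r
    cache$fuse <- ff
  }

  y <- fused
  for (k in (d - 2):0) {
    up <- upsample2(y)
    cc <- concat_ch(skips[[k + 1]], up)
    b1 <- conv_block_forward(cc, pr, buffers, sprintf("dec%d_1", k),
                             cfg$norm, training)
    buffers <- b1$buffers
    b2 <- conv_block_forward(b1$a, pr, buffers, sprintf("dec%d_2", k),
                             cfg$norm, training)
    buffers <- b2$buffers
    cache$dec[[k + 1]] <- list(y_in_dim = dim(y), b1 = b1$cache, a1 = b1$a,
                               b2 = b2$cache)
    y <- b2$a
  }

  out <- list()
  if (cfg$seg_head_enabled) {
    hs <- pget(pr, "head_seg")
    logits <- conv_layer_forward(y, hs$W, hs$b, 1L)
    out$logits <- logits
    out$prob <- softmax_channels(logits)
  }
  if (cfg$reg_head_enabled) {
    hr <- pget(pr, "head_reg")
    out$phi <- conv_layer_forward(y, hr$W, hr$b, 1L)
  }
  if (keep_cache || training) {
    cache$feat <- y
    cache$buffers <- buffers
    cache$training <- training
    out$cache <- cache
  }
  out
}

# Backward pass: d_logits / d_phi are gradients of the scalar loss with
# respect to the head outputs (either may be NULL). Returns a named list of
# parameter gradients matching model$params.
model_backward <- function(model, cache, d_logits = NULL, d_phi = NULL) {
  cfg <- model$cfg
  pr <- model$params
  d <- cfg$depth
  ch <- level_channels(cfg)
  grads <- list()

  dfeat <- cache$feat * 0
  if (!is.null(d_logits)) {
    hs <- pget(pr, "head_seg")
    bw <- conv_layer_backward(cache$feat, hs$W, d_logits, 1L)
    grads[["head_seg.W"]] <- bw$dw
    grads[["head_seg.b"]] <- bw$db
    dfeat <- dfeat + bw$dx
  }
  if (!is.null(d_phi)) {
    hr <- pget(pr, "head_reg")
    bw <- conv_layer_backward(cache$feat, hr$W, d_phi, 1L)
    grads[["head_reg.W"]] <- bw$dw
    grads[["head_reg.b"]] <- bw$db
    dfeat <- dfeat + bw$dx
  }

  # decoder: level 0 is the output end; walk back up to the fused bottleneck
  training <- isTRUE(cache$training)
  dskip <- vector("list", d)
  dy <- dfeat
  for (k in 0:(d - 2)) {
    st <- cache$dec[[k + 1]]
    bb2 <- conv_block_backward(dy, pr, sprintf("dec%d_2", k), st$b2,
                               cfg$norm, training, grads)
    grads <- bb2$grads
    bb1 <- conv_block_backward(bb2$dx, pr, sprintf("dec%d_1", k), st$b1,
                               cfg$norm, training, grads)
    grads <- bb1$grads
    nsk <- ch[k + 1]
    dcc <- bb1$dx
    dskip[[k + 1]] <- dcc[, , seq_len(nsk), drop = FALSE]
    dup <- dcc[, , (nsk + 1):dim(dcc)[3], drop = FALSE]
    dy <- upsample2_bw(dup, st$y_in_dim)
  }
  dfused <- dy

  # fusion
  if (cfg$aux_enabled) {
    fparams <- fusion_param_list(pr, cfg$fusion)
    fb <- fuse_backward(dfused, cache$enc[[d]]$a2, cache$aux_r, cfg$fusion,
                        fparams, cache$fuse)
    dbott <- fb$dmain
    grads <- c(grads, fb$grads)
  } else {
    dbott <- dfused
  }
  dskip[[d]] <- dbott

  # encoder, deepest to shallowest
  din_next <- NULL
  for (k in (d - 1):0) {
    st <- cache$enc[[k + 1]]
    da2 <- dskip[[k + 1]]
    if (is.null(da2)) da2 <- st$a2 * 0
    if (k < d - 1 && !is.null(din_next))
      da2 <- da2 + maxpool2_bw(din_next, st$idx, dim(st$a2))
    bb2 <- conv_block_backward(da2, pr, sprintf("enc%d_2", k), st$b2,
                               cfg$norm, training, grads)
    grads <- bb2$grads
    bb1 <- conv_block_backward(bb2$dx, pr, sprintf("enc%d_1", k), st$b1,
                               cfg$norm, training, grads)
    grads <- bb1$grads
    din_next <- bb1$dx
  }
  grads
}

#' Predict a label mask
#'
#' Segmentation rule: argmax of the softmax head when it is enabled;
#' otherwise the level-set sign rule (a pixel is assigned the foreground
#' class whose predicted `phi` is most negative, background where all
#' foreground `phi >= 0`; for the common two-class case this is simply
#' `phi_1 < 0`).
#'
#' @param model A `segmentation_model`.
#' @param image Input image matrix.
#' @param aux_embedding Optional cached auxiliary embedding.
#' @return Integer matrix of predicted class labels.
#' @export
predict_mask <- function(model, image, aux_embedding = NULL) {
  out <- model_forward(model, image, aux_embedding = aux_embedding)
  if (model$cfg$seg_head_enabled) {
    p <- out$prob
    lab <- apply_argmax(p) - 1L
  } else {
    phi <- out$phi
    C <- dim(phi)[3]
    lab <- matrix(0L, dim(phi)[1], dim(phi)[2])
    fg <- phi[, , 2:C, drop = FALSE]
    amin <- apply_argmax(-fg)           # most-negative foreground phi
    minv <- fg[cbind(as.vector(row(lab)), as.vector(col(lab)),
                     as.vector(amin))]
    sel <- matrix(minv < 0, nrow(lab), ncol(lab))
    lab[sel] <- amin[sel]
  }
  lab
}

apply_argmax <- function(x) {
  C <- dim(x)[3]
  best <- matrix(1L, dim(x)[1], dim(x)[2])
  bv <- x[, , 1]
  if (C > 1) for (k in 2:C) {
    sel <- x[, , k] > bv
    bv[sel] <- x[, , k][sel]
    best[sel] <- k
  }
  best
}
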