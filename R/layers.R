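# Thin R wrappers around the compiled layer kernels, parameter
# initialization and the Adam optimizer. Weight matrices are stored in
# im2col layout: (K*K*Cin) x Cout, with the row index ordered as
# (kernel row, kernel col, input channel).

conv_layer_forward <- function(x, W, b, K) {
  d <- dim(x)
  cpp_conv2d_forward(x, W, b, d[1], d[2], d[3], K)
}

conv_layer_backward <- function(x, W, dy, K) {
  d <- dim(x)
  cpp_conv2d_backward(x, W, dy, d[1], d[2], d[3], K)
}

relu <- function(x) cpp_relu(x)

maxpool2 <- function(x) {
  d <- dim(x)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0)
    stop("maxpool2 requires even spatial dims", call. = FALSE)
  cpp_maxpool2_forward(x, d[1], d[2], d[3])
}

maxpool2_bw <- function(dy, idx, in_dim) {
  cpp_maxpool2_backward(dy, idx, in_dim[1], in_dim[2], in_dim[3])
}

upsample2 <- function(x) {
  d <- dim(x)
  cpp_upsample2_forward(x, d[1], d[2], d[3])
}

upsample2_bw <- function(dy, in_dim) {
  cpp_upsample2_backward(dy, in_dim[1], in_dim[2], in_dim[3])
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[1:2] == db[1:2]))
    stop("spatial dims must match for channel concatenation", call. = FALSE)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# He-normal initialization for a conv weight matrix; draws from the caller's
# RNG stream (callers scope it with with_local_seed).
init_conv <- function(K, cin, cout, gain = 2) {
  sd <- sqrt(gain / (K * K * cin))
  list(W = matrix(rnorm(K * K * cin * cout, sd = sd), K * K * cin, cout),
       b = numeric(cout))
}

adam_init <- function(params) {
  flat <- lapply(params, function(p) list(m = p * 0, v = p * 0))
  list(t = 0, state = flat)
}

adam_step <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- opt$state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    opt$state[[nm]] <- st
  }
  list(params = params, opt = opt)
}

# Fused batch-norm (batch-of-one statistics, running buffers for
# inference) + ReLU; compiled kernels.
bn_relu_forward <- function(z, gamma, beta, buf, training,
                            momentum = 0.1, eps = 1e-5) {
  d <- dim(z)
  cpp_bn_relu_forward(z, gamma, beta, buf$rmean, buf$rvar, training,
                      momentum, eps, d[1], d[2], d[3])
}

bn_relu_backward <- function(da, a, xhat, inv_sd, gamma, training) {
  d <- dim(da)
  cpp_bn_relu_backward(da, a, xhat, inv_sd, gamma, training,
                       d[1], d[2], d[3])
}

softmax_channels <- function(z) {
  C <- dim(z)[3]
  m <- z[, , 1]
  if (C > 1) for (k in 2:C) m <- pmax(m, z[, , k])
  e <- exp(z - array(rep(m, C), dim(z)))
  s <- e[, , 1]
  if (C > 1) for (k in 2:C) s <- s + e[, , k]
  e / array(rep(s, C), dim(z))
}
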