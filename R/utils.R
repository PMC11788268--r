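# Internal helpers: local RNG scoping, object fingerprints, validation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a given seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fingerprint an R object
#'
#' Deterministic content hash (MD5 of the uncompressed serialization),
#' used to verify that frozen encoder parameters are bitwise unchanged
#' after training and to validate checkpoint configs on reload.
#'
#' @param obj Any serializable R object.
#' @return A 32-character hexadecimal string.
#' @export
fingerprint <- function(obj) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

stop_if_not_matrix <- function(x, name) {
  if (!is.matrix(x)) stop(sprintf("`%s` must be a matrix", name), call. = FALSE)
}

as_chw_array <- function(x) {
  # Promote a matrix to an H x W x 1 array; pass 3D arrays through.
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L))
  else if (length(dim(x)) == 3L) x
  else stop("expected a matrix or an H x W x C array", call. = FALSE)
}

check_same_dim <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop("shape mismatch between inputs", call. = FALSE)
}
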