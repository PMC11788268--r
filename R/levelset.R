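# Level-set core: signed-distance maps from label masks, the sharpened
# level set, discrete spatial derivatives and the curvature field.
#
# The level-set function phi is the signed Euclidean distance to the object
# boundary: negative strictly inside the object, zero on boundary pixels,
# positive outside. On a pixel grid the "boundary" is taken to be the set of
# foreground pixels with at least one 4-connected background neighbour, which
# gives the discrete zero level set an explicit pixel support.

#' Construct a label mask
#'
#' A label mask is an integer class map over an H x W pixel grid with values
#' in `0..num_classes-1` (0 is conventionally background), plus the physical
#' pixel spacing used by distance computations.
#'
#' @param data Integer matrix of class labels.
#' @param num_classes Number of classes `C`; defaults to `max(data) + 1`.
#' @param pixel_spacing Physical units per pixel as `c(sy, sx)`.
#' @return An object of class `label_mask`.
#' @examples
#' m <- label_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
label_mask <- function(data, num_classes = NULL, pixel_spacing = c(1, 1)) {
  stop_if_not_matrix(data, "data")
  if (any(data != round(data)) || any(data < 0))
    stop("label mask values must be nonnegative integers", call. = FALSE)
  storage.mode(data) <- "integer"
  num_classes <- as.integer(num_classes %||% (max(data) + 1L))
  if (num_classes < 1L) stop("num_classes must be >= 1", call. = FALSE)
  if (any(data >= num_classes))
    stop("all label values must be < num_classes", call. = FALSE)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("pixel_spacing must be two positive numbers (sy, sx)", call. = FALSE)
  structure(list(data = data, num_classes = num_classes,
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask %d x %d, %d classes, spacing (%g, %g)>\n",
              nrow(x$data), ncol(x$data), x$num_classes,
              x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

# Boundary pixels of a binary mask: foreground with a 4-connected background
# neighbour. Returns an integer matrix (1 = boundary).
boundary_pixels <- function(mask) {
  m <- mask
  if (is.logical(m)) m <- m * 1L
  storage.mode(m) <- "integer"
  cpp_boundary4(m)
}

#' Signed Euclidean distance to the object boundary
#'
#' Computes the level-set function of a binary mask: the exact Euclidean
#' distance from each pixel centre to the nearest boundary-pixel centre,
#' negated strictly inside the object, zero on boundary pixels and positive
#' outside. Boundary pixels are foreground pixels with at least one
#' 4-connected background neighbour. The field is clipped to
#' `[-d_max, d_max]` where `d_max` is the physical image diagonal; a mask
#' with no boundary (all foreground or all background) yields a constant
#' field at `+d_max`.
#'
#' @param mask Binary matrix (logical or 0/1).
#' @param spacing Physical pixel spacing `c(sy, sx)`.
#' @return Numeric matrix of signed distances, same shape as `mask`.
#' @examples
#' signed_distance(matrix(c(0, 0, 1, 0, 0), 1, 5))
#' @export
signed_distance <- function(mask, spacing = c(1, 1)) {
  stop_if_not_matrix(mask, "mask")
  if (any(spacing <= 0)) stop("spacing components must be > 0", call. = FALSE)
  fg <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  d_max <- sqrt((H * spacing[1])^2 + (W * spacing[2])^2)
  bnd <- boundary_pixels(fg)
  if (!any(bnd == 1L)) {
    return(matrix(d_max, H, W))
  }
  d <- cpp_edt(bnd, spacing[1], spacing[2])
  phi <- d
  inside <- fg & bnd == 0L
  phi[inside] <- -d[inside]
  phi[phi > d_max] <- d_max
  phi[phi < -d_max] <- -d_max
  phi
}

#' Convert a label mask to a per-class level-set map
#'
#' One signed-distance channel per class `j` in `0..C-1`, each computed from
#' the binary indicator of that class. The background class is included by
#' default so that losses summing over all classes see a level set for every
#' channel; `foreground_only = TRUE` drops channel 0.
#'
#' @param mask A [label_mask] or integer matrix.
#' @param num_classes Required if `mask` is a bare matrix.
#' @param spacing Pixel spacing, taken from the `label_mask` if available.
#' @param foreground_only Drop the background channel.
#' @return An `H x W x C` array of class `levelset_map` with attributes
#'   `classes` (the class ids per channel) and `spacing`.
#' @export
labels_to_levelset <- function(mask, num_classes = NULL, spacing = NULL,
                               foreground_only = FALSE) {
  if (inherits(mask, "label_mask")) {
    num_classes <- mask$num_classes
    spacing <- spacing %||% mask$pixel_spacing
    mask <- mask$data
  }
  spacing <- spacing %||% c(1, 1)
  if (is.null(num_classes)) num_classes <- max(mask) + 1L
  classes <- if (foreground_only) seq_len(num_classes - 1L) else 0:(num_classes - 1L)
  if (length(classes) == 0L) stop("no classes to convert", call. = FALSE)
  phi <- array(0, c(nrow(mask), ncol(mask), length(classes)))
  for (k in seq_along(classes)) {
    phi[, , k] <- signed_distance(mask == classes[k], spacing = spacing)
  }
  structure(phi, classes = as.integer(classes), spacing = as.numeric(spacing),
            class = c("levelset_map", class(phi)))
}

#' Sharpen a level set into a near-binary field
#'
#' Applies the elementwise logistic `sigmoid(-scale * phi)`, turning the
#' zero level set into the region of largest gradient: values are above 0.5
#' exactly where `phi < 0` (inside) and below 0.5 outside. The default
#' scale of 1000 saturates the sigmoid away from a roughly one-pixel band
#' around the boundary; this is deliberate and makes the subsequent
#' curvature field concentrate on the boundary.
#'
#' @param phi Level-set matrix or `H x W x C` array.
#' @param scale Positive sharpening factor.
#' @return Array of the same shape with values strictly inside (0, 1).
#' @export
sharpen_levelset <- function(phi, scale = 1000) {
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  1 / (1 + exp(pmin(pmax(scale * phi, -700), 700)))
}

# -- discrete derivative stencils -------------------------------------------
# Central differences with replicated edges; the mixed derivative is the
# a-derivative of the b-derivative. `a` indexes rows, `b` indexes columns.

shift_dn <- function(f) f[c(2:nrow(f), nrow(f)), , drop = FALSE]        # f[i+1]
shift_up <- function(f) f[c(1L, 1:(nrow(f) - 1L)), , drop = FALSE]      # f[i-1]
shift_rt <- function(f) f[, c(2:ncol(f), ncol(f)), drop = FALSE]        # f[,j+1]
shift_lf <- function(f) f[, c(1L, 1:(ncol(f) - 1L)), drop = FALSE]      # f[,j-1]

deriv_a  <- function(f) (shift_dn(f) - shift_up(f)) / 2
deriv_b  <- function(f) (shift_rt(f) - shift_lf(f)) / 2
deriv_aa <- function(f) shift_dn(f) + shift_up(f) - 2 * f
deriv_bb <- function(f) shift_rt(f) + shift_lf(f) - 2 * f

# Adjoints of the shift operators (needed for backpropagation through the
# curvature loss). shift_dn maps f -> y with y_i = f_{i+1} (i < H), y_H = f_H.
adj_shift_dn <- function(g) {
  H <- nrow(g)
  h <- g * 0
  h[2:H, ] <- g[1:(H - 1), ]
  h[H, ] <- h[H, ] + g[H, ]
  h
}
adj_shift_up <- function(g) {
  H <- nrow(g)
  h <- g * 0
  h[1:(H - 1), ] <- g[2:H, ]
  h[1, ] <- h[1, ] + g[1, ]
  h
}
adj_shift_rt <- function(g) {
  W <- ncol(g)
  h <- g * 0
  h[, 2:W] <- g[, 1:(W - 1)]
  h[, W] <- h[, W] + g[, W]
  h
}
adj_shift_lf <- function(g) {
  W <- ncol(g)
  h <- g * 0
  h[, 1:(W - 1)] <- g[, 2:W]
  h[, 1] <- h[, 1] + g[, 1]
  h
}

adj_deriv_a  <- function(g) (adj_shift_dn(g) - adj_shift_up(g)) / 2
adj_deriv_b  <- function(g) (adj_shift_rt(g) - adj_shift_lf(g)) / 2
adj_deriv_aa <- function(g) adj_shift_dn(g) + adj_shift_up(g) - 2 * g
adj_deriv_bb <- function(g) adj_shift_rt(g) + adj_shift_lf(g) - 2 * g

#' Discrete spatial derivatives of a 2D field
#'
#' First and second derivatives by central differences with replicated-edge
#' padding. Rows are the `a` coordinate, columns are `b`. The mixed
#' derivative `gab` is computed as the a-derivative of the b-derivative.
#'
#' @param grid Numeric matrix, at least 3 x 3.
#' @return A list with elements `ga`, `gb`, `gaa`, `gbb`, `gab`.
#' @export
spatial_derivatives <- function(grid) {
  stop_if_not_matrix(grid, "grid")
  if (nrow(grid) < 3 || ncol(grid) < 3)
    stop("grid must be at least 3 x 3", call. = FALSE)
  gb <- deriv_b(grid)
  list(ga = deriv_a(grid), gb = gb,
       gaa = deriv_aa(grid), gbb = deriv_bb(grid),
       gab = deriv_a(gb))
}

curvature_channel <- function(s, eps) {
  d <- spatial_derivatives(s)
  num <- (1 + d$ga^2) * d$gbb + (1 + d$gb^2) * d$gaa - 2 * d$ga * d$gb * d$gab
  den <- 2 * (1 + d$ga^2 + d$gb^2)^1.5 + eps
  num / den
}

#' Curvature field of a sharpened level set
#'
#' Mean-curvature-style expression
#' `K = ((1 + ga^2) gbb + (1 + gb^2) gaa - 2 ga gb gab) /
#'      (2 (1 + ga^2 + gb^2)^1.5 + eps)`
#' computed channelwise from the discrete derivatives of the sharpened
#' field. The small `eps` keeps the ratio finite where the field is flat
#' (there the numerator vanishes too, so `eps` does not bias the boundary
#' band). For a rasterized disk of radius `r` the mean curvature over the
#' boundary band approaches `1/r`.
#'
#' @param sharpened Matrix or `H x W x C` array, typically from
#'   [sharpen_levelset()].
#' @param eps Positive stabilizer added to the denominator.
#' @return Curvature values, same shape as the input.
#' @export
curvature_map <- function(sharpened, eps = 1e-8) {
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (is.matrix(sharpened)) return(curvature_channel(sharpened, eps))
  x <- as_chw_array(sharpened)
  out <- array(0, dim(x))
  for (k in seq_len(dim(x)[3])) out[, , k] <- curvature_channel(x[, , k], eps)
  out
}

#' Write / read a level-set map stack
#'
#' Serializes a level-set array together with its channel class ids and
#' pixel spacing (keys `phi`, `classes`, `spacing`).
#'
#' @param phi An array from [labels_to_levelset()].
#' @param path File path (`.rds`).
#' @return `read_levelset` returns the `levelset_map` array.
#' @export
write_levelset <- function(phi, path) {
  saveRDS(list(phi = unclass(phi),
               classes = attr(phi, "classes"),
               spacing = attr(phi, "spacing")),
          path)
  invisible(path)
}

#' @rdname write_levelset
#' @export
read_levelset <- function(path) {
  x <- readRDS(path)
  structure(x$phi, classes = x$classes, spacing = x$spacing,
            class = c("levelset_map", class(x$phi)))
}

#' Read a PNG mask or grayscale image
#'
#' Masks are 8-bit PNGs with pixel value `k` meaning class `k`; images are
#' read as grayscale normalized to `[0, 1]` (color inputs are averaged over
#' channels).
#'
#' @param path PNG file path.
#' @param pixel_spacing Spacing recorded on the returned mask.
#' @return `read_mask_png` returns a [label_mask]; `read_image_png` a
#'   numeric matrix in `[0, 1]`.
#' @export
read_mask_png <- function(path, pixel_spacing = c(1, 1)) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  label_mask(matrix(as.integer(round(x * 255)), nrow(x), ncol(x)),
             pixel_spacing = pixel_spacing)
}

#' @rdname read_mask_png
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE],
                                       c(1, 2), mean)
  x
}
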