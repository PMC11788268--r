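# Synthetic benchmark data: the circle dataset used for the
# out-of-distribution brightness-shift study, plus irregular blob fixtures
# for property tests. Everything is a pure function of its spec and seed so
# tests and experiments run with no downloads.

#' Specification of a synthetic circle dataset
#'
#' Each sample is one bright disk of uniform-random radius and position
#' (fully inside the frame) on a constant background, with optional additive
#' Gaussian noise, and its exact binary rasterization as the ground-truth
#' mask (a pixel belongs to the circle when its centre is within `r` of the
#' circle centre; no anti-aliasing, so the distance-transform ground truth
#' is unambiguous). The brightness-shift protocol of the benchmark assigns
#' brightness 1 to training circles and half of that to test circles.
#'
#' @param n_images Number of samples.
#' @param image_size `c(H, W)` pixels.
#' @param radius_range `c(r_min, r_max)` in pixels; `r_max` must fit in the
#'   frame.
#' @param brightness Foreground intensity in `(0, 1]`.
#' @param background_value Background intensity (< brightness).
#' @param noise_sd SD of additive Gaussian noise (0 disables).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `circle_dataset_spec` list.
#' @export
circle_dataset_spec <- function(n_images = 200, image_size = c(256, 256),
                                radius_range = c(12, 48), brightness = 1,
                                background_value = 0, noise_sd = 0,
                                seed = 1) {
  if (radius_range[1] > radius_range[2] || radius_range[1] <= 0)
    stop("invalid radius range", call. = FALSE)
  if (radius_range[2] > min(image_size) / 2 - 1)
    stop("r_max must be < min(H, W) / 2 (leaving room for the 1 px margin)",
         call. = FALSE)
  if (brightness <= background_value)
    stop("brightness must exceed background_value", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 radius_range = as.numeric(radius_range),
                 brightness = brightness,
                 background_value = background_value,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "circle_dataset_spec")
}

rasterize_circle <- function(H, W, cy, cx, r) {
  dy <- (seq_len(H) - cy)^2
  dx <- (seq_len(W) - cx)^2
  outer(dy, dx, "+") <= r^2
}

#' Generate a synthetic circle dataset
#'
#' @param spec A [circle_dataset_spec].
#' @return A list of class `circle_dataset` whose elements each hold
#'   `image` (numeric matrix) and `mask` (a binary [label_mask]), plus the
#'   spec as an attribute.
#' @export
generate_circle_dataset <- function(spec) {
  stopifnot(inherits(spec, "circle_dataset_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  samples <- with_local_seed(spec$seed, lapply(seq_len(spec$n_images), function(i) {
    r <- runif(1, spec$radius_range[1], spec$radius_range[2])
    cy <- runif(1, r + 1, H - r)
    cx <- runif(1, r + 1, W - r)
    m <- rasterize_circle(H, W, cy, cx, r)
    img <- matrix(spec$background_value, H, W)
    img[m] <- spec$brightness
    if (spec$noise_sd > 0) img <- img + matrix(rnorm(H * W, sd = spec$noise_sd), H, W)
    list(image = img,
         mask = label_mask(m * 1L, num_classes = 2L),
         center = c(cy, cx), radius = r)
  }))
  structure(samples, spec = spec, class = "circle_dataset")
}

#' @export
print.circle_dataset <- function(x, ...) {
  s <- attr(x, "spec")
  cat(sprintf("<circle_dataset: %d images %dx%d, r in [%g, %g], brightness %g, seed %d>\n",
              length(x), s$image_size[1], s$image_size[2],
              s$radius_range[1], s$radius_range[2], s$brightness, s$seed))
  invisible(x)
}

#' Irregular blob fixture
#'
#' Deterministic irregular shapes for property tests: `n_blobs` Gaussian
#' bumps at random positions are summed and thresholded into a mask; the
#' image is the smooth field itself. `n_blobs = 0` yields an empty mask.
#'
#' @param seed Integer seed.
#' @param size Image side length (>= 16).
#' @param n_blobs Number of bumps.
#' @return List with `image` (matrix) and `mask` ([label_mask]).
#' @export
generate_blob_fixture <- function(seed = 1, size = 64, n_blobs = 3) {
  if (size < 16) stop("size must be >= 16", call. = FALSE)
  with_local_seed(seed, {
    field <- matrix(0, size, size)
    for (i in seq_len(n_blobs)) {
      cy <- runif(1, size * 0.2, size * 0.8)
      cx <- runif(1, size * 0.2, size * 0.8)
      sg <- runif(1, size / 16, size / 6)
      field <- field + exp(-(outer((seq_len(size) - cy)^2,
                                   (seq_len(size) - cx)^2, "+")) / (2 * sg^2))
    }
    mask <- field > 0.5
    list(image = field, mask = label_mask(mask * 1L, num_classes = 2L))
  })
}

#' Write / read a dataset as PNG pairs with a YAML manifest
#'
#' Lays the dataset out as `images/%04d.png`, `masks/%04d.png` plus a
#' `spec.yaml` manifest holding the generating spec and a content
#' fingerprint; `read_circle_dataset` validates the fingerprint.
#'
#' @param dataset A `circle_dataset`.
#' @param dir Output directory.
#' @export
write_circle_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset)) {
    img <- pmin(pmax(dataset[[i]]$image, 0), 1)
    png::writePNG(img, file.path(dir, "images", sprintf("%04d.png", i)))
    png::writePNG(dataset[[i]]$mask$data / 255,
                  file.path(dir, "masks", sprintf("%04d.png", i)))
  }
  spec <- attr(dataset, "spec")
  yaml::write_yaml(list(spec = unclass(spec),
                        n = length(dataset),
                        fingerprint = dataset_fingerprint(dataset)),
                   file.path(dir, "spec.yaml"))
  invisible(dir)
}

dataset_fingerprint <- function(dataset) {
  fingerprint(lapply(dataset, function(s) s$mask$data))
}

#' @rdname write_circle_dataset
#' @export
read_circle_dataset <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  files <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  samples <- lapply(seq_along(files), function(i) {
    img <- read_image_png(file.path(dir, "images", sprintf("%04d.png", i)))
    msk <- read_mask_png(file.path(dir, "masks", sprintf("%04d.png", i)))
    list(image = img, mask = msk)
  })
  spec <- do.call(circle_dataset_spec, man$spec[names(man$spec) != "class"])
  ds <- structure(samples, spec = spec, class = "circle_dataset")
  if (!identical(dataset_fingerprint(ds), man$fingerprint))
    stop("dataset fingerprint mismatch: files were modified", call. = FALSE)
  ds
}
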