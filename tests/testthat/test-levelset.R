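# Level-set core: signed distances, sharpening, derivatives, curvature.

test_that("signed_distance matches the hand example and no-boundary conventions", {
  expect_equal(signed_distance(matrix(c(0, 0, 1, 0, 0), 1, 5)),
               matrix(c(2, 1, 0, 1, 2), 1, 5))
  # all-background: constant at the clip value (image diagonal)
  z <- signed_distance(matrix(0, 8, 8))
  expect_true(all(z == sqrt(2) * 8))
  # all-foreground likewise has no boundary
  o <- signed_distance(matrix(1, 6, 4))
  expect_true(all(o == sqrt(36 + 16)))
})

test_that("signed_distance equals the exhaustive boundary-distance oracle", {
  set.seed(42)
  for (t in 1:40) {
    H <- sample(2:16, 1); W <- sample(2:16, 1)
    m <- rand_mask(H, W)
    expect_equal(signed_distance(m), oracle_signed_distance(m))
  }
})

test_that("signed_distance honors anisotropic pixel spacing", {
  set.seed(7)
  for (t in 1:10) {
    m <- rand_mask(9, 11)
    sp <- c(runif(1, 0.5, 3), runif(1, 0.5, 3))
    expect_equal(signed_distance(m, spacing = sp),
                 oracle_signed_distance(m, spacing = sp), tolerance = 1e-12)
  }
})

test_that("sign structure: negative strictly inside, zero on boundary, positive outside", {
  set.seed(8)
  for (t in 1:20) {
    m <- rand_mask(12, 12)
    phi <- signed_distance(m)
    b <- boundary_pixels <- shapeprior:::boundary_pixels(m) == 1L
    expect_true(all(phi[m == 1 & !b] < 0))
    expect_true(all(phi[b] == 0))
    expect_true(all(phi[m == 0] > 0))
  }
})

test_that("signed_distance is translation equivariant away from clipping", {
  m <- matrix(0L, 32, 32); m[8:14, 9:16] <- 1L
  m2 <- matrix(0L, 32, 32); m2[13:19, 12:19] <- 1L  # shifted by (5, 3)
  phi <- signed_distance(m)
  phi2 <- signed_distance(m2)
  # compare on a window where neither field is clipped
  expect_equal(phi2[11:26, 6:26], phi[6:21, 3:23])
})

test_that("labels_to_levelset builds one channel per class", {
  m <- matrix(0L, 8, 8); m[3:5, 3:6] <- 1L
  lm <- label_mask(m, num_classes = 3)   # class 2 empty
  phi <- labels_to_levelset(lm)
  expect_equal(dim(phi), c(8, 8, 3))
  expect_equal(phi[, , 1], signed_distance(m == 0))
  expect_equal(phi[, , 2], signed_distance(m == 1))
  expect_true(all(phi[, , 3] == sqrt(128)))  # empty class: constant fill
  fg <- labels_to_levelset(lm, foreground_only = TRUE)
  expect_equal(dim(fg)[3], 2)
  # binary mask: the two channels are sign-flipped away from the boundary band
  phi2 <- labels_to_levelset(label_mask(m, num_classes = 2))
  away <- abs(phi2[, , 2]) > 1.5 & abs(phi2[, , 1]) > 1.5
  expect_true(all(sign(phi2[, , 1][away]) == -sign(phi2[, , 2][away])))
})

test_that("sharpen_levelset matches the logistic closed form and is monotone", {
  expect_equal(sharpen_levelset(matrix(0, 1, 1)), matrix(0.5, 1, 1))
  expect_equal(sharpen_levelset(matrix(-0.01, 1, 1), scale = 1000),
               matrix(1 / (1 + exp(-10)), 1, 1), tolerance = 1e-12)
  expect_equal(sharpen_levelset(matrix(-5, 1, 1))[1], 1, tolerance = 1e-12)
  phi <- matrix(seq(-3, 3, length.out = 101), 101, 1)
  s <- sharpen_levelset(phi, scale = 2)
  expect_true(all(diff(s[, 1]) < 0))        # strictly decreasing in phi
  expect_true(all(s > 0 & s < 1))
  expect_true(all((s > 0.5) == (phi < 0)))
})

test_that("spatial_derivatives are exact on polynomial fields and match the loop oracle", {
  a <- matrix(rep(1:7, 9), 7, 9)
  d <- spatial_derivatives(a)
  inn <- 2:6
  expect_true(all(d$ga[inn, ] == 1))
  # the replicated edge bends the second differences at the border rows only
  expect_true(all(d$gb == 0) && all(d$gaa[inn, ] == 0) &&
                all(d$gbb == 0) && all(d$gab == 0))
  ab <- outer(1:7, 1:9)
  dab <- spatial_derivatives(ab)
  expect_true(all(dab$gab[2:6, 2:8] == 1))
  set.seed(5)
  f <- matrix(rnorm(81), 9, 9)
  got <- spatial_derivatives(f)
  want <- oracle_derivatives(f)
  for (nm in names(want)) expect_equal(got[[nm]], want[[nm]])
  expect_error(spatial_derivatives(matrix(0, 2, 5)), "3 x 3")
})

test_that("derivative stencil adjoints satisfy the inner-product identity", {
  set.seed(9)
  ops <- list(c(shapeprior:::deriv_a, shapeprior:::adj_deriv_a),
              c(shapeprior:::deriv_b, shapeprior:::adj_deriv_b),
              c(shapeprior:::deriv_aa, shapeprior:::adj_deriv_aa),
              c(shapeprior:::deriv_bb, shapeprior:::adj_deriv_bb))
  for (op in ops) {
    f <- matrix(rnorm(60), 6, 10)
    g <- matrix(rnorm(60), 6, 10)
    expect_equal(sum(op[[1]](f) * g), sum(f * op[[2]](g)), tolerance = 1e-12)
  }
})

test_that("curvature is zero on flat fields and cancels along a straight edge", {
  expect_true(all(curvature_map(matrix(0.7, 16, 16)) == 0))
  # a straight boundary has zero line curvature: the graph-curvature field
  # is antisymmetric across the edge, so its signed band mean vanishes
  # (pointwise |K| reflects the bending of the sigmoid profile itself)
  m <- matrix(0L, 64, 64); m[, 1:32] <- 1L
  phi <- signed_distance(m)
  K <- curvature_map(sharpen_levelset(phi))
  band <- abs(phi) <= 1.5
  expect_lt(abs(mean(K[band])), 0.01)
})

test_that("disk boundary-band curvature scales inversely with radius", {
  # The graph mean-curvature field concentrates on the boundary band and its
  # band mean is proportional to 1/r: the ratio mean(K) * r is constant
  # across radii. (The absolute constant depends on the sharpening scale.)
  vals <- sapply(c(10, 20, 40), function(r) {
    m <- disk_mask(256, 128.3, 129.1, r) * 1L
    phi <- signed_distance(m)
    K <- curvature_map(sharpen_levelset(phi))
    mean(K[abs(phi) <= 1.5]) * r
  })
  expect_true(all(vals > 0))
  expect_lt(max(vals) / min(vals), 1.35)
})

test_that("curvature agrees with the independent loop oracle", {
  set.seed(11)
  s <- sharpen_levelset(signed_distance(rand_mask(12, 12)), scale = 1)
  expect_equal(curvature_map(s), oracle_curvature(s), tolerance = 1e-12)
})

test_that("level-set maps round-trip through the serializer", {
  m <- matrix(0L, 10, 10); m[4:6, 5:8] <- 1L
  phi <- labels_to_levelset(label_mask(m, pixel_spacing = c(2, 1)))
  f <- tempfile(fileext = ".rds")
  write_levelset(phi, f)
  back <- read_levelset(f)
  expect_equal(unclass(back), unclass(phi), ignore_attr = TRUE)
  expect_equal(attr(back, "spacing"), c(2, 1))
  expect_equal(attr(back, "classes"), 0:1)
  unlink(f)
})

test_that("PNG mask and image readers invert the dataset writer", {
  ds <- generate_circle_dataset(circle_dataset_spec(
    n_images = 2, image_size = c(32, 32), radius_range = c(4, 8), seed = 2))
  dir <- tempfile()
  write_circle_dataset(ds, dir)
  m <- read_mask_png(file.path(dir, "masks", "0001.png"))
  expect_equal(m$data, ds[[1]]$mask$data)
  img <- read_image_png(file.path(dir, "images", "0001.png"))
  expect_equal(img, ds[[1]]$image, tolerance = 1 / 255)
  unlink(dir, recursive = TRUE)
})
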