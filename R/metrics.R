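# Evaluation metrics: DICE similarity coefficient (as a percentage) and the
# average symmetric surface distance (ASD). "Surface" means the boundary
# pixel set under 4-connectivity, the same convention as the level-set core.

mask_of_class <- function(x, class_id) {
  if (inherits(x, "label_mask")) x <- x$data
  x == class_id
}

#' DICE similarity coefficient
#'
#' Overlap metric `2 |A n B| / (|A| + |B|)` for one class, reported as a
#' percentage in `[0, 100]`. When the class is absent from both masks the
#' score is 100 by convention (perfect agreement on absence).
#'
#' @param pred,truth Label masks ([label_mask] or integer matrices).
#' @param class_id Class whose overlap is measured.
#' @return DICE percentage.
#' @export
dice_coefficient <- function(pred, truth, class_id = 1) {
  a <- mask_of_class(pred, class_id)
  b <- mask_of_class(truth, class_id)
  check_same_dim(a, b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(100)
  200 * sum(a & b) / (na + nb)
}

#' Average symmetric surface distance
#'
#' Mean Euclidean distance between the boundaries of two masks: for each
#' boundary pixel of one mask the distance to the nearest boundary pixel of
#' the other is taken; the two directional means are averaged. Boundary
#' pixels are foreground pixels with a 4-connected background neighbour.
#' Distances honor the physical `spacing`. If either class is empty (no
#' boundary exists) the metric is undefined; a finite penalty equal to the
#' physical image diagonal is returned, marked with attribute
#' `empty = TRUE`, so that averages over a test set remain defined.
#'
#' @inheritParams dice_coefficient
#' @param spacing Physical pixel spacing `c(sy, sx)`.
#' @return ASD in physical units (attribute `empty` flags the penalty case).
#' @export
average_surface_distance <- function(pred, truth, class_id = 1,
                                     spacing = c(1, 1)) {
  if (inherits(pred, "label_mask")) spacing <- pred$pixel_spacing
  a <- mask_of_class(pred, class_id)
  b <- mask_of_class(truth, class_id)
  check_same_dim(a, b)
  ba <- boundary_pixels(a)
  bb <- boundary_pixels(b)
  H <- nrow(ba); W <- ncol(ba)
  if (!any(ba == 1L) || !any(bb == 1L)) {
    pen <- sqrt((H * spacing[1])^2 + (W * spacing[2])^2)
    return(structure(pen, empty = TRUE))
  }
  da <- cpp_edt(bb, spacing[1], spacing[2])   # distance to boundary of B
  db <- cpp_edt(ba, spacing[1], spacing[2])
  (mean(da[ba == 1L]) + mean(db[bb == 1L])) / 2
}

#' Per-image metric report
#'
#' Computes DICE and ASD for every foreground class of one prediction.
#'
#' @inheritParams average_surface_distance
#' @param num_classes Number of classes (foreground classes `1..C-1` are
#'   evaluated).
#' @param image_id Identifier recorded in the table.
#' @return A data.frame with columns `image_id`, `class`, `dice_percent`,
#'   `asd`, `empty`.
#' @export
metric_report <- function(pred, truth, num_classes = 2, spacing = c(1, 1),
                          image_id = NA_character_) {
  rows <- lapply(seq_len(num_classes - 1L), function(cl) {
    asd <- average_surface_distance(pred, truth, cl, spacing)
    data.frame(image_id = image_id, class = cl,
               dice_percent = dice_coefficient(pred, truth, cl),
               asd = as.numeric(asd),
               empty = isTRUE(attr(asd, "empty")))
  })
  do.call(rbind, rows)
}

#' Summarize and write a metric table
#'
#' `summarize_metrics` reduces a per-image table to mean and SD of both
#' metrics; `write_metrics_csv` writes the per-image rows followed by a
#' summary row formatted `mean ± SD`.
#'
#' @param df Per-image metric table from [metric_report()] rows.
#' @return A one-row data.frame with `dice_mean`, `dice_sd`, `asd_mean`,
#'   `asd_sd`, `n`.
#' @export
summarize_metrics <- function(df) {
  data.frame(dice_mean = mean(df$dice_percent),
             dice_sd = if (nrow(df) > 1) sd(df$dice_percent) else 0,
             asd_mean = mean(df$asd),
             asd_sd = if (nrow(df) > 1) sd(df$asd) else 0,
             n = nrow(df))
}

#' @rdname summarize_metrics
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(df, path) {
  s <- summarize_metrics(df)
  out <- df[, c("image_id", "class", "dice_percent", "asd")]
  out$image_id <- as.character(out$image_id)
  out <- rbind(out, data.frame(
    image_id = "summary", class = NA,
    dice_percent = sprintf("%.2f ± %.2f", s$dice_mean, s$dice_sd),
    asd = sprintf("%.2f ± %.2f", s$asd_mean, s$asd_sd),
    stringsAsFactors = FALSE))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
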