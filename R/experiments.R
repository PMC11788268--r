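# Config-driven training and evaluation, plus the out-of-distribution
# circle experiment: train on bright circles, test on half-brightness
# circles, with and without the level-set/curvature supervision.

#' Experiment run configuration
#'
#' Bundles the architecture, loss weights, data source and training
#' settings of one run. Defaults describe the desk-scale synthetic-circle
#' study: a small plain U-Net (no auxiliary encoder, as the brightness-shift
#' benchmark uses a bare U-Net), 128 x 128 images, Adam.
#'
#' @param architecture An [arch_config].
#' @param weights A [loss_weights].
#' @param scale,eps Sharpening scale and curvature stabilizer.
#' @param data A [circle_dataset_spec] or a directory path written by
#'   [write_circle_dataset()].
#' @param seed Training seed (weight init and batch sampling).
#' @param steps Number of optimization steps (>= 1).
#' @param batch_size Images per step.
#' @param learning_rate Adam learning rate.
#' @param optimizer Optimizer name (only `"adam"` is provided).
#' @param output_dir Optional directory for CSV/YAML outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(architecture = arch_config(input_size = c(128, 128),
                                                  depth = 3, base_channels = 8,
                                                  aux_enabled = FALSE,
                                                  norm = "none"),
                       weights = loss_weights(), scale = 1000, eps = 1e-8,
                       data = circle_dataset_spec(image_size = c(128, 128)),
                       seed = 1, steps = 600, batch_size = 4,
                       learning_rate = 1e-3, optimizer = "adam",
                       output_dir = NULL) {
  if (steps < 1) stop("steps must be >= 1", call. = FALSE)
  if (optimizer != "adam") stop("only adam is available", call. = FALSE)
  structure(list(architecture = architecture, weights = weights,
                 scale = scale, eps = eps, data = data,
                 train = list(seed = as.integer(seed),
                              steps = as.integer(steps),
                              batch_size = as.integer(batch_size),
                              learning_rate = learning_rate,
                              optimizer = optimizer),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' YAML layout has sections `architecture`, `loss`, `data`, `train`.
#'
#' @param cfg A [run_config].
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(list(
    architecture = unclass(cfg$architecture),
    loss = c(unclass(cfg$weights), list(scale = cfg$scale, eps = cfg$eps)),
    data = if (is.character(cfg$data)) list(path = cfg$data)
           else unclass(cfg$data),
    train = cfg$train,
    output_dir = cfg$output_dir), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  arch <- do.call(arch_config, y$architecture)
  lw <- loss_weights(y$loss$lambda1, y$loss$lambda2, y$loss$lambda3)
  data <- if (!is.null(y$data$path)) y$data$path
          else do.call(circle_dataset_spec, y$data)
  run_config(architecture = arch, weights = lw,
             scale = y$loss$scale %||% 1000, eps = y$loss$eps %||% 1e-8,
             data = data, seed = y$train$seed, steps = y$train$steps,
             batch_size = y$train$batch_size,
             learning_rate = y$train$learning_rate,
             optimizer = y$train$optimizer %||% "adam",
             output_dir = y$output_dir)
}

resolve_dataset <- function(data) {
  if (inherits(data, "circle_dataset")) data
  else if (inherits(data, "circle_dataset_spec")) generate_circle_dataset(data)
  else if (is.character(data)) read_circle_dataset(data)
  else stop("data must be a dataset, a spec, or a directory path",
            call. = FALSE)
}

one_hot <- function(mask, num_classes) {
  y <- array(0, c(nrow(mask), ncol(mask), num_classes))
  for (k in seq_len(num_classes)) y[, , k] <- (mask == k - 1) * 1
  y
}

#' Train a model
#'
#' Optimizes the weighted total loss (segmentation DICE + CE, level-set
#' MSE, curvature) with Adam over minibatches sampled from the training
#' set. Ground-truth level sets, their sharpened curvature fields and the
#' frozen auxiliary embeddings are precomputed once per image. The
#' auxiliary encoder receives no updates. Training aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param cfg A [run_config].
#' @param dataset Optional pre-built `circle_dataset` (otherwise resolved
#'   from `cfg$data`).
#' @param verbose Print progress every 50 steps.
#' @return An object of class `trained_model`: fields `model`, `log`
#'   (per-step loss data.frame), `cfg`, and `aux_fingerprint` before/after.
#' @export
train <- function(cfg, dataset = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dataset <- resolve_dataset(dataset %||% cfg$data)
  arch <- cfg$architecture
  C <- arch$num_classes
  w <- cfg$weights
  model <- build_model(arch, seed = cfg$train$seed)
  aux_fp_before <- if (arch$aux_enabled) model$aux$fingerprint else NA_character_

  n <- length(dataset)
  ys <- lapply(dataset, function(s) one_hot(s$mask$data, C))
  need_reg <- arch$reg_head_enabled
  phis <- if (need_reg)
    lapply(dataset, function(s) unclass(labels_to_levelset(s$mask))) else NULL
  ktrues <- if (need_reg && w$lambda3 > 0)
    lapply(phis, function(p) curvature_map(sharpen_levelset(p, cfg$scale),
                                           cfg$eps)) else NULL
  embs <- if (arch$aux_enabled)
    lapply(dataset, function(s) model$aux$encode(s$image)) else NULL

  opt <- adam_init(model$params)
  log <- vector("list", cfg$train$steps)

  with_local_seed(cfg$train$seed + 7L, {
    for (step in seq_len(cfg$train$steps)) {
      idx <- sample.int(n, cfg$train$batch_size, replace = n < cfg$train$batch_size)
      gacc <- NULL
      comp <- c(dice = 0, ce = 0, mse = 0, curv = 0)
      for (i in idx) {
        out <- model_forward(model, dataset[[i]]$image,
                             aux_embedding = if (!is.null(embs)) embs[[i]],
                             keep_cache = TRUE, training = TRUE)
        model$buffers <- out$cache$buffers
        d_logits <- NULL
        d_phi <- NULL
        if (arch$seg_head_enabled && w$lambda1 > 0) {
          d_logits <- w$lambda1 * seg_loss_grad_logits(out$prob, ys[[i]])
          comp["dice"] <- comp["dice"] + dice_loss(out$prob, ys[[i]])
          comp["ce"] <- comp["ce"] + cross_entropy_loss(out$prob, ys[[i]])
        }
        if (need_reg) {
          d_phi <- 0
          if (w$lambda2 > 0) {
            d_phi <- d_phi + w$lambda2 * levelset_mse_grad(out$phi, phis[[i]])
            comp["mse"] <- comp["mse"] + levelset_mse(out$phi, phis[[i]])
          }
          if (w$lambda3 > 0) {
            d_phi <- d_phi + w$lambda3 *
              curvature_loss_grad_cached(out$phi, ktrues[[i]], cfg$scale, cfg$eps)
            comp["curv"] <- comp["curv"] +
              curvature_loss_cached(out$phi, ktrues[[i]], cfg$scale, cfg$eps)
          }
          if (identical(d_phi, 0)) d_phi <- NULL
        }
        g <- model_backward(model, out$cache, d_logits = d_logits,
                            d_phi = d_phi)
        gacc <- if (is.null(gacc)) g else {
          for (nm in names(g)) gacc[[nm]] <- gacc[[nm]] + g[[nm]]
          gacc
        }
      }
      nb <- length(idx)
      for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] / nb
      comp <- comp / nb
      seg <- comp[["dice"]] + comp[["ce"]]
      tot <- w$lambda1 * seg + w$lambda2 * comp[["mse"]] +
        w$lambda3 * comp[["curv"]]
      if (!is.finite(tot))
        stop(sprintf("training diverged at step %d (non-finite loss)", step),
             call. = FALSE)
      upd <- adam_step(model$params, gacc, opt, lr = cfg$train$learning_rate)
      model$params <- upd$params
      opt <- upd$opt
      log[[step]] <- data.frame(step = step, seg = seg, dice = comp[["dice"]],
                                ce = comp[["ce"]], mse = comp[["mse"]],
                                curv = comp[["curv"]], total = tot)
      if (verbose && step %% 50 == 0)
        message(sprintf("step %d: total %.4f (seg %.4f mse %.1f curv %.4f)",
                        step, tot, seg, comp[["mse"]], comp[["curv"]]))
    }
  })

  aux_fp_after <- if (arch$aux_enabled) model$aux$fingerprint else NA_character_
  structure(list(model = model, log = do.call(rbind, log), cfg = cfg,
                 aux_fingerprint_before = aux_fp_before,
                 aux_fingerprint_after = aux_fp_after),
            class = "trained_model")
}

#' Evaluate a model on a dataset
#'
#' Predicts every image ([predict_mask()]: softmax argmax, or the
#' `phi < 0` rule when the segmentation head is absent) and computes DICE
#' and ASD per image, plus a mean ± SD summary.
#'
#' @param fit A `trained_model` (or bare `segmentation_model`).
#' @param dataset A `circle_dataset`, spec, or dataset directory.
#' @param out_dir Optional directory: predicted masks are written there as
#'   `pred_%04d.png` (class value k stored as grey level k).
#' @return An `experiment_result`: `per_image` data.frame, `summary`
#'   one-row data.frame.
#' @export
evaluate <- function(fit, dataset, out_dir = NULL) {
  model <- if (inherits(fit, "trained_model")) fit$model else fit
  dataset <- resolve_dataset(dataset)
  C <- model$cfg$num_classes
  nc_data <- max(vapply(dataset, function(s) max(s$mask$data), 0L)) + 1L
  if (nc_data > C)
    stop("dataset has more classes than the model", call. = FALSE)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset), function(i) {
    pred <- predict_mask(model, dataset[[i]]$image)
    if (!is.null(out_dir))
      png::writePNG(pred / 255, file.path(out_dir,
                                          sprintf("pred_%04d.png", i)))
    metric_report(pred, dataset[[i]]$mask$data, num_classes = C,
                  spacing = dataset[[i]]$mask$pixel_spacing,
                  image_id = sprintf("%04d", i))
  })
  per_image <- do.call(rbind, rows)
  structure(list(per_image = per_image,
                 summary = summarize_metrics(per_image)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("DICE %.2f ± %.2f %%, ASD %.2f ± %.2f (n = %d)\n",
              s$dice_mean, s$dice_sd, s$asd_mean, s$asd_sd, s$n))
  invisible(x)
}

#' Out-of-distribution circle experiment
#'
#' The brightness-shift study: generate a training set of brightness-1.0
#' circles and a test set of brightness-0.5 circles from one seed family,
#' train two models that differ only in the level-set supervision — the
#' full objective (regression head, lambda2/lambda3 on) versus a plain
#' DICE+CE U-Net (regression head removed, lambda2 = lambda3 = 0) — and
#' evaluate both on the dim test set.
#'
#' @param base_cfg A [run_config] for the with-curvature arm; `NULL` uses
#'   the defaults (128 x 128, depth-3 U-Net, 200 train / 100 test).
#' @param seed Seed family for data generation and training.
#' @param n_test Test images.
#' @param out_dir Optional directory: writes `table.csv` (the two-row
#'   comparison), per-arm loss curves and resolved configs.
#' @param verbose Print training progress.
#' @return List of class `ood_result`: `with_curvature` and
#'   `without_curvature` `experiment_result`s and `table` (two-row
#'   data.frame with dice/asd mean and SD).
#' @export
run_ood_circle_experiment <- function(base_cfg = NULL, seed = 1,
                                      n_test = 100, out_dir = NULL,
                                      verbose = FALSE) {
  cfg <- base_cfg %||% run_config(
    seed = seed,
    data = circle_dataset_spec(image_size = c(128, 128), seed = seed))
  spec <- if (inherits(cfg$data, "circle_dataset_spec")) cfg$data
          else stop("the OOD experiment needs a circle_dataset_spec",
                    call. = FALSE)
  train_spec <- circle_dataset_spec(n_images = spec$n_images,
                                    image_size = spec$image_size,
                                    radius_range = spec$radius_range,
                                    brightness = 1.0,
                                    background_value = spec$background_value,
                                    noise_sd = spec$noise_sd,
                                    seed = spec$seed)
  test_spec <- circle_dataset_spec(n_images = n_test,
                                   image_size = spec$image_size,
                                   radius_range = spec$radius_range,
                                   brightness = 0.5,
                                   background_value = spec$background_value,
                                   noise_sd = spec$noise_sd,
                                   seed = spec$seed + 10000L)
  train_ds <- generate_circle_dataset(train_spec)
  test_ds <- generate_circle_dataset(test_spec)

  cfg_with <- cfg
  cfg_with$data <- train_spec
  arch_wo <- cfg$architecture
  arch_wo$reg_head_enabled <- FALSE
  cfg_without <- cfg
  cfg_without$architecture <- arch_wo
  cfg_without$weights <- loss_weights(cfg$weights$lambda1, 0, 0)
  cfg_without$data <- train_spec

  fit_with <- train(cfg_with, dataset = train_ds, verbose = verbose)
  fit_without <- train(cfg_without, dataset = train_ds, verbose = verbose)
  pd <- function(arm) if (!is.null(out_dir)) file.path(out_dir, arm)
  res_with <- evaluate(fit_with, test_ds, out_dir = pd("predictions_with"))
  res_without <- evaluate(fit_without, test_ds,
                          out_dir = pd("predictions_without"))

  tab <- rbind(
    cbind(data.frame(arm = "with_curvature"), res_with$summary),
    cbind(data.frame(arm = "without_curvature"), res_without$summary))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, "table.csv"), row.names = FALSE)
    write_loss_csv(fit_with$log, file.path(out_dir, "loss_with_curvature.csv"))
    write_loss_csv(fit_without$log,
                   file.path(out_dir, "loss_without_curvature.csv"))
    write_run_config(cfg_with, file.path(out_dir, "config_with_curvature.yaml"))
    write_run_config(cfg_without,
                     file.path(out_dir, "config_without_curvature.yaml"))
  }
  structure(list(with_curvature = res_with, without_curvature = res_without,
                 fit_with = fit_with, fit_without = fit_without,
                 table = tab),
            class = "ood_result")
}

#' @export
print.ood_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' One file holding the weights, the architecture config, the training
#' seed and (for a mock auxiliary encoder) its reconstruction spec. The
#' loader rebuilds the auxiliary encoder and validates the stored config
#' fingerprint.
#'
#' @param fit A `trained_model` or `segmentation_model`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "trained_model")) fit$model else fit
  ck <- list(params = model$params, buffers = model$buffers,
             cfg = model$cfg, seed = model$seed,
             aux_spec = if (model$cfg$aux_enabled) model$aux$spec,
             cfg_hash = fingerprint(model$cfg))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(fingerprint(ck$cfg), ck$cfg_hash))
    stop("checkpoint config hash mismatch", call. = FALSE)
  aux <- NULL
  if (ck$cfg$aux_enabled) {
    if (is.null(ck$aux_spec) || ck$aux_spec$type != "mock")
      stop("checkpoint lacks a reconstructible auxiliary encoder",
           call. = FALSE)
    aux <- mock_auxiliary_encoder(ck$aux_spec$seed, ck$aux_spec$channels)
  }
  model <- build_model(ck$cfg, aux_encoder = aux, seed = ck$seed)
  model$params <- ck$params
  model$buffers <- ck$buffers
  model
}
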