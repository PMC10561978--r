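#' Exponential learning-rate decay
#'
#' `lr(epoch) = lr0 * gamma^epoch` with a 0-based epoch index, stepped once
#' per epoch.
#'
#' @param lr0 initial learning rate (default 1.25e-3).
#' @param gamma decay base in `(0, 1]` (default 0.95).
#' @param epoch epoch index, `>= 0`.
#' @return The learning rate.
#' @examples
#' lr_schedule(1.25e-3, 0.95, 20)  # 4.4811e-4
#' @export
lr_schedule <- function(lr0 = 1.25e-3, gamma = 0.95, epoch = 0) {
  if (epoch < 0) stop("lr_schedule: epoch must be >= 0")
  if (gamma <= 0 || gamma > 1) stop("lr_schedule: gamma must be in (0, 1]")
  lr0 * gamma^epoch
}

#' Training configuration
#'
#' Defaults follow the published training recipe where one is stated
#' (AdamW, initial learning rate 1.25e-3, exponential decay with gamma 0.95,
#' 20 epochs, weight decay 5e-3) and this package's own choices elsewhere
#' (batch size 8, gradient-norm clipping at 10, best checkpoint selected by
#' validation F1).
#'
#' @param lr0,gamma,epochs,weight_decay optimizer schedule (see above).
#' @param batch_size images per optimizer step.
#' @param seed master seed for weight initialization and data order.
#' @param loss_weights a [loss_weights()].
#' @param net a [net_config()].
#' @param score_threshold,top_k,iou_threshold decoding/evaluation settings
#'   used for the per-epoch validation metrics.
#' @param angle_wrap use the 180-degree-wrapped angle loss (default `FALSE`,
#'   the plain absolute difference).
#' @param clip_norm global gradient-norm clip.
#' @param validate_every run the validation pass every this many epochs (the
#'   final epoch is always validated); 1 validates every epoch.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr0 = 1.25e-3, gamma = 0.95, epochs = 20,
                         weight_decay = 5e-3, batch_size = 8, seed = 0,
                         loss_weights = stomakit::loss_weights(),
                         net = net_config(), score_threshold = 0.3,
                         top_k = 100, iou_threshold = 0.5,
                         angle_wrap = FALSE, clip_norm = 10,
                         validate_every = 1) {
  if (lr0 <= 0) stop("train_config: lr0 must be positive")
  if (gamma <= 0 || gamma > 1) stop("train_config: gamma must be in (0, 1]")
  if (epochs < 1) stop("train_config: epochs must be >= 1")
  structure(list(lr0 = lr0, gamma = gamma, epochs = as.integer(epochs),
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss_weights = loss_weights, net = net,
                 score_threshold = score_threshold, top_k = as.integer(top_k),
                 iou_threshold = iou_threshold,
                 angle_wrap = isTRUE(angle_wrap), clip_norm = clip_norm,
                 validate_every = as.integer(validate_every)),
            class = "train_config")
}

# Normalize the accepted data forms (dataset directory, list of
# synth_samples, or list of (image, annotations, split)) into one layout.
as_training_set <- function(data) {
  if (is.character(data) && length(data) == 1) {
    ds <- read_dataset(data)
    return(ds$samples)
  }
  stopifnot(is.list(data), length(data) > 0)
  out <- lapply(data, function(s) {
    if (inherits(s, "synth_sample"))
      list(image = s$image, annotations = s$annotations, split = NULL)
    else list(image = s$image, annotations = s$annotations, split = s$split)
  })
  if (all(vapply(out, function(s) is.null(s$split), logical(1)))) {
    n_train <- floor(3 * length(out) / 4)
    for (i in seq_along(out))
      out[[i]]$split <- if (i <= n_train) "train" else "val"
  }
  out
}

# One forward + loss evaluation on the tape; returns loss nodes and values.
image_losses <- function(tape, net, sample, targets, cfg, training = TRUE) {
  img <- sample$image
  if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1L)
  x <- new_leaf(img / 127.5 - 1, nograd = TRUE)
  nodes <- net_fwd_nodes(tape, net, x, training = training)
  lw <- cfg$loss_weights
  l_hm <- focal_loss_fwd(tape, nodes$heatmap, targets$heatmap_q,
                         lw$alpha, lw$beta)
  lin <- targets$center_lin
  off_at <- gather_cells_fwd(tape, nodes$offset, lin)
  size_at <- gather_cells_fwd(tape, nodes$size, lin)
  ang_at <- gather_cells_fwd(tape, nodes$angle, lin)
  l_off <- l1_loss_fwd(tape, off_at, targets$offset_O)
  l_size <- l1_loss_fwd(tape, size_at, targets$size_S)
  l_ang <- angle_loss_fwd(tape, ang_at, targets$angle_theta, cfg$angle_wrap)
  l_con <- cond_loss_fwd(tape, size_at, targets$gsmax_G, targets$density,
                         targets$pixel_scale, targets$stride,
                         conductance_params())
  comp <- list(heatmap = l_hm, offset = l_off, size = l_size, angle = l_ang,
               conductance = l_con)
  tot <- wsum_fwd(tape, comp, lw$w)
  vals <- vapply(comp, function(n) n$value, numeric(1))
  list(total = tot, values = vals, total_value = tot$value)
}

# Tape-free total loss from decoded head arrays (used for validation logs).
head_loss_values <- function(heads, targets, cfg) {
  lw <- cfg$loss_weights
  p <- pmin(pmax(heads$heatmap, 1e-7), 1 - 1e-7)
  lin <- targets$center_lin
  gh <- nrow(heads$heatmap)
  gather <- function(arr) {
    m <- arr; dim(m) <- c(gh * ncol(heads$heatmap), dim(arr)[3])
    m[lin, , drop = FALSE]
  }
  off_at <- gather(heads$offset)
  size_at <- gather(heads$size)
  ang_at <- heads$angle[lin]
  l_con <- conductance_loss(size_at,
                            boxes_from_targets(targets),
                            targets$density, targets$pixel_scale,
                            targets$stride)
  comp <- c(heatmap = heatmap_loss(p, targets$heatmap_q, lw$alpha, lw$beta),
            offset = offset_loss(off_at, targets$offset_O),
            size = size_loss(size_at, targets$size_S),
            angle = angle_loss(ang_at, targets$angle_theta, cfg$angle_wrap),
            conductance = as.numeric(l_con))
  as.numeric(total_loss(comp, lw))
}

# Reconstruct plain boxes from encoded targets (centers are approximate to
# the cell grid, which is irrelevant for size-only consumers).
boxes_from_targets <- function(targets) {
  lapply(seq_len(targets$K), function(k)
    rotated_box((targets$center_cells[k, 1] + targets$offset_O[k, 1]) *
                  targets$stride,
                (targets$center_cells[k, 2] + targets$offset_O[k, 2]) *
                  targets$stride,
                max(targets$size_S[k, 1], 1e-3) * targets$stride,
                max(targets$size_S[k, 2], 1e-3) * targets$stride,
                targets$angle_theta[k]))
}

#' Fit the rotated-stomata detector
#'
#' Trains the anchor-free detection network with AdamW (decoupled weight
#' decay), per-epoch exponential learning-rate decay and the five-term loss.
#' Per-epoch training/validation losses and validation precision/recall/F1
#' (rotated IoU matching on decoded boxes) are logged; the weights with the
#' best validation F1 are kept and restored in the returned model. Fully
#' deterministic for a fixed configuration, data and seed.
#'
#' @param data a dataset directory written by [generate_dataset()], a list of
#'   `synth_sample`s, or a list of `list(image, annotations, split)`.
#' @param config a [train_config()].
#' @param out_dir optional directory for the metrics CSV
#'   (`training_log.csv`) and the best checkpoint (`checkpoint.rds`).
#' @param verbose print one line per epoch.
#' @return An object of class `rsd_model`: the fitted network plus `history`
#'   (per-epoch metrics), `config`, `best_epoch`, `best_f1`,
#'   `val_gsmax_mse`.
#' @export
train_detector <- function(data, config = train_config(), out_dir = NULL,
                           verbose = FALSE) {
  samples <- as_training_set(data)
  tr_idx <- which(vapply(samples, function(s) s$split == "train", logical(1)))
  va_idx <- which(vapply(samples, function(s) s$split == "val", logical(1)))
  if (!length(tr_idx)) stop("train_detector: no training images")
  net <- with_seed(config$seed, build_network(config$net))
  params <- network_params(net)
  opt <- adamw_state(params)
  max_stride <- 2L * 2L^length(net$stages)
  targets <- lapply(samples, function(s) {
    h <- nrow(s$image); w <- ncol(s$image)
    gh <- as.integer(ceiling(h / max_stride) * max_stride / config$net$output_stride)
    gw <- as.integer(ceiling(w / max_stride) * max_stride / config$net$output_stride)
    encode_targets(s$annotations, stride = config$net$output_stride,
                   grid_h = gh, grid_w = gw)
  })
  history <- NULL
  best_f1 <- -Inf; best_epoch <- 0L; best <- snapshot_weights(net)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(config$lr0, config$gamma, epoch - 1)
    ord <- with_seed(config$seed * 1009L + epoch, sample(tr_idx))
    term_sums <- c(heatmap = 0, offset = 0, size = 0, angle = 0,
                   conductance = 0)
    tot_sum <- 0
    nb <- 0L
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(length(ord), i + config$batch_size - 1L)]
      i <- i + config$batch_size
      zero_grads(params)
      for (bi in batch) {
        tape <- new_tape()
        il <- image_losses(tape, net, samples[[bi]], targets[[bi]], config)
        if (!is.finite(il$total_value))
          stop("train_detector: non-finite loss at epoch ", epoch,
               ", image ", bi, " (terms: ",
               paste(sprintf("%s=%.4g", names(il$values), il$values),
                     collapse = ", "), ")")
        term_sums <- term_sums + il$values
        tot_sum <- tot_sum + il$total_value
        nb <- nb + 1L
        tape_backward(tape, il$total, seed = 1 / length(batch))
      }
      step <- step + 1L
      opt <- adamw_step(params, opt, lr, config$weight_decay, t = step,
                        clip_norm = config$clip_norm)
    }
    # validation: losses in eval mode plus decoded-detection metrics
    val_tot <- NA_real_; vm <- list(precision = NA, recall = NA, f1 = NA)
    val_mse <- NA_real_; val_mse_e2e <- NA_real_
    do_val <- length(va_idx) > 0 &&
      (epoch %% max(1L, config$validate_every %||% 1L) == 0L ||
         epoch == config$epochs)
    if (do_val) {
      vt <- 0
      dets <- list(); gts <- list()
      g_pred <- numeric(0); g_true <- numeric(0); g_e2e <- numeric(0)
      for (k in seq_along(va_idx)) {
        vi <- va_idx[k]
        heads <- network_forward(net, samples[[vi]]$image, training = FALSE)
        vt <- vt + head_loss_values(heads, targets[[vi]], config)
        dd <- decode_detections(heads, top_k = config$top_k,
                                score_threshold = config$score_threshold)
        dets[[k]] <- dd
        gts[[k]] <- samples[[vi]]$annotations$boxes
        ann <- samples[[vi]]$annotations
        tr_pred <- measure_image(dd, ann$image_width_px, ann$image_height_px,
                                 ann$pixel_scale)
        tr_true <- measure_image(ann$boxes, ann$image_width_px,
                                 ann$image_height_px, ann$pixel_scale)
        # conductance accuracy under the package convention: the true image
        # density enters both sides, so the comparison isolates the
        # size-measurement error the conductance loss supervises (the
        # end-to-end value with the detected density is logged alongside)
        dens_true <- tr_true$density_per_mm2
        g_iso <- if (tr_pred$count > 0)
          gsmax(mean(tr_pred$lengths_um), mean(tr_pred$widths_um), dens_true)
        else 0
        g_pred <- c(g_pred, g_iso)
        g_true <- c(g_true, gsmax(mean(tr_true$lengths_um),
                                  mean(tr_true$widths_um), dens_true))
        g_e2e <- c(g_e2e, tr_pred$gsmax_mol_m2_s)
      }
      val_tot <- vt / length(va_idx)
      ev <- evaluate_detections(dets, gts, config$iou_threshold)
      vm <- ev
      val_mse <- mean((g_pred - g_true)^2)
      val_mse_e2e <- mean((g_e2e - g_true)^2)
      if (ev$f1 > best_f1) {
        best_f1 <- ev$f1; best_epoch <- epoch
        best <- snapshot_weights(net)
      }
    } else if (length(va_idx) == 0) {
      best <- snapshot_weights(net); best_epoch <- epoch
    }
    row <- data.frame(epoch = epoch, lr = lr,
                      train_total = tot_sum / max(1, nb),
                      val_total = val_tot,
                      LH = term_sums["heatmap"] / max(1, nb),
                      Loff = term_sums["offset"] / max(1, nb),
                      Lsize = term_sums["size"] / max(1, nb),
                      Lang = term_sums["angle"] / max(1, nb),
                      Lcon = term_sums["conductance"] / max(1, nb),
                      val_precision = vm$precision, val_recall = vm$recall,
                      val_f1 = vm$f1, val_gsmax_mse = val_mse,
                      val_gsmax_mse_e2e = val_mse_e2e,
                      row.names = NULL)
    history <- rbind(history, row)
    if (verbose)
      message(sprintf(
        "epoch %2d  lr %.2e  train %.4f  val %.4f  P %.3f R %.3f F1 %.3f",
        epoch, lr, row$train_total, row$val_total,
        if (is.na(vm$precision)) 0 else vm$precision,
        if (is.na(vm$recall)) 0 else vm$recall,
        if (is.na(vm$f1)) 0 else vm$f1))
  }
  set_network_weights(net, best$values, best$norm_stats)
  model <- structure(list(network = net, config = config, history = history,
                          best_epoch = best_epoch,
                          best_f1 = if (is.finite(best_f1)) best_f1 else NA_real_,
                          val_gsmax_mse = history$val_gsmax_mse[best_epoch],
                          val_gsmax_mse_e2e =
                            history$val_gsmax_mse_e2e[best_epoch],
                          n_train = length(tr_idx), n_val = length(va_idx)),
                     class = "rsd_model")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(history, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
    save_network(net, file.path(out_dir, "checkpoint.rds"))
  }
  model
}

#' @export
print.rsd_model <- function(x, ...) {
  cat("Rotated-stomata detector (anchor-free keypoint heatmap)\n")
  cat(sprintf("  backbone preset: %s;  %d train / %d val images;  %d epochs\n",
              x$config$net$preset, x$n_train, x$n_val, x$config$epochs))
  if (!is.na(x$best_f1))
    cat(sprintf("  best validation F1: %.3f (epoch %d, rotated IoU %.2f)\n",
                x$best_f1, x$best_epoch, x$config$iou_threshold))
  invisible(x)
}

#' @export
summary.rsd_model <- function(object, ...) {
  h <- object$history
  out <- list(history = h, best_epoch = object$best_epoch,
              best_f1 = object$best_f1,
              final = h[nrow(h), ],
              val_gsmax_mse = object$val_gsmax_mse)
  class(out) <- "summary.rsd_model"
  out
}

#' @export
print.summary.rsd_model <- function(x, ...) {
  cat("Training history (per epoch):\n")
  print(x$history, digits = 4, row.names = FALSE)
  cat(sprintf("\nBest epoch %d: validation F1 %.3f, gsmax MSE %.4g\n",
              x$best_epoch, x$best_f1, x$val_gsmax_mse))
  invisible(x)
}

#' Detect stomata in new images
#'
#' @param object a fitted `rsd_model`.
#' @param newdata a gray image matrix, a list of such matrices, or a list of
#'   samples with an `image` element.
#' @param score_threshold,top_k decoding settings (defaults from training
#'   config).
#' @param ... unused.
#' @return For a single image, a list of detections (`box` + `score`);
#'   for a list input, a list of such lists.
#' @export
predict.rsd_model <- function(object, newdata,
                              score_threshold = object$config$score_threshold,
                              top_k = object$config$top_k, ...) {
  single <- is.matrix(newdata)
  imgs <- if (single) list(newdata)
  else lapply(newdata, function(s) if (is.list(s)) s$image else s)
  out <- lapply(imgs, function(im) {
    heads <- network_forward(object$network, im, training = FALSE)
    decode_detections(heads, top_k = top_k, score_threshold = score_threshold)
  })
  if (single) out[[1]] else out
}

#' Plot training diagnostics or detections
#'
#' `which = "history"` draws the train/validation loss curves and the
#' validation F1 trace; `which = "detections"` overlays decoded boxes (and
#' optionally ground truth) on an image.
#'
#' @param x a fitted `rsd_model`.
#' @param which `"history"` or `"detections"`.
#' @param image gray image matrix (required for `"detections"`).
#' @param truth optional list of ground-truth [rotated_box()]es.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.rsd_model <- function(x, which = c("history", "detections"),
                           image = NULL, truth = NULL, ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$history
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    graphics::matplot(h$epoch, cbind(h$train_total, h$val_total), type = "l",
                      lty = 1, col = c("black", "red"), xlab = "epoch",
                      ylab = "total loss", ...)
    graphics::legend("topright", c("train", "validation"), lty = 1,
                     col = c("black", "red"), bty = "n")
    graphics::plot(h$epoch, h$val_f1, type = "b", xlab = "epoch",
                   ylab = "validation F1", ylim = c(0, 1), ...)
  } else {
    if (is.null(image)) stop("plot(..., which='detections') needs an image")
    graphics::image(t(image)[, nrow(image):1], col = grDevices::gray.colors(256),
                    axes = FALSE, asp = nrow(image) / ncol(image))
    draw <- function(b, col) {
      m <- box_corners(b)
      xs <- (m[, 1] + 0.5) / ncol(image)
      ys <- 1 - (m[, 2] + 0.5) / nrow(image)
      graphics::polygon(xs, ys, border = col, lwd = 2)
    }
    dets <- predict(x, image)
    for (d in dets) draw(d$box, "red")
    if (!is.null(truth)) for (b in truth) draw(b, "green3")
  }
  invisible(x)
}
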