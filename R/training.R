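# Training loop: Adam (or SGD-momentum) on the BCE-dice loss, mini-batches of
# slice samples, once-per-epoch validation, patience-based early stopping,
# checkpointing, and the evaluation / volume-prediction harness.

#' Training configuration
#'
#' Defaults follow the published recipe: BCE-dice loss, at most 1000 epochs,
#' early-stop patience 20, batch size 4, Adam with learning rate 3e-4 and
#' weight decay 1e-4. The recipe lists both Adam and momentum 0.9; that is
#' read as Adam's beta1 = 0.9 (`optimizer = "sgd"` switches to classical
#' SGD with momentum 0.9 for the alternative reading).
#'
#' @param loss Loss name; only `"bce_dice"` is implemented.
#' @param max_epochs Epoch cap.
#' @param patience Early-stop patience (epochs without improvement).
#' @param batch_size Mini-batch size.
#' @param optimizer `"adam"` or `"sgd"` (momentum SGD).
#' @param lr Learning rate.
#' @param momentum Adam beta1 / SGD momentum.
#' @param beta2 Adam second-moment decay.
#' @param weight_decay L2 penalty coefficient.
#' @param monitor `"dice"` (validation mean dice, maximized) or `"loss"`
#'   (validation loss, minimized) for model selection and early stopping.
#' @param smooth Dice smoothing constant of the loss.
#' @param seed RNG seed covering shuffling and dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(loss = "bce_dice", max_epochs = 1000L, patience = 20L,
                         batch_size = 4L, optimizer = c("adam", "sgd"),
                         lr = 3e-4, momentum = 0.9, beta2 = 0.999,
                         weight_decay = 1e-4, monitor = c("dice", "loss"),
                         smooth = 1, seed = 1L) {
  stopifnot(identical(loss, "bce_dice"))
  structure(list(loss = loss, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 optimizer = match.arg(optimizer), lr = lr,
                 momentum = momentum, beta2 = beta2,
                 weight_decay = weight_decay, monitor = match.arg(monitor),
                 smooth = smooth, seed = as.integer(seed)),
            class = "train_config")
}

# ---------------------------------------------------------------------------
# optimizers over parameter trees

opt_init <- function(params, cfg) {
  z <- zero_grads(params)
  if (cfg$optimizer == "adam") list(t = 0L, m = z, v = z)
  else list(t = 0L, m = z)
}

# one optimizer step; returns list(params, state)
opt_step <- function(params, grads, state, cfg) {
  lr <- cfg$lr; wd <- cfg$weight_decay
  if (cfg$optimizer == "adam") {
    b1 <- cfg$momentum; b2 <- cfg$beta2; eps <- 1e-8
    state$t <- state$t + 1L
    t <- state$t
    rec <- function(p, g, m, v) {
      nms <- names(p) %||% rep("", length(p))
      for (i in seq_along(p)) {
        key <- if (nzchar(nms[i])) nms[i] else i
        if (nms[i] %in% PARAM_LEAVES && is.numeric(p[[i]])) {
          gr <- g[[key]] + wd * p[[i]]
          m[[key]] <- b1 * m[[key]] + (1 - b1) * gr
          v[[key]] <- b2 * v[[key]] + (1 - b2) * gr * gr
          mhat <- m[[key]] / (1 - b1^t)
          vhat <- v[[key]] / (1 - b2^t)
          p[[i]] <- p[[i]] - lr * mhat / (sqrt(vhat) + eps)
        } else if (is.list(p[[i]])) {
          sub <- rec(p[[i]], g[[key]], m[[key]], v[[key]])
          p[[i]] <- sub$p; m[[key]] <- sub$m; v[[key]] <- sub$v
        }
      }
      list(p = p, m = m, v = v)
    }
    r <- rec(params, grads, state$m, state$v)
    list(params = r$p, state = list(t = state$t, m = r$m, v = r$v))
  } else {
    mu <- cfg$momentum
    rec <- function(p, g, m) {
      nms <- names(p) %||% rep("", length(p))
      for (i in seq_along(p)) {
        key <- if (nzchar(nms[i])) nms[i] else i
        if (nms[i] %in% PARAM_LEAVES && is.numeric(p[[i]])) {
          gr <- g[[key]] + wd * p[[i]]
          m[[key]] <- mu * m[[key]] + gr
          p[[i]] <- p[[i]] - lr * m[[key]]
        } else if (is.list(p[[i]])) {
          sub <- rec(p[[i]], g[[key]], m[[key]])
          p[[i]] <- sub$p; m[[key]] <- sub$m
        }
      }
      list(p = p, m = m)
    }
    r <- rec(params, grads, state$m)
    list(params = r$p, state = list(t = state$t + 1L, m = r$m))
  }
}

# ---------------------------------------------------------------------------
# gradient steps

# loss and parameter gradients for one mini-batch (list of slice samples)
batch_loss_grads <- function(net, batch, cfg, training = TRUE) {
  acc <- NULL
  loss <- 0
  for (s in batch) {
    fw <- masunet_fwd(net, s$image, training = training)
    l <- bce_dice_loss(fw$y, s$masks, smooth = cfg$smooth)
    if (!is.finite(l))
      stop(sprintf("non-finite loss on volume %s slice %d (%s)",
                   s$volume_id, s$slice, s$aug), call. = FALSE)
    loss <- loss + l / length(batch)
    dy <- bce_dice_grad(fw$y, s$masks, smooth = cfg$smooth) / length(batch)
    g <- masunet_bwd(net, fw$cache, dy)
    acc <- if (is.null(acc)) g else tree_map2(`+`, acc, g)
  }
  list(loss = loss, grads = acc)
}

# n_steps optimizer steps cycling over shuffled mini-batches (no reseeding)
run_steps <- function(net, opt_state, samples, cfg, n_steps) {
  losses <- numeric(n_steps)
  order <- sample(length(samples))
  pos <- 1L
  for (step in seq_len(n_steps)) {
    if (pos + cfg$batch_size - 1L > length(samples)) {
      order <- sample(length(samples))
      pos <- 1L
    }
    take <- order[pos:min(pos + cfg$batch_size - 1L, length(order))]
    pos <- pos + cfg$batch_size
    bg <- batch_loss_grads(net, samples[take], cfg)
    losses[step] <- bg$loss
    st <- opt_step(net$params, bg$grads, opt_state, cfg)
    net$params <- st$params
    opt_state <- st$state
  }
  list(net = net, opt_state = opt_state, losses = losses)
}

#' Run a fixed number of optimizer steps on a set of slices
#'
#' Convenience harness for overfitting experiments and smoke tests: shuffled
#' mini-batches of `cfg$batch_size`, `n_steps` optimizer steps, no validation
#' or early stopping. Deterministic given `cfg$seed`.
#'
#' @param net A `masunet` object.
#' @param samples List of slice samples (image + masks).
#' @param cfg A [train_config()].
#' @param n_steps Number of optimizer steps.
#' @return List with the trained `net` and the per-step `losses`.
#' @export
train_steps <- function(net, samples, cfg = train_config(), n_steps) {
  if (!length(samples)) stop("no training samples", call. = FALSE)
  with_seed(cfg$seed, {
    r <- run_steps(net, opt_init(net$params, cfg), samples, cfg, n_steps)
    list(net = r$net, losses = r$losses)
  })
}

#' Early-stopping decision
#'
#' Improvement means a validation score strictly greater than the best so far
#' (tolerance 1e-6); training stops once `patience` epochs have passed since
#' the last improvement.
#'
#' @param state List with `val_history`, the per-epoch validation scores
#'   (higher is better).
#' @param patience Number of epochs without improvement tolerated.
#' @return `TRUE` to stop, `FALSE` to continue.
#' @export
early_stopping_check <- function(state, patience) {
  h <- state$val_history
  if (!length(h)) stop("empty validation history", call. = FALSE)
  best <- -Inf; best_epoch <- 0L
  for (i in seq_along(h)) {
    if (h[i] > best + 1e-6) { best <- h[i]; best_epoch <- i }
  }
  (length(h) - best_epoch) >= patience
}

# mean dice over validation volumes (mean of per-class pooled-per-volume dice)
# and mean validation loss, from one eval-mode forward per slice
validate_net <- function(net, val_groups, cfg, threshold = 0.5) {
  vloss <- 0; n <- 0
  reports <- list()
  for (vid in names(val_groups)) {
    ss <- val_groups[[vid]]
    pred <- array(0, c(dim(ss[[1]]$masks), length(ss)))
    truth <- array(0, c(dim(ss[[1]]$masks), length(ss)))
    for (i in seq_along(ss)) {
      fw <- masunet_fwd(net, ss[[i]]$image, training = FALSE)
      vloss <- vloss + bce_dice_loss(fw$y, ss[[i]]$masks, smooth = cfg$smooth)
      n <- n + 1
      pred[, , , i] <- (sigmoid(fw$y) > threshold) * 1
      truth[, , , i] <- ss[[i]]$masks
    }
    reports[[vid]] <- evaluate_volume(pred, truth, volume_id = vid)
  }
  report <- do.call(rbind, reports)
  s <- summarize_metrics(report)
  list(mean_dice = mean(s$dice), val_loss = vloss / n, report = report,
       dice_by_class = stats::setNames(s$dice, s$class))
}

group_by_volume <- function(samples) {
  split(samples, vapply(samples, `[[`, character(1), "volume_id"))
}

#' Train the network on a volume split
#'
#' Preprocesses the training and validation volumes into slices, triples the
#' training slices by offline augmentation (validation slices are never
#' augmented), then runs mini-batch training with once-per-epoch validation.
#' The weights with the best validation score are retained; training stops at
#' `cfg$patience` epochs without improvement or at `cfg$max_epochs`.
#'
#' @param net A `masunet` object.
#' @param split A `dataset_split` from [split_dataset()].
#' @param cfg A [train_config()].
#' @param target_size Slice size fed to the network.
#' @param aug_cfg An [augmentation_config()], or `NULL` to disable
#'   augmentation.
#' @param modalities Image channels to use (must match `net$cfg$in_channels`).
#' @param threshold Probability threshold used for validation dice.
#' @param verbose Print one line per epoch?
#' @return List with the best `net` and a `state` record (`epoch`,
#'   `best_score`, `best_epoch`, `history` data frame).
#' @export
train_model <- function(net, split, cfg = train_config(),
                        target_size = c(64L, 64L),
                        aug_cfg = augmentation_config(), modalities = 1L,
                        threshold = 0.5, verbose = FALSE) {
  stopifnot(inherits(split, "dataset_split"), inherits(cfg, "train_config"))
  if (!length(split$validation)) stop("validation set is empty", call. = FALSE)
  if (!length(split$train)) stop("training set is empty", call. = FALSE)
  train_samples <- unlist(lapply(split$train, preprocess_volume,
                                 target_size = target_size,
                                 modalities = modalities), recursive = FALSE)
  if (!is.null(aug_cfg)) train_samples <- augment_offline(train_samples, aug_cfg)
  val_samples <- unlist(lapply(split$validation, preprocess_volume,
                               target_size = target_size,
                               modalities = modalities), recursive = FALSE)
  val_groups <- group_by_volume(val_samples)
  steps_per_epoch <- max(1L, length(train_samples) %/% cfg$batch_size)
  best_params <- net$params
  best_score <- -Inf; best_epoch <- 0L
  history <- NULL
  with_seed(cfg$seed, {
    opt_state <- opt_init(net$params, cfg)
    for (epoch in seq_len(cfg$max_epochs)) {
      r <- run_steps(net, opt_state, train_samples, cfg, steps_per_epoch)
      net <- r$net; opt_state <- r$opt_state
      val <- validate_net(net, val_groups, cfg, threshold)
      score <- if (cfg$monitor == "dice") val$mean_dice else -val$val_loss
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(r$losses), val_loss = val$val_loss,
        val_mean_dice = val$mean_dice,
        val_dice_pz = unname(val$dice_by_class["PZ"]),
        val_dice_tz = unname(val$dice_by_class["TZ"])))
      if (score > best_score + 1e-6) {
        best_score <- score; best_epoch <- epoch
        best_params <- net$params
      }
      if (verbose)
        message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val dice %.4f",
                        epoch, mean(r$losses), val$val_loss, val$mean_dice))
      state <- list(val_history = if (cfg$monitor == "dice") history$val_mean_dice
                    else -history$val_loss)
      if (early_stopping_check(state, cfg$patience)) break
    }
  })
  net$params <- best_params
  list(net = net,
       state = list(epoch = nrow(history), best_score = best_score,
                    best_epoch = best_epoch,
                    epochs_since_improvement = nrow(history) - best_epoch,
                    history = history))
}

#' Evaluate a network on labeled volumes
#'
#' Predicts every slice in eval mode, pools pixel counts per volume, and
#' reports Dice, PPV and sensitivity per volume and class plus dataset means.
#'
#' @param net A `masunet` object.
#' @param volumes List of labeled volume records.
#' @param target_size Slice size fed to the network.
#' @param threshold Probability threshold for binarization.
#' @param modalities Image channels used.
#' @return List with the per-volume `report` data frame and the per-class
#'   `summary` of dataset means.
#' @export
evaluate_model <- function(net, volumes, target_size = c(64L, 64L),
                           threshold = 0.5, modalities = 1L) {
  if (!all(vapply(volumes, `[[`, logical(1), "labeled")))
    stop("all volumes must be labeled for evaluation", call. = FALSE)
  samples <- unlist(lapply(volumes, preprocess_volume,
                           target_size = target_size, modalities = modalities),
                    recursive = FALSE)
  val <- validate_net(net, group_by_volume(samples),
                      train_config(seed = 1L), threshold)
  list(report = val$report, summary = summarize_metrics(val$report))
}

#' Predict the label volume for one volume record
#'
#' Slices are preprocessed to `target_size`, predicted in eval mode,
#' binarized with overlap resolution, resized back to the native in-plane
#' resolution (nearest-neighbour), and restacked. Optionally writes a NIfTI
#' aligned to the input spacing and per-slice PNG overlays (green PZ,
#' red TZ).
#'
#' @param net A `masunet` object.
#' @param v A volume record (labels not required).
#' @param target_size Slice size fed to the network.
#' @param threshold Probability threshold.
#' @param modalities Image channels used.
#' @param out_path Optional output NIfTI path for the label volume.
#' @param overlay_dir Optional directory for per-slice PNG overlays.
#' @return Integer label volume `(H, W, S)` with codes 0/1/2.
#' @export
predict_volume <- function(net, v, target_size = c(64L, 64L), threshold = 0.5,
                           modalities = 1L, out_path = NULL,
                           overlay_dir = NULL) {
  samples <- preprocess_volume(v, target_size = target_size,
                               modalities = modalities)
  d <- dim(v$image)
  out <- array(0L, d[1:3])
  if (!is.null(overlay_dir))
    dir.create(overlay_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(samples)) {
    pm <- predict_masks(net, samples[[s]]$image, threshold)
    lab <- resize_slice(pm$label + 0, d[1], d[2], "nearest")
    out[, , s] <- as.integer(round(lab))
    if (!is.null(overlay_dir))
      write_overlay_png(v$image[, , s, modalities[1]], out[, , s],
                        file.path(overlay_dir, sprintf("%s_slice%02d.png",
                                                       v$volume_id, s)))
  }
  if (!is.null(out_path)) {
    nb <- RNifti::asNifti(array(as.numeric(out), dim(out)))
    RNifti::pixdim(nb) <- v$spacing
    RNifti::writeNifti(nb, out_path)
  }
  out
}

# ---------------------------------------------------------------------------
# checkpoints

#' Save a checkpoint
#'
#' Writes the parameter archive (`<prefix>.rds`) and a JSON sidecar
#' (`<prefix>.json`) recording the architecture configuration and build seed.
#'
#' @param net A `masunet` object.
#' @param prefix Path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
save_checkpoint <- function(net, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  saveRDS(net$params, paste0(prefix, ".rds"))
  jsonlite::write_json(list(config = unclass(net$cfg), seed = net$seed,
                            package_version = as.character(utils::packageVersion("masunet"))),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Load a checkpoint
#'
#' Rebuilds the network from the JSON sidecar's configuration and seed, then
#' replaces the parameters with the archived ones. The sidecar configuration
#' is validated against `expected_cfg` when given.
#'
#' @param prefix Path prefix used in [save_checkpoint()].
#' @param expected_cfg Optional [masunet_config()] that must match the
#'   sidecar.
#' @return A `masunet` object.
#' @export
load_checkpoint <- function(prefix, expected_cfg = NULL) {
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  args <- side$config[setdiff(names(side$config), "depth")]
  args <- lapply(args, function(a) if (is.list(a)) unlist(a) else a)
  cfg <- do.call(masunet_config, args)
  if (!is.null(expected_cfg) && !identical(unclass(expected_cfg), unclass(cfg)))
    stop("checkpoint configuration does not match the expected configuration",
         call. = FALSE)
  net <- build_masunet(cfg, seed = side$seed)
  net$params <- readRDS(paste0(prefix, ".rds"))
  net
}
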