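# Training orchestration: dataset splitting, the training loop for the
# encoder-decoder network under either loss contract, prediction, and
# checkpoint I/O.

#' Training configuration
#'
#' @param target_scheme `"binary"` (disc masks + BCE) or `"gaussian"`
#'   (normalized density maps + KL divergence).
#' @param encoder_name Width/depth preset of the built-in
#'   encoder-decoder: `"micro"`, `"small"` or `"base"`; default
#'   `"small"`.
#' @param loss `"bce"` or `"kldiv"`; must match the scheme (the default
#'   is derived from it).
#' @param epochs Number of training epochs (default 500).
#' @param lr,betas Adam learning rate and moment decays.
#' @param batch_size Images per optimizer step (gradient accumulation).
#' @param split_fractions Train/validation/test fractions (sum to 1).
#' @param seed Integer seed controlling initialization, shuffling and
#'   augmentation draws.
#' @param augmentation An [augmentation_spec()].
#' @param radius_mm Disc radius used to rasterize binary targets.
#' @param sigma_mm Gaussian kernel sd used to rasterize density targets.
#' @param eval_radius_mm Matching radius for the validation F1.
#' @param extraction An [extraction_params()] used when decoding
#'   validation predictions.
#' @return An object of class `train_config`.
#' @export
train_config <- function(target_scheme = c("binary", "gaussian"),
                         encoder_name = "small",
                         loss = NULL,
                         epochs = 500L,
                         lr = 1e-3,
                         betas = c(0.9, 0.999),
                         batch_size = 1L,
                         split_fractions = c(0.6, 0.2, 0.2),
                         seed = 42L,
                         augmentation = augmentation_spec(),
                         radius_mm = 2,
                         sigma_mm = 1,
                         eval_radius_mm = 2,
                         extraction = extraction_params()) {
  target_scheme <- match.arg(target_scheme)
  if (is.null(loss)) loss <- if (target_scheme == "binary") "bce" else "kldiv"
  ok <- (target_scheme == "binary" && loss == "bce") ||
        (target_scheme == "gaussian" && loss == "kldiv")
  if (!ok) {
    stop(sprintf("loss '%s' is incompatible with target scheme '%s'",
                 loss, target_scheme), call. = FALSE)
  }
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  if (abs(sum(split_fractions) - 1) > 1e-8 || any(split_fractions <= 0)) {
    stop("`split_fractions` must be positive and sum to 1", call. = FALSE)
  }
  unet_widths(encoder_name) # validates the preset name
  structure(list(target_scheme = target_scheme, encoder_name = encoder_name,
                 loss = loss, epochs = as.integer(epochs), lr = lr,
                 betas = betas, batch_size = as.integer(batch_size),
                 split_fractions = split_fractions, seed = as.integer(seed),
                 augmentation = augmentation, radius_mm = radius_mm,
                 sigma_mm = sigma_mm, eval_radius_mm = eval_radius_mm,
                 extraction = extraction),
            class = "train_config")
}

#' Randomly partition image ids into train/validation/test
#'
#' Sizes are the rounded fractions of `length(image_ids)` (the test
#' part takes the remainder); the partition is disjoint, exhaustive and
#' a pure function of the seed. The caller's RNG state is left intact.
#'
#' @param image_ids Character or integer vector of ids.
#' @param fractions Length-3 positive vector summing to 1.
#' @param seed Integer seed.
#' @return `list(train =, val =, test =)` id vectors.
#' @export
split_dataset <- function(image_ids, fractions = c(0.6, 0.2, 0.2), seed = 42L) {
  n <- length(image_ids)
  if (n < 3L) stop("need at least 3 images to split", call. = FALSE)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be 3 positive numbers summing to 1", call. = FALSE)
  }
  perm <- with_preserved_rng(seed, sample(n))
  n_tr <- round(fractions[1L] * n)
  n_va <- round(fractions[2L] * n)
  n_te <- n - n_tr - n_va
  if (n_te < 0L) { n_va <- n_va + n_te; n_te <- 0L }
  list(train = image_ids[perm[seq_len(n_tr)]],
       val = image_ids[perm[n_tr + seq_len(n_va)]],
       test = image_ids[perm[n_tr + n_va + seq_len(n_te)]])
}

# evaluate `expr` under `seed` without disturbing the caller's RNG
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# rasterize the training target for one sample under a config
make_target <- function(annotations, config) {
  if (config$target_scheme == "binary") {
    make_binary_mask(annotations, radius_mm = config$radius_mm)$raster
  } else {
    suppressWarnings(
      make_gaussian_mask(annotations, sigma_mm = config$sigma_mm,
                         normalize = TRUE)$raster)
  }
}

check_sample <- function(s, i) {
  if (is.null(s$image) || length(dim(s$image)) != 3L) {
    stop(sprintf("sample %d: `image` must be an H x W x 3 array", i), call. = FALSE)
  }
  if (!inherits(s$annotations, "point_annotation_set")) {
    stop(sprintf("sample %d: `annotations` must be a point_annotation_set", i),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Train the segmentation network
#'
#' Runs the full training loop: per-epoch shuffling, augmentation,
#' forward/backward through the built-in encoder-decoder, Adam updates,
#' and per-epoch validation (loss, and detection F1 obtained by
#' decoding validation predictions with [extract_centers()] and scoring
#' them with [match_centers()] at `eval_radius_mm`). The returned model
#' carries the parameters of the epoch with the best validation F1.
#'
#' @param dataset `list(train =, val =)`, each a list of samples; a
#'   sample is `list(image = H x W x 3 array in [0,1], annotations =
#'   point_annotation_set, target = optional raster)`. Missing targets
#'   are rasterized from the annotations per the config scheme.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `spikelet_model`: list with `params`
#'   (best-epoch weights), `config`, `history` (data frame epoch /
#'   train_loss / val_loss / val_f1), `best_epoch`.
#' @export
train_segmentation_model <- function(dataset, config, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  train <- dataset$train; val <- dataset$val
  if (length(train) == 0L || length(val) == 0L) {
    stop("both the train and validation subsets must be non-empty", call. = FALSE)
  }
  for (i in seq_along(train)) check_sample(train[[i]], i)
  for (i in seq_along(val)) check_sample(val[[i]], i)

  set.seed(config$seed)
  params <- unet_init(config$encoder_name)
  opt <- adam_init(params)
  aug <- build_augmentation_pipeline(config$augmentation)
  h <- config$augmentation$resize_to[1L]
  w <- config$augmentation$resize_to[2L]
  gaussian <- config$target_scheme == "gaussian"

  # pre-rasterize targets at original geometry
  tgt <- lapply(train, function(s) {
    if (!is.null(s$target)) s$target else make_target(s$annotations, config)
  })
  # validation tensors at training geometry (no augmentation)
  val_x <- lapply(val, function(s) image_to_features(resize_image(s$image, h, w)))
  val_t <- lapply(val, function(s) {
    t0 <- if (!is.null(s$target)) s$target else make_target(s$annotations, config)
    if (gaussian) {
      t1 <- resize_bilinear(t0, h, w)
      t1 / sum(t1)
    } else {
      resize_nearest(t0, h, w)
    }
  })

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_f1 = numeric(0))
  best_f1 <- -Inf; best_params <- params; best_epoch <- 0L
  n_tr <- length(train)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n_tr)
    ep_loss <- 0
    acc <- NULL; acc_n <- 0L
    for (ii in seq_along(ord)) {
      s <- train[[ord[ii]]]
      a <- aug(s$image, tgt[[ord[ii]]], s$annotations$points)
      t <- a$target
      if (gaussian) {
        ssum <- sum(t)
        t <- if (ssum > 0) t / ssum else matrix(1 / (h * w), h, w)
      }
      x <- image_to_features(a$image)
      fw <- unet_forward(params, x, h, w, keep = TRUE)
      z <- fw$logits
      if (gaussian) {
        lss <- loss_kldiv(log_softmax(z), as.numeric(t))
        dz <- grad_kldiv_logits(z, t)
      } else {
        lss <- loss_bce(z, as.numeric(t))
        dz <- grad_bce(z, t)
      }
      if (!is.finite(lss)) {
        stop(sprintf("training diverged: non-finite loss at epoch %d (image '%s')",
                     epoch, s$annotations$image_id), call. = FALSE)
      }
      ep_loss <- ep_loss + lss
      g <- unet_backward(params, fw$cache, dz)
      if (is.null(acc)) acc <- g
      else for (k in names(acc)) acc[[k]] <- acc[[k]] + g[[k]]
      acc_n <- acc_n + 1L
      if (acc_n == config$batch_size || ii == length(ord)) {
        for (k in names(acc)) acc[[k]] <- acc[[k]] / acc_n
        upd <- adam_step(params, acc, opt, lr = config$lr, betas = config$betas)
        params <- upd$params; opt <- upd$state
        acc <- NULL; acc_n <- 0L
      }
    }
    ep_loss <- ep_loss / n_tr

    # validation loss + detection F1
    vl <- 0; tp <- 0L; fp <- 0L; fn <- 0L
    for (j in seq_along(val)) {
      z <- unet_forward(params, val_x[[j]], h, w)$logits
      vl <- vl + if (gaussian) loss_kldiv(log_softmax(z), as.numeric(val_t[[j]]))
                 else loss_bce(z, as.numeric(val_t[[j]]))
      map <- decode_map(z, h, w, val[[j]]$annotations$image_size, gaussian)
      ctr <- extract_centers(map, scheme = config$target_scheme,
                             params = config$extraction,
                             scale = val[[j]]$annotations$scale)
      mr <- match_centers(ctr, val[[j]]$annotations$points,
                          radius_mm = config$eval_radius_mm,
                          scale = val[[j]]$annotations$scale)
      tp <- tp + nrow(mr$tp_pairs); fp <- fp + length(mr$fp); fn <- fn + length(mr$fn)
    }
    vl <- vl / length(val)
    vf1 <- f1_from_counts(tp, fp, fn)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = vl, val_f1 = vf1))
    if (vf1 > best_f1) {
      best_f1 <- vf1; best_params <- params; best_epoch <- epoch
    }
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  val F1 %.4f",
                      epoch, ep_loss, vl, vf1))
    }
  }

  structure(list(params = best_params, config = config, history = history,
                 best_epoch = best_epoch, schema_version = 1L),
            class = "spikelet_model")
}

# logits at training geometry -> probability/density map at the
# original image geometry
decode_map <- function(z, h, w, orig_size, gaussian) {
  if (gaussian) {
    m <- matrix(exp(log_softmax(z)), h, w)
    m <- resize_bilinear(m, orig_size[1L], orig_size[2L])
    m / sum(m)
  } else {
    m <- matrix(stats::plogis(z), h, w)
    resize_bilinear(m, orig_size[1L], orig_size[2L])
  }
}

#' Predict a per-pixel map for one image
#'
#' The image is resized to the training geometry, pushed through the
#' network, and the predicted map is resampled back to the original
#' image size so that extracted centers live in original pixel
#' coordinates. Binary-scheme maps hold per-pixel probabilities in
#' \[0,1\]; Gaussian-scheme maps are non-negative and sum to 1.
#'
#' @param model A `spikelet_model`.
#' @param image H x W x 3 array in \[0,1\].
#' @return H x W numeric matrix.
#' @export
predict_mask <- function(model, image) {
  stopifnot(inherits(model, "spikelet_model"))
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("`image` must be an H x W x 3 array", call. = FALSE)
  }
  h <- model$config$augmentation$resize_to[1L]
  w <- model$config$augmentation$resize_to[2L]
  x <- image_to_features(resize_image(image, h, w))
  z <- unet_forward(model$params, x, h, w)$logits
  decode_map(z, h, w, dim(image)[1:2], model$config$target_scheme == "gaussian")
}

#' @export
print.spikelet_model <- function(x, ...) {
  cat(sprintf("<spikelet_model> %s/%s encoder '%s'; %d epoch(s), best epoch %d (val F1 %.4f)\n",
              x$config$target_scheme, x$config$loss, x$config$encoder_name,
              nrow(x$history), x$best_epoch,
              if (x$best_epoch > 0) x$history$val_f1[x$best_epoch] else NA_real_))
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' A single-file archive embedding the parameters, the resolved
#' configuration, the training history and a schema version.
#'
#' @param model A `spikelet_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "spikelet_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("unrecognized checkpoint schema", call. = FALSE)
  }
  class(obj$config) <- "train_config"
  class(obj$config$augmentation) <- "augmentation_spec"
  class(obj$config$extraction) <- "extraction_params"
  structure(obj, class = "spikelet_model")
}

#' Write the per-epoch training log as CSV
#'
#' @param model A `spikelet_model`.
#' @param path Output CSV path (columns epoch, train_loss, val_loss,
#'   val_f1).
#' @return Invisibly, `path`.
#' @export
write_training_log <- function(model, path) {
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
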