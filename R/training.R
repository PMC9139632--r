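# Balanced patch pool construction, on-the-fly augmentation, and the
# optimisation loop (Adam, L2 regularisation, plateau-halving LR schedule).

#' Training configuration
#'
#' Defaults follow the reference protocol: initial learning rate 1e-4,
#' halved (factor 0.5) when the validation metric stops improving for more
#' than 2 epochs, at most 30 epochs, batch size 256, Adam with L2
#' regularisation beta = 1e-5, dice + binary cross-entropy loss.
#'
#' @param initial_lr initial learning rate.
#' @param lr_factor multiplicative LR reduction on plateau.
#' @param lr_patience epochs without improvement tolerated before reducing.
#' @param max_epochs maximum number of epochs.
#' @param batch_size patches per optimisation step.
#' @param l2_beta L2 regularisation strength.
#' @param loss `"dice_bce"`, `"bce"` or `"dice"`.
#' @param augment_prob probability of each augmentation (flips, rotation,
#'   blur) per patch per epoch.
#' @param rotation_deg maximum rotation magnitude in degrees.
#' @param gamma_range range of the random gamma augmentation.
#' @param seed integer seed governing shuffling and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(initial_lr = 1e-4, lr_factor = 0.5,
                         lr_patience = 2L, max_epochs = 30L,
                         batch_size = 256L, l2_beta = 1e-5,
                         loss = c("dice_bce", "bce", "dice"),
                         augment_prob = 0.5, rotation_deg = 15,
                         gamma_range = c(0.8, 1.25), seed = 1L) {
  loss <- match.arg(loss)
  if (initial_lr <= 0 || lr_factor <= 0 || batch_size < 1L)
    stop("train_config: rates and sizes must be positive")
  if (lr_patience >= max_epochs)
    stop("train_config: lr_patience must be smaller than max_epochs")
  structure(list(initial_lr = initial_lr, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), l2_beta = l2_beta,
                 loss = loss, augment_prob = augment_prob,
                 rotation_deg = rotation_deg, gamma_range = gamma_range,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---------------------------------------------------------------------------
# Balanced pool
# ---------------------------------------------------------------------------

#' Build a class-balanced patch pool
#'
#' Healthy patches vastly outnumber tumor patches, so the healthy class is
#' undersampled (uniformly, without replacement) down to the per-class
#' target, while the tumor class is resampled with replacement up to the
#' same size when undersupplied (augmentation diversifies the repeats). The
#' final per-class size is `min(per_class_target, number of healthy
#' patches)`. Selection is deterministic given `seed`.
#'
#' Methods exist for a list of [extract_stack()] patch stacks, for a
#' [index_patches()] index (nothing is materialised; use
#' [materialize_pool()] before training), and for a plain data frame with a
#' logical `tumor` column (a class-only stub, useful for bookkeeping tests).
#'
#' @param patches the patch source (list, `patch_index`, or data.frame).
#' @param per_class_target target patches per class (default 30000).
#' @param seed integer seed.
#' @return A `balanced_pool` with elements `healthy` and `tumor` (indices or
#'   stacks, per method), `per_class_target`, `seed`.
#' @export
balance_pool <- function(patches, per_class_target = 30000L, seed = 1L) {
  UseMethod("balance_pool")
}

balance_indices <- function(is_tumor, per_class_target, seed) {
  n_t <- sum(is_tumor)
  n_h <- sum(!is_tumor)
  if (n_t == 0L)
    stop("balance_pool: no tumor patches in the pool (untrainable)")
  if (n_h == 0L)
    stop("balance_pool: no healthy patches in the pool")
  n_per <- min(per_class_target, n_h)
  hi <- which(!is_tumor)
  ti <- which(is_tumor)
  with_seed(seed, {
    h_sel <- if (n_h > n_per) sample(hi, n_per) else hi
    t_sel <- if (n_t >= n_per) {
      if (n_t > n_per) sample(ti, n_per) else ti
    } else {
      sample(ti, n_per, replace = TRUE)
    }
    list(healthy = h_sel, tumor = t_sel)
  })
}

#' @export
balance_pool.list <- function(patches, per_class_target = 30000L, seed = 1L) {
  cls <- vapply(patches, patch_class, "")
  sel <- balance_indices(cls == "tumor", per_class_target, seed)
  structure(list(healthy = patches[sel$healthy], tumor = patches[sel$tumor],
                 per_class_target = as.integer(per_class_target),
                 seed = as.integer(seed)),
            class = "balanced_pool")
}

#' @export
balance_pool.data.frame <- function(patches, per_class_target = 30000L,
                                    seed = 1L) {
  if (is.null(patches$tumor))
    stop("balance_pool: data frame must have a `tumor` column")
  sel <- balance_indices(as.logical(patches$tumor), per_class_target, seed)
  structure(list(healthy = patches[sel$healthy, , drop = FALSE],
                 tumor = patches[sel$tumor, , drop = FALSE],
                 per_class_target = as.integer(per_class_target),
                 seed = as.integer(seed)),
            class = "balanced_pool")
}

#' @export
balance_pool.patch_index <- function(patches, per_class_target = 30000L,
                                     seed = 1L) {
  sel <- balance_indices(patches$table$tumor, per_class_target, seed)
  structure(list(healthy = patches$table[sel$healthy, , drop = FALSE],
                 tumor = patches$table[sel$tumor, , drop = FALSE],
                 per_class_target = as.integer(per_class_target),
                 seed = as.integer(seed), index = patches),
            class = c("balanced_pool_index", "balanced_pool"))
}

#' Combine patch indices from several volumes
#'
#' @param indices list of `patch_index` objects (one per phantom/patient).
#' @return a `patch_index_set` usable with [balance_pool()].
#' @export
combine_indices <- function(indices) {
  tabs <- lapply(seq_along(indices), function(i) {
    tb <- indices[[i]]$table
    tb$case <- i
    tb
  })
  structure(list(table = do.call(rbind, tabs), indices = indices),
            class = c("patch_index", "patch_index_set"))
}

#' @export
balance_pool.patch_index_set <- balance_pool.patch_index

#' Materialise a balanced pool of index rows into patch stacks
#'
#' @param pool a `balanced_pool` built from a patch index.
#' @return a `balanced_pool` holding actual `patch_stack` objects.
#' @export
materialize_pool <- function(pool) {
  stopifnot(inherits(pool, "balanced_pool_index"))
  idx <- pool$index
  fetch <- function(tb) {
    lapply(seq_len(nrow(tb)), function(i) {
      if (!is.null(tb$case)) {
        src <- idx$indices[[tb$case[i]]]
      } else src <- idx
      extract_stack(src$image, src$gt, tb$z[i], tb$row[i], tb$col[i],
                    src$patch_size, src$context)
    })
  }
  structure(list(healthy = fetch(pool$healthy), tumor = fetch(pool$tumor),
                 per_class_target = pool$per_class_target, seed = pool$seed),
            class = "balanced_pool")
}

# ---------------------------------------------------------------------------
# Augmentation
# ---------------------------------------------------------------------------

#' Randomly augment a patch stack
#'
#' Independently applies, each with probability `prob`: horizontal flip,
#' vertical flip, rotation (uniform in `±rotation_deg`, bilinear for the
#' image channels, nearest-neighbour for the label so it stays binary),
#' Gaussian blur (image channels only), and gamma correction (image
#' channels only). The same spatial transform is applied to all channels
#' and the label crop, so the patch class is preserved. Uses the current
#' RNG stream; wrap in a seeded context for reproducibility.
#'
#' @param p a `patch_stack`.
#' @param prob per-augmentation probability (0 disables everything).
#' @param rotation_deg maximum rotation magnitude in degrees.
#' @param blur_sigma_range Gaussian blur sigma range in pixels.
#' @param gamma_range gamma correction exponent range.
#' @return the augmented `patch_stack`.
#' @export
augment <- function(p, prob = 0.5, rotation_deg = 15,
                    blur_sigma_range = c(0.5, 1.5),
                    gamma_range = c(0.8, 1.25)) {
  stopifnot(inherits(p, "patch_stack"))
  if (prob <= 0) return(p)
  dat <- p$data
  lab <- p$label_crop
  nc <- dim(dat)[3]
  if (stats::runif(1) < prob) {            # horizontal flip (cols)
    dat <- dat[, rev(seq_len(dim(dat)[2])), , drop = FALSE]
    if (!is.null(lab)) lab <- lab[, rev(seq_len(ncol(lab)))]
  }
  if (stats::runif(1) < prob) {            # vertical flip (rows)
    dat <- dat[rev(seq_len(dim(dat)[1])), , , drop = FALSE]
    if (!is.null(lab)) lab <- lab[rev(seq_len(nrow(lab))), ]
  }
  if (stats::runif(1) < prob) {            # rotation about the patch centre
    ang <- stats::runif(1, -rotation_deg, rotation_deg)
    P <- dim(dat)[1]
    for (c in seq_len(nc))
      dat[, , c] <- ebimage_rotate(dat[, , c], ang, "bilinear")
    if (!is.null(lab)) {
      lab <- ebimage_rotate(lab, ang, "none")
      lab <- (lab > 0.5) * 1L
      dim(lab) <- c(P, P)
    }
  }
  if (stats::runif(1) < prob) {            # blur, image channels only
    sg <- stats::runif(1, blur_sigma_range[1], blur_sigma_range[2])
    for (c in seq_len(nc))
      dat[, , c] <- as.numeric(EBImage::gblur(dat[, , c], sigma = sg)) |>
        array(dim(dat)[1:2])
  }
  if (stats::runif(1) < prob) {            # random gamma, image channels only
    g <- stats::runif(1, gamma_range[1], gamma_range[2])
    dat <- pmin(pmax(dat, 0), 1)^g
  }
  p$data <- dat
  p$label_crop <- lab
  p
}

ebimage_rotate <- function(m, angle, filter) {
  out <- EBImage::rotate(m, angle, filter = filter, output.dim = dim(m),
                         bg.col = 0)
  array(as.numeric(out), dim(m))
}

# ---------------------------------------------------------------------------
# Batch assembly and the training loop
# ---------------------------------------------------------------------------

# stack a list of patch_stacks into x (P x P x C x N) and y (P x P x 1 x N)
stacks_to_batch <- function(stacks) {
  P <- dim(stacks[[1]]$data)[1]
  C <- dim(stacks[[1]]$data)[3]
  N <- length(stacks)
  x <- array(0, c(P, P, C, N))
  y <- array(0, c(P, P, 1, N))
  for (i in seq_len(N)) {
    x[, , , i] <- stacks[[i]]$data
    if (!is.null(stacks[[i]]$label_crop))
      y[, , 1, i] <- stacks[[i]]$label_crop
  }
  list(x = x, y = y)
}

#' Train the U-Net on a balanced pool
#'
#' Optimises with Adam plus L2 regularisation, halving the learning rate
#' (factor `lr_factor`) when the validation loss has not improved for more
#' than `lr_patience` epochs, for at most `max_epochs` epochs. Patches are
#' shuffled and augmented on the fly each epoch. Fully reproducible given
#' `config$seed`.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param pool a materialised `balanced_pool`.
#' @param config a [train_config()].
#' @param validation list of held-out `patch_stack`s used for the plateau
#'   metric; if `NULL`, the training loss is monitored.
#' @param verbose print one line per epoch.
#' @return `list(model, history)`; `history` is a data.frame with one row
#'   per epoch: `epoch`, `lr`, `train_loss`, `val_loss`, `val_dice`.
#' @export
train_model <- function(model, pool, config = train_config(),
                        validation = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(pool, "balanced_pool"))
  if (inherits(pool, "balanced_pool_index"))
    pool <- materialize_pool(pool)
  stacks <- c(pool$healthy, pool$tumor)
  if (length(stacks) == 0L) stop("train_model: empty pool")
  vbatch <- if (!is.null(validation) && length(validation))
    stacks_to_batch(validation) else NULL

  state <- adam_init(model$params)
  sched <- lr_plateau_init(config$initial_lr, config$lr_factor,
                           config$lr_patience)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_loss = numeric(),
                     val_dice = numeric())
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(length(stacks))
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        aug <- lapply(stacks[ids], augment, prob = config$augment_prob,
                      rotation_deg = config$rotation_deg,
                      gamma_range = config$gamma_range)
        b <- stacks_to_batch(aug)
        fw <- unet_forward(model, b$x, training = TRUE)
        model <- fw$model
        ls <- unet_loss(fw$prob, b$y, config$loss)
        if (!is.finite(ls$loss))
          stop("train_model: non-finite loss at epoch ", epoch)
        grads <- unet_backward(model, fw$cache, ls$glogit)
        upd <- adam_step(model$params, grads, state, sched$lr,
                         config$l2_beta)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + ls$loss
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      if (!is.null(vbatch)) {
        vf <- unet_forward(model, vbatch$x, training = FALSE)
        vl <- unet_loss(vf$prob, vbatch$y, config$loss)$loss
        vd <- soft_dice(vf$prob, vbatch$y)
      } else {
        vl <- ep_loss
        vd <- NA_real_
      }
      hist <- rbind(hist, data.frame(epoch = epoch, lr = sched$lr,
                                     train_loss = ep_loss, val_loss = vl,
                                     val_dice = vd))
      if (verbose)
        message(sprintf("epoch %2d  lr %.2e  train %.4f  val %.4f  dice %.3f",
                        epoch, sched$lr, ep_loss, vl, vd))
      sched <- lr_plateau_step(sched, vl)
    }
  })
  list(model = model, history = hist)
}

#' Simulate the plateau LR schedule against a fixed metric trace
#'
#' Pure helper exposing the scheduler: feeds the per-epoch metric values to
#' the plateau rule and returns the learning rate in force at each epoch.
#'
#' @param metrics numeric vector of per-epoch monitored values.
#' @param initial_lr,factor,patience schedule parameters.
#' @return numeric vector, `lr[i]` = learning rate used during epoch `i`.
#' @export
lr_schedule <- function(metrics, initial_lr = 1e-4, factor = 0.5,
                        patience = 2L) {
  st <- lr_plateau_init(initial_lr, factor, patience)
  lr <- numeric(length(metrics))
  for (i in seq_along(metrics)) {
    lr[i] <- st$lr
    st <- lr_plateau_step(st, metrics[i])
  }
  lr
}

# ---------------------------------------------------------------------------
# Checkpoints
# ---------------------------------------------------------------------------

#' Save / load a trained model
#'
#' The weights go to an `.rds` file; a JSON sidecar (same path + `.json`)
#' records the architecture, seed and training configuration for
#' provenance.
#'
#' @param model a `unet_model`.
#' @param path checkpoint path (`.rds`).
#' @param config optional `train_config` recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, config = NULL) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  side <- list(spec = unclass(model$spec), seed = model$seed,
               config = if (!is.null(config)) unclass(config) else NULL,
               package_version = as.character(utils::packageVersion("bmseg")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "unet_model"))
    stop("load_model: '", path, "' is not a unet_model checkpoint")
  m
}
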