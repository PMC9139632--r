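# A 2D U-Net with a 5-slice input, built on the package's C++ kernels.
#
# Encoder level l: [conv3x3 -> BN -> ELU] x2 with base_filters * 2^(l-1)
# channels, then 2x2 max pooling. Decoder level l: 2x2 transposed
# convolution halving the channels, skip concatenation, then the same double
# conv block. Head: 1x1 convolution + sigmoid giving a per-pixel probability
# over the reference slice. Batch normalisation sits before the ELU.
#
# Feature maps are R arrays H x W x C x N. All parameters live in a flat
# named list so the Adam update is a single loop.

#' U-Net architecture specification
#'
#' @param in_channels input channels; 5 for the default 2.5D stack
#'   (2 context slices each side of the reference slice).
#' @param depth number of 2x2 poolings (default 4).
#' @param base_filters channels of the first encoder level (default 64).
#' @param patch_size input patch edge in pixels; must be divisible by
#'   `2^depth`.
#' @return A `unet_spec` list.
#' @export
unet_spec <- function(in_channels = 5L, depth = 4L, base_filters = 64L,
                      patch_size = 128L) {
  in_channels <- as.integer(in_channels)
  depth <- as.integer(depth)
  base_filters <- as.integer(base_filters)
  patch_size <- as.integer(patch_size)
  if (depth < 1L || base_filters < 1L || in_channels < 1L)
    stop("unet_spec: depth, base_filters and in_channels must be >= 1")
  if (patch_size %% (2^depth) != 0L)
    stop("unet_spec: patch_size (", patch_size,
         ") must be divisible by 2^depth (", 2^depth, ")")
  structure(list(in_channels = in_channels, depth = depth,
                 base_filters = base_filters, patch_size = patch_size),
            class = "unet_spec")
}

#' Build a trainable U-Net
#'
#' Weights use He-normal initialisation; batch-norm scales start at 1 and
#' shifts at 0. The returned model maps a batch of stacks (array
#' `P x P x in_channels x N`) to per-pixel probabilities in \[0, 1\].
#'
#' @param spec a [unet_spec()].
#' @param seed integer seed for the weight initialisation.
#' @return A `unet_model`.
#' @export
build_unet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  with_seed(seed, {
    params <- list()
    bn <- list()
    D <- spec$depth
    f <- function(l) spec$base_filters * 2L^(l - 1L)

    add_conv <- function(params, name, cin, cout) {
      sdv <- sqrt(2 / (9 * cin))
      params[[paste0(name, "_w")]] <-
        array(stats::rnorm(9 * cin * cout, 0, sdv), c(3, 3, cin, cout))
      params[[paste0(name, "_b")]] <- numeric(cout)
      params[[paste0(name, "_g")]] <- rep(1, cout)   # BN gamma
      params[[paste0(name, "_be")]] <- numeric(cout) # BN beta
      params
    }
    for (l in seq_len(D)) {
      cin <- if (l == 1L) spec$in_channels else f(l - 1L)
      params <- add_conv(params, paste0("enc", l, "_c1"), cin, f(l))
      params <- add_conv(params, paste0("enc", l, "_c2"), f(l), f(l))
    }
    params <- add_conv(params, "bott_c1", f(D), f(D + 1L))
    params <- add_conv(params, "bott_c2", f(D + 1L), f(D + 1L))
    for (l in rev(seq_len(D))) {
      cab <- f(l + 1L)
      sdv <- sqrt(2 / (4 * cab))
      params[[paste0("dec", l, "_up_w")]] <-
        array(stats::rnorm(4 * cab * f(l), 0, sdv), c(2, 2, cab, f(l)))
      params[[paste0("dec", l, "_up_b")]] <- numeric(f(l))
      params <- add_conv(params, paste0("dec", l, "_c1"), 2L * f(l), f(l))
      params <- add_conv(params, paste0("dec", l, "_c2"), f(l), f(l))
    }
    params$head_w <- matrix(stats::rnorm(f(1L), 0, sqrt(2 / f(1L))), ncol = 1)
    params$head_b <- 0

    for (nm in names(params)) {
      if (endsWith(nm, "_g")) {
        ch <- length(params[[nm]])
        base <- sub("_g$", "", nm)
        bn[[base]] <- list(mean = numeric(ch), var = rep(1, ch))
      }
    }
    structure(list(spec = spec, params = params, bn = bn, seed = seed),
              class = "unet_model")
  })
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<unet_model> depth %d, base %d, in %d ch, %d parameters\n",
              x$spec$depth, x$spec$base_filters, x$spec$in_channels, np))
  invisible(x)
}

# --- layer primitives -------------------------------------------------------

elu_fwd <- function(x) {
  y <- x
  neg <- x < 0
  y[neg] <- exp(x[neg]) - 1
  y
}
elu_bwd <- function(gy, y) {
  g <- gy
  neg <- y < 0
  g[neg] <- gy[neg] * (y[neg] + 1)
  g
}

bn_fwd <- function(x, gamma, beta, stats, training, eps = 1e-5,
                   momentum = 0.1) {
  d <- dim(x)
  C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)  # (H*W*N) x C
  if (training) {
    mu <- colMeans(xm)
    va <- pmax(colMeans(xm^2) - mu^2, 0)
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * va
  } else {
    mu <- stats$mean
    va <- stats$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, invstd, "*")
  ym <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d),
       stats = stats)
}

bn_bwd <- function(gy, cache, gamma) {
  d <- cache$dims
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  gym <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat
  ggamma <- colSums(gym * xhat)
  gbeta <- colSums(gym)
  t1 <- sweep(gym, 2, gbeta / m, "-")
  t2 <- sweep(xhat, 2, ggamma / m, "*")
  gxm <- sweep(t1 - t2, 2, gamma * cache$invstd, "*")
  gx <- aperm(array(gxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

conv_unit_fwd <- function(x, model, name, training) {
  p <- model$params
  z <- .cpp_conv2d_fwd(x, p[[paste0(name, "_w")]], p[[paste0(name, "_b")]])
  bn <- bn_fwd(z, p[[paste0(name, "_g")]], p[[paste0(name, "_be")]],
               model$bn[[name]], training)
  y <- elu_fwd(bn$y)
  list(y = y, stats = bn$stats,
       cache = list(x = x, bn = bn$cache, act = y))
}

conv_unit_bwd <- function(gy, cache, model, name, grads) {
  p <- model$params
  g1 <- elu_bwd(gy, cache$act)
  g2 <- bn_bwd(g1, cache$bn, p[[paste0(name, "_g")]])
  g3 <- .cpp_conv2d_bwd(cache$x, p[[paste0(name, "_w")]], g2$gx)
  grads[[paste0(name, "_w")]] <- g3$gw
  grads[[paste0(name, "_b")]] <- g3$gb
  grads[[paste0(name, "_g")]] <- g2$ggamma
  grads[[paste0(name, "_be")]] <- g2$gbeta
  list(gx = g3$gx, grads = grads)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# --- full network -----------------------------------------------------------

unet_forward <- function(model, x, training = FALSE) {
  D <- model$spec$depth
  cache <- list()
  h <- x
  for (l in seq_len(D)) {
    for (u in c("c1", "c2")) {
      nm <- paste0("enc", l, "_", u)
      r <- conv_unit_fwd(h, model, nm, training)
      model$bn[[nm]] <- r$stats
      cache[[nm]] <- r$cache
      h <- r$y
    }
    cache[[paste0("skip", l)]] <- h
    mp <- .cpp_maxpool2_fwd(h)
    cache[[paste0("pool", l)]] <- list(idx = mp$idx, H = dim(h)[1],
                                       W = dim(h)[2])
    h <- mp$y
  }
  for (u in c("c1", "c2")) {
    nm <- paste0("bott_", u)
    r <- conv_unit_fwd(h, model, nm, training)
    model$bn[[nm]] <- r$stats
    cache[[nm]] <- r$cache
    h <- r$y
  }
  for (l in rev(seq_len(D))) {
    upn <- paste0("dec", l, "_up")
    cache[[paste0(upn, "_x")]] <- h
    h <- .cpp_upconv2_fwd(h, model$params[[paste0(upn, "_w")]],
                          model$params[[paste0(upn, "_b")]])
    skip <- cache[[paste0("skip", l)]]
    cache[[paste0("cat", l)]] <- c(dim(h)[3], dim(skip)[3])
    h <- concat_ch(h, skip)
    for (u in c("c1", "c2")) {
      nm <- paste0("dec", l, "_", u)
      r <- conv_unit_fwd(h, model, nm, training)
      model$bn[[nm]] <- r$stats
      cache[[nm]] <- r$cache
      h <- r$y
    }
  }
  # 1x1 conv head + sigmoid
  d <- dim(h)
  hm <- matrix(aperm(h, c(1, 2, 4, 3)), ncol = d[3])
  logit <- hm %*% model$params$head_w + model$params$head_b
  prob <- 1 / (1 + exp(-logit))
  cache$head_x <- hm
  cache$head_dims <- d
  parr <- aperm(array(prob, c(d[1], d[2], d[4], 1)), c(1, 2, 4, 3))
  list(prob = parr, cache = cache, model = model)
}

unet_backward <- function(model, cache, glogit) {
  # glogit: H x W x 1 x N gradient of the loss w.r.t. the head logits
  D <- model$spec$depth
  grads <- list()
  d <- cache$head_dims
  gl <- matrix(aperm(glogit, c(1, 2, 4, 3)), ncol = 1)
  grads$head_w <- crossprod(cache$head_x, gl)
  grads$head_b <- sum(gl)
  ghm <- gl %*% t(model$params$head_w)
  gh <- aperm(array(ghm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))

  for (l in seq_len(D)) {
    for (u in c("c2", "c1")) {
      nm <- paste0("dec", l, "_", u)
      r <- conv_unit_bwd(gh, cache[[nm]], model, nm, grads)
      gh <- r$gx
      grads <- r$grads
    }
    sp <- cache[[paste0("cat", l)]]
    gup <- gh[, , seq_len(sp[1]), , drop = FALSE]
    gskip <- gh[, , sp[1] + seq_len(sp[2]), , drop = FALSE]
    upn <- paste0("dec", l, "_up")
    r <- .cpp_upconv2_bwd(cache[[paste0(upn, "_x")]],
                          model$params[[paste0(upn, "_w")]], gup)
    grads[[paste0(upn, "_w")]] <- r$gw
    grads[[paste0(upn, "_b")]] <- r$gb
    gh <- r$gx
    cache[[paste0("gskip", l)]] <- gskip
  }
  for (u in c("c2", "c1")) {
    nm <- paste0("bott_", u)
    r <- conv_unit_bwd(gh, cache[[nm]], model, nm, grads)
    gh <- r$gx
    grads <- r$grads
  }
  for (l in rev(seq_len(D))) {
    pl <- cache[[paste0("pool", l)]]
    gh <- .cpp_maxpool2_bwd(gh, pl$idx, pl$H, pl$W)
    gh <- gh + cache[[paste0("gskip", l)]]
    for (u in c("c2", "c1")) {
      nm <- paste0("enc", l, "_", u)
      r <- conv_unit_bwd(gh, cache[[nm]], model, nm, grads)
      gh <- r$gx
      grads <- r$grads
    }
  }
  grads
}

#' Run the network on a batch of stacks (inference mode)
#'
#' Uses the running batch-norm statistics accumulated during training.
#'
#' @param model a `unet_model`.
#' @param x array `P x P x in_channels x N` (a single `P x P x C` stack is
#'   promoted to a batch of one).
#' @return array `P x P x N` of per-pixel probabilities in \[0, 1\].
#' @export
unet_predict <- function(model, x) {
  stopifnot(inherits(model, "unet_model"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  r <- unet_forward(model, x, training = FALSE)
  d <- dim(r$prob)
  array(r$prob, c(d[1], d[2], d[4]))
}

# --- loss -------------------------------------------------------------------

# Per-batch loss and the gradient w.r.t. the head logits.
# "dice_bce": soft dice + binary cross-entropy, the default for extreme
# foreground imbalance; "bce" and "dice" are selectable.
unet_loss <- function(prob, target, kind = "dice_bce", eps = 1e-7,
                      smooth = 1) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  t <- target
  m <- length(p)
  g <- array(0, dim(prob))
  loss <- 0
  if (kind %in% c("bce", "dice_bce")) {
    loss <- loss - mean(t * log(p) + (1 - t) * log(1 - p))
    g <- g + (p - t) / m
  }
  if (kind %in% c("dice", "dice_bce")) {
    num <- 2 * sum(p * t) + smooth
    den <- sum(p) + sum(t) + smooth
    loss <- loss + (1 - num / den)
    gdice_dp <- -(2 * t / den - num / den^2)
    g <- g + gdice_dp * p * (1 - p)
  }
  list(loss = loss, glogit = g)
}

# soft dice of a probability map vs a binary target (no gradient)
soft_dice <- function(prob, target, smooth = 1) {
  (2 * sum(prob * target) + smooth) / (sum(prob) + sum(target) + smooth)
}

# --- Adam with decoupled L2 (weight decay on conv/upconv weights) -----------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, l2_beta = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (grepl("_w$", nm)) g <- g + l2_beta * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# --- plateau LR schedule ----------------------------------------------------

# Halve the learning rate when the monitored metric has not improved for
# more than `patience` epochs (lower is better). Returns the updated state.
lr_plateau_step <- function(state, metric) {
  if (metric < state$best - state$eps) {
    state$best <- metric
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (state$bad > state$patience) {
      state$lr <- state$lr * state$factor
      state$bad <- 0L
    }
  }
  state
}

lr_plateau_init <- function(lr, factor = 0.5, patience = 2L, eps = 1e-8) {
  list(lr = lr, factor = factor, patience = as.integer(patience),
       best = Inf, bad = 0L, eps = eps)
}

# run RNG-dependent code reproducibly without disturbing the global stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}
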