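# Shared fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately avoid the package's own kernels: flood-fill labelling,
# all-pairs distances, and offset-enumeration dilation.

lv <- function(arr, spacing = c(1, 1, 1)) label_volume(arr, spacing)

random_mask <- function(dims, p = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(as.integer(stats::runif(prod(dims)) < p), dims)
}

# flood-fill 26-connectivity labelling, queue-based, pure R
bf_label3d <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(m == 1L & lab == 0L)) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      co <- arrayInd(v, d)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (!dz && !dy && !dx) next
        n <- co + c(dz, dy, dx)
        if (any(n < 1) || any(n > d)) next
        u <- n[1] + d[1] * ((n[2] - 1) + d[2] * (n[3] - 1))
        if (m[u] == 1L && lab[u] == 0L) {
          lab[u] <- nxt
          queue <- c(queue, u)
        }
      }
    }
  }
  lab
}

# all-pairs directed distances: for each foreground voxel of `qry`, minimum
# physical distance to the foreground of `ref`
bf_directed_dists <- function(ref, qry, spacing) {
  rf <- arrayInd(which(ref == 1L), dim(ref))
  qf <- arrayInd(which(qry == 1L), dim(qry))
  vapply(seq_len(nrow(qf)), function(k) {
    dd <- sweep(rf, 2, qf[k, ], "-")
    dd <- sweep(dd, 2, spacing, "*")
    sqrt(min(rowSums(dd^2)))
  }, 1.0)
}

# dilation by enumerating all integer offsets within the physical radius
bf_dilate <- function(m, radius_mm, spacing) {
  d <- dim(m)
  rng <- floor(radius_mm / spacing)
  offs <- as.matrix(expand.grid(dz = -rng[1]:rng[1], dy = -rng[2]:rng[2],
                                dx = -rng[3]:rng[3]))
  keep <- sqrt(colSums((t(offs) * spacing)^2)) <= radius_mm + 1e-12
  offs <- offs[keep, , drop = FALSE]
  out <- array(0L, d)
  fg <- arrayInd(which(m == 1L), d)
  for (k in seq_len(nrow(fg))) {
    pts <- sweep(offs, 2, fg[k, ], "+")
    ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 &
      pts[, 2] <= d[2] & pts[, 3] >= 1 & pts[, 3] <= d[3]
    pts <- pts[ok, , drop = FALSE]
    out[pts] <- 1L
  }
  out
}

# brute-force enumeration of patch windows: all 0-based offsets o with
# o + patch <= extent at multiples of stride, plus the flush-border offset
bf_axis_offsets <- function(extent, patch, stride) {
  offs <- integer()
  o <- 0L
  while (o + patch <= extent) {
    offs <- c(offs, o)
    o <- o + stride
  }
  union(offs, extent - patch)
}

# a tiny, quick phantom for unit tests
tiny_phantom <- function(seed = 7, n_lesions = 3, shape = c(12, 64, 64),
                         spacing = c(1, 1.5, 1.5), ...) {
  generate_phantom(phantom_spec(shape = shape, spacing = spacing,
                                n_lesions = n_lesions, n_vessels = 1,
                                noise_sigma = 0.02, seed = seed, ...))
}

# the desk-scale study profile used by the end-to-end recovery checks
e2e_phantom_spec <- function(seed) {
  phantom_spec(shape = c(40, 256, 256), spacing = c(1, 0.78, 0.78),
               n_lesions = 8, lesion_volume_range_cc = c(0.01, 0.8),
               lesion_contrast = 2.0, n_vessels = 3, bias_amplitude = 0.15,
               noise_sigma = 0.03, seed = seed)
}

e2e_preprocess <- function(ph) scale_intensity(correct_bias_field(ph$image))
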