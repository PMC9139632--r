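# Intensity normalisation chain applied before patching:
# bias-field correction -> percentile intensity scaling -> gamma correction.

#' Correct a multiplicative bias field
#'
#' MR intensities carry a smooth multiplicative inhomogeneity ("bias") field.
#' Mode `"polynomial"` (the default, self-contained path) fits a low-order
#' polynomial in normalised spatial coordinates to the log-intensities of
#' head voxels, exponentiates the fit into a strictly positive field with
#' unit geometric mean, and divides it out. Mode `"n4"` delegates to the N4
#' algorithm in SimpleITK through the system `python` interpreter, writing
#' and reading temporary NIfTI files; it requires `python` with SimpleITK on
#' the PATH.
#'
#' @param v `image_volume` with non-negative intensities.
#' @param mode `"polynomial"` or `"n4"`.
#' @param degree polynomial degree for `"polynomial"` mode (default 2).
#' @param return_field if `TRUE`, return `list(corrected, field)`.
#' @return Corrected `image_volume` (or a list when `return_field = TRUE`).
#' @export
correct_bias_field <- function(v, mode = c("polynomial", "n4"), degree = 2L,
                               return_field = FALSE) {
  stopifnot(inherits(v, "image_volume"))
  mode <- match.arg(mode)
  x <- v$data
  if (min(x) < 0)
    stop("correct_bias_field: intensities must be non-negative")
  if (max(x) == 0)
    stop("correct_bias_field: all-zero volume (degenerate input)")

  if (mode == "n4") {
    out <- n4_via_simpleitk(v)
    if (return_field) {
      fld <- v$data / pmax(out$data, .Machine$double.eps)
      return(list(corrected = out,
                  field = image_volume(fld, v$spacing, v$origin)))
    }
    return(out)
  }

  # head mask: voxels clearly above the air background (a fixed fraction of
  # the near-maximum intensity separates head tissue from air reliably)
  nz <- x[x > 0]
  thr <- 0.25 * stats::quantile(nz, 0.99, names = FALSE)
  mask <- which(x > thr)
  if (length(mask) < 50L)
    stop("correct_bias_field: too few foreground voxels to fit a field")
  # fit on the dominant tissue class only (intensities near the head
  # median): bright anatomy such as the scalp rim or enhancing lesions
  # would otherwise masquerade as bias
  med <- stats::median(x[mask])
  tissue <- mask[x[mask] > 0.6 * med & x[mask] < 1.4 * med]
  if (length(tissue) >= 50L) mask <- tissue

  d <- dim(x)
  idx <- arrayInd(mask, d)
  # normalised coordinates in [-1, 1]
  co <- sweep(sweep(idx - 1, 2, pmax(d - 1, 1) / 2, "/"), 2, 1, "-")
  # subsample for the fit; field is evaluated everywhere afterwards
  if (length(mask) > 50000L) {
    keep <- as.integer(seq(1L, length(mask), length.out = 50000L))
    fit_co <- co[keep, , drop = FALSE]
    fit_y <- log(x[mask[keep]])
  } else {
    fit_co <- co
    fit_y <- log(x[mask])
  }

  B <- poly_basis(fit_co, degree)
  beta <- qr.coef(qr(B), fit_y)
  beta[is.na(beta)] <- 0

  # evaluate log-field on the full grid, slice by slice to bound memory
  logf <- array(0, dim = d)
  zc <- (seq_len(d[1]) - 1) / max(d[1] - 1, 1) * 2 - 1
  yc <- (seq_len(d[2]) - 1) / max(d[2] - 1, 1) * 2 - 1
  xc <- (seq_len(d[3]) - 1) / max(d[3] - 1, 1) * 2 - 1
  grid_yx <- cbind(rep(yc, times = d[3]), rep(xc, each = d[2]))
  for (z in seq_len(d[1])) {
    co_z <- cbind(zc[z], grid_yx)
    logf[z, , ] <- poly_basis(co_z, degree) %*% beta
  }
  logf <- logf - mean(logf[mask])      # unit geometric mean over the head
  fld <- exp(logf)
  corrected <- image_volume(x / fld, v$spacing, v$origin)
  if (return_field)
    list(corrected = corrected, field = image_volume(fld, v$spacing, v$origin))
  else corrected
}

# full polynomial basis in 3 variables up to `degree`
poly_basis <- function(co, degree) {
  pows <- expand.grid(i = 0:degree, j = 0:degree, k = 0:degree)
  pows <- pows[rowSums(pows) <= degree, , drop = FALSE]
  B <- matrix(1, nrow(co), nrow(pows))
  for (t in seq_len(nrow(pows))) {
    B[, t] <- co[, 1]^pows$i[t] * co[, 2]^pows$j[t] * co[, 3]^pows$k[t]
  }
  B
}

n4_via_simpleitk <- function(v) {
  py <- Sys.which("python")
  if (!nzchar(py))
    stop("correct_bias_field(mode = 'n4') needs `python` with SimpleITK on the PATH")
  tin <- tempfile(fileext = ".nii.gz")
  tout <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  write_volume(v, tin)
  code <- paste(
    "import SimpleITK as sitk, sys",
    "img = sitk.ReadImage(sys.argv[1], sitk.sitkFloat32)",
    "out = sitk.N4BiasFieldCorrection(img)",
    "sitk.WriteImage(out, sys.argv[2])",
    sep = "; ")
  status <- system2(py, c("-c", shQuote(code), shQuote(tin), shQuote(tout)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(tout))
    stop("correct_bias_field: the SimpleITK N4 call failed (status ", status, ")")
  out <- read_volume(tout)
  out$spacing <- v$spacing
  out$origin <- v$origin
  out
}

#' Percentile intensity scaling to the unit interval
#'
#' Clips intensities at the lower/upper percentiles of the nonzero voxels
#' (so background air does not dominate the histogram) and affinely maps the
#' clipped range to \[0, 1\]. The defaults clip at the 0.5th and 99.5th
#' percentiles, discarding only extreme tails.
#'
#' @param v `image_volume`.
#' @param lower_pct,upper_pct percentile bounds, `0 <= lower < upper <= 100`.
#' @return `image_volume` with values in \[0, 1\].
#' @export
scale_intensity <- function(v, lower_pct = 0.5, upper_pct = 99.5) {
  stopifnot(inherits(v, "image_volume"))
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100))
    stop("scale_intensity: need 0 <= lower_pct < upper_pct <= 100")
  x <- v$data
  nz <- x[x != 0]
  if (length(nz) == 0L) nz <- x
  qs <- stats::quantile(nz, c(lower_pct, upper_pct) / 100, names = FALSE)
  # the extreme percentiles anchor at the true volume extrema, so (0, 100)
  # scaling of a volume already spanning [0, 1] is the exact identity
  if (lower_pct == 0) qs[1] <- min(x)
  if (upper_pct == 100) qs[2] <- max(x)
  if (qs[2] <= qs[1]) {
    warning("scale_intensity: degenerate intensity range; returning zeros")
    return(image_volume(array(0, dim(x)), v$spacing, v$origin))
  }
  x <- (pmin(pmax(x, qs[1]), qs[2]) - qs[1]) / (qs[2] - qs[1])
  image_volume(x, v$spacing, v$origin)
}

#' Gamma correction
#'
#' Voxelwise power transform `x^gamma` on intensities already scaled to
#' \[0, 1\]. Used as a random augmentation during training and as the
#' identity (`gamma = 1`) at inference.
#'
#' @param v `image_volume` with values in \[0, 1\].
#' @param gamma positive exponent.
#' @return `image_volume`.
#' @export
apply_gamma <- function(v, gamma) {
  stopifnot(inherits(v, "image_volume"))
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("apply_gamma: `gamma` must be a positive scalar")
  rng <- range(v$data)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("apply_gamma: intensities must be in [0, 1]; run scale_intensity first")
  image_volume(pmin(pmax(v$data, 0), 1)^gamma, v$spacing, v$origin)
}
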