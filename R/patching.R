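# The 2.5D overlapping-patch engine: grid planning, 5-slice stack
# extraction, patch labelling, and probability-averaged reconstruction.
#
# Windows are half-open and 0-based: a patch at (row, col) covers rows
# [row, row + patch_size) and likewise for columns.

#' Plan an overlapping patch grid for one slice
#'
#' Offsets start at 0 and advance by `stride`; when `extent - patch_size` is
#' not a multiple of the stride, a final flush offset at
#' `extent - patch_size` is appended so every pixel is covered. With the
#' reference settings (1024-pixel axis, 128-pixel patch, 64-pixel stride)
#' each axis has 15 offsets, i.e. 225 patches per slice.
#'
#' @param rows,cols slice extent in pixels.
#' @param patch_size patch edge in pixels (default 128).
#' @param stride sliding interval in pixels (default 64).
#' @return A `patch_grid`: list with `patch_size`, `stride`, `row_offsets`,
#'   `col_offsets` (0-based, sorted).
#' @export
plan_grid <- function(rows, cols, patch_size = 128L, stride = 64L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (patch_size > min(rows, cols))
    stop("plan_grid: patch_size exceeds the slice extent")
  if (stride <= 0L || stride > patch_size)
    stop("plan_grid: need 0 < stride <= patch_size")
  structure(
    list(patch_size = patch_size, stride = stride,
         row_offsets = axis_offsets(rows, patch_size, stride),
         col_offsets = axis_offsets(cols, patch_size, stride)),
    class = "patch_grid"
  )
}

axis_offsets <- function(extent, patch, stride) {
  offs <- seq.int(0L, extent - patch, by = stride)
  if (offs[length(offs)] != extent - patch)
    offs <- c(offs, extent - patch)
  as.integer(offs)
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d x %d patches of %d px at stride %d\n",
              length(x$row_offsets), length(x$col_offsets),
              x$patch_size, x$stride))
  invisible(x)
}

#' Extract one 2.5D patch stack
#'
#' Crops the window at `(row, col)` from the five consecutive axial slices
#' `z - 2 ... z + 2` (more generally `context` slices each side) into the
#' input channels; slices beyond the volume boundary are replaced by edge
#' replication. The label crop is taken from the reference slice `z` of the
#' ground truth only, because the network's target is the reference slice.
#'
#' @param image `image_volume`.
#' @param gt optional aligned `label_volume`; when supplied, `label_crop`
#'   and the patch class are filled in.
#' @param z 0-based reference slice index.
#' @param row,col 0-based top-left window coordinates.
#' @param patch_size window edge in pixels.
#' @param context slices of context each side of the reference (default 2,
#'   i.e. 5 channels).
#' @return A `patch_stack`: list with `data` (patch_size x patch_size x
#'   channels), `reference_slice`, `row`, `col`, `label_crop` (or NULL).
#' @export
extract_stack <- function(image, gt = NULL, z, row, col, patch_size = 128L,
                          context = 2L) {
  stopifnot(inherits(image, "image_volume"))
  d <- dim(image$data)
  patch_size <- as.integer(patch_size)
  if (z < 0 || z >= d[1] || row < 0 || col < 0 ||
      row + patch_size > d[2] || col + patch_size > d[3])
    stop("extract_stack: window (z=", z, ", row=", row, ", col=", col,
         ") falls outside the volume")
  zs <- pmin(pmax((z - context):(z + context), 0L), d[1] - 1L)
  ri <- (row + 1L):(row + patch_size)
  ci <- (col + 1L):(col + patch_size)
  dat <- aperm(image$data[zs + 1L, ri, ci, drop = FALSE], c(2, 3, 1))
  lab <- NULL
  if (!is.null(gt)) {
    check_same_grid(image, gt, "image and ground truth")
    lab <- gt$data[z + 1L, ri, ci]
  }
  structure(
    list(data = dat, reference_slice = as.integer(z),
         row = as.integer(row), col = as.integer(col), label_crop = lab),
    class = "patch_stack"
  )
}

#' Patch class: tumor iff the reference-slice label crop has any foreground
#' @param p a `patch_stack` with a label crop.
#' @return `"tumor"` or `"healthy"`.
#' @export
patch_class <- function(p) {
  stopifnot(inherits(p, "patch_stack"), !is.null(p$label_crop))
  if (any(p$label_crop > 0L)) "tumor" else "healthy"
}

#' Extract every patch stack of a volume
#'
#' One stack per (slice, row offset, col offset) triple; the count is
#' `slices * |row_offsets| * |col_offsets|`. Materialises all stacks in
#' memory — intended for small volumes; use [index_patches()] +
#' [balance_pool()] for training-scale data.
#'
#' @inheritParams extract_stack
#' @param grid a `patch_grid` from [plan_grid()].
#' @return list of `patch_stack`.
#' @export
extract_all <- function(image, gt = NULL, grid, context = 2L) {
  stopifnot(inherits(grid, "patch_grid"))
  d <- dim(image$data)
  if (!is.null(gt)) check_same_grid(image, gt, "image and ground truth")
  out <- vector("list",
                d[1] * length(grid$row_offsets) * length(grid$col_offsets))
  k <- 0L
  for (z in seq_len(d[1]) - 1L)
    for (row in grid$row_offsets)
      for (col in grid$col_offsets) {
        k <- k + 1L
        out[[k]] <- extract_stack(image, gt, z, row, col,
                                  grid$patch_size, context)
      }
  out
}

#' Tabulate all patch windows of a volume without materialising them
#'
#' Classifies every (z, row, col) window as tumor or healthy from the
#' ground-truth reference slice via 2D integral images, returning a compact
#' index used for balanced pool construction. The volumes are kept by
#' reference so selected stacks can be materialised on demand.
#'
#' @inheritParams extract_all
#' @return A `patch_index`: list with `table` (data.frame z, row, col,
#'   tumor), `image`, `gt`, `patch_size`, `context`.
#' @export
index_patches <- function(image, gt, grid, context = 2L) {
  stopifnot(inherits(grid, "patch_grid"))
  check_same_grid(image, gt, "image and ground truth")
  d <- dim(image$data)
  P <- grid$patch_size
  ro <- grid$row_offsets
  co <- grid$col_offsets
  nz <- d[1]
  res <- vector("list", nz)
  for (z in seq_len(nz)) {
    sl <- gt$data[z, , ]
    S <- matrix(0, d[2] + 1L, d[3] + 1L)
    S[-1, -1] <- apply(apply(sl, 2, cumsum), 1, cumsum) |> t()
    ws <- S[ro + P + 1L, co + P + 1L, drop = FALSE] -
      S[ro + 1L, co + P + 1L, drop = FALSE] -
      S[ro + P + 1L, co + 1L, drop = FALSE] +
      S[ro + 1L, co + 1L, drop = FALSE]
    res[[z]] <- data.frame(
      z = z - 1L,
      row = rep(ro, times = length(co)),
      col = rep(co, each = length(ro)),
      tumor = as.vector(ws) > 0
    )
  }
  structure(
    list(table = do.call(rbind, res), image = image, gt = gt,
         patch_size = P, context = as.integer(context)),
    class = "patch_index"
  )
}

#' Merge overlapping patch probabilities back onto a slice
#'
#' Each output pixel is the arithmetic mean of the predictions of all
#' patches covering it — the probability-averaging rule for overlapping
#' windows. All patches are weighted equally.
#'
#' @param patches list of lists with `row`, `col` (0-based top-left) and
#'   `prob` (patch_size x patch_size matrix in \[0, 1\]).
#' @param rows,cols slice extent in pixels.
#' @return rows x cols probability matrix in \[0, 1\].
#' @export
merge_probabilities <- function(patches, rows, cols) {
  acc <- matrix(0, rows, cols)
  cnt <- matrix(0L, rows, cols)
  for (p in patches) {
    pr <- p$prob
    if (min(pr) < -1e-9 || max(pr) > 1 + 1e-9)
      stop("merge_probabilities: probabilities must be in [0, 1]")
    ri <- (p$row + 1L):(p$row + nrow(pr))
    ci <- (p$col + 1L):(p$col + ncol(pr))
    if (max(ri) > rows || max(ci) > cols)
      stop("merge_probabilities: patch at (", p$row, ",", p$col,
           ") falls outside the slice")
    acc[ri, ci] <- acc[ri, ci] + pr
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  if (any(cnt == 0L))
    stop("merge_probabilities: ", sum(cnt == 0L),
         " pixels are covered by no patch")
  acc / cnt
}
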