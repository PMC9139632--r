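# Whole-volume prediction by sliding-window 2.5D inference, thresholding,
# lesion extraction, and minimum-volume rejection.

#' Predict a whole volume with sliding-window 2.5D inference
#'
#' For each axial slice, every patch stack on the grid is run through the
#' network and the per-patch probabilities are merged back by arithmetic
#' averaging over all patches covering each pixel. The image must have been
#' preprocessed identically to training.
#'
#' @param model a `unet_model`.
#' @param image preprocessed `image_volume` (intensities in \[0, 1\]).
#' @param grid a `patch_grid`; its patch size must match the model's.
#' @param context context slices each side (must give the model's input
#'   channel count).
#' @return `image_volume` probability map aligned voxelwise with `image`.
#' @export
predict_volume <- function(model, image, grid = NULL, context = 2L) {
  stopifnot(inherits(model, "unet_model"), inherits(image, "image_volume"))
  d <- dim(image$data)
  if (is.null(grid))
    grid <- plan_grid(d[2], d[3], model$spec$patch_size,
                      model$spec$patch_size %/% 2L)
  if (grid$patch_size != model$spec$patch_size)
    stop("predict_volume: grid patch size (", grid$patch_size,
         ") does not match the model's (", model$spec$patch_size, ")")
  if (2L * context + 1L != model$spec$in_channels)
    stop("predict_volume: context ", context, " gives ", 2 * context + 1,
         " channels but the model expects ", model$spec$in_channels)
  P <- grid$patch_size
  offs <- expand.grid(row = grid$row_offsets, col = grid$col_offsets)
  np <- nrow(offs)
  prob <- array(0, d)
  for (z in seq_len(d[1]) - 1L) {
    x <- array(0, c(P, P, model$spec$in_channels, np))
    for (i in seq_len(np)) {
      st <- extract_stack(image, NULL, z, offs$row[i], offs$col[i], P,
                          context)
      x[, , , i] <- st$data
    }
    pr <- unet_predict(model, x)
    patches <- lapply(seq_len(np), function(i)
      list(row = offs$row[i], col = offs$col[i], prob = pr[, , i]))
    prob[z + 1L, , ] <- merge_probabilities(patches, d[2], d[3])
  }
  image_volume(prob, image$spacing, image$origin)
}

#' Threshold a probability map into a binary mask
#'
#' A voxel is foreground iff its probability is `>= threshold`.
#'
#' @param prob `image_volume` with values in \[0, 1\].
#' @param threshold scalar cut (default 0.5).
#' @return `label_volume`.
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(inherits(prob, "image_volume"))
  if (min(prob$data) < -1e-9 || max(prob$data) > 1 + 1e-9)
    stop("binarize: values must be in [0, 1]")
  label_volume((prob$data >= threshold) * 1L, prob$spacing, prob$origin)
}

#' Extract connected lesions from a binary mask
#'
#' Connected components under 26-connectivity in 3D; each component is one
#' candidate lesion, labelled with its physical volume in cc and centroid
#' in mm.
#'
#' @param mask `label_volume`.
#' @param source `"prediction"` or `"ground_truth"` (bookkeeping tag).
#' @return A `lesion_set`: list with `lesions` (each `id`, `voxels` — n x 3
#'   0-based (z, y, x) matrix — `volume_cc`, `centroid_mm`), `labels`
#'   (labelled array), `source`, `spacing`.
#' @export
find_lesions <- function(mask, source = c("prediction", "ground_truth")) {
  stopifnot(inherits(mask, "label_volume"))
  source <- match.arg(source)
  lab <- .cpp_label3d(mask$data)
  n <- max(lab)
  vox_cc <- voxel_volume_cc(mask$spacing)
  lesions <- vector("list", n)
  if (n > 0) {
    idx <- which(lab > 0)
    comp <- lab[idx]
    coords <- arrayInd(idx, dim(lab)) - 1L
    ord <- order(comp)
    comp <- comp[ord]
    coords <- coords[ord, , drop = FALSE]
    bounds <- c(0L, cumsum(tabulate(comp, n)))
    for (i in seq_len(n)) {
      vox <- coords[(bounds[i] + 1L):bounds[i + 1L], , drop = FALSE]
      colnames(vox) <- c("z", "y", "x")
      lesions[[i]] <- list(
        id = i,
        voxels = vox,
        volume_cc = nrow(vox) * vox_cc,
        centroid_mm = colMeans(vox) * mask$spacing
      )
    }
  }
  structure(list(lesions = lesions, labels = lab, source = source,
                 spacing = mask$spacing, dim = dim(mask$data)),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  v <- vapply(x$lesions, function(l) l$volume_cc, 1.0)
  cat(sprintf("<lesion_set> %d %s lesion(s)", length(v), x$source))
  if (length(v))
    cat(sprintf(", volumes %.4g-%.4g cc", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Number of lesions in a set
#' @param ls a `lesion_set`.
#' @return integer count.
#' @export
n_lesions <- function(ls) length(ls$lesions)

#' Reject lesions below a minimum physical volume
#'
#' Retains exactly the lesions with `volume_cc >= min_volume_cc` (the
#' rejection rule is a strict `<` on the volume). Idempotent.
#'
#' @param ls a `lesion_set`.
#' @param min_volume_cc rejection threshold in cc (default 0.02).
#' @return the filtered `lesion_set` (label array updated to match).
#' @export
filter_small <- function(ls, min_volume_cc = 0.02) {
  stopifnot(inherits(ls, "lesion_set"))
  if (min_volume_cc < 0)
    stop("filter_small: `min_volume_cc` must be non-negative")
  keep <- vapply(ls$lesions, function(l) l$volume_cc >= min_volume_cc,
                 TRUE)
  dropped <- ls$lesions[!keep]
  for (l in dropped)
    ls$labels[l$voxels + 1L] <- 0L
  ls$lesions <- ls$lesions[keep]
  ls
}

#' Rasterise a lesion set back into a binary mask
#'
#' @param ls a `lesion_set`.
#' @return `label_volume` whose foreground is the union of the lesions.
#' @export
lesions_to_mask <- function(ls) {
  stopifnot(inherits(ls, "lesion_set"))
  label_volume((ls$labels > 0L) * 1L, ls$spacing)
}

#' Lesion table
#'
#' @param ls a `lesion_set`.
#' @return data.frame with one row per lesion: id, n_voxels, volume_cc,
#'   centroid (mm).
#' @export
lesion_table <- function(ls) {
  stopifnot(inherits(ls, "lesion_set"))
  if (!length(ls$lesions))
    return(data.frame(id = integer(), n_voxels = integer(),
                      volume_cc = numeric(), centroid_z_mm = numeric(),
                      centroid_y_mm = numeric(), centroid_x_mm = numeric()))
  do.call(rbind, lapply(ls$lesions, function(l)
    data.frame(id = l$id, n_voxels = nrow(l$voxels),
               volume_cc = l$volume_cc,
               centroid_z_mm = l$centroid_mm[1],
               centroid_y_mm = l$centroid_mm[2],
               centroid_x_mm = l$centroid_mm[3])))
}

#' Full prediction postprocessing: threshold, label, reject small lesions
#'
#' @param prob probability `image_volume`.
#' @param threshold probability cut (default 0.5).
#' @param min_volume_cc minimum lesion volume retained, cc (default 0.02).
#' @return list with `mask` (`label_volume` after rejection) and `lesions`
#'   (`lesion_set`).
#' @export
postprocess_prediction <- function(prob, threshold = 0.5,
                                   min_volume_cc = 0.02) {
  ls <- filter_small(find_lesions(binarize(prob, threshold)), min_volume_cc)
  list(mask = lesions_to_mask(ls), lesions = ls)
}
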