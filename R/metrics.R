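# Lesion-level detection statistics and segmentation metrics:
# sensitivity, average false positives per patient, Dice, Dice with
# dilation (3 mm physical sphere), and the 95th-percentile Hausdorff
# distance, with per-lesion and volume-binned reports.

#' Detection bookkeeping container
#'
#' @param tp ground-truth lesions detected.
#' @param fn ground-truth lesions missed.
#' @param fp_per_patient integer vector of false-positive counts, one per
#'   patient.
#' @param matches optional list: for each GT lesion id, the predicted
#'   lesion ids overlapping it.
#' @return A `detection_result`.
#' @export
detection_result <- function(tp, fn, fp_per_patient = integer(),
                             matches = NULL) {
  stopifnot(tp >= 0, fn >= 0, all(fp_per_patient >= 0))
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp_per_patient = as.integer(fp_per_patient),
                 matches = matches),
            class = "detection_result")
}

#' Match predicted lesions to ground-truth lesions
#'
#' A GT lesion counts as detected (TP) iff at least one predicted lesion
#' shares at least one voxel with it; a predicted lesion overlapping no GT
#' lesion is a false positive. One predicted lesion may validate several GT
#' lesions. Both sets must live on the same grid.
#'
#' @param gt,pr `lesion_set`s from [find_lesions()] on the same grid.
#' @return A [detection_result()] (single patient: `fp_per_patient` has
#'   length 1) with `matches` and the FP lesion ids in `fp_ids`.
#' @export
match_lesions <- function(gt, pr) {
  stopifnot(inherits(gt, "lesion_set"), inherits(pr, "lesion_set"))
  if (!identical(gt$dim, pr$dim) || max(abs(gt$spacing - pr$spacing)) > 1e-9)
    stop("match_lesions: lesion sets are on different grids")
  both <- gt$labels > 0L & pr$labels > 0L
  matches <- rep(list(integer()), n_lesions(gt))
  hit_pr <- integer()
  if (any(both)) {
    g <- gt$labels[both]
    p <- pr$labels[both]
    ov <- unique(cbind(g, p))
    for (k in seq_len(nrow(ov)))
      matches[[ov[k, 1]]] <- sort(c(matches[[ov[k, 1]]], ov[k, 2]))
    hit_pr <- unique(ov[, 2])
  }
  detected <- vapply(matches, function(m) length(m) > 0L, TRUE)
  fp_ids <- setdiff(vapply(pr$lesions, function(l) l$id, 1L), hit_pr)
  d <- detection_result(sum(detected), sum(!detected),
                        fp_per_patient = length(fp_ids), matches = matches)
  d$fp_ids <- as.integer(fp_ids)
  d$detected <- detected
  d
}

#' Lesion-level detection sensitivity, TP / (TP + FN)
#'
#' @param d a `detection_result` (or any list with `tp` and `fn`).
#' @return fraction in \[0, 1\].
#' @export
sensitivity <- function(d) {
  tp <- d$tp; fn <- d$fn
  if (tp + fn <= 0)
    stop("sensitivity: undefined, no ground-truth lesions (tp + fn = 0)")
  tp / (tp + fn)
}

#' Average false positives per patient
#'
#' The sum of per-patient false-positive counts divided by the number of
#' patients. Accepts a `detection_result`, a vector of per-patient counts,
#' or a total count together with `n_patients`.
#'
#' @param fp a `detection_result`, a numeric vector of per-patient FP
#'   counts, or a single total FP count (then `n_patients` is required).
#' @param n_patients number of patients; defaults to the length of the
#'   per-patient vector.
#' @return FPs per patient.
#' @export
avg_fp_rate <- function(fp, n_patients = NULL) {
  if (inherits(fp, "detection_result")) fp <- fp$fp_per_patient
  fp <- as.numeric(fp)
  if (is.null(n_patients)) n_patients <- length(fp)
  if (n_patients < 1) stop("avg_fp_rate: need at least one patient")
  sum(fp) / n_patients
}

#' Dice overlap coefficient, 2|GT intersect PR| / (|GT| + |PR|)
#'
#' Two empty masks give 1 by convention; empty vs non-empty gives 0.
#'
#' @param gt,pr aligned `label_volume`s.
#' @return fraction in \[0, 1\].
#' @export
dice <- function(gt, pr) {
  stopifnot(inherits(gt, "label_volume"), inherits(pr, "label_volume"))
  check_same_grid(gt, pr, "gt and pr masks")
  dice_arr(gt$data, pr$data)
}

dice_arr <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Morphological dilation by a physical radius
#'
#' Dilates with a spherical structuring element of radius `radius_mm`,
#' voxelised for the (possibly anisotropic) spacing: a voxel joins the
#' dilated mask iff its centre lies within `radius_mm` of some foreground
#' voxel centre, measured in mm. Implemented through the exact Euclidean
#' distance transform, so the element is a true physical-units ball.
#'
#' @param m `label_volume`.
#' @param radius_mm dilation radius in mm (0 is the identity).
#' @return dilated `label_volume`.
#' @export
dilate_mask <- function(m, radius_mm) {
  stopifnot(inherits(m, "label_volume"))
  if (radius_mm < 0) stop("dilate_mask: radius must be >= 0")
  if (radius_mm == 0 || sum(m$data) == 0L) return(m)
  d <- .cpp_edt3d(m$data, m$spacing)
  label_volume((d <= radius_mm + 1e-12) * 1L, m$spacing, m$origin)
}

#' Dice with dilation (DWD)
#'
#' Dice computed after dilating both masks by the same physical margin
#' (default 3 mm), reflecting the contour margin tolerated clinically in
#' stereotactic radiotherapy. At radius 0 it reduces to plain [dice()].
#'
#' @inheritParams dice
#' @param radius_mm dilation radius in mm (default 3).
#' @return fraction in \[0, 1\].
#' @export
dice_with_dilation <- function(gt, pr, radius_mm = 3) {
  dice(dilate_mask(gt, radius_mm), dilate_mask(pr, radius_mm))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' For every foreground voxel of the prediction, its minimum physical
#' distance to the ground-truth foreground; returns the 95th percentile of
#' these directed distances (linear interpolation between order
#' statistics). The symmetric variant takes the maximum of the two directed
#' values.
#'
#' @inheritParams dice
#' @param percentile percentile of the directed distances (default 95).
#' @param symmetric if `TRUE`, `max(hd(pr -> gt), hd(gt -> pr))`.
#' @return distance in mm.
#' @export
hd95 <- function(gt, pr, percentile = 95, symmetric = FALSE) {
  stopifnot(inherits(gt, "label_volume"), inherits(pr, "label_volume"))
  check_same_grid(gt, pr, "gt and pr masks")
  if (sum(gt$data) == 0L || sum(pr$data) == 0L)
    stop("hd95: undefined for an empty mask (lesion not detected)")
  fwd <- directed_percentile_dist(gt, pr, percentile)
  if (!symmetric) return(fwd)
  max(fwd, directed_percentile_dist(pr, gt, percentile))
}

directed_percentile_dist <- function(ref, qry, percentile) {
  d <- .cpp_edt3d(ref$data, ref$spacing)
  stats::quantile(d[qry$data > 0L], percentile / 100, names = FALSE,
                  type = 7)
}

# ---------------------------------------------------------------------------
# Per-lesion report and volume-binned aggregation
# ---------------------------------------------------------------------------

volume_bin <- function(v) {
  cut(v, breaks = c(-Inf, 0.02, 0.04, 0.06, 0.08, 0.1, Inf),
      labels = c("<0.02", "0.02-0.04", "0.04-0.06", "0.06-0.08",
                 "0.08-0.1", ">0.1"),
      right = TRUE)
}

#' Per-lesion segmentation metrics
#'
#' For each ground-truth lesion, computes Dice, Dice-with-dilation and
#' directed HD95 between that lesion's mask and the predicted foreground
#' restricted to the lesion's bounding box expanded by `margin_mm`, so one
#' lesion's error does not pollute another's score. Undetected lesions get
#' dice/dwd of 0 and `NA` HD95 (excluded from aggregation).
#'
#' @param gt_ls ground-truth `lesion_set`.
#' @param pr predicted `label_volume` (after postprocessing).
#' @param margin_mm locality margin around each lesion's bounding box (mm,
#'   default 3).
#' @param dilation_mm DWD dilation radius (mm, default 3).
#' @return data.frame: one row per GT lesion with id, volume_cc, bin,
#'   detected, dice, dwd, hd95_mm plus the local voxel counts used for
#'   pooled aggregation.
#' @export
per_lesion_report <- function(gt_ls, pr, margin_mm = 3, dilation_mm = 3) {
  stopifnot(inherits(gt_ls, "lesion_set"), inherits(pr, "label_volume"))
  if (!identical(gt_ls$dim, dim(pr$data)))
    stop("per_lesion_report: gt and prediction are on different grids")
  sp <- gt_ls$spacing
  d <- gt_ls$dim
  halo <- ceiling((margin_mm + dilation_mm) / sp)  # room for dilation too
  marg <- ceiling(margin_mm / sp)
  rows <- lapply(gt_ls$lesions, function(l) {
    bb_lo <- apply(l$voxels, 2, min)
    bb_hi <- apply(l$voxels, 2, max)
    lo <- pmax(bb_lo - halo, 0)
    hi <- pmin(bb_hi + halo, d - 1L)
    iz <- (lo[1]:hi[1]) + 1L; iy <- (lo[2]:hi[2]) + 1L
    ix <- (lo[3]:hi[3]) + 1L
    gt_loc <- array(0L, c(length(iz), length(iy), length(ix)))
    vv <- sweep(l$voxels, 2, lo, "-") + 1L
    gt_loc[vv] <- 1L
    pr_loc <- pr$data[iz, iy, ix, drop = FALSE]
    # prediction restricted to bbox + margin (not the full halo)
    sel_lo <- pmax(bb_lo - marg, 0) - lo + 1L
    sel_hi <- pmin(bb_hi + marg, d - 1L) - lo + 1L
    sel <- array(0L, dim(pr_loc))
    sel[sel_lo[1]:sel_hi[1], sel_lo[2]:sel_hi[2], sel_lo[3]:sel_hi[3]] <- 1L
    pr_loc <- pr_loc * sel
    gt_v <- label_volume(gt_loc, sp)
    pr_v <- label_volume(pr_loc, sp)
    detected <- sum(gt_loc & pr_loc) > 0L
    dc <- dice_arr(gt_loc, pr_loc)
    gtd <- dilate_mask(gt_v, dilation_mm)
    prd <- dilate_mask(pr_v, dilation_mm)
    dwd <- dice_arr(gtd$data, prd$data)
    hd <- if (detected) hd95(gt_v, pr_v) else NA_real_
    data.frame(id = l$id, volume_cc = l$volume_cc,
               bin = as.character(volume_bin(l$volume_cc)),
               detected = detected,
               dice = if (detected) dc else 0,
               dwd = if (detected) dwd else 0,
               hd95_mm = hd,
               n_gt = sum(gt_loc), n_pr = sum(pr_loc),
               n_inter = sum(gt_loc & pr_loc),
               n_gt_dil = sum(gtd$data), n_pr_dil = sum(prd$data),
               n_inter_dil = sum(gtd$data & prd$data))
  })
  if (!length(rows))
    return(data.frame(id = integer(), volume_cc = numeric(),
                      bin = character(), detected = logical(),
                      dice = numeric(), dwd = numeric(),
                      hd95_mm = numeric(), n_gt = integer(),
                      n_pr = integer(), n_inter = integer(),
                      n_gt_dil = integer(), n_pr_dil = integer(),
                      n_inter_dil = integer()))
  do.call(rbind, rows)
}

#' Evaluate one case (one patient): detection + per-lesion segmentation
#'
#' Runs [find_lesions()] on both masks, applies the minimum-volume
#' rejection to the prediction, matches lesions, and computes the
#' per-lesion report.
#'
#' @param gt ground-truth `label_volume`.
#' @param pr predicted `label_volume` (binary, pre-rejection).
#' @param min_volume_cc minimum predicted-lesion volume retained (cc).
#' @param margin_mm,dilation_mm see [per_lesion_report()].
#' @return list with `detection` ([detection_result()]), `per_lesion`
#'   (data.frame), `pr_lesions` (filtered `lesion_set`).
#' @export
evaluate_case <- function(gt, pr, min_volume_cc = 0.02, margin_mm = 3,
                          dilation_mm = 3) {
  gt_ls <- find_lesions(gt, "ground_truth")
  pr_ls <- filter_small(find_lesions(pr, "prediction"), min_volume_cc)
  det <- match_lesions(gt_ls, pr_ls)
  rep <- per_lesion_report(gt_ls, lesions_to_mask(pr_ls), margin_mm,
                           dilation_mm)
  list(detection = det, per_lesion = rep, gt_lesions = gt_ls,
       pr_lesions = pr_ls)
}

#' Aggregate evaluated cases into a volume-binned report
#'
#' One row per volume bin plus `<=0.1` and `Total` rows: lesion count,
#' sensitivity (percent), false-positive count (FP lesions binned by their
#' own volume), mean per-lesion Dice/DWD, pooled Dice/DWD (from summed
#' voxel counts), and mean HD95 over detected lesions only. Detection
#' bookkeeping (tp + fn = lesion count) is asserted.
#'
#' @param cases list of [evaluate_case()] results (one per patient).
#' @return list with `by_bin` (data.frame), `summary` (named list with
#'   sensitivity, avg_fp_rate, dice, dwd, hd95_mm), `n_patients`.
#' @export
metrics_report <- function(cases) {
  per <- do.call(rbind, lapply(cases, `[[`, "per_lesion"))
  fp_counts <- vapply(cases, function(cs) sum(cs$detection$fp_per_patient),
                      1L)
  fp_vols <- as.numeric(unlist(lapply(cases, function(cs) {
    ids <- cs$detection$fp_ids
    vapply(cs$pr_lesions$lesions[match(ids, vapply(cs$pr_lesions$lesions,
                                                   `[[`, 1L, "id"))],
           function(l) l$volume_cc, 1.0)
  })))
  n_gt_total <- sum(vapply(cases, function(cs) n_lesions(cs$gt_lesions), 1L))
  tp <- sum(vapply(cases, function(cs) cs$detection$tp, 1L))
  fn <- sum(vapply(cases, function(cs) cs$detection$fn, 1L))
  stopifnot(tp + fn == n_gt_total, nrow(per) == n_gt_total)

  bin_row <- function(sel, fp_sel, label) {
    b <- per[sel, , drop = FALSE]
    det <- b$detected
    data.frame(
      volume_bin = label,
      n_lesions = nrow(b),
      sensitivity_pct = if (nrow(b)) 100 * mean(det) else NA_real_,
      n_fps = sum(fp_sel),
      dice = if (nrow(b)) mean(b$dice) else NA_real_,
      dice_pooled = if (sum(b$n_gt + b$n_pr) > 0)
        2 * sum(b$n_inter) / sum(b$n_gt + b$n_pr) else NA_real_,
      dwd = if (nrow(b)) mean(b$dwd) else NA_real_,
      dwd_pooled = if (sum(b$n_gt_dil + b$n_pr_dil) > 0)
        2 * sum(b$n_inter_dil) / sum(b$n_gt_dil + b$n_pr_dil) else NA_real_,
      hd95_mm = if (any(det & !is.na(b$hd95_mm)))
        mean(b$hd95_mm[det], na.rm = TRUE) else NA_real_
    )
  }
  bins <- c(">0.1", "<=0.1", "0.08-0.1", "0.06-0.08", "0.04-0.06",
            "0.02-0.04", "<0.02", "Total")
  rows <- lapply(bins, function(bn) {
    sel <- switch(bn,
                  ">0.1" = per$volume_cc > 0.1,
                  "<=0.1" = per$volume_cc <= 0.1,
                  "Total" = rep(TRUE, nrow(per)),
                  per$bin == bn)
    fsel <- switch(bn,
                   ">0.1" = fp_vols > 0.1,
                   "<=0.1" = fp_vols <= 0.1,
                   "Total" = rep(TRUE, length(fp_vols)),
                   as.character(volume_bin(fp_vols)) == bn)
    if (bn == "<0.02" && !any(sel)) return(NULL)
    bin_row(sel, fsel, bn)
  })
  by_bin <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  tot <- by_bin[by_bin$volume_bin == "Total", ]
  list(by_bin = by_bin,
       summary = list(sensitivity = tp / (tp + fn),
                      avg_fp_rate = avg_fp_rate(fp_counts),
                      dice = tot$dice, dwd = tot$dwd,
                      hd95_mm = tot$hd95_mm),
       n_patients = length(cases))
}
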