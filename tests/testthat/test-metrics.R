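test_that("lesion matching follows the one-voxel-overlap rule", {
  # perfect prediction
  m <- random_mask(c(6, 12, 12), 0.1, seed = 3)
  gt <- find_lesions(lv(m), "ground_truth")
  pr <- find_lesions(lv(m), "prediction")
  d <- match_lesions(gt, pr)
  expect_equal(d$tp, n_lesions(gt))
  expect_equal(d$fn, 0)
  expect_equal(sum(d$fp_per_patient), 0)

  # empty prediction: everything missed
  d0 <- match_lesions(gt, find_lesions(lv(array(0L, c(6, 12, 12)))))
  expect_equal(d0$tp, 0)
  expect_equal(d0$fn, n_lesions(gt))

  # one predicted blob spanning two GT lesions validates both, no FP
  g <- array(0L, c(3, 20, 5))
  g[2, 2:4, 2] <- 1L
  g[2, 10:12, 2] <- 1L
  p <- array(0L, c(3, 20, 5))
  p[2, 2:12, 2] <- 1L
  d2 <- match_lesions(find_lesions(lv(g), "ground_truth"),
                      find_lesions(lv(p)))
  expect_equal(d2$tp, 2)
  expect_equal(d2$fn, 0)
  expect_equal(sum(d2$fp_per_patient), 0)

  # grid mismatch is an error
  expect_error(match_lesions(gt, find_lesions(lv(array(0L, c(5, 12, 12))))),
               "different grids")
})

test_that("sensitivity and FP-rate arithmetic follow their definitions", {
  expect_equal(sensitivity(detection_result(56, 2)), 56 / 58)
  expect_equal(round(100 * sensitivity(detection_result(56, 2)), 1), 96.6)
  expect_equal(sensitivity(detection_result(10, 0)), 1)
  expect_equal(sensitivity(detection_result(12, 2)), 12 / 14)
  expect_error(sensitivity(detection_result(0, 0)), "undefined")

  expect_equal(avg_fp_rate(15, n_patients = 12), 1.25)
  expect_equal(avg_fp_rate(rep(0, 8)), 0)
  expect_equal(avg_fp_rate(c(6, 0, 0)), 2)
  expect_error(avg_fp_rate(integer(0)), "at least one")
})

test_that("dice follows the overlap formula with the empty-mask conventions", {
  a <- array(0L, c(3, 4, 4)); a[1, 1, 1] <- 1L; a[1, 2, 1] <- 1L
  b <- array(0L, c(3, 4, 4)); b[1, 2, 1] <- 1L; b[1, 3, 1] <- 1L
  expect_equal(dice(lv(a), lv(b)), 0.5)        # 2*1 / (2+2)
  expect_equal(dice(lv(a), lv(a)), 1)
  disj <- array(0L, c(3, 4, 4)); disj[3, 4, 4] <- 1L
  expect_equal(dice(lv(a), lv(disj)), 0)
  e <- array(0L, c(3, 4, 4))
  expect_equal(dice(lv(e), lv(e)), 1)          # both empty
  expect_equal(dice(lv(a), lv(e)), 0)
  # symmetry on random masks
  for (s in 1:5) {
    x <- random_mask(c(5, 8, 8), 0.3, seed = s)
    y <- random_mask(c(5, 8, 8), 0.3, seed = s + 50)
    expect_equal(dice(lv(x), lv(y)), dice(lv(y), lv(x)))
  }
})

test_that("dilation is a physical-units ball honouring anisotropic spacing", {
  # radius 0 is the identity
  m <- random_mask(c(5, 8, 8), 0.2, seed = 1)
  expect_identical(dilate_mask(lv(m), 0)$data, m)

  # single voxel, unit spacing, 3 mm radius: 123 integer-lattice points
  single <- array(0L, c(9, 9, 9)); single[5, 5, 5] <- 1L
  expect_equal(sum(dilate_mask(lv(single), 3)$data), 123)

  # monotone: the input is contained in every dilation
  for (r in c(0.5, 1, 2)) {
    dl <- dilate_mask(lv(m), r)
    expect_true(all(dl$data[m == 1L] == 1L))
  }

  # anisotropic spacing agrees with the offset-enumeration oracle
  sp <- c(1, 0.5, 0.7)
  for (s in 1:6) {
    mm <- random_mask(c(6, 9, 9), 0.1, seed = 200 + s)
    got <- dilate_mask(lv(mm, sp), 1.8)$data
    expect_identical(got, bf_dilate(mm, 1.8, sp), info = paste("seed", s))
  }
})

test_that("dice with dilation reduces to dice at radius 0 and matches the oracle", {
  x <- random_mask(c(5, 8, 8), 0.25, seed = 9)
  y <- random_mask(c(5, 8, 8), 0.25, seed = 10)
  expect_equal(dice_with_dilation(lv(x), lv(y), 0), dice(lv(x), lv(y)))
  expect_equal(dice_with_dilation(lv(x), lv(x), 3), 1)

  # two single voxels 2 mm apart at 1 mm spacing, 3 mm dilation:
  # exact value from the brute-force voxel dilation oracle
  a <- array(0L, c(9, 11, 9)); a[5, 5, 5] <- 1L
  b <- array(0L, c(9, 11, 9)); b[5, 7, 5] <- 1L
  sp <- c(1, 1, 1)
  da <- bf_dilate(a, 3, sp); db <- bf_dilate(b, 3, sp)
  expected <- 2 * sum(da & db) / (sum(da) + sum(db))
  expect_equal(dice_with_dilation(lv(a), lv(b), 3), expected)
  expect_gt(expected, 0.5)                    # high overlap at this margin
  expect_equal(dice(lv(a), lv(b)), 0)         # though disjoint undilated
})

test_that("directed HD95 matches the all-pairs oracle", {
  # identical masks: zero distance
  m <- random_mask(c(6, 8, 8), 0.3, seed = 77)
  expect_equal(hd95(lv(m), lv(m)), 0)

  # one voxel 5 mm from a single-voxel reference
  g <- array(0L, c(11, 5, 5)); g[3, 3, 3] <- 1L
  p <- array(0L, c(11, 5, 5)); p[8, 3, 3] <- 1L
  expect_equal(hd95(lv(g), lv(p)), 5)

  # the directed measure is not symmetric in general
  p2 <- array(0L, c(11, 5, 5)); p2[3, 3, 3] <- 1L; p2[8, 3, 3] <- 1L
  expect_false(isTRUE(all.equal(hd95(lv(g), lv(p2)), hd95(lv(p2), lv(g)))))
  expect_equal(hd95(lv(g), lv(p2), symmetric = TRUE),
               max(hd95(lv(g), lv(p2)), hd95(lv(p2), lv(g))))

  expect_error(hd95(lv(array(0L, c(3, 3, 3))), lv(m[1:3, 1:3, 1:3])),
               "empty")
})

test_that("per-lesion reports are local, binned, and conserve counts", {
  ph <- tiny_phantom(seed = 41, n_lesions = 4)
  gt_ls <- find_lesions(ph$gt, "ground_truth")

  # perfect prediction: every lesion detected with dice 1 and hd95 0
  rep1 <- per_lesion_report(gt_ls, ph$gt)
  expect_equal(nrow(rep1), n_lesions(gt_ls))
  expect_true(all(rep1$detected))
  expect_true(all(rep1$dice == 1))
  expect_true(all(rep1$dwd == 1))
  expect_true(all(rep1$hd95_mm == 0))

  # empty prediction: all undetected, dice 0, hd95 missing
  empty <- label_volume(array(0L, ph$gt$data |> dim()), ph$gt$spacing)
  rep0 <- per_lesion_report(gt_ls, empty)
  expect_true(all(!rep0$detected))
  expect_true(all(rep0$dice == 0))
  expect_true(all(is.na(rep0$hd95_mm)))

  # bins partition the lesion set
  expect_equal(sum(table(rep1$bin)), n_lesions(gt_ls))
})

test_that("the aggregated report conserves detection bookkeeping", {
  ph1 <- tiny_phantom(seed = 51, n_lesions = 3)
  ph2 <- tiny_phantom(seed = 52, n_lesions = 4)
  # prediction = ground truth plus one spurious blob (an FP) per case
  mk_pr <- function(ph) {
    p <- ph$gt$data
    p[2, 2:4, 2:4] <- 1L
    label_volume(p, ph$gt$spacing)
  }
  cases <- list(evaluate_case(ph1$gt, mk_pr(ph1), min_volume_cc = 0),
                evaluate_case(ph2$gt, mk_pr(ph2), min_volume_cc = 0))
  rep <- metrics_report(cases)
  tot <- rep$by_bin[rep$by_bin$volume_bin == "Total", ]
  expect_equal(tot$n_lesions,
               n_lesions(cases[[1]]$gt_lesions) +
                 n_lesions(cases[[2]]$gt_lesions))
  expect_equal(rep$summary$sensitivity, 1)
  expect_equal(rep$summary$avg_fp_rate, 1)    # one FP in each of 2 patients
  expect_equal(rep$n_patients, 2)
  # bin lesion counts sum to the total row
  bins <- rep$by_bin[!rep$by_bin$volume_bin %in% c("Total", "<=0.1"), ]
  sub <- bins[bins$volume_bin != ">0.1", ]
  expect_equal(sum(sub$n_lesions) +
                 bins$n_lesions[bins$volume_bin == ">0.1"],
               tot$n_lesions)
})
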