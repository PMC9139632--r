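test_that("grid planning matches the sliding-window rule", {
  g <- plan_grid(1024, 1024, 128, 64)
  expect_length(g$row_offsets, 15)             # (1024-128)/64 + 1
  expect_length(g$col_offsets, 15)
  expect_equal(g$row_offsets, seq(0L, 896L, by = 64L))

  g1 <- plan_grid(128, 128, 128, 64)
  expect_equal(g1$row_offsets, 0L)             # patch == slice

  gb <- plan_grid(200, 200, 128, 64)
  expect_equal(gb$row_offsets, c(0L, 64L, 72L)) # flush border patch

  expect_error(plan_grid(100, 100, 128, 64), "exceeds")
  expect_error(plan_grid(200, 200, 128, 0), "stride")
  expect_error(plan_grid(200, 200, 128, 129), "stride")
})

test_that("grid planning agrees with brute-force window enumeration", {
  set.seed(14)
  for (k in 1:25) {
    extent <- sample(40:300, 1)
    patch <- sample(8:min(extent, 128), 1)
    stride <- sample(seq_len(patch), 1)
    offs <- plan_grid(extent, extent, patch, stride)$row_offsets
    expect_equal(offs, sort(bf_axis_offsets(extent, patch, stride)),
                 info = sprintf("extent=%d patch=%d stride=%d",
                                extent, patch, stride))
    # full coverage
    covered <- logical(extent)
    for (o in offs) covered[(o + 1):(o + patch)] <- TRUE
    expect_true(all(covered))
  }
})

test_that("stack extraction crops five slices with edge replication", {
  set.seed(4)
  img <- image_volume(array(rnorm(6 * 20 * 20), c(6, 20, 20)), c(1, 1, 1))
  gt <- label_volume(array(0L, c(6, 20, 20)), c(1, 1, 1))
  gt$data[6, 5:7, 5:7] <- 1L   # foreground only on 0-based slice 5

  # interior reference slice: channels are the literal five slices
  st <- extract_stack(img, gt, z = 3, row = 2, col = 4, patch_size = 8)
  expect_identical(dim(st$data), c(8L, 8L, 5L))
  for (k in 1:5)
    expect_equal(st$data[, , k], img$data[k + 1, 3:10, 5:12])

  # z = 0: channels replicate the first slice -> (0,0,0,1,2)
  s0 <- extract_stack(img, gt, z = 0, row = 0, col = 0, patch_size = 8)
  expect_equal(s0$data[, , 1], s0$data[, , 3])
  expect_equal(s0$data[, , 2], s0$data[, , 3])
  expect_equal(s0$data[, , 3], img$data[1, 1:8, 1:8])
  expect_equal(s0$data[, , 4], img$data[2, 1:8, 1:8])
  expect_equal(s0$data[, , 5], img$data[3, 1:8, 1:8])

  # patch class comes from the reference-slice label crop only: the same
  # window is healthy when referenced off the labelled slice
  expect_equal(patch_class(extract_stack(img, gt, 3, 2, 2, 8)), "healthy")
  expect_equal(patch_class(extract_stack(img, gt, 5, 2, 2, 8)), "tumor")

  expect_error(extract_stack(img, gt, 3, 15, 0, 8), "outside")
  expect_error(extract_stack(img, gt, 7, 0, 0, 8), "outside")
})

test_that("extract_all yields one stack per (slice, row, col) triple", {
  img <- image_volume(array(0, c(3, 40, 40)), c(1, 1, 1))
  gt <- label_volume(array(0L, c(3, 40, 40)), c(1, 1, 1))
  grid <- plan_grid(40, 40, 16, 8)
  all <- extract_all(img, gt, grid)
  expect_length(all, 3 * length(grid$row_offsets) * length(grid$col_offsets))

  one <- extract_all(image_volume(array(0, c(1, 16, 16)), c(1, 1, 1)),
                     grid = plan_grid(16, 16, 16, 8))
  expect_length(one, 1)
})

test_that("patch index counts tumor windows like brute-force intersection", {
  ph <- tiny_phantom(seed = 31)
  grid <- plan_grid(64, 64, 16, 8)
  idx <- index_patches(ph$image, ph$gt, grid)
  d <- dim(ph$gt$data)
  expect_equal(nrow(idx$table),
               d[1] * length(grid$row_offsets) * length(grid$col_offsets))
  # brute force: a window is tumor iff its reference-slice crop hits GT
  for (k in sample(nrow(idx$table), 200)) {
    r <- idx$table[k, ]
    crop <- ph$gt$data[r$z + 1, (r$row + 1):(r$row + 16),
                       (r$col + 1):(r$col + 16)]
    expect_identical(r$tumor, any(crop > 0), info = paste("row", k))
  }
  expect_equal(sum(idx$table$tumor),
               sum(vapply(seq_len(nrow(idx$table)), function(k) {
                 r <- idx$table[k, ]
                 any(ph$gt$data[r$z + 1, (r$row + 1):(r$row + 16),
                                (r$col + 1):(r$col + 16)] > 0)
               }, TRUE)))
})

test_that("probability merging averages all covering patches", {
  # pixel covered by two patches predicting 0.4 and 0.8 -> 0.6
  p <- list(list(row = 0L, col = 0L, prob = matrix(0.4, 8, 8)),
            list(row = 4L, col = 0L, prob = matrix(0.8, 8, 8)))
  m <- merge_probabilities(p, 12, 8)
  expect_equal(m[5, 1], 0.6)
  expect_equal(m[1, 1], 0.4)
  expect_equal(m[12, 8], 0.8)

  # constant predictions merge to the constant
  g <- plan_grid(40, 40, 16, 8)
  pc <- list()
  for (r in g$row_offsets) for (cc in g$col_offsets)
    pc[[length(pc) + 1]] <- list(row = r, col = cc,
                                 prob = matrix(0.7, 16, 16))
  expect_true(all(merge_probabilities(pc, 40, 40) == 0.7))

  # round-trip: patches cut from a fixed map reproduce it exactly
  set.seed(5)
  P <- matrix(runif(40 * 40), 40, 40)
  pr <- list()
  for (r in g$row_offsets) for (cc in g$col_offsets)
    pr[[length(pr) + 1]] <- list(row = r, col = cc,
                                 prob = P[(r + 1):(r + 16),
                                          (cc + 1):(cc + 16)])
  expect_equal(merge_probabilities(pr, 40, 40), P, tolerance = 1e-12)

  # uncovered pixels are a hard error
  expect_error(merge_probabilities(p, 20, 8), "covered by no patch")
  bad <- list(list(row = 0L, col = 0L, prob = matrix(1.4, 8, 8)))
  expect_error(merge_probabilities(bad, 8, 8), "\\[0, 1\\]")
})
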