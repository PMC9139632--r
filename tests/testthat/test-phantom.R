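test_that("phantoms are fully determined by their seed", {
  s <- phantom_spec(shape = c(10, 48, 48), spacing = c(1, 2, 2),
                    n_lesions = 3, seed = 5)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$gt$data, b$gt$data)
  expect_identical(a$lesion_specs, b$lesion_specs)
  s2 <- phantom_spec(shape = c(10, 48, 48), spacing = c(1, 2, 2),
                     n_lesions = 3, seed = 6)
  expect_false(identical(generate_phantom(s2)$image$data, a$image$data))
})

test_that("ground truth and lesion set are mutually consistent", {
  ph <- tiny_phantom(seed = 19, n_lesions = 5)
  expect_equal(n_lesions(ph$lesions), nrow(ph$lesion_specs))
  expect_equal(sum(vapply(ph$lesions$lesions, function(l) nrow(l$voxels),
                          1L)),
               sum(ph$gt$data))
  # analytic ellipsoid volume vs target volume
  v_analytic <- with(ph$lesion_specs,
                     4 / 3 * pi * a_mm * b_mm * c_mm / 1000)
  expect_equal(v_analytic, ph$lesion_specs$target_cc, tolerance = 1e-8)
})

test_that("voxelised lesion volumes are close to their analytic targets", {
  # fine in-plane grid so voxelisation error is small for >= 0.02 cc
  ph <- generate_phantom(phantom_spec(
    shape = c(30, 160, 160), spacing = c(1, 0.195, 0.195),
    n_lesions = 3, lesion_volume_range_cc = c(0.02, 0.08),
    n_vessels = 0, noise_sigma = 0, bias_amplitude = 0, seed = 3))
  vox <- sort(vapply(ph$lesions$lesions, `[[`, 1.0, "volume_cc"))
  tgt <- sort(ph$lesion_specs$target_cc)
  expect_true(all(abs(vox - tgt) / tgt < 0.15))
})

test_that("small spherical volumes give the expected equivalent radius", {
  # 0.04 cc sphere: r = (3 * 40 mm^3 / 4 pi)^(1/3) ~ 2.12 mm
  r <- (3 * 0.04 * 1000 / (4 * pi))^(1 / 3)
  expect_equal(r, 2.122, tolerance = 1e-3)
  ph <- generate_phantom(phantom_spec(
    shape = c(24, 96, 96), spacing = c(1, 0.5, 0.5), n_lesions = 1,
    lesion_volume_range_cc = c(0.04, 0.04), n_vessels = 0,
    noise_sigma = 0, seed = 8))
  ax <- unlist(ph$lesion_specs[1, c("a_mm", "b_mm", "c_mm")])
  expect_equal(prod(ax)^(1 / 3), r, tolerance = 1e-6)  # geometric mean
})

test_that("zero lesions give an empty ground truth", {
  ph <- generate_phantom(phantom_spec(shape = c(8, 32, 32),
                                      spacing = c(1, 2, 2), n_lesions = 0,
                                      seed = 2))
  expect_equal(sum(ph$gt$data), 0)
  expect_equal(n_lesions(ph$lesions), 0)
})

test_that("impossible placements fail after bounded retries", {
  expect_error(generate_phantom(phantom_spec(
    shape = c(6, 16, 16), spacing = c(1, 1, 1), n_lesions = 40,
    lesion_volume_range_cc = c(0.3, 0.5), seed = 1)),
    "could not place")
})

test_that("lesion volume sampling hits the small-lesion fraction", {
  v <- sample_lesion_volumes(10000, c(0.004, 1.2), 0.582, seed = 4)
  expect_true(all(v >= 0.004 & v <= 1.2))
  expect_lt(abs(mean(v < 0.1) - 0.582), 0.02)

  one <- sample_lesion_volumes(1, c(0.01, 0.05), seed = 9)
  expect_length(one, 1)
  expect_true(one >= 0.01 && one <= 0.05)

  expect_identical(sample_lesion_volumes(50, seed = 3),
                   sample_lesion_volumes(50, seed = 3))
  expect_error(sample_lesion_volumes(5, c(-1, 2)), "invalid")
})

test_that("bias fields stay within their declared bounds", {
  v <- image_volume(array(1, c(8, 16, 16)), c(1, 1, 1))
  for (s in 1:5) {
    b <- add_bias_field(v, 0.25, seed = s)
    expect_gte(min(b$field$data), 1 - 0.25 - 1e-12)
    expect_lte(max(b$field$data), 1 + 0.25 + 1e-12)
  }
  id <- add_bias_field(v, 0, seed = 1)
  expect_identical(id$volume$data, v$data)
  expect_true(all(id$field$data == 1))
})

test_that("bias correction closes the loop on a biased phantom", {
  ph <- generate_phantom(phantom_spec(
    shape = c(12, 48, 48), spacing = c(1, 1.5, 1.5), n_lesions = 2,
    n_vessels = 0, bias_amplitude = 0, noise_sigma = 0.01, seed = 15))
  b <- add_bias_field(ph$image, 0.3, seed = 77)
  corrected <- correct_bias_field(b$volume, mode = "polynomial")
  head_vox <- ph$image$data > 0.1
  cor_before <- stats::cor(b$volume$data[head_vox], ph$image$data[head_vox])
  cor_after <- stats::cor(corrected$data[head_vox], ph$image$data[head_vox])
  expect_gt(cor_after, cor_before)
})
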