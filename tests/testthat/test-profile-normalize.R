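test_that("profile recovers the phantom's chromatic statistics", {
  ph <- small_phantom(seed = 3)
  prof <- stain_profile(ph$image)

  # stain vectors within 5 degrees of truth
  st <- ph$spec$stain_matrix_true
  expect_lt(acos(pmin(1, sum(prof$stains[1, ] * st[1, ]))) * 180 / pi, 5)
  expect_lt(acos(pmin(1, sum(prof$stains[2, ] * st[2, ]))) * 180 / pi, 5)

  # p99 concentration scales within 5% of the true fields' p99
  ct <- matrix(ph$concentrations_true, ncol = 2)[as.vector(ph$mask_true), ]
  expect_lt(abs(prof$scale_h / quantile(ct[, 1], .99) - 1), 0.05)
  expect_lt(abs(prof$scale_e / quantile(ct[, 2], .99) - 1), 0.05)

  # repeated fits are identical (deterministic pipeline)
  expect_identical(unclass(prof)[1:4], unclass(stain_profile(ph$image))[1:4])
})

test_that("disjoint crops of a homogeneous phantom agree on scales", {
  # crops must hold enough nuclei for a stable upper-tail (p99)
  # concentration estimate; ~35 glands per half suffices
  ph <- generate_phantom(phantom_spec(width = 768, height = 1536,
                                      n_glands = 70, seed = 6))
  top <- ph$image[1:768, , , drop = FALSE]
  bot <- ph$image[769:1536, , , drop = FALSE]
  p1 <- stain_profile(top); p2 <- stain_profile(bot)
  expect_lt(abs(p1$scale_h / p2$scale_h - 1), 0.05)
  expect_lt(abs(p1$scale_e / p2$scale_e - 1), 0.05)
})

test_that("profiles persist as deterministic plain text", {
  prof <- stain_profile(small_phantom(seed = 3)$image, source_id = "t")
  f1 <- tempfile(fileext = ".txt"); f2 <- tempfile(fileext = ".txt")
  write_stain_profile(prof, f1); write_stain_profile(prof, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_stain_profile(f1)
  expect_equal(back$stains, prof$stains, tolerance = 1e-10)
  expect_equal(back$scale_h, prof$scale_h, tolerance = 1e-10)
  expect_equal(back$illuminant, prof$illuminant, tolerance = 1e-10)
  expect_identical(back$source_id, "t")
  expect_error(read_stain_profile(tempfile()), class = "sn_io_error")
})

test_that("self-normalization is the identity up to quantization", {
  ph <- small_phantom(seed = 3, sigma = 0)
  prof <- stain_profile(ph$image)
  wb <- white_balance(ph$image, prof$illuminant)
  nrm <- normalize_image(ph$image, prof)
  mask <- detect_tissue(ph$image)
  expect_gte(mean(max_channel_diff(nrm, wb)[mask] <= 3), 0.99)

  # idempotence: a second pass moves almost nothing
  nrm2 <- normalize_image(nrm, prof)
  expect_lte(mean(max_channel_diff(nrm2, nrm) > 2), 0.01)

  # predict() is the same operation
  expect_identical(predict(prof, ph$image), nrm)
})

test_that("degraded phantoms are pulled back to the target profile", {
  ph <- small_phantom(seed = 3)
  prof <- stain_profile(ph$image)
  for (m in c("reddish", "greyish", "weak")) {
    dg <- degrade(ph, m, 0.8)
    nrm <- normalize_image(dg$image, prof)
    # re-estimate concentrations in the target basis
    cc <- matrix(compute_concentrations(rgb_to_od(nrm), prof$stains), ncol = 2)
    mask <- as.vector(detect_tissue(nrm))
    expect_lt(abs(quantile(cc[mask, 1], .99) / prof$scale_h - 1), 0.05,
              label = paste(m, "H scale"))
    expect_lt(abs(quantile(cc[mask, 2], .99) / prof$scale_e - 1), 0.05,
              label = paste(m, "E scale"))
    # background is pushed to near-white (contrast contract)
    bg <- !detect_tissue(nrm)
    for (c in 1:3) expect_gte(median(nrm[, , c][bg]), 250)
  }
})

test_that("normalization preserves concentration rank order", {
  ph <- small_phantom(seed = 8)
  target <- small_phantom(seed = 3)
  prof <- stain_profile(target$image)
  nrm <- normalize_image(ph$image, prof)
  # source-side H concentrations vs re-estimated ones on the output
  src <- matrix(stainnorm:::source_stats(ph$image)$conc, ncol = 2)
  out <- matrix(compute_concentrations(rgb_to_od(nrm), prof$stains), ncol = 2)
  mask <- which(as.vector(detect_tissue(ph$image)))
  set.seed(1)
  i <- sample(mask, 1e4, replace = TRUE)
  j <- sample(mask, 1e4, replace = TRUE)
  # compare pairs that differ beyond the quantization floor
  informative <- abs(src[i, 1] - src[j, 1]) > 0.02
  concordant <- sign(src[i, 1] - src[j, 1]) == sign(out[i, 1] - out[j, 1])
  expect_gte(mean(concordant[informative]), 0.99)
})

test_that("normalization propagates tissue and stain failures", {
  prof <- stain_profile(small_phantom(seed = 3)$image)
  blank <- array(255, c(128, 128, 3))
  expect_error(suppressWarnings(normalize_image(blank, prof)),
               class = "sn_insufficient_tissue_error")
  expect_error(normalize_image(small_phantom(seed = 3)$image, list()),
               class = "sn_validation_error")
})
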