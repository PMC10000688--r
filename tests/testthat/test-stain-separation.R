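ref_h <- c(0.65, 0.70, 0.29) / sqrt(sum(c(0.65, 0.70, 0.29)^2))
ref_e <- c(0.07, 0.99, 0.11) / sqrt(sum(c(0.07, 0.99, 0.11)^2))

# direct Beer-Lambert OD cloud with known stain vectors (no imaging)
synthetic_od <- function(n, sigma, seed = 1) {
  set.seed(seed)
  # mixture: near-pure H (nuclei), near-pure E (stroma), and blends
  grp <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  ch <- ifelse(grp == 1, runif(n, 0.4, 1), runif(n, 0, 0.1))
  ce <- ifelse(grp == 2, runif(n, 0.3, 0.8), runif(n, 0, 0.15))
  ce[grp == 3] <- runif(sum(grp == 3), 0.2, 0.6)
  ch[grp == 3] <- runif(sum(grp == 3), 0.2, 0.6)
  od <- cbind(ch, ce) %*% rbind(ref_h, ref_e) +
    matrix(rnorm(3 * n, 0, sigma), n, 3)
  list(od = array(pmax(od, 0), c(n, 1, 3)), conc = cbind(ch, ce))
}

test_that("stain_matrix validates geometry", {
  m <- stain_matrix(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  expect_equal(rowSums(m^2), c(H = 1, E = 1), tolerance = 1e-12)
  expect_error(stain_matrix(c(1, 0, 0), c(1, 1e-4, 0)),
               class = "sn_degenerate_stain_error")
  expect_error(stain_matrix(c(-0.1, 1, 0), c(0, 1, 0)),
               class = "sn_validation_error")
  expect_error(stain_matrix(c(0, 0, 0), c(0, 1, 0)),
               class = "sn_validation_error")
})

test_that("Macenko estimation recovers known stain vectors", {
  s <- synthetic_od(20000, sigma = 0.01)
  est <- estimate_stain_matrix(s$od)
  a_h <- acos(pmin(1, sum(est[1, ] * ref_h))) * 180 / pi
  a_e <- acos(pmin(1, sum(est[2, ] * ref_e))) * 180 / pi
  expect_lt(a_h, 5)
  expect_lt(a_e, 5)
  # H labeling rule: larger red-channel absorbance than E
  expect_gt(est[1, 1], est[2, 1])

  # permutation invariance: statistics are order-free
  set.seed(7)
  perm <- sample(20000)
  od_perm <- array(matrix(s$od, ncol = 3)[perm, ], c(20000, 1, 3))
  expect_equal(estimate_stain_matrix(od_perm), est, tolerance = 1e-9)
})

test_that("degenerate and insufficient inputs are refused", {
  # rank-1 cloud: a single pure stain
  ch <- runif(5000, 0.2, 1)
  od1 <- array(ch %*% t(ref_h), c(5000, 1, 3))
  expect_error(estimate_stain_matrix(od1), class = "sn_degenerate_stain_error")
  # fewer than 100 pixels above the OD-norm threshold
  s <- synthetic_od(99, sigma = 0)
  expect_error(estimate_stain_matrix(s$od),
               class = "sn_insufficient_tissue_error")
  expect_error(estimate_stain_matrix(array(0, c(50, 50, 3))),
               class = "sn_insufficient_tissue_error")
})

test_that("concentrations solve the noiseless separation exactly", {
  stains <- stain_matrix(ref_h, ref_e)
  od <- array(c(0.7, 0.3) %*% stains, c(1, 1, 3))
  cc <- compute_concentrations(od, stains)
  expect_equal(as.vector(cc), c(0.7, 0.3), tolerance = 1e-9)
  expect_equal(as.vector(compute_concentrations(array(0, c(2, 2, 3)), stains)),
               rep(0, 8))
})

test_that("nnls solver is non-negative and never worse than clipped pinv", {
  stains <- stain_matrix(ref_h, ref_e)
  set.seed(3)
  # off-wedge points force negative unconstrained solutions
  od <- array(abs(matrix(rnorm(300 * 3, 0.2, 0.2), ncol = 3)), c(300, 1, 3))
  c_pinv <- matrix(compute_concentrations(od, stains), ncol = 2)
  c_nnls <- matrix(compute_concentrations(od, stains, method = "nnls"), ncol = 2)
  expect_gte(min(c_nnls), 0)
  x <- matrix(od, ncol = 3)
  res <- function(cc) rowSums((x - cc %*% stains)^2)
  expect_true(all(res(c_nnls) <= res(c_pinv) + 1e-12))
})

test_that("reconstruction is monotone and inverts separation", {
  stains <- stain_matrix(ref_h, ref_e)
  expect_equal(as.vector(reconstruct(array(0, c(2, 2, 2)), stains)),
               rep(255, 12))
  # increasing cH at a pixel never brightens any channel
  base <- array(c(0.3, 0.2), c(1, 1, 2))
  more <- base; more[1, 1, 1] <- 0.8
  expect_true(all(reconstruct(more, stains) <= reconstruct(base, stains)))
  expect_error(reconstruct(array(-1, c(1, 1, 2)), stains),
               class = "sn_domain_error")

  # in-span round trip: reconstruct(compute_concentrations(x)) == x +/- 1
  s <- synthetic_od(2000, sigma = 0, seed = 9)
  img <- od_to_rgb(s$od)
  od2 <- rgb_to_od(img)
  rec <- reconstruct(compute_concentrations(od2, stains), stains)
  expect_lte(max(abs(rec - img)), 1)
})

test_that("separation survives 8-bit quantization within 0.02 OD", {
  stains <- stain_matrix(ref_h, ref_e)
  set.seed(11)
  n <- 5000
  # stay in the regime where 8-bit quantization costs < 0.02 OD: the
  # darkest channel must keep a transmitted intensity above ~12 levels
  conc <- cbind(runif(n, 0, 1), runif(n, 0, 0.6))
  img <- reconstruct(array(conc, c(n, 1, 2)), stains)
  cc <- matrix(compute_concentrations(rgb_to_od(img), stains), ncol = 2)
  expect_lte(max(abs(cc - conc)), 2e-2)
  # and recovery is essentially perfect in correlation
  expect_gt(cor(cc[, 1], conc[, 1]), 0.999)
  expect_gt(cor(cc[, 2], conc[, 2]), 0.999)
})
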