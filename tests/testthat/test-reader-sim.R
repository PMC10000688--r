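test_that("rating tables are deterministic and well-formed", {
  spec <- reader_study_spec(n_slides = 20, seed = 11)
  a <- simulate_reader_study(spec)
  expect_identical(a, simulate_reader_study(spec))
  expect_equal(nrow(a), 20 * 4)
  expect_true(all(a$quality %in% 1:10))
  expect_true(all(a$gg %in% 0:5))
  expect_true(all(a$confidence %in% 1:10))
  expect_true(all(a$time_s > 0))
  expect_equal(sort(unique(a$arm)), c("normalized", "original"))
})

test_that("latent-noise calibration hits the kappa target", {
  # closed-form curve is monotone decreasing in the latent noise
  p <- rep(1 / 6, 6)
  taus <- c(0.2, 0.5, 1, 2)
  ks <- sapply(taus, stainnorm:::expected_intra_kappa, gg_distribution = p)
  expect_true(all(diff(ks) < 0))

  # target 1 is the degenerate exact-rating limit
  s1 <- simulate_reader_study(reader_study_spec(
    n_slides = 50, intra_rater_kappa_target = 1, seed = 2))
  g <- function(p_, a_) s1$gg[s1$pathologist == p_ & s1$arm == a_]
  expect_identical(g("P1", "original"), g("P1", "normalized"))
  expect_equal(weighted_kappa(g("P1", "original"), g("P1", "normalized")), 1)

  # simulated intra-rater kappa lands near a non-trivial target
  big <- simulate_reader_study(reader_study_spec(
    n_slides = 4000, intra_rater_kappa_target = 0.85, seed = 3))
  gb <- function(p_, a_) big$gg[big$pathologist == p_ & big$arm == a_]
  k_hat <- weighted_kappa(gb("P1", "original"), gb("P1", "normalized"))
  expect_lt(abs(k_hat - 0.85), 0.04)
})

test_that("GG marginals converge to the specified case mix", {
  p <- c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05)
  tab <- simulate_reader_study(reader_study_spec(
    n_slides = 10000, gg_distribution = p,
    intra_rater_kappa_target = 1, seed = 4))
  one_arm <- tab[tab$pathologist == "P1" & tab$arm == "original", ]
  freq <- as.vector(table(factor(one_arm$gg, levels = 0:5))) / 10000
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(freq - p) <= 3 * se))
})

test_that("injected effects are recovered at study scale", {
  # quality shift +2: mean recovered median shift within +/- 0.5
  shifts <- sapply(1:40, function(s) {
    tab <- simulate_reader_study(reader_study_spec(
      n_slides = 93, quality_shift = 2, seed = s))
    q <- function(a_) tab$quality[tab$pathologist == "P1" & tab$arm == a_]
    median(q("normalized")) - median(q("original"))
  })
  expect_lt(abs(mean(shifts) - 2), 0.5)

  # time ratio multiplies the normalized-arm medians
  tab <- simulate_reader_study(reader_study_spec(
    n_slides = 2000, time_ratio = 0.75, seed = 5))
  tm <- function(p_, a_) median(tab$time_s[tab$pathologist == p_ & tab$arm == a_])
  expect_lt(abs(tm("P1", "normalized") / tm("P1", "original") - 0.75), 0.05)
})

test_that("rating CSV round trip validates its schema", {
  tab <- simulate_reader_study(reader_study_spec(n_slides = 10, seed = 1))
  f <- tempfile(fileext = ".csv")
  write_ratings(tab, f)
  back <- read_ratings(f)
  expect_equal(back, tab)
  broken <- tab[, setdiff(names(tab), "confidence")]
  f2 <- tempfile(fileext = ".csv")
  write.csv(broken, f2, row.names = FALSE)
  err <- tryCatch(read_ratings(f2), error = identity)
  expect_s3_class(err, "sn_format_error")
  expect_match(conditionMessage(err), "confidence")
})

test_that("study specs validate their parameters", {
  expect_error(reader_study_spec(n_slides = 1), class = "sn_validation_error")
  expect_error(reader_study_spec(gg_distribution = rep(0.2, 6)),
               class = "sn_validation_error")
  expect_error(reader_study_spec(time_ratio = 1.2),
               class = "sn_validation_error")
  expect_error(reader_study_spec(intra_rater_kappa_target = 0),
               class = "sn_validation_error")
})
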