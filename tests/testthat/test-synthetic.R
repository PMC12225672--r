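test_that("marker profiles have the expected shapes and normalization", {
  cfg <- synthetic_config(n_fractions = 6, seed = 1)
  M <- gen_marker_profiles(cfg)
  expect_equal(dim(M), c(6, 3))
  expect_equal(unname(colSums(M)), rep(1, 3), tolerance = 1e-12)
  expect_identical(unname(which.max(M[, "plastid"])), 1L)
  expect_identical(unname(which.max(M[, "vacuole"])), 6L)
  ratio <- max(M[, "cytosol"]) / min(M[, "cytosol"])
  expect_lt(ratio, cfg$flatness_bound)

  # delta-peaked shapes at n_fractions = 3 give an identity-like matrix
  cfg3 <- synthetic_config(
    n_fractions = 3,
    marker_shape_params = list(
      plastid = list(peak = 1, width = 0.05),
      cytosol = list(peak = 2, width = 0.05, amp = 1e6),
      vacuole = list(peak = 3, width = 0.05)),
    flatness_bound = Inf, seed = 1)
  M3 <- gen_marker_profiles(cfg3)
  expect_equal(unname(M3), diag(3), tolerance = 1e-3)
})

test_that("config validation rejects degenerate setups", {
  expect_error(synthetic_config(n_fractions = 2), "n_fractions")
  expect_error(synthetic_config(true_shares = list(x = c(0.5, 0.6, 0.2))),
               "sum to 1")
  expect_error(synthetic_config(noise_cv = -0.1), "non-negative")
  # two identical marker profiles are non-identifiable
  cfg <- synthetic_config(marker_shape_params = list(
    plastid = list(peak = 1, width = 0.9),
    cytosol = list(peak = 1, width = 0.9, amp = 1e9),
    vacuole = list(peak = 6, width = 0.9)), flatness_bound = Inf)
  expect_error(gen_marker_profiles(cfg), "identical|peak")
})

test_that("noiseless NAF samples are exact convex combinations", {
  shares <- list(sucrose = c(0.5, 0.3, 0.2))
  cfg <- synthetic_config(noise_cv = 0, true_shares = shares,
                          n_replicates = 2, seed = 9)
  fr <- gen_naf_samples(cfg)
  M <- attr(fr, "marker_profiles")
  expected <- as.numeric(M %*% c(0.5, 0.3, 0.2))
  for (s in unique(fr$sample)) {
    d <- fr[fr$sample == s, ]
    expect_equal(d$sucrose, expected, tolerance = 1e-12)
    expect_equal(d$marker_plastid, unname(M[, "plastid"]),
                 tolerance = 1e-12)
  }
  # pure-compartment metabolite equals that marker profile
  cfg1 <- synthetic_config(noise_cv = 0,
                           true_shares = list(x = c(1, 0, 0)),
                           n_replicates = 1, seed = 9)
  fr1 <- gen_naf_samples(cfg1)
  expect_equal(fr1$x, fr1$marker_plastid, tolerance = 1e-12)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- synthetic_config(noise_cv = 0.1, seed = 42)
  expect_identical(gen_naf_samples(cfg), gen_naf_samples(cfg))
  lk1 <- gen_leakage_series(40, 0.25, n = 5, seed = 42, noise_cv = 0.05)
  lk2 <- gen_leakage_series(40, 0.25, n = 5, seed = 42, noise_cv = 0.05)
  expect_identical(lk1, lk2)
  m1 <- gen_morphometry(morphometry_means_22C(), 0.1, 5, 42)
  m2 <- gen_morphometry(morphometry_means_22C(), 0.1, 5, 42)
  expect_identical(m1, m2)
  # and the caller's RNG stream is untouched
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(gen_naf_samples(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noisy replicate means converge to the noiseless profile", {
  cfg <- synthetic_config(noise_cv = 0.1, n_replicates = 20, seed = 5)
  fr <- gen_naf_samples(cfg)
  M <- attr(fr, "marker_profiles")
  clean <- as.numeric(M %*% cfg$true_shares$sucrose)
  obs <- tapply(fr$sucrose, fr$fraction, mean)
  se <- tapply(fr$sucrose, fr$fraction, stats::sd) / sqrt(20)
  expect_true(all(abs(as.numeric(obs) - clean) <= 3 * as.numeric(se)))
})

test_that("leakage generator hits the step limit and round-trips", {
  # slope -> Inf, midpoint 40: no injury at 30 min, full at 45 min
  lk <- gen_leakage_series(40, Inf, n = 2, seed = 1, noise_cv = 0)
  ti <- attr(lk, "true_injury")
  expect_equal(ti[["t30"]], 0)
  expect_equal(ti[["t45"]], 100)
  # EC pairs honour 0 < EC_initial <= EC_total
  expect_true(all(lk$ec_initial > 0 & lk$ec_initial <= lk$ec_total))
})

test_that("morphometry generator respects means and the simplex", {
  m <- gen_morphometry(morphometry_means_22C(), cv = 0, n = 3, seed = 1)
  expect_true(all(m$morphometry$leaf_height_mm == 0.187))
  expect_true(all(abs(rowSums(
    m$segmentation[, c("prop_plastid", "prop_cytosol",
                       "prop_vacuole")]) - 1) < 1e-12))
  # law of large numbers: sample mean within 1% of the configured mean
  big <- gen_morphometry(morphometry_means_22C(), cv = 0.1, n = 1000,
                         seed = 2)
  expect_equal(mean(big$morphometry$leaf_height_mm), 0.187,
               tolerance = 0.01)
  props <- big$segmentation[, c("prop_plastid", "prop_cytosol",
                                "prop_vacuole")]
  expect_true(all(abs(rowSums(props) - 1) < 1e-12))
})

test_that("written synthetic datasets round-trip with ground truth", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(noise_cv = 0, seed = 3)
  paths <- write_synthetic_dataset(cfg, dir)
  expect_true(all(file.exists(paths)))
  truth <- yaml::read_yaml(paths[["ground_truth"]])
  expect_equal(truth$seed, 3)
  expect_equal(unname(unlist(truth$true_shares$sucrose)),
               unname(cfg$true_shares$sucrose))
  fr <- read.delim(paths[["fractions"]])
  expect_equal(nrow(fr), cfg$n_fractions * cfg$n_replicates)
})
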