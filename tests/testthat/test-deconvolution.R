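test_that("normalize_profile scales to the simplex", {
  expect_equal(normalize_profile(c(2, 2, 4)), c(0.25, 0.25, 0.5))
  expect_equal(normalize_profile(c(0, 1, 0)), c(0, 1, 0))
  x <- c(1, 3, 6)
  expect_equal(normalize_profile(7 * x), normalize_profile(x))
  expect_error(normalize_profile(c(0, 0, 0), name = "UGPase"), "UGPase")
  expect_error(normalize_profile(c(-1, 2)), "negative")
})

test_that("exact convex combinations are recovered to 1e-9", {
  set.seed(101)
  M <- gen_marker_profiles(synthetic_config())
  for (i in 1:20) {
    s_true <- random_simplex_point()
    m <- as.numeric(M %*% s_true)
    fit <- deconvolve_shares(m, M)
    expect_equal(unname(fit$shares), s_true, tolerance = 1e-9)
    expect_lt(fit$residual_norm, 1e-9)
  }
  # pure compartment: metabolite equal to one marker column
  fit <- deconvolve_shares(M[, "plastid"], M)
  expect_equal(unname(fit$shares), c(1, 0, 0), tolerance = 1e-9)
})

test_that("solution matches the exhaustive simplex grid search", {
  set.seed(202)
  for (i in 1:10) {
    prob <- random_deconv_problem(6)
    fit <- deconvolve_shares(prob$m, prob$M)
    oracle <- oracle_simplex_lsq(prob$M, prob$m)
    # the exact solver can only do better than the grid
    expect_lte(fit$residual_norm, oracle$rn + 1e-9)
    expect_lt(oracle$rn - fit$residual_norm, 5e-3)
  }
  # and on an 8-fraction problem
  prob <- random_deconv_problem(8)
  fit <- deconvolve_shares(prob$m, prob$M)
  oracle <- oracle_simplex_lsq(prob$M, prob$m)
  expect_lte(fit$residual_norm, oracle$rn + 1e-9)
  expect_lt(oracle$rn - fit$residual_norm, 5e-3)
})

test_that("degenerate marker matrices are rejected", {
  M <- gen_marker_profiles(synthetic_config())
  bad <- cbind(M[, 1], M[, 1], M[, 3])
  expect_error(deconvolve_shares(M[, 1], bad), "rank")
  expect_error(deconvolve_shares(c(0.5, 0.5), M[1:2, ]),
               "fewer fractions")
})

test_that("shares are invariant to consistent fraction permutation", {
  set.seed(303)
  prob <- random_deconv_problem(6)
  fit1 <- deconvolve_shares(prob$m, prob$M)
  perm <- sample(6)
  fit2 <- deconvolve_shares(prob$m[perm], prob$M[perm, ])
  expect_equal(fit1$shares, fit2$shares, tolerance = 1e-9)
  expect_equal(fit1$residual_norm, fit2$residual_norm, tolerance = 1e-12)
})

test_that("replicate profiles deconvolve to the configured truth", {
  cfg <- synthetic_config(noise_cv = 0, seed = 6)
  fr <- gen_naf_samples(cfg)
  res <- deconvolve_profiles(fr)
  for (met in names(cfg$true_shares)) {
    got <- unlist(res[res$metabolite == met,
                      c("share_plastid", "share_cytosol",
                        "share_vacuole")])
    expect_equal(unname(got), unname(cfg$true_shares[[met]]),
                 tolerance = 1e-9)
  }
  expect_true(all(abs(rowSums(res[, c("share_plastid", "share_cytosol",
                                      "share_vacuole")]) - 1) < 1e-9))
})

test_that("bootstrap intervals are seeded, degenerate for identical reps", {
  cfg <- synthetic_config(noise_cv = 0, n_replicates = 4, seed = 8)
  fr <- gen_naf_samples(cfg)
  b1 <- bootstrap_shares(fr, n_boot = 50, seed = 1)
  b2 <- bootstrap_shares(fr, n_boot = 50, seed = 1)
  expect_identical(b1, b2)
  # noiseless replicates are identical -> zero-width intervals at truth
  expect_equal(b1$lower, b1$upper, tolerance = 1e-12)
  suc <- b1[b1$metabolite == "sucrose", ]
  expect_equal(suc$lower[match(c("plastid", "cytosol", "vacuole"),
                               suc$compartment)],
               unname(cfg$true_shares$sucrose), tolerance = 1e-9)
  # noisy case: intervals contain the truth
  cfgn <- synthetic_config(noise_cv = 0.05, n_replicates = 6, seed = 8)
  bn <- bootstrap_shares(gen_naf_samples(cfgn), n_boot = 100, seed = 2)
  for (met in names(cfgn$true_shares)) {
    d <- bn[bn$metabolite == met, ]
    truth <- cfgn$true_shares[[met]]
    hit <- mapply(function(cp, lo, hi)
      truth[[cp]] >= lo - 0.05 && truth[[cp]] <= hi + 0.05,
      d$compartment, d$lower, d$upper)
    expect_true(all(hit))
  }
  expect_error(bootstrap_shares(fr, n_boot = 0, seed = 1), "n_boot")
})

test_that("fit diagnostics report perfect and poor reconstructions", {
  M <- gen_marker_profiles(synthetic_config())
  m <- as.numeric(M %*% c(0.5, 0.3, 0.2))
  fit <- deconvolve_shares(m, M)
  diag <- fit_diagnostics(fit)
  expect_equal(diag$residuals, rep(0, 6), tolerance = 1e-9)
  expect_equal(diag$r2, 1, tolerance = 1e-9)
  # a profile unrelated to any marker mixture triggers the warning
  set.seed(404)
  noise <- normalize_profile(c(0.9, 0.05, 0.9, 0.05, 0.9, 0.05))
  fit_noise <- deconvolve_shares(noise, M, metabolite = "junk")
  expect_warning(fit_diagnostics(fit_noise, warn_r2 = 0.9), "junk")
  # oracle and module agree on the residual norm they report
  oracle <- oracle_simplex_lsq(M, noise)
  expect_equal(fit_noise$residual_norm, oracle$rn, tolerance = 5e-3)
})
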