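#' Normalize a fraction profile to a relative distribution
#'
#' Scales non-negative per-fraction values so they sum to one, turning raw
#' marker activities or metabolite abundances into relative distributions
#' over the density gradient.
#'
#' @param x Non-negative numeric vector of per-fraction values.
#' @param name Label used in error messages (a marker or metabolite name).
#' @return Numeric vector summing to 1, proportional to `x`.
#' @examples
#' normalize_profile(c(2, 2, 4))  # 0.25 0.25 0.50
#' @export
normalize_profile <- function(x, name = "profile") {
  if (any(!is.finite(x)) || any(x < 0))
    stop("'", name, "' contains negative or non-finite values",
         call. = FALSE)
  s <- sum(x)
  if (s <= 0)
    stop("'", name, "' is all zero and cannot be normalized",
         call. = FALSE)
  x / s
}

# Exact minimizer of ||M s - m||_2 over the probability simplex, by
# enumerating the faces of the simplex (active-set). With K compartments
# there are 2^K - 1 candidate supports; each gives an equality-constrained
# least-squares problem solved through its KKT system. Ties in residual
# norm are broken by the minimum-norm solution.
simplex_lsq <- function(M, m, tol = 1e-10) {
  K <- ncol(M)
  best <- NULL
  supports <- unlist(lapply(seq_len(K), function(k)
    utils::combn(K, k, simplify = FALSE)), recursive = FALSE)
  for (A in supports) {
    MA <- M[, A, drop = FALSE]
    k <- length(A)
    KKT <- rbind(cbind(2 * crossprod(MA), rep(1, k)),
                 c(rep(1, k), 0))
    rhs <- c(2 * crossprod(MA, m), 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    sA <- sol[seq_len(k)]
    if (any(sA < -1e-9)) next
    s <- numeric(K)
    s[A] <- pmax(sA, 0)
    s <- s / sum(s)
    rn <- sqrt(sum((M %*% s - m)^2))
    if (is.null(best) || rn < best$rn - tol ||
        (rn < best$rn + tol && sum(s^2) < sum(best$s^2) - tol))
      best <- list(s = s, rn = rn)
  }
  if (is.null(best))
    stop("simplex-constrained least squares found no feasible solution",
         call. = FALSE)
  best
}

#' Deconvolve a metabolite profile into compartment shares
#'
#' Estimates the relative distribution of a metabolite over plastid,
#' cytosol and vacuole from its density-fraction profile and the three
#' marker-enzyme profiles. The estimator is constrained least squares on
#' the probability simplex: it returns the share vector `s` minimizing
#' `||M s - m||_2` subject to `s >= 0`, `sum(s) = 1`, where the columns
#' of `M` are the normalized marker distributions and `m` the normalized
#' metabolite distribution. An exact convex combination is recovered to
#' numerical precision.
#'
#' @param metabolite_distribution Numeric vector over fractions (raw or
#'   normalized; it is normalized internally).
#' @param marker_distributions Matrix with one column per compartment
#'   marker (plastid, cytosol, vacuole order), same fractions as the
#'   metabolite.
#' @param metabolite Label for messages.
#' @return List of class `"compartment_shares"` with `shares` (named,
#'   sums to 1), `residual_norm`, and `fitted` values.
#' @examples
#' M <- gen_marker_profiles(synthetic_config())
#' m <- as.numeric(M %*% c(0.5, 0.3, 0.2))
#' deconvolve_shares(m, M)$shares
#' @export
deconvolve_shares <- function(metabolite_distribution, marker_distributions,
                              metabolite = "metabolite") {
  M <- as.matrix(marker_distributions)
  if (nrow(M) < ncol(M))
    stop("fewer fractions than compartments: deconvolution is ",
         "underdetermined", call. = FALSE)
  if (length(metabolite_distribution) != nrow(M))
    stop("metabolite and marker profiles cover different fractions",
         call. = FALSE)
  if (qr(M)$rank < ncol(M))
    stop("marker matrix is rank-deficient; compartments are not ",
         "identifiable", call. = FALSE)
  M <- apply(M, 2, normalize_profile, name = "marker")
  m <- normalize_profile(metabolite_distribution, name = metabolite)
  fit <- simplex_lsq(M, m)
  shares <- stats::setNames(fit$s, colnames(marker_distributions) %||%
                              compartments())
  structure(list(shares = shares,
                 residual_norm = fit$rn,
                 fitted = as.numeric(M %*% fit$s),
                 observed = m,
                 metabolite = metabolite),
            class = "compartment_shares")
}

#' @export
print.compartment_shares <- function(x, ...) {
  cat("Compartment shares for", x$metabolite, "\n")
  print(round(x$shares, 4))
  cat(sprintf("residual norm: %.3e\n", x$residual_norm))
  invisible(x)
}

# Deconvolve every metabolite of one replicate's fraction profile.
deconvolve_replicate <- function(df, metabolites) {
  M <- as.matrix(df[, c("marker_plastid", "marker_cytosol",
                        "marker_vacuole")])
  colnames(M) <- compartments()
  out <- lapply(metabolites, function(met)
    deconvolve_shares(df[[met]], M, metabolite = met))
  stats::setNames(out, metabolites)
}

#' Deconvolve a replicate set of NAF fraction profiles
#'
#' Runs the simplex-constrained deconvolution per replicate gradient and
#' aggregates shares across replicates by the median (renormalized to the
#' simplex), the per-sample-gradient analysis strategy.
#'
#' @param profiles Data frame in `fractions.tsv` layout: columns
#'   `sample`, `fraction`, `density`, `marker_plastid`, `marker_cytosol`,
#'   `marker_vacuole`, plus one column per metabolite.
#' @param metabolites Metabolite column names; defaults to all columns
#'   after the marker columns.
#' @return Data frame (metabolite, share_plastid, share_cytosol,
#'   share_vacuole, residual_norm, r2, n_replicates) with attribute
#'   `per_replicate` holding the replicate-level share table.
#' @examples
#' fr <- gen_naf_samples(synthetic_config(noise_cv = 0, seed = 1))
#' deconvolve_profiles(fr)
#' @export
deconvolve_profiles <- function(profiles, metabolites = NULL) {
  fixed <- c("sample", "fraction", "density", "marker_plastid",
             "marker_cytosol", "marker_vacuole")
  missing <- setdiff(fixed, names(profiles))
  if (length(missing))
    stop("profiles lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  metabolites <- metabolites %||% setdiff(names(profiles), fixed)
  if (!length(metabolites))
    stop("no metabolite columns found", call. = FALSE)
  reps <- split(profiles, profiles$sample)
  per_rep <- do.call(rbind, lapply(names(reps), function(s) {
    d <- reps[[s]]
    d <- d[order(d$fraction), ]
    if (any(diff(d$density) <= 0))
      stop("densities must be strictly increasing within sample ", s,
           call. = FALSE)
    fits <- deconvolve_replicate(d, metabolites)
    do.call(rbind, lapply(metabolites, function(met) {
      f <- fits[[met]]
      data.frame(sample = s, metabolite = met,
                 share_plastid = f$shares[["plastid"]],
                 share_cytosol = f$shares[["cytosol"]],
                 share_vacuole = f$shares[["vacuole"]],
                 residual_norm = f$residual_norm)
    }))
  }))
  rownames(per_rep) <- NULL
  agg <- do.call(rbind, lapply(metabolites, function(met) {
    d <- per_rep[per_rep$metabolite == met, ]
    med <- c(stats::median(d$share_plastid),
             stats::median(d$share_cytosol),
             stats::median(d$share_vacuole))
    med <- med / sum(med)
    data.frame(metabolite = met,
               share_plastid = med[1], share_cytosol = med[2],
               share_vacuole = med[3],
               residual_norm = stats::median(d$residual_norm),
               n_replicates = nrow(d))
  }))
  rownames(agg) <- NULL
  attr(agg, "per_replicate") <- per_rep
  agg
}

#' Bootstrap uncertainty for deconvolved compartment shares
#'
#' Resamples replicate gradients with replacement, re-aggregates the
#' per-replicate shares, and reports per-share quantile intervals.
#'
#' @param profiles Fraction-profile data frame (see
#'   [deconvolve_profiles()]); needs at least 2 replicates.
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param probs Quantiles reported (default 2.5 % and 97.5 %).
#' @param metabolites Optional metabolite subset.
#' @return Data frame (metabolite, compartment, lower, upper, level).
#' @export
bootstrap_shares <- function(profiles, n_boot, seed,
                             probs = c(0.025, 0.975),
                             metabolites = NULL) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  reps <- unique(profiles$sample)
  if (length(reps) < 2)
    stop("bootstrap requires at least 2 replicate profiles",
         call. = FALSE)
  base <- deconvolve_profiles(profiles, metabolites)
  per_rep <- attr(base, "per_replicate")
  mets <- base$metabolite
  boot <- with_seed(derive_seed(seed, "bootstrap"), {
    draws <- array(NA_real_, dim = c(n_boot, length(mets), 3),
                   dimnames = list(NULL, mets, compartments()))
    for (b in seq_len(n_boot)) {
      take <- sample(reps, length(reps), replace = TRUE)
      d <- do.call(rbind, lapply(take, function(s)
        per_rep[per_rep$sample == s, ]))
      for (met in mets) {
        dm <- d[d$metabolite == met, ]
        med <- c(stats::median(dm$share_plastid),
                 stats::median(dm$share_cytosol),
                 stats::median(dm$share_vacuole))
        draws[b, met, ] <- med / sum(med)
      }
    }
    draws
  })
  out <- do.call(rbind, lapply(mets, function(met)
    do.call(rbind, lapply(compartments(), function(cp) {
      q <- stats::quantile(boot[, met, cp], probs, names = FALSE)
      data.frame(metabolite = met, compartment = cp,
                 lower = q[1], upper = q[2],
                 level = diff(probs))
    }))))
  rownames(out) <- NULL
  out
}

#' Reconstruction diagnostics for a deconvolution fit
#'
#' Reports per-fraction residuals `m - M s` and the coefficient of
#' determination of the reconstruction. A pure-noise metabolite (profile
#' unrelated to any marker) yields a low R-squared; values below
#' `warn_r2` trigger a warning.
#'
#' @param shares A `"compartment_shares"` fit from [deconvolve_shares()].
#' @param warn_r2 Warning threshold on R-squared (default 0.5).
#' @return List with `residuals`, `r2`, `residual_norm`.
#' @export
fit_diagnostics <- function(shares, warn_r2 = 0.5) {
  stopifnot(inherits(shares, "compartment_shares"))
  res <- shares$observed - shares$fitted
  sst <- sum((shares$observed - mean(shares$observed))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  if (is.finite(r2) && r2 < warn_r2)
    warning(sprintf(
      "poor reconstruction for %s (R^2 = %.3f < %.2f): profile may not ",
      shares$metabolite, r2, warn_r2),
      "be a mixture of the marker compartments", call. = FALSE)
  list(residuals = res, r2 = r2, residual_norm = shares$residual_norm)
}
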