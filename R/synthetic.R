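#' Configuration for the synthetic NAF dataset generator
#'
#' Bundles every tunable of the synthetic-data module: the density-gradient
#' geometry, the true subcellular shares to be recovered, the shapes of the
#' three marker-enzyme profiles, the multiplicative noise level and the seed.
#' The generated data emulate non-aqueous fractionation (NAF) of lyophilized
#' leaf tissue: a plastid marker (pyrophosphatase) peaking in the lightest
#' fraction, a vacuolar marker (acid phosphatase) peaking in the densest, a
#' near-flat cytosolic marker (UGPase), and metabolite profiles that are
#' convex combinations of the three.
#'
#' @param n_fractions Number of density steps (default 6, densities
#'   1.35--1.60 g/cm^3 in 0.05 steps).
#' @param densities Fraction densities in g/cm^3, strictly increasing;
#'   defaults to an equally spaced grid from 1.35 to 1.60.
#' @param n_replicates Number of replicate gradients.
#' @param true_shares Named list mapping each metabolite to a length-3
#'   non-negative vector (plastid, cytosol, vacuole) summing to 1.
#' @param marker_shape_params List with entries `plastid`, `cytosol`,
#'   `vacuole`; each a list with `peak` (fraction index, may be fractional)
#'   and `width` (Gaussian SD in fraction-index units); `cytosol`
#'   additionally takes `amp`, the bump height on top of a flat baseline.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise applied per cell of the fraction matrix; 0 disables noise.
#' @param flatness_bound Maximum allowed max/min ratio of the cytosolic
#'   marker profile; `Inf` disables the check.
#' @param seed Integer seed; all generators derive private substreams
#'   from it.
#'
#' @return An object of class `"naf_config"`.
#' @examples
#' cfg <- synthetic_config(noise_cv = 0, seed = 1)
#' cfg$true_shares$sucrose
#' @export
synthetic_config <- function(n_fractions = 6L,
                             densities = NULL,
                             n_replicates = 4L,
                             true_shares = list(
                               sucrose  = c(0.20, 0.15, 0.65),
                               glucose  = c(0.10, 0.20, 0.70),
                               fructose = c(0.15, 0.25, 0.60)),
                             marker_shape_params = list(
                               plastid = list(peak = 1, width = 0.9),
                               cytosol = list(peak = 2.5, width = 1.5,
                                              amp = 0.35),
                               vacuole = list(peak = n_fractions,
                                              width = 0.9)),
                             noise_cv = 0.05,
                             flatness_bound = 3,
                             seed = 1L) {
  n_fractions <- as.integer(n_fractions)
  if (n_fractions < 3L)
    stop("n_fractions must be >= 3 (one fraction per compartment marker)",
         call. = FALSE)
  if (is.null(densities))
    densities <- seq(1.35, 1.60, length.out = n_fractions)
  if (length(densities) != n_fractions || any(diff(densities) <= 0))
    stop("densities must be strictly increasing, one per fraction",
         call. = FALSE)
  assert_scalar_number(noise_cv, "noise_cv", nonneg = TRUE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  for (m in names(true_shares)) {
    s <- true_shares[[m]]
    if (length(s) != 3L)
      stop("true_shares[['", m, "']] must have 3 entries", call. = FALSE)
    check_simplex(s, tol = 1e-12, name = paste0("true_shares[['", m, "']]"))
    true_shares[[m]] <- stats::setNames(as.numeric(s), compartments())
  }
  structure(list(n_fractions = n_fractions,
                 densities = as.numeric(densities),
                 n_replicates = as.integer(n_replicates),
                 true_shares = true_shares,
                 marker_shape_params = marker_shape_params,
                 noise_cv = noise_cv,
                 flatness_bound = flatness_bound,
                 seed = as.integer(seed)),
            class = "naf_config")
}

#' @export
print.naf_config <- function(x, ...) {
  cat("Synthetic NAF configuration\n")
  cat(sprintf("  fractions:   %d (rho %.2f-%.2f g/cm^3)\n", x$n_fractions,
              min(x$densities), max(x$densities)))
  cat(sprintf("  replicates:  %d\n", x$n_replicates))
  cat(sprintf("  metabolites: %s\n", paste(names(x$true_shares),
                                           collapse = ", ")))
  cat(sprintf("  noise CV:    %g   seed: %d\n", x$noise_cv, x$seed))
  invisible(x)
}

#' Generate the three marker-enzyme fraction profiles
#'
#' Builds normalized relative distributions over density fractions for the
#' plastidial, cytosolic and vacuolar marker enzymes. Plastid and vacuole
#' markers are discretized Gaussian bumps anchored at the lightest and
#' densest fraction respectively; the cytosolic marker is a flat baseline
#' with a small bump near the second/third fraction, mirroring the
#' qualitative behaviour of pyrophosphatase, acid phosphatase and UGPase
#' on heptane-tetrachlorethylene gradients.
#'
#' @param config A [synthetic_config()] object.
#' @return A `n_fractions x 3` matrix with columns `plastid`, `cytosol`,
#'   `vacuole`; each column sums to 1.
#' @examples
#' M <- gen_marker_profiles(synthetic_config())
#' colSums(M)  # all 1
#' @export
gen_marker_profiles <- function(config) {
  stopifnot(inherits(config, "naf_config"))
  n <- config$n_fractions
  idx <- seq_len(n)
  shp <- config$marker_shape_params
  bump <- function(peak, width) {
    w <- max(width, 1e-8)
    exp(-(idx - peak)^2 / (2 * w^2))
  }
  plastid <- bump(shp$plastid$peak %||% 1, shp$plastid$width %||% 0.9)
  vacuole <- bump(shp$vacuole$peak %||% n, shp$vacuole$width %||% 0.9)
  amp <- shp$cytosol$amp %||% 0.35
  cytosol <- 1 + amp * bump(shp$cytosol$peak %||% 2.5,
                            shp$cytosol$width %||% 1.5)
  M <- cbind(plastid = plastid / sum(plastid),
             cytosol = cytosol / sum(cytosol),
             vacuole = vacuole / sum(vacuole))
  rownames(M) <- sprintf("F%d", idx)
  if (which.max(M[, "plastid"]) != 1L)
    stop("plastid marker must peak in the lightest fraction", call. = FALSE)
  if (which.max(M[, "vacuole"]) != n)
    stop("vacuolar marker must peak in the densest fraction", call. = FALSE)
  ratio <- max(M[, "cytosol"]) / min(M[, "cytosol"])
  if (is.finite(config$flatness_bound) && ratio > config$flatness_bound)
    stop(sprintf(
      "cytosolic marker max/min ratio %.2f exceeds flatness bound %.2f",
      ratio, config$flatness_bound), call. = FALSE)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
    if (max(abs(M[, pair[1]] - M[, pair[2]])) < 1e-8)
      stop("two marker profiles are identical; deconvolution would be ",
           "non-identifiable", call. = FALSE)
  M
}

#' Ground truth attached to a synthetic dataset
#'
#' Collects the quantities a generated dataset was built from, so that
#' downstream estimates can be compared against them: true shares per
#' metabolite, true compartment volumes, the injury-curve parameters and
#' the seed. Regeneration with the same config is bit-identical.
#'
#' @param config A [synthetic_config()] object.
#' @param morpho_means Condition means (see [morphometry_means_22C()])
#'   from which the true compartment volumes are derived through the
#'   volumetric chain; ignored if `true_volumes` is given.
#' @param true_volumes Optional named numeric vector of compartment
#'   volumes in mL/gDW (plastid, cytosol, vacuole) overriding the
#'   derived values.
#' @param injury_midpoint,injury_slope Logistic injury-curve parameters
#'   (minutes, 1/minutes).
#' @return An object of class `"naf_ground_truth"`.
#' @export
ground_truth <- function(config,
                         morpho_means = morphometry_means_22C(),
                         true_volumes = NULL,
                         injury_midpoint = 40, injury_slope = 0.25) {
  stopifnot(inherits(config, "naf_config"))
  if (is.null(true_volumes)) {
    dv <- disc_volume(morpho_means$disc_radius_mm,
                      morpho_means$leaf_height_mm)
    vg <- volume_per_gdw(dv, morpho_means$disc_dry_weight_mg)
    cm <- cell_material_volume(vg, porosity = morpho_means$porosity)
    true_volumes <- compartment_volumes(cm, morpho_means$proportions)
  }
  structure(list(true_shares = config$true_shares,
                 true_volumes = true_volumes,
                 injury = c(midpoint = injury_midpoint,
                            slope = injury_slope),
                 seed = config$seed),
            class = "naf_ground_truth")
}

#' Generate replicate NAF fraction profiles with known shares
#'
#' Each metabolite's noiseless profile is the convex combination of the
#' marker profiles weighted by its true shares; multiplicative lognormal
#' noise with the configured CV is then applied per cell (markers and
#' metabolites alike). The lognormal is mean-one, so replicate means
#' converge to the noiseless profile.
#'
#' @param config A [synthetic_config()] object.
#' @param truth Optional [ground_truth()]; defaults to
#'   `ground_truth(config)`.
#' @return A data frame in `fractions.tsv` layout (sample, fraction,
#'   density, marker_plastid, marker_cytosol, marker_vacuole, one column
#'   per metabolite), with attributes `ground_truth` and
#'   `marker_profiles`.
#' @examples
#' fr <- gen_naf_samples(synthetic_config(noise_cv = 0, seed = 7))
#' head(fr)
#' @export
gen_naf_samples <- function(config, truth = ground_truth(config)) {
  stopifnot(inherits(config, "naf_config"))
  M <- gen_marker_profiles(config)
  n <- config$n_fractions
  mets <- names(config$true_shares)
  cv <- config$noise_cv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noisify <- function(x) {
    if (sdlog == 0) return(x)
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  rows <- with_seed(derive_seed(config$seed, "naf"), {
    out <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      df <- data.frame(sample = sprintf("rep%02d", r),
                       fraction = seq_len(n),
                       density = config$densities)
      df$marker_plastid <- noisify(M[, "plastid"])
      df$marker_cytosol <- noisify(M[, "cytosol"])
      df$marker_vacuole <- noisify(M[, "vacuole"])
      for (m in mets) {
        clean <- as.numeric(M %*% config$true_shares[[m]])
        df[[m]] <- noisify(clean)
      }
      out[[r]] <- df
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "ground_truth") <- truth
  attr(res, "marker_profiles") <- M
  res
}

#' Generate synthetic electrolyte-leakage conductivity series
#'
#' Emulates the paired-conductivity assay: leaf discs heated for
#' increasing durations, conductivity read after overnight shaking
#' (EC_initial) and again after boiling (EC_total). The expected index of
#' injury follows a logistic curve in exposure time, anchored so that the
#' unheated reference (t = 0) carries zero injury; the fractional release
#' at t = 0 is `r0_base`.
#'
#' @param damage_midpoint Logistic midpoint in minutes.
#' @param slope Logistic steepness in 1/minutes; `Inf` gives a step.
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @param timepoints Heat-exposure durations in minutes; must include 0.
#' @param r0_base Fractional electrolyte release of the unheated sample.
#' @param ec_total_mean Mean total conductivity in uS/cm after boiling.
#' @param noise_cv CV of multiplicative lognormal noise on EC_total and
#'   on the injury fraction scale; 0 disables noise.
#' @return Data frame (replicate, duration_min, ec_initial, ec_total)
#'   with attribute `true_injury` giving the noiseless injury (%) per
#'   timepoint.
#' @examples
#' lk <- gen_leakage_series(40, 0.25, n = 6, seed = 3, noise_cv = 0)
#' attr(lk, "true_injury")
#' @export
gen_leakage_series <- function(damage_midpoint, slope, n, seed,
                               timepoints = c(0, 30, 45, 60),
                               r0_base = 0.15, ec_total_mean = 800,
                               noise_cv = 0) {
  assert_scalar_number(damage_midpoint, "damage_midpoint", positive = TRUE)
  if (!identical(slope, Inf))
    assert_scalar_number(slope, "slope", positive = TRUE)
  if (!0 %in% timepoints)
    stop("timepoints must include the unheated reference t = 0",
         call. = FALSE)
  if (r0_base <= 0 || r0_base >= 1)
    stop("r0_base must lie in (0, 1)", call. = FALSE)
  logistic <- function(t) {
    if (identical(slope, Inf)) as.numeric(t > damage_midpoint)
    else 1 / (1 + exp(-slope * (t - damage_midpoint)))
  }
  # Rescale so injury is exactly 0 at t = 0 (the reference defines R_0).
  l0 <- logistic(0)
  injury <- function(t) 100 * (logistic(t) - l0) / (1 - l0)
  true_inj <- injury(timepoints)
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  res <- with_seed(derive_seed(seed, "leakage"), {
    grid <- expand.grid(replicate = seq_len(n), duration_min = timepoints)
    grid <- grid[order(grid$replicate, grid$duration_min), ]
    ec_tot <- rep(ec_total_mean, nrow(grid))
    if (sdlog > 0)
      ec_tot <- ec_tot * stats::rlnorm(nrow(grid), -sdlog^2 / 2, sdlog)
    id <- injury(grid$duration_min)
    if (sdlog > 0) {
      jitter <- stats::rnorm(nrow(grid), 0, noise_cv * 100)
      id <- pmin(pmax(id + jitter, 0), 100)
    }
    r_t <- r0_base + (1 - r0_base) * id / 100
    data.frame(replicate = grid$replicate,
               duration_min = grid$duration_min,
               ec_initial = r_t * ec_tot,
               ec_total = ec_tot)
  })
  rownames(res) <- NULL
  attr(res, "true_injury") <- stats::setNames(true_inj,
                                              paste0("t", timepoints))
  res
}

#' Generate synthetic leaf morphometry and segmentation samples
#'
#' Scatters per-sample morphometric measurements (disc radius, leaf
#' height, disc dry weight) and segmentation class proportions around
#' supplied condition means: values are Gaussian with the given CV,
#' truncated at zero, and class proportions are renormalized to the
#' simplex after jittering.
#'
#' @param condition_means List with numeric entries `disc_radius_mm`,
#'   `leaf_height_mm`, `disc_dry_weight_mg`, `porosity`, and `proportions`
#'   (named vector over plastid/cytosol/vacuole summing to 1).
#' @param cv Coefficient of variation; 0 returns the means exactly.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return List with data frames `morphometry` (sample, disc_radius_mm,
#'   leaf_height_mm, disc_dry_weight_mg) and `segmentation` (sample,
#'   porosity, prop_plastid, prop_cytosol, prop_vacuole).
#' @examples
#' m22 <- morphometry_means_22C()
#' gen_morphometry(m22, cv = 0, n = 2, seed = 1)$morphometry
#' @export
gen_morphometry <- function(condition_means, cv, n, seed) {
  req <- c("disc_radius_mm", "leaf_height_mm", "disc_dry_weight_mg",
           "porosity", "proportions")
  missing <- setdiff(req, names(condition_means))
  if (length(missing))
    stop("condition_means lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  check_simplex(condition_means$proportions, tol = 1e-3,
                name = "compartment proportions")
  assert_scalar_number(cv, "cv", nonneg = TRUE)
  jitter_pos <- function(mu, k) {
    if (cv == 0) return(rep(mu, k))
    pmax(stats::rnorm(k, mu, cv * mu), mu * 1e-6)
  }
  with_seed(derive_seed(seed, "morphometry"), {
    morph <- data.frame(
      sample = sprintf("s%02d", seq_len(n)),
      disc_radius_mm = jitter_pos(condition_means$disc_radius_mm, n),
      leaf_height_mm = jitter_pos(condition_means$leaf_height_mm, n),
      disc_dry_weight_mg = jitter_pos(condition_means$disc_dry_weight_mg, n))
    props <- t(vapply(seq_len(n), function(i) {
      p <- jitter_pos_vec(condition_means$proportions, cv)
      p / sum(p)
    }, numeric(3)))
    colnames(props) <- paste0("prop_", compartments())
    seg <- data.frame(
      sample = morph$sample,
      porosity = pmin(jitter_pos(condition_means$porosity, n), 0.95))
    seg <- cbind(seg, as.data.frame(props))
    list(morphometry = morph, segmentation = seg)
  })
}

# vectorized truncated-Gaussian jitter for a proportion vector
jitter_pos_vec <- function(mu, cv) {
  if (cv == 0) return(mu)
  pmax(stats::rnorm(length(mu), mu, cv * mu), mu * 1e-6)
}

#' Condition means for the control (22 degree) leaf measurement set
#'
#' Published condition means for 4-week rosette leaves grown at 22 C:
#' disc radius 4 mm, leaf height 0.187 mm, disc dry weight 0.622 mg,
#' SBF-SEM porosity 27.8 %, and compartment proportions 13.89 % plastid,
#' 3.51 % cytosol, 82.6 % vacuole.
#'
#' @return List suitable for [gen_morphometry()].
#' @export
morphometry_means_22C <- function() {
  list(disc_radius_mm = 4, leaf_height_mm = 0.187,
       disc_dry_weight_mg = 0.622, porosity = 0.278,
       proportions = c(plastid = 0.1389, cytosol = 0.0351,
                       vacuole = 0.8260))
}

#' Condition means for the heat-acclimated (7 d at 34 degree) measurement set
#'
#' @return List suitable for [gen_morphometry()]; leaf height 0.138 mm,
#'   dry weight 0.645 mg, porosity 22.9 %, proportions 13.65 / 3.63 /
#'   82.72 %.
#' @export
morphometry_means_34C <- function() {
  list(disc_radius_mm = 4, leaf_height_mm = 0.138,
       disc_dry_weight_mg = 0.645, porosity = 0.229,
       proportions = c(plastid = 0.1365, cytosol = 0.0363,
                       vacuole = 0.8272))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the tab-separated tables every downstream stage reads
#' (`fractions.tsv`, `leakage.tsv`, `morphometry.tsv`,
#' `segmentation.tsv`) plus `ground_truth.yaml` holding the generating
#' parameters.
#'
#' @param config A [synthetic_config()] object.
#' @param outdir Output directory (created if absent).
#' @param leakage_midpoint,leakage_slope Injury-curve parameters.
#' @param morpho_means Condition means for [gen_morphometry()].
#' @param morpho_cv,n_leakage,n_morpho Sampling settings.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_dataset <- function(config, outdir,
                                    leakage_midpoint = 40,
                                    leakage_slope = 0.25,
                                    morpho_means = morphometry_means_22C(),
                                    morpho_cv = 0, n_leakage = 6,
                                    n_morpho = 6) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- ground_truth(config, morpho_means = morpho_means,
                        injury_midpoint = leakage_midpoint,
                        injury_slope = leakage_slope)
  fr <- gen_naf_samples(config, truth)
  lk <- gen_leakage_series(leakage_midpoint, leakage_slope, n = n_leakage,
                           seed = config$seed, noise_cv = config$noise_cv)
  mm <- gen_morphometry(morpho_means, cv = morpho_cv, n = n_morpho,
                        seed = config$seed)
  paths <- c(fractions = file.path(outdir, "fractions.tsv"),
             leakage = file.path(outdir, "leakage.tsv"),
             morphometry = file.path(outdir, "morphometry.tsv"),
             segmentation = file.path(outdir, "segmentation.tsv"),
             ground_truth = file.path(outdir, "ground_truth.yaml"))
  write_tsv(fr, paths["fractions"])
  write_tsv(lk, paths["leakage"])
  write_tsv(mm$morphometry, paths["morphometry"])
  write_tsv(mm$segmentation, paths["segmentation"])
  yaml::write_yaml(list(
    seed = config$seed,
    noise_cv = config$noise_cv,
    true_shares = lapply(truth$true_shares, as.list),
    true_volumes = as.list(truth$true_volumes),
    injury = as.list(truth$injury)), paths["ground_truth"])
  invisible(paths)
}
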