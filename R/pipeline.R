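#' Pipeline configuration
#'
#' Assembles everything one end-to-end run needs: where inputs come from
#' (bundled synthetic generation or existing TSV tables), condition
#' label, bulk metabolite amounts, kinetics constants, the seed and the
#' output directory.
#'
#' @param outdir Output directory.
#' @param seed Integer seed recorded in the run manifest and used by all
#'   generators.
#' @param condition Condition label (e.g. `"22C"` or `"34C_7d"`).
#' @param synthetic A [synthetic_config()] to generate inputs, or `NULL`
#'   to read existing tables.
#' @param inputs Named paths (`fractions`, `leakage`, `morphometry`,
#'   `segmentation`) when `synthetic` is `NULL`.
#' @param amounts Data frame (metabolite, amount) of bulk amounts in
#'   umol/gDW; the default is an illustrative leaf sugar profile.
#' @param kinetics Named list per enzyme of [kinetic_parameters()];
#'   defaults are the labelled example set.
#' @param assays Data frame (enzyme, vmax, t_opt_K, ea_J_per_mol).
#' @param t_growth_K Growth temperature in Kelvin.
#' @param morpho_means Condition means passed to the morphometry
#'   generator when running synthetically.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir, seed = 1L, condition = "22C",
                            synthetic = synthetic_config(seed = seed),
                            inputs = NULL,
                            amounts = data.frame(
                              metabolite = c("sucrose", "glucose",
                                             "fructose", "starch"),
                              amount = c(5, 2, 1.5, 20)),
                            kinetics = list(
                              nInv = kinetic_parameters(),
                              aInv = kinetic_parameters()),
                            assays = data.frame(
                              enzyme = c("SPS", "nInv", "aInv", "cwInv"),
                              vmax = c(2, 1.5, 3, 1),
                              t_opt_K = c(298.15, 303.15, 303.15, 303.15),
                              ea_J_per_mol = rep(50000, 4)),
                            t_growth_K = celsius_to_kelvin(22),
                            morpho_means = morphometry_means_22C()) {
  if (is.null(synthetic) && is.null(inputs))
    stop("either a synthetic config or input paths are required",
         call. = FALSE)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 condition = condition, synthetic = synthetic,
                 inputs = inputs, amounts = amounts,
                 kinetics = kinetics, assays = assays,
                 t_growth_K = t_growth_K, morpho_means = morpho_means),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes ingestion (synthetic generation or table reading), the
#' injury-index stage, NAF deconvolution, volumetrics, concentration
#' conversion and kinetics simulation, writing one TSV per stage plus a
#' run manifest with input checksums, the seed and package version.
#' Reruns with an unchanged config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with all stage results and the manifest
#'   path.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- ingestion ---------------------------------------------------------
  paths <- stage("ingest", {
    if (!is.null(config$synthetic)) {
      indir <- file.path(config$outdir, "inputs")
      write_synthetic_dataset(config$synthetic, indir,
                              morpho_means = config$morpho_means)
    } else {
      need <- c("fractions", "leakage", "morphometry", "segmentation")
      missing <- setdiff(need, names(config$inputs))
      if (length(missing))
        stop("missing input paths: ", paste(missing, collapse = ", "))
      unlist(config$inputs)
    }
  })
  fractions <- read_tsv(paths[["fractions"]])
  leakage_tab <- read_tsv(paths[["leakage"]])
  morpho <- read_tsv(paths[["morphometry"]])
  seg <- read_tsv(paths[["segmentation"]])
  say("ingested ", nrow(fractions), " fraction rows, ",
      nrow(leakage_tab), " conductivity rows")

  # -- leakage -----------------------------------------------------------
  injury <- stage("leakage", injury_curve(leakage_tab))
  write_tsv(injury$values, file.path(config$outdir, "injury.tsv"))
  write_tsv(injury$summary, file.path(config$outdir, "injury_summary.tsv"))
  say("injury index for ", nrow(injury$summary), " timepoints")

  # -- naf deconvolution -------------------------------------------------
  shares <- stage("naf", deconvolve_profiles(fractions))
  shares_out <- cbind(shares[, "metabolite", drop = FALSE],
                      condition = config$condition,
                      shares[, setdiff(names(shares), "metabolite")])
  write_tsv(shares_out, file.path(config$outdir, "shares.tsv"))
  say("deconvolved ", nrow(shares), " metabolites over ",
      shares$n_replicates[1], " replicates")

  # -- volumetrics -------------------------------------------------------
  vols <- stage("volumetrics", leaf_volumetrics(morpho, seg))
  vol_tab <- data.frame(condition = config$condition,
                        t(vols$means))
  write_tsv(vol_tab, file.path(config$outdir, "volumes.tsv"))
  comp_vols <- c(plastid = vols$means[["vol_plastid_ml_per_gdw"]],
                 cytosol = vols$means[["vol_cytosol_ml_per_gdw"]],
                 vacuole = vols$means[["vol_vacuole_ml_per_gdw"]])
  say("cell material ",
      round(vols$means[["cell_material_mm3_per_gdw"]], 1), " mm3/gDW")

  # -- concentrations ----------------------------------------------------
  concs <- stage("concentrations", {
    bulk <- config$amounts
    bulk$condition <- config$condition
    sh <- shares
    sh$condition <- config$condition
    subcellular_concentrations(bulk, sh, comp_vols)
  })
  write_tsv(concs, file.path(config$outdir, "subcellular.tsv"))
  say("subcellular table: ", nrow(concs), " rows")

  # -- kinetics ----------------------------------------------------------
  rates <- stage("kinetics", {
    cell_vol <- vols$means[["cell_material_mm3_per_gdw"]] / 1000
    in_vivo_flux(concs, config$assays, config$kinetics,
                 config$t_growth_K, cell_vol)
  })
  write_tsv(rates, file.path(config$outdir, "rates.tsv"))
  curves <- stage("kinetics", {
    do.call(rbind, lapply(seq_len(nrow(rates)), function(i) {
      enz <- rates$enzyme[i]
      p <- config$kinetics[[enz]]
      p$v_max <- rates$vmax_adj[i]
      comp <- rates$compartment[i]
      fc <- concs[concs$compartment == comp, ]
      f <- mean(fc$concentration_mM[fc$metabolite == "fructose"])
      g <- mean(fc$concentration_mM[fc$metabolite == "glucose"])
      cbind(enzyme = enz,
            simulate_rate_curve(seq(0, 100, by = 1), f, g, p))
    }))
  })
  write_tsv(curves, file.path(config$outdir, "rate_curves.tsv"))
  say("kinetics: ", nrow(rates), " in vivo fluxes")

  # -- manifest ----------------------------------------------------------
  outputs <- c("injury.tsv", "injury_summary.tsv", "shares.tsv",
               "volumes.tsv", "subcellular.tsv", "rates.tsv",
               "rate_curves.tsv")
  manifest <- list(
    seed = config$seed,
    condition = config$condition,
    package_version = as.character(utils::packageVersion("subcellsugars")),
    input_checksums = {
      x <- tools::md5sum(unname(paths[setdiff(names(paths),
                                              "ground_truth")]))
      as.list(stats::setNames(x, basename(names(x))))
    },
    output_checksums = {
      x <- tools::md5sum(file.path(config$outdir, outputs))
      as.list(stats::setNames(x, basename(names(x))))
    })
  manifest_path <- file.path(config$outdir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  say("manifest written")
  invisible(list(paths = paths, injury = injury, shares = shares,
                 volumetrics = vols, concentrations = concs,
                 rates = rates, curves = curves,
                 manifest = manifest_path))
}

#' Validate pipeline input tables
#'
#' Schema and sanity checks per table: required columns, simplex
#' constraints on proportions, positivity of conductivities and volumes.
#' Reports rather than raises.
#'
#' @param paths Named character vector or list of table paths; recognized
#'   names are `fractions`, `leakage`, `morphometry`, `segmentation`,
#'   `shares`.
#' @return Data frame (table, check, status, detail) with status
#'   `"pass"` or `"fail"`.
#' @export
validate_inputs <- function(paths) {
  out <- list()
  add <- function(tab, check, ok, detail = "") {
    out[[length(out) + 1]] <<- data.frame(
      table = tab, check = check,
      status = if (ok) "pass" else "fail", detail = detail)
  }
  get_table <- function(nm) {
    p <- paths[[nm]]
    if (is.null(p) || !file.exists(p)) {
      add(nm, "file_exists", FALSE, paste0("missing: ", p %||% "<unset>"))
      return(NULL)
    }
    add(nm, "file_exists", TRUE)
    read_tsv(p)
  }
  if ("fractions" %in% names(paths)) {
    d <- get_table("fractions")
    if (!is.null(d)) {
      need <- c("sample", "fraction", "density", "marker_plastid",
                "marker_cytosol", "marker_vacuole")
      miss <- setdiff(need, names(d))
      add("fractions", "schema", length(miss) == 0,
          paste(miss, collapse = ", "))
      num <- d[, setdiff(names(d), c("sample", "fraction"))]
      bad <- which(as.matrix(num) < 0, arr.ind = TRUE)
      add("fractions", "non_negative", nrow(bad) == 0,
          if (nrow(bad)) paste("row", bad[1, 1]) else "")
    }
  }
  if ("leakage" %in% names(paths)) {
    d <- get_table("leakage")
    if (!is.null(d)) {
      miss <- setdiff(c("replicate", "duration_min", "ec_initial",
                        "ec_total"), names(d))
      add("leakage", "schema", length(miss) == 0,
          paste(miss, collapse = ", "))
      if (!length(miss)) {
        neg <- which(d$ec_initial < 0 | d$ec_total <= 0)
        add("leakage", "conductivity_positive", length(neg) == 0,
            if (length(neg)) paste("row", neg[1]) else "")
        swap <- which(d$ec_initial > d$ec_total)
        add("leakage", "initial_le_total", length(swap) == 0,
            if (length(swap)) paste("row", swap[1]) else "")
        add("leakage", "has_t0", 0 %in% d$duration_min)
      }
    }
  }
  if ("segmentation" %in% names(paths)) {
    d <- get_table("segmentation")
    if (!is.null(d)) {
      pc <- c("prop_plastid", "prop_cytosol", "prop_vacuole")
      miss <- setdiff(c("porosity", pc), names(d))
      add("segmentation", "schema", length(miss) == 0,
          paste(miss, collapse = ", "))
      if (!length(miss)) {
        sums <- rowSums(d[, pc])
        bad <- which(abs(sums - 1) > 1e-3)
        add("segmentation", "proportions_simplex", length(bad) == 0,
            if (length(bad)) sprintf("row %d sums to %.4f", bad[1],
                                     sums[bad[1]]) else "")
        add("segmentation", "porosity_range",
            all(d$porosity >= 0 & d$porosity < 1))
      }
    }
  }
  if ("morphometry" %in% names(paths)) {
    d <- get_table("morphometry")
    if (!is.null(d)) {
      need <- c("disc_radius_mm", "leaf_height_mm", "disc_dry_weight_mg")
      miss <- setdiff(need, names(d))
      add("morphometry", "schema", length(miss) == 0,
          paste(miss, collapse = ", "))
      if (!length(miss))
        add("morphometry", "positive",
            all(as.matrix(d[, need]) > 0))
    }
  }
  if ("shares" %in% names(paths)) {
    d <- get_table("shares")
    if (!is.null(d)) {
      sc <- c("share_plastid", "share_cytosol", "share_vacuole")
      miss <- setdiff(sc, names(d))
      add("shares", "schema", length(miss) == 0,
          paste(miss, collapse = ", "))
      if (!length(miss)) {
        sums <- rowSums(d[, sc])
        bad <- which(abs(sums - 1) > 1e-6)
        add("shares", "simplex", length(bad) == 0,
            if (length(bad)) sprintf("row %d sums to %.4f", bad[1],
                                     sums[bad[1]]) else "")
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
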