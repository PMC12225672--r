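#' Partition bulk metabolite amounts into compartments
#'
#' Multiplies each bulk amount (umol/gDW) by the NAF-derived compartment
#' shares; mass is conserved exactly. Starch is excluded from
#' partitioning (it is plastidial by biology and not resolved by the
#' three-compartment gradient) and passes through as a bulk amount.
#'
#' @param bulk Data frame with columns `metabolite`, `amount` (umol/gDW)
#'   and optionally `condition`, `replicate`.
#' @param shares Data frame from [deconvolve_profiles()] with columns
#'   `metabolite`, `share_plastid`, `share_cytosol`, `share_vacuole`
#'   (and optionally `condition`).
#' @param passthrough Metabolites exempt from partitioning (default
#'   `"starch"`).
#' @return Data frame (metabolite, \[condition, replicate,\] compartment,
#'   amount_umol_per_gdw); passthrough metabolites get compartment
#'   `"bulk"`.
#' @examples
#' bulk <- data.frame(metabolite = "sucrose", amount = 10)
#' sh <- data.frame(metabolite = "sucrose", share_plastid = 0.1,
#'                  share_cytosol = 0.1, share_vacuole = 0.8)
#' partition_amounts(bulk, sh)
#' @export
partition_amounts <- function(bulk, shares, passthrough = "starch") {
  if (any(bulk$amount < 0))
    stop("bulk amounts must be non-negative", call. = FALSE)
  by_cond <- "condition" %in% names(bulk) && "condition" %in% names(shares)
  rows <- lapply(seq_len(nrow(bulk)), function(i) {
    met <- bulk$metabolite[i]
    base <- bulk[i, setdiff(names(bulk), c("metabolite", "amount")),
                 drop = FALSE]
    if (met %in% passthrough) {
      return(cbind(data.frame(metabolite = met), base,
                   data.frame(compartment = "bulk",
                              amount_umol_per_gdw = bulk$amount[i])))
    }
    sh <- shares[shares$metabolite == met, ]
    if (by_cond) sh <- sh[sh$condition == bulk$condition[i], ]
    if (nrow(sh) == 0)
      stop("no compartment shares available for metabolite '", met, "'",
           call. = FALSE)
    s <- c(plastid = sh$share_plastid[1], cytosol = sh$share_cytosol[1],
           vacuole = sh$share_vacuole[1])
    check_simplex(s, tol = 1e-6,
                  name = paste0("shares for ", met))
    cbind(data.frame(metabolite = rep(met, 3)),
          base[rep(1, 3), , drop = FALSE],
          data.frame(compartment = compartments(),
                     amount_umol_per_gdw = bulk$amount[i] * s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a compartment amount to a molar concentration
#'
#' umol per gram dry weight divided by mL per gram dry weight is
#' umol/mL, i.e. millimolar — the unit bridge between metabolite assays
#' and compartment volumetrics.
#'
#' @param amount_umol_per_gdw Amount in umol/gDW.
#' @param volume_ml_per_gdw Compartment volume in mL/gDW, positive.
#' @param compartment Label for error messages.
#' @return Concentration in mM. Vectorized.
#' @examples
#' to_concentration(1, 0.38)  # ~2.63 mM cytosolic
#' @export
to_concentration <- function(amount_umol_per_gdw, volume_ml_per_gdw,
                             compartment = "compartment") {
  if (any(amount_umol_per_gdw < 0))
    stop("amounts must be non-negative", call. = FALSE)
  if (any(volume_ml_per_gdw <= 0))
    stop("zero or negative volume for ", compartment, call. = FALSE)
  amount_umol_per_gdw / volume_ml_per_gdw
}

#' Subcellular amounts and concentrations from bulk data
#'
#' The central transformation: bulk amounts x NAF shares give
#' per-compartment amounts; dividing by compartment volumes gives
#' millimolar concentrations. Shares enter as condition-level medians
#' while amounts may be replicate-level (shares and amounts usually come
#' from different sample sets); that propagation choice is recorded in
#' the result's metadata attribute.
#'
#' @param bulk Data frame (metabolite, amount, \[condition, replicate\]).
#' @param shares Share table (see [partition_amounts()]).
#' @param volumes Named compartment volumes in mL/gDW, or a list per
#'   condition when `bulk` has a `condition` column.
#' @param passthrough Metabolites exempt from partitioning.
#' @return Data frame (metabolite, \[condition, replicate,\] compartment,
#'   amount_umol_per_gdw, concentration_mM); passthrough rows carry `NA`
#'   concentration.
#' @export
subcellular_concentrations <- function(bulk, shares, volumes,
                                       passthrough = "starch") {
  parts <- partition_amounts(bulk, shares, passthrough)
  by_cond_vol <- is.list(volumes) && !is.null(names(volumes)) &&
    !all(compartments() %in% names(volumes))
  conc <- vapply(seq_len(nrow(parts)), function(i) {
    cp <- parts$compartment[i]
    if (cp == "bulk") return(NA_real_)
    v <- if (by_cond_vol) volumes[[parts$condition[i]]] else volumes
    if (!cp %in% names(v))
      stop("missing volume for compartment '", cp, "'", call. = FALSE)
    to_concentration(parts$amount_umol_per_gdw[i], v[[cp]], cp)
  }, numeric(1))
  parts$concentration_mM <- conc
  attr(parts, "metadata") <- list(
    share_level = "condition-median",
    amount_level = "as-supplied (replicate or mean)")
  parts
}

#' Paired comparison of subcellular concentrations across two conditions
#'
#' Produces the side-by-side table of amounts, concentrations and fold
#' changes between two conditions (e.g. control vs heat-acclimated). No
#' significance testing is attempted.
#'
#' @param concs Data frame from [subcellular_concentrations()] with a
#'   `condition` column covering exactly two levels, or a list of two
#'   such single-condition frames named by condition.
#' @return Data frame (metabolite, compartment, amount and concentration
#'   per condition, fold_change_amount, fold_change_concentration); fold
#'   changes are second condition over first.
#' @export
condition_report <- function(concs) {
  if (is.list(concs) && !is.data.frame(concs)) {
    stopifnot(length(concs) == 2, !is.null(names(concs)))
    conds <- names(concs)
    for (nm in conds)
      concs[[nm]][["condition"]] <- rep(nm, nrow(concs[[nm]]))
    concs <- do.call(rbind, concs)
  } else {
    conds <- unique(concs$condition)
  }
  if (nrow(concs)) concs <- concs[concs$compartment != "bulk", ]
  if (nrow(concs) == 0) {
    warning("no partitioned metabolites to compare", call. = FALSE)
    return(data.frame())
  }
  if (length(conds) != 2 || !all(sort(unique(concs$condition)) ==
                                   sort(conds)))
    stop("condition_report needs exactly two conditions", call. = FALSE)
  agg <- stats::aggregate(
    concs[, c("amount_umol_per_gdw", "concentration_mM")],
    by = list(metabolite = concs$metabolite,
              compartment = concs$compartment,
              condition = concs$condition),
    FUN = mean)
  a <- agg[agg$condition == conds[1], ]
  b <- agg[agg$condition == conds[2], ]
  m <- merge(a, b, by = c("metabolite", "compartment"),
             suffixes = paste0("_", conds))
  m[[paste0("condition_", conds[1])]] <- NULL
  m[[paste0("condition_", conds[2])]] <- NULL
  m$fold_change_amount <-
    m[[paste0("amount_umol_per_gdw_", conds[2])]] /
    m[[paste0("amount_umol_per_gdw_", conds[1])]]
  m$fold_change_concentration <-
    m[[paste0("concentration_mM_", conds[2])]] /
    m[[paste0("concentration_mM_", conds[1])]]
  m[order(m$metabolite, m$compartment), ]
}
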