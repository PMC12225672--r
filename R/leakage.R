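#' Fractional release of electrolytes
#'
#' Ratio of the conductivity measured after overnight shaking to the total
#' conductivity after boiling the sample, `R = EC_initial / EC_total`.
#' The assay's 1:4 dilution cancels in the ratio and is not modelled.
#'
#' @param ec_initial Conductivity after shaking (uS/cm), non-negative.
#' @param ec_total Conductivity after boiling at 95 C (uS/cm), positive.
#' @return Fractional release in \[0, 1\]. Vectorized.
#' @examples
#' fractional_release(50, 200)  # 0.25
#' @export
fractional_release <- function(ec_initial, ec_total) {
  if (any(!is.finite(ec_initial)) || any(!is.finite(ec_total)))
    stop("conductivities must be finite", call. = FALSE)
  if (any(ec_total <= 0))
    stop("ec_total must be strictly positive", call. = FALSE)
  if (any(ec_initial < 0))
    stop("ec_initial must be non-negative", call. = FALSE)
  if (any(ec_initial > ec_total * (1 + 1e-12)))
    stop("ec_initial exceeds ec_total; measurements appear swapped",
         call. = FALSE)
  pmin(ec_initial / ec_total, 1)
}

#' Index of injury from fractional electrolyte release
#'
#' `I_d = 100 * (R_t - R_0) / (1 - R_0)`, the percent membrane damage of a
#' heated sample relative to its unheated reference. Values below zero
#' (heated sample leaking less than the reference) are reported, not
#' clamped, since they usually flag swapped measurements.
#'
#' @param r_t Fractional release of the heated sample, in \[0, 1\].
#' @param r_0 Fractional release of the unheated reference, in \[0, 1).
#' @param label Optional replicate label used in error messages.
#' @return Index of injury in percent (100 = total injury). Vectorized
#'   over `r_t`.
#' @examples
#' index_of_injury(0.6, 0.2)  # 50
#' @export
index_of_injury <- function(r_t, r_0, label = NULL) {
  if (any(!is.finite(r_t)) || any(!is.finite(r_0)))
    stop("fractional releases must be finite", call. = FALSE)
  if (any(r_0 < 0) || any(r_t < 0) || any(r_t > 1 + 1e-12))
    stop("fractional releases must lie in [0, 1]", call. = FALSE)
  if (any(r_0 >= 1)) {
    who <- if (is.null(label)) "" else paste0(" (replicate ", label, ")")
    stop("index of injury undefined: unheated reference released all ",
         "electrolytes (R_0 >= 1)", who, call. = FALSE)
  }
  100 * (r_t - r_0) / (1 - r_0)
}

#' Injury time course from a conductivity series
#'
#' Computes the index of injury for every replicate and heat-exposure
#' duration of a conductivity table. Each replicate's own t = 0
#' measurement provides the unheated reference R_0 (set
#' `r0 = "group_mean"` to use the mean R_0 of all replicates instead).
#'
#' @param series Data frame with columns `replicate`, `duration_min`,
#'   `ec_initial`, `ec_total`; every replicate must include
#'   `duration_min == 0`.
#' @param r0 `"per_replicate"` (default) or `"group_mean"`.
#' @return List of class `"injury_result"` with `values` (replicate-level
#'   injuries) and `summary` (median and quartiles per duration).
#' @examples
#' lk <- gen_leakage_series(40, 0.25, n = 4, seed = 2, noise_cv = 0)
#' injury_curve(lk)$summary
#' @export
injury_curve <- function(series, r0 = c("per_replicate", "group_mean")) {
  r0 <- match.arg(r0)
  need <- c("replicate", "duration_min", "ec_initial", "ec_total")
  missing <- setdiff(need, names(series))
  if (length(missing))
    stop("series lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  series$R <- fractional_release(series$ec_initial, series$ec_total)
  base <- series[series$duration_min == 0, ]
  if (nrow(base) == 0)
    stop("no t = 0 reference measurements in series", call. = FALSE)
  r0_by_rep <- tapply(base$R, base$replicate, mean)
  out <- lapply(split(series, series$replicate), function(d) {
    rep_id <- d$replicate[1]
    if (!as.character(rep_id) %in% names(r0_by_rep))
      stop("replicate ", rep_id, " lacks a t = 0 reference", call. = FALSE)
    r_0 <- if (r0 == "per_replicate")
      r0_by_rep[[as.character(rep_id)]] else mean(r0_by_rep)
    data.frame(replicate = rep_id,
               duration_min = d$duration_min,
               injury_pct = index_of_injury(d$R, r_0, label = rep_id))
  })
  values <- do.call(rbind, out)
  rownames(values) <- NULL
  agg <- function(f) tapply(values$injury_pct, values$duration_min, f)
  summary <- data.frame(
    duration_min = as.numeric(names(agg(stats::median))),
    median = as.numeric(agg(stats::median)),
    q1 = as.numeric(agg(function(x) stats::quantile(x, 0.25))),
    q3 = as.numeric(agg(function(x) stats::quantile(x, 0.75))),
    n = as.numeric(agg(length)))
  structure(list(values = values, summary = summary, r0_mode = r0),
            class = "injury_result")
}

#' @export
print.injury_result <- function(x, ...) {
  cat("Electrolyte-leakage index of injury (R_0:", x$r0_mode, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
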