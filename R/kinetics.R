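# Gas constant, J mol^-1 K^-1 (module constant).
GAS_CONSTANT <- 8.314

#' Arrhenius pre-exponential factor from an activity at its optimum
#'
#' An enzyme activity measured at its temperature optimum pins down the
#' Arrhenius factor `C` in `V = C * exp(-Ea / (R T))`:
#' `C = Vmax_opt * exp(Ea / (R * T_opt))`, so that re-evaluating the
#' equation at `T_opt` returns the measured activity exactly.
#'
#' @param v_max_opt Activity at the assay temperature optimum (> 0).
#' @param e_a Activation energy in J/mol (>= 0).
#' @param t_opt Assay optimum temperature in Kelvin (298.15 K for SPS,
#'   303.15 K for invertases).
#' @return Arrhenius factor `C`, same units as `v_max_opt`.
#' @examples
#' arrhenius_factor(100, 50000, 303.15)
#' @export
arrhenius_factor <- function(v_max_opt, e_a, t_opt) {
  assert_scalar_number(v_max_opt, "v_max_opt", positive = TRUE)
  assert_scalar_number(e_a, "e_a", nonneg = TRUE)
  assert_scalar_number(t_opt, "t_opt", positive = TRUE)
  v_max_opt * exp(e_a / (GAS_CONSTANT * t_opt))
}

#' Temperature-adjusted maximal activity
#'
#' Evaluates `Vmax_adj = C * exp(-Ea / (R T))` at a target temperature,
#' rescaling an assay-optimum activity to physiologically relevant
#' growth temperatures. Monotone increasing in temperature for
#' `e_a > 0`.
#'
#' @param c_factor Arrhenius factor from [arrhenius_factor()].
#' @param e_a Activation energy in J/mol.
#' @param t_target Target temperature in Kelvin; values below 200 are
#'   rejected as likely Celsius input.
#' @return Adjusted Vmax. Vectorized over `t_target`.
#' @examples
#' C <- arrhenius_factor(100, 50000, 303.15)
#' adjust_vmax(C, 50000, 295.15)  # activity at 22 C
#' @export
adjust_vmax <- function(c_factor, e_a, t_target) {
  if (any(t_target < 200))
    stop("temperature must be Kelvin (got ", min(t_target),
         "; add 273.15 if Celsius)", call. = FALSE)
  if (c_factor <= 0) stop("c_factor must be positive", call. = FALSE)
  c_factor * exp(-e_a / (GAS_CONSTANT * t_target))
}

#' Celsius to Kelvin at the configuration boundary
#'
#' @param t_celsius Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(t_celsius) t_celsius + 273.15

#' Normalize an enzyme activity to cell volume
#'
#' Dividing an activity per gram dry weight by the cell-material volume
#' per gram dry weight (e.g. 10.93 mL/gDW at 22 C, 8.26 mL/gDW after
#' heat acclimation) yields a rate per mL of cell water, commensurable
#' with millimolar substrate concentrations.
#'
#' @param activity_per_gdw Activity in units/gDW.
#' @param cell_volume_ml_per_gdw Cell volume in mL/gDW (> 0).
#' @return Activity per mL cell volume. Vectorized.
#' @examples
#' normalize_activity_to_volume(10.93, 10.93)  # 1
#' @export
normalize_activity_to_volume <- function(activity_per_gdw,
                                         cell_volume_ml_per_gdw) {
  if (any(cell_volume_ml_per_gdw <= 0))
    stop("cell volume must be strictly positive", call. = FALSE)
  if (any(activity_per_gdw < 0))
    stop("activity must be non-negative", call. = FALSE)
  activity_per_gdw / cell_volume_ml_per_gdw
}

#' Kinetic parameter set for invertase rate simulation
#'
#' Bundles the Michaelis constant and the inhibition constants of the
#' sucrose-cleavage rate law. The defaults are a clearly labelled
#' example set for demonstration only — every constant must be
#' overridden with assay-derived values for real inference.
#'
#' @param v_max Maximal rate (e.g. mM/min after volume normalization).
#' @param k_m Michaelis constant for sucrose (mM).
#' @param k_i_frc Competitive inhibition constant for fructose (mM).
#' @param k_i_glc Noncompetitive inhibition constant for glucose (mM).
#' @param alpha Mixed-inhibition factor for glucose; `1` (default) is
#'   classical noncompetitive inhibition.
#' @return List of class `"kinetic_parameters"`.
#' @export
kinetic_parameters <- function(v_max = 1, k_m = 10, k_i_frc = 5,
                               k_i_glc = 5, alpha = 1) {
  for (nm in c("v_max", "k_m", "k_i_frc", "k_i_glc", "alpha"))
    assert_scalar_number(get(nm), nm, positive = TRUE)
  structure(list(v_max = v_max, k_m = k_m, k_i_frc = k_i_frc,
                 k_i_glc = k_i_glc, alpha = alpha),
            class = "kinetic_parameters")
}

#' Invertase rate under competitive and noncompetitive inhibition
#'
#' Michaelis--Menten sucrose cleavage with fructose as a competitive
#' inhibitor (raising the apparent Km) and glucose as a noncompetitive
#' inhibitor (lowering the apparent Vmax). For `alpha = 1` the rate law
#' is
#' \deqn{v = \frac{V_{max}}{1 + g/K_{i,Glc}} \cdot
#'   \frac{s}{K_m (1 + f/K_{i,Frc}) + s}}
#' which reduces to plain Michaelis--Menten at `f = g = 0`. `alpha`
#' generalizes the glucose term to mixed inhibition (uncompetitive
#' component with constant `alpha * K_i_glc`).
#'
#' @param s Sucrose concentration in mM (vectorized).
#' @param f Fructose concentration in mM.
#' @param g Glucose concentration in mM.
#' @param p A [kinetic_parameters()] set.
#' @return Reaction rate, same units as `p$v_max`.
#' @examples
#' p <- kinetic_parameters(v_max = 6, k_m = 10, k_i_frc = 5, k_i_glc = 5)
#' mixed_inhibition_rate(10, 0, 0, p)  # half-saturation: 3
#' mixed_inhibition_rate(10, 5, 5, p)  # Vmax/6: 1
#' @export
mixed_inhibition_rate <- function(s, f, g, p) {
  stopifnot(inherits(p, "kinetic_parameters"))
  if (any(s < 0) || any(f < 0) || any(g < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  denom <- p$k_m * (1 + f / p$k_i_frc) * (1 + g / p$k_i_glc) +
    s * (1 + g / (p$alpha * p$k_i_glc))
  p$v_max * s / denom
}

#' Simulate inhibited and uninhibited rate curves over a sucrose grid
#'
#' Evaluates the rate law with and without hexose inhibition over a
#' sucrose concentration grid and flags the physiologically relevant
#' concentration window if supplied.
#'
#' @param s_grid Increasing non-negative sucrose grid (mM).
#' @param f,g Fructose and glucose concentrations (mM).
#' @param p A [kinetic_parameters()] set.
#' @param in_vivo_range Optional length-2 numeric giving the in-vivo
#'   sucrose window (mM) to annotate.
#' @return Data frame (s_mM, rate_uninhibited, rate_inhibited, in_vivo).
#' @export
simulate_rate_curve <- function(s_grid, f, g, p, in_vivo_range = NULL) {
  if (length(s_grid) == 0) stop("empty sucrose grid", call. = FALSE)
  if (any(s_grid < 0) || any(diff(s_grid) < 0))
    stop("s_grid must be non-negative and non-decreasing", call. = FALSE)
  uninhib <- mixed_inhibition_rate(s_grid, 0, 0, p)
  inhib <- mixed_inhibition_rate(s_grid, f, g, p)
  in_vivo <- if (is.null(in_vivo_range)) rep(NA, length(s_grid))
  else s_grid >= in_vivo_range[1] & s_grid <= in_vivo_range[2]
  data.frame(s_mM = s_grid, rate_uninhibited = uninhib,
             rate_inhibited = inhib, in_vivo = in_vivo)
}

#' In vivo invertase fluxes from subcellular concentrations
#'
#' Estimates a single sucrose-cleavage rate per invertase and condition:
#' the cytosolic neutral invertase (nInv) sees cytosolic sucrose,
#' fructose and glucose; the vacuolar acidic invertase (aInv) sees the
#' vacuolar pools. Measured Vmax values are Arrhenius-adjusted to the
#' growth temperature and normalized to cell volume first. The
#' cell-wall invertase has no resolved apoplastic substrate pool and is
#' excluded.
#'
#' @param concs Data frame from [subcellular_concentrations()] for one
#'   condition (metabolite, compartment, concentration_mM).
#' @param assays Data frame (enzyme, vmax, t_opt_K, ea_J_per_mol) with
#'   rows for `nInv` and `aInv`; `vmax` in units/gDW at the assay
#'   optimum.
#' @param params Named list of [kinetic_parameters()] per enzyme
#'   (`k_m`, `k_i_frc`, `k_i_glc` are used; `v_max` is replaced by the
#'   adjusted, volume-normalized value).
#' @param t_growth_K Growth temperature in Kelvin.
#' @param cell_volume_ml_per_gdw Cell-material volume in mL/gDW used for
#'   activity normalization.
#' @return Data frame (enzyme, compartment, vmax_adj, rate,
#'   rate_uninhibited).
#' @export
in_vivo_flux <- function(concs, assays, params, t_growth_K,
                         cell_volume_ml_per_gdw) {
  enzyme_comp <- c(nInv = "cytosol", aInv = "vacuole")
  get_conc <- function(met, comp) {
    v <- concs$concentration_mM[concs$metabolite == met &
                                  concs$compartment == comp]
    if (length(v) == 0)
      stop("missing ", comp, " concentration for ", met, call. = FALSE)
    mean(v)
  }
  out <- lapply(names(enzyme_comp), function(enz) {
    comp <- enzyme_comp[[enz]]
    a <- assays[assays$enzyme == enz, ]
    if (nrow(a) == 0)
      stop("no assay record for enzyme ", enz, call. = FALSE)
    C <- arrhenius_factor(a$vmax[1], a$ea_J_per_mol[1], a$t_opt_K[1])
    vadj <- adjust_vmax(C, a$ea_J_per_mol[1], t_growth_K)
    vnorm <- normalize_activity_to_volume(vadj, cell_volume_ml_per_gdw)
    p <- params[[enz]]
    stopifnot(inherits(p, "kinetic_parameters"))
    p$v_max <- vnorm
    s <- get_conc("sucrose", comp)
    f <- get_conc("fructose", comp)
    g <- get_conc("glucose", comp)
    data.frame(enzyme = enz, compartment = comp,
               vmax_adj = vnorm,
               rate = mixed_inhibition_rate(s, f, g, p),
               rate_uninhibited = mixed_inhibition_rate(s, 0, 0, p))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
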