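#' Leaf-disc volume from punch radius and leaf height
#'
#' `V = pi * r^2 * h`, the cylinder cut by a cork borer of radius `r`
#' through a leaf of thickness `h`.
#'
#' @param radius_mm Punch radius in mm (4 mm punches give a 50.26 mm^2
#'   disc).
#' @param height_mm Leaf thickness in mm, from light micrographs.
#' @return Disc volume in mm^3. Vectorized.
#' @examples
#' disc_volume(4, 0.187)  # ~9.40 mm^3
#' @export
disc_volume <- function(radius_mm, height_mm) {
  if (any(radius_mm <= 0)) stop("radius must be positive", call. = FALSE)
  if (any(height_mm < 0)) stop("height must be non-negative", call. = FALSE)
  pi * radius_mm^2 * height_mm
}

#' Tissue volume per gram dry weight
#'
#' @param disc_volume_mm3 Leaf-disc volume in mm^3.
#' @param dry_weight_mg Disc dry weight in mg.
#' @return Volume per gram dry weight in mm^3/g. Vectorized.
#' @examples
#' volume_per_gdw(9.415, 0.622)  # ~15137 mm^3/g
#' @export
volume_per_gdw <- function(disc_volume_mm3, dry_weight_mg) {
  if (any(dry_weight_mg <= 0))
    stop("dry weight must be strictly positive", call. = FALSE)
  disc_volume_mm3 / (dry_weight_mg / 1000)
}

#' Cell-material volume after removing intercellular gas space
#'
#' Subtracts the gas-space volume (or equivalently applies `1 - porosity`)
#' from the tissue volume per gram dry weight. The gas-space estimate may
#' come from 3D SBF-SEM segmentation or from 2D section areas; both enter
#' through the same argument, with the provenance recorded by the caller.
#'
#' @param volume_per_gdw Tissue volume in mm^3/gDW.
#' @param gas_space_volume Gas-space volume in mm^3/gDW (give either this
#'   or `porosity`).
#' @param porosity Gas-space fraction of tissue volume in \[0, 1).
#' @return Cell-material volume in mm^3/gDW. Vectorized.
#' @examples
#' cell_material_volume(15131, 4199.5)       # 10931.5
#' cell_material_volume(15131, porosity = 0.278)
#' @export
cell_material_volume <- function(volume_per_gdw, gas_space_volume = NULL,
                                 porosity = NULL) {
  if (is.null(gas_space_volume) == is.null(porosity))
    stop("supply exactly one of gas_space_volume or porosity",
         call. = FALSE)
  if (!is.null(porosity)) {
    if (any(porosity < 0) || any(porosity >= 1))
      stop("porosity must lie in [0, 1)", call. = FALSE)
    gas_space_volume <- volume_per_gdw * porosity
  }
  out <- volume_per_gdw - gas_space_volume
  if (any(out < 0))
    stop("gas-space volume exceeds total volume", call. = FALSE)
  out
}

#' Absolute compartment volumes per gram dry weight
#'
#' Splits the cell-material volume among plastid, cytosol and vacuole
#' according to the 3D segmentation proportions and converts mm^3 to mL.
#' The nucleus and unsegmented small organelles are assumed folded into
#' the cytosol proportion upstream.
#'
#' @param cell_material Cell-material volume in mm^3/gDW.
#' @param proportions Named non-negative vector over compartments summing
#'   to 1 (percentages from segmentation, as fractions).
#' @param tol Tolerance on the proportion sum (default 1e-3, admitting
#'   percentages printed to two decimals).
#' @return Named vector of compartment volumes in mL/gDW.
#' @examples
#' compartment_volumes(10931.8,
#'   c(plastid = 0.1389, cytosol = 0.0351, vacuole = 0.8260))
#' @export
compartment_volumes <- function(cell_material, proportions, tol = 1e-3) {
  assert_scalar_number(cell_material, "cell_material", nonneg = TRUE)
  if (any(proportions < 0))
    stop("proportions must be non-negative", call. = FALSE)
  if (abs(sum(proportions) - 1) > tol)
    stop(sprintf("compartment proportions sum to %.6f, not 1",
                 sum(proportions)), call. = FALSE)
  cell_material * proportions / 1000
}

#' Tissue-type percentages from section areas
#'
#' Normalizes measured section areas per cell-type class (palisade and
#' spongy mesophyll, epidermis, vascular bundle, gas space) to
#' percentages summing to 100.
#'
#' @param areas Named non-negative numeric vector of areas in mm^2.
#' @return Named vector of percentages.
#' @examples
#' tissue_fractions(c(palisade = 25, spongy = 25, epidermis = 50))
#' @export
tissue_fractions <- function(areas) {
  if (any(areas < 0)) stop("areas must be non-negative", call. = FALSE)
  total <- sum(areas)
  if (total <= 0) stop("total section area is zero", call. = FALSE)
  100 * areas / total
}

#' Full leaf volumetrics from morphometry and segmentation samples
#'
#' Chains disc volume, volume per gram dry weight, gas-space correction
#' and compartment splitting per sample, then averages — matching a
#' measurement workflow where per-sample values are computed first and
#' condition means taken afterwards.
#'
#' @param morphometry Data frame with columns `sample`,
#'   `disc_radius_mm`, `leaf_height_mm`, `disc_dry_weight_mg`.
#' @param segmentation Data frame with columns `sample`, `porosity`,
#'   `prop_plastid`, `prop_cytosol`, `prop_vacuole` (a single-row frame
#'   is recycled over all morphometry samples, mirroring one segmented
#'   SBF-SEM block per condition).
#' @return List of class `"leaf_volumetrics"`: `per_sample` data frame
#'   and `means` (named vector with disc volume, volume per gDW, gas
#'   space, cell material in mm^3 and compartment volumes in mL/gDW).
#' @export
leaf_volumetrics <- function(morphometry, segmentation) {
  need_m <- c("sample", "disc_radius_mm", "leaf_height_mm",
              "disc_dry_weight_mg")
  need_s <- c("porosity", "prop_plastid", "prop_cytosol", "prop_vacuole")
  if (length(setdiff(need_m, names(morphometry))))
    stop("morphometry table lacks required columns", call. = FALSE)
  if (length(setdiff(need_s, names(segmentation))))
    stop("segmentation table lacks required columns", call. = FALSE)
  if (nrow(segmentation) == 1 && nrow(morphometry) > 1) {
    segmentation <- segmentation[rep(1, nrow(morphometry)), ]
    segmentation$sample <- morphometry$sample
  }
  d <- merge(morphometry, segmentation, by = "sample")
  per <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    dv <- disc_volume(d$disc_radius_mm[i], d$leaf_height_mm[i])
    vg <- volume_per_gdw(dv, d$disc_dry_weight_mg[i])
    gas <- vg * d$porosity[i]
    cm <- cell_material_volume(vg, gas)
    props <- c(plastid = d$prop_plastid[i], cytosol = d$prop_cytosol[i],
               vacuole = d$prop_vacuole[i])
    cv <- compartment_volumes(cm, props)
    data.frame(sample = d$sample[i],
               disc_volume_mm3 = dv,
               volume_per_gdw_mm3 = vg,
               gas_space_mm3_per_gdw = gas,
               cell_material_mm3_per_gdw = cm,
               vol_plastid_ml_per_gdw = cv[["plastid"]],
               vol_cytosol_ml_per_gdw = cv[["cytosol"]],
               vol_vacuole_ml_per_gdw = cv[["vacuole"]])
  }))
  rownames(per) <- NULL
  means <- colMeans(per[, -1])
  structure(list(per_sample = per, means = means),
            class = "leaf_volumetrics")
}

#' @export
print.leaf_volumetrics <- function(x, ...) {
  cat("Leaf volumetrics (means over", nrow(x$per_sample), "samples)\n")
  print(round(x$means, 3))
  invisible(x)
}

#' Condition-level compartment volumes from printed summary inputs
#'
#' Convenience wrapper reproducing the summary-table calculation from the
#' three published inputs: volume per gram dry weight, gas-space volume
#' and compartment proportions.
#'
#' @param volume_per_gdw Tissue volume in mm^3/gDW.
#' @param gas_space_volume Gas-space volume in mm^3/gDW.
#' @param proportions Named compartment proportions (fractions).
#' @return List with `cell_material` (mm^3/gDW) and `volumes` (mL/gDW).
#' @examples
#' summary_volumes(15131, 4199.5,
#'   c(plastid = 0.1389, cytosol = 0.0351, vacuole = 0.8260))
#' @export
summary_volumes <- function(volume_per_gdw, gas_space_volume, proportions) {
  cm <- cell_material_volume(volume_per_gdw, gas_space_volume)
  list(cell_material = cm,
       volumes = compartment_volumes(cm, proportions))
}
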