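#' Wellburn coefficient matrix for 80% acetone extracts
#'
#' Linear coefficients converting baseline-corrected absorbances at 663.2,
#' 646.8 and 470.0 nm into chlorophyll-a, chlorophyll-b and total
#' carotenoid concentrations (ug mL^-1) for 80% (v/v) acetone extracts
#' read on a spectrophotometer with 0.1-0.5 nm spectral resolution:
#' \itemize{
#'   \item Chl a = 12.25 A663.2 - 2.79 A646.8
#'   \item Chl b = 21.50 A646.8 - 5.10 A663.2
#'   \item Car = (1000 A470 - 1.82 Chl a - 85.02 Chl b)/198
#' }
#' The matrix form is used so that the system can be inverted to generate
#' synthetic extracts with known concentrations, and its invertibility is
#' checked on load.
#'
#' @param resolution Spectral resolution class; only the `"0.1-0.5nm"`
#'   80%-acetone set is currently shipped.
#' @return 3x3 matrix `K` with `c(chl_a, chl_b, car) = K %*% c(A663.2,
#'   A646.8, A470)`.
#' @export
wellburn_coefficients <- function(resolution = "0.1-0.5nm") {
  resolution <- match.arg(resolution)
  ka <- c(12.25, -2.79, 0)
  kb <- c(-5.10, 21.50, 0)
  kc <- (c(0, 0, 1000) - 1.82 * ka - 85.02 * kb) / 198
  K <- rbind(chl_a = ka, chl_b = kb, car = kc)
  colnames(K) <- c("a663_2", "a646_8", "a470")
  if (abs(det(K)) < 1e-8) stop("pigment coefficient matrix is singular")
  K
}

#' Photosynthetic pigment concentrations from extract absorbances
#'
#' Subtracts the 750 nm turbidity baseline from each analytical
#' wavelength, applies the Wellburn 80%-acetone equations to obtain
#' chlorophyll-a, chlorophyll-b and total carotenoid concentrations in
#' ug mL^-1, and rescales to a fresh-mass basis (ug per g fresh mass)
#' using the extract volume and sample mass.
#'
#' @param a470,a646_8,a663_2,a750 Absorbances at the four wavelengths.
#' @param fresh_mass_mg Fresh mass of the extracted sample, mg.
#' @param extract_volume_ml Extract volume, mL.
#' @param coefficients Coefficient matrix, see [wellburn_coefficients()].
#' @return List with `chl_a`, `chl_b`, `chl_ab`, `car` in ug g^-1 fresh
#'   mass and the per-mL concentrations under `per_ml`.
#' @export
pigment_concentrations <- function(a470, a646_8, a663_2, a750 = 0,
                                   fresh_mass_mg, extract_volume_ml,
                                   coefficients = wellburn_coefficients()) {
  if (any(c(a470, a646_8, a663_2, a750) < 0))
    stop("absorbances must be non-negative")
  if (any(fresh_mass_mg <= 0) || any(extract_volume_ml <= 0))
    stop("fresh mass and extract volume must be positive")
  A <- rbind(a663_2 - a750, a646_8 - a750, a470 - a750)
  if (any(A[1:2, ] < 0))
    stop("invalid extract: chlorophyll absorbance below the A750 baseline")
  conc_ml <- coefficients %*% A  # ug mL^-1
  scale <- extract_volume_ml / (fresh_mass_mg / 1000)  # mL per g FM
  out <- sweep(conc_ml, 2, scale, `*`)
  list(chl_a = unname(out["chl_a", ]), chl_b = unname(out["chl_b", ]),
       chl_ab = unname(out["chl_a", ] + out["chl_b", ]),
       car = unname(out["car", ]),
       per_ml = list(chl_a = unname(conc_ml["chl_a", ]),
                     chl_b = unname(conc_ml["chl_b", ]),
                     car = unname(conc_ml["car", ])))
}

#' Chlorophyll and xanthophyll-cycle pigment ratios
#'
#' Computes the ratios used to characterise light acclimation of the
#' pigment pool: Chl a/b, Car/(Chl a+b), the share of the xanthophyll-cycle
#' pool within total carotenoids (VAZ/Car) and the de-epoxidation share of
#' zeaxanthin within that pool (Z/VAZ).
#'
#' @param violaxanthin,antheraxanthin,zeaxanthin Xanthophyll-cycle pigment
#'   concentrations (mmol per mol Chl a+b, or any common unit).
#' @param total_car Total carotenoid concentration in the same unit;
#'   must be >= V + A + Z.
#' @param chl_a,chl_b Chlorophyll concentrations in a common unit (molar
#'   in, molar-based ratio out; mass in, mass-based ratio out — the basis
#'   is whatever the inputs carry).
#' @return List with `chl_a_b`, `car_chl`, `vaz_car`, `z_vaz`; undefined
#'   ratios (zero denominators) are returned as `NA` with attribute
#'   `undefined` listing them, never as silent zeros.
#' @export
pigment_ratios <- function(violaxanthin, antheraxanthin, zeaxanthin,
                           total_car, chl_a, chl_b) {
  vals <- c(violaxanthin, antheraxanthin, zeaxanthin, total_car, chl_a, chl_b)
  if (any(vals < 0)) stop("pigment concentrations must be non-negative")
  vaz <- violaxanthin + antheraxanthin + zeaxanthin
  if (total_car < vaz)
    stop("total carotenoids cannot be smaller than the VAZ pool")
  undefined <- character()
  chl_a_b <- if (chl_b > 0) chl_a / chl_b else {
    undefined <- c(undefined, "chl_a_b"); NA_real_
  }
  car_chl <- if (chl_a + chl_b > 0) total_car / (chl_a + chl_b) else {
    undefined <- c(undefined, "car_chl"); NA_real_
  }
  vaz_car <- if (total_car > 0) vaz / total_car else {
    undefined <- c(undefined, "vaz_car"); NA_real_
  }
  z_vaz <- if (vaz > 0) zeaxanthin / vaz else {
    undefined <- c(undefined, "z_vaz"); NA_real_
  }
  out <- list(chl_a_b = chl_a_b, car_chl = car_chl,
              vaz_car = vaz_car, z_vaz = z_vaz)
  attr(out, "undefined") <- undefined
  out
}
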