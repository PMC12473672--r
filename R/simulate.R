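#' Ground-truth parameter set for one clone x light combination
#'
#' Bundles the "true" values the synthetic generators draw from, so every
#' downstream analysis stage can be tested by parameter recovery. Defaults
#' describe a generic mid-range duckweed culture; [default_clone_params()]
#' supplies a full 4-clone x 2-light design with values in the ranges the
#' study system exhibits.
#'
#' @param clone_id Clone label.
#' @param light_level `"low"` or `"high"`.
#' @param rgr_true Relative growth rate, day^-1 (0.36-0.55 in this system).
#' @param frond_length_mean Mature frond length, mm.
#' @param length_width_ratio Length-to-width ratio (>= 1).
#' @param fma_true Frond mass-to-area ratio, mg cm^-2.
#' @param yii_young,yii_mature Y(II) of a 1 mm frond and of a mature frond;
#'   `0 < yii_young <= yii_mature < 1`.
#' @param ynpq_share Fraction of the non-photochemical loss (1 - Y(II))
#'   that is regulated, in \[0, 1\].
#' @param alpha_true Initial RLC slope, electrons per photon.
#' @param retrmax_true Maximal electron transport rate, umol e- m^-2 s^-1.
#' @param chl_a_true,chl_b_true,car_true Pigment contents, ug g^-1 fresh mass.
#' @param noise_sd Per-channel Gaussian noise sd (yield units for images).
#' @return List of class `clone_light_params`.
#' @export
clone_light_params <- function(clone_id, light_level = c("low", "high"),
                               rgr_true = 0.45, frond_length_mean = 4.0,
                               length_width_ratio = 1.5, fma_true = 2.0,
                               yii_young = 0.45, yii_mature = 0.55,
                               ynpq_share = 0.6, alpha_true = 0.30,
                               retrmax_true = 60,
                               chl_a_true = 800, chl_b_true = 300,
                               car_true = 200, noise_sd = 0.01) {
  light_level <- match.arg(light_level)
  if (rgr_true <= 0 || alpha_true <= 0 || retrmax_true <= 0)
    stop("rgr_true, alpha_true and retrmax_true must be positive")
  if (!(yii_young > 0 && yii_young <= yii_mature && yii_mature < 1))
    stop("need 0 < yii_young <= yii_mature < 1")
  if (ynpq_share < 0 || ynpq_share > 1)
    stop("ynpq_share must lie in [0, 1]")
  if (length_width_ratio < 1)
    stop("length_width_ratio must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(
    clone_id = clone_id, light_level = light_level, rgr_true = rgr_true,
    frond_length_mean = frond_length_mean,
    length_width_ratio = length_width_ratio, fma_true = fma_true,
    yii_young = yii_young, yii_mature = yii_mature,
    ynpq_share = ynpq_share, alpha_true = alpha_true,
    retrmax_true = retrmax_true, chl_a_true = chl_a_true,
    chl_b_true = chl_b_true, car_true = car_true, noise_sd = noise_sd
  ), class = "clone_light_params")
}

#' Default 4-clone x 2-light ground-truth design
#'
#' Eight parameter sets emulating a panel of four Lemna gibba clones grown
#' under a low (100 umol m^-2 s^-1) and a high (243 umol m^-2 s^-1) light
#' regime: growth rates span 0.36-0.55 day^-1, mature-frond Y(II) is
#' higher under low light (0.66-0.68 vs 0.54-0.56), 1-mm-frond Y(II) is
#' more variable under low light (0.51-0.61 vs 0.43-0.48), and high-light
#' plants have higher rETRmax and FMA but lower chlorophyll per fresh mass.
#'
#' @return Named list of [clone_light_params()] objects, one per
#'   clone x light combination.
#' @export
default_clone_params <- function() {
  spec <- list(
    #             rgr_lo rgr_hi len  lw   fma_lo fma_hi yiy_lo yim_lo yiy_hi yim_hi
    cloneA = list(0.43, 0.50, 3.6, 1.70, 1.6, 2.0, 0.56, 0.66, 0.45, 0.54),
    cloneB = list(0.47, 0.55, 3.4, 1.75, 1.7, 2.1, 0.53, 0.67, 0.47, 0.55),
    cloneC = list(0.42, 0.48, 4.4, 1.50, 1.5, 1.9, 0.51, 0.66, 0.43, 0.56),
    cloneD = list(0.36, 0.41, 4.6, 1.45, 2.4, 2.9, 0.61, 0.68, 0.48, 0.56)
  )
  out <- list()
  for (cl in names(spec)) {
    s <- spec[[cl]]
    for (lv in c("low", "high")) {
      hi <- lv == "high"
      key <- paste(cl, lv, sep = "_")
      out[[key]] <- clone_light_params(
        clone_id = cl, light_level = lv,
        rgr_true = if (hi) s[[2]] else s[[1]],
        frond_length_mean = if (hi) 0.93 * s[[3]] else s[[3]],
        length_width_ratio = if (hi) 0.97 * s[[4]] else s[[4]],
        fma_true = if (hi) s[[6]] else s[[5]],
        yii_young = if (hi) s[[9]] else s[[7]],
        yii_mature = if (hi) s[[10]] else s[[8]],
        ynpq_share = if (hi) 0.65 else 0.45,
        alpha_true = if (hi) 0.28 else 0.31,
        retrmax_true = if (hi) 78 else 48,
        chl_a_true = if (hi) 650 else 850,
        chl_b_true = if (hi) 230 else 320,
        car_true = if (hi) 210 else 190,
        noise_sd = 0.012
      )
    }
  }
  out
}

#' Simulate a frond-count growth series
#'
#' Frond numbers grow exponentially at the clone's true relative growth
#' rate; with noise enabled, daily counts are Poisson around the
#' exponential mean. Colony counts are drawn so that the mean colony size
#' (FN/CN) matches `colony_size_mean`, and senescent fronds are binomial
#' with rate `senescence_rate`. In noise-free mode all counts are the
#' rounded expectations, so downstream growth-rate estimation recovers
#' `rgr_true` to rounding error.
#'
#' @param params [clone_light_params()] object.
#' @param fn0 Initial frond count (>= 1).
#' @param days Number of days to simulate (>= 1).
#' @param seed Integer seed.
#' @param noise Logical; `FALSE` gives deterministic rounded expectations.
#' @param colony_size_mean Target mean fronds per colony.
#' @param senescence_rate Per-frond senescence probability by day 7.
#' @return Data frame `(day, frond_count, colony_count, senescent_count)`
#'   for days `0:days`.
#' @export
simulate_growth_series <- function(params, fn0 = 12, days = 7, seed = 1,
                                   noise = TRUE, colony_size_mean = 3,
                                   senescence_rate = 0.05) {
  stopifnot(inherits(params, "clone_light_params"))
  if (fn0 < 1 || days < 1) stop("fn0 and days must be positive")
  set.seed(seed)
  day <- 0:days
  mu <- fn0 * exp(params$rgr_true * day)
  if (noise) {
    fn <- c(fn0, pmax(1, stats::rpois(days, mu[-1])))
    cn <- pmax(1, stats::rbinom(days + 1, fn, 1 / colony_size_mean))
    sen <- stats::rbinom(days + 1, fn, senescence_rate * day / max(day))
  } else {
    fn <- round(mu)
    cn <- pmax(1, round(fn / colony_size_mean))
    sen <- round(fn * senescence_rate * day / max(day))
  }
  data.frame(day = day, frond_count = fn, colony_count = cn,
             senescent_count = pmin(sen, fn))
}

#' Simulate mature-frond morphometry for a vessel
#'
#' Representative mature fronds: lengths Gaussian around the clone's
#' mature mean (5% cv), width from the clone's length-to-width ratio.
#'
#' @param params [clone_light_params()] object.
#' @param n_fronds Fronds measured per vessel.
#' @param seed Integer seed.
#' @return Data frame `(frond_id, length, width, area, roundness)`.
#' @export
simulate_morphometry <- function(params, n_fronds = 5, seed = 1) {
  stopifnot(inherits(params, "clone_light_params"))
  set.seed(seed)
  len <- stats::rnorm(n_fronds, params$frond_length_mean,
                      0.05 * params$frond_length_mean)
  len <- pmax(len, 0.5)
  # width varies slightly around the clone's shape ratio
  wid <- len / params$length_width_ratio * stats::rnorm(n_fronds, 1, 0.02)
  wid <- pmin(wid, len)
  data.frame(frond_id = seq_len(n_fronds), length = len, width = wid,
             area = ellipse_area(len, wid), roundness = len / wid)
}

#' Simulate a fast (OJIP) fluorescence transient
#'
#' Builds a monotone non-decreasing transient on a logarithmic time grid
#' from 10 us to 2 s that passes exactly through the requested landmarks
#' (F0 at 50 us, FJ at 2 ms, FI at 30 ms, Fm at `t_fm`), using monotone
#' piecewise-cubic interpolation in log-time between them. The canonical
#' landmark times are included in the sample grid, so landmark
#' re-extraction recovers the inputs exactly in noise-free mode.
#'
#' @param f0,fj,fi,fm Landmark fluorescences (AU); `f0 < fj <= fi <= fm`.
#' @param f300 Optional fluorescence at 300 us; defaults to a point on the
#'   monotone O-J interpolant.
#' @param t_fm Time of the maximum, s.
#' @param n Number of logarithmically spaced samples.
#' @param noise_sd Additive Gaussian noise sd (AU).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Data frame of class `ojip_transient` with `time_s`,
#'   `fluorescence`.
#' @export
simulate_ojip <- function(f0, fj, fi, fm, f300 = NULL, t_fm = 0.3,
                          n = 160, noise_sd = 0, seed = 1) {
  if (!(f0 < fj && fj <= fi && fi <= fm))
    stop("landmark ordering violated: need f0 < fj <= fi <= fm")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  knots_t <- c(1e-5, 5e-5, 2e-3, 3e-2, t_fm, 2)
  knots_f <- c(f0, f0, fj, fi, fm, fm)
  if (!is.null(f300)) {
    if (!(f300 >= f0 && f300 <= fj))
      stop("f300 must lie between f0 and fj")
    knots_t <- sort(c(knots_t, 3e-4))
    knots_f <- c(f0, f0, f300, fj, fi, fm, fm)
  }
  sf <- stats::splinefun(log10(knots_t), knots_f, method = "hyman")
  tt <- sort(unique(c(10^seq(-5, log10(2), length.out = n),
                      5e-5, 3e-4, 2e-3, 3e-2, t_fm)))
  ff <- sf(log10(tt))
  if (noise_sd > 0) {
    set.seed(seed)
    ff <- ff + stats::rnorm(length(ff), 0, noise_sd)
  }
  structure(data.frame(time_s = tt, fluorescence = ff),
            class = c("ojip_transient", "data.frame"))
}

#' Simulate a rapid light curve
#'
#' ETR follows the saturating exponential
#' `rETRmax * (1 - exp(-alpha * PPFD / rETRmax))` plus Gaussian noise;
#' per-step Y(II) is back-computed from ETR through the standard ETR
#' formula (at the zero-irradiance step Y(II) is the limiting
#' `alpha / (psii_fraction * absorptance)`).
#'
#' @param alpha_true Initial slope, e- photon^-1.
#' @param retrmax_true Plateau, umol e- m^-2 s^-1.
#' @param ppfd_steps Irradiance steps; default 13 steps spanning 0-700.
#' @param noise_sd Gaussian sd added to ETR (same units as ETR).
#' @param seed Integer seed.
#' @param psii_fraction,absorptance ETR formula constants.
#' @return Data frame of class `rapid_light_curve` with `ppfd`, `y_ii`,
#'   `etr`.
#' @export
simulate_rlc <- function(alpha_true, retrmax_true,
                         ppfd_steps = c(0, 10, 25, 45, 80, 125, 190, 260,
                                        335, 420, 510, 600, 700),
                         noise_sd = 0, seed = 1,
                         psii_fraction = 0.5, absorptance = 0.84) {
  if (alpha_true <= 0 || retrmax_true <= 0)
    stop("alpha_true and retrmax_true must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (ppfd_steps[1] != 0 || any(diff(ppfd_steps) <= 0))
    stop("ppfd_steps must be strictly increasing and start at 0")
  etr <- retrmax_true * (1 - exp(-alpha_true * ppfd_steps / retrmax_true))
  if (noise_sd > 0) {
    set.seed(seed)
    etr <- pmax(0, etr + stats::rnorm(length(etr), 0, noise_sd))
    etr[1] <- 0
  }
  fac <- psii_fraction * absorptance
  y_ii <- ifelse(ppfd_steps > 0, pmin(1, etr / (ppfd_steps * fac)),
                 pmin(1, alpha_true / fac))
  structure(data.frame(ppfd = ppfd_steps, y_ii = y_ii, etr = etr),
            class = c("rapid_light_curve", "data.frame"))
}

#' Simulate slow-kinetics quenching records
#'
#' Draws records whose yields centre on the clone's true Y(II) and NPQ
#' share: Fm is normalised to 1, Fo follows a typical dark-adapted ratio,
#' and F/Fm' are solved from the target yields so that the partition
#' recovers the truth in noise-free mode.
#'
#' @param params [clone_light_params()] object.
#' @param n Number of records.
#' @param seed Integer seed.
#' @param actinic_ppfd Nominal actinic irradiance stored with the records
#'   (81 for low-, 231 for high-light samples by default).
#' @param noise_sd Gaussian sd on the target Y(II) before solving.
#' @return Data frame `(fo, fm, f, fm_prime, actinic_ppfd)`.
#' @export
simulate_quenching <- function(params, n = 6, seed = 1,
                               actinic_ppfd = NULL,
                               noise_sd = params$noise_sd) {
  stopifnot(inherits(params, "clone_light_params"))
  set.seed(seed)
  if (is.null(actinic_ppfd))
    actinic_ppfd <- if (params$light_level == "high") 231 else 81
  y_ii <- rep(params$yii_mature, n) +
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  y_ii <- pmin(pmax(y_ii, 0.05), 0.9)
  y_npq <- params$ynpq_share * (1 - y_ii)
  y_no <- 1 - y_ii - y_npq
  fm <- 1
  f <- y_no * fm               # Y(NO) = F/Fm
  fm_prime <- f / (1 - y_ii)   # Y(II) = (Fm' - F)/Fm'
  data.frame(fo = 0.2 * fm, fm = fm, f = f, fm_prime = fm_prime,
             actinic_ppfd = actinic_ppfd)
}

#' Simulate a spectrophotometric pigment extract
#'
#' Inverts the Wellburn coefficient matrix to produce absorbances that
#' decode exactly to the requested pigment concentrations, then adds the
#' turbidity baseline and optional noise.
#'
#' @param params [clone_light_params()] object carrying the true contents
#'   (ug g^-1 fresh mass).
#' @param fresh_mass_mg Sample fresh mass, mg.
#' @param extract_volume_ml Extract volume, mL.
#' @param a750 Turbidity baseline added to all wavelengths.
#' @param noise_sd Gaussian sd on each absorbance.
#' @param seed Integer seed.
#' @return One-row data frame with the four absorbances, `fresh_mass_mg`
#'   and `extract_volume_ml`.
#' @export
simulate_pigment_extract <- function(params, fresh_mass_mg = 40,
                                     extract_volume_ml = 2, a750 = 0.01,
                                     noise_sd = 0, seed = 1) {
  stopifnot(inherits(params, "clone_light_params"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  scale <- extract_volume_ml / (fresh_mass_mg / 1000)  # mL per g FM
  conc_ml <- c(params$chl_a_true, params$chl_b_true, params$car_true) / scale
  K <- wellburn_coefficients()
  A <- solve(K, conc_ml) + a750
  if (noise_sd > 0) {
    set.seed(seed)
    A <- A + stats::rnorm(3, 0, noise_sd)
  }
  data.frame(a470 = A[3], a646_8 = A[2], a663_2 = A[1], a750 = a750,
             fresh_mass_mg = fresh_mass_mg,
             extract_volume_ml = extract_volume_ml)
}

#' Simulate an HPLC carotenoid composition
#'
#' Splits the clone's carotenoid pool (on a chlorophyll basis) into a
#' xanthophyll-cycle (VAZ) share and a de-epoxidised zeaxanthin share that
#' both increase under high light.
#'
#' @param params [clone_light_params()] object.
#' @param total_car_mmol Total carotenoids, mmol (mol Chl a+b)^-1.
#' @param vaz_share VAZ pool as a fraction of total carotenoids; default
#'   higher under high light.
#' @param z_share Zeaxanthin fraction of the VAZ pool.
#' @return One-row data frame with `violaxanthin`, `antheraxanthin`,
#'   `zeaxanthin`, `other_car`, `total_car` (mmol per mol Chl a+b).
#' @export
simulate_carotenoid_composition <- function(params, total_car_mmol = 250,
                                            vaz_share = NULL, z_share = NULL) {
  stopifnot(inherits(params, "clone_light_params"))
  hi <- params$light_level == "high"
  if (is.null(vaz_share)) vaz_share <- if (hi) 0.38 else 0.28
  if (is.null(z_share)) z_share <- if (hi) 0.35 else 0.10
  vaz <- vaz_share * total_car_mmol
  z <- z_share * vaz
  a <- 0.15 * vaz
  v <- vaz - z - a
  data.frame(violaxanthin = v, antheraxanthin = a, zeaxanthin = z,
             other_car = total_car_mmol - vaz, total_car = total_car_mmol)
}
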