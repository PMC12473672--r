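#' Partition absorbed excitation energy into Y(II), Y(NPQ) and Y(NO)
#'
#' From a slow-kinetics quenching record (steady-state fluorescence F under
#' actinic light, light-adapted maximum Fm' and dark-adapted maximum Fm),
#' computes the three complementary quantum yields:
#' `Y(II) = (Fm' - F)/Fm'` (photochemistry),
#' `Y(NO) = F/Fm` (non-regulated dissipation),
#' `Y(NPQ) = F/Fm' - F/Fm` (regulated non-photochemical quenching).
#' The three yields sum to 1 by construction.
#'
#' @param f Steady-state fluorescence under actinic light (AU).
#' @param fm_prime Light-adapted maximal fluorescence (AU).
#' @param fm Dark-adapted maximal fluorescence (AU).
#' @return List with `y_ii`, `y_npq`, `y_no`.
#' @examples
#' quenching_partition(0.2, 0.4, 1.0)  # Y(II)=0.5, Y(NPQ)=0.3, Y(NO)=0.2
#' @export
quenching_partition <- function(f, fm_prime, fm) {
  if (any(f <= 0) || any(fm_prime <= 0) || any(fm <= 0))
    stop("fluorescence values must be positive")
  if (any(fm_prime > fm))
    stop("inconsistent record: Fm' exceeds dark-adapted Fm")
  if (any(f > fm_prime))
    stop("inconsistent record: F exceeds Fm'")
  list(y_ii = (fm_prime - f) / fm_prime,
       y_npq = f / fm_prime - f / fm,
       y_no = f / fm)
}

#' Maximal dark-adapted PSII photochemical yield
#'
#' @param fo Minimal dark-adapted fluorescence (AU).
#' @param fm Maximal dark-adapted fluorescence (AU); must exceed `fo`.
#' @return `Fv/Fm = (Fm - Fo)/Fm`.
#' @export
fv_fm <- function(fo, fm) {
  if (any(fo <= 0)) stop("Fo must be positive")
  if (any(fm <= fo)) stop("degenerate record: Fm must exceed Fo")
  (fm - fo) / fm
}

#' PSII electron transport rate
#'
#' `ETR = Y(II) * PPFD * psii_fraction * absorptance`, with the usual
#' assumptions of an even excitation split between the photosystems (0.5)
#' and an empirical leaf absorptance of 0.84.
#'
#' @param y_ii Effective PSII yield in \[0, 1\].
#' @param ppfd Actinic photon flux density, umol m^-2 s^-1.
#' @param psii_fraction Fraction of absorbed photons reaching PSII.
#' @param absorptance Fraction of incident light absorbed by the plant.
#' @return ETR in umol electrons m^-2 s^-1.
#' @examples
#' electron_transport_rate(0.5, 100)  # 21
#' @export
electron_transport_rate <- function(y_ii, ppfd, psii_fraction = 0.5,
                                    absorptance = 0.84) {
  if (any(y_ii < 0) || any(y_ii > 1)) stop("Y(II) must lie in [0, 1]")
  if (any(ppfd < 0)) stop("PPFD must be non-negative")
  y_ii * ppfd * psii_fraction * absorptance
}

#' Fit a rapid light curve with a saturating exponential
#'
#' Fits `ETR(I) = a * (1 - exp(-b * I))` to a stepped-irradiance rapid
#' light curve by least squares and reports the standard derived
#' parameters: `retrmax = a` (the plateau), `alpha = a * b` (the initial
#' slope, i.e. the derivative at zero irradiance) and `ek = retrmax/alpha
#' = 1/b` (onset of light saturation). Positivity of both parameters is
#' enforced by fitting on the log scale; starting values are the maximal
#' observed ETR and the secant slope of the first non-zero steps.
#'
#' @param ppfd Irradiance steps, umol m^-2 s^-1; at least 5 distinct values
#'   including 0.
#' @param etr Electron transport rate at each step. Supply either `etr` or
#'   `y_ii` (from which ETR is computed via [electron_transport_rate()]).
#' @param y_ii Optional per-step Y(II) values.
#' @param psii_fraction,absorptance Passed to [electron_transport_rate()]
#'   when `y_ii` is given.
#' @param max_restarts Number of perturbed restarts on non-convergence.
#' @return List of class `rlc_fit` with `alpha`, `retrmax`, `ek`, `rss`,
#'   `converged` and the fitted values.
#' @export
fit_rlc <- function(ppfd, etr = NULL, y_ii = NULL, psii_fraction = 0.5,
                    absorptance = 0.84, max_restarts = 5) {
  if (is.null(etr)) {
    if (is.null(y_ii)) stop("supply either etr or y_ii")
    etr <- electron_transport_rate(y_ii, ppfd, psii_fraction, absorptance)
  }
  if (length(ppfd) != length(etr)) stop("ppfd and etr lengths differ")
  if (length(unique(ppfd)) < 5)
    stop("need at least 5 distinct irradiance steps")
  if (!any(ppfd == 0))
    stop("the rapid light curve must include a zero-irradiance step")
  if (all(etr <= 0)) stop("degenerate curve: all ETR values are zero")
  ord <- order(ppfd)
  I <- ppfd[ord]; E <- etr[ord]
  a0 <- max(E)
  nz <- which(I > 0 & E > 0)
  b0 <- if (length(nz) >= 1) max(E[nz[1]] / I[nz[1]], 1e-6) / a0 else 1e-3
  dat <- data.frame(I = I, E = E)
  fit <- NULL
  start <- c(la = log(a0), lb = log(b0))
  for (k in seq_len(max_restarts + 1)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(E ~ exp(la) * (1 - exp(-exp(lb) * I)),
                        data = dat, start = as.list(start),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
    start <- start + stats::rnorm(2, sd = 0.3)
  }
  if (is.null(fit))
    stop("rapid-light-curve fit failed to converge after restarts")
  cf <- stats::coef(fit)
  a <- exp(cf[["la"]]); b <- exp(cf[["lb"]])
  structure(list(
    alpha = a * b, retrmax = a, ek = 1 / b,
    rss = sum(stats::residuals(fit)^2),
    converged = TRUE,
    fitted = a * (1 - exp(-b * I)),
    ppfd = I, etr = E
  ), class = "rlc_fit")
}

#' Quenching partition for a table of records
#'
#' @param records Data frame with columns `fo`, `fm`, `f`, `fm_prime` and
#'   optionally `actinic_ppfd`.
#' @return The input with `fv_fm`, `y_ii`, `y_npq`, `y_no` and (when
#'   `actinic_ppfd` is present) `etr` columns appended.
#' @export
quenching_table <- function(records) {
  stopifnot(all(c("fo", "fm", "f", "fm_prime") %in% names(records)))
  p <- quenching_partition(records$f, records$fm_prime, records$fm)
  out <- records
  out$fv_fm <- fv_fm(records$fo, records$fm)
  out$y_ii <- p$y_ii
  out$y_npq <- p$y_npq
  out$y_no <- p$y_no
  if ("actinic_ppfd" %in% names(records))
    out$etr <- electron_transport_rate(p$y_ii, records$actinic_ppfd)
  out
}
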