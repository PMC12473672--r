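#' Within-frond Y(II) maturation model
#'
#' Photochemical efficiency of duckweed fronds increases with frond
#' length (maturation) and, above an onset length, displays a basipetal
#' axial gradient (the apical, ontogenetically older tissue performs
#' better than the basal zone). The model is a logistic in frond length
#' with an additive axial ramp:
#' `YII(u, L) = yii_young + (yii_mature - yii_young) * logistic((L - l50)/s)
#'  + grad_amp * (u - 0.5) * logistic((L - l50)/s)`
#' where `u` in \[0, 1\] is the relative position along the base-to-tip
#' axis (0 = base) and `L` the frond length in mm.
#'
#' @param u Relative axial position, 0 = base, 1 = tip.
#' @param length_mm Frond length, mm.
#' @param params [clone_light_params()] object.
#' @param l50 Length at half-maturation, mm; the gradient onset.
#' @param s Logistic scale, mm.
#' @param grad_amp Full base-to-tip amplitude of the axial gradient
#'   (yield units) at full maturation.
#' @return Y(II) values clamped to \[0.02, 0.98\].
#' @export
yii_maturation <- function(u, length_mm, params, l50 = 2.75, s = 0.4,
                           grad_amp = 0.05) {
  m <- stats::plogis((length_mm - l50) / s)
  y <- params$yii_young + (params$yii_mature - params$yii_young) * m +
    grad_amp * (u - 0.5) * m
  pmin(pmax(y, 0.02), 0.98)
}

#' Render a synthetic chlorophyll-fluorescence imaging scene
#'
#' Generates the 2-D parameter rasters an imaging fluorometer would
#' deliver: a Y(II), Y(NPQ) and Y(NO) image (background sentinel -1), an
#' integer label mask (0 = background, k = frond k) and per-frond base/tip
#' anchor coordinates. Fronds are non-overlapping rotated ellipses on a
#' 640 x 480 canvas at 4.6 px mm^-1; foreground Y(II) follows
#' [yii_maturation()], Y(NPQ) is `ynpq_share * (1 - YII)` and Y(NO) the
#' remainder, so the three yields close to 1 at every foreground pixel.
#'
#' Frond lengths are drawn uniformly between `min_length_mm` and ~5% above
#' the clone's mature mean, emulating the mixed-age colonies the imaging
#' protocol samples.
#'
#' @param params [clone_light_params()] object.
#' @param n_fronds Number of fronds to place (>= 1).
#' @param seed Integer seed.
#' @param width,height Canvas size in pixels.
#' @param scale Pixels per mm.
#' @param min_length_mm Smallest frond length drawn.
#' @param noise Logical; add per-pixel Gaussian noise (sd `params$noise_sd`)
#'   to Y(II) before deriving the other yields (closure is preserved).
#' @param geometry Optional data frame `(cx, cy, angle, length_mm)`
#'   overriding random placement (one row per frond); used for
#'   deterministic geometric tests.
#' @param l50,s,grad_amp Passed to [yii_maturation()].
#' @param max_retries Placement attempts per frond before failing.
#' @return List of class `frond_scene`: `parameter_images` (named list of
#'   matrices `YII`, `YNPQ`, `YNO`), `label_mask`, `anchors` (data frame
#'   with base/tip pixel coordinates and true length), `scale`.
#' @export
render_scene <- function(params, n_fronds = 30, seed = 1, width = 640,
                         height = 480, scale = 4.6, min_length_mm = 1.1,
                         noise = FALSE, geometry = NULL, l50 = 2.75,
                         s = 0.4, grad_amp = 0.05, max_retries = 60) {
  stopifnot(inherits(params, "clone_light_params"))
  if (n_fronds < 1) stop("n_fronds must be >= 1")
  set.seed(seed)
  lab <- matrix(0L, nrow = height, ncol = width)
  yii <- matrix(-1, nrow = height, ncol = width)
  anchors <- data.frame(frond_id = integer(), base_x = integer(),
                        base_y = integer(), tip_x = integer(),
                        tip_y = integer(), length_mm = numeric())
  max_len <- 1.05 * params$frond_length_mean
  for (k in seq_len(n_fronds)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      if (!is.null(geometry)) {
        g <- geometry[k, ]
        cx <- g$cx; cy <- g$cy; th <- g$angle; L <- g$length_mm
      } else {
        L <- stats::runif(1, min_length_mm, max_len)
        th <- stats::runif(1, 0, pi)
        a_px <- L * scale / 2
        cx <- stats::runif(1, a_px + 2, width - a_px - 2)
        cy <- stats::runif(1, a_px + 2, height - a_px - 2)
      }
      a_px <- L * scale / 2
      b_px <- (L / params$length_width_ratio) * scale / 2
      # bounding box of the rotated ellipse, 1-px margin
      hw <- sqrt((a_px * cos(th))^2 + (b_px * sin(th))^2) + 1
      hh <- sqrt((a_px * sin(th))^2 + (b_px * cos(th))^2) + 1
      xs <- max(1, floor(cx - hw)):min(width, ceiling(cx + hw))
      ys <- max(1, floor(cy - hh)):min(height, ceiling(cy + hh))
      dx <- outer(rep(1, length(ys)), xs - cx)
      dy <- outer(ys - cy, rep(1, length(xs)))
      ax <- (dx * cos(th) + dy * sin(th)) / a_px   # axial, -1..1
      tv <- (-dx * sin(th) + dy * cos(th)) / b_px  # transverse
      inside <- ax^2 + tv^2 <= 1
      if (!any(inside)) next
      sub <- lab[ys, xs, drop = FALSE]
      if (any(sub[inside] != 0)) next  # would overlap an existing frond
      u <- (ax[inside] + 1) / 2        # 0 at base, 1 at tip
      yv <- yii_maturation(u, L, params, l50 = l50, s = s,
                           grad_amp = grad_amp)
      if (noise && params$noise_sd > 0)
        yv <- pmin(pmax(yv + stats::rnorm(length(yv), 0, params$noise_sd),
                        0.02), 0.98)
      sub[inside] <- k
      lab[ys, xs] <- sub
      ysub <- yii[ys, xs, drop = FALSE]
      ysub[inside] <- yv
      yii[ys, xs] <- ysub
      dir <- c(cos(th), sin(th))
      base <- c(cx, cy) - 0.92 * a_px * dir
      tip <- c(cx, cy) + 0.92 * a_px * dir
      # pull anchors inward until they land on the frond's own label
      for (frac in seq(0.92, 0, by = -0.04)) {
        base <- round(c(cx, cy) - frac * a_px * dir)
        if (lab[base[2], base[1]] == k) break
      }
      for (frac in seq(0.92, 0, by = -0.04)) {
        tip <- round(c(cx, cy) + frac * a_px * dir)
        if (lab[tip[2], tip[1]] == k) break
      }
      anchors <- rbind(anchors, data.frame(
        frond_id = k, base_x = base[1], base_y = base[2],
        tip_x = tip[1], tip_y = tip[2], length_mm = L))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("failed to place frond ", k, " without overlap after ",
           max_retries, " retries; reduce n_fronds or frond size")
  }
  ynpq <- ifelse(yii >= 0, params$ynpq_share * (1 - yii), -1)
  yno <- ifelse(yii >= 0, 1 - yii - params$ynpq_share * (1 - yii), -1)
  structure(list(
    parameter_images = list(YII = yii, YNPQ = ynpq, YNO = yno),
    label_mask = lab, anchors = anchors, scale = scale
  ), class = "frond_scene")
}

#' @export
print.frond_scene <- function(x, ...) {
  cat("frond_scene:", nrow(x$anchors), "fronds on",
      ncol(x$label_mask), "x", nrow(x$label_mask), "px canvas at",
      x$scale, "px/mm\n")
  invisible(x)
}
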