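#' Extract a base-to-tip transect from a parameter-image scene
#'
#' Samples the Y(II)/Y(NPQ)/Y(NO) rasters along the straight segment from
#' the frond's base anchor to its tip anchor at 1-pixel steps with
#' nearest-pixel lookup, restricted to the frond's own label region.
#' Pixels where the segment crosses background (or another label) are
#' flagged as gaps and returned as `NA`.
#'
#' @param scene A `frond_scene` (see [render_scene()]) or an equivalent
#'   list with `parameter_images`, `label_mask`, `anchors`, `scale`.
#' @param frond_id Label of the frond to sample.
#' @return List of class `frond_transect`: `frond_id`, `pos_px`, `pos_mm`
#'   (distance from base), `values` (data frame `yii`, `ynpq`, `yno`),
#'   `frond_length_px`, `frond_length_mm`, `frond_mean` (named vector of
#'   per-parameter means over non-gap pixels), `n_gaps`.
#' @export
extract_transect <- function(scene, frond_id) {
  a <- scene$anchors[scene$anchors$frond_id == frond_id, ]
  if (nrow(a) != 1) stop("unknown frond_id: ", frond_id)
  lab <- scene$label_mask
  inb <- function(x, y) x >= 1 & x <= ncol(lab) & y >= 1 & y <= nrow(lab)
  if (!inb(a$base_x, a$base_y) || lab[a$base_y, a$base_x] != frond_id ||
      !inb(a$tip_x, a$tip_y) || lab[a$tip_y, a$tip_x] != frond_id)
    stop("anchor error: base/tip anchors must lie inside the frond mask")
  d <- sqrt((a$tip_x - a$base_x)^2 + (a$tip_y - a$base_y)^2)
  n_steps <- max(2, ceiling(d) + 1)
  tfrac <- seq(0, 1, length.out = n_steps)
  px <- round(a$base_x + tfrac * (a$tip_x - a$base_x))
  py <- round(a$base_y + tfrac * (a$tip_y - a$base_y))
  pos_px <- tfrac * d
  idx <- cbind(py, px)
  on_frond <- lab[idx] == frond_id
  vals <- data.frame(
    yii = ifelse(on_frond, scene$parameter_images$YII[idx], NA_real_),
    ynpq = ifelse(on_frond, scene$parameter_images$YNPQ[idx], NA_real_),
    yno = ifelse(on_frond, scene$parameter_images$YNO[idx], NA_real_))
  structure(list(
    frond_id = frond_id, pos_px = pos_px, pos_mm = pos_px / scene$scale,
    values = vals, frond_length_px = d, frond_length_mm = d / scene$scale,
    frond_mean = colMeans(vals, na.rm = TRUE),
    n_gaps = sum(!on_frond)
  ), class = "frond_transect")
}

#' Extract all transects of a scene
#'
#' @param scene A `frond_scene`.
#' @return List of `frond_transect` objects, one per labeled frond.
#' @export
scene_transects <- function(scene) {
  lapply(scene$anchors$frond_id, function(k) extract_transect(scene, k))
}

#' Pixel-level transect database
#'
#' @param transects List of `frond_transect` objects.
#' @return Data frame `(frond_id, pos_px, pos_mm, yii, ynpq, yno)`, one
#'   row per transect pixel (gap pixels carry `NA` values).
#' @export
pixel_database <- function(transects) {
  do.call(rbind, lapply(transects, function(tr) {
    data.frame(frond_id = tr$frond_id, pos_px = tr$pos_px,
               pos_mm = tr$pos_mm, yii = tr$values$yii,
               ynpq = tr$values$ynpq, yno = tr$values$yno)
  }))
}

#' Frond-averaged parameter table
#'
#' One row per frond passing the minimum-length filter (default 6 px,
#' i.e. > 1.0 mm at 4.6 px mm^-1), ordered by frond length then id.
#'
#' @param transects List of `frond_transect` objects.
#' @param min_length_px Minimum transect length in pixels.
#' @return Data frame `(frond_id, frond_length_px, frond_length_mm,
#'   mean_yii, mean_ynpq, mean_yno)`.
#' @export
frond_average_table <- function(transects, min_length_px = 6) {
  if (length(transects) == 0) stop("no transects supplied")
  keep <- vapply(transects, function(tr) tr$frond_length_px >= min_length_px,
                 logical(1))
  rows <- lapply(transects[keep], function(tr) {
    data.frame(frond_id = tr$frond_id,
               frond_length_px = tr$frond_length_px,
               frond_length_mm = tr$frond_length_mm,
               mean_yii = tr$frond_mean[["yii"]],
               mean_ynpq = tr$frond_mean[["ynpq"]],
               mean_yno = tr$frond_mean[["yno"]])
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$frond_length_mm, tab$frond_id), , drop = FALSE]
}

#' Minimum analysable frond length in mm
#'
#' The pixel-length filter expressed in physical units:
#' `min_length_px / scale`.
#'
#' @param min_length_px Minimum transect length, pixels.
#' @param scale Pixels per mm.
#' @return Length in mm.
#' @export
min_transect_length_mm <- function(min_length_px = 6, scale = 4.6) {
  if (min_length_px <= 0 || scale <= 0) stop("arguments must be positive")
  min_length_px / scale
}

#' Ontogeny regression of frond-mean parameters on frond length
#'
#' Ordinary least-squares fit of each frond-averaged fluorescence
#' parameter on frond length, the standard test for ontogeny-dependent
#' trends. Predictions at reference lengths (e.g. 1 mm and the mature
#' length) can be obtained from the returned fits.
#'
#' @param table Frond-average table from [frond_average_table()].
#' @param parameters Which mean columns to regress.
#' @return List with `summary` (data frame: parameter, slope, intercept,
#'   r2, p) and `fits` (named list of `lm` objects).
#' @export
ontogeny_regression <- function(table,
                                parameters = c("mean_yii", "mean_ynpq",
                                               "mean_yno")) {
  if (nrow(table) < 3) stop("need at least 3 fronds for a regression")
  if (length(unique(table$frond_length_mm)) < 2)
    stop("rank deficiency: all frond lengths identical")
  fits <- list()
  rows <- lapply(parameters, function(p) {
    fit <- stats::lm(table[[p]] ~ frond_length_mm, data = table)
    fits[[p]] <<- fit
    if (stats::sd(table[[p]]) == 0) {
      # constant response: flat line, no explainable variance
      return(data.frame(parameter = p, slope = 0,
                        intercept = table[[p]][1], r2 = 0, p = NA_real_))
    }
    sm <- summary(fit)
    pval <- if (nrow(sm$coefficients) > 1 && sm$coefficients[2, 2] > 0)
      sm$coefficients[2, 4] else NA_real_
    data.frame(parameter = p, slope = stats::coef(fit)[[2]],
               intercept = stats::coef(fit)[[1]],
               r2 = sm$r.squared, p = pval)
  })
  list(summary = do.call(rbind, rows), fits = fits)
}

#' Predict a fitted ontogeny trend at reference lengths
#'
#' @param regression Result of [ontogeny_regression()].
#' @param parameter Which parameter's fit to evaluate.
#' @param lengths_mm Frond lengths at which to predict.
#' @return Named numeric vector of predictions.
#' @export
predict_ontogeny <- function(regression, parameter = "mean_yii",
                             lengths_mm = c(1, 4)) {
  fit <- regression$fits[[parameter]]
  if (is.null(fit)) stop("no fit stored for ", parameter)
  p <- stats::predict(fit,
                      newdata = data.frame(frond_length_mm = lengths_mm))
  stats::setNames(as.numeric(p), paste0(lengths_mm, "mm"))
}

#' Build a size-ordered within-frond interpolation map
#'
#' Pools transect pixels into a grid of equal-count frond size classes
#' (x-axis, ordered by frond length) by within-frond position bins
#' (y-axis, absolute distance from the base in mm). Overlapping pixels in
#' a cell are reduced by their median. Under-populated largest size
#' classes (n below `min_per_bin`, at most the top `max_drop`) are
#' excluded. A smooth surface (tensor-product spline) is fitted over the
#' occupied cells for visualisation; cells with no contributing pixels
#' stay missing and are never extrapolated.
#'
#' @param transects List of `frond_transect` objects.
#' @param parameter Which parameter to map (`"yii"`, `"ynpq"`, `"yno"`).
#' @param size_bins Number of equal-count size classes.
#' @param pos_bin_mm Height of the position bins, mm.
#' @param min_per_bin Minimum fronds per size class.
#' @param max_drop Maximum number of top size classes to drop.
#' @param min_length_px Minimum transect length filter.
#' @return List of class `ontogeny_map`: `grid` (median matrix, rows =
#'   position bins from the base, cols = size classes), `smooth` (spline
#'   surface over occupied cells), `counts` (contributing pixels per
#'   cell), `pos_mm` (bin centres), `class_length_mm` (median frond
#'   length per retained class), `dropped_classes`.
#' @export
build_ontogeny_map <- function(transects, parameter = "yii", size_bins = 8,
                               pos_bin_mm = 0.25, min_per_bin = 3,
                               max_drop = 2, min_length_px = 6) {
  keep <- Filter(function(tr) tr$frond_length_px >= min_length_px, transects)
  if (length(keep) < 5)
    stop("insufficient data: fewer than 5 fronds pass the length filter")
  len <- vapply(keep, `[[`, numeric(1), "frond_length_mm")
  ids <- vapply(keep, `[[`, numeric(1), "frond_id")
  ord <- order(len, ids)
  keep <- keep[ord]; len <- len[ord]
  size_bins <- min(size_bins, length(keep))
  cls <- ceiling(seq_along(keep) / (length(keep) / size_bins))
  cls <- pmin(cls, size_bins)
  # drop under-populated top classes (at most max_drop)
  dropped <- integer()
  for (k in seq_len(max_drop)) {
    top <- max(setdiff(seq_len(size_bins), dropped))
    if (sum(cls == top & !(cls %in% dropped)) < min_per_bin)
      dropped <- c(dropped, top) else break
  }
  retain <- !(cls %in% dropped)
  if (!any(retain)) stop("insufficient data: all size classes dropped")
  keep <- keep[retain]; cls <- cls[retain]; len <- len[retain]
  max_pos <- max(vapply(keep, function(tr) max(tr$pos_mm), numeric(1)))
  breaks <- seq(0, max_pos + pos_bin_mm, by = pos_bin_mm)
  n_pos <- length(breaks) - 1
  classes <- sort(unique(cls))
  grid <- matrix(NA_real_, nrow = n_pos, ncol = length(classes))
  counts <- matrix(0L, nrow = n_pos, ncol = length(classes))
  for (j in seq_along(classes)) {
    trs <- keep[cls == classes[j]]
    pos <- unlist(lapply(trs, `[[`, "pos_mm"))
    val <- unlist(lapply(trs, function(tr) tr$values[[parameter]]))
    ok <- !is.na(val)
    bin <- findInterval(pos[ok], breaks, rightmost.closed = TRUE)
    bin <- pmin(bin, n_pos)
    med <- tapply(val[ok], bin, stats::median)
    grid[as.integer(names(med)), j] <- med
    cnt <- tapply(val[ok], bin, length)
    counts[as.integer(names(cnt)), j] <- as.integer(cnt)
  }
  occupied <- which(!is.na(grid), arr.ind = TRUE)
  smooth <- grid
  if (nrow(occupied) >= 20) {
    df <- data.frame(v = grid[occupied], x = occupied[, 2], y = occupied[, 1])
    kx <- min(5, length(unique(df$x))); ky <- min(5, length(unique(df$y)))
    if (kx >= 3 && ky >= 3) {
      gfit <- try(mgcv::gam(v ~ te(x, y, k = c(kx, ky)), data = df),
                  silent = TRUE)
      if (!inherits(gfit, "try-error")) {
        pred <- stats::predict(gfit, newdata = df)
        smooth[occupied] <- as.numeric(pred)
      }
    }
  }
  structure(list(
    grid = grid, smooth = smooth, counts = counts,
    pos_mm = breaks[-1] - pos_bin_mm / 2,
    class_length_mm = vapply(classes, function(cc)
      stats::median(len[cls == cc]), numeric(1)),
    dropped_classes = dropped, parameter = parameter
  ), class = "ontogeny_map")
}

#' Compare apical and basal zones of an ontogeny map
#'
#' For size-class columns whose median frond length exceeds
#' `onset_length_mm`, averages the occupied cells of the apical third and
#' the basal third of each column.
#'
#' @param map An `ontogeny_map`.
#' @param onset_length_mm Only columns with longer fronds are used.
#' @return List with `apical_mean`, `basal_mean`, `n_columns`.
#' @export
map_zone_means <- function(map, onset_length_mm = 2.5) {
  cols <- which(map$class_length_mm > onset_length_mm)
  if (length(cols) == 0)
    stop("no size classes above the onset length")
  ap <- bs <- numeric()
  for (j in cols) {
    occ <- which(!is.na(map$grid[, j]))
    if (length(occ) < 3) next
    third <- max(1, floor(length(occ) / 3))
    bs <- c(bs, map$grid[occ[seq_len(third)], j])
    ap <- c(ap, map$grid[occ[seq(length(occ) - third + 1, length(occ))], j])
  }
  list(apical_mean = mean(ap), basal_mean = mean(bs),
       n_columns = length(cols))
}
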