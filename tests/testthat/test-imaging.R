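uniform_scene <- function(yii = 0.5, lengths = 3, angles = 0, seed = 1) {
  p <- clone_light_params("x", "low", yii_young = yii, yii_mature = yii,
                          ynpq_share = 0.6)
  n <- length(lengths)
  geom <- data.frame(cx = seq(80, 560, length.out = max(n, 2))[seq_len(n)],
                     cy = 240, angle = angles, length_mm = lengths)
  render_scene(p, n_fronds = n, seed = seed, geometry = geom, grad_amp = 0)
}

test_that("transects over a uniform frond are constant with the right mean", {
  sc <- uniform_scene(0.5)
  tr <- extract_transect(sc, 1)
  vals <- tr$values$yii[!is.na(tr$values$yii)]
  expect_true(all(abs(vals - 0.5) < 1e-12))
  expect_equal(tr$frond_mean[["yii"]], 0.5)
  expect_equal(tr$pos_px[1], 0)
  expect_true(all(diff(tr$pos_px) > 0))
  expect_equal(tr$pos_mm, tr$pos_px / sc$scale)
})

test_that("an axial gradient appears as a monotone base-to-tip profile", {
  p <- clone_light_params("x", "low", yii_young = 0.4, yii_mature = 0.6)
  geom <- data.frame(cx = 320, cy = 240, angle = 0, length_mm = 5)
  sc <- render_scene(p, n_fronds = 1, seed = 1, geometry = geom,
                     l50 = 2, s = 0.3, grad_amp = 0.2)
  tr <- extract_transect(sc, 1)
  v <- tr$values$yii[!is.na(tr$values$yii)]
  expect_true(all(diff(v) >= -1e-9))
  expect_gt(v[length(v)], v[1])
})

test_that("transect extraction is rotation-invariant to pixel tolerance", {
  sc0 <- uniform_scene(0.5, lengths = c(4, 4), angles = c(0, pi / 3))
  tr0 <- extract_transect(sc0, 1)
  tr1 <- extract_transect(sc0, 2)
  expect_lt(abs(tr0$frond_length_px - tr1$frond_length_px), 2)
  expect_equal(tr0$frond_mean[["yii"]], tr1$frond_mean[["yii"]],
               tolerance = 1e-9)
})

test_that("the frond-average table filters short fronds and sorts by length", {
  sc <- uniform_scene(0.5, lengths = c(0.8, 2.5, 4), angles = 0)
  trs <- scene_transects(sc)
  fa <- frond_average_table(trs, min_length_px = 6)
  # the 0.8 mm frond is below 6 px at 4.6 px/mm
  expect_equal(nrow(fa), 2)
  expect_true(all(diff(fa$frond_length_mm) > 0))
  fa_all <- frond_average_table(trs, min_length_px = 0)
  expect_equal(nrow(fa_all), 3)
})

test_that("the pixel database and frond means are mutually consistent", {
  p <- clone_light_params("x", "low", yii_young = 0.43, yii_mature = 0.55)
  sc <- render_scene(p, n_fronds = 10, seed = 21, noise = TRUE)
  trs <- scene_transects(sc)
  px <- pixel_database(trs)
  for (tr in trs) {
    sub <- px[px$frond_id == tr$frond_id, ]
    expect_equal(mean(sub$yii, na.rm = TRUE), tr$frond_mean[["yii"]],
                 tolerance = 1e-12)
  }
  closure <- px$yii + px$ynpq + px$yno
  expect_lt(max(abs(closure - 1), na.rm = TRUE), 1e-6)
})

test_that("the 6-px filter corresponds to just over 1 mm", {
  expect_equal(min_transect_length_mm(6, 4.6), 6 / 4.6)
  expect_gt(min_transect_length_mm(6, 4.6), 1.0)
  expect_equal(min_transect_length_mm(6, 4.6), 1.304, tolerance = 5e-4)
})

test_that("ontogeny regression reproduces exact and degenerate fits", {
  tab <- data.frame(frond_id = 1:6, frond_length_mm = 1:6,
                    mean_yii = 0.4 + 0.05 * (1:6),
                    mean_ynpq = rep(0.3, 6), mean_yno = 0.3 - 0.05 * (1:6))
  reg <- suppressWarnings(ontogeny_regression(tab))  # exact fit
  s <- reg$summary
  expect_equal(s$slope[s$parameter == "mean_yii"], 0.05, tolerance = 1e-12)
  expect_equal(s$r2[s$parameter == "mean_yii"], 1, tolerance = 1e-9)
  expect_equal(s$slope[s$parameter == "mean_ynpq"], 0, tolerance = 1e-12)
  expect_equal(s$r2[s$parameter == "mean_ynpq"], 0)
  pred <- predict_ontogeny(reg, "mean_yii", c(1, 4))
  expect_equal(unname(pred), c(0.45, 0.6), tolerance = 1e-12)
  const <- tab; const$frond_length_mm <- 2
  expect_error(ontogeny_regression(const), "rank")
})

test_that("regression prediction at 1 mm falls in the young-frond band", {
  p <- clone_light_params("x", "high", yii_young = 0.43, yii_mature = 0.55)
  sc <- render_scene(p, n_fronds = 30, seed = 31, noise = TRUE)
  fa <- frond_average_table(scene_transects(sc))
  reg <- ontogeny_regression(fa)
  at1 <- predict_ontogeny(reg, "mean_yii", 1)
  expect_gt(at1, 0.43 - 0.03)
  expect_lt(at1, 0.48 + 0.03)
})

test_that("the ontogeny map applies the median rule and stays flat when uniform", {
  sc <- uniform_scene(0.5, lengths = seq(1.5, 4.5, length.out = 6),
                      angles = 0)
  mp <- build_ontogeny_map(scene_transects(sc), size_bins = 3,
                           min_per_bin = 1)
  expect_true(all(abs(mp$grid[!is.na(mp$grid)] - 0.5) < 1e-12))
  # explicit median oracle on an enumerated pixel set
  expect_equal(stats::median(c(0.4, 0.5, 0.9)), 0.5)
  expect_equal(stats::median(c(0.4, 0.4, 0.5, 0.9, 0.9)), 0.5)
})

test_that("under-populated top size classes are dropped", {
  sc <- uniform_scene(0.5, lengths = c(rep(2, 6), 6), angles = 0,
                      seed = 2)
  mp <- build_ontogeny_map(scene_transects(sc), size_bins = 4,
                           min_per_bin = 3)
  expect_true(length(mp$dropped_classes) >= 1)
  expect_lt(max(mp$class_length_mm), 5)
})

test_that("the apical zone outgrows the basal zone above the onset length", {
  p <- clone_light_params("x", "low", yii_young = 0.43, yii_mature = 0.55)
  sc <- render_scene(p, n_fronds = 30, seed = 41, l50 = 2.5, s = 0.3,
                     grad_amp = 0.08)
  mp <- build_ontogeny_map(scene_transects(sc))
  z <- map_zone_means(mp, onset_length_mm = 2.5)
  expect_gt(z$apical_mean, z$basal_mean)
})

test_that("anchor errors and insufficient data raise informative signals", {
  sc <- uniform_scene(0.5)
  sc$anchors$base_x[1] <- 1  # background corner
  expect_error(extract_transect(sc, 1), "anchor")
  sc2 <- uniform_scene(0.5, lengths = c(2, 3), angles = 0)
  expect_error(build_ontogeny_map(scene_transects(sc2)), "insufficient")
})
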