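test_that("noise-free growth series follows the exponential law exactly", {
  p <- clone_light_params("x", "low", rgr_true = 0.36)
  g <- simulate_growth_series(p, fn0 = 10, days = 7, noise = FALSE)
  expect_equal(g$frond_count[g$day == 7], round(10 * exp(0.36 * 7)))
  expect_equal(g$frond_count[g$day == 7], 124)
  expect_true(all(diff(g$frond_count) >= 0))
  rgr_hat <- relative_growth_rate(g$frond_count[1], g$frond_count[8])
  expect_lt(abs(rgr_hat - 0.36), 6e-4)
  # zero-growth identity via a tiny positive rate rounded away
  p0 <- clone_light_params("x", "low", rgr_true = 1e-9)
  g0 <- simulate_growth_series(p0, fn0 = 10, days = 7, noise = FALSE)
  expect_true(all(g0$frond_count == 10))
  expect_error(simulate_growth_series(p, fn0 = 0), "positive")
})

test_that("growth series counts are integer, bounded and seed-deterministic", {
  p <- clone_light_params("x", "high", rgr_true = 0.5)
  g1 <- simulate_growth_series(p, seed = 11)
  g2 <- simulate_growth_series(p, seed = 11)
  expect_identical(g1, g2)
  expect_true(all(g1$senescent_count <= g1$frond_count))
  expect_true(all(g1$colony_count <= g1$frond_count))
  expect_true(all(g1$frond_count == round(g1$frond_count)))
})

test_that("simulated OJIP transients pass exactly through their landmarks", {
  tr <- simulate_ojip(500, 1500, 2000, 2500)
  expect_true(all(diff(tr$fluorescence) >= -1e-9))
  lm <- extract_landmarks(tr)
  expect_equal(lm$f0, 500, tolerance = 1e-9)
  expect_equal(lm$fj, 1500, tolerance = 1e-9)
  expect_equal(lm$fi, 2000, tolerance = 1e-9)
  expect_equal(lm$fm, 2500, tolerance = 1e-9)
  expect_equal(fv_fm(lm$f0, lm$fm), 0.8, tolerance = 1e-9)
  vj <- (lm$fj - lm$f0) / (lm$fm - lm$f0)
  expect_equal(vj, 0.5, tolerance = 1e-9)
  expect_error(simulate_ojip(2500, 2500, 2500, 2500), "ordering")
  expect_error(simulate_ojip(500, 400, 2000, 2500), "ordering")
})

test_that("rapid-light-curve generator anchors at zero and saturates", {
  rl <- simulate_rlc(0.3, 60)
  expect_equal(rl$etr[rl$ppfd == 0], 0)
  big <- simulate_rlc(0.3, 60, ppfd_steps = c(0, 1e4, 2e4, 5e4, 1e5))
  expect_equal(max(big$etr), 60, tolerance = 1e-6)
  expect_error(simulate_rlc(0.3, 60, noise_sd = -1), "noise_sd")
  # round-trip recovery on the noise-free 13-step curve
  ft <- fit_rlc(rl$ppfd, rl$etr)
  expect_lt(abs(ft$alpha - 0.3) / 0.3, 1e-3)
  expect_lt(abs(ft$retrmax - 60) / 60, 1e-3)
})

test_that("rendered scenes satisfy the quenching closure at every pixel", {
  p <- clone_light_params("x", "low", yii_young = 0.43, yii_mature = 0.55,
                          ynpq_share = 0.55)
  sc <- render_scene(p, n_fronds = 12, seed = 5, noise = TRUE)
  fg <- sc$label_mask > 0
  total <- sc$parameter_images$YII[fg] + sc$parameter_images$YNPQ[fg] +
    sc$parameter_images$YNO[fg]
  expect_lt(max(abs(total - 1)), 1e-9)
  expect_true(all(sc$parameter_images$YII[!fg] == -1))
  # anchors inside own label region
  for (i in seq_len(nrow(sc$anchors))) {
    a <- sc$anchors[i, ]
    expect_equal(sc$label_mask[a$base_y, a$base_x], a$frond_id)
    expect_equal(sc$label_mask[a$tip_y, a$tip_x], a$frond_id)
  }
})

test_that("a flat maturation model gives a spatially uniform scene", {
  p <- clone_light_params("x", "low", yii_young = 0.5, yii_mature = 0.5)
  sc <- render_scene(p, n_fronds = 6, seed = 3, grad_amp = 0)
  fg <- sc$label_mask > 0
  expect_true(all(abs(sc$parameter_images$YII[fg] - 0.5) < 1e-12))
})

test_that("frond-mean Y(II) increases with frond length in noise-free scenes", {
  p <- clone_light_params("x", "low", yii_young = 0.43, yii_mature = 0.55)
  lengths <- c(1.5, 2.2, 3.0, 3.8, 4.5)
  geom <- data.frame(cx = seq(60, 580, length.out = 5), cy = 240,
                     angle = 0, length_mm = lengths)
  sc <- render_scene(p, n_fronds = 5, seed = 1, geometry = geom)
  fa <- frond_average_table(scene_transects(sc))
  expect_true(all(diff(fa$mean_yii[order(fa$frond_length_mm)]) > 0))
})

test_that("scene rendering is seed-deterministic and fails gracefully", {
  p <- clone_light_params("x", "high")
  s1 <- render_scene(p, n_fronds = 8, seed = 7, noise = TRUE)
  s2 <- render_scene(p, n_fronds = 8, seed = 7, noise = TRUE)
  expect_identical(s1$parameter_images$YII, s2$parameter_images$YII)
  expect_identical(s1$anchors, s2$anchors)
  big <- clone_light_params("x", "low", frond_length_mean = 40)
  expect_error(render_scene(big, n_fronds = 200, seed = 1, max_retries = 3),
               "place")
})

test_that("synthetic quenching records decode back to the target yields", {
  p <- clone_light_params("x", "high", yii_mature = 0.55, ynpq_share = 0.65,
                          noise_sd = 0)
  q <- simulate_quenching(p, n = 4, seed = 2, noise_sd = 0)
  yt <- quenching_table(q)
  expect_equal(yt$y_ii, rep(0.55, 4), tolerance = 1e-12)
  expect_equal(yt$y_npq, rep(0.65 * 0.45, 4), tolerance = 1e-12)
  expect_equal(yt$actinic_ppfd, rep(231, 4))
})

test_that("synthetic pigment extracts invert the coefficient matrix exactly", {
  p <- clone_light_params("x", "low", chl_a_true = 750, chl_b_true = 300,
                          car_true = 200)
  ex <- simulate_pigment_extract(p, fresh_mass_mg = 40, extract_volume_ml = 2)
  pc <- pigment_concentrations(ex$a470, ex$a646_8, ex$a663_2, ex$a750,
                               ex$fresh_mass_mg, ex$extract_volume_ml)
  expect_equal(pc$chl_a, 750, tolerance = 1e-9)
  expect_equal(pc$chl_b, 300, tolerance = 1e-9)
  expect_equal(pc$car, 200, tolerance = 1e-9)
})
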