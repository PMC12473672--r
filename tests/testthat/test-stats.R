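balanced_table <- function(seed, effect_clone = 0, effect_light = 0,
                           effect_int = 0, sd = 1, n_rep = 6,
                           lognormal = FALSE) {
  set.seed(seed)
  d <- expand.grid(clone = paste0("c", 1:4), light = c("low", "high"),
                   rep = seq_len(n_rep))
  mu <- 10 + effect_clone * as.integer(d$clone) +
    effect_light * (d$light == "high") +
    effect_int * (d$clone == "c1") * (d$light == "high")
  if (lognormal) {
    d$response <- exp(rnorm(nrow(d), log(mu), 0.5))
  } else {
    d$response <- rnorm(nrow(d), mu, sd)
  }
  d
}

test_that("well-behaved data pass the precondition checks on most seeds", {
  flags <- vapply(1:20, function(s)
    check_assumptions(balanced_table(s))$log_transform_applied, logical(1))
  expect_gt(mean(!flags), 0.5)
})

test_that("skewed heteroscedastic data trigger the log-transform branch", {
  flags <- vapply(1:20, function(s)
    check_assumptions(balanced_table(s, effect_clone = 3,
                                     lognormal = TRUE))$log_transform_applied,
    logical(1))
  expect_gt(mean(flags), 0.5)
})

test_that("constant responses are passed through with a warning", {
  tab <- balanced_table(1)
  tab$response <- 5
  expect_warning(chk <- check_assumptions(tab), "constant")
  expect_false(chk$log_transform_applied)
})

test_that("the log-transform guard rejects non-positive responses", {
  tab <- balanced_table(1)
  set.seed(2)
  tab$response <- stats::rexp(nrow(tab))^3  # strongly non-normal
  tab$response[1] <- -1
  expect_error(check_assumptions(tab), "transform failure")
})

test_that("the 2x2 hand example decomposes into SS (8, 2, 0, 0)", {
  d <- data.frame(clone = rep(c("a", "a", "b", "b"), each = 2),
                  light = rep(c("low", "high", "low", "high"), each = 2),
                  response = c(1, 1, 2, 2, 3, 3, 4, 4))
  aw <- two_way_anova_omega(d)
  expect_equal(aw$ss[aw$term == "clone"], 8, tolerance = 1e-12)
  expect_equal(aw$ss[aw$term == "light"], 2, tolerance = 1e-12)
  expect_equal(aw$ss[aw$term == "clone:light"], 0, tolerance = 1e-12)
  expect_equal(aw$ss[aw$term == "Residuals"], 0, tolerance = 1e-12)
})

test_that("all-constant responses give zero SS and omega-squared by convention", {
  d <- balanced_table(1)
  d$response <- 7
  aw <- two_way_anova_omega(d)
  expect_true(all(aw$ss == 0))
  expect_equal(aw$omega_sq[aw$term != "Residuals"], c(0, 0, 0))
})

test_that("SS and F match the mean-decomposition oracle on random tables", {
  for (s in 1:50) {
    d <- random_balanced_table(s)
    aw <- two_way_anova_omega(d)
    or <- anova_oracle(d$response, d$clone, d$light)
    expect_equal(aw$ss[aw$term == "clone"], unname(or$ss["a"]),
                 tolerance = 1e-9)
    expect_equal(aw$ss[aw$term == "light"], unname(or$ss["b"]),
                 tolerance = 1e-9)
    expect_equal(aw$ss[aw$term == "clone:light"], unname(or$ss["ab"]),
                 tolerance = 1e-9)
    expect_equal(aw$ss[aw$term == "Residuals"], unname(or$ss["e"]),
                 tolerance = 1e-9)
    expect_equal(aw$f[aw$term == "clone"], unname(or$f["a"]),
                 tolerance = 1e-9)
    expect_equal(aw$f[aw$term == "clone:light"], unname(or$f["ab"]),
                 tolerance = 1e-9)
    expect_equal(sum(aw$ss), sum(or$ss), tolerance = 1e-9)
  }
})

test_that("omega-squared of null terms is near zero on average", {
  om <- vapply(1:200, function(s) {
    aw <- two_way_anova_omega(balanced_table(s))
    aw$omega_sq[aw$term == "clone:light"]
  }, numeric(1))
  expect_lt(abs(mean(om)), 0.02)
})

test_that("Bonferroni adjustment is monotone and capped at 1", {
  p <- c(0.001, 0.01, 0.2, 0.5)
  adj <- bonferroni(p, 6)
  expect_equal(adj, pmin(1, p * 6))
  expect_true(all(diff(adj) >= 0))
  expect_equal(bonferroni(bonferroni(0.9, 6), 1), 1)
})

test_that("a strong interaction fires the interaction branch", {
  hits <- vapply(1:20, function(s) {
    cc <- cascade(balanced_table(s, effect_int = 3))
    "interaction" %in% cc$branch_taken
  }, logical(1))
  expect_gte(sum(hits), 15)
  cc <- cascade(balanced_table(1, effect_int = 3))
  if ("interaction" %in% cc$branch_taken) {
    expect_true(all(c("light=low", "light=high") %in% cc$posthoc$scope))
    expect_equal(cc$posthoc$p_adj,
                 pmin(1, cc$posthoc$p_raw * 6))
  }
})

test_that("null data mostly take no branch (type-I control)", {
  none <- vapply(1:60, function(s) {
    identical(cascade(balanced_table(s + 500))$branch_taken, "none")
  }, logical(1))
  expect_gt(mean(none), 0.7)
})

test_that("a clone main effect in pigment mode uses the nonparametric path", {
  cc <- cascade(balanced_table(7, effect_clone = 2), mode = "pigment")
  expect_true("clone_main" %in% cc$branch_taken)
  expect_equal(nrow(cc$posthoc), 6)  # 4 clones -> 6 pairs
  expect_equal(cc$posthoc$p_adj, pmin(1, cc$posthoc$p_raw * 6))
})

test_that("a light main effect produces per-clone F- and t-contrasts", {
  cc <- cascade(balanced_table(3, effect_light = 3))
  expect_true("light_main" %in% cc$branch_taken)
  expect_equal(nrow(cc$light_contrasts), 4)
  expect_true(all(cc$light_contrasts$t_test_p < 0.05))
})

test_that("the cascade is a pure function of its inputs", {
  tab <- balanced_table(11, effect_clone = 1.5, effect_light = 2)
  c1 <- cascade(tab)
  c2 <- cascade(tab)
  expect_identical(c1$branch_taken, c2$branch_taken)
  expect_identical(c1$two_way, c2$two_way)
})

test_that("ANCOVA detects a pure offset between light groups", {
  set.seed(5)
  tab <- data.frame(frond_length_mm = rep(seq(1, 5, length.out = 30), 2),
                    light = rep(c("low", "high"), each = 30))
  tab$mean_yii <- 0.4 + 0.03 * tab$frond_length_mm +
    0.1 * (tab$light == "low") + rnorm(60, 0, 1e-6)
  a <- ancova_light_contrast(tab)
  expect_equal(abs(a$group_effect), 0.1, tolerance = 1e-4)
  expect_lt(a$p, 1e-10)
  tab$mean_yii <- 0.4 + 0.03 * tab$frond_length_mm + rnorm(60, 0, 1e-6)
  a0 <- ancova_light_contrast(tab)
  expect_lt(abs(a0$group_effect), 1e-4)
})

test_that("ANCOVA separates the study's light regimes at realistic noise", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    len <- runif(60, 1, 5)
    light <- rep(c("low", "high"), each = 30)
    yii <- ifelse(light == "low", 0.55 + 0.0275 * len, 0.44 + 0.0275 * len) +
      rnorm(60, 0, 0.02)
    tab <- data.frame(frond_length_mm = len, light = light, mean_yii = yii)
    ancova_light_contrast(tab)$p < 1e-4
  }, logical(1))
  expect_gte(sum(hits), 18)
})
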