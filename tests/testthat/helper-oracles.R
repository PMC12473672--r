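# Independent oracles used across tests.

# JIP parameters re-derived from first definitions, structured differently
# from the implementation (everything expressed through Fv and raw marks).
jip_oracle <- function(f0, f300, fj, fm) {
  fv <- fm - f0
  phi <- 1 - f0 / fm
  vj <- (fj - f0) / fv
  mo <- 4 * (f300 - f0) / fv
  tro <- mo / vj
  list(fv_fm = phi,
       vj = vj,
       mo = mo,
       tro_rc = tro,
       abs_rc = mo / (vj * phi),
       eto_rc = mo / vj - mo,
       dio_rc = mo / (vj * phi) - tro,
       pi_abs = (phi * vj / mo) * (phi / (1 - phi)) * ((1 - vj) / vj))
}

random_landmarks <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    f0 <- runif(1, 300, 700)
    fm <- f0 * runif(1, 3, 6)
    fj <- f0 + runif(1, 0.2, 0.8) * (fm - f0)
    f300 <- f0 + runif(1, 0.05, 0.95) * (fj - f0)
    list(f0 = f0, f300 = f300, fj = fj, fm = fm)
  })
}

random_quenching_records <- function(n, seed = 42) {
  set.seed(seed)
  fm <- 1
  fo <- runif(n, 0.1, 0.3)
  fm_prime <- runif(n, 0.35, 1) * fm
  f <- fo + runif(n) * (fm_prime - fo)
  data.frame(fo = fo, fm = fm, f = f, fm_prime = fm_prime)
}

# Brute-force balanced two-way ANOVA by explicit mean decomposition.
anova_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  gm <- mean(y)
  am <- tapply(y, a, mean)[a]
  bm <- tapply(y, b, mean)[b]
  cm <- tapply(y, interaction(a, b), mean)[interaction(a, b)]
  ss_a <- sum((am - gm)^2)
  ss_b <- sum((bm - gm)^2)
  ss_ab <- sum((cm - am - bm + gm)^2)
  ss_e <- sum((y - cm)^2)
  df_a <- nlevels(a) - 1
  df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_e <- length(y) - nlevels(a) * nlevels(b)
  ms_e <- ss_e / df_e
  list(ss = c(a = ss_a, b = ss_b, ab = ss_ab, e = ss_e),
       f = c(a = (ss_a / df_a) / ms_e, b = (ss_b / df_b) / ms_e,
             ab = (ss_ab / df_ab) / ms_e))
}

random_balanced_table <- function(seed, n_rep = 6) {
  set.seed(seed)
  d <- expand.grid(clone = paste0("c", 1:4), light = c("low", "high"),
                   rep = seq_len(n_rep))
  d$response <- rnorm(nrow(d), mean = 10, sd = 2) +
    as.integer(d$clone) * runif(1, 0, 2) +
    (d$light == "high") * runif(1, 0, 2)
  d
}
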