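#' Check ANOVA preconditions and log-transform on violation
#'
#' Homogeneity of variances is tested with a median-centred Levene
#' (Brown-Forsythe) test across the clone x light cells, and normality
#' with a Shapiro-Wilk test on the residuals of the two-factor model. If
#' either test rejects at `alpha`, responses are natural-log-transformed
#' and the flag is set. Constant responses (where Shapiro-Wilk is
#' undefined) pass through untransformed with a warning.
#'
#' @param table Data frame with columns `response`, `clone`, `light`.
#' @param alpha Significance threshold for the precondition tests.
#' @param center Centre for the Levene test (`"median"` is the
#'   Brown-Forsythe variant).
#' @return List with `levene_p`, `shapiro_p`, `log_transform_applied`,
#'   and `table` (transformed when the flag is set).
#' @export
check_assumptions <- function(table, alpha = 0.05,
                              center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(all(c("response", "clone", "light") %in% names(table)))
  if (any(!is.finite(table$response))) stop("responses must be finite")
  tab <- table
  tab$clone <- factor(tab$clone)
  tab$light <- factor(tab$light)
  cell <- interaction(tab$clone, tab$light, drop = TRUE)
  if (stats::sd(tab$response) == 0) {
    warning("constant responses: precondition tests undefined, no transform")
    return(list(levene_p = NA_real_, shapiro_p = NA_real_,
                log_transform_applied = FALSE, table = tab))
  }
  lev <- car::leveneTest(tab$response, cell,
                         center = if (center == "median") stats::median
                                  else mean)
  levene_p <- lev[["Pr(>F)"]][1]
  res <- stats::residuals(stats::aov(response ~ clone * light, data = tab))
  shapiro_p <- tryCatch(stats::shapiro.test(res)$p.value,
                        error = function(e) NA_real_)
  violated <- (is.finite(levene_p) && levene_p < alpha) ||
    (is.finite(shapiro_p) && shapiro_p < alpha)
  if (violated) {
    if (any(tab$response <= 0))
      stop("transform failure: log-transform required but responses ",
           "are not all positive")
    tab$response <- log(tab$response)
  }
  list(levene_p = levene_p, shapiro_p = shapiro_p,
       log_transform_applied = violated, table = tab)
}

#' Two-way ANOVA with omega-squared effect sizes
#'
#' Balanced two-factor (clone x light) analysis of variance with the
#' omega-squared effect size for each term:
#' `omega2 = (SS_term - df_term * MS_error) / (SS_total + MS_error)`.
#' Omega-squared may be negative for null terms and is reported
#' unclamped, except for all-constant data where every term is 0 by
#' convention. Unbalanced inputs are accepted with a warning (the
#' sequential decomposition then depends on term order).
#'
#' @param table Data frame with `response`, `clone`, `light`.
#' @return Data frame with one row per term (`clone`, `light`,
#'   `clone:light`, `Residuals`): `df`, `ss`, `ms`, `f`, `p`, `omega_sq`.
#' @export
two_way_anova_omega <- function(table) {
  stopifnot(all(c("response", "clone", "light") %in% names(table)))
  tab <- table
  tab$clone <- factor(tab$clone)
  tab$light <- factor(tab$light)
  n_cell <- table(tab$clone, tab$light)
  if (any(n_cell < 2)) stop("need at least 2 replicates per cell")
  if (length(unique(as.vector(n_cell))) > 1)
    warning("unbalanced design: sequential SS decomposition is order-dependent")
  if (stats::sd(tab$response) == 0) {
    terms <- c("clone", "light", "clone:light", "Residuals")
    dfs <- c(nlevels(tab$clone) - 1, nlevels(tab$light) - 1,
             (nlevels(tab$clone) - 1) * (nlevels(tab$light) - 1),
             nrow(tab) - nlevels(tab$clone) * nlevels(tab$light))
    return(data.frame(term = terms, df = dfs, ss = 0, ms = 0,
                      f = c(NA, NA, NA, NA), p = c(NA, NA, NA, NA),
                      omega_sq = c(0, 0, 0, NA)))
  }
  fit <- stats::aov(response ~ clone * light, data = tab)
  sm <- summary(fit)[[1]]
  term <- trimws(rownames(sm))
  ss <- sm[["Sum Sq"]]; df <- sm[["Df"]]
  ms_error <- ss[term == "Residuals"] / df[term == "Residuals"]
  ss_total <- sum(ss)
  omega <- (ss - df * ms_error) / (ss_total + ms_error)
  omega[term == "Residuals"] <- NA
  data.frame(term = term, df = df, ss = ss, ms = sm[["Mean Sq"]],
             f = sm[["F value"]], p = sm[["Pr(>F)"]], omega_sq = omega)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)`; monotone in `p` and idempotent at the cap.
#'
#' @param p Raw p-values.
#' @param m Number of comparisons.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m) {
  if (m < 1) stop("number of comparisons must be >= 1")
  pmin(1, p * m)
}

#' Run the branch-dependent statistical decision cascade
#'
#' Implements the decision tree used for every clone x light response
#' variable:
#' \enumerate{
#'   \item Precondition checks (Levene, Shapiro-Wilk), log-transforming
#'     on violation ([check_assumptions()]).
#'   \item Two-way ANOVA with omega-squared effect sizes.
#'   \item If the interaction is significant: clones are compared
#'     separately within each light level by one-way ANOVA, with
#'     Bonferroni-corrected pairwise post hoc comparisons.
#'   \item If there is no interaction but a significant clone main
#'     effect: clone means pooled over both light levels are compared by
#'     one-way ANOVA and Tukey post hoc (parametric mode), or by
#'     Kruskal-Wallis and pairwise Mann-Whitney (pigment mode); post hoc
#'     p-values are Bonferroni-corrected.
#'   \item If the light main effect is significant: variances and means
#'     of the low- vs high-light cultures of each clone are compared by
#'     two-sample F- and t-tests.
#' }
#'
#' @param table Data frame with `response`, `clone`, `light`.
#' @param alpha Significance threshold (0.05 throughout the pipeline).
#' @param mode `"parametric"` (Tukey) or `"pigment"` (Kruskal-Wallis +
#'   Mann-Whitney) for the clone-main-effect branch.
#' @return List of class `anova_cascade`: `assumptions`, `two_way`,
#'   `branch_taken` (character vector, possibly several of
#'   `"interaction"`, `"clone_main"`, `"light_main"`, or `"none"`),
#'   `posthoc` (pairwise comparisons with raw and adjusted p),
#'   `light_contrasts` (per-clone F- and t-test p-values).
#' @export
cascade <- function(table, alpha = 0.05, mode = c("parametric", "pigment")) {
  mode <- match.arg(mode)
  chk <- check_assumptions(table, alpha)
  tab <- chk$table
  aw <- two_way_anova_omega(tab)
  p_int <- aw$p[aw$term == "clone:light"]
  p_clone <- aw$p[aw$term == "clone"]
  p_light <- aw$p[aw$term == "light"]
  branch <- character()
  posthoc <- NULL
  light_contrasts <- NULL

  # degenerate subgroups (zero variance) yield NA rather than aborting
  safe_p <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  pairwise_oneway <- function(d, label) {
    lv <- levels(droplevels(d$clone))
    prs <- utils::combn(lv, 2, simplify = FALSE)
    m <- length(prs)
    rows <- lapply(prs, function(pr) {
      x <- d$response[d$clone == pr[1]]
      y <- d$response[d$clone == pr[2]]
      praw <- if (mode == "pigment")
        safe_p(stats::wilcox.test(x, y, exact = FALSE)$p.value)
      else
        safe_p(stats::t.test(x, y, var.equal = TRUE)$p.value)
      data.frame(scope = label, a = pr[1], b = pr[2], p_raw = praw)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- bonferroni(out$p_raw, m)
    out
  }

  if (is.finite(p_int) && p_int < alpha) {
    branch <- c(branch, "interaction")
    posthoc <- do.call(rbind, lapply(levels(tab$light), function(lv) {
      d <- tab[tab$light == lv, ]
      ow <- safe_p(stats::oneway.test(response ~ clone, data = d,
                                      var.equal = TRUE)$p.value)
      ph <- pairwise_oneway(d, paste0("light=", lv))
      ph$oneway_p <- ow
      ph
    }))
  } else if (is.finite(p_clone) && p_clone < alpha) {
    branch <- c(branch, "clone_main")
    omni_p <- if (mode == "pigment")
      safe_p(stats::kruskal.test(response ~ clone, data = tab)$p.value)
    else
      safe_p(stats::oneway.test(response ~ clone, data = tab,
                                var.equal = TRUE)$p.value)
    posthoc <- pairwise_oneway(tab, "pooled")
    posthoc$oneway_p <- omni_p
  }
  if (is.finite(p_light) && p_light < alpha) {
    branch <- c(branch, "light_main")
    light_contrasts <- do.call(rbind, lapply(levels(tab$clone), function(cl) {
      d <- tab[tab$clone == cl, ]
      lv <- levels(droplevels(d$light))
      x <- d$response[d$light == lv[1]]
      y <- d$response[d$light == lv[2]]
      data.frame(clone = cl,
                 f_test_p = safe_p(stats::var.test(x, y)$p.value),
                 t_test_p = safe_p(stats::t.test(x, y,
                                                 var.equal = TRUE)$p.value))
    }))
  }
  if (length(branch) == 0) branch <- "none"
  structure(list(assumptions = chk[c("levene_p", "shapiro_p",
                                     "log_transform_applied")],
                 two_way = aw, branch_taken = branch, posthoc = posthoc,
                 light_contrasts = light_contrasts, alpha = alpha,
                 mode = mode),
            class = "anova_cascade")
}

#' ANCOVA light contrast on frond-averaged data
#'
#' Tests whether low- and high-light fronds differ in a frond-mean
#' fluorescence parameter after adjusting for frond length
#' (common-slope model `response ~ length + light`).
#'
#' @param table Data frame with columns `frond_length_mm`, `light` and the
#'   response column named by `parameter`.
#' @param parameter Response column name.
#' @return List with `group_effect` (length-adjusted difference, second
#'   factor level minus the first/reference level), `effect_label`,
#'   `p` (light term p-value), `fit`.
#' @export
ancova_light_contrast <- function(table, parameter = "mean_yii") {
  stopifnot(all(c("frond_length_mm", "light", parameter) %in% names(table)))
  tab <- data.frame(response = table[[parameter]],
                    frond_length_mm = table$frond_length_mm,
                    light = factor(table$light))
  if (nlevels(tab$light) != 2) stop("light must have exactly 2 levels")
  if (length(unique(tab$frond_length_mm)) < 2)
    stop("rank deficiency: frond lengths are constant")
  fit <- stats::lm(response ~ frond_length_mm + light, data = tab)
  sm <- summary(fit)
  cf <- sm$coefficients
  row <- grep("^light", rownames(cf))
  lv <- levels(tab$light)
  list(group_effect = unname(cf[row, 1]),  # second level minus reference
       effect_label = paste(lv[2], "-", lv[1]),
       p = unname(cf[row, 4]), fit = fit)
}

#' @export
print.anova_cascade <- function(x, ...) {
  cat("Two-way ANOVA cascade (mode:", x$mode, ")\n")
  cat("  log-transform applied:", x$assumptions$log_transform_applied, "\n")
  print(x$two_way, row.names = FALSE)
  cat("  branch taken:", paste(x$branch_taken, collapse = " + "), "\n")
  invisible(x)
}
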