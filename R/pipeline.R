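#' Build a run configuration
#'
#' A run configuration bundles the master seed, the per-clone ground-truth
#' parameter sets, the output directory and stage toggles. It serialises
#' losslessly to YAML, and every pipeline run writes a snapshot of the
#' configuration next to its outputs.
#'
#' @param seed Master integer seed; per-stage streams are derived from it
#'   by fixed offsets.
#' @param clone_params Named list of [clone_light_params()] objects.
#' @param output_dir Output directory.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "growth", "fluorescence", "pigments", "imaging",
#'   "stats")`.
#' @param n_vessels Vessels per clone x light combination (growth/ChlF
#'   sample size).
#' @param n_pigment_samples Pigment replicates per combination.
#' @param n_fronds_imaged Fronds rendered per imaging scene.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, clone_params = default_clone_params(),
                       output_dir = "results",
                       stages = c("simulate", "growth", "fluorescence",
                                  "pigments", "imaging", "stats"),
                       n_vessels = 6, n_pigment_samples = 4,
                       n_fronds_imaged = 30) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(seed = as.integer(seed), clone_params = clone_params,
                 output_dir = output_dir, stages = stages,
                 n_vessels = n_vessels,
                 n_pigment_samples = n_pigment_samples,
                 n_fronds_imaged = n_fronds_imaged),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_run_config` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  plain <- config
  plain$clone_params <- lapply(config$clone_params, unclass)
  yaml::write_yaml(unclass(plain), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$clone_params <- lapply(raw$clone_params, function(p)
    do.call(clone_light_params, p))
  do.call(run_config, raw[c("seed", "clone_params", "output_dir", "stages",
                            "n_vessels", "n_pigment_samples",
                            "n_fronds_imaged")])
}

# deterministic per-stage seed streams derived from the master seed
stage_seed <- function(config, stage, unit = 0) {
  offs <- c(simulate = 1000L, growth = 2000L, fluorescence = 3000L,
            pigments = 4000L, imaging = 5000L, stats = 6000L)
  (config$seed + offs[[stage]] + as.integer(unit)) %% .Machine$integer.max
}

write_csv_file <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full simulate-analyze-map-stats pipeline
#'
#' Executes the enabled stages in dependency order against synthetic data
#' generated from the configuration's ground-truth parameters, writes all
#' stage outputs as CSV under `config$output_dir`, and returns a manifest
#' listing every artifact with its md5 checksum. Reruns with the same
#' configuration reproduce identical checksums.
#'
#' Stages: `simulate` draws count, morphometry, quenching, RLC, OJIP and
#' pigment inputs; `growth` computes RGR/colony size/senescence/FMA;
#' `fluorescence` computes JIP parameters, quenching partitions and RLC
#' fits; `pigments` decodes extract absorbances and carotenoid ratios;
#' `imaging` renders one scene per clone x light and builds the transect
#' databases, ontogeny regressions and maps; `stats` runs the ANOVA
#' cascade on the assembled response tables.
#'
#' @param config A [run_config()].
#' @return List of class `run_manifest` with `artifacts` (data frame:
#'   file, md5), `stages_run`, `config_snapshot` (path), and in-memory
#'   `results` for downstream inspection.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  results <- list()
  combos <- names(config$clone_params)

  snapshot <- file.path(config$output_dir, "run_config.yaml")
  write_run_config(config, snapshot)

  if ("simulate" %in% config$stages) {
    counts <- morpho <- quench <- rlcs <- extracts <- comps <- list()
    ojips <- list()
    for (i in seq_along(combos)) {
      p <- config$clone_params[[combos[i]]]
      for (v in seq_len(config$n_vessels)) {
        sd_i <- stage_seed(config, "simulate", i * 100 + v)
        key <- paste(combos[i], v, sep = "_v")
        cnt <- simulate_growth_series(p, seed = sd_i)
        cnt$combo <- combos[i]; cnt$vessel <- v
        counts[[key]] <- cnt
        mo <- simulate_morphometry(p, seed = sd_i)
        mo$combo <- combos[i]; mo$vessel <- v
        morpho[[key]] <- mo
        qu <- simulate_quenching(p, n = 1, seed = sd_i)
        qu$combo <- combos[i]; qu$vessel <- v
        quench[[key]] <- qu
        rl <- simulate_rlc(p$alpha_true, p$retrmax_true,
                           noise_sd = 0.02 * p$retrmax_true, seed = sd_i)
        rl$combo <- combos[i]; rl$vessel <- v
        rlcs[[key]] <- rl
        fvfm_true <- 0.83 - 0.02 * (p$light_level == "high")
        f0 <- 500
        ojips[[key]] <- simulate_ojip(f0, 1500, 2000, f0 / (1 - fvfm_true),
                                      noise_sd = 5, seed = sd_i)
      }
      for (sct in seq_len(config$n_pigment_samples)) {
        sd_i <- stage_seed(config, "pigments", i * 100 + sct)
        key <- paste(combos[i], sct, sep = "_s")
        ex <- simulate_pigment_extract(p, noise_sd = 0.002, seed = sd_i)
        ex$combo <- combos[i]; ex$sample <- sct
        extracts[[key]] <- ex
        cc <- simulate_carotenoid_composition(p)
        cc$combo <- combos[i]; cc$sample <- sct
        comps[[key]] <- cc
      }
    }
    results$counts <- do.call(rbind, counts)
    results$morpho <- do.call(rbind, morpho)
    results$quench <- do.call(rbind, quench)
    results$rlc <- do.call(rbind, rlcs)
    results$ojip <- ojips
    results$extracts <- do.call(rbind, extracts)
    results$compositions <- do.call(rbind, comps)
    files <- c(files,
               write_csv_file(results$counts, config$output_dir, "counts.csv"),
               write_csv_file(results$morpho, config$output_dir, "morpho.csv"),
               write_csv_file(results$quench, config$output_dir,
                              "quenching.csv"),
               write_csv_file(results$rlc, config$output_dir, "rlc.csv"),
               write_csv_file(results$extracts, config$output_dir,
                              "extracts.csv"),
               write_csv_file(results$compositions, config$output_dir,
                              "carotenoid_composition.csv"))
  }

  if ("growth" %in% config$stages && !is.null(results$counts)) {
    rows <- lapply(split(results$counts,
                         list(results$counts$combo, results$counts$vessel)),
                   function(d) {
      gs <- growth_summary(d)
      cbind(data.frame(combo = d$combo[1], vessel = d$vessel[1]), gs)
    })
    growth <- do.call(rbind, rows)
    mo <- results$morpho
    agg <- stats::aggregate(cbind(length, width, area, roundness) ~
                              combo + vessel, data = mo, FUN = mean)
    growth <- merge(growth, agg, by = c("combo", "vessel"))
    results$growth <- growth[order(growth$combo, growth$vessel), ]
    files <- c(files, write_csv_file(results$growth, config$output_dir,
                                     "growth_summary.csv"))
  }

  if ("fluorescence" %in% config$stages && !is.null(results$quench)) {
    results$quench_yields <- quenching_table(results$quench)
    jip <- jip_table(results$ojip)
    jip$combo <- sub("_v[0-9]+$", "", jip$sample)
    results$jip <- jip
    fits <- lapply(split(results$rlc, list(results$rlc$combo,
                                           results$rlc$vessel)),
                   function(d) {
      ft <- fit_rlc(d$ppfd, d$etr)
      data.frame(combo = d$combo[1], vessel = d$vessel[1],
                 alpha = ft$alpha, retrmax = ft$retrmax, ek = ft$ek,
                 rss = ft$rss)
    })
    results$rlc_fits <- do.call(rbind, fits)
    files <- c(files,
               write_csv_file(results$quench_yields, config$output_dir,
                              "quenching_yields.csv"),
               write_csv_file(results$jip, config$output_dir, "jip.csv"),
               write_csv_file(results$rlc_fits, config$output_dir,
                              "rlc_fits.csv"))
  }

  if ("pigments" %in% config$stages && !is.null(results$extracts)) {
    ex <- results$extracts
    pc <- pigment_concentrations(ex$a470, ex$a646_8, ex$a663_2, ex$a750,
                                 ex$fresh_mass_mg, ex$extract_volume_ml)
    pig <- data.frame(combo = ex$combo, sample = ex$sample,
                      chl_a = pc$chl_a, chl_b = pc$chl_b,
                      chl_ab = pc$chl_ab, car = pc$car)
    cmp <- results$compositions
    ratio_rows <- lapply(seq_len(nrow(cmp)), function(i) {
      r <- pigment_ratios(cmp$violaxanthin[i], cmp$antheraxanthin[i],
                          cmp$zeaxanthin[i], cmp$total_car[i],
                          pig$chl_a[i], pig$chl_b[i])
      data.frame(combo = cmp$combo[i], sample = cmp$sample[i],
                 chl_a_b = r$chl_a_b, car_chl = r$car_chl,
                 vaz_car = r$vaz_car, z_vaz = r$z_vaz)
    })
    results$pigments <- pig
    results$pigment_ratios <- do.call(rbind, ratio_rows)
    files <- c(files,
               write_csv_file(pig, config$output_dir,
                              "pigment_concentrations.csv"),
               write_csv_file(results$pigment_ratios, config$output_dir,
                              "pigment_ratios.csv"))
  }

  if ("imaging" %in% config$stages) {
    fa_all <- list(); px_all <- list(); reg_all <- list()
    for (i in seq_along(combos)) {
      p <- config$clone_params[[combos[i]]]
      sc <- render_scene(p, n_fronds = config$n_fronds_imaged,
                         seed = stage_seed(config, "imaging", i),
                         noise = TRUE)
      trs <- scene_transects(sc)
      fa <- frond_average_table(trs)
      fa$combo <- combos[i]
      fa$clone <- p$clone_id
      fa$light <- p$light_level
      fa_all[[combos[i]]] <- fa
      px <- pixel_database(trs)
      px$combo <- combos[i]
      px_all[[combos[i]]] <- px
      reg <- ontogeny_regression(fa)$summary
      reg$combo <- combos[i]
      reg_all[[combos[i]]] <- reg
    }
    results$frond_averages <- do.call(rbind, fa_all)
    results$pixel_db <- do.call(rbind, px_all)
    results$ontogeny_fits <- do.call(rbind, reg_all)
    files <- c(files,
               write_csv_file(results$frond_averages, config$output_dir,
                              "frond_averages.csv"),
               write_csv_file(results$ontogeny_fits, config$output_dir,
                              "ontogeny_regressions.csv"))
  }

  if ("stats" %in% config$stages && !is.null(results$growth)) {
    resp <- results$growth
    meta <- do.call(rbind, lapply(combos, function(cb) {
      p <- config$clone_params[[cb]]
      data.frame(combo = cb, clone = p$clone_id, light = p$light_level)
    }))
    resp <- merge(resp, meta, by = "combo")
    traits <- c("rgr", "colony_size", "senescence_pct", "area", "roundness")
    casc <- lapply(traits, function(tr) {
      tab <- data.frame(response = resp[[tr]], clone = resp$clone,
                        light = resp$light)
      cascade(tab)
    })
    names(casc) <- traits
    results$cascades <- casc
    stat_rows <- do.call(rbind, lapply(traits, function(tr) {
      aw <- casc[[tr]]$two_way
      aw$trait <- tr
      aw$branch <- paste(casc[[tr]]$branch_taken, collapse = "+")
      aw
    }))
    files <- c(files, write_csv_file(stat_rows, config$output_dir,
                                     "anova_cascades.csv"))
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  manifest <- manifest[order(manifest$file), ]
  structure(list(artifacts = manifest, stages_run = config$stages,
                 config_snapshot = snapshot, results = results),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run:", paste(x$stages_run, collapse = " -> "), "\n")
  print(x$artifacts, row.names = FALSE)
  invisible(x)
}
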