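## Validation metrics and the scenario orchestrator: simulate -> panels ->
## dimensionality -> GWAS -> prediction -> metrics, replicated with
## deterministic child seeds.

#' Prediction accuracy
#'
#' Pearson correlation between true and estimated breeding values of the
#' test animals.
#'
#' @param tbv true breeding values
#' @param gebv estimated breeding values (same animals, same order)
#' @return correlation
#' @export
accuracy <- function(tbv, gebv) {
  stopifnot(length(tbv) == length(gebv), length(tbv) >= 3)
  if (var(tbv) <= 0 || var(gebv) <= 0)
    stop("zero variance: accuracy undefined")
  cor(tbv, gebv)
}

#' Dispersion of genomic predictions
#'
#' Regression coefficient of TBV on GEBV; values below 1 flag inflation,
#' above 1 deflation.
#'
#' @inheritParams accuracy
#' @return slope `cov(tbv, gebv) / var(gebv)`
#' @export
dispersion_b1 <- function(tbv, gebv) {
  stopifnot(length(tbv) == length(gebv))
  v <- var(gebv)
  if (v <= 0) stop("zero GEBV variance: b1 undefined")
  cov(tbv, gebv) / v
}

#' Percent accuracy gain from adding preselected variants
#'
#' @param acc_with accuracy with the augmented panel
#' @param acc_base baseline accuracy (the plain chip)
#' @return gain in percent, `100 * (acc_with - acc_base) / acc_base`
#' @export
accuracy_gain_pct <- function(acc_with, acc_base) {
  stopifnot(acc_base > 0)
  100 * (acc_with - acc_base) / acc_base
}

#' Run one scenario replicate end to end
#'
#' Simulates a population, builds the sequence and chip panels, computes
#' the eigen-profile of the SNP-only GRM over all genotyped animals,
#' derives the EIGx selection sets, runs the EMMAX scan per discovery
#' level, augments the chip with significant (and optionally TOPv)
#' variants, and evaluates ssGBLUP / PBLUP on the test set.
#'
#' @param config a [sim_config()]
#' @param x_levels EIGx percentages used as discovery/training sizes
#' @param top_v integer vector of TOPv augmentation sizes (may be empty)
#' @param models subset of `c("ssGBLUP", "PBLUP")`
#' @param seed replicate seed
#' @param alpha family-wise error rate for the scan
#' @param scheme passed to [make_selection_sets()]
#' @return data.frame of per-level, per-panel, per-model metrics
#' @export
run_scenario_replicate <- function(config, x_levels = c(50, 90, 98),
                                   top_v = integer(0),
                                   models = c("ssGBLUP", "PBLUP"),
                                   seed = 1, alpha = 0.05,
                                   scheme = "disjoint") {
  sim <- simulate_population(config, seed = seed)
  pop <- sim$pop; map <- sim$map; arch <- sim$arch; phen <- sim$phen
  seq_panel <- build_sequence_panel(map)
  chip <- build_chip_panel(map, step = 10)
  geno_ped <- pop$ped[pop$ped$genotyped, c("id", "generation")]
  ## dimensionality: SNP-only GRM over all genotyped animals
  snp_ids <- map$locus_id[map$class == "SNP"]
  g_all <- genotype_matrix(pop, geno_ped$id, snp_ids)
  prof <- eigen_profile(build_grm_vanraden(g_all))
  rm(g_all)
  sets <- make_selection_sets(geno_ped, prof, x_levels, scheme = scheme,
                              seed = derive_seed(seed, 10))
  rows <- list()
  tbv_test <- true_breeding_values(pop, arch, sets$test)
  for (lv_name in names(sets$levels)) {
    lv <- sets$levels[[lv_name]]
    disc <- lv$discovery
    gd <- genotype_matrix(pop, disc, seq_panel)
    y <- phen$phenotype[match(disc, phen$id)]
    vc <- reml_null(y, build_grm_centered_scan(gd))
    assoc <- assoc_scan(y, gd, vc, map = map, alpha = alpha)
    hits <- classify_hits(assoc)
    disc_freqs <- colMeans(gd) / 2
    pct <- total_var_explained(hits$qtn_ids, arch,
                               disc_freqs[as.character(arch$qtn_ids)])
    rm(gd)
    panels <- list(chip, augment_panel(chip, assoc, "SIG"))
    for (v in top_v) panels <- c(panels, list(augment_panel(chip, assoc, "TOPv", v = v)))
    for (model in models) {
      use_panels <- if (model == "PBLUP") panels[1] else panels
      for (pn in use_panels) {
        ev <- run_prediction_scenario(pop, phen, pn, sets, level = lv_name,
                                      model = model,
                                      sigma_u2 = arch$sigma_u2,
                                      sigma_e2 = config$sigma_e2)
        rows[[length(rows) + 1]] <- data.frame(
          level = lv_name, n_set = lv$n, model = model,
          panel = ev$panel,
          n_sig_qtn = hits$n_significant_qtn,
          n_sig_snp = hits$n_significant_snp,
          pct_var_total = pct,
          accuracy = accuracy(tbv_test, ev$gebv),
          b1 = dispersion_b1(tbv_test, ev$gebv))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a replicated experiment grid
#'
#' Executes [run_scenario_replicate()] for every scenario row and
#' replicate, with child seeds derived from the master seed by the
#' documented counter scheme, and returns the stacked metric table.
#' Optionally writes per-replicate and aggregated TSVs plus a JSON run
#' manifest.
#'
#' @param base_config a [sim_config()] supplying everything the scenario
#'   grid does not override
#' @param scenarios data.frame whose columns override `sim_config` fields
#'   (typically `n_sires`, `n_qtn`, `h2`)
#' @param n_replicates replicates per scenario (5 in the full design)
#' @param seed master seed
#' @param x_levels,top_v,models,alpha,scheme passed through
#' @param out_dir optional output directory for TSVs and the manifest
#' @return a `metric_table` data.frame: one row per scenario x replicate x
#'   level x panel x model
#' @export
run_experiment <- function(base_config, scenarios = data.frame(row = 1),
                           n_replicates = 1, seed = 1,
                           x_levels = c(50, 90, 98),
                           top_v = integer(0),
                           models = c("ssGBLUP", "PBLUP"),
                           alpha = 0.05, scheme = "disjoint",
                           out_dir = NULL) {
  stopifnot(nrow(scenarios) >= 1)
  cfg_fields <- names(base_config)
  all_rows <- list()
  for (sc in seq_len(nrow(scenarios))) {
    cfg <- base_config
    for (col in intersect(names(scenarios), cfg_fields)) {
      cfg[[col]] <- scenarios[[col]][sc]
    }
    ## keep derived variance fields consistent when h2 is overridden
    cfg$sigma_u2 <- cfg$h2 * cfg$phenotypic_variance
    cfg$sigma_e2 <- (1 - cfg$h2) * cfg$phenotypic_variance
    for (rep in seq_len(n_replicates)) {
      rep_seed <- derive_seed(seed, sc, rep)
      res <- tryCatch(
        run_scenario_replicate(cfg, x_levels = x_levels, top_v = top_v,
                               models = models, seed = rep_seed,
                               alpha = alpha, scheme = scheme),
        error = function(e) {
          warning("scenario ", sc, " replicate ", rep, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      meta <- scenarios[sc, , drop = FALSE]
      rownames(meta) <- NULL
      res <- cbind(scenario = sc, meta[rep(1, nrow(res)), , drop = FALSE],
                   replicate = rep, seed = rep_seed, res)
      all_rows[[length(all_rows) + 1]] <- res
    }
  }
  if (!length(all_rows)) stop("every replicate failed")
  tbl <- do.call(rbind, all_rows)
  rownames(tbl) <- NULL
  class(tbl) <- c("metric_table", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(tbl, file.path(out_dir, "metrics_replicates.tsv"),
                       sep = "\t")
    data.table::fwrite(aggregate_metrics(tbl),
                       file.path(out_dir, "metrics_aggregate.tsv"), sep = "\t")
    manifest <- list(seed = seed, n_replicates = n_replicates,
                     scenarios = scenarios,
                     x_levels = x_levels, top_v = top_v, models = models,
                     alpha = alpha, scheme = scheme,
                     package_version = as.character(utils::packageVersion("eigdim")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  tbl
}

#' Aggregate a metric table to means and standard errors
#'
#' @param tbl a `metric_table` from [run_experiment()]
#' @return data.frame with mean and SE (`sd / sqrt(n_replicates)`) of every
#'   metric per scenario x level x panel x model; SE is NA for a single
#'   replicate
#' @export
aggregate_metrics <- function(tbl) {
  dt <- data.table::as.data.table(tbl)
  keys <- intersect(c("scenario", "n_sires", "n_qtn", "h2", "level",
                      "model", "panel"), names(dt))
  metrics <- intersect(c("pct_var_total", "n_sig_qtn", "n_sig_snp",
                         "accuracy", "b1"), names(dt))
  agg <- dt[, c(lapply(.SD, mean),
                setNames(lapply(.SD, function(z)
                  if (length(z) > 1) sd(z) / sqrt(length(z)) else NA_real_),
                  paste0(metrics, "_se")),
                list(n_replicates = .N)),
            by = keys, .SDcols = metrics]
  as.data.frame(agg)
}
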