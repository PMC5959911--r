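# Configuration handling and the umbrella pipeline that chains every stage
# on synthetic data: simulate -> screen-call -> growth/drc -> filter-expr ->
# targets -> enrich -> tumor-de. One top-level seed is expanded
# deterministically per stage so a config reruns byte-identically.

# Recognised config keys, per section. NULL section value = scalar key.
CONFIG_SCHEMA <- list(
  seed = NULL,
  screen = c("n_perturbations", "fraction_sensitiser", "fraction_toxic",
             "fraction_both", "noise_cv", "n_replicates", "plate_size",
             "sens_threshold", "vehicle_threshold", "sens_margin",
             "control_drug_viability", "drug"),
  growth = c("doubling_time_h", "t_end_h", "step_h", "start_confluency"),
  dose_response = c("ic50", "hill", "lower", "upper", "doses",
                    "n_replicates", "noise_cv"),
  expression = c("n_genes", "n_planted_down", "n_control", "n_mimic",
                 "noise_cv", "frac_low_signal", "alpha", "mirna"),
  enrichment = c("n_sets", "set_size", "universe_size", "top"),
  tumor = c("n_genes", "n_normal", "n_tumor", "n_planted_up", "fold",
            "missing_rate", "noise_cv", "alpha", "min_fold")
)

default_pipeline_config <- function() {
  list(
    seed = 1L,
    screen = list(n_perturbations = 200, fraction_sensitiser = 0.2,
                  fraction_toxic = 0.05, fraction_both = 0.05,
                  noise_cv = 0.05, n_replicates = 2, plate_size = 384,
                  sens_threshold = 80, vehicle_threshold = 80,
                  sens_margin = 10, control_drug_viability = 80,
                  drug = "docetaxel"),
    growth = list(doubling_time_h = 24, t_end_h = 48, step_h = 2,
                  start_confluency = 1),
    dose_response = list(ic50 = 5, hill = 1, lower = 5, upper = 100,
                         doses = c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64),
                         n_replicates = 4, noise_cv = 0.05),
    expression = list(n_genes = 300, n_planted_down = 30, n_control = 4,
                      n_mimic = 4, noise_cv = 0.1, frac_low_signal = 0.1,
                      alpha = 0.05, mirna = "miR-sim"),
    enrichment = list(n_sets = 10, set_size = 25, universe_size = 300,
                      top = 10),
    tumor = list(n_genes = 300, n_normal = 12, n_tumor = 12,
                 n_planted_up = 20, fold = 2, missing_rate = 0.05,
                 noise_cv = 0.2, alpha = 0.05, min_fold = 1.5)
  )
}

#' Validate a pipeline configuration
#'
#' Checks section and key names against the recognised schema (unknown keys
#' are rejected with an error naming the key) and range-checks the
#' parameters that gate later stages, before any stage runs.
#'
#' @param config Nested list as from [read_pipeline_config()]; missing
#'   sections/keys fall back to defaults.
#' @return The merged, validated config (invisibly usable by
#'   [run_pipeline()]).
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  unknown_sec <- setdiff(names(config), names(CONFIG_SCHEMA))
  if (length(unknown_sec)) {
    stop(sprintf("unknown config key: %s", unknown_sec[1]), call. = FALSE)
  }
  for (sec in names(config)) {
    allowed <- CONFIG_SCHEMA[[sec]]
    if (is.null(allowed)) next
    unknown <- setdiff(names(config[[sec]]), allowed)
    if (length(unknown)) {
      stop(sprintf("unknown config key: %s.%s", sec, unknown[1]),
           call. = FALSE)
    }
  }
  merged <- default_pipeline_config()
  for (sec in names(config)) {
    if (is.null(CONFIG_SCHEMA[[sec]])) {
      merged[[sec]] <- config[[sec]]
    } else {
      for (k in names(config[[sec]])) merged[[sec]][[k]] <- config[[sec]][[k]]
    }
  }
  # YAML sequences mixing integers and floats parse as lists; flatten
  merged$dose_response$doses <- as.numeric(unlist(merged$dose_response$doses))
  s <- merged$screen
  for (k in c("sens_threshold", "vehicle_threshold",
              "control_drug_viability")) {
    if (s[[k]] < 0 || s[[k]] > 100) {
      stop(sprintf("screen.%s must lie in [0, 100]", k), call. = FALSE)
    }
  }
  for (sec in c("expression", "tumor")) {
    a <- merged[[sec]]$alpha
    if (a <= 0 || a > 1) {
      stop(sprintf("%s.alpha must lie in (0, 1]", sec), call. = FALSE)
    }
  }
  if (merged$tumor$min_fold < 1) {
    stop("tumor.min_fold must be >= 1", call. = FALSE)
  }
  merged
}

#' Read a pipeline configuration file
#'
#' YAML or JSON, keyed on the file extension; the result round-trips
#' losslessly through [write_pipeline_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_pipeline_config(cfg)
}

#' Write a pipeline configuration file
#'
#' @param config Config list.
#' @param path Output `.yaml`/`.yml` or `.json` path.
#' @export
write_pipeline_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' Executes every stage in order on data simulated from the config's single
#' top-level seed (expanded deterministically per stage), writing each
#' intermediate table as TSV, the exact config used, a log with a parameter
#' echo, and a machine-readable `summary.json`. Reruns with the same config
#' produce byte-identical summaries.
#'
#' @param config Config list (validated here) or path to a config file.
#' @param out_dir Run directory, created if absent.
#' @return The run summary (list), invisibly; written as
#'   `summary.json` in `out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  log_msg <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = logfile, append = TRUE)
  }
  cat("", file = logfile)
  log_msg("pipeline start; seed=%d", config$seed)
  log_msg("config echo: %s",
          jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  write_pipeline_config(config, file.path(out_dir, "config_used.yaml"))
  seed <- as.integer(config$seed)
  stage_seed <- function(i) (seed * 101L + i * 7919L) %% .Machine$integer.max
  summary <- list(seed = seed)

  # -- screen ---------------------------------------------------------------
  sc <- config$screen
  sim <- simulate_screen(screen_sim_config(
    seed = stage_seed(1L), n_perturbations = sc$n_perturbations,
    fraction_sensitiser = sc$fraction_sensitiser,
    fraction_toxic = sc$fraction_toxic, fraction_both = sc$fraction_both,
    control_drug_viability = sc$control_drug_viability,
    noise_cv = sc$noise_cv, n_replicates = sc$n_replicates,
    plate_size = sc$plate_size, drug = sc$drug
  ))
  write_tsv(sim$wells, file.path(out_dir, "screen_wells.tsv"))
  write_tsv(sim$truth, file.path(out_dir, "screen_truth.tsv"))
  records <- normalize_to_control(sim$wells)
  write_tsv(records, file.path(out_dir, "screen_viability.tsv"))
  calls <- call_sensitisers(records, drug = sc$drug,
                            sens_threshold = sc$sens_threshold,
                            vehicle_threshold = sc$vehicle_threshold,
                            sens_margin = sc$sens_margin)
  write_tsv(as.data.frame(calls), file.path(out_dir, "screen_hit_calls.tsv"))
  hs <- summarize_hits(calls)
  qc <- positive_control_qc(records)
  truth_class <- sim$truth$true_class[
    match(calls$perturbation_id, sim$truth$perturbation_id)]
  summary$screen <- list(
    n_perturbations = nrow(calls),
    hits = as.list(hs$counts),
    n_strong = hs$n_strong,
    sensitiser_sensitivity = round(
      mean(calls$category[truth_class == "sensitiser"] == "sensitiser"), 4),
    sensitiser_specificity = round(
      mean(calls$category[truth_class != "sensitiser"] != "sensitiser"), 4),
    positive_control_viability_pct = round(unname(qc$viability_pct), 2),
    positive_control_qc_pass = qc$pass
  )
  log_msg("screen: %d calls (%d sensitisers)", nrow(calls),
          hs$counts[["sensitiser"]])

  # -- growth + dose-response ----------------------------------------------
  gr <- config$growth
  curve <- simulate_confluency(gr$doubling_time_h,
                               seq(0, gr$t_end_h, by = gr$step_h),
                               start_confluency = gr$start_confluency)
  write_tsv(curve, file.path(out_dir, "confluency.tsv"))
  win <- select_linear_phase(curve)
  dt <- doubling_time(curve, win$t_a, win$t_b)
  dr <- config$dose_response
  drt <- simulate_dose_response(dr$ic50, dr$hill, dr$lower, dr$upper,
                                doses = dr$doses,
                                n_replicates = dr$n_replicates,
                                noise_cv = dr$noise_cv,
                                seed = stage_seed(2L))
  write_tsv(drt, file.path(out_dir, "dose_response.tsv"))
  fit <- fit_dose_response(drt)
  summary$growth_dose <- list(
    doubling_time_h = round(dt, 4),
    linear_phase = list(t_a = win$t_a, t_b = win$t_b),
    ic50_nM = round(fit$ic50, 4),
    ic20_nM = round(ic_value(fit, 20), 4),
    hill = round(fit$hill, 4),
    max_response_pct = round(fit$max_response, 2)
  )
  log_msg("growth/drc: DT=%.2f h, IC50=%.3f nM", dt, fit$ic50)

  # -- expression filters + targets ----------------------------------------
  ex <- config$expression
  esim <- simulate_expression(
    n_genes = ex$n_genes, n_planted_down = ex$n_planted_down,
    n_control = ex$n_control, n_mimic = ex$n_mimic,
    noise_cv = ex$noise_cv, frac_low_signal = ex$frac_low_signal,
    seed = stage_seed(3L)
  )
  de <- de_from_expression(esim$matrix, esim$groups, ref = "control")
  write_tsv(de, file.path(out_dir, "expression_de.tsv"))
  de_f <- filter_low_signal(de, esim$matrix, esim$groups)
  write_tsv(de_f, file.path(out_dir, "expression_de_filtered.tsv"))
  down <- downregulated_set(de_f, alpha = ex$alpha)
  writeLines(down, file.path(out_dir, "downregulated_genes.txt"))
  evidence <- with_seed(stage_seed(4L), {
    pool <- rownames(esim$matrix)
    lapply(stats::setNames(nm = c("tarbase", "targetscan", "mirdb")),
           function(s) data.frame(
             mirna_id = ex$mirna,
             gene_id = sample(pool, min(60, length(pool))),
             stringsAsFactors = FALSE))
  })
  consensus <- aggregate_predictions(evidence, mode = "k_of_n", k = 2)
  ann <- annotate_targets(down, consensus, ex$mirna)
  summary$expression <- list(
    n_genes = ex$n_genes,
    n_removed_low_signal = attr(de_f, "n_removed"),
    n_downregulated = length(down),
    planted_recovered_pct = round(
      100 * mean(esim$planted %in% down), 2),
    target_summary = ann$summary
  )
  log_msg("expression: %d downregulated, %d filtered",
          length(down), attr(de_f, "n_removed"))

  # -- enrichment -----------------------------------------------------------
  en <- config$enrichment
  collection <- with_seed(stage_seed(5L), {
    pool <- rownames(esim$matrix)
    sets <- lapply(seq_len(en$n_sets), function(i)
      sample(pool, en$set_size))
    names(sets) <- sprintf("SET%02d", seq_len(en$n_sets))
    # one set seeded with planted genes so a real enrichment signal exists
    sets[["PLANTED_SET"]] <- unique(c(
      esim$planted,
      sample(pool, max(0, en$set_size - length(esim$planted)))))
    structure(list(name = "synthetic", sets = sets,
                   descriptions = stats::setNames(rep("na", length(sets)),
                                                  names(sets))),
              class = "gene_set_collection")
  })
  write_gmt(collection, file.path(out_dir, "gene_sets.gmt"))
  enr <- enrich_collection(down, collection,
                           universe_size = en$universe_size, top = en$top)
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  summary$enrichment <- list(
    n_recognised = attr(enr, "n_recognised"),
    top_set = enr$set_name[1],
    top_p = signif(enr$p_value[1], 6)
  )
  log_msg("enrichment: top set %s (p=%.3g)", enr$set_name[1], enr$p_value[1])

  # -- tumor evaluation -----------------------------------------------------
  tu <- config$tumor
  tsim <- simulate_tumor_matrix(
    n_genes = tu$n_genes, n_normal = tu$n_normal, n_tumor = tu$n_tumor,
    n_planted_up = tu$n_planted_up, fold = tu$fold,
    missing_rate = tu$missing_rate, noise_cv = tu$noise_cv,
    seed = stage_seed(6L)
  )
  cleaned <- clean_matrix(tsim$matrix)
  tde <- two_group_de(cleaned, "normal", "tumor",
                      alpha = tu$alpha, min_fold = tu$min_fold)
  write_tsv(tde, file.path(out_dir, "tumor_de.tsv"))
  z <- zscore_matrix(cleaned)
  write_tsv(data.frame(gene_id = rownames(z), z, check.names = FALSE),
            file.path(out_dir, "tumor_zscores.tsv"))
  frac <- upregulated_fraction(tsim$planted, tde)
  summary$tumor <- list(
    n_genes_after_cleaning = nrow(cleaned$values),
    n_removed = attr(cleaned, "n_removed"),
    n_imputed = attr(cleaned, "n_imputed"),
    n_significant_up = sum(tde$significant_up),
    planted_up_pct = frac$pct_up
  )
  log_msg("tumor: %d significant up (%d%% of planted)",
          sum(tde$significant_up), frac$pct_up)

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("pipeline done")
  invisible(summary)
}
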