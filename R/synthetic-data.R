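# Seeded generators for every input the pipeline consumes: screen plates,
# confluency time courses, dose-response tables, expression matrices and
# tumor matrices, each returned together with its ground truth.

#' Configuration for a synthetic mimic/inhibitor screen
#'
#' Builds and validates the parameter set for [simulate_screen()]. The
#' defaults encode the screening design the pipeline assumes: taxane given at
#' an IC20 dose (non-targeting control viability under drug is 80% of
#' vehicle), perturbations drawn from four classes (null, sensitiser, toxic,
#' toxic + sensitiser), multiplicative log-normal signal noise, and a
#' per-plate signal factor that forces per-plate normalization downstream.
#'
#' Effect ranges are per-class intervals for two multiplicative viability
#' factors: `vehicle` (applied under both treatments) and `drug_extra`
#' (applied only under drug, on top of the drug's own IC20 effect). A
#' sensitiser is near-neutral under vehicle with `drug_extra` well below 1;
#' a toxic perturbation depresses vehicle viability (default 20-40% band)
#' with no conditional drug effect; a toxic sensitiser combines both.
#'
#' @param seed Integer seed; identical seed + config gives identical tables.
#' @param n_perturbations Number of library perturbations (mimics).
#' @param fraction_sensitiser,fraction_toxic,fraction_both Class proportions
#'   in `[0, 1]`; their sum must be at most 1 and the remainder is null.
#' @param control_drug_viability Percent viability of drug-treated
#'   non-targeting control relative to vehicle-treated control; 80 encodes
#'   the IC20 dosing contract.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   signal noise.
#' @param n_replicates Replicate wells per perturbation per treatment.
#' @param plate_size Wells per plate (including control wells).
#' @param effect_ranges Named list of per-class factor intervals; see
#'   Details. Classes: `sensitiser`, `toxic`, `toxic_sensitiser`, each a list
#'   with `vehicle` and `drug_extra` length-2 numeric ranges.
#' @param cell_line Cell-line label stamped on every well.
#' @param drug Drug treatment label (`"docetaxel"` or `"cabazitaxel"`).
#' @param drug_dose_nM Dose recorded on drug-treated wells, in nM.
#' @param plate_effect_sd Log-scale SD of the per-plate base-signal factor.
#' @param n_control_wells Non-targeting wells per plate.
#' @param n_positive_wells Lethal positive-control wells per plate.
#' @param base_signal Expected raw luminescence of an unperturbed
#'   vehicle-treated well.
#' @param positive_control_viability Viability factor of the lethal positive
#'   control (fraction of control, both treatments).
#' @return A list of class `"screen_sim_config"`.
#' @export
screen_sim_config <- function(seed = 1L,
                              n_perturbations = 100L,
                              fraction_sensitiser = 0.1,
                              fraction_toxic = 0.05,
                              fraction_both = 0.05,
                              control_drug_viability = 80,
                              noise_cv = 0.05,
                              n_replicates = 2L,
                              plate_size = 384L,
                              effect_ranges = NULL,
                              cell_line = "PC3",
                              drug = "docetaxel",
                              drug_dose_nM = 20,
                              plate_effect_sd = 0.15,
                              n_control_wells = 8L,
                              n_positive_wells = 4L,
                              base_signal = 1e6,
                              positive_control_viability = 0.05) {
  fr <- c(fraction_sensitiser, fraction_toxic, fraction_both)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("class fractions must be nonnegative and sum to at most 1",
         call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (control_drug_viability <= 0 || control_drug_viability > 100) {
    stop("control_drug_viability must be in (0, 100]", call. = FALSE)
  }
  if (is.null(effect_ranges)) {
    effect_ranges <- list(
      sensitiser        = list(vehicle = c(0.90, 1.05), drug_extra = c(0.40, 0.70)),
      toxic             = list(vehicle = c(0.20, 0.40), drug_extra = c(0.95, 1.05)),
      toxic_sensitiser  = list(vehicle = c(0.20, 0.60), drug_extra = c(0.50, 0.80))
    )
  }
  needed <- c("sensitiser", "toxic", "toxic_sensitiser")
  if (!all(needed %in% names(effect_ranges))) {
    stop("effect_ranges must name sensitiser, toxic and toxic_sensitiser",
         call. = FALSE)
  }
  n_ctrl <- n_control_wells + n_positive_wells
  if (plate_size <= n_ctrl) {
    stop("plate_size must exceed the number of control wells", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    n_perturbations = as.integer(n_perturbations),
    fraction_sensitiser = fraction_sensitiser,
    fraction_toxic = fraction_toxic,
    fraction_both = fraction_both,
    control_drug_viability = control_drug_viability,
    noise_cv = noise_cv,
    n_replicates = as.integer(n_replicates),
    plate_size = as.integer(plate_size),
    effect_ranges = effect_ranges,
    cell_line = cell_line,
    drug = drug,
    drug_dose_nM = drug_dose_nM,
    plate_effect_sd = plate_effect_sd,
    n_control_wells = as.integer(n_control_wells),
    n_positive_wells = as.integer(n_positive_wells),
    base_signal = base_signal,
    positive_control_viability = positive_control_viability
  ), class = "screen_sim_config")
}

#' Simulate a plate-based sensitisation screen
#'
#' Generates raw well-level luminescence measurements for a mimic screen run
#' under vehicle and drug, together with the ground-truth class and effect
#' factors of every perturbation. Expected signals compose multiplicatively:
#' vehicle wells read `base x plate_effect x vehicle_factor`, drug wells read
#' additionally `x (control_drug_viability/100) x drug_extra_factor`. The
#' drug's own IC20 effect applies to non-targeting control wells too, so
#' after per-treatment normalization a null perturbation sits at 100% under
#' both treatments while its raw drug/vehicle signal ratio is 0.8.
#'
#' @param config A [screen_sim_config()] object.
#' @return A list with elements `wells` (data frame with columns `plate_id`,
#'   `well`, `cell_line`, `perturbation_id`, `perturbation_class`,
#'   `treatment`, `dose`, `signal`) and `truth` (data frame with columns
#'   `perturbation_id`, `true_class`, `true_vehicle_factor`,
#'   `true_drug_extra_factor`).
#' @seealso [normalize_to_control()], [call_sensitisers()]
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    n <- config$n_perturbations
    n_sens <- round(config$fraction_sensitiser * n)
    n_tox <- round(config$fraction_toxic * n)
    n_both <- round(config$fraction_both * n)
    if (n_sens + n_tox + n_both > n) {
      stop("class fractions leave no room for null perturbations",
           call. = FALSE)
    }
    classes <- rep(
      c("sensitiser", "toxic", "toxic_sensitiser", "null"),
      c(n_sens, n_tox, n_both, n - n_sens - n_tox - n_both)
    )
    classes <- sample(classes)
    ids <- sprintf("mir%04d", seq_len(n))

    veh <- rep(1, n)
    extra <- rep(1, n)
    for (cl in c("sensitiser", "toxic", "toxic_sensitiser")) {
      idx <- which(classes == cl)
      if (length(idx)) {
        rng <- config$effect_ranges[[cl]]
        veh[idx] <- runif_range(length(idx), rng$vehicle)
        extra[idx] <- runif_range(length(idx), rng$drug_extra)
      }
    }
    truth <- data.frame(
      perturbation_id = ids,
      true_class = classes,
      true_vehicle_factor = veh,
      true_drug_extra_factor = extra,
      stringsAsFactors = FALSE
    )

    per_plate <- config$plate_size - config$n_control_wells -
      config$n_positive_wells
    n_chunks <- ceiling(n / per_plate)
    chunk <- rep(seq_len(n_chunks), each = per_plate)[seq_len(n)]
    drug_factor <- config$control_drug_viability / 100

    blocks <- vector("list", 0L)
    for (r in seq_len(config$n_replicates)) {
      for (trt in c("vehicle", config$drug)) {
        for (ch in seq_len(n_chunks)) {
          pert_idx <- which(chunk == ch)
          plate_id <- sprintf("P%02d_%s_r%d", ch, trt, r)
          plate_eff <- stats::rlnorm(1, 0, config$plate_effect_sd)
          pc <- c(
            rep("non_targeting", config$n_control_wells),
            rep("positive_control", config$n_positive_wells),
            rep("mimic", length(pert_idx))
          )
          pid <- c(
            rep("NTC", config$n_control_wells),
            rep("PLK1_siRNA", config$n_positive_wells),
            ids[pert_idx]
          )
          vf <- c(
            rep(1, config$n_control_wells),
            rep(config$positive_control_viability, config$n_positive_wells),
            veh[pert_idx]
          )
          ef <- c(
            rep(1, config$n_control_wells + config$n_positive_wells),
            extra[pert_idx]
          )
          mu <- config$base_signal * plate_eff * vf
          if (trt != "vehicle") mu <- mu * drug_factor * ef
          nw <- length(mu)
          blocks[[length(blocks) + 1L]] <- data.frame(
            plate_id = plate_id,
            well = sprintf("W%03d", seq_len(nw)),
            cell_line = config$cell_line,
            perturbation_id = pid,
            perturbation_class = pc,
            treatment = trt,
            dose = if (trt == "vehicle") 0 else config$drug_dose_nM,
            signal = mu * rlnorm_cv(nw, config$noise_cv),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    wells <- do.call(rbind, blocks)
    rownames(wells) <- NULL
    list(wells = wells, truth = truth)
  })
}

#' Simulate a logistic confluency time course
#'
#' Logistic growth whose exponential (early) phase has the requested
#' doubling time; values are clipped to `[0, capacity]`.
#'
#' @param doubling_time_h Doubling time in the exponential phase, hours (> 0).
#' @param t_grid Time points in hours.
#' @param start_confluency Confluency at time 0, percent.
#' @param capacity Plateau confluency, percent.
#' @param noise_sd Additive Gaussian noise SD in percent (default 0).
#' @param seed Optional seed used when `noise_sd > 0`.
#' @return Data frame with columns `time_h` and `confluency_pct`.
#' @export
simulate_confluency <- function(doubling_time_h, t_grid,
                                start_confluency = 1, capacity = 100,
                                noise_sd = 0, seed = NULL) {
  if (doubling_time_h <= 0) stop("doubling time must be > 0", call. = FALSE)
  if (start_confluency <= 0 || start_confluency >= capacity) {
    stop("start_confluency must lie in (0, capacity)", call. = FALSE)
  }
  r <- log(2) / doubling_time_h
  a <- (capacity - start_confluency) / start_confluency
  conf <- capacity / (1 + a * exp(-r * t_grid))
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(conf), 0, noise_sd) else
      with_seed(seed, stats::rnorm(length(conf), 0, noise_sd))
    conf <- conf + noise
  }
  conf <- pmin(pmax(conf, 0), capacity)
  data.frame(time_h = t_grid, confluency_pct = conf)
}

#' Simulate a dose-response viability table
#'
#' Mean viability follows a 4-parameter log-logistic (Hill) curve; replicate
#' measurements carry multiplicative log-normal noise. Zero doses are stored
#' as vehicle anchor rows at the upper asymptote and are not fed through the
#' log-dose curve.
#'
#' @param ic50 Half-maximal concentration, nM (> 0).
#' @param hill Hill slope (positive for a decreasing viability curve).
#' @param lower,upper Lower/upper viability asymptotes, percent.
#' @param doses Dose vector, nM; may include 0 (vehicle anchor).
#' @param n_replicates Replicates per dose.
#' @param noise_cv CV of multiplicative noise on viability.
#' @param seed Integer seed.
#' @return Data frame with columns `dose_nM`, `replicate`, `viability_pct`.
#' @export
simulate_dose_response <- function(ic50, hill = 1, lower = 0, upper = 100,
                                   doses, n_replicates = 4, noise_cv = 0.05,
                                   seed = 1L) {
  if (ic50 <= 0) stop("ic50 must be > 0", call. = FALSE)
  if (lower >= upper) stop("lower must be < upper", call. = FALSE)
  if (length(doses) == 0) stop("dose list must be nonempty", call. = FALSE)
  mu <- ifelse(
    doses == 0, upper,
    lower + (upper - lower) / (1 + (doses / ic50)^hill)
  )
  with_seed(seed, {
    out <- data.frame(
      dose_nM = rep(doses, each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = length(doses)),
      viability_pct = rep(mu, each = n_replicates) *
        rlnorm_cv(length(doses) * n_replicates, noise_cv)
    )
    out
  })
}

#' Simulate an RNA-seq-like expression matrix with planted downregulation
#'
#' Log-normal baseline abundances (RPKM-like units) for two groups (default
#' 4 control + 4 mimic samples); a chosen set of genes is scaled down in the
#' mimic group by a factor drawn from `fold_range_down`. A configurable
#' fraction of genes is given sub-unit abundance in both groups and near-zero
#' noise so the low-signal/low-variance filter has something to remove.
#'
#' @param n_genes Number of genes.
#' @param n_planted_down Number of genes downregulated in the mimic group.
#' @param n_control,n_mimic Samples per group (>= 2 each).
#' @param fold_range_down Range of mimic/control ratios for planted genes.
#' @param noise_cv CV of per-sample multiplicative noise.
#' @param frac_low_signal Fraction of (non-planted) genes forced to RPKM < 1
#'   in both groups with sub-median variance.
#' @param seed Integer seed.
#' @return List with `matrix` (genes x samples), `groups` (per-sample labels
#'   `"control"`/`"mimic"`), `planted` (planted gene ids) and `low_signal`
#'   (ids of the forced low-signal genes).
#' @export
simulate_expression <- function(n_genes = 200, n_planted_down = 20,
                                n_control = 4, n_mimic = 4,
                                fold_range_down = c(0.3, 0.6),
                                noise_cv = 0.1, frac_low_signal = 0.1,
                                seed = 1L) {
  if (n_control < 2 || n_mimic < 2) {
    stop("each group needs >= 2 samples (variance undefined otherwise)",
         call. = FALSE)
  }
  if (n_planted_down > n_genes) {
    stop("n_planted_down must be <= n_genes", call. = FALSE)
  }
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    planted <- if (n_planted_down > 0) genes[seq_len(n_planted_down)] else
      character(0)
    n_low <- round(frac_low_signal * n_genes)
    low_pool <- setdiff(genes, planted)
    low <- if (n_low > 0) low_pool[seq_len(min(n_low, length(low_pool)))] else
      character(0)

    base <- stats::rlnorm(n_genes, meanlog = log(20), sdlog = 1.2)
    names(base) <- genes
    base[low] <- stats::runif(length(low), 0.05, 0.5)

    fold <- stats::setNames(rep(1, n_genes), genes)
    fold[planted] <- runif_range(length(planted), fold_range_down)

    n_s <- n_control + n_mimic
    groups <- rep(c("control", "mimic"), c(n_control, n_mimic))
    samples <- sprintf("%s_%d", groups,
                       c(seq_len(n_control), seq_len(n_mimic)))
    mu <- outer(base, rep(1, n_s))
    mu[, groups == "mimic"] <- mu[, groups == "mimic"] * fold
    cvs <- stats::setNames(rep(noise_cv, n_genes), genes)
    cvs[low] <- noise_cv / 100  # near-deterministic, guarantees sub-median variance
    noise <- matrix(1, n_genes, n_s)
    for (g in seq_len(n_genes)) noise[g, ] <- rlnorm_cv(n_s, cvs[g])
    m <- mu * noise
    dimnames(m) <- list(genes, samples)
    list(matrix = m, groups = groups, planted = planted, low_signal = low)
  })
}

#' Simulate a tumor expression matrix with planted upregulation and missing values
#'
#' Microarray-like log-normal intensities for two tissue groups; planted
#' genes are upregulated in the tumor group by `fold`; entries go missing
#' completely at random at `missing_rate`, and a configurable number of
#' genes get > 50% missingness within one group to exercise the removal rule.
#'
#' @param n_genes Number of genes.
#' @param n_normal,n_tumor Samples per tissue group (>= 2 each).
#' @param n_planted_up Number of upregulated genes.
#' @param fold Tumor/normal mean ratio for planted genes (typically >= 1.5).
#' @param missing_rate Probability an entry is missing, in `[0, 1)`.
#' @param n_high_missing Genes forced to > 50% missingness in the normal
#'   group (drawn from the non-planted pool).
#' @param noise_cv CV of multiplicative noise.
#' @param seed Integer seed.
#' @return A [tumor_matrix()] plus attributes: list with `matrix`, `groups`,
#'   `planted`, `high_missing`.
#' @export
simulate_tumor_matrix <- function(n_genes = 500, n_normal = 20, n_tumor = 20,
                                  n_planted_up = 25, fold = 2,
                                  missing_rate = 0.05, n_high_missing = 0,
                                  noise_cv = 0.2, seed = 1L) {
  if (n_normal < 2 || n_tumor < 2) {
    stop("each tissue group needs >= 2 samples", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (n_planted_up > n_genes) stop("n_planted_up must be <= n_genes",
                                   call. = FALSE)
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    planted <- if (n_planted_up > 0) genes[seq_len(n_planted_up)] else
      character(0)
    n_s <- n_normal + n_tumor
    groups <- rep(c("normal", "tumor"), c(n_normal, n_tumor))
    samples <- sprintf("%s_%d", groups,
                       c(seq_len(n_normal), seq_len(n_tumor)))
    base <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 0.8)
    mu <- outer(base, rep(1, n_s))
    mu[genes %in% planted, groups == "tumor"] <-
      mu[genes %in% planted, groups == "tumor"] * fold
    m <- mu * matrix(rlnorm_cv(n_genes * n_s, noise_cv), n_genes, n_s)
    dimnames(m) <- list(genes, samples)
    if (missing_rate > 0) {
      m[matrix(stats::runif(n_genes * n_s) < missing_rate,
               n_genes, n_s)] <- NA_real_
    }
    high <- character(0)
    if (n_high_missing > 0) {
      pool <- setdiff(genes, planted)
      high <- pool[seq_len(min(n_high_missing, length(pool)))]
      norm_idx <- which(groups == "normal")
      k <- floor(length(norm_idx) / 2) + 1L  # strictly more than half
      for (g in high) m[g, sample(norm_idx, k)] <- NA_real_
    }
    tm <- tumor_matrix(m, groups)
    list(matrix = tm, groups = groups, planted = planted, high_missing = high)
  })
}
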