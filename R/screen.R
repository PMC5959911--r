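# Plate normalization and hit calling for the mimic/inhibitor screen.

#' Normalize well signals to the non-targeting control of the same plate and treatment
#'
#' Viability of each perturbation is its signal as a percentage of the mean
#' non-targeting control signal within the same (plate, treatment) stratum;
#' cross-plate pooling is disallowed so that plate effects cancel. Per-well
#' percentages are then averaged across replicate wells of a perturbation
#' (within a stratum this equals the ratio of mean raw signals).
#'
#' @param wells Data frame of well measurements with columns `plate_id`,
#'   `well`, `cell_line`, `perturbation_id`, `perturbation_class`,
#'   `treatment`, `dose`, `signal`.
#' @return Data frame of viability records: `perturbation_id`, `cell_line`,
#'   `perturbation_class`, `treatment`, `viability_pct`, `n_wells`, `sd_pct`.
#'   Non-targeting records sit at 100% by construction.
#' @export
normalize_to_control <- function(wells) {
  check_columns(wells, c("plate_id", "well", "cell_line", "perturbation_id",
                         "perturbation_class", "treatment", "dose", "signal"),
                "well table")
  if (any(wells$signal < 0)) stop("signals must be >= 0", call. = FALSE)

  stratum <- interaction(wells$plate_id, wells$treatment, drop = TRUE)
  ctrl <- wells$perturbation_class == "non_targeting"
  ctrl_mean <- tapply(wells$signal[ctrl], stratum[ctrl], mean)

  used <- levels(stratum)
  missing <- setdiff(used, names(ctrl_mean))
  if (length(missing)) {
    stop(sprintf("stratum lacking non-targeting control wells: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- names(ctrl_mean)[!is.finite(ctrl_mean) | ctrl_mean <= 0]
  if (length(bad)) {
    stop(sprintf("non-positive control mean in stratum: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  pct <- 100 * wells$signal / as.numeric(ctrl_mean[as.character(stratum)])
  key <- interaction(wells$perturbation_id, wells$cell_line, wells$treatment,
                     drop = TRUE)
  agg <- data.frame(
    perturbation_id = tapply(wells$perturbation_id, key, `[`, 1),
    cell_line = tapply(wells$cell_line, key, `[`, 1),
    perturbation_class = tapply(wells$perturbation_class, key, `[`, 1),
    treatment = tapply(wells$treatment, key, `[`, 1),
    viability_pct = as.numeric(tapply(pct, key, mean)),
    n_wells = as.integer(tapply(pct, key, length)),
    sd_pct = as.numeric(tapply(pct, key, stats::sd)),
    stringsAsFactors = FALSE
  )
  rownames(agg) <- NULL
  agg[order(agg$perturbation_id, agg$treatment), , drop = FALSE]
}

#' Remove blacklisted perturbations
#'
#' Drops records whose `perturbation_id` appears in a user-supplied blacklist
#' (e.g. microRNAs with known cardiotoxicity). Ids on the blacklist that do
#' not occur in the records are ignored with a warning.
#'
#' @param records Data frame with a `perturbation_id` column.
#' @param blacklist Character vector of perturbation ids to drop.
#' @return The filtered records, with attribute `n_removed`.
#' @export
exclude_blacklist <- function(records, blacklist) {
  check_columns(records, "perturbation_id", "records")
  blacklist <- unique(blacklist)
  absent <- setdiff(blacklist, records$perturbation_id)
  if (length(absent)) {
    warning(sprintf("%d blacklist id(s) not present in records: %s",
                    length(absent),
                    paste(utils::head(absent, 5), collapse = ", ")))
  }
  keep <- !(records$perturbation_id %in% blacklist)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Pair vehicle/drug viability records into one row per perturbation,
# excluding control classes from calls.
pair_viability <- function(records, drug) {
  check_columns(records, c("perturbation_id", "cell_line", "treatment",
                           "viability_pct"), "viability records")
  if (!drug %in% records$treatment) {
    stop(sprintf("no records for treatment '%s'", drug), call. = FALSE)
  }
  cls <- if ("perturbation_class" %in% names(records))
    records$perturbation_class else rep("mimic", nrow(records))
  callable <- !(cls %in% c("non_targeting", "positive_control"))
  r <- records[callable & records$treatment %in% c("vehicle", drug), ,
               drop = FALSE]
  veh <- r[r$treatment == "vehicle", ]
  drg <- r[r$treatment == drug, ]
  ids <- union(veh$perturbation_id, drg$perturbation_id)
  miss <- c(setdiff(ids, veh$perturbation_id), setdiff(ids, drg$perturbation_id))
  if (length(miss)) {
    stop(sprintf("perturbation(s) missing a vehicle or drug record: %s",
                 paste(unique(miss), collapse = ", ")), call. = FALSE)
  }
  m <- match(ids, veh$perturbation_id)
  d <- match(ids, drg$perturbation_id)
  data.frame(
    perturbation_id = ids,
    cell_line = veh$cell_line[m],
    drug = drug,
    viability_vehicle_pct = veh$viability_pct[m],
    viability_drug_pct = drg$viability_pct[d],
    stringsAsFactors = FALSE
  )
}

#' Call taxane sensitisers with the dual-threshold rule
#'
#' A perturbation is a *sensitiser* when its drug-treated viability falls
#' below `sens_threshold` percent of the drug-treated control while its
#' vehicle-treated viability stays above `vehicle_threshold` percent
#' (strict inequalities; a value exactly at 80 is not a hit). Perturbations
#' failing the vehicle gate are *toxic*, or *toxic_sensitiser* when drug
#' viability drops more than `sens_margin` points below vehicle viability.
#' The `strong` tier flags drug viability below 50%.
#'
#' @param records Viability records as from [normalize_to_control()]; must
#'   contain a `vehicle` and a `drug` record for every perturbation.
#' @param drug Drug treatment label to call against.
#' @param sens_threshold Drug-viability threshold, percent (default 80).
#' @param vehicle_threshold Vehicle-viability threshold, percent (default 80).
#' @param sens_margin Sensitisation margin separating toxic from
#'   toxic_sensitiser, percentage points (default 10).
#' @param strong_threshold Drug viability below this is flagged strong
#'   (default 50).
#' @return Data frame of hit calls (class `"hit_calls"`): `perturbation_id`,
#'   `cell_line`, `drug`, `viability_vehicle_pct`, `viability_drug_pct`,
#'   `category` (none / sensitiser / toxic / toxic_sensitiser), `strong`.
#' @export
call_sensitisers <- function(records, drug,
                             sens_threshold = 80, vehicle_threshold = 80,
                             sens_margin = 10, strong_threshold = 50) {
  paired <- pair_viability(records, drug)
  v <- paired$viability_vehicle_pct
  d <- paired$viability_drug_pct
  category <- ifelse(
    v > vehicle_threshold,
    ifelse(d < sens_threshold, "sensitiser", "none"),
    ifelse(d < v - sens_margin, "toxic_sensitiser", "toxic")
  )
  paired$category <- category
  paired$strong <- d < strong_threshold
  class(paired) <- c("hit_calls", "data.frame")
  paired
}

#' Classify siRNA knockdowns as toxic, sensitiser or both
#'
#' Band-based classification for follow-up siRNA knockdowns: *toxic* when
#' vehicle viability is at or below `vehicle_threshold` with no additional
#' drug effect; *sensitiser* when vehicle viability is above the threshold
#' and drug-treated viability sits at least `sens_margin` points below the
#' drug-treated control; *toxic_sensitiser* when a toxic knockdown loses at
#' least `sens_margin` further points under drug.
#'
#' @inheritParams call_sensitisers
#' @param toxic_band Informational viability band for toxic knockdowns,
#'   percent; records are flagged `in_toxic_band` when vehicle viability
#'   falls inside it (the rule itself uses `vehicle_threshold`).
#' @param vehicle_threshold Vehicle viability at or below this marks
#'   toxicity (default 80).
#' @param gene Optional character vector mapping each record's
#'   `perturbation_id` to a gene symbol; used for the distinct-gene summary.
#' @return A `"hit_calls"` data frame as for [call_sensitisers()], plus
#'   `in_toxic_band` and (if supplied) `gene`.
#' @seealso [summarize_hits()] for per-category counts and the
#'   distinct-gene total.
#' @export
classify_sirna <- function(records, drug, toxic_band = c(20, 40),
                           sens_margin = 10, vehicle_threshold = 80,
                           strong_threshold = 50, gene = NULL) {
  paired <- pair_viability(records, drug)
  v <- paired$viability_vehicle_pct
  d <- paired$viability_drug_pct
  category <- ifelse(
    v > vehicle_threshold,
    ifelse(100 - d >= sens_margin, "sensitiser", "none"),
    ifelse(v - d >= sens_margin, "toxic_sensitiser", "toxic")
  )
  paired$category <- category
  paired$strong <- d < strong_threshold
  paired$in_toxic_band <- v >= toxic_band[1] & v <= toxic_band[2]
  if (!is.null(gene)) {
    if (is.null(names(gene))) {
      stop("gene must be a named vector keyed by perturbation_id",
           call. = FALSE)
    }
    paired$gene <- unname(gene[paired$perturbation_id])
  }
  class(paired) <- c("hit_calls", "data.frame")
  paired
}

#' Summarize hit calls
#'
#' Counts calls per category and reports the number of distinct genes (or
#' perturbations, when no gene column is present) with any non-null effect.
#'
#' @param calls A `"hit_calls"` data frame, possibly spanning several drugs.
#' @return List with `counts` (named vector over the four categories),
#'   `n_hit_genes` (distinct genes with category other than `"none"`),
#'   `n_strong` (calls with the strong flag).
#' @export
summarize_hits <- function(calls) {
  stopifnot(is.data.frame(calls), "category" %in% names(calls))
  lv <- c("none", "sensitiser", "toxic", "toxic_sensitiser")
  counts <- table(factor(calls$category, levels = lv))
  id <- if ("gene" %in% names(calls)) calls$gene else calls$perturbation_id
  hit <- calls$category != "none"
  list(
    counts = stats::setNames(as.integer(counts), lv),
    n_hit_genes = length(unique(id[hit])),
    n_strong = sum(calls$strong)
  )
}

#' @export
print.hit_calls <- function(x, ...) {
  s <- summarize_hits(x)
  cat(sprintf("Hit calls for %d perturbation(s)\n", nrow(x)))
  cat(sprintf("  sensitiser: %d  toxic: %d  toxic_sensitiser: %d  none: %d\n",
              s$counts["sensitiser"], s$counts["toxic"],
              s$counts["toxic_sensitiser"], s$counts["none"]))
  cat(sprintf("  strong (<50%% drug viability): %d\n", s$n_strong))
  invisible(x)
}

#' Transfection quality control from positive-control wells
#'
#' The lethal positive control (PLK1-style siRNA) is excluded from hit
#' statistics but its normalized viability is reported as a transfection QC
#' metric; effective transfection is expected to leave it at or below
#' `max_viability` percent.
#'
#' @param records Viability records including `positive_control` rows.
#' @param max_viability QC pass threshold, percent (default 25).
#' @return List with `viability_pct` (per treatment) and `pass`.
#' @export
positive_control_qc <- function(records, max_viability = 25) {
  check_columns(records, c("perturbation_class", "treatment", "viability_pct"),
                "viability records")
  pc <- records[records$perturbation_class == "positive_control", ]
  if (!nrow(pc)) stop("no positive-control records present", call. = FALSE)
  v <- tapply(pc$viability_pct, pc$treatment, mean)
  list(viability_pct = v, pass = all(v <= max_viability))
}
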