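# Small constructors shared across test files.

# Noise-free well table: one plate per treatment, explicit control signals.
make_wells <- function(perts, treatment, signals, ctrl_signal = 1000,
                       plate_id = paste0("P1_", treatment)) {
  n_ctrl <- 2
  data.frame(
    plate_id = plate_id,
    well = sprintf("W%03d", seq_len(n_ctrl + length(perts))),
    cell_line = "PC3",
    perturbation_id = c(rep("NTC", n_ctrl), perts),
    perturbation_class = c(rep("non_targeting", n_ctrl),
                           rep("mimic", length(perts))),
    treatment = treatment,
    dose = if (treatment == "vehicle") 0 else 20,
    signal = c(rep(ctrl_signal, n_ctrl), signals),
    stringsAsFactors = FALSE
  )
}

# Viability records straight from percentages (skips normalization).
make_records <- function(ids, vehicle_pct, drug_pct, drug = "docetaxel") {
  rbind(
    data.frame(perturbation_id = ids, cell_line = "PC3",
               perturbation_class = "mimic", treatment = "vehicle",
               viability_pct = vehicle_pct, n_wells = 1L, sd_pct = 0,
               stringsAsFactors = FALSE),
    data.frame(perturbation_id = ids, cell_line = "PC3",
               perturbation_class = "mimic", treatment = drug,
               viability_pct = drug_pct, n_wells = 1L, sd_pct = 0,
               stringsAsFactors = FALSE)
  )
}

# Independent one-line restatement of the printed dual-threshold rule,
# used as the oracle for call_sensitisers.
oracle_category <- function(vehicle, drug, margin = 10) {
  if (vehicle > 80) {
    if (drug < 80) "sensitiser" else "none"
  } else {
    if (drug < vehicle - margin) "toxic_sensitiser" else "toxic"
  }
}

# Exhaustive hypergeometric upper tail by enumerating every n-subset of a
# universe of size N containing K labelled successes.
enum_hyper_tail <- function(n, K, k, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}
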