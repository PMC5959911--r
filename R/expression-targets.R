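# Post-differential-expression transcript filters, set arithmetic and
# microRNA target-evidence annotation. The differential-expression fit
# itself (a count model) is consumed as a table, not implemented here.

KNOWN_SOURCES <- c("tarbase", "starbase", "mirtarbase", "targetscan",
                   "mirdb", "diana")
EXPERIMENTAL_SOURCES <- "tarbase"

#' Remove low-signal, low-variance transcripts from a DE table
#'
#' A transcript is removed when it is essentially unexpressed *and* flat:
#' group-mean abundance below `rpkm_threshold` in **both** groups, and
#' across-sample variance below the median of per-gene variances. The
#' median is computed once, over all genes present before filtering, on the
#' pooled samples of both groups (per-group variance available via
#' `variance = "per_group"`, which then requires the gene to be sub-median
#' in both groups).
#'
#' @param de DE table: data frame with at least `gene_id`.
#' @param expr Expression matrix (genes x samples), e.g.
#'   `simulate_expression()$matrix`.
#' @param groups Per-sample group labels (two groups).
#' @param rpkm_threshold Abundance floor, RPKM-like units (default 1).
#' @param variance `"pooled"` (default) or `"per_group"` median-variance
#'   convention.
#' @return The filtered DE table with attributes `n_removed` and
#'   `removed_genes`.
#' @export
filter_low_signal <- function(de, expr, groups, rpkm_threshold = 1,
                              variance = c("pooled", "per_group")) {
  variance <- match.arg(variance)
  check_columns(de, "gene_id", "DE table")
  stopifnot(is.matrix(expr), length(groups) == ncol(expr))
  gl <- unique(groups)
  if (length(gl) != 2) stop("expr must carry exactly two groups", call. = FALSE)
  absent <- setdiff(de$gene_id, rownames(expr))
  if (length(absent)) {
    stop(sprintf("DE gene(s) absent from expression matrix: %s",
                 paste(utils::head(absent, 5), collapse = ", ")),
         call. = FALSE)
  }
  m1 <- rowMeans(expr[, groups == gl[1], drop = FALSE])
  m2 <- rowMeans(expr[, groups == gl[2], drop = FALSE])
  low_expr <- m1 < rpkm_threshold & m2 < rpkm_threshold
  row_var <- function(m) apply(m, 1, stats::var)
  if (variance == "pooled") {
    v <- row_var(expr)
    low_var <- v < stats::median(v)
  } else {
    v1 <- row_var(expr[, groups == gl[1], drop = FALSE])
    v2 <- row_var(expr[, groups == gl[2], drop = FALSE])
    low_var <- v1 < stats::median(v1) & v2 < stats::median(v2)
  }
  drop_gene <- rownames(expr)[low_expr & low_var]
  keep <- !(de$gene_id %in% drop_gene)
  out <- de[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "removed_genes") <- de$gene_id[!keep]
  out
}

#' Significantly downregulated gene set
#'
#' Genes called down with BH-adjusted p strictly below `alpha`.
#'
#' @param de DE table with `gene_id`, `adjusted_p` and either a `direction`
#'   column (`"up"`/`"down"`) or a linear `fold_change` (down when < 1).
#' @param alpha Significance cutoff on adjusted p (default 0.05, strict).
#' @return Character vector of gene ids.
#' @export
downregulated_set <- function(de, alpha = 0.05) {
  check_columns(de, c("gene_id", "adjusted_p"), "DE table")
  down <- if ("direction" %in% names(de)) {
    de$direction == "down"
  } else {
    check_columns(de, "fold_change", "DE table")
    de$fold_change < 1
  }
  de$gene_id[down & de$adjusted_p < alpha]
}

#' Overlap between two gene sets
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @return List with `n_a`, `n_b`, `n_common`, `pct_of_a`, `pct_of_b`
#'   (percentages integer-rounded, half away from zero).
#' @export
overlap_summary <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  common <- length(intersect(a, b))
  list(
    n_a = length(a), n_b = length(b), n_common = common,
    pct_of_a = pct_of(common, length(a)),
    pct_of_b = pct_of(common, length(b))
  )
}

#' Annotate genes with microRNA target evidence
#'
#' Flags each gene of a query set as an experimentally supported target, a
#' predicted target, or unsupported for the given microRNA, and summarizes
#' the counts as integer percentages of the query set. A gene with both
#' experimental and predicted support is counted as experimental.
#'
#' @param genes Character vector of gene ids (the downregulated set).
#' @param evidence Target-evidence table: `mirna_id`, `gene_id`, `source`,
#'   `evidence_class` (`"experimental"`/`"predicted"`).
#' @param mirna MicroRNA id to annotate against.
#' @return List with `annotation` (data frame `gene_id`, `status`) and
#'   `summary` (`n`, `n_experimental`, `pct_experimental`, `n_predicted`,
#'   `pct_predicted`, `n_unsupported`).
#' @export
annotate_targets <- function(genes, evidence, mirna) {
  genes <- unique(genes)
  if (nrow(evidence)) {
    check_columns(evidence, c("mirna_id", "gene_id", "source",
                              "evidence_class"), "evidence table")
    ev <- evidence[evidence$mirna_id == mirna, ]
  } else {
    ev <- data.frame(gene_id = character(0), evidence_class = character(0))
  }
  exp_genes <- unique(ev$gene_id[ev$evidence_class == "experimental"])
  pred_genes <- setdiff(unique(ev$gene_id[ev$evidence_class == "predicted"]),
                        exp_genes)
  status <- ifelse(genes %in% exp_genes, "experimental",
                   ifelse(genes %in% pred_genes, "predicted", "unsupported"))
  n <- length(genes)
  n_exp <- sum(status == "experimental")
  n_pred <- sum(status == "predicted")
  list(
    annotation = data.frame(gene_id = genes, status = status,
                            stringsAsFactors = FALSE),
    summary = list(
      n = n,
      n_experimental = n_exp, pct_experimental = pct_of(n_exp, n),
      n_predicted = n_pred, pct_predicted = pct_of(n_pred, n),
      n_unsupported = n - n_exp - n_pred
    )
  )
}

#' Aggregate target predictions across sources
#'
#' Combines per-source (microRNA, gene) target tables into one consensus
#' evidence table. `union` keeps a pair supported by at least one source,
#' `intersection` requires all sources, `k_of_n` at least `k`. A pair is
#' classed experimental when any supporting source is experimental
#' (TarBase by default), else predicted.
#'
#' @param per_source_tables Named list of data frames (name = source, one of
#'   tarbase, starbase, mirtarbase, targetscan, mirdb, diana), each with
#'   columns `mirna_id` and `gene_id` and optionally `evidence_class`.
#' @param mode `"union"`, `"intersection"` or `"k_of_n"`.
#' @param k Minimum source count for `k_of_n`.
#' @return Evidence table `mirna_id`, `gene_id`, `source` (comma-joined
#'   supporting sources), `evidence_class`, `n_sources`.
#' @export
aggregate_predictions <- function(per_source_tables,
                                  mode = c("union", "intersection", "k_of_n"),
                                  k = NULL) {
  mode <- match.arg(mode)
  sources <- names(per_source_tables)
  if (is.null(sources) || any(!nzchar(sources))) {
    stop("per_source_tables must be a named list", call. = FALSE)
  }
  unknown <- setdiff(sources, KNOWN_SOURCES)
  if (length(unknown)) {
    stop(sprintf("unknown source label(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(KNOWN_SOURCES, collapse = ", ")), call. = FALSE)
  }
  n_src <- length(sources)
  if (mode == "k_of_n") {
    if (is.null(k)) stop("k is required for mode 'k_of_n'", call. = FALSE)
    if (k > n_src) stop("k must be <= number of sources", call. = FALSE)
  }
  rows <- lapply(sources, function(s) {
    tab <- per_source_tables[[s]]
    check_columns(tab, c("mirna_id", "gene_id"), sprintf("table '%s'", s))
    cls <- if ("evidence_class" %in% names(tab)) tab$evidence_class else
      rep(if (s %in% EXPERIMENTAL_SOURCES) "experimental" else "predicted",
          nrow(tab))
    data.frame(mirna_id = tab$mirna_id, gene_id = tab$gene_id,
               source = s, evidence_class = cls, stringsAsFactors = FALSE)
  })
  all_ev <- unique(do.call(rbind, rows))
  if (!nrow(all_ev)) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      source = character(0), evidence_class = character(0),
                      n_sources = integer(0)))
  }
  key <- paste(all_ev$mirna_id, all_ev$gene_id, sep = "\r")
  splits <- split(all_ev, key)
  agg <- do.call(rbind, lapply(splits, function(d) {
    data.frame(
      mirna_id = d$mirna_id[1], gene_id = d$gene_id[1],
      source = paste(sort(unique(d$source)), collapse = ","),
      evidence_class = if (any(d$evidence_class == "experimental"))
        "experimental" else "predicted",
      n_sources = length(unique(d$source)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  min_n <- switch(mode, union = 1L, intersection = n_src, k_of_n = as.integer(k))
  out <- agg[agg$n_sources >= min_n, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simple per-gene differential expression for synthetic matrices
#'
#' Convenience DE generator for simulated abundance matrices: per-gene Welch
#' t-test on `log2(x + 0.5)` with BH adjustment and linear fold change from
#' group means. This is a plain two-group test for planted-effect recovery
#' studies on synthetic data, not a count-model fit, and is no substitute
#' for one on real sequencing counts.
#'
#' @param expr Abundance matrix (genes x samples).
#' @param groups Per-sample labels; exactly two groups.
#' @param ref Reference (denominator) group label; defaults to the first.
#' @return DE table: `gene_id`, `fold_change` (treatment/reference),
#'   `p_value`, `adjusted_p`, `direction`.
#' @export
de_from_expression <- function(expr, groups, ref = NULL) {
  stopifnot(is.matrix(expr), length(groups) == ncol(expr))
  gl <- unique(groups)
  if (length(gl) != 2) stop("exactly two groups required", call. = FALSE)
  if (is.null(ref)) ref <- gl[1]
  trt <- setdiff(gl, ref)
  a <- expr[, groups == ref, drop = FALSE]
  b <- expr[, groups == trt, drop = FALSE]
  la <- log2(a + 0.5)
  lb <- log2(b + 0.5)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    tryCatch(stats::t.test(lb[i, ], la[i, ])$p.value, error = function(e) 1)
  }, numeric(1))
  fc <- rowMeans(b) / rowMeans(a)
  data.frame(
    gene_id = rownames(expr),
    fold_change = fc,
    p_value = p,
    adjusted_p = stats::p.adjust(p, method = "BH"),
    direction = ifelse(fc < 1, "down", "up"),
    stringsAsFactors = FALSE
  )
}
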