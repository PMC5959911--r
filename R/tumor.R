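# Tumor-expression evaluation: missing-value cleaning, per-gene two-group
# t-tests with BH adjustment and fold filtering, z-scored heatmap export.

#' Construct a tumor expression matrix
#'
#' Light container pairing an intensity matrix (genes x samples, `NA` for
#' missing) with per-sample tissue-group labels.
#'
#' @param values Numeric matrix with gene row names and sample column names.
#' @param groups Character vector of tissue-group labels, one per sample.
#' @return Object of class `"tumor_matrix"`.
#' @export
tumor_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), length(groups) == ncol(values))
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("gene%04d", seq_len(nrow(values)))
  }
  structure(list(values = values, groups = as.character(groups)),
            class = "tumor_matrix")
}

#' @export
print.tumor_matrix <- function(x, ...) {
  cat(sprintf("Tumor matrix: %d genes x %d samples (%s); %d missing values\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", names(table(x$groups)),
                            table(x$groups)), collapse = ", "),
              sum(is.na(x$values))))
  invisible(x)
}

#' Clean a tumor matrix: missingness removal and minimum imputation
#'
#' Removes any gene with more than 50% missing values within any single
#' tissue group (strictly more: exactly half is retained), then replaces the
#' remaining missing entries with the minimum observed value of the whole
#' dataset.
#'
#' @param tm A [tumor_matrix()].
#' @param max_missing Maximum tolerated per-group missing fraction
#'   (default 0.5).
#' @return The cleaned `"tumor_matrix"` with attributes `n_removed` and
#'   `n_imputed`.
#' @export
clean_matrix <- function(tm, max_missing = 0.5) {
  stopifnot(inherits(tm, "tumor_matrix"))
  m <- tm$values
  groups <- tm$groups
  frac_missing <- sapply(unique(groups), function(g) {
    rowMeans(is.na(m[, groups == g, drop = FALSE]))
  })
  frac_missing <- matrix(frac_missing, nrow = nrow(m))
  drop <- apply(frac_missing, 1, max) > max_missing
  m <- m[!drop, , drop = FALSE]
  n_imputed <- sum(is.na(m))
  if (n_imputed) {
    m[is.na(m)] <- min(m, na.rm = TRUE)
  }
  for (g in unique(groups)) {
    if (sum(groups == g) < 2) {
      stop(sprintf("tissue group '%s' has fewer than 2 samples", g),
           call. = FALSE)
    }
  }
  out <- tumor_matrix(m, groups)
  attr(out, "n_removed") <- sum(drop)
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Two-group differential expression on a cleaned tumor matrix
#'
#' Per-gene two-sided t-test (Welch by default; pooled-variance via
#' `var_equal = TRUE`) between two tissue groups, BH adjustment across all
#' tested genes, and linear fold change from group means. A gene is
#' `significant_up` when adjusted p <= `alpha` (inclusive) and fold
#' >= `min_fold`; the symmetric down call uses fold <= `1/min_fold`. Input
#' flagged as log2-scale is exponentiated before fold computation, since the
#' fold threshold is a linear-scale statement.
#'
#' @param tm A cleaned [tumor_matrix()].
#' @param group1 Reference (denominator) group label, e.g. `"normal"`.
#' @param group2 Comparison (numerator) group label, e.g. `"tumor"`.
#' @param alpha Adjusted-p cutoff (default 0.05, inclusive).
#' @param min_fold Fold-change cutoff (default 1.5).
#' @param var_equal Use the pooled-variance t-test (default `FALSE`, Welch).
#' @param log2_input Set when intensities are log2-scale.
#' @return Data frame: `gene_id`, `fold_change` (group2/group1),
#'   `p_value`, `adjusted_p`, `significant_up`, `significant_down`.
#' @export
two_group_de <- function(tm, group1, group2, alpha = 0.05, min_fold = 1.5,
                         var_equal = FALSE, log2_input = FALSE) {
  stopifnot(inherits(tm, "tumor_matrix"))
  m <- tm$values
  groups <- tm$groups
  for (g in c(group1, group2)) {
    if (sum(groups == g) < 2) {
      stop(sprintf("group '%s' needs >= 2 samples", g), call. = FALSE)
    }
  }
  a <- m[, groups == group1, drop = FALSE]
  b <- m[, groups == group2, drop = FALSE]
  n_degenerate <- 0L
  p <- vapply(seq_len(nrow(m)), function(i) {
    if (stats::sd(a[i, ]) == 0 && stats::sd(b[i, ]) == 0) {
      n_degenerate <<- n_degenerate + 1L
      return(1)
    }
    stats::t.test(b[i, ], a[i, ], var.equal = var_equal)$p.value
  }, numeric(1))
  if (n_degenerate) {
    warning(sprintf(
      "%d gene(s) with zero variance in both groups: p set to 1",
      n_degenerate))
  }
  lin <- if (log2_input) 2^m else m
  fc <- rowMeans(lin[, groups == group2, drop = FALSE]) /
    rowMeans(lin[, groups == group1, drop = FALSE])
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(
    gene_id = rownames(m),
    fold_change = fc,
    p_value = p,
    adjusted_p = adj,
    significant_up = adj <= alpha & fc >= min_fold,
    significant_down = adj <= alpha & fc <= 1 / min_fold,
    stringsAsFactors = FALSE
  )
}

#' Per-gene standard scores for heatmap display
#'
#' Centres and scales each gene row to zero mean and unit variance using
#' the population (divide-by-n) standard deviation. Zero-variance rows are
#' emitted as zeros with a warning.
#'
#' @param tm A cleaned [tumor_matrix()] (or plain numeric matrix).
#' @return Numeric matrix of z-scores with the input dimnames.
#' @export
zscore_matrix <- function(tm) {
  m <- if (inherits(tm, "tumor_matrix")) tm$values else tm
  stopifnot(is.matrix(m))
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))
  flat <- sdp == 0
  if (any(flat)) {
    warning(sprintf("%d constant row(s) emitted as zeros", sum(flat)))
    sdp[flat] <- 1
  }
  z <- (m - mu) / sdp
  z[flat, ] <- 0
  z
}

#' Fraction of a gene panel significantly upregulated
#'
#' Percentage of panel genes, among those present in the DE results, that
#' are `significant_up`; integer-rounded. Panel genes absent from the DE
#' table are reported separately, not counted in the denominator.
#'
#' @param gene_panel Character vector of gene ids.
#' @param de Result table from [two_group_de()].
#' @return List with `pct_up`, `n_up`, `n_present`, `absent` (ids not in
#'   `de`).
#' @export
upregulated_fraction <- function(gene_panel, de) {
  if (!length(gene_panel)) stop("gene panel must be nonempty", call. = FALSE)
  check_columns(de, c("gene_id", "significant_up"), "DE results")
  panel <- unique(gene_panel)
  present <- panel[panel %in% de$gene_id]
  absent <- setdiff(panel, present)
  up <- sum(de$significant_up[match(present, de$gene_id)])
  pct <- if (length(present)) pct_of(up, length(present)) else 0
  list(pct_up = pct, n_up = up, n_present = length(present), absent = absent)
}
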