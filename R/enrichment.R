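# Hypergeometric gene-set over-representation testing against GMT
# collections, with BH adjustment and ranked output.

#' Read a GMT gene-set collection
#'
#' Parses the tab-separated MSigDB dialect: one set per line as
#' `name<TAB>description<TAB>member...`. Duplicate members within a set are
#' dropped with a warning; a line with fewer than three fields is a parse
#' error reported with its line number.
#'
#' @param path Path to a GMT file.
#' @param name Collection name (defaults to the file name).
#' @return A list of class `"gene_set_collection"` with elements `name`,
#'   `sets` (named list of member vectors) and `descriptions`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short)) {
    stop(sprintf("GMT parse error: line %d has fewer than 3 fields",
                 short[1]), call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1)
  dups <- vapply(sets, anyDuplicated, integer(1)) > 0
  if (any(dups)) {
    warning(sprintf("duplicate members removed in set(s): %s",
                    paste(names(sets)[dups], collapse = ", ")))
    sets <- lapply(sets, unique)
  }
  structure(list(
    name = name,
    sets = sets,
    descriptions = stats::setNames(vapply(fields, `[`, character(1), 2),
                                   names(sets))
  ), class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#'
#' @param collection A `"gene_set_collection"` (or named list of member
#'   vectors).
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  if (!inherits(collection, "gene_set_collection")) {
    collection <- list(sets = collection,
                       descriptions = rep("na", length(collection)))
    names(collection$descriptions) <- names(collection$sets)
  }
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection '%s': %d sets, %d distinct genes\n",
              x$name, length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `k` members of a `K`-gene set in a
#' random draw of `n` genes from a universe of `N`, i.e. `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Evaluated through the log-space tail of
#' [stats::phyper()] for numerical safety at extreme overlaps.
#'
#' @param query_size Number of drawn genes `n`.
#' @param set_size Number of successes in the universe `K`.
#' @param overlap Observed overlap `k`.
#' @param universe Universe size `N`.
#' @return The p-value `P(X >= k)`.
#' @export
hypergeom_overlap_p <- function(query_size, set_size, overlap, universe) {
  if (set_size > universe || query_size > universe) {
    stop("set and query sizes must not exceed the universe", call. = FALSE)
  }
  if (overlap > min(query_size, set_size) || overlap < 0) {
    stop("overlap must lie in [0, min(query_size, set_size)]", call. = FALSE)
  }
  if (overlap == 0) return(1)
  exp(stats::phyper(overlap - 1, set_size, universe - set_size, query_size,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (sort ascending, `adj_i = min_{j >= i} m p_j / j`
#' capped at 1, returned in input order), delegated to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation of a query set across a collection
#'
#' Intersects the query with the collection's namespace (the union of all
#' set members — genes the collection can recognise), then tests each set's
#' overlap with the recognised query by the upper-tail hypergeometric test,
#' BH-adjusts across sets, and returns rows ranked by ascending p-value.
#'
#' @param query Character vector of query gene ids.
#' @param collection A `"gene_set_collection"`.
#' @param universe_size Universe size `N` for the test. Required: printed
#'   overlap p-values depend on it and no silent default is appropriate.
#' @param top Optionally return only the first `top` rows after ranking.
#' @return Data frame: `set_name`, `genes_in_set`, `genes_in_overlap`,
#'   `p_value`, `adjusted_p`, `rank`; attribute `n_recognised` gives the
#'   recognised-query size used as the draw.
#' @export
enrich_collection <- function(query, collection, universe_size, top = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(query)) stop("query must be nonempty", call. = FALSE)
  if (missing(universe_size) || is.null(universe_size)) {
    stop("universe_size is required", call. = FALSE)
  }
  namespace <- unique(unlist(collection$sets))
  recognised <- intersect(unique(query), namespace)
  if (!length(recognised)) {
    stop(sprintf("no query genes recognised by the collection (0 of %d)",
                 length(unique(query))), call. = FALSE)
  }
  n <- length(recognised)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    k <- length(intersect(recognised, members))
    data.frame(
      set_name = nm,
      genes_in_set = length(members),
      genes_in_overlap = k,
      p_value = hypergeom_overlap_p(n, length(members), k, universe_size),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top)) out <- utils::head(out, top)
  attr(out, "n_recognised") <- n
  out
}
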