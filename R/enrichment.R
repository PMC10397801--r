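#' Overlap two gene sets
#'
#' @param a,b character vectors of gene identifiers.
#' @param labels names for the two sets.
#' @return a list of class `overlap_result` with the shared genes (sorted,
#'   unique), the exclusive counts and the set sizes.
#' @export
overlap_genes <- function(a, b, labels = c("A", "B")) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  shared <- sort(intersect(a, b))
  structure(list(labels = labels, size_a = length(a), size_b = length(b),
                 shared = shared, n_shared = length(shared),
                 only_a = length(setdiff(a, b)), only_b = length(setdiff(b, a))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %s (%d) vs %s (%d): %d shared, %d/%d exclusive\n",
              x$labels[1], x$size_a, x$labels[2], x$size_b,
              x$n_shared, x$only_a, x$only_b))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values (capped at 1, input order preserved).
#' Validates the input and delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, never below the raw values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, tests over-representation of the query in the term's
#' genes with the hypergeometric upper tail
#' `p = P(X >= k)`, `X ~ Hypergeometric(N, K, n)`, where `N` is the
#' universe size, `K` the term size within the universe, `n` the query size
#' and `k` the observed overlap; BH adjustment across all terms. Term genes
#' are intersected with the universe first; the query must be a subset of
#' the universe.
#'
#' @param query character vector of genes of interest.
#' @param gene_sets named list, term id -> character vector of genes.
#' @param universe character vector of background genes.
#' @return data.frame with `term`, `K`, `N`, `n`, `k`, `genes`
#'   (comma-separated overlap), `p_value`, `fdr`, ordered by `p_value`.
#' @export
hypergeom_enrich <- function(query, gene_sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  query <- unique(as.character(query))
  if (!all(query %in% universe)) {
    stop("query contains genes absent from the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(term) {
    tg <- intersect(unique(as.character(gene_sets[[term]])), universe)
    K <- length(tg)
    ov <- intersect(query, tg)
    k <- length(ov)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, K = K, N = N, n = n, k = k,
               genes = paste(sort(ov), collapse = ","),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(term = character(0), K = integer(0), N = integer(0),
                      n = integer(0), k = integer(0), genes = character(0),
                      p_value = numeric(0), fdr = numeric(0)))
  }
  res$fdr <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a gene-set file
#'
#' Accepts GMT (term, description, genes...) or two-column TSV
#' (term, gene).
#'
#' @param path file path.
#' @return named list term -> gene vector.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  two_col <- all(lengths(fields) == 2)
  if (two_col) {
    df <- data.frame(term = vapply(fields, `[`, character(1), 1),
                     gene = vapply(fields, `[`, character(1), 2),
                     stringsAsFactors = FALSE)
    lapply(split(df$gene, df$term), unique)
  } else {
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- vapply(fields, `[`, character(1), 1)
    sets
  }
}
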