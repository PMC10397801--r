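#' Count unique fragments per gene
#'
#' A fragment is counted for a gene when all of its aligned blocks fall
#' within that gene's exon union on the matching strand and it is
#' assignable to exactly one gene; fragments touching no gene or more than
#' one gene are discarded (tallied in the `n_ambiguous` / `n_unassigned`
#' attributes). Input should already be deduplicated / unique-mapping as
#' appropriate.
#'
#' @param aset an `alignment_set`.
#' @param ann a `gene_annotation`.
#' @return named integer vector of counts (one per annotated gene) with
#'   bookkeeping attributes.
#' @export
count_genes <- function(aset, ann) {
  stopifnot(is(aset, "alignment_set"))
  gene_ids <- mcols(ann$genes)$gene_id
  counts <- setNames(integer(length(gene_ids)), gene_ids)
  ga <- aset$ga
  if (!length(ga)) {
    attr(counts, "n_ambiguous") <- 0L
    attr(counts, "n_unassigned") <- 0L
    return(counts)
  }
  blocks <- grglist(ga)                     # aligned blocks per fragment
  eu <- exon_union(ann)
  bl <- unlist(blocks, use.names = FALSE)
  read_of <- rep(seq_along(blocks), lengths(blocks))
  eu_fl <- unlist(eu, use.names = FALSE)
  gene_of <- rep(names(eu), lengths(eu))
  ov <- findOverlaps(bl, eu_fl)             # strand-aware
  n_amb <- 0L
  if (length(ov)) {
    ## containment: covered width within the gene's exon union must equal
    ## the fragment's total block width (union pieces are disjoint)
    owidth <- width(pintersect(bl[queryHits(ov)], eu_fl[subjectHits(ov)]))
    key <- paste(read_of[queryHits(ov)], gene_of[subjectHits(ov)], sep = "\r")
    covered <- rowsum(owidth, key)
    parts <- strsplit(rownames(covered), "\r", fixed = TRUE)
    rd <- as.integer(vapply(parts, `[`, character(1), 1))
    gn <- vapply(parts, `[`, character(1), 2)
    bw <- as.integer(sum(width(blocks)))
    ok <- covered[, 1] == bw[rd]
    rd <- rd[ok]; gn <- gn[ok]
    ngenes <- table(rd)
    uniq_reads <- as.integer(names(ngenes)[ngenes == 1])
    n_amb <- sum(ngenes > 1)
    sel <- rd %in% uniq_reads
    tab <- table(gn[sel])
    counts[names(tab)] <- as.integer(tab)
  }
  attr(counts, "n_ambiguous") <- as.integer(n_amb)
  attr(counts, "n_unassigned") <- length(ga) - sum(counts) -
    as.integer(n_amb)
  counts
}

#' Build a gene-counts container
#'
#' @param counts gene x sample integer matrix.
#' @param lengths named union-exon gene lengths in bases.
#' @param library_sizes per-sample totals of mapped fragments; defaults to
#'   the column sums.
#' @return a list of class `gene_counts`.
#' @export
gene_counts <- function(counts, lengths, library_sizes = colSums(counts)) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            all(rownames(counts) %in% names(lengths)))
  lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  structure(list(counts = counts, lengths = lengths,
                 library_sizes = library_sizes),
            class = "gene_counts")
}

#' Union-exon gene lengths
#'
#' @param ann a `gene_annotation`.
#' @return named numeric vector of summed reduced exon widths.
#' @export
gene_lengths <- function(ann) {
  eu <- exon_union(ann)
  setNames(as.numeric(sum(width(eu))), names(eu))
}

#' Compute FPKM
#'
#' `FPKM(g, s) = count(g, s) * 1e9 / (length(g) * library_size(s))` —
#' fragments per kilobase of union-exon length per million mapped fragments.
#'
#' @param gc a [gene_counts()] object.
#' @return numeric matrix of FPKM values, same dimensions as the counts.
#' @export
compute_fpkm <- function(gc) {
  stopifnot(is(gc, "gene_counts"))
  if (any(gc$library_sizes <= 0)) stop("library sizes must be positive")
  sweep(sweep(gc$counts * 1e9, 1, gc$lengths, "/"), 2, gc$library_sizes, "/")
}

#' Differential expression screen
#'
#' A deliberately simple replacement for a negative-binomial GLM fit:
#' size factors by median-of-ratios normalisation, a per-gene two-sample
#' Student's t-test on `log2(normalised count + 1)`, and fold changes from
#' the normalised condition means (with a pseudocount of 1 when a condition
#' mean is zero). A gene is a DEG when `FC > fc_up` or `FC < fc_down` and
#' `p < p_thresh` — no multiple-testing adjustment is applied, matching the
#' stated screening rule. Genes with zero counts everywhere are excluded.
#' An externally produced DEG table with columns
#' (`gene_id`, `fold_change`, `p_value`) can be substituted downstream
#' wherever this result is consumed.
#'
#' @param gc a [gene_counts()] object.
#' @param design data.frame with `sample`, `condition` (reference first).
#' @param fc_up,fc_down fold-change cut-offs.
#' @param p_thresh raw p-value cut-off.
#' @return data.frame with `gene_id`, `base_mean`, `fold_change`,
#'   `log2_fc`, `p_value`, `direction` (`up`/`down`/`ns`), `is_deg`.
#' @export
de_filter <- function(gc, design, fc_up = 2, fc_down = 0.5, p_thresh = 0.05) {
  stopifnot(is(gc, "gene_counts"),
            all(design$sample %in% colnames(gc$counts)))
  conds <- unique(design$condition)
  if (length(conds) != 2) stop("design must contain exactly two conditions")
  ref_s <- design$sample[design$condition == conds[1]]
  alt_s <- design$sample[design$condition == conds[2]]
  if (length(ref_s) < 2 || length(alt_s) < 2) {
    stop("at least two replicates per condition are required")
  }
  cnt <- gc$counts[, c(ref_s, alt_s), drop = FALSE]
  keep <- rowSums(cnt) > 0
  cnt <- cnt[keep, , drop = FALSE]
  sf <- size_factors(cnt)
  norm <- sweep(cnt, 2, sf, "/")
  lg <- log2(norm + 1)
  mean_ref <- rowMeans(norm[, ref_s, drop = FALSE])
  mean_alt <- rowMeans(norm[, alt_s, drop = FALSE])
  fc <- (mean_alt + (mean_alt == 0)) / (mean_ref + (mean_ref == 0))
  pv <- vapply(seq_len(nrow(lg)), function(i) {
    x <- lg[i, ref_s]; y <- lg[i, alt_s]
    if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      return(if (mean(y) == mean(x)) 1 else 0)
    }
    t.test(y, x, var.equal = TRUE)$p.value
  }, numeric(1))
  is_deg <- (fc > fc_up | fc < fc_down) & pv < p_thresh
  data.frame(gene_id = rownames(cnt),
             base_mean = rowMeans(norm),
             fold_change = fc, log2_fc = log2(fc), p_value = pv,
             direction = ifelse(!is_deg, "ns", ifelse(fc > 1, "up", "down")),
             is_deg = is_deg,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Median-of-ratios size factors (reference = geometric mean over samples).
size_factors <- function(cnt) {
  lgm <- rowMeans(log(cnt))
  use <- is.finite(lgm)
  if (!any(use)) return(setNames(rep(1, ncol(cnt)), colnames(cnt)))
  sf <- apply(cnt, 2, function(x) exp(median((log(x) - lgm)[use])))
  sf / exp(mean(log(sf)))   # normalise to geometric mean 1
}
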