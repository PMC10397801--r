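#' Assign feature categories and host genes to peaks
#'
#' Each peak gets exactly one category with precedence
#' `CDS > nc_exon > intron > antisense > intergenic`, evaluated on
#' same-strand overlap first (exons of protein-coding genes count as CDS,
#' exons of noncoding genes as nc_exon, remaining gene-body overlap as
#' intron) and then opposite-strand gene overlap (antisense). `host_genes`
#' lists all same-strand genes the peak overlaps, or the antisense gene for
#' antisense peaks; intergenic peaks have none.
#'
#' @param peaks a `GRanges` of peaks.
#' @param ann a `gene_annotation`.
#' @return `peaks` with `category` and `host_genes` (comma-separated)
#'   metadata columns.
#' @export
annotate_peaks <- function(peaks, ann) {
  if (!length(peaks)) {
    mcols(peaks)$category <- character(0)
    mcols(peaks)$host_genes <- character(0)
    return(peaks)
  }
  genes <- ann$genes
  exons <- ann$exons
  coding_gene <- mcols(genes)$gene_id[mcols(genes)$biotype == "protein_coding"]
  ex_coding <- exons[mcols(exons)$gene_id %in% coding_gene]
  ex_nc <- exons[!(mcols(exons)$gene_id %in% coding_gene)]

  has_hit <- function(subj) countOverlaps(peaks, subj) > 0
  same_cds <- has_hit(ex_coding)
  same_nc <- has_hit(ex_nc)
  same_gene <- has_hit(genes)
  anti_genes <- invert_strand_gr(genes)
  anti <- countOverlaps(peaks, anti_genes) > 0

  category <- ifelse(same_cds, "CDS",
              ifelse(same_nc, "nc_exon",
              ifelse(same_gene, "intron",
              ifelse(anti, "antisense", "intergenic"))))

  sh <- findOverlaps(peaks, genes)
  ah <- findOverlaps(peaks, anti_genes)
  hosts <- character(length(peaks))
  samel <- split(mcols(genes)$gene_id[subjectHits(sh)], queryHits(sh))
  antil <- split(mcols(genes)$gene_id[subjectHits(ah)], queryHits(ah))
  for (i in seq_along(peaks)) {
    key <- as.character(i)
    hosts[i] <- if (category[i] == "antisense") {
      paste(sort(unique(antil[[key]])), collapse = ",")
    } else if (category[i] == "intergenic") {
      ""
    } else {
      paste(sort(unique(samel[[key]])), collapse = ",")
    }
  }
  mcols(peaks)$category <- category
  mcols(peaks)$host_genes <- hosts
  peaks
}

invert_strand_gr <- function(gr) {
  s <- as.character(strand(gr))
  strand(gr) <- ifelse(s == "+", "-", ifelse(s == "-", "+", "*"))
  gr
}

#' Genes targeted by a peak set
#'
#' Union of the `host_genes` of all annotated peaks; intergenic peaks
#' contribute nothing.
#'
#' @param peaks annotated peaks (see [annotate_peaks()]).
#' @return sorted character vector of gene identifiers.
#' @export
peaks_to_genes <- function(peaks) {
  if (!length(peaks)) return(character(0))
  stopifnot(!is.null(mcols(peaks)$host_genes))
  g <- unlist(strsplit(mcols(peaks)$host_genes, ",", fixed = TRUE))
  sort(unique(g[nzchar(g)]))
}

#' Peak category composition
#'
#' Percentage of peaks per feature category, the tabular analogue of the
#' usual peak-distribution pie charts.
#'
#' @param peaks annotated peaks.
#' @return data.frame with `category`, `n`, `percent`.
#' @export
peak_category_summary <- function(peaks) {
  cats <- c("CDS", "nc_exon", "intron", "antisense", "intergenic")
  n <- vapply(cats, function(ct) sum(mcols(peaks)$category == ct), numeric(1))
  data.frame(category = cats, n = as.integer(n),
             percent = if (length(peaks)) 100 * n / length(peaks) else rep(0, 5),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write peaks as BED6+
#'
#' Columns: chrom, start (0-based), end, name, score (= max depth), strand,
#' then `perm_p`, `input_ratio_obs`, `category`, `host_genes` when present.
#'
#' @param peaks a `GRanges` of peaks.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = if (is.null(names(peaks))) sprintf("peak_%04d", seq_along(peaks)) else names(peaks),
                   score = mcols(peaks)$max_depth,
                   strand = as.character(strand(peaks)),
                   stringsAsFactors = FALSE)
  for (col in c("perm_p", "input_ratio_obs", "category", "host_genes")) {
    if (!is.null(mcols(peaks)[[col]])) df[[col]] <- mcols(peaks)[[col]]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an externally produced peak BED file
#'
#' Accepts BED6 peaks from another caller for the same downstream
#' integration (annotation, gene mapping, overlaps).
#'
#' @param path BED file.
#' @return a `GRanges`.
#' @export
read_peaks_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
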