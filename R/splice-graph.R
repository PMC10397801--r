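#' Build a splice graph from an annotation
#'
#' Per gene, collects the unique exon intervals, the annotated junction set
#' (pairs of adjacent exons within a transcript, keyed by the last base of
#' the upstream exon and the first base of the downstream exon), and flags
#' which exon intervals act as transcription-first or transcription-last
#' exons in at least one transcript. Single-exon transcripts contribute no
#' junctions.
#'
#' @param ann a `gene_annotation`.
#' @return an object of class `splice_graph`: a named list of per-gene
#'   graphs, each with `gene_id`, `chrom`, `strand`, `span`, `exons`
#'   (data.frame start/end), `junctions` (data.frame left/right),
#'   `first_keys`, `last_keys` (exon interval keys), `internal_keys`.
#' @export
build_splice_graph <- function(ann) {
  ex <- ann$exons
  df <- data.frame(chrom = as.character(seqnames(ex)), start = start(ex),
                   end = end(ex), strand = as.character(strand(ex)),
                   gene_id = mcols(ex)$gene_id,
                   transcript_id = mcols(ex)$transcript_id,
                   stringsAsFactors = FALSE)
  graphs <- lapply(split(df, df$gene_id), function(gd) {
    strand <- gd$strand[1]
    U <- unique(gd[, c("start", "end")])
    U <- U[order(U$start, U$end), , drop = FALSE]
    rownames(U) <- NULL
    aj <- list()
    first_keys <- last_keys <- character(0)
    for (td in split(gd, gd$transcript_id)) {
      td <- td[order(td$start), , drop = FALSE]
      ne <- nrow(td)
      if (ne > 1) {
        aj[[length(aj) + 1L]] <- data.frame(left = td$end[-ne],
                                            right = td$start[-1])
      }
      ## transcription-first is the left-most exon on '+', right-most on '-'
      fi <- if (strand == "-") ne else 1L
      li <- if (strand == "-") 1L else ne
      first_keys <- c(first_keys, exon_key(td$start[fi], td$end[fi]))
      last_keys <- c(last_keys, exon_key(td$start[li], td$end[li]))
    }
    junctions <- if (length(aj)) unique(do.call(rbind, aj)) else
      data.frame(left = integer(0), right = integer(0))
    junctions <- junctions[order(junctions$left, junctions$right), , drop = FALSE]
    rownames(junctions) <- NULL
    all_keys <- exon_key(U$start, U$end)
    list(gene_id = gd$gene_id[1], chrom = gd$chrom[1], strand = strand,
         span = c(min(gd$start), max(gd$end)),
         exons = U, junctions = junctions,
         first_keys = unique(first_keys), last_keys = unique(last_keys),
         internal_keys = setdiff(all_keys, union(first_keys, last_keys)))
  })
  class(graphs) <- "splice_graph"
  graphs
}

exon_key <- function(start, end) paste(start, end, sep = "-")
junc_key <- function(left, right) paste(left, right, sep = ">")

#' @export
print.splice_graph <- function(x, ...) {
  nj <- sum(vapply(x, function(g) nrow(g$junctions), numeric(1)))
  cat("splice_graph:", length(x), "genes,", nj, "annotated junctions\n")
  invisible(x)
}
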