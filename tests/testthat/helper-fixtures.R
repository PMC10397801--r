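# Shared fixture builders: everything is constructed in code at test time.

SEQLEN <- c(chrT = 100000L)

# alignment_set from explicit records
aln <- function(pos, cigar, strand = "+", chrom = "chrT", role = "IP",
                seqlengths = SEQLEN) {
  n <- length(pos)
  ga <- riptide:::make_galignments(rep(chrom, n), pos,
                                   rep(strand, length.out = n),
                                   seqlengths, cigar = rep(cigar, length.out = n))
  alignment_set(ga, role = role)
}

# annotation from a compact exon spec: list(gene_id = list(strand=, tx=list(tid=matrix)))
# each transcript is a 2-column matrix of exon start/end
tiny_annotation <- function(spec, chrom = "chrT", seqlengths = SEQLEN,
                            biotype = NULL) {
  rows <- list()
  for (gid in names(spec)) {
    g <- spec[[gid]]
    for (tid in names(g$tx)) {
      m <- g$tx[[tid]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = m[, 1], end = m[, 2], strand = g$strand,
        gene_id = gid, transcript_id = paste0(gid, ".", tid),
        stringsAsFactors = FALSE)
    }
  }
  riptide:::build_annotation_from_exons(do.call(rbind, rows),
                                        biotype = biotype,
                                        seqlengths = seqlengths)
}

# three-exon plus-strand gene used across tests:
# exons 101-200, 301-400, 501-600
gene3 <- function(strand = "+", gid = "gA") {
  spec <- list(list(strand = strand,
                    tx = list(t1 = cbind(c(101, 301, 501), c(200, 400, 600)))))
  names(spec) <- gid
  tiny_annotation(spec)
}

# junction table row constructor
jtab <- function(left, right, strand = "+", chrom = "chrT", ...) {
  counts <- list(...)
  if (!length(counts)) counts <- list(s1 = rep(5L, length(left)))
  df <- data.frame(chrom = chrom, left = left, right = right, strand = strand,
                   stringsAsFactors = FALSE)
  for (nm in names(counts)) df[[nm]] <- counts[[nm]]
  df
}

jset_df <- function(l, r) data.frame(left = l, right = r)

event_key <- function(e) {
  paste(e$gene, e$type, e$alt_region[1], e$alt_region[2],
        paste(sort(paste(e$inclusion$left, e$inclusion$right)), collapse = "|"),
        paste(sort(paste(e$exclusion$left, e$exclusion$right)), collapse = "|"))
}

narrow_safely <- function(gr, by) {
  gr <- gr[width(gr) > 2 * by + 1]
  narrow(gr, start = by + 1, end = -(by + 1))
}
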