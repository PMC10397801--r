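#' Simulate an iRIP-seq library pair with injected binding peaks
#'
#' Generates an IP library and an input library over the transcribed
#' (exon-union) space of a synthetic annotation. Input read starts are
#' uniform over transcribed positions. IP reads are the superposition of a
#' uniform background and, inside each injected peak interval, extra reads
#' confined to the peak such that the expected per-base depth inside a peak
#' is `peak_enrichment` times the background depth. With
#' `peak_enrichment = 1` the IP and input libraries follow the same
#' generative law (a null pair). Read counts match the configuration
#' exactly; read strand equals the host gene's strand.
#'
#' @param ann a `gene_annotation` from [make_annotation()].
#' @param config a [sim_config()] object.
#' @return a list with elements `ip` and `input` (each an `alignment_set`)
#'   and `truth`, a list whose `peaks` element is a GRanges of the injected
#'   intervals (with `gene_id`).
#' @export
simulate_rip <- function(ann, config) {
  validate_sim_config(config)
  set.seed(offset_seed(config$seed, 1L))
  rl <- config$read_length
  jit <- config$length_jitter
  rl_max <- rl + jit
  E <- config$peak_enrichment

  ex <- exon_space(ann, rl_max)
  S <- sum(ex$n_starts)
  if (S <= 0) stop("no exon provides room for reads of length ", rl)

  ## choose peak intervals inside sufficiently long exons
  margin <- 5L
  eligible <- which(ex$len >= config$peak_width + 2L * margin)
  if (length(eligible) < config$n_peaks) {
    stop("not enough exons of length >= ", config$peak_width + 2L * margin,
         " to place ", config$n_peaks, " peaks")
  }
  host <- sort(sample(eligible, config$n_peaks))
  ps <- ex$start[host] + margin +
    floor(runif(config$n_peaks) * (ex$len[host] - config$peak_width - 2L * margin + 1L))
  truth <- GRanges(ex$chrom[host], IRanges(ps, ps + config$peak_width - 1L),
                   strand = ex$strand[host], gene_id = ex$gene_id[host],
                   seqlengths = ann$seqlengths)

  ## split the IP library into uniform background + per-peak extra reads so
  ## that E[depth inside peak] = E * E[background depth]
  w <- config$peak_width
  n_bg0 <- config$n_ip_reads / (1 + (E - 1) * config$n_peaks * w / S)
  m <- if (config$n_peaks) round((E - 1) * (n_bg0 / S) * rep(w, config$n_peaks)) else integer(0)
  n_bg <- config$n_ip_reads - sum(m)
  if (n_bg <= 0) stop("peak mass exceeds the IP library; lower peak_enrichment or n_peaks")

  frag_len <- function(n) {
    if (jit == 0) rep(rl, n) else rl + sample(seq(-jit, jit), n, replace = TRUE)
  }
  bg_starts <- sample_exon_starts(ex, n_bg)
  bg_len <- frag_len(n_bg)
  peak_starts <- peak_chroms <- peak_strands <- peak_len <- NULL
  if (config$n_peaks && sum(m)) {
    idx <- rep(seq_len(config$n_peaks), m)
    peak_len <- frag_len(sum(m))
    peak_starts <- ps[idx] + floor(runif(sum(m)) * (w - peak_len + 1L))
    peak_chroms <- ex$chrom[host][idx]
    peak_strands <- ex$strand[host][idx]
  }

  ip_chrom <- c(bg_starts$chrom, peak_chroms)
  ip_pos <- c(bg_starts$pos, peak_starts)
  ip_strand <- c(bg_starts$strand, peak_strands)
  ip_len <- c(bg_len, peak_len)
  ord <- order(ip_chrom, ip_pos)
  ip <- alignment_set(
    make_galignments(ip_chrom[ord], ip_pos[ord], ip_strand[ord],
                     ann$seqlengths, width = ip_len[ord]),
    role = "IP")

  ins <- sample_exon_starts(ex, config$n_input_reads)
  in_len <- frag_len(config$n_input_reads)
  ord <- order(ins$chrom, ins$pos)
  input <- alignment_set(
    make_galignments(ins$chrom[ord], ins$pos[ord], ins$strand[ord],
                     ann$seqlengths, width = in_len[ord]),
    role = "input")

  list(ip = ip, input = input,
       truth = list(peaks = truth,
                    n_background_reads = n_bg,
                    n_peak_reads = sum(m)))
}

## Flat table of per-gene exon-union intervals with read-start capacity.
exon_space <- function(ann, read_length) {
  grl <- exon_union(ann)
  gr <- unlist(grl, use.names = FALSE)
  gene_id <- rep(names(grl), lengths(grl))
  len <- width(gr)
  keep <- len >= read_length
  gr <- gr[keep]
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), strand = as.character(strand(gr)),
             gene_id = gene_id[keep], len = len[keep],
             n_starts = len[keep] - read_length + 1L,
             stringsAsFactors = FALSE)
}

## Uniform read starts over the exon start space (weights = capacity).
sample_exon_starts <- function(ex, n) {
  if (n == 0) return(list(chrom = character(0), pos = integer(0), strand = character(0)))
  i <- sample.int(nrow(ex), n, replace = TRUE, prob = ex$n_starts)
  pos <- ex$start[i] + floor(runif(n) * ex$n_starts[i])
  list(chrom = ex$chrom[i], pos = as.integer(pos), strand = ex$strand[i])
}

offset_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
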