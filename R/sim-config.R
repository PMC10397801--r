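#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [make_annotation()], [simulate_rip()] and [simulate_rnaseq()]. Defaults
#' describe a desk-scale benchmark genome: 1 Mb, 20 multi-exon genes whose
#' exons are comparable in size to a protein binding footprint, a 50 nt RIP
#' fragment length (nuclease-digested RIP fragments are short), 50k reads per
#' RIP library, and a 3 vs 3 RNA-seq design with negative-binomial gene
#' counts.
#'
#' @param genome_length total genome size in bases.
#' @param n_chromosomes number of chromosomes; genes are distributed evenly.
#' @param n_genes number of non-overlapping genes.
#' @param exon_length_range,intron_length_range,exons_per_gene_range
#'   integer ranges (min, max) sampled uniformly per exon/intron/gene.
#' @param read_length nominal read/fragment length in bases.
#' @param length_jitter half-range of the uniform fragment-length variation
#'   of the RIP libraries (lengths are `read_length` +/- `length_jitter`),
#'   emulating nuclease digestion; defaults to `read_length %/% 5`.
#' @param n_ip_reads,n_input_reads exact read counts of the IP and input
#'   RIP libraries.
#' @param n_rnaseq_reads_per_sample expected total gene-body reads per
#'   RNA-seq sample; realised totals are negative-binomial sums.
#' @param n_peaks number of binding peaks injected into the IP library.
#' @param peak_width width of each injected peak in bases.
#' @param peak_enrichment fold increase of IP read density inside peaks
#'   relative to the uniform transcribed background; must be >= 1 (1 = null).
#' @param event_spec data.frame with columns `type` (one of the nine event
#'   types, see [classify_events()]), `ratio_nc`, `ratio_oe` (true inclusion
#'   ratios per condition, in \[0,1\]). One gene is used per event.
#' @param de_spec data.frame with columns `gene` (index or id) and
#'   `fold_change` (> 0) of planted expression changes (OE relative to NC).
#' @param junction_read_depth sequencing depth at each junction locus of a
#'   planted event; junction counts are Binomial(depth, isoform fraction).
#' @param dispersion negative-binomial dispersion shared across genes
#'   (variance = mu + dispersion * mu^2).
#' @param coding_fraction fraction of genes flagged protein-coding (the rest
#'   are noncoding; used by peak feature annotation).
#' @param seed integer seed; identical configurations give identical output.
#'
#' @return a validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 4, genome_length = 2e5, n_peaks = 4)
#' ann <- make_annotation(cfg)
sim_config <- function(genome_length = 1e6,
                       n_chromosomes = 1,
                       n_genes = 20,
                       exon_length_range = c(210L, 270L),
                       intron_length_range = c(200L, 400L),
                       exons_per_gene_range = c(45L, 60L),
                       read_length = 50,
                       length_jitter = NULL,
                       n_ip_reads = 50000,
                       n_input_reads = 50000,
                       n_rnaseq_reads_per_sample = 20000,
                       n_peaks = 30,
                       peak_width = 200,
                       peak_enrichment = 8,
                       event_spec = default_event_spec(),
                       de_spec = NULL,
                       junction_read_depth = 200,
                       dispersion = 0.1,
                       coding_fraction = 0.8,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.numeric(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    n_genes = as.integer(n_genes),
    exon_length_range = as.integer(exon_length_range),
    intron_length_range = as.integer(intron_length_range),
    exons_per_gene_range = as.integer(exons_per_gene_range),
    read_length = as.integer(read_length),
    length_jitter = as.integer(if (is.null(length_jitter)) read_length %/% 5 else length_jitter),
    n_ip_reads = as.integer(n_ip_reads),
    n_input_reads = as.integer(n_input_reads),
    n_rnaseq_reads_per_sample = as.integer(n_rnaseq_reads_per_sample),
    n_peaks = as.integer(n_peaks),
    peak_width = as.integer(peak_width),
    peak_enrichment = as.numeric(peak_enrichment),
    event_spec = event_spec,
    de_spec = de_spec,
    junction_read_depth = as.integer(junction_read_depth),
    dispersion = as.numeric(dispersion),
    coding_fraction = as.numeric(coding_fraction),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_event_spec <- function() {
  data.frame(
    type = ase_types(),
    ratio_nc = 0.3,
    ratio_oe = 0.7,
    stringsAsFactors = FALSE
  )
}

#' The nine recognised alternative splicing event types
#'
#' @return character vector of event type labels.
#' @export
ase_types <- function() {
  c("ES", "cassette", "A5SS", "A3SS", "MXE", "5pMXE", "3pMXE",
    "A3SS&ES", "A5SS&ES")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$genome_length > 0, cfg$n_chromosomes >= 1, cfg$n_genes >= 1,
    length(cfg$exon_length_range) == 2,
    cfg$exon_length_range[1] <= cfg$exon_length_range[2],
    cfg$exon_length_range[1] > 0,
    length(cfg$intron_length_range) == 2,
    cfg$intron_length_range[1] <= cfg$intron_length_range[2],
    cfg$intron_length_range[1] > 0,
    cfg$exons_per_gene_range[1] >= 1,
    cfg$exons_per_gene_range[1] <= cfg$exons_per_gene_range[2],
    cfg$read_length > 0,
    cfg$n_ip_reads > 0, cfg$n_input_reads > 0,
    cfg$n_rnaseq_reads_per_sample > 0,
    cfg$n_peaks >= 0, cfg$peak_width > 0,
    cfg$junction_read_depth > 0,
    cfg$dispersion >= 0,
    cfg$coding_fraction >= 0, cfg$coding_fraction <= 1
  )
  if (cfg$peak_enrichment < 1) {
    stop("peak_enrichment must be >= 1 (1 gives a null IP library)")
  }
  if (cfg$length_jitter < 0 || cfg$length_jitter >= cfg$read_length) {
    stop("length_jitter must be in [0, read_length)")
  }
  if (cfg$read_length + cfg$length_jitter > cfg$peak_width) {
    stop("read_length + length_jitter must not exceed peak_width")
  }
  es <- cfg$event_spec
  if (!is.null(es) && nrow(es)) {
    stopifnot(all(c("type", "ratio_nc", "ratio_oe") %in% names(es)))
    bad <- setdiff(es$type, ase_types())
    if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "))
    if (any(es$ratio_nc < 0 | es$ratio_nc > 1 | es$ratio_oe < 0 | es$ratio_oe > 1)) {
      stop("inclusion ratios must lie in [0, 1]")
    }
  }
  ds <- cfg$de_spec
  if (!is.null(ds) && nrow(ds)) {
    stopifnot(all(c("gene", "fold_change") %in% names(ds)))
    if (any(ds$fold_change <= 0)) stop("fold changes must be positive")
  }
  invisible(cfg)
}
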