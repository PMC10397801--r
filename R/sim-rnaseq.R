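#' Simulate a replicated RNA-seq comparison with planted effects
#'
#' Produces spliced single-end alignments for a 3 vs 3 design (conditions
#' `NC` and `OE`). Per gene and sample, body-read totals are drawn from a
#' negative binomial with shared dispersion; planted fold changes scale the
#' OE means. For each planted splicing event (see [make_annotation()]),
#' every inclusion junction receives `Binomial(junction_read_depth, ratio)`
#' spliced reads and every exclusion junction
#' `Binomial(junction_read_depth, 1 - ratio)`, where `ratio` is the
#' condition's true inclusion ratio — i.e. each junction locus is sequenced
#' at the configured depth and the isoform fraction decides how the reads
#' split.
#'
#' @param ann a `gene_annotation` carrying event templates.
#' @param config a [sim_config()] object.
#' @param n_rep replicates per condition.
#' @return list with `samples` (list of `alignment_set`, one per sample),
#'   `design` (data.frame sample/condition) and `truth` (event and DE truth
#'   plus the realised per-gene count matrix).
#' @export
simulate_rnaseq <- function(ann, config, n_rep = 3L) {
  validate_sim_config(config)
  set.seed(offset_seed(config$seed, 2L))
  rl <- config$read_length
  gene_ids <- mcols(ann$genes)$gene_id
  n_genes <- length(gene_ids)
  samples <- c(paste0("NC_", seq_len(n_rep)), paste0("OE_", seq_len(n_rep)))
  condition <- rep(c("NC", "OE"), each = n_rep)

  mu <- rep(config$n_rnaseq_reads_per_sample / n_genes, n_genes)
  fc <- rep(1, n_genes)
  if (!is.null(config$de_spec) && nrow(config$de_spec)) {
    gi <- config$de_spec$gene
    idx <- if (is.numeric(gi)) as.integer(gi) else match(as.character(gi), gene_ids)
    if (any(is.na(idx)) || any(idx < 1 | idx > n_genes)) {
      stop("de_spec references unknown genes")
    }
    fc[idx] <- config$de_spec$fold_change
  }

  counts <- matrix(0L, n_genes, length(samples),
                   dimnames = list(gene_ids, samples))
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  for (j in seq_along(samples)) {
    m <- if (condition[j] == "OE") mu * fc else mu
    counts[, j] <- draw_nb(n_genes, m, size)
  }

  ex <- exon_space(ann, rl)
  sets <- vector("list", length(samples))
  names(sets) <- samples
  templates <- ann$event_templates
  for (j in seq_along(samples)) {
    ## gene body reads
    chroms <- character(0); pos <- integer(0); strd <- character(0); cig <- character(0)
    for (g in seq_len(n_genes)) {
      ng <- counts[g, j]
      if (ng == 0) next
      exg <- ex[ex$gene_id == gene_ids[g], , drop = FALSE]
      if (!nrow(exg)) next
      s <- sample_exon_starts(exg, ng)
      chroms <- c(chroms, s$chrom); pos <- c(pos, s$pos); strd <- c(strd, s$strand)
      cig <- c(cig, rep(sprintf("%dM", rl), ng))
    }
    ## junction reads for planted events
    for (tpl in templates) {
      ratio <- if (condition[j] == "OE") tpl$ratio_oe else tpl$ratio_nc
      for (side in c("inclusion", "exclusion")) {
        p <- if (side == "inclusion") ratio else 1 - ratio
        js <- tpl[[side]]
        for (q in seq_len(nrow(js))) {
          cnt <- rbinom(1, config$junction_read_depth, p)
          if (cnt == 0) next
          o <- 5L + floor(runif(cnt) * (rl - 9L))   # upstream anchor 5..rl-5
          gap <- js$right[q] - js$left[q] - 1L
          chroms <- c(chroms, rep(tpl$chrom, cnt))
          pos <- c(pos, as.integer(js$left[q] - o + 1L))
          strd <- c(strd, rep(tpl$strand, cnt))
          cig <- c(cig, sprintf("%dM%dN%dM", o, gap, rl - o))
        }
      }
    }
    ord <- order(chroms, pos)
    sets[[j]] <- alignment_set(
      make_galignments(chroms[ord], pos[ord], strd[ord], ann$seqlengths,
                       cigar = cig[ord]),
      role = samples[j])
  }

  event_truth <- if (length(templates)) {
    data.frame(event_id = vapply(templates, `[[`, character(1), "event_id"),
               gene_id = vapply(templates, `[[`, character(1), "gene_id"),
               type = vapply(templates, `[[`, character(1), "type"),
               ratio_nc = vapply(templates, `[[`, numeric(1), "ratio_nc"),
               ratio_oe = vapply(templates, `[[`, numeric(1), "ratio_oe"),
               stringsAsFactors = FALSE)
  } else data.frame()
  de_truth <- data.frame(gene_id = gene_ids, fold_change = fc,
                         direction = ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none")),
                         stringsAsFactors = FALSE)

  list(samples = sets,
       design = data.frame(sample = samples, condition = condition,
                           stringsAsFactors = FALSE),
       truth = list(events = event_truth, de = de_truth, counts = counts))
}

draw_nb <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = size)
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Count-level generator shared with [simulate_rnaseq()]; used to benchmark
#' the differential-expression screen without building alignments.
#' Differentially expressed genes are split evenly between up- (times
#' `fold_change`) and down-regulation (divided by `fold_change`) in the
#' second condition.
#'
#' @param n_genes number of genes.
#' @param mean_count baseline expected count per gene.
#' @param de_fraction fraction of genes with a planted fold change.
#' @param fold_change planted fold change (> 1).
#' @param dispersion shared NB dispersion.
#' @param n_rep replicates per condition.
#' @param seed integer seed.
#' @return list with `counts` (matrix with NC_/OE_ columns), `lengths`
#'   (constant 1 kb gene lengths) and `truth` (gene, fold_change, is_de).
#' @export
simulate_gene_counts <- function(n_genes = 1000, mean_count = 100,
                                 de_fraction = 0.1, fold_change = 4,
                                 dispersion = 0.1, n_rep = 3L, seed = 1L) {
  stopifnot(fold_change > 1, de_fraction >= 0, de_fraction <= 1)
  set.seed(offset_seed(seed, 3L))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  n_de <- round(de_fraction * n_genes)
  de_idx <- sample.int(n_genes, n_de)
  fc <- rep(1, n_genes)
  if (n_de) {
    up <- de_idx[seq_len(ceiling(n_de / 2))]
    down <- setdiff(de_idx, up)
    fc[up] <- fold_change
    fc[down] <- 1 / fold_change
  }
  samples <- c(paste0("NC_", seq_len(n_rep)), paste0("OE_", seq_len(n_rep)))
  size <- if (dispersion > 0) 1 / dispersion else Inf
  counts <- matrix(0L, n_genes, 2 * n_rep, dimnames = list(gene_ids, samples))
  for (j in seq_len(2 * n_rep)) {
    m <- if (j > n_rep) mean_count * fc else rep(mean_count, n_genes)
    counts[, j] <- draw_nb(n_genes, m, size)
  }
  list(counts = counts,
       lengths = setNames(rep(1000, n_genes), gene_ids),
       truth = data.frame(gene_id = gene_ids, fold_change = fc,
                          is_de = fc != 1,
                          direction = ifelse(fc > 1, "up",
                                             ifelse(fc < 1, "down", "none")),
                          stringsAsFactors = FALSE))
}

#' Simulate junction counts for splicing events
#'
#' Count-level generator shared with [simulate_rnaseq()]: builds abstract
#' splice events of the requested types on a synthetic coordinate frame and
#' draws per-junction counts as `Binomial(depth, fraction)` per replicate,
#' with the inclusion fraction set per condition. Used to benchmark
#' [quantify_ratios()] and [test_rase()].
#'
#' @param types character vector (recycled) of event types; determines the
#'   number of inclusion/exclusion junctions (ES/cassette 2/1, MXE 2/2,
#'   others 1/1).
#' @param ratio_nc,ratio_oe true inclusion ratios (recycled over events).
#' @param n_events number of events.
#' @param depth junction-locus sequencing depth.
#' @param n_rep replicates per condition.
#' @param seed integer seed.
#' @return list with `events` (a `splice_events` list), `junctions`
#'   (junction table with one count column per sample), `design` and `truth`.
#' @export
simulate_junction_counts <- function(n_events, types = "ES",
                                     ratio_nc = 0.5, ratio_oe = ratio_nc,
                                     depth = 200, n_rep = 3L, seed = 1L) {
  set.seed(offset_seed(seed, 4L))
  types <- rep_len(types, n_events)
  ratio_nc <- rep_len(ratio_nc, n_events)
  ratio_oe <- rep_len(ratio_oe, n_events)
  samples <- c(paste0("NC_", seq_len(n_rep)), paste0("OE_", seq_len(n_rep)))
  condition <- rep(c("NC", "OE"), each = n_rep)

  events <- vector("list", n_events)
  jrows <- list()
  block <- 10000L
  for (i in seq_len(n_events)) {
    ninc <- if (types[i] %in% c("ES", "cassette", "MXE")) 2L else 1L
    nexc <- if (types[i] == "MXE") 2L else 1L
    base <- (i - 1L) * block
    inc <- data.frame(left = base + 100L * seq_len(ninc),
                      right = base + 100L * seq_len(ninc) + 50L)
    exc <- data.frame(left = base + 5000L + 100L * seq_len(nexc),
                      right = base + 5000L + 100L * seq_len(nexc) + 50L)
    events[[i]] <- list(event_id = sprintf("ev%05d", i),
                        gene = sprintf("g%05d", i), chrom = "chrSim",
                        strand = "+", type = types[i],
                        inclusion = inc, exclusion = exc,
                        alt_region = c(base + 1L, base + 6000L))
    for (side in c("inclusion", "exclusion")) {
      js <- events[[i]][[side]]
      for (q in seq_len(nrow(js))) {
        p <- if (side == "inclusion") c(ratio_nc[i], ratio_oe[i]) else
          1 - c(ratio_nc[i], ratio_oe[i])
        cnt <- rbinom(2 * n_rep, depth, p[ifelse(condition == "OE", 2, 1)])
        jrows[[length(jrows) + 1L]] <- c(list(chrom = "chrSim", left = js$left[q],
                                              right = js$right[q], strand = "+"),
                                         as.list(setNames(cnt, samples)))
      }
    }
  }
  junctions <- do.call(rbind, lapply(jrows, function(r) as.data.frame(r)))
  class(events) <- "splice_events"
  list(events = events, junctions = junctions,
       design = data.frame(sample = samples, condition = condition,
                           stringsAsFactors = FALSE),
       truth = data.frame(event_id = vapply(events, `[[`, character(1), "event_id"),
                          type = types, ratio_nc = ratio_nc, ratio_oe = ratio_oe,
                          stringsAsFactors = FALSE))
}
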