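small_cfg <- function(...) {
  sim_config(n_genes = 10, genome_length = 5e5, n_peaks = 6,
             exons_per_gene_range = c(10, 12), seed = 11, ...)
}

test_that("annotation layout respects the configuration", {
  cfg <- small_cfg()
  ann <- make_annotation(cfg)
  expect_length(ann$genes, 10)
  expect_length(ann$event_templates, nrow(cfg$event_spec))
  # pairwise non-overlap per strand
  for (s in c("+", "-")) {
    g <- ann$genes[strand(ann$genes) == s]
    expect_true(all(countOverlaps(g, g) == 1))
  }
  # every planted event template references a real gene and stays inside it
  for (tpl in ann$event_templates) {
    gene <- ann$genes[tpl$gene_id]
    expect_true(all(tpl$inclusion$left >= start(gene) &
                      tpl$inclusion$right <= end(gene)))
    expect_true(all(tpl$exclusion$left >= start(gene) &
                      tpl$exclusion$right <= end(gene)))
  }
})

test_that("a one-gene three-exon annotation has two annotated junctions", {
  cfg <- sim_config(n_genes = 1, genome_length = 5e4, n_peaks = 0,
                    exons_per_gene_range = c(3, 3), event_spec = NULL,
                    n_ip_reads = 100, n_input_reads = 100, seed = 2)
  ann <- make_annotation(cfg)
  expect_length(ann$genes, 1)
  expect_length(ann$exons, 3)
  graph <- build_splice_graph(ann)
  expect_equal(nrow(graph[[1]]$junctions), 2)
})

test_that("identical configurations give byte-identical GTF output", {
  cfg <- small_cfg()
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  write_gtf(make_annotation(cfg), f1)
  write_gtf(make_annotation(small_cfg()), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an oversubscribed genome is rejected with a sizing error", {
  cfg <- small_cfg()
  cfg$genome_length <- 2e4
  expect_error(make_annotation(cfg), "too small")
})

test_that("RIP simulation conserves read counts and is deterministic", {
  cfg <- small_cfg(n_ip_reads = 20000, n_input_reads = 15000)
  ann <- make_annotation(cfg)
  rip <- simulate_rip(ann, cfg)
  expect_equal(library_size(rip$ip), 20000)
  expect_equal(library_size(rip$input), 15000)
  rip2 <- simulate_rip(ann, cfg)
  expect_identical(start(rip$ip$ga), start(rip2$ip$ga))
  expect_identical(cigar(rip$input$ga), cigar(rip2$input$ga))
})

test_that("enrichment below one is rejected; enrichment one gives a null pair", {
  expect_error(small_cfg(peak_enrichment = 0.5), "peak_enrichment")
  cfg <- small_cfg(peak_enrichment = 1)
  rip <- simulate_rip(make_annotation(cfg), cfg)
  expect_equal(rip$truth$n_peak_reads, 0)
  expect_equal(rip$truth$n_background_reads, library_size(rip$ip))
})

test_that("mean depth inside truth peaks is about peak_enrichment times background", {
  cfg <- small_cfg(peak_enrichment = 8)
  ann <- make_annotation(cfg)
  rip <- simulate_rip(ann, cfg)
  cov <- compute_coverage(rip$ip)
  truth <- rip$truth$peaks
  rl_max <- cfg$read_length + cfg$length_jitter
  eu <- unlist(riptide:::exon_union(ann), use.names = FALSE)
  # background measured on exon-interior plateau bases away from peaks
  plateau <- setdiff(narrow_safely(eu, rl_max),
                     resize(truth, width(truth) + 2 * rl_max, fix = "center"))
  mean_depth <- function(gr) {
    tot <- 0; n <- 0
    for (i in seq_along(gr)) {
      r <- riptide:::strand_cov(cov, as.character(strand(gr[i])))[[
        as.character(seqnames(gr[i]))]]
      tot <- tot + sum(as.numeric(r[start(gr[i]):end(gr[i])]))
      n <- n + width(gr[i])
    }
    tot / n
  }
  ratio <- mean_depth(truth) / mean_depth(plateau)
  # whole-peak mean = background-in-peak (slightly below plateau because of
  # exon-edge coverage ramps) + (E-1) x plateau; see the methods vignette
  expect_gt(ratio, cfg$peak_enrichment - 0.7)
  expect_lt(ratio, cfg$peak_enrichment + 0.4)
})

test_that("RNA-seq body/junction read budgets add up and truth passes through", {
  es <- data.frame(type = "ES", ratio_nc = 0.2, ratio_oe = 0.8)
  cfg <- small_cfg(event_spec = es, n_rnaseq_reads_per_sample = 5000)
  ann <- make_annotation(cfg)
  rna <- simulate_rnaseq(ann, cfg)
  expect_equal(nrow(rna$design), 6)
  expect_identical(rna$truth$events$ratio_nc, 0.2)
  expect_identical(rna$truth$events$ratio_oe, 0.8)
  for (s in rna$design$sample) {
    ga <- rna$samples[[s]]$ga
    body <- sum(njunc(ga) == 0)
    expect_equal(body, sum(rna$truth$counts[, s]))
    expect_equal(length(ga) - body, sum(njunc(ga) > 0))
  }
})

test_that("junction count draws recover the configured inclusion fraction", {
  sim <- simulate_junction_counts(100, types = "ES", ratio_nc = 0.5,
                                  depth = 200, seed = 42)
  ratios <- quantify_ratios(sim$events, sim$junctions, "NC_1")
  expect_true(mean(abs(ratios[, 1] - 0.5) <= 0.10) >= 0.95)
})
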