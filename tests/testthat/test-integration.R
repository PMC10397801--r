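test_that("gene-set overlaps are exact set operations", {
  o <- overlap_genes(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(o$shared, c("B", "C"))
  expect_equal(c(o$only_a, o$only_b), c(1, 1))
  expect_equal(o$n_shared + o$only_a + o$only_b,
               length(union(c("A", "B", "C"), c("B", "C", "D"))))
  expect_equal(overlap_genes(c("A"), c("B"))$n_shared, 0)
  sub <- overlap_genes(c("A", "B"), c("A", "B", "C"))
  expect_equal(sub$shared, c("A", "B"))
})

# exhaustive enumeration oracle: upper-tail hypergeometric by counting draws
enum_hyper <- function(N, K, n, k) {
  hits <- utils::combn(N, n, function(draw) sum(draw <= K) >= k)
  mean(hits)
}

test_that("hypergeometric p-values match exhaustive enumeration", {
  sets <- list(term = paste0("g", 1:5))
  uni <- paste0("g", 1:10)
  res <- hypergeom_enrich(paste0("g", c(1, 2, 3, 4)), sets, uni)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p_value, enum_hyper(10, 5, 4, 4), tolerance = 1e-12)
  # no overlap -> p = 1; term == universe -> k == n forced, p = 1
  res0 <- hypergeom_enrich(paste0("g", 6:9), sets, uni)
  expect_equal(res0$k, 0)
  expect_equal(res0$p_value, 1)
  resU <- hypergeom_enrich(paste0("g", 1:4), list(all = uni), uni)
  expect_equal(resU$p_value, 1)
  # random small universes against the enumerator
  set.seed(99)
  for (i in 1:20) {
    N <- sample(6:12, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    uni <- paste0("g", seq_len(N))
    q <- sample(uni, n)
    r <- hypergeom_enrich(q, list(t = paste0("g", seq_len(K))), uni)
    expect_equal(r$p_value, enum_hyper(N, K, n, r$k), tolerance = 1e-12)
  }
  expect_error(hypergeom_enrich("g1", sets, character(0)), "universe")
  expect_error(hypergeom_enrich("zz", sets, uni), "absent")
})

test_that("BH adjustment reproduces the step-up values and its invariants", {
  p <- c(0.01, 0.02, 0.04, 0.50)
  expect_equal(bh_adjust(p), c(0.04, 0.04, 0.04 * 4 / 3, 0.50), tolerance = 1e-12)
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  q <- runif(50)
  expect_true(all(bh_adjust(q) >= q))
  perm <- sample(50)
  expect_equal(bh_adjust(q[perm]), bh_adjust(q)[perm])
})

test_that("gene-set files round-trip in GMT and two-column form", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("termA\tdesc\tg1\tg2\tg3", "termB\tdesc\tg2\tg4"), gmt)
  s1 <- read_gene_sets(gmt)
  expect_equal(s1$termA, c("g1", "g2", "g3"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("termA\tg1", "termA\tg2", "termB\tg4"), tsv)
  s2 <- read_gene_sets(tsv)
  expect_equal(s2$termA, c("g1", "g2"))
})

pipe_cfg <- function(seed = 5) {
  sim_config(seed = seed, n_genes = 12, genome_length = 6e5, n_peaks = 6,
             exons_per_gene_range = c(12, 15),
             n_ip_reads = 30000, n_input_reads = 30000,
             n_rnaseq_reads_per_sample = 12000,
             de_spec = data.frame(gene = 10:12, fold_change = c(4, 4, 0.25)))
}

test_that("the pipeline runs end to end and is reproducible", {
  d1 <- file.path(tempdir(), "pipe_a")
  d2 <- file.path(tempdir(), "pipe_b")
  cfg <- list(synthetic = pipe_cfg(), seed = 5)
  pars <- peak_call_params(n_perm = 50, seed = 5)
  r1 <- run_pipeline(cfg, d1, pars)
  r2 <- run_pipeline(cfg, d2, pars)
  for (f in c("peaks.bed", "deg.tsv", "rase.tsv", "events.tsv",
              "counts.tsv", "overlaps.tsv", "summary.json")) {
    expect_true(file.exists(file.path(d1, f)), label = f)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # truth-aware recovery metrics are attached for synthetic runs
  expect_true(r1$summary$peak_recall >= 0.8)
  expect_true(r1$summary$deg_recall >= 2 / 3)
  expect_gt(r1$summary$n_rase, 0)
  # without a gene-set file the enrichment stage is skipped with a notice
  expect_false(file.exists(file.path(d1, "enrichment.tsv")))
  expect_true(any(grepl("enrichment stage skipped", readLines(file.path(d1, "run.log")))))
})

test_that("the pipeline runs the enrichment stage when gene sets are given", {
  d <- file.path(tempdir(), "pipe_gs")
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c(paste(c("termA", "d", sprintf("gene%03d", 1:6)), collapse = "\t"),
               paste(c("termB", "d", sprintf("gene%03d", 7:12)), collapse = "\t")),
             gmt)
  cfg <- list(synthetic = pipe_cfg(), seed = 5, gene_sets = gmt)
  r <- run_pipeline(cfg, d, peak_call_params(n_perm = 50, seed = 5))
  expect_true(file.exists(file.path(d, "enrichment.tsv")))
  expect_equal(nrow(r$enrichment), 2)
  expect_true(all(r$enrichment$fdr >= r$enrichment$p_value))
})

test_that("missing input paths fail before any computation", {
  expect_error(run_pipeline(list(gtf = tempfile()), tempdir()), "gtf|required|missing")
})
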