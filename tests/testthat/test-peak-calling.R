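pp <- function(...) peak_call_params(n_perm = 100, seed = 9, ...)

test_that("window scan tiles chromosomes and records means and medians", {
  # constant depth 10 over bases 1-100
  a <- aln(rep(1, 10), "100M")
  scan <- scan_windows(compute_coverage(a), pp())
  e <- scan$entries[["chrT+"]]
  expect_equal(e$n_windows, 20000)            # 100 kb / 5 bp
  expect_equal(e$means[1:20], rep(10, 20))
  expect_equal(e$medians[1:20], rep(10, 20))
  expect_equal(e$means[21], 0)
  # all-zero track
  z <- scan_windows(compute_coverage(aln(integer(0), character(0))), pp())
  expect_true(all(z$entries[["chrT+"]]$means == 0))
  # partial-coverage window arithmetic: depth 7 on bases 4-8 only
  b <- aln(rep(4, 7), "5M")
  sb <- scan_windows(compute_coverage(b), pp())$entries[["chrT+"]]
  expect_equal(sb$means[1], 2 / 5 * 7)        # bases 4,5 of window 1-5
  expect_equal(sb$means[2], 3 / 5 * 7)        # bases 6,7,8 of window 6-10
})

test_that("uniform coverage at background level yields no candidate peaks", {
  a <- aln(rep(1, 10), sprintf("%dM", SEQLEN[["chrT"]]))
  cand <- call_candidate_peaks(scan_windows(compute_coverage(a), pp()), pp())
  expect_length(cand, 0)
  # and an empty track gives an empty result, not an error
  none <- call_candidate_peaks(
    scan_windows(compute_coverage(aln(integer(0), character(0))), pp()), pp())
  expect_length(none, 0)
})

test_that("an isolated plateau is called with the documented boundaries", {
  # depth 60 on 1001-1200, zero elsewhere: one candidate, exactly the plateau
  a <- aln(rep(1001, 60), "200M")
  cand <- call_candidate_peaks(scan_windows(compute_coverage(a), pp()), pp())
  expect_length(cand, 1)
  expect_equal(start(cand), 1001)
  expect_equal(end(cand), 1200)
  expect_equal(cand$max_depth, 60)
})

test_that("the median clause opens candidates when the fold clause cannot", {
  # 40 bp at depth 51 (median 51 > 50) next to a big block that raises the
  # chromosome mean so that 2.5 x background exceeds 51
  a <- aln(c(rep(1001, 51), rep(5001, 1000)),
           c(rep("40M", 51), rep("2500M", 1000)))
  sc <- scan_windows(compute_coverage(a), pp())
  bg <- sc$entries[["chrT+"]]$chrom_mean
  expect_gt(2.5 * bg, 51)                     # fold clause unavailable
  cand <- call_candidate_peaks(sc, pp())
  hit <- subsetByOverlaps(cand, GRanges("chrT", IRanges(1001, 1040), "+"))
  expect_length(hit, 1)
  expect_equal(hit$max_depth, 51)
})

test_that("candidates are merged and never overlap on a strand", {
  cfg <- sim_config(n_genes = 6, genome_length = 3e5, n_peaks = 4,
                    exons_per_gene_range = c(10, 12), event_spec = NULL, seed = 4)
  rip <- simulate_rip(make_annotation(cfg), cfg)
  cand <- call_candidate_peaks(
    scan_windows(compute_coverage(dedup_pcr(rip$ip)), pp()), pp())
  for (s in c("+", "-")) {
    cs <- cand[strand(cand) == s]
    expect_true(all(countOverlaps(cs, cs, maxgap = 0L) == 1))
  }
})

test_that("raising the initiation fold never increases the candidate count", {
  cfg <- sim_config(n_genes = 6, genome_length = 3e5, n_peaks = 4,
                    exons_per_gene_range = c(10, 12), event_spec = NULL, seed = 4)
  rip <- simulate_rip(make_annotation(cfg), cfg)
  scan <- scan_windows(compute_coverage(dedup_pcr(rip$ip)), pp())
  n <- vapply(c(2.5, 4, 8, 20), function(f)
    length(call_candidate_peaks(scan, pp(init_fold = f))), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("permutation p is degenerate-safe, floored, and deterministic", {
  # single-exon gene spanning the whole domain: one read, observed max 1,
  # every redistribution reproduces it -> p = 1
  ann1 <- tiny_annotation(list(gA = list(strand = "+",
                                         tx = list(t1 = cbind(2001, 4000)))))
  one <- aln(2500, "30M")
  pk <- GRanges("chrT", IRanges(2001, 4000), "+", max_depth = 1L)
  got <- permutation_test(pk, one, ann1, pp())
  expect_equal(got$perm_p, 1)
  # 100 reads stacked at one position in an intergenic 10-kb flank domain:
  # re-stacking is essentially impossible -> p at the add-one floor
  far <- tiny_annotation(list(gA = list(strand = "+",
                                        tx = list(t1 = cbind(90001, 92000)))))
  stack <- aln(rep(20001, 100), "30M")
  pk2 <- GRanges("chrT", IRanges(20001, 20030), "+", max_depth = 100L)
  got2 <- permutation_test(pk2, stack, far, pp())
  expect_equal(got2$perm_p, 1 / 101)
  got3 <- permutation_test(pk2, stack, far, pp())
  expect_identical(got2$perm_p, got3$perm_p)
  # the estimator never leaves [1/(n_perm+1), 1]
  expect_true(all(got2$perm_p >= 1 / 101 & got2$perm_p <= 1))
})

test_that("significance filter applies the p-value OR depth-rescue rule", {
  pk <- GRanges("chrT", IRanges(c(1, 101, 201) * 10, width = 50), "+",
                max_depth = c(12L, 3L, 9L),
                perm_p = c(0.2, 0.01, 0.2))
  kept <- filter_significant(pk, pp())
  expect_equal(kept$max_depth, c(12L, 3L))    # rescue clause, then p clause
})

test_that("input filter normalises by library size and is inclusive at the cut", {
  params <- pp()
  peak <- GRanges("chrT", IRanges(1001, 1100), "+", max_depth = 10L)
  lib <- function(n_in_peak, n_total, role) {
    pos <- c(rep(1010, n_in_peak), seq_len(n_total - n_in_peak) + 30000)
    aln(pos, "20M", role = role)
  }
  # IP 40/1000 vs input 1/1000: ratio (40/1000)/((1+1)/1000) = 20 -> kept
  out <- input_enrichment_filter(peak, lib(40, 1000, "IP"), lib(1, 1000, "input"),
                                 params)
  expect_equal(out$input_ratio_obs, 20)
  # IP 8/1000 vs input 2/1000: (8/1000)/((2+1)/1000) = 8/3 -> dropped
  out2 <- input_enrichment_filter(peak, lib(8, 1000, "IP"), lib(2, 1000, "input"),
                                  params)
  expect_length(out2, 0)
  # ratio exactly 4.0 is kept (>= is inclusive): IP 8, input 1 (+1)
  out3 <- input_enrichment_filter(peak, lib(8, 1000, "IP"), lib(1, 1000, "input"),
                                  params)
  expect_equal(out3$input_ratio_obs, 4)
  expect_length(out3, 1)
  # empty libraries are an error
  expect_error(input_enrichment_filter(peak, aln(integer(0), character(0)),
                                       lib(1, 10, "input"), params), "non-empty")
})

test_that("raising the input ratio threshold never increases final peaks", {
  cfg <- sim_config(n_genes = 6, genome_length = 3e5, n_peaks = 4,
                    exons_per_gene_range = c(10, 12), event_spec = NULL, seed = 4)
  ann <- make_annotation(cfg)
  rip <- simulate_rip(ann, cfg)
  res <- call_peaks(rip$ip, rip$input, ann, pp())
  n <- vapply(c(2, 4, 6, 10), function(r)
    length(input_enrichment_filter(res$significant, res$ip, res$input,
                                   pp(input_ratio = r))), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("peak categories follow the documented precedence", {
  ann <- tiny_annotation(
    list(gC = list(strand = "+", tx = list(t1 = cbind(c(101, 501), c(200, 600)))),
         gN = list(strand = "+", tx = list(t1 = cbind(c(1101, 1501), c(1200, 1600))))),
    biotype = c(gC = "protein_coding", gN = "noncoding"))
  pk <- GRanges("chrT",
                IRanges(c(120, 1120, 230, 150, 5001), c(180, 1180, 330, 180, 5100)),
                c("+", "+", "+", "-", "+"))
  got <- annotate_peaks(pk, ann)
  expect_equal(got$category,
               c("CDS", "nc_exon", "intron", "antisense", "intergenic"))
  expect_equal(got$host_genes, c("gC", "gN", "gC", "gC", ""))
  # exon overlap beats intron overlap within the same gene
  both <- annotate_peaks(GRanges("chrT", IRanges(150, 450), "+"), ann)
  expect_equal(both$category, "CDS")
  # and peak genes collect hosts, skipping intergenic peaks
  expect_equal(peaks_to_genes(got), c("gC", "gN"))
  expect_equal(peaks_to_genes(got[5]), character(0))
  summ <- peak_category_summary(got)
  expect_equal(sum(summ$n), 5)
  expect_equal(summ$percent[summ$category == "CDS"], 20)
})
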