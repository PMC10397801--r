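test_that("splice graph collects exons, junctions and end flags", {
  ann <- gene3()
  g <- build_splice_graph(ann)$gA
  expect_equal(nrow(g$exons), 3)
  expect_equal(g$junctions, data.frame(left = c(200, 400), right = c(301, 501)))
  expect_equal(g$first_keys, "101-200")
  expect_equal(g$last_keys, "501-600")
  # two transcripts sharing exons: junction set is the union
  ann2 <- tiny_annotation(list(gA = list(strand = "+", tx = list(
    t1 = cbind(c(101, 301, 501), c(200, 400, 600)),
    t2 = cbind(c(101, 501), c(200, 600))))))
  g2 <- build_splice_graph(ann2)$gA
  expect_equal(nrow(g2$junctions), 3)
  # single-exon transcripts contribute no junctions; empty annotation allowed
  ann3 <- tiny_annotation(list(gA = list(strand = "+", tx = list(t1 = cbind(101, 600)))))
  expect_equal(nrow(build_splice_graph(ann3)$gA$junctions), 0)
})

test_that("an exon-skipping junction is classified with its junction sets", {
  graph <- build_splice_graph(gene3())
  j <- jtab(c(200, 400, 200), c(301, 501, 501), s1 = c(8L, 9L, 5L))
  ev <- classify_events(j, graph)
  expect_length(ev, 1)
  e <- ev[[1]]
  expect_equal(e$type, "ES")
  expect_equal(e$inclusion, jset_df(c(200, 400), c(301, 501)))
  expect_equal(e$exclusion, jset_df(200, 501))
  expect_equal(e$alt_region, c(301, 400))
})

test_that("alternative splice sites map to A3SS/A5SS by strand", {
  # novel acceptor 30 nt inside exon 2, donor annotated: A3SS on '+'
  graph <- build_splice_graph(gene3())
  j <- jtab(c(200, 400, 200), c(301, 501, 331), s1 = c(8L, 9L, 5L))
  ev <- classify_events(j, graph)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$type, "A3SS")
  expect_equal(ev[[1]]$inclusion, jset_df(200, 301))
  expect_equal(ev[[1]]$exclusion, jset_df(200, 331))
  # mirrored on the minus strand the same topology is an A5SS
  gm <- build_splice_graph(gene3(strand = "-"))
  jm <- jtab(c(200, 400, 200), c(301, 501, 331), strand = "-",
             s1 = c(8L, 9L, 5L))
  evm <- classify_events(jm, gm)
  expect_equal(evm[[1]]$type, "A5SS")
})

test_that("purely annotated junction evidence yields no events", {
  graph <- build_splice_graph(gene3())
  expect_length(classify_events(jtab(c(200, 400), c(301, 501)), graph), 0)
})

test_that("novel junctions below the support floor are ignored", {
  graph <- build_splice_graph(gene3())
  j <- jtab(c(200, 400, 200), c(301, 501, 501), s1 = c(8L, 9L, 1L))
  expect_length(classify_events(j, graph), 0)
  expect_length(classify_events(j, graph, min_novel_reads = 1L), 1)
})

test_that("junctions outside all genes are counted as orphans", {
  graph <- build_splice_graph(gene3())
  j <- jtab(c(200, 5000), c(301, 6000), s1 = c(5L, 5L))
  expect_message(ev <- classify_events(j, graph), "not attributable")
  expect_equal(attr(ev, "n_orphan"), 1)
})

test_that("inclusion ratios follow I/(I+E) with the coverage floor", {
  ev <- list(list(event_id = "e1", gene = "gA", chrom = "chrT", strand = "+",
                  type = "ES",
                  inclusion = jset_df(c(200, 400), c(301, 501)),
                  exclusion = jset_df(200, 501),
                  alt_region = c(301, 400)))
  class(ev) <- "splice_events"
  j <- jtab(c(200, 400, 200), c(301, 501, 501),
            s1 = c(40L, 60L, 50L),      # I = mean(40,60) = 50, E = 50
            s2 = c(30L, 30L, 0L),       # E = 0 -> ratio 1
            s3 = c(2L, 2L, 2L))         # I+E = 4 < 10 -> missing
  r <- quantify_ratios(ev, j, c("s1", "s2", "s3"))
  expect_equal(unname(r[1, ]), c(0.5, 1, NA))
})

test_that("the ratio t-test handles identical, separated and missing cases", {
  design <- data.frame(sample = c("NC_1", "NC_2", "NC_3", "OE_1", "OE_2", "OE_3"),
                       condition = rep(c("NC", "OE"), each = 3))
  r <- rbind(flat = c(0.4, 0.4, 0.4, 0.4, 0.4, 0.4),
             strong = c(0.10, 0.12, 0.11, 0.88, 0.90, 0.91),
             missing = c(0.5, NA, NA, 0.6, 0.7, 0.8))
  colnames(r) <- design$sample
  res <- test_rase(r, design)
  expect_equal(attr(res, "n_skipped"), 1)
  expect_equal(res$p_value[res$event_id == "flat"], 1)
  expect_equal(res$t_statistic[res$event_id == "flat"], 0)
  strong <- res[res$event_id == "strong", ]
  expect_lt(strong$p_value, 1e-3)
  expect_true(strong$significant)
  expect_equal(strong$delta_ratio, mean(c(0.88, 0.90, 0.91)) - mean(c(0.10, 0.12, 0.11)))
  # t-test agrees with the standard implementation
  expect_equal(strong$p_value,
               t.test(c(0.88, 0.90, 0.91), c(0.10, 0.12, 0.11),
                      var.equal = TRUE)$p.value)
  expect_true(all(res$fdr >= res$p_value))
})

test_that("swapping condition labels negates deltas and preserves p-values", {
  sim <- simulate_junction_counts(20, types = c("ES", "A5SS"),
                                  ratio_nc = 0.3, ratio_oe = 0.6, seed = 5)
  r <- quantify_ratios(sim$events, sim$junctions)
  res1 <- test_rase(r, sim$design)
  flipped <- sim$design[c(4:6, 1:3), ]   # OE becomes the reference condition
  res2 <- test_rase(r, flipped)
  expect_equal(res2$delta_ratio, -res1$delta_ratio)
  expect_equal(res2$p_value, res1$p_value)
})

test_that("classifier matches the brute-force enumerator on random models", {
  for (s in 1:40) {
    m <- random_splice_model(s * 13)
    a <- suppressMessages(classify_events(m$junctions, m$graph))
    b <- oracle_classify(m$junctions, m$graph)
    expect_identical(sort(vapply(a, event_key, character(1))),
                     sort(vapply(b, event_key, character(1))),
                     label = paste("model", s, m$type))
  }
})

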