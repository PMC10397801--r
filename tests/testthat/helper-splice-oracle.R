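# Brute-force splicing-event enumerator, independent of the package
# classifier: every rule is applied by exhaustive loops over exon pairs and
# junctions, following the documented topology definitions. Used to check
# classify_events() for exact agreement on randomly generated gene models.

oracle_classify <- function(junctions, graph, min_novel_reads = 2L) {
  cnt_cols <- setdiff(names(junctions), c("chrom", "left", "right", "strand"))
  total <- rowSums(junctions[, cnt_cols, drop = FALSE])
  out <- list()
  for (g in graph) {
    keep <- junctions$chrom == g$chrom & junctions$strand == g$strand &
      junctions$left >= g$span[1] & junctions$right <= g$span[2]
    oj <- junctions[keep, c("left", "right"), drop = FALSE]
    oj$total <- total[keep]
    out <- c(out, oracle_gene(g, oj, min_novel_reads))
  }
  # deduplicate on (gene, type, alt region), first wins, like the classifier
  keys <- vapply(out, function(e)
    paste(e$gene, e$type, e$alt_region[1], e$alt_region[2]), character(1))
  out[!duplicated(keys)]
}

oracle_gene <- function(g, oj, min_novel_reads) {
  U <- g$exons
  ev <- list()
  if (!nrow(U)) return(ev)
  aj <- g$junctions
  is_annot <- function(l, r) {
    any(aj$left == l & aj$right == r)
  }
  sup <- logical(nrow(oj))
  for (q in seq_len(nrow(oj))) {
    need <- if (is_annot(oj$left[q], oj$right[q])) 1L else min_novel_reads
    sup[q] <- oj$total[q] >= need
  }
  os <- oj[sup, , drop = FALSE]
  observed <- function(l, r) any(os$left == l & os$right == r)
  exists_j <- function(l, r) observed(l, r) || is_annot(l, r)
  plus <- g$strand == "+"
  key_of <- function(i) paste(U$start[i], U$end[i], sep = "-")
  add <- function(type, inc_l, inc_r, exc_l, exc_r, alt) {
    ev[[length(ev) + 1L]] <<- list(
      gene = g$gene_id, chrom = g$chrom, strand = g$strand, type = type,
      inclusion = data.frame(left = inc_l, right = inc_r),
      exclusion = data.frame(left = exc_l, right = exc_r),
      alt_region = alt)
  }

  # --- exon pair patterns ---
  n <- nrow(U)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a >= b) next
    if (!(U$end[a] < U$start[b])) next
    if (exists_j(U$end[a], U$start[b])) next
    kA <- key_of(a); kB <- key_of(b)
    internalA <- !(kA %in% g$first_keys) && !(kA %in% g$last_keys)
    internalB <- !(kB %in% g$first_keys) && !(kB %in% g$last_keys)
    if (internalA && internalB) {
      # exhaustive search for nearest common neighbours
      bestC <- NA
      for (cc in seq_len(n)) {
        if (U$end[cc] < U$start[a] &&
            observed(U$end[cc], U$start[a]) && observed(U$end[cc], U$start[b])) {
          if (is.na(bestC) || U$end[cc] > U$end[bestC]) bestC <- cc
        }
      }
      bestD <- NA
      for (dd in seq_len(n)) {
        if (U$start[dd] > U$end[b] &&
            observed(U$end[a], U$start[dd]) && observed(U$end[b], U$start[dd])) {
          if (is.na(bestD) || U$start[dd] < U$start[bestD]) bestD <- dd
        }
      }
      if (!is.na(bestC) && !is.na(bestD)) {
        incA_l <- c(U$end[bestC], U$end[a]); incA_r <- c(U$start[a], U$start[bestD])
        incB_l <- c(U$end[bestC], U$end[b]); incB_r <- c(U$start[b], U$start[bestD])
        if (plus) add("MXE", incA_l, incA_r, incB_l, incB_r, c(U$start[a], U$end[b]))
        else add("MXE", incB_l, incB_r, incA_l, incA_r, c(U$start[a], U$end[b]))
      }
    }
    if (kA %in% g$first_keys && kB %in% g$first_keys) {
      if (plus) {
        shared <- NA
        for (r in os$right[os$left == U$end[a]]) {
          if (r > U$end[b] && observed(U$end[b], r)) {
            if (is.na(shared) || r < shared) shared <- r
          }
        }
        if (!is.na(shared)) {
          add("5pMXE", U$end[a], shared, U$end[b], shared, c(U$start[a], U$end[b]))
        }
      } else {
        shared <- NA
        for (l in os$left[os$right == U$start[a]]) {
          if (l < U$start[a] && observed(l, U$start[b])) {
            if (is.na(shared) || l > shared) shared <- l
          }
        }
        if (!is.na(shared)) {
          add("5pMXE", shared, U$start[b], shared, U$start[a], c(U$start[a], U$end[b]))
        }
      }
    }
    if (kA %in% g$last_keys && kB %in% g$last_keys) {
      if (plus) {
        shared <- NA
        for (l in os$left[os$right == U$start[a]]) {
          if (l < U$start[a] && observed(l, U$start[b])) {
            if (is.na(shared) || l > shared) shared <- l
          }
        }
        if (!is.na(shared)) {
          add("3pMXE", shared, U$start[a], shared, U$start[b], c(U$start[a], U$end[b]))
        }
      } else {
        shared <- NA
        for (r in os$right[os$left == U$end[a]]) {
          if (r > U$end[b] && observed(U$end[b], r)) {
            if (is.na(shared) || r < shared) shared <- r
          }
        }
        if (!is.na(shared)) {
          add("3pMXE", U$end[b], shared, U$end[a], shared, c(U$start[a], U$end[b]))
        }
      }
    }
  }

  # --- single novel junction patterns ---
  for (q in seq_len(nrow(os))) {
    l <- os$left[q]; r <- os$right[q]
    if (is_annot(l, r)) next
    skipped <- which(U$start > l & U$end < r)
    lA <- any(U$end == l)
    rA <- any(U$start == r)
    k <- length(skipped)
    if (k >= 1) {
      s1 <- min(U$start[skipped]); sk <- max(U$end[skipped])
      il <- if (lA) l else {
        cand <- U$end[U$end < s1]; if (length(cand)) max(cand) else NA
      }
      ir <- if (rA) r else {
        cand <- U$start[U$start > sk]; if (length(cand)) min(cand) else NA
      }
      if (is.na(il) || is.na(ir)) next
      if (lA && rA) {
        add(if (k == 1) "ES" else "cassette", c(il, sk), c(s1, ir), l, r, c(s1, sk))
      } else if (lA || rA) {
        novel_left <- !lA
        type <- if (novel_left == plus) "A5SS&ES" else "A3SS&ES"
        add(type, c(il, sk), c(s1, ir), l, r, c(s1, sk))
      }
    } else if (lA && !rA) {
      cand <- aj$right[aj$left == l & aj$right != r]
      if (length(cand)) {
        d <- abs(cand - r)
        r2 <- min(cand[d == min(d)])
        add(if (plus) "A3SS" else "A5SS", l, r2, l, r,
            c(min(r, r2), max(r, r2) - 1L))
      }
    } else if (rA && !lA) {
      cand <- aj$left[aj$right == r & aj$left != l]
      if (length(cand)) {
        d <- abs(cand - l)
        l2 <- min(cand[d == min(d)])
        add(if (plus) "A5SS" else "A3SS", l2, r, l, r,
            c(min(l, l2) + 1L, max(l, l2)))
      }
    }
  }
  ev
}

# Random gene model with one planted event of a given (or random) type plus
# optional noise junctions; returns the annotation, junction table and the
# planted type.
random_splice_model <- function(seed, type = NULL, noise = TRUE) {
  set.seed(seed)
  if (is.null(type)) type <- sample(ase_types(), 1)
  strand <- sample(c("+", "-"), 1)
  n_ex <- sample(8:12, 1)
  el <- sample(80:200, n_ex, replace = TRUE)
  il <- sample(100:300, n_ex - 1, replace = TRUE)
  es <- cumsum(c(1000L, el[-n_ex] + il))
  ee <- es + el - 1L
  built <- riptide:::build_event_gene("g1", "chrT", strand, es, ee, type, 1L)
  ann <- riptide:::build_annotation_from_exons(
    built$exons[, c("chrom", "start", "end", "strand", "gene_id", "transcript_id")],
    seqlengths = SEQLEN)
  graph <- build_splice_graph(ann)
  tpl <- built$template
  jl <- c(graph$g1$junctions$left, tpl$exclusion$left, tpl$inclusion$left)
  jr <- c(graph$g1$junctions$right, tpl$exclusion$right, tpl$inclusion$right)
  cnt <- sample(2:20, length(jl), replace = TRUE)
  if (noise && runif(1) < 0.7) {
    for (i in seq_len(sample(1:2, 1))) {
      a <- sort(sample(seq(min(es) + 1, max(ee) - 1), 2))
      if (a[2] - a[1] < 20) next
      jl <- c(jl, a[1]); jr <- c(jr, a[2])
      cnt <- c(cnt, sample(1:5, 1))   # may fall below the novel-support floor
    }
  }
  keep <- !duplicated(paste(jl, jr))
  junc <- jtab(jl[keep], jr[keep], strand = strand, s1 = cnt[keep])
  list(ann = ann, graph = graph, junctions = junc, type = type)
}
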