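#' Classify alternative splicing events from junction evidence
#'
#' Interprets the observed junction table against the splice graph and emits
#' the nine junction-topology event types. Novel (unannotated) junctions
#' require `min_novel_reads` supporting reads; annotated junctions count as
#' observed with a single read. Junctions that fall in no gene (or on the
#' wrong strand) are ignored and tallied in the `n_orphan` attribute. Each
#' event is emitted once per distinct (gene, alternative region, type).
#'
#' The topology rules, with donor/acceptor read in transcription direction:
#'
#' * **ES** — a novel junction joining two annotated exon boundaries and
#'   skipping exactly one annotated exon; inclusion = the two annotated
#'   junctions flanking the skipped exon, exclusion = the skipping junction.
#' * **cassette** — as ES but skipping two or more exons as a unit.
#' * **A5SS / A3SS** — a novel junction sharing its acceptor (A5SS) or donor
#'   (A3SS) with an annotated junction while using a novel donor (A5SS) or
#'   acceptor (A3SS) that is not an annotated exon boundary, and skipping
#'   nothing.
#' * **A5SS&ES / A3SS&ES** — the alternative-site junction additionally
#'   skips at least one annotated exon; inclusion = the annotated junctions
#'   flanking the skipped unit.
#' * **MXE** — two internal, disjoint exons never joined to each other, each
#'   with observed junctions from a common upstream exon and to a common
#'   downstream exon; inclusion = the path through the 5'-most of the two.
#' * **5pMXE / 3pMXE** — the MXE pattern at alternative first (last) exons:
#'   two transcription-first (last) exons with observed junctions into a
#'   common acceptor (from a common donor).
#'
#' @param junctions a junction table from [extract_junctions()] (count
#'   columns are summed over samples for detection).
#' @param graph a [build_splice_graph()] object.
#' @param min_novel_reads minimum total reads supporting a novel junction.
#' @return a `splice_events` list; each element has `event_id`, `gene`,
#'   `chrom`, `strand`, `type`, `inclusion`/`exclusion` junction
#'   data.frames (`left`, `right`) and `alt_region`.
#' @export
classify_events <- function(junctions, graph, min_novel_reads = 2L) {
  stopifnot(is(graph, "splice_graph"))
  cnt_cols <- setdiff(names(junctions), c("chrom", "left", "right", "strand"))
  total <- if (length(cnt_cols)) rowSums(junctions[, cnt_cols, drop = FALSE]) else
    rep(1L, nrow(junctions))
  assigned <- rep(FALSE, nrow(junctions))
  events <- list()
  for (g in graph) {
    sel <- which(junctions$chrom == g$chrom & junctions$strand == g$strand &
                   junctions$left >= g$span[1] & junctions$right <= g$span[2])
    assigned[sel] <- TRUE
    oj <- junctions[sel, c("left", "right"), drop = FALSE]
    oj$total <- total[sel]
    events <- c(events, classify_gene_events(g, oj, min_novel_reads))
  }
  events <- dedupe_events(events)
  class(events) <- "splice_events"
  attr(events, "n_orphan") <- sum(!assigned)
  if (any(!assigned)) {
    message(sum(!assigned), " junction(s) not attributable to any gene; ignored")
  }
  events
}

## Rules applied within one gene. `oj`: data.frame left/right/total.
classify_gene_events <- function(g, oj, min_novel_reads) {
  U <- g$exons
  if (!nrow(U)) return(list())
  aj_keys <- junc_key(g$junctions$left, g$junctions$right)
  novel <- !(junc_key(oj$left, oj$right) %in% aj_keys)
  supported <- ifelse(novel, oj$total >= min_novel_reads, oj$total >= 1L)
  ojs <- oj[supported, , drop = FALSE]
  ojs_keys <- junc_key(ojs$left, ojs$right)
  seen <- union(aj_keys, ojs_keys)   # junction existence (annotated or observed)
  plus <- g$strand == "+"
  ukeys <- exon_key(U$start, U$end)
  ev <- list()
  emit <- function(type, inc, exc, alt_region) {
    ev[[length(ev) + 1L]] <<- list(
      event_id = sprintf("%s:%s:%d-%d", g$gene_id, type, alt_region[1], alt_region[2]),
      gene = g$gene_id, chrom = g$chrom, strand = g$strand, type = type,
      inclusion = inc, exclusion = exc, alt_region = alt_region)
  }

  ## ---- mutually exclusive exon patterns (pairs of exon intervals) ----
  nU <- nrow(U)
  if (nU >= 2) for (a in seq_len(nU - 1)) for (b in seq((a + 1), nU)) {
    A <- U[a, ]; B <- U[b, ]
    if (A$end >= B$start) next                      # must be disjoint, A left of B
    if (junc_key(A$end, B$start) %in% seen) next    # never joined to each other
    keyA <- ukeys[a]; keyB <- ukeys[b]
    if (keyA %in% g$internal_keys && keyB %in% g$internal_keys) {
      cand_c <- U[U$end < A$start &
                    junc_key(U$end, A$start) %in% ojs_keys &
                    junc_key(U$end, B$start) %in% ojs_keys, , drop = FALSE]
      cand_d <- U[U$start > B$end &
                    junc_key(A$end, U$start) %in% ojs_keys &
                    junc_key(B$end, U$start) %in% ojs_keys, , drop = FALSE]
      if (nrow(cand_c) && nrow(cand_d)) {
        C <- cand_c[which.max(cand_c$end), ]
        D <- cand_d[which.min(cand_d$start), ]
        pathA <- jset(c(C$end, A$end), c(A$start, D$start))
        pathB <- jset(c(C$end, B$end), c(B$start, D$start))
        if (plus) emit("MXE", pathA, pathB, c(A$start, B$end))
        else emit("MXE", pathB, pathA, c(A$start, B$end))
      }
    }
    first_pair <- keyA %in% g$first_keys && keyB %in% g$first_keys
    last_pair <- keyA %in% g$last_keys && keyB %in% g$last_keys
    if (first_pair && plus) {
      ## common downstream acceptor right of B
      r <- common_site(ojs, left1 = A$end, left2 = B$end, min_right = B$end)
      if (!is.na(r)) emit("5pMXE", jset(A$end, r), jset(B$end, r), c(A$start, B$end))
    }
    if (first_pair && !plus) {
      l <- common_site(ojs, right1 = A$start, right2 = B$start, max_left = A$start)
      if (!is.na(l)) emit("5pMXE", jset(l, B$start), jset(l, A$start), c(A$start, B$end))
    }
    if (last_pair && plus) {
      l <- common_site(ojs, right1 = A$start, right2 = B$start, max_left = A$start)
      if (!is.na(l)) emit("3pMXE", jset(l, A$start), jset(l, B$start), c(A$start, B$end))
    }
    if (last_pair && !plus) {
      r <- common_site(ojs, left1 = A$end, left2 = B$end, min_right = B$end)
      if (!is.na(r)) emit("3pMXE", jset(B$end, r), jset(A$end, r), c(A$start, B$end))
    }
  }

  ## ---- single novel junction patterns ----
  nv <- ojs[!(ojs_keys %in% aj_keys), , drop = FALSE]
  for (q in seq_len(nrow(nv))) {
    l <- nv$left[q]; r <- nv$right[q]
    skipped <- U[U$start > l & U$end < r, , drop = FALSE]
    lA <- l %in% U$end
    rA <- r %in% U$start
    k <- nrow(skipped)
    if (k >= 1) {
      s1 <- min(skipped$start)
      sk <- max(skipped$end)
      il <- if (lA) l else max_or_na(U$end[U$end < s1])
      ir <- if (rA) r else min_or_na(U$start[U$start > sk])
      if (is.na(il) || is.na(ir)) next
      inc <- jset(c(il, sk), c(s1, ir))
      if (lA && rA) {
        emit(if (k == 1) "ES" else "cassette", inc, jset(l, r), c(s1, sk))
      } else if (lA != rA) {
        novel_left <- !lA
        type <- if (novel_left == plus) "A5SS&ES" else "A3SS&ES"
        emit(type, inc, jset(l, r), c(s1, sk))
      }
    } else {
      if (lA && !rA) {
        ## donor fixed, acceptor varies
        partners <- g$junctions[g$junctions$left == l & g$junctions$right != r, , drop = FALSE]
        if (nrow(partners)) {
          r2 <- nearest_site(partners$right, r)
          type <- if (plus) "A3SS" else "A5SS"
          emit(type, jset(l, r2), jset(l, r), c(min(r, r2), max(r, r2) - 1L))
        }
      } else if (rA && !lA) {
        partners <- g$junctions[g$junctions$right == r & g$junctions$left != l, , drop = FALSE]
        if (nrow(partners)) {
          l2 <- nearest_site(partners$left, l)
          type <- if (plus) "A5SS" else "A3SS"
          emit(type, jset(l2, r), jset(l, r), c(min(l, l2) + 1L, max(l, l2)))
        }
      }
    }
  }
  ev
}

common_site <- function(ojs, left1 = NULL, left2 = NULL, min_right = NULL,
                        right1 = NULL, right2 = NULL, max_left = NULL) {
  if (!is.null(left1)) {
    r1 <- ojs$right[ojs$left == left1]
    r2 <- ojs$right[ojs$left == left2]
    shared <- intersect(r1, r2)
    shared <- shared[shared > min_right]
    if (length(shared)) min(shared) else NA_integer_
  } else {
    l1 <- ojs$left[ojs$right == right1]
    l2 <- ojs$left[ojs$right == right2]
    shared <- intersect(l1, l2)
    shared <- shared[shared < max_left]
    if (length(shared)) max(shared) else NA_integer_
  }
}

nearest_site <- function(sites, x) {
  d <- abs(sites - x)
  cand <- sites[d == min(d)]
  min(cand)
}

max_or_na <- function(x) if (length(x)) max(x) else NA_integer_
min_or_na <- function(x) if (length(x)) min(x) else NA_integer_

dedupe_events <- function(events) {
  if (!length(events)) return(events)
  keys <- vapply(events, function(e)
    paste(e$gene, e$type, e$alt_region[1], e$alt_region[2]), character(1))
  events[!duplicated(keys)]
}

#' @export
print.splice_events <- function(x, ...) {
  cat("splice_events:", length(x), "event(s)\n")
  if (length(x)) {
    print(table(vapply(x, `[[`, character(1), "type")))
  }
  invisible(x)
}

#' Tabulate splice events
#'
#' One row per event with junction sets serialised as
#' `left>right` lists.
#'
#' @param events a `splice_events` list.
#' @return a data.frame.
#' @export
events_table <- function(events) {
  if (!length(events)) {
    return(data.frame(event_id = character(0), gene = character(0),
                      chrom = character(0), strand = character(0),
                      type = character(0), alt_start = integer(0),
                      alt_end = integer(0), inclusion = character(0),
                      exclusion = character(0)))
  }
  do.call(rbind, lapply(events, function(e) {
    data.frame(event_id = e$event_id, gene = e$gene, chrom = e$chrom,
               strand = e$strand, type = e$type,
               alt_start = e$alt_region[1], alt_end = e$alt_region[2],
               inclusion = paste(junc_key(e$inclusion$left, e$inclusion$right),
                                 collapse = ";"),
               exclusion = paste(junc_key(e$exclusion$left, e$exclusion$right),
                                 collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
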