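#' Peak calling parameters
#'
#' Tuning knobs of the sliding-window peak caller. Defaults follow the
#' in-silico random-clustering procedure: the genome is tiled with 5-bp windows from the
#' start of each chromosome; a candidate opens on a run of 8 consecutive
#' windows at 2.5 times the background depth, or on any window whose median
#' depth exceeds 50; the candidate closes before the first run of 8
#' consecutive windows at or below 4% of the running peak maximum. Reads are
#' redistributed `n_perm` times for the empirical significance test; peaks
#' pass if the permutation p-value is below `p_thresh` *or* the maximum depth
#' reaches `depth_rescue`, and the final set additionally requires at least
#' `input_ratio`-fold library-size-normalised enrichment over the input
#' library.
#'
#' @param window window width in bases.
#' @param init_fold fold over background depth opening a candidate.
#' @param init_run number of consecutive qualifying windows required to open.
#' @param median_floor window median depth that opens a candidate regardless
#'   of background.
#' @param end_frac fraction of the running peak maximum at or below which a
#'   window counts as terminating.
#' @param end_run number of consecutive terminating windows that close a peak.
#' @param n_perm number of read redistributions.
#' @param p_thresh permutation p-value threshold.
#' @param depth_rescue maximum depth at which a peak is kept regardless of p.
#' @param input_ratio minimum IP/input normalised abundance ratio (inclusive).
#' @param pseudocount reads added to the input peak count to avoid division
#'   by zero.
#' @param flank permutation domain half-width for intergenic peaks, bases.
#' @param background baseline for `init_fold`: mean depth of the
#'   chromosome (per strand) or of the whole genome.
#' @param seed integer seed for the permutation test.
#' @return a list of class `peak_call_params`.
#' @export
peak_call_params <- function(window = 5L, init_fold = 2.5, init_run = 8L,
                             median_floor = 50, end_frac = 0.04, end_run = 8L,
                             n_perm = 500L, p_thresh = 0.05, depth_rescue = 10,
                             input_ratio = 4, pseudocount = 1, flank = 5000L,
                             background = c("chromosome", "genome"),
                             seed = 1L) {
  p <- list(window = as.integer(window), init_fold = init_fold,
            init_run = as.integer(init_run), median_floor = median_floor,
            end_frac = end_frac, end_run = as.integer(end_run),
            n_perm = as.integer(n_perm), p_thresh = p_thresh,
            depth_rescue = depth_rescue, input_ratio = input_ratio,
            pseudocount = pseudocount, flank = as.integer(flank),
            background = match.arg(background), seed = as.integer(seed))
  stopifnot(p$window >= 1, p$init_fold > 0, p$init_run >= 1,
            p$median_floor > 0, p$end_frac > 0, p$end_frac < 1,
            p$end_run >= 1, p$p_thresh > 0, p$depth_rescue > 0,
            p$input_ratio > 0, p$pseudocount >= 0, p$flank >= 0)
  if (p$n_perm < 1) stop("n_perm must be >= 1")
  class(p) <- "peak_call_params"
  p
}

#' Tile the genome with depth windows
#'
#' Splits every chromosome/strand into non-overlapping windows of
#' `params$window` bases starting at position 1 (the trailing partial window
#' is kept) and records each window's mean and median depth, plus the
#' chromosome-mean and genome-mean background depth per strand.
#'
#' @param cov a `coverage_track` from [compute_coverage()].
#' @param params a [peak_call_params()] object.
#' @return an object of class `window_scan`.
#' @export
scan_windows <- function(cov, params = peak_call_params()) {
  stopifnot(is(cov, "coverage_track"))
  w <- params$window
  entries <- list()
  for (s in c("+", "-")) {
    covs <- strand_cov(cov, s)
    genome_len <- sum(vapply(covs, length, numeric(1)))
    genome_mass <- sum(cov$aligned_bases[[if (s == "+") "plus" else "minus"]])
    for (chrom in names(covs)) {
      x <- as.numeric(covs[[chrom]])
      n <- length(x)
      nw <- ceiling(n / w)
      ends <- pmin(seq_len(nw) * w, n)
      starts <- (seq_len(nw) - 1L) * w + 1L
      cs <- cumsum(x)
      sums <- cs[ends] - c(0, cs[head(ends, -1)])
      means <- sums / (ends - starts + 1)
      medians <- window_medians(x, w, nw, starts, ends)
      entries[[paste0(chrom, s)]] <- list(
        chrom = chrom, strand = s, n_windows = nw, chrom_length = n,
        means = means, medians = medians,
        chrom_mean = sum(x) / n,
        genome_mean = genome_mass / genome_len)
    }
  }
  structure(list(entries = entries, window = w, cov = cov),
            class = "window_scan")
}

window_medians <- function(x, w, nw, starts, ends) {
  if (w == 1) return(x)
  full <- which(ends - starts + 1L == w)
  med <- numeric(nw)
  if (length(full) && w %% 2 == 1 && length(x) >= w) {
    rm <- runmed(x, w, endrule = "keep")
    med[full] <- rm[starts[full] + (w - 1L) %/% 2L]
  } else if (length(full)) {
    med[full] <- vapply(full, function(i) median(x[starts[i]:ends[i]]), numeric(1))
  }
  partial <- setdiff(seq_len(nw), full)
  for (i in partial) med[i] <- median(x[starts[i]:ends[i]])
  med
}

#' @export
print.window_scan <- function(x, ...) {
  cat("window_scan:", length(x$entries), "chromosome-strand tracks, window",
      x$window, "bp\n")
  invisible(x)
}

#' Call candidate peaks from a window scan
#'
#' A candidate opens at the first window of a run of at least
#' `params$init_run` consecutive windows whose mean depth reaches
#' `params$init_fold` times the background, or at any window whose median
#' depth exceeds `params$median_floor`. The candidate then extends rightward
#' tracking its running maximum window depth and closes immediately before
#' the first run of `params$end_run` consecutive windows at or below
#' `params$end_frac` of that maximum; the terminating low-depth windows are
#' trimmed. Overlapping or adjacent candidates are merged, and each peak's
#' `max_depth` is the maximum per-base depth inside it. A background of zero
#' (an empty track) yields an empty result.
#'
#' @param scan a `window_scan`.
#' @param params a [peak_call_params()] object.
#' @return a `GRanges` of candidate peaks with `max_depth` metadata.
#' @export
call_candidate_peaks <- function(scan, params = peak_call_params()) {
  stopifnot(is(scan, "window_scan"))
  w <- scan$window
  out <- GRanges()
  for (e in scan$entries) {
    bg <- if (params$background == "chromosome") e$chrom_mean else e$genome_mean
    M <- e$means
    nw <- e$n_windows
    if (nw == 0) next
    thr <- params$init_fold * bg
    init_ok <- M > 0 & (bg > 0 & M >= thr)
    opens <- integer(0)
    r <- rle(init_ok)
    rend <- cumsum(r$lengths)
    rstart <- rend - r$lengths + 1L
    opens <- rstart[r$values & r$lengths >= params$init_run]
    opens <- sort(union(opens, which(e$medians > params$median_floor)))
    if (!length(opens)) next
    cand <- matrix(0L, 0, 2)
    resume <- 0L
    for (a in opens) {
      if (a <= resume) next
      cmax <- 0
      low_run <- 0L
      last_above <- a
      j <- a
      while (j <= nw) {
        v <- M[j]
        if (v > cmax) cmax <- v
        if (v <= params$end_frac * cmax) {
          low_run <- low_run + 1L
          if (low_run >= params$end_run) break
        } else {
          low_run <- 0L
          last_above <- j
        }
        j <- j + 1L
      }
      cand <- rbind(cand, c(a, last_above))
      resume <- j
    }
    if (!nrow(cand)) next
    gstart <- (cand[, 1] - 1L) * w + 1L
    gend <- pmin(cand[, 2] * w, e$chrom_length)
    gr <- reduce(GRanges(e$chrom, IRanges(gstart, gend), strand = e$strand))
    covr <- strand_cov(scan$cov, e$strand)[[e$chrom]]
    mcols(gr)$max_depth <- viewMaxs(Views(covr, start(gr), end(gr)))
    suppressWarnings(out <- c(out, gr))
  }
  if (length(out)) names(out) <- sprintf("peak_%04d", seq_along(out))
  out
}

#' Permutation significance test for peaks
#'
#' For each peak, the reads of its permutation domain are redistributed
#' uniformly at random `params$n_perm` times (read lengths preserved) and
#' the maximum per-base depth within the peak interval is recorded; the
#' empirical p-value uses the add-one estimator
#' `(1 + #permutation statistics >= observed max depth) / (n_perm + 1)`,
#' so p is always in `[1/(n_perm+1), 1]`. The domain is the host gene's
#' transcribed (exon-union) space for genic peaks — the space RIP reads are
#' drawn from — and a `params$flank` window around the peak for intergenic
#' peaks.
#'
#' @param peaks `GRanges` of candidate peaks with `max_depth`.
#' @param ip the (deduplicated) IP `alignment_set`.
#' @param ann a `gene_annotation`.
#' @param params a [peak_call_params()] object.
#' @return `peaks` with added metadata columns `perm_p` and `host_gene_span`.
#' @export
permutation_test <- function(peaks, ip, ann, params = peak_call_params()) {
  if (!length(peaks)) {
    mcols(peaks)$perm_p <- numeric(0)
    return(peaks)
  }
  stopifnot(is(ip, "alignment_set"))
  set.seed(params$seed)
  ga <- ip$ga
  genes <- ann$genes
  eu <- exon_union(ann)
  hits <- findOverlaps(peaks, genes)
  host <- rep(NA_integer_, length(peaks))
  host[queryHits(hits)] <- subjectHits(hits)   # last hit wins; genes don't overlap
  obs <- mcols(peaks)$max_depth
  cnt <- integer(length(peaks))
  pk_start <- start(peaks)
  pk_end <- end(peaks)

  run_domain <- function(domain_gr, peak_idx) {
    ## domain_gr: GRanges pieces (sorted) forming the concatenated domain;
    ## returns the count of permutation statistics >= observed, per peak
    D <- sum(width(domain_gr))
    offs <- cumsum(c(0L, head(width(domain_gr), -1L)))
    reads <- subsetByOverlaps(ga, domain_gr)
    nr <- length(reads)
    local_cnt <- integer(length(peak_idx))
    if (nr == 0 || D < 2) {
      ## no reads: every permutation trivially matches an all-zero profile
      return(ifelse(obs[peak_idx] <= 0, params$n_perm, 0L))
    }
    wr <- pmin(qwidth(reads), D)
    ## domain-space index positions covered by each peak (plain arithmetic)
    ds <- start(domain_gr); de <- end(domain_gr)
    pmap <- lapply(peak_idx, function(i) {
      js <- which(ds <= pk_end[i] & de >= pk_start[i])
      unlist(lapply(js, function(j) {
        lo <- max(pk_start[i], ds[j]); hi <- min(pk_end[i], de[j])
        (offs[j] + lo - ds[j] + 1L):(offs[j] + hi - ds[j] + 1L)
      }), use.names = FALSE)
    })
    ## reads are placed uniformly within the domain pieces they fit in
    ## (a genomic read cannot straddle two exons unspliced), grouped by
    ## length; piece + offset come from one uniform draw via the inverse CDF
    piece_len <- width(domain_gr)
    by_len <- split(seq_len(nr), wr)
    lens <- as.integer(names(by_len))
    grp <- lapply(lens, function(l) {
      wts <- pmax(0, piece_len - l + 1)
      if (sum(wts) == 0) NULL else cumsum(wts)
    })
    for (k in seq_len(params$n_perm)) {
      starts <- integer(nr)
      for (li in seq_along(lens)) {
        ii <- by_len[[li]]
        cw <- grp[[li]]
        if (is.null(cw)) {
          starts[ii] <- 1L + floor(runif(length(ii)) *
                                     max(1, D - lens[li] + 1))
        } else {
          u <- runif(length(ii)) * cw[length(cw)]
          pc <- findInterval(u, cw) + 1L
          starts[ii] <- offs[pc] + 1L + floor(u - c(0, cw)[pc])
        }
      }
      depth <- cumsum(tabulate(starts, D) - tabulate(starts + wr, D))
      for (q in seq_along(peak_idx)) {
        idx <- pmap[[q]]
        if (length(idx) && max(depth[idx]) >= obs[peak_idx[q]]) {
          local_cnt[q] <- local_cnt[q] + 1L
        }
      }
    }
    local_cnt
  }

  genic <- which(!is.na(host))
  for (g in unique(host[genic])) {
    idx <- genic[host[genic] == g]
    gid <- mcols(genes)$gene_id[g]
    dom <- sort(eu[[gid]])
    strand(dom) <- strand(genes[g])
    cnt[idx] <- run_domain(dom, idx)
  }
  for (i in which(is.na(host))) {
    chrlen <- ann$seqlengths[[as.character(seqnames(peaks[i]))]]
    dom <- GRanges(seqnames(peaks[i]),
                   IRanges(max(1L, start(peaks[i]) - params$flank),
                           min(chrlen, end(peaks[i]) + params$flank)),
                   strand = strand(peaks[i]))
    cnt[i] <- run_domain(dom, i)
  }
  mcols(peaks)$perm_p <- (1 + cnt) / (params$n_perm + 1)
  mcols(peaks)$host_gene_span <- ifelse(is.na(host), NA_character_,
                                        mcols(genes)$gene_id[host])
  peaks
}

#' Significance filter for peaks
#'
#' Keeps peaks with a permutation p-value below `params$p_thresh` *or* a
#' maximum depth of at least `params$depth_rescue` (the depth rescue
#' clause).
#'
#' @inheritParams permutation_test
#' @return the retained `GRanges`.
#' @export
filter_significant <- function(peaks, params = peak_call_params()) {
  if (!length(peaks)) return(peaks)
  stopifnot(!is.null(mcols(peaks)$perm_p))
  peaks[mcols(peaks)$perm_p < params$p_thresh |
          mcols(peaks)$max_depth >= params$depth_rescue]
}

#' IP-versus-input enrichment filter
#'
#' Computes, per peak, the library-size-normalised ratio
#' `(IP reads in peak / IP library size) /
#'  ((input reads in peak + pseudocount) / input library size)` and keeps
#' peaks whose ratio is at least `params$input_ratio` (inclusive).
#'
#' @param peaks significant peaks (`GRanges`).
#' @param ip,input deduplicated `alignment_set`s; both library sizes must be
#'   positive.
#' @param params a [peak_call_params()] object.
#' @return the final `GRanges` with `ip_reads`, `input_reads` and
#'   `input_ratio_obs` metadata.
#' @export
input_enrichment_filter <- function(peaks, ip, input,
                                    params = peak_call_params()) {
  stopifnot(is(ip, "alignment_set"), is(input, "alignment_set"))
  n_ip <- library_size(ip)
  n_in <- library_size(input)
  if (n_ip == 0 || n_in == 0) stop("both libraries must be non-empty")
  if (!length(peaks)) {
    mcols(peaks)$input_ratio_obs <- numeric(0)
    return(peaks)
  }
  ipc <- countOverlaps(peaks, ip$ga)
  inc <- countOverlaps(peaks, input$ga)
  ratio <- (ipc / n_ip) / ((inc + params$pseudocount) / n_in)
  mcols(peaks)$ip_reads <- ipc
  mcols(peaks)$input_reads <- inc
  mcols(peaks)$input_ratio_obs <- ratio
  peaks[ratio >= params$input_ratio]
}

#' Call peaks end to end
#'
#' Convenience wrapper: duplicate removal, coverage, window scan, candidate
#' calling, permutation test, significance filter and input filter.
#'
#' @param ip,input `alignment_set`s (deduplicated internally).
#' @param ann a `gene_annotation`.
#' @param params a [peak_call_params()] object.
#' @param dedup remove PCR duplicates first.
#' @return list with `candidates`, `significant` and `peaks` (final), plus
#'   the deduplicated libraries.
#' @export
call_peaks <- function(ip, input, ann, params = peak_call_params(),
                       dedup = TRUE) {
  if (dedup) {
    ip <- dedup_pcr(ip)
    input <- dedup_pcr(input)
  }
  cov <- compute_coverage(ip)
  scan <- scan_windows(cov, params)
  cand <- call_candidate_peaks(scan, params)
  cand <- permutation_test(cand, ip, ann, params)
  sig <- filter_significant(cand, params)
  final <- input_enrichment_filter(sig, ip, input, params)
  list(candidates = cand, significant = sig, peaks = final,
       ip = ip, input = input)
}
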