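#' Stranded per-base coverage
#'
#' Computes integer read depth per base and strand from an alignment set.
#' Junction gaps (CIGAR `N`) contribute no depth. Total depth mass equals the
#' summed aligned block lengths of the contributing records.
#'
#' @param aset an `alignment_set` (deduplicate first for peak calling).
#' @return an object of class `coverage_track`: a list with `RleList`
#'   elements `plus` and `minus` (one Rle per chromosome) and the library's
#'   aligned-base totals per chromosome/strand in `aligned_bases`.
#' @export
compute_coverage <- function(aset) {
  stopifnot(is(aset, "alignment_set"))
  ga <- aset$ga
  cov_for <- function(s) {
    GenomicAlignments::coverage(ga[strand(ga) == s])
  }
  plus <- cov_for("+")
  minus <- cov_for("-")
  ab <- function(covlist) vapply(covlist, function(r) sum(as.numeric(runValue(r) *
                                                             S4Vectors::runLength(r))), numeric(1))
  structure(list(plus = plus, minus = minus,
                 aligned_bases = list(plus = ab(plus), minus = ab(minus)),
                 library_size = library_size(aset)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track over", length(x$plus), "chromosome(s);",
      "aligned bases: +", sum(x$aligned_bases$plus),
      "/ -", sum(x$aligned_bases$minus), "\n")
  invisible(x)
}

strand_cov <- function(cov, strand) if (strand == "+") cov$plus else cov$minus

#' Write a coverage track as bedGraph
#'
#' One file per strand is produced (`<prefix>.plus.bedGraph`,
#' `<prefix>.minus.bedGraph`).
#'
#' @param cov a `coverage_track`.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_bedgraph <- function(cov, prefix) {
  paths <- character(0)
  for (s in c("plus", "minus")) {
    path <- paste0(prefix, ".", s, ".bedGraph")
    rtracklayer::export(GRanges(cov[[s]])[, "score"], path, format = "bedGraph")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Extract splice junction counts
#'
#' Tabulates the distinct junctions (read-through intron gaps) observed in
#' one or more alignment sets. A junction is keyed by chromosome, the last
#' aligned base of the upstream block (`left`), the first aligned base of the
#' downstream block (`right`), and strand; one count column is produced per
#' sample. Counts are invariant under record order.
#'
#' @param sets a list of `alignment_set` objects (or a single one).
#' @return a `data.frame` (the junction table) with columns `chrom`, `left`,
#'   `right`, `strand`, then one integer column per sample id.
#' @export
extract_junctions <- function(sets) {
  if (is(sets, "alignment_set")) sets <- list(sets)
  stopifnot(length(sets) > 0)
  sample_ids <- vapply(sets, function(s) s$sample_id, character(1))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in alignment sets")
  per <- lapply(sets, function(aset) {
    ga <- aset$ga
    spliced <- ga[njunc(ga) > 0]
    if (!length(spliced)) {
      return(data.frame(chrom = character(0), left = integer(0),
                        right = integer(0), strand = character(0),
                        n = integer(0)))
    }
    jl <- GenomicAlignments::junctions(spliced)
    j <- unlist(jl, use.names = FALSE)
    key <- data.frame(chrom = as.character(seqnames(j)),
                      left = start(j) - 1L, right = end(j) + 1L,
                      strand = as.character(strand(j)),
                      stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(n = rep(1L, nrow(key))), key, FUN = sum)
    agg
  })
  all_keys <- unique(do.call(rbind, lapply(per, function(d) d[, 1:4])))
  all_keys <- all_keys[order(all_keys$chrom, all_keys$left, all_keys$right,
                             all_keys$strand), , drop = FALSE]
  rownames(all_keys) <- NULL
  kid <- function(d) paste(d$chrom, d$left, d$right, d$strand, sep = "\r")
  base <- kid(all_keys)
  for (i in seq_along(per)) {
    cnt <- integer(nrow(all_keys))
    m <- match(kid(per[[i]]), base)
    cnt[m] <- per[[i]]$n
    all_keys[[sample_ids[i]]] <- cnt
  }
  all_keys
}
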