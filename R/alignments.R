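#' Alignment sets
#'
#' An `alignment_set` bundles the retained alignments of one library
#' (a `GAlignments` object) with its role in the experiment (`"IP"`,
#' `"input"`, or a condition/replicate label such as `"NC_1"`) and a sample
#' identifier. `library_size` is the number of retained records.
#'
#' @param ga a `GAlignments` object.
#' @param role library role: `"IP"`, `"input"`, or `"<condition>_<replicate>"`.
#' @param sample_id sample identifier; defaults to the role.
#' @return an object of class `alignment_set`.
#' @export
alignment_set <- function(ga, role, sample_id = role) {
  stopifnot(is(ga, "GAlignments"), is.character(role), length(role) == 1)
  structure(list(ga = ga, role = role, sample_id = sample_id),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("alignment_set [", x$role, "]: ", length(x$ga), " records\n", sep = "")
  invisible(x)
}

#' @rdname alignment_set
#' @param x an `alignment_set`.
#' @export
library_size <- function(x) {
  stopifnot(is(x, "alignment_set"))
  length(x$ga)
}

#' Read alignments from SAM/BAM
#'
#' Loads one library, keeping primary mapped records only. With
#' `unique_only = TRUE` (the default) secondary/supplementary records are
#' excluded and a minimum mapping quality can be required, so that only
#' uniquely mapped reads enter gene counting and peak calling.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @param role,sample_id see [alignment_set()].
#' @param unique_only drop secondary/supplementary alignments.
#' @param min_mapq minimum mapping quality (NA = no filter).
#' @return an `alignment_set`.
#' @export
read_alignments <- function(path, role, sample_id = role,
                            unique_only = TRUE, min_mapq = NA_integer_) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(asBam(path, destination = dest,
                                  overwrite = TRUE, indexDestination = FALSE))
  }
  flags <- scanBamFlag(isUnmappedQuery = FALSE,
                       isSecondaryAlignment = if (unique_only) FALSE else NA,
                       isSupplementaryAlignment = if (unique_only) FALSE else NA)
  param <- ScanBamParam(flag = flags,
                        mapqFilter = if (is.na(min_mapq)) NA_integer_ else min_mapq)
  ga <- readGAlignments(bam, param = param)
  alignment_set(ga, role = role, sample_id = sample_id)
}

#' Write an alignment set as SAM
#'
#' Emits a minimal valid single-end SAM file (header with `@SQ` lines,
#' records with CIGAR `N` gaps for spliced reads). Strandedness is encoded
#' in the FLAG field. Output is deterministic for a given set.
#'
#' @param aset an `alignment_set`.
#' @param path output path (`.sam`).
#' @param seqlengths named chromosome lengths for the header; taken from the
#'   alignments' seqinfo when omitted.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aset, path, seqlengths = NULL) {
  stopifnot(is(aset, "alignment_set"))
  ga <- aset$ga
  if (is.null(seqlengths)) {
    seqlengths <- GenomeInfoDb::seqlengths(ga)
    if (any(is.na(seqlengths))) stop("seqlengths required to write SAM header")
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths)))
  n <- length(ga)
  flag <- ifelse(as.character(strand(ga)) == "-", 16L, 0L)
  qw <- qwidth(ga)
  recs <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                  sprintf("%s_r%06d", aset$sample_id, seq_len(n)),
                  flag, as.character(seqnames(ga)), start(ga), cigar(ga),
                  strrep("N", qw))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Remove PCR duplicates
#'
#' Collapses records that share chromosome, strand, start position and block
#' structure (CIGAR) to a single representative, mirroring standard
#' positional deduplication of PCR amplicons. The result is independent of
#' record order and idempotent.
#'
#' @param aset an `alignment_set`.
#' @return a deduplicated `alignment_set`.
#' @export
dedup_pcr <- function(aset) {
  stopifnot(is(aset, "alignment_set"))
  ga <- aset$ga
  key <- paste(as.character(seqnames(ga)), start(ga),
               as.character(strand(ga)), cigar(ga), sep = "\r")
  ord <- order(key)
  keep <- ord[!duplicated(key[ord])]
  alignment_set(ga[sort(keep)], role = aset$role, sample_id = aset$sample_id)
}

## In-memory constructor used by the simulators: unspliced or 2-block reads.
## gaps == 0 means contiguous (cigar "<w>M"); otherwise blocks of width w1/w2
## around an N gap.
make_galignments <- function(chrom, pos, strand, seqlengths,
                             width = NULL, cigar = NULL) {
  if (is.null(cigar)) cigar <- rep(sprintf("%dM", width), length.out = length(chrom))
  GAlignments(seqnames = Rle(factor(chrom, levels = names(seqlengths))),
              pos = as.integer(pos), cigar = cigar,
              strand = Rle(factor(strand, levels = c("+", "-", "*"))),
              seqlengths = seqlengths)
}
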