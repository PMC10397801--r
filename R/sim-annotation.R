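#' Generate a synthetic gene annotation
#'
#' Lays out `n_genes` non-overlapping multi-exon genes on alternating strands
#' across the configured chromosomes. Every gene gets one full-length
#' transcript; genes hosting a planted splicing event additionally carry the
#' isoform structure that event type requires (e.g. two transcripts with
#' mutually exclusive exons for an MXE event), and the corresponding
#' inclusion/exclusion junction sets are recorded as event templates used by
#' [simulate_rnaseq()].
#'
#' @param config a [sim_config()] object.
#' @return an object of class `gene_annotation`: a list with elements
#'   `genes` (GRanges with `gene_id`, `biotype`), `exons` (GRanges with
#'   `gene_id`, `transcript_id`, `exon_rank` in transcription order),
#'   `seqlengths` (named vector) and `event_templates` (list, possibly empty).
#' @export
make_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_ev <- if (is.null(config$event_spec)) 0L else nrow(config$event_spec)
  if (n_ev > config$n_genes) {
    stop("more planted events than genes; one gene is used per event")
  }

  min_exons <- max(config$exons_per_gene_range[1], if (n_ev) 8L else 1L)
  n_exons <- sample_range(c(min_exons, max(min_exons, config$exons_per_gene_range[2])),
                          config$n_genes)

  ## per-gene exon/intron lengths and genomic layout within the gene
  gene_structs <- lapply(seq_len(config$n_genes), function(g) {
    ne <- n_exons[g]
    el <- sample_range(config$exon_length_range, ne)
    il <- if (ne > 1) sample_range(config$intron_length_range, ne - 1) else integer(0)
    starts <- cumsum(c(1L, head(el, -1) + il))
    list(exon_start = starts, exon_end = starts + el - 1L,
         span = starts[ne] + el[ne] - 1L)
  })
  spans <- vapply(gene_structs, `[[`, numeric(1), "span")

  ## distribute genes over chromosomes, random intergenic gaps
  chrom_of <- rep(seq_len(config$n_chromosomes), length.out = config$n_genes)
  chrom_len <- floor(config$genome_length / config$n_chromosomes)
  offsets <- numeric(config$n_genes)
  min_gap <- 100
  for (chr in seq_len(config$n_chromosomes)) {
    idx <- which(chrom_of == chr)
    free <- chrom_len - sum(spans[idx]) - (length(idx) + 1) * min_gap
    if (free < 0) {
      stop("genome too small for the requested gene structures ",
           "(chromosome ", chr, " short by ", -free, " bases)")
    }
    extra <- if (length(idx)) diff(c(0, sort(runif(length(idx), 0, free)))) else numeric(0)
    pos <- min_gap
    for (k in seq_along(idx)) {
      pos <- pos + floor(extra[k])
      offsets[idx[k]] <- pos
      pos <- pos + spans[idx[k]] + min_gap
    }
  }

  strand_of <- rep(c("+", "-"), length.out = config$n_genes)
  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
  coding <- seq_len(config$n_genes) <= round(config$coding_fraction * config$n_genes)
  ## interleave so both strands carry both biotypes
  coding <- coding[order(seq_len(config$n_genes) %% 2, decreasing = TRUE)]

  seqlengths <- setNames(rep(chrom_len, config$n_chromosomes),
                         paste0("chr", seq_len(config$n_chromosomes)))

  exon_rows <- list()
  templates <- list()
  for (g in seq_len(config$n_genes)) {
    st <- gene_structs[[g]]
    es <- st$exon_start + offsets[g]
    ee <- st$exon_end + offsets[g]
    chrom <- paste0("chr", chrom_of[g])
    strand <- strand_of[g]
    gid <- gene_ids[g]
    if (g <= n_ev) {
      spec_row <- config$event_spec[g, ]
      built <- build_event_gene(gid, chrom, strand, es, ee,
                                spec_row$type, g)
      exon_rows[[g]] <- built$exons
      tpl <- built$template
      tpl$ratio_nc <- spec_row$ratio_nc
      tpl$ratio_oe <- spec_row$ratio_oe
      templates[[length(templates) + 1L]] <- tpl
    } else {
      exon_rows[[g]] <- transcript_rows(gid, paste0(gid, ".t1"), chrom, strand, es, ee)
    }
  }
  exon_df <- do.call(rbind, exon_rows)
  exons <- GRanges(exon_df$chrom, IRanges(exon_df$start, exon_df$end),
                   strand = exon_df$strand, gene_id = exon_df$gene_id,
                   transcript_id = exon_df$transcript_id,
                   exon_rank = exon_df$exon_rank,
                   seqlengths = seqlengths)
  gene_start <- vapply(split(exon_df$start, exon_df$gene_id), min, numeric(1))
  gene_end <- vapply(split(exon_df$end, exon_df$gene_id), max, numeric(1))
  ord <- gene_ids
  genes <- GRanges(paste0("chr", chrom_of), IRanges(gene_start[ord], gene_end[ord]),
                   strand = strand_of, gene_id = gene_ids,
                   biotype = ifelse(coding, "protein_coding", "noncoding"),
                   seqlengths = seqlengths)
  names(genes) <- gene_ids

  ann <- structure(list(genes = genes, exons = exons,
                        seqlengths = seqlengths,
                        event_templates = templates),
                   class = "gene_annotation")
  validate_annotation(ann)
  ann
}

sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

transcript_rows <- function(gid, tid, chrom, strand, starts, ends, keep = NULL) {
  if (is.null(keep)) keep <- seq_along(starts)
  keep <- sort(keep)
  rank <- if (strand == "+") seq_along(keep) else rev(seq_along(keep))
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             strand = strand, gene_id = gid, transcript_id = tid,
             exon_rank = rank, stringsAsFactors = FALSE)
}

jset <- function(l, r) data.frame(left = l, right = r)

## Construct the isoform structure a planted event type requires, plus the
## inclusion/exclusion junction template. Exons are indexed genomically
## left-to-right; `m` is an internal slot near the gene middle.
build_event_gene <- function(gid, chrom, strand, es, ee, type, event_idx) {
  n <- length(es)
  stopifnot(n >= 8)
  m <- max(3L, n %/% 2L)
  shift <- 30L
  t1 <- paste0(gid, ".t1")
  t2 <- paste0(gid, ".t2")
  full <- transcript_rows(gid, t1, chrom, strand, es, ee)
  exons <- full
  plus <- strand == "+"

  inc <- exc <- NULL
  if (type == "ES") {
    inc <- jset(c(ee[m - 1], ee[m]), c(es[m], es[m + 1]))
    exc <- jset(ee[m - 1], es[m + 1])
  } else if (type == "cassette") {
    inc <- jset(c(ee[m - 1], ee[m + 1]), c(es[m], es[m + 2]))
    exc <- jset(ee[m - 1], es[m + 2])
  } else if (type == "A5SS") {
    inc <- jset(ee[m], es[m + 1])
    exc <- if (plus) jset(ee[m] - shift, es[m + 1]) else jset(ee[m], es[m + 1] + shift)
  } else if (type == "A3SS") {
    inc <- jset(ee[m], es[m + 1])
    exc <- if (plus) jset(ee[m], es[m + 1] + shift) else jset(ee[m] - shift, es[m + 1])
  } else if (type == "A5SS&ES") {
    inc <- jset(c(ee[m - 1], ee[m]), c(es[m], es[m + 1]))
    exc <- if (plus) jset(ee[m - 1] - shift, es[m + 1]) else jset(ee[m - 1], es[m + 1] + shift)
  } else if (type == "A3SS&ES") {
    inc <- jset(c(ee[m - 1], ee[m]), c(es[m], es[m + 1]))
    exc <- if (plus) jset(ee[m - 1], es[m + 1] + shift) else jset(ee[m - 1] - shift, es[m + 1])
  } else if (type == "MXE") {
    ## t1 uses exon m, t2 uses exon m+1; neither isoform joins the two
    exons <- rbind(
      transcript_rows(gid, t1, chrom, strand, es, ee, keep = setdiff(seq_len(n), m + 1L)),
      transcript_rows(gid, t2, chrom, strand, es, ee, keep = setdiff(seq_len(n), m))
    )
    pathA <- jset(c(ee[m - 1], ee[m]), c(es[m], es[m + 2]))
    pathB <- jset(c(ee[m - 1], ee[m + 1]), c(es[m + 1], es[m + 2]))
    if (plus) { inc <- pathA; exc <- pathB } else { inc <- pathB; exc <- pathA }
  } else if (type == "5pMXE") {
    if (plus) {
      ## alternative first exons 1 and 2 joining exon 3
      exons <- rbind(
        transcript_rows(gid, t1, chrom, strand, es, ee, keep = setdiff(seq_len(n), 2L)),
        transcript_rows(gid, t2, chrom, strand, es, ee, keep = setdiff(seq_len(n), 1L))
      )
      inc <- jset(ee[1], es[3])
      exc <- jset(ee[2], es[3])
    } else {
      ## minus strand: first exons are the right-most two
      exons <- rbind(
        transcript_rows(gid, t1, chrom, strand, es, ee, keep = setdiff(seq_len(n), n - 1L)),
        transcript_rows(gid, t2, chrom, strand, es, ee, keep = setdiff(seq_len(n), n))
      )
      inc <- jset(ee[n - 2], es[n])
      exc <- jset(ee[n - 2], es[n - 1])
    }
  } else if (type == "3pMXE") {
    if (plus) {
      ## alternative last exons n-1 and n
      exons <- rbind(
        transcript_rows(gid, t1, chrom, strand, es, ee, keep = setdiff(seq_len(n), n)),
        transcript_rows(gid, t2, chrom, strand, es, ee, keep = setdiff(seq_len(n), n - 1L))
      )
      inc <- jset(ee[n - 2], es[n - 1])
      exc <- jset(ee[n - 2], es[n])
    } else {
      ## minus strand: last exons are the left-most two
      exons <- rbind(
        transcript_rows(gid, t1, chrom, strand, es, ee, keep = setdiff(seq_len(n), 1L)),
        transcript_rows(gid, t2, chrom, strand, es, ee, keep = setdiff(seq_len(n), 2L))
      )
      inc <- jset(ee[2], es[3])
      exc <- jset(ee[1], es[3])
    }
  } else {
    stop("unknown event type: ", type)
  }

  template <- list(event_id = sprintf("sim_ev%03d", event_idx),
                   gene_id = gid, chrom = chrom, strand = strand,
                   type = type, inclusion = inc, exclusion = exc)
  list(exons = exons, template = template)
}

validate_annotation <- function(ann) {
  stopifnot(is(ann$genes, "GRanges"), is(ann$exons, "GRanges"))
  for (s in c("+", "-")) {
    g <- ann$genes[strand(ann$genes) == s]
    if (length(g) > 1 && any(countOverlaps(g, g) > 1)) {
      stop("generated genes overlap on strand ", s)
    }
  }
  invisible(ann)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", length(x$genes), "genes,",
      length(x$exons), "exon records,",
      length(x$event_templates), "event template(s)\n")
  invisible(x)
}

#' Write an annotation to GTF
#'
#' Emits gene, transcript and exon features with `gene_id`/`transcript_id`
#' attributes. Deterministic: the same annotation always produces identical
#' bytes.
#'
#' @param ann a `gene_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  ex <- ann$exons
  df <- data.frame(
    chrom = as.character(seqnames(ex)),
    start = start(ex), end = end(ex), strand = as.character(strand(ex)),
    gene_id = mcols(ex)$gene_id, transcript_id = mcols(ex)$transcript_id,
    exon_rank = mcols(ex)$exon_rank, stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$gene_id, df$transcript_id, df$start), ]
  bt <- setNames(mcols(ann$genes)$biotype, mcols(ann$genes)$gene_id)
  lines <- character(0)
  for (gid in unique(df$gene_id)) {
    gd <- df[df$gene_id == gid, ]
    lines <- c(lines, sprintf(
      "%s\triptide\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
      gd$chrom[1], min(gd$start), max(gd$end), gd$strand[1], gid, bt[[gid]]))
    for (tid in unique(gd$transcript_id)) {
      td <- gd[gd$transcript_id == tid, ]
      lines <- c(lines, sprintf(
        "%s\triptide\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        td$chrom[1], min(td$start), max(td$end), td$strand[1], gid, tid))
      lines <- c(lines, sprintf(
        "%s\triptide\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; exon_number \"%d\"; gene_biotype \"%s\";",
        td$chrom, td$start, td$end, td$strand, gid, tid, td$exon_rank, bt[[gid]]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation from GTF/GFF
#'
#' Imports exon features via rtracklayer and rebuilds the `gene_annotation`
#' container used throughout the package. Transcripts are reconstructed from
#' `transcript_id`; exon ranks follow transcription order. Gene biotype is
#' taken from a `gene_biotype` attribute when present (default
#' `protein_coding`).
#'
#' @param path GTF/GFF file.
#' @param seqlengths optional named vector of chromosome lengths; inferred
#'   from the furthest feature when missing.
#' @return a `gene_annotation`.
#' @export
read_annotation <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path)
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(ex)) stop("no exon features found in ", path)
  gene_id <- as.character(mcols(ex)$gene_id)
  transcript_id <- as.character(mcols(ex)$transcript_id)
  biotype <- if ("gene_biotype" %in% names(mcols(gr))) {
    gn <- gr[tolower(as.character(gr$type)) == "gene"]
    setNames(as.character(mcols(gn)$gene_biotype), as.character(mcols(gn)$gene_id))
  } else NULL
  if (is.null(seqlengths)) {
    seqlengths <- vapply(split(end(ex), as.character(seqnames(ex))), max, numeric(1))
  }
  build_annotation_from_exons(
    data.frame(chrom = as.character(seqnames(ex)), start = start(ex),
               end = end(ex), strand = as.character(strand(ex)),
               gene_id = gene_id, transcript_id = transcript_id,
               stringsAsFactors = FALSE),
    biotype = biotype, seqlengths = seqlengths)
}

## Shared constructor used by read_annotation() and test fixtures.
build_annotation_from_exons <- function(df, biotype = NULL, seqlengths = NULL) {
  stopifnot(all(c("chrom", "start", "end", "strand", "gene_id", "transcript_id") %in%
                  names(df)))
  if (is.null(seqlengths)) {
    seqlengths <- vapply(split(df$end, df$chrom), function(e) max(e) + 1000, numeric(1))
  }
  df <- df[order(df$gene_id, df$transcript_id, df$start), ]
  df$exon_rank <- NA_integer_
  for (i in split(seq_len(nrow(df)), df$transcript_id)) {
    r <- seq_along(i)
    if (df$strand[i[1]] == "-") r <- rev(r)
    df$exon_rank[i] <- r
  }
  exons <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                   gene_id = df$gene_id, transcript_id = df$transcript_id,
                   exon_rank = df$exon_rank, seqlengths = seqlengths)
  gsp <- split(seq_len(nrow(df)), df$gene_id)
  gene_ids <- names(gsp)
  genes <- GRanges(
    vapply(gsp, function(i) df$chrom[i[1]], character(1)),
    IRanges(vapply(gsp, function(i) min(df$start[i]), numeric(1)),
            vapply(gsp, function(i) max(df$end[i]), numeric(1))),
    strand = vapply(gsp, function(i) df$strand[i[1]], character(1)),
    gene_id = gene_ids,
    biotype = if (is.null(biotype)) "protein_coding" else
      unname(ifelse(is.na(biotype[gene_ids]), "protein_coding", biotype[gene_ids])),
    seqlengths = seqlengths)
  names(genes) <- gene_ids
  structure(list(genes = genes, exons = exons, seqlengths = seqlengths,
                 event_templates = list()),
            class = "gene_annotation")
}

## Per-gene exon-union GRangesList (reduced, same strand as gene).
exon_union <- function(ann) {
  grl <- split(ann$exons, mcols(ann$exons)$gene_id)
  reduce(grl)
}
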