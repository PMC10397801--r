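#' Quantify inclusion ratios per event and sample
#'
#' The inclusion ratio of an event in one sample is `I / (I + E)`, where `I`
#' is the mean read count over the event's inclusion junctions and `E` the
#' mean over its exclusion junctions (junctions absent from the table count
#' zero). The ratio is missing (`NA`) when `I + E` falls below `min_reads`.
#'
#' @param events a `splice_events` list.
#' @param junctions a junction table with one count column per sample.
#' @param samples sample columns to quantify; defaults to all count columns.
#' @param min_reads minimum summed junction evidence to define a ratio.
#' @return numeric matrix (events x samples) of ratios in `[0, 1]` or `NA`.
#' @export
quantify_ratios <- function(events, junctions, samples = NULL, min_reads = 10) {
  cnt_cols <- setdiff(names(junctions), c("chrom", "left", "right", "strand"))
  if (is.null(samples)) samples <- cnt_cols
  stopifnot(all(samples %in% cnt_cols))
  key <- paste(junctions$chrom, junctions$left, junctions$right,
               junctions$strand, sep = "\r")
  ratios <- matrix(NA_real_, length(events), length(samples),
                   dimnames = list(vapply(events, `[[`, character(1), "event_id"),
                                   samples))
  counts_of <- function(e, side, s) {
    js <- e[[side]]
    m <- match(paste(e$chrom, js$left, js$right, e$strand, sep = "\r"), key)
    v <- ifelse(is.na(m), 0, junctions[[s]][m])
    mean(v)
  }
  for (i in seq_along(events)) {
    for (j in seq_along(samples)) {
      I <- counts_of(events[[i]], "inclusion", samples[j])
      E <- counts_of(events[[i]], "exclusion", samples[j])
      if (I + E >= min_reads && I + E > 0) ratios[i, j] <- I / (I + E)
    }
  }
  ratios
}

#' Test for regulated splicing changes between conditions
#'
#' Per event, the per-replicate inclusion ratios of the two conditions are
#' compared with a two-sample Student's t-test (equal variances by default;
#' set `var_equal = FALSE` for Welch). P-values are adjusted with the
#' Benjamini-Hochberg procedure across all tested events jointly, and an
#' event is called significant when its FDR is at or below `fdr_cutoff`.
#' Events with fewer than two non-missing ratios in either condition are
#' skipped (counted in the `n_skipped` attribute). `delta_ratio` is the
#' treatment mean minus the reference mean, conditions taken in the order
#' they appear in `design`.
#'
#' @param ratios matrix from [quantify_ratios()].
#' @param design data.frame with columns `sample` and `condition`
#'   (two conditions; the first occurring condition is the reference).
#' @param fdr_cutoff significance threshold on the BH-adjusted p-value.
#' @param var_equal use the equal-variance (Student) t-test.
#' @return data.frame with one row per tested event: `event_id`,
#'   `mean_ref`, `mean_alt`, `delta_ratio`, `t_statistic`, `p_value`,
#'   `fdr`, `significant`.
#' @export
test_rase <- function(ratios, design, fdr_cutoff = 0.05, var_equal = TRUE) {
  stopifnot(all(c("sample", "condition") %in% names(design)),
            all(design$sample %in% colnames(ratios)))
  conds <- unique(design$condition)
  if (length(conds) != 2) stop("design must contain exactly two conditions")
  ref_s <- design$sample[design$condition == conds[1]]
  alt_s <- design$sample[design$condition == conds[2]]
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(ratios))) {
    x <- ratios[i, ref_s]
    y <- ratios[i, alt_s]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      ## degenerate: no within-group variability
      tt <- list(statistic = if (mean(y) == mean(x)) 0 else Inf * sign(mean(y) - mean(x)),
                 p.value = if (mean(y) == mean(x)) 1 else 0)
    } else {
      ht <- t.test(y, x, var.equal = var_equal)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = rownames(ratios)[i],
      mean_ref = mean(x), mean_alt = mean(y),
      delta_ratio = mean(y) - mean(x),
      t_statistic = tt$statistic, p_value = tt$p.value,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    res <- data.frame(event_id = character(0), mean_ref = numeric(0),
                      mean_alt = numeric(0), delta_ratio = numeric(0),
                      t_statistic = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), significant = logical(0))
    attr(res, "n_skipped") <- n_skipped
    return(res)
  }
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p_value)
  res$significant <- res$fdr <= fdr_cutoff
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}
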