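#' Fraction of enzyme-low cells by the control-median gate
#'
#' Edited, protein-depleted cells are defined as those whose fluorescence
#' intensity falls strictly below the median of the control population; the
#' returned fraction estimates knockout efficiency. Against an identically
#' distributed population the gate returns ~0.5 by construction.
#'
#' @param test,control Tibbles with an `intensity` column (or bare numeric
#'   vectors), one row per cell.
#' @return Fraction in \[0, 1\].
#' @export
enzyme_low_fraction <- function(test, control) {
  ti <- if (is.data.frame(test)) test$intensity else test
  ci <- if (is.data.frame(control)) control$intensity else control
  if (!length(ti) || !length(ci)) abort("Both populations must be non-empty.")
  mean(ti < median(ci))
}

#' Score a candidate clone as knockout against a depleted reference
#'
#' A clone is scored KO when its mean signal lies within `k` standard
#' deviations of the reference population's mean (closed interval, default
#' k = 2) -- the reference being a population with the mark fully depleted,
#' e.g. cells treated with a selective catalytic inhibitor.
#'
#' @param clone_mean Mean signal of the clone (scalar or vector of clones).
#' @param reference Tibble with `intensity` (>= 2 cells) or numeric vector.
#' @param k Gate half-width in reference SDs (default 2).
#' @param clone_id Optional labels for the output.
#' @return Tibble: `clone_id`, `mean_signal`, `reference_mean`,
#'   `reference_sd`, `k`, `is_ko`.
#' @export
score_clone_ko <- function(clone_mean, reference, k = 2, clone_id = NULL) {
  ri <- if (is.data.frame(reference)) reference$intensity else reference
  if (length(ri) < 2) abort("Reference needs >= 2 cells for a defined SD.")
  m <- mean(ri); s <- sd(ri)
  if (s == 0) warn("Reference SD is 0; only exact equality scores KO.")
  tibble(
    clone_id = clone_id %||% sprintf("clone%d", seq_along(clone_mean)),
    mean_signal = clone_mean,
    reference_mean = m,
    reference_sd = s,
    k = k,
    is_ko = abs(clone_mean - m) <= k * s
  )
}

#' Compare growth rates via per-replicate log-linear slopes
#'
#' Fits, for each replicate, the least-squares slope of `log2(signal)`
#' against time restricted to the closed `window` (default 24-48 h), then
#' compares the two conditions' slope sets with a two-sided two-sample
#' t-test. With zero slope variance in both groups the test is degenerate:
#' equal means give t = 0, P = 1; unequal means are flagged with a missing P.
#'
#' @param curves Tibble: `condition`, `replicate`, `time`, `signal`, with
#'   exactly two conditions (or use `conditions` to pick two).
#' @param window Closed time window in hours.
#' @param conditions Optional length-2 character to select/order conditions.
#' @param var_equal Pooled (default) or Welch test.
#' @return One-row tibble: `condition_a`, `condition_b`, `slope_a`,
#'   `slope_b`, `t_stat`, `p_value`, `df`, `degenerate`, plus a
#'   `replicate_slopes` list-column.
#' @export
growth_rate_test <- function(curves, window = c(24, 48), conditions = NULL,
                             var_equal = TRUE) {
  stopifnot(all(c("condition", "replicate", "time", "signal") %in% names(curves)))
  conditions <- conditions %||% unique(curves$condition)
  if (length(conditions) != 2) abort("Exactly two conditions are compared.")
  win <- curves %>%
    filter(.data$condition %in% conditions,
           .data$time >= window[1], .data$time <= window[2])
  cover <- win %>%
    group_by(.data$condition, .data$replicate) %>%
    summarise(n_t = n_distinct(.data$time), .groups = "drop")
  if (nrow(cover) == 0 || any(cover$n_t < 2)) {
    abort(sprintf("Every replicate needs >= 2 timepoints inside the closed %g-%g h window.",
                  window[1], window[2]))
  }
  slopes <- win %>%
    group_by(.data$condition, .data$replicate) %>%
    summarise(slope = unname(coef(lm(log2(.data$signal) ~ .data$time))[2]),
              .groups = "drop")
  sa <- slopes$slope[slopes$condition == conditions[1]]
  sb <- slopes$slope[slopes$condition == conditions[2]]
  if (length(sa) < 2 || length(sb) < 2) abort("Need >= 2 replicates per condition.")

  if (sd(sa) == 0 && sd(sb) == 0) {
    degen <- mean(sa) != mean(sb)
    t_stat <- if (degen) Inf * sign(mean(sa) - mean(sb)) else 0
    p <- if (degen) NA_real_ else 1
    df <- length(sa) + length(sb) - 2
  } else {
    tt <- stats::t.test(sa, sb, var.equal = var_equal)
    t_stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
    degen <- FALSE
  }
  tibble(
    condition_a = conditions[1], condition_b = conditions[2],
    slope_a = mean(sa), slope_b = mean(sb),
    t_stat = t_stat, p_value = p, df = df, degenerate = degen,
    replicate_slopes = list(slopes)
  )
}

# normalize/validate a peak tibble (0-based half-open)
validate_peaks <- function(peaks, strict = FALSE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  bad <- peaks$start >= peaks$end
  if (any(bad)) abort("Invalid intervals: start must be < end (0-based half-open).")
  srt <- arrange(as_tibble(peaks), .data$chrom, .data$start, .data$end)
  if (strict && !identical(srt$start, peaks$start)) abort("Peaks are not sorted within chromosome.")
  srt
}

#' Consensus peaks across replicates
#'
#' Retains signal regions supported by every replicate of a condition:
#' peaks are first filtered by `fold_change >= min_fold` (inclusive,
#' default 5), then a region is kept if at least one filtered peak from
#' *each* replicate overlaps it by >= `min_overlap` bp (default 1). The
#' consensus interval is the union of the overlapping replicate intervals.
#' The result is invariant to replicate order and idempotent.
#'
#' @param replicate_peaks List of peak tibbles (`chrom`, `start`, `end`,
#'   `fold_change`), one per replicate, 0-based half-open coordinates. Use
#'   `one_based = TRUE` for 1-based closed inputs.
#' @param min_fold Inclusive fold-change cutoff (default 5).
#' @param min_overlap Minimum overlap in bp for "presence" (default 1).
#' @param one_based Convert 1-based closed input coordinates.
#' @return Peak tibble: `chrom`, `start`, `end`, `n_replicates`.
#' @export
consensus_peaks <- function(replicate_peaks, min_fold = 5, min_overlap = 1L,
                            one_based = FALSE) {
  stopifnot(is.list(replicate_peaks), length(replicate_peaks) >= 1)
  reps <- purrr::map(replicate_peaks, function(p) {
    p <- as_tibble(p)
    if (one_based) p$start <- p$start - 1L
    if (!"fold_change" %in% names(p)) p$fold_change <- Inf
    validate_peaks(filter(p, .data$fold_change >= min_fold))
  })
  all_peaks <- bind_rows(reps, .id = ".rep")
  if (!nrow(all_peaks)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_replicates = integer()))
  }
  purrr::map(split(all_peaks, all_peaks$chrom), function(chr_peaks) {
    ir <- IRanges::IRanges(start = chr_peaks$start + 1L, end = chr_peaks$end)
    merged <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(merged, ir, minoverlap = min_overlap)
    support <- tibble(
      region = S4Vectors::queryHits(hits),
      rep = chr_peaks$.rep[S4Vectors::subjectHits(hits)],
      peak = S4Vectors::subjectHits(hits)
    )
    keep <- support %>%
      group_by(.data$region) %>%
      summarise(n_replicates = n_distinct(.data$rep), .groups = "drop") %>%
      filter(.data$n_replicates == length(reps))
    if (!nrow(keep)) return(NULL)
    # union of the contributing replicate intervals for each kept region
    support %>%
      semi_join(keep, by = "region") %>%
      mutate(start = chr_peaks$start[.data$peak], end = chr_peaks$end[.data$peak]) %>%
      group_by(.data$region) %>%
      summarise(chrom = chr_peaks$chrom[1], start = min(.data$start),
                end = max(.data$end), n_replicates = n_distinct(.data$rep),
                .groups = "drop") %>%
      select("chrom", "start", "end", "n_replicates")
  }) %>%
    purrr::compact() %>%
    bind_rows() -> out
  if (!nrow(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_replicates = integer()))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Differential peak labelling on precomputed statistics
#'
#' Applies the published retention and differential criteria to a consensus
#' peak statistics table: peaks are retained when their log2 concentration
#' reaches `min_conc` (default 5) in at least one condition; a retained
#' peak is differential iff `|log2_fc| >= min_abs_log2fc` (inclusive,
#' default 1) and `fdr < max_fdr` (strict, default 1e-4). The unaffected
#' fraction is `1 - differential / retained`.
#'
#' @param stats Tibble with `log2_fc`, `fdr`, and either `log2_conc`
#'   (maximum over conditions) or `log2_conc_a`/`log2_conc_b`.
#' @param min_conc,min_abs_log2fc,max_fdr Thresholds as above.
#' @param compute_fdr If TRUE and `fdr` is absent, derive it from a
#'   `p_value` column by Benjamini-Hochberg; otherwise a missing `fdr` is an
#'   error.
#' @return List with class `ern_peak_calls`: `peaks` (input plus `retained`,
#'   `differential`), `n_retained`, `n_differential`,
#'   `unaffected_fraction`.
#' @export
differential_peaks <- function(stats, min_conc = 5, min_abs_log2fc = 1,
                               max_fdr = 1e-4, compute_fdr = FALSE) {
  stats <- as_tibble(stats)
  if (!"fdr" %in% names(stats)) {
    if (compute_fdr && "p_value" %in% names(stats)) {
      stats$fdr <- stats::p.adjust(stats$p_value, method = "BH")
    } else {
      abort("`stats` must carry an fdr column (or p_value with compute_fdr = TRUE).")
    }
  }
  conc_cols <- intersect(c("log2_conc", "log2_conc_a", "log2_conc_b"), names(stats))
  if (!length(conc_cols)) abort("`stats` must carry log2 concentration column(s).")
  conc_max <- do.call(pmax, c(unname(stats[conc_cols]), list(na.rm = TRUE)))

  peaks <- stats %>%
    mutate(
      retained = conc_max >= min_conc,
      differential = .data$retained &
        abs(.data$log2_fc) >= min_abs_log2fc & .data$fdr < max_fdr
    )
  n_ret <- sum(peaks$retained)
  n_diff <- sum(peaks$differential)
  structure(
    list(
      peaks = peaks, n_retained = n_ret, n_differential = n_diff,
      unaffected_fraction = if (n_ret > 0) 1 - n_diff / n_ret else NA_real_
    ),
    class = "ern_peak_calls"
  )
}

#' @export
print.ern_peak_calls <- function(x, ...) {
  cat(sprintf("%d peaks retained, %d differential (%.1f%% unaffected)\n",
              x$n_retained, x$n_differential, 100 * x$unaffected_fraction))
  invisible(x)
}
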