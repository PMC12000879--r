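# Shared fixture builders: everything is generated in code at test time.

# tiny library: n targets in up to 2 classes + TNP2 control
tiny_library <- function(n = 4, paralogue_fraction = 0) {
  build_default_library(
    n_targets = n,
    classes = c("lysine acetylation", "chromatin remodeling"),
    paralogue_fraction = paralogue_fraction,
    seed = 11
  )
}

# one-plate screen with explicit counts: controls all `control_count`,
# targets from a named vector gene -> count, single condition/replicate
manual_screen <- function(target_counts, control_count = 100,
                          n_controls = 3, condition = "WT", replicate = 1L) {
  wells <- ernscreen:::interior_wells()
  genes <- c(names(target_counts), rep("TNP2", n_controls))
  layout <- tibble::tibble(
    plate_id = "P1",
    well = wells[seq_along(genes)],
    gene_id = genes,
    is_control = genes == "TNP2"
  )
  screen <- tibble::tibble(
    plate_id = "P1",
    well = layout$well,
    gene_id = layout$gene_id,
    condition = condition,
    replicate = replicate,
    cell_count = c(unname(target_counts), rep(control_count, n_controls))
  )
  list(layout = layout, screen = screen)
}

# independent pooled two-sample t oracle (closed form, no lm)
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  est <- mean(b) - mean(a)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  stat <- est / se
  list(coefficient = est, std_error = se, statistic = stat,
       p = 2 * stats::pt(-abs(stat), n1 + n2 - 2))
}

# brute-force chi-square of homogeneity from observed/total count vectors
chisq_oracle <- function(observed, totals) {
  rate <- sum(observed) / sum(totals)
  exp1 <- totals * rate
  exp0 <- totals * (1 - rate)
  obs0 <- totals - observed
  sum((observed - exp1)^2 / exp1 + (obs0 - exp0)^2 / exp0)
}

# brute-force consensus-peak oracle: all-pairs overlap enumeration on one
# chromosome; returns union intervals supported by every replicate
consensus_oracle <- function(reps, min_fold = 5) {
  reps <- lapply(reps, function(p) p[p$fold_change >= min_fold, , drop = FALSE])
  all <- do.call(rbind, reps)
  if (!nrow(all)) return(all[, c("start", "end")])
  # merge everything base by base; a merged run of bases is kept if every
  # replicate has a peak overlapping the run
  bases <- sort(unique(unlist(Map(seq, all$start, all$end - 1))))
  runs <- split(bases, cumsum(c(1, diff(bases) != 1)))
  keep <- Filter(function(r) {
    lo <- min(r); hi <- max(r) + 1
    all(vapply(reps, function(p) any(p$start < hi & p$end > lo), logical(1)))
  }, runs)
  out <- do.call(rbind, lapply(keep, function(r) {
    lo <- min(r); hi <- max(r) + 1
    contrib <- all[all$start < hi & all$end > lo, , drop = FALSE]
    data.frame(start = min(contrib$start), end = max(contrib$end))
  }))
  if (is.null(out)) return(data.frame(start = integer(), end = integer()))
  out[order(out$start), , drop = FALSE]
}
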