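#' Per-gene fitness scores from an arrayed knockout screen
#'
#' For each well, condition and replicate, the score is
#' `log2(cell_count / mean(negative-control counts on the same plate, same
#' condition and replicate))`; control wells are scored against the same
#' control mean. Because both numerator and denominator sit on one plate,
#' any plate-wide multiplicative effect cancels. Per-replicate scores are
#' then averaged into a mean with its SEM, matching the mean +- SEM of
#' replicates convention of arrayed screens.
#'
#' @param screen Screen tibble (`plate_id`, `well`, `gene_id`, `condition`,
#'   `replicate`, `cell_count`).
#' @param layout Plate layout tibble with `is_control`.
#' @param pseudo_count Added to every count before the ratio; 0 (default)
#'   makes non-positive counts or control means an error.
#' @return A tibble with class `ern_fitness`: one row per
#'   (plate, well, gene, condition) with `replicate_scores` (list-column),
#'   `mean_score`, `sem`, `n_reps`, `is_control`.
#' @export
compute_fitness_scores <- function(screen, layout, pseudo_count = 0) {
  screen <- validate_screen(screen)
  layout <- validate_layout(layout)
  scr <- screen %>%
    inner_join(select(layout, "plate_id", "well", "is_control"),
               by = c("plate_id", "well"))
  if (nrow(scr) < nrow(screen)) abort("Screen records refer to wells absent from the layout.")

  ctrl_means <- scr %>%
    filter(.data$is_control) %>%
    group_by(.data$plate_id, .data$condition, .data$replicate) %>%
    summarise(control_mean = mean(.data$cell_count + pseudo_count), .groups = "drop")
  missing_ctrl <- anti_join(
    distinct(scr, .data$plate_id, .data$condition, .data$replicate),
    ctrl_means, by = c("plate_id", "condition", "replicate")
  )
  if (nrow(missing_ctrl)) abort("Every plate needs >= 1 negative-control well per condition and replicate.")
  if (any(ctrl_means$control_mean <= 0)) abort("Control mean <= 0; supply a pseudo_count to proceed.")
  if (any(scr$cell_count + pseudo_count <= 0)) abort("Non-positive cell_count; supply a pseudo_count to proceed.")

  per_rep <- scr %>%
    left_join(ctrl_means, by = c("plate_id", "condition", "replicate")) %>%
    mutate(score = log2((.data$cell_count + pseudo_count) / .data$control_mean))

  out <- per_rep %>%
    group_by(.data$plate_id, .data$well, .data$gene_id, .data$condition, .data$is_control) %>%
    summarise(
      replicate_scores = list(.data$score[order(.data$replicate)]),
      mean_score = mean(.data$score),
      sem = if (n() > 1) sd(.data$score) / sqrt(n()) else NA_real_,
      n_reps = n(),
      .groups = "drop"
    ) %>%
    arrange(.data$condition, .data$plate_id, .data$well)
  class(out) <- unique(c("ern_fitness", class(out)))
  out
}

#' Half-maximal-effect threshold for indispensability
#'
#' Genes whose fitness effect is stronger than half the maximal observed
#' effect are called indispensable. By default the threshold is half the
#' minimum mean target score; it can be overridden with a fixed value, as
#' done for lines whose worst knockouts trend toward eradication (where the
#' published threshold was fixed at -1).
#'
#' @param scores An `ern_fitness` tibble (one condition).
#' @param override Optional fixed threshold; returned as-is when supplied.
#' @return A single threshold on the log2 fitness scale.
#' @export
half_maximal_threshold <- function(scores, override = NULL) {
  if (!is.null(override)) return(override)
  target_scores <- scores$mean_score[!scores$is_control]
  if (!length(target_scores)) abort("No target scores supplied.")
  min(0, min(target_scores)) / 2
}

#' Three-tier dispensability classification
#'
#' Partitions target genes by mean fitness score: fully dispensable when the
#' score lies within the closed observed range of negative-control scores;
#' indispensable when strictly below the half-maximal threshold; partially
#' dispensable otherwise. Scores equal to a control-range endpoint are fully
#' dispensable ("within the observed range"); a score exactly at the
#' half-maximal threshold is only partially dispensable ("stronger than").
#'
#' @param scores An `ern_fitness` tibble for one condition, containing both
#'   target and control rows (controls define the range unless
#'   `control_range` is given).
#' @param half_max Threshold from [half_maximal_threshold()].
#' @param control_range Optional numeric `c(min, max)` replacing the range
#'   observed in `scores`.
#' @return Tibble with class `ern_dispensability`: `gene_id`, `mean_score`,
#'   `call` (factor fully_dispensable/partially_dispensable/indispensable),
#'   plus `control_min`, `control_max`, `half_max` columns.
#' @export
classify_dispensability <- function(scores, half_max, control_range = NULL) {
  if (length(unique(scores$condition)) > 1) {
    abort("Classify one condition at a time.")
  }
  if (is.null(control_range)) {
    ctrl <- scores$mean_score[scores$is_control]
    if (!length(ctrl)) abort("No control wells in `scores`; supply `control_range`.")
    control_range <- range(ctrl)
  }
  if (half_max >= control_range[1]) {
    abort(sprintf(
      "Half-maximal threshold (%.4g) must lie below the control-range minimum (%.4g); the two regimes would overlap.",
      half_max, control_range[1]
    ))
  }
  out <- scores %>%
    filter(!.data$is_control) %>%
    mutate(
      call = factor(
        case_when(
          .data$mean_score >= control_range[1] & .data$mean_score <= control_range[2] ~ "fully_dispensable",
          .data$mean_score < half_max ~ "indispensable",
          TRUE ~ "partially_dispensable"
        ),
        levels = c("fully_dispensable", "partially_dispensable", "indispensable")
      ),
      control_min = control_range[1],
      control_max = control_range[2],
      half_max = half_max
    ) %>%
    select("gene_id", "condition", "mean_score", "call",
           "control_min", "control_max", "half_max")
  class(out) <- unique(c("ern_dispensability", class(out)))
  out
}
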