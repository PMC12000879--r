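#' Plate offsets: mean log2 negative-control count
#'
#' The interaction model removes systematic plate effects by subtracting,
#' from every log2 count, the mean of the *log2-transformed* control counts
#' of the same plate, condition and replicate. Note this deliberately
#' differs from the fitness-score normalization, which divides by the mean
#' of the *raw* control counts.
#'
#' @inheritParams compute_fitness_scores
#' @return Tibble: `plate_id`, `condition`, `replicate`, `offset`.
#' @export
plate_offsets <- function(screen, layout) {
  screen <- validate_screen(screen)
  layout <- validate_layout(layout)
  screen %>%
    inner_join(select(layout, "plate_id", "well", "is_control"),
               by = c("plate_id", "well")) %>%
    filter(.data$is_control) %>%
    group_by(.data$plate_id, .data$condition, .data$replicate) %>%
    summarise(offset = mean(log2(.data$cell_count)), .groups = "drop")
}

# core Wald machinery on offset-adjusted values; equivalent to OLS with an
# intercept and a binary condition indicator, i.e. a pooled two-sample t
fit_condition_effect <- function(y_ref, y_test, wald = c("t", "normal")) {
  wald <- match.arg(wald)
  n1 <- length(y_ref); n2 <- length(y_test)
  n_obs <- n1 + n2
  fit <- lm(y ~ cond, data = data.frame(
    y = c(y_ref, y_test),
    cond = factor(rep(c("ref", "test"), c(n1, n2)), levels = c("ref", "test"))
  ))
  beta <- unname(coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  # guard against pure floating-point residue in constant-within-group input
  scale <- mean(c(y_ref, y_test)^2)
  if (rss <= scale * 1e-24) rss <- 0
  if (abs(beta) <= sqrt(max(scale, 1)) * 1e-12) beta <- 0
  df <- n_obs - 2L
  se <- sqrt(rss / df * (1 / n1 + 1 / n2))
  degenerate <- FALSE
  if (se == 0) {
    if (abs(beta) < .Machine$double.eps^0.5) {
      p <- 1; stat <- 0
    } else {
      p <- 0; stat <- Inf; degenerate <- TRUE  # lower limit of the reference distribution
    }
  } else {
    stat <- beta / se
    p <- if (wald == "t") 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  }
  tibble(coefficient = beta, std_error = se, statistic = stat,
         wald_p = p, n_obs = n_obs, df = df, degenerate = degenerate)
}

#' Fit the per-gene offset model for one gene
#'
#' Ordinary least squares on offset-adjusted values
#' `y' = log2(count) - offset` with an intercept and a binary condition
#' indicator -- the per-gene form of
#' `lm(log_value ~ offset(log_plate_controls) + Condition)`. The condition
#' coefficient estimates the genetic-interaction effect on the log2 scale
#' and is tested with a two-sided Wald test. With few replicates the exact
#' reference under the Gaussian model is t with `n_obs - 2` df (default);
#' `wald = "normal"` selects the asymptotic normal reference.
#'
#' @param adjusted_ref,adjusted_test Offset-adjusted log2 values in the
#'   reference and test condition (>= 2 each).
#' @param wald `"t"` (default) or `"normal"` reference distribution.
#' @return One-row tibble: `coefficient`, `std_error`, `statistic`,
#'   `wald_p`, `n_obs`, `df`, `degenerate`.
#' @export
fit_interaction_model <- function(adjusted_ref, adjusted_test, wald = c("t", "normal")) {
  if (length(adjusted_ref) < 2 || length(adjusted_test) < 2) {
    abort("Need >= 2 replicates per condition for a defined Wald test.")
  }
  fit_condition_effect(adjusted_ref, adjusted_test, wald)
}

#' Genome-wide genetic-interaction tests from a screen table
#'
#' Applies the offset model separately to each target gene, comparing a test
#' background condition against the reference, with per-plate mean log2
#' control counts as offsets.
#'
#' @inheritParams compute_fitness_scores
#' @param reference,test Condition labels to compare.
#' @param wald Reference distribution, see [fit_interaction_model()].
#' @return Tibble with class `ern_interactions`: one row per target gene
#'   with the model columns plus `reference` and `test`.
#' @export
fit_interactions <- function(screen, layout, reference = "WT", test = "KO",
                             wald = c("t", "normal")) {
  wald <- match.arg(wald)
  screen <- validate_screen(screen)
  layout <- validate_layout(layout)
  if (!all(c(reference, test) %in% screen$condition)) {
    abort("`reference` and `test` must both appear in the screen table.")
  }
  offs <- plate_offsets(screen, layout)
  adj <- screen %>%
    inner_join(select(layout, "plate_id", "well", "is_control"),
               by = c("plate_id", "well")) %>%
    filter(!.data$is_control, .data$condition %in% c(reference, test)) %>%
    left_join(offs, by = c("plate_id", "condition", "replicate")) %>%
    mutate(adjusted = log2(.data$cell_count) - .data$offset)

  out <- adj %>%
    group_by(.data$gene_id) %>%
    summarise(fit_condition_effect(
      .data$adjusted[.data$condition == reference],
      .data$adjusted[.data$condition == test],
      wald = wald
    ), .groups = "drop") %>%
    mutate(reference = reference, test = test)
  class(out) <- unique(c("ern_interactions", class(out)))
  out
}

#' Call significant genetic interactors
#'
#' A gene is an interactor iff `wald_p < p_threshold` and
#' `|coefficient| > coef_threshold`, both strict -- the raw-P dual criterion
#' used for synthetic-sick calling (defaults P < 1e-3, |coef| > 0.2 on the
#' log2 scale). No multiple-testing correction is applied.
#'
#' @param tests Output of [fit_interactions()] (or any tibble with
#'   `gene_id`, `coefficient`, `wald_p`).
#' @param p_threshold,coef_threshold Strict cutoffs.
#' @return `tests` with added `is_interactor`, `direction`, `p_threshold`,
#'   `coef_threshold`; class `ern_interaction_calls`.
#' @export
call_interactions <- function(tests, p_threshold = 1e-3, coef_threshold = 0.2) {
  stopifnot(p_threshold > 0, coef_threshold >= 0)
  out <- tests %>%
    mutate(
      is_interactor = .data$wald_p < p_threshold & abs(.data$coefficient) > coef_threshold,
      direction = sign(.data$coefficient),
      p_threshold = p_threshold,
      coef_threshold = coef_threshold
    )
  class(out) <- unique(c("ern_interaction_calls", class(out)))
  out
}

#' Classify interaction phenotypes across transformation
#'
#' Compares interactor calls made in an untransformed and a transformed
#' background over the same gene universe: `unique` = significant only upon
#' transformation; `enhanced` = significant in both with a more-negative
#' transformed coefficient; `shared_unchanged` = significant in both
#' otherwise; `none` = neither (genes significant only when untransformed
#' are flagged in `untransformed_only`).
#'
#' @param untransformed,transformed Outputs of [call_interactions()] for the
#'   two contexts.
#' @return Tibble: `gene_id`, `class`, `coefficient_untransformed`,
#'   `coefficient_transformed`, `untransformed_only`.
#' @export
classify_transformation_phenotypes <- function(untransformed, transformed) {
  diff1 <- setdiff(untransformed$gene_id, transformed$gene_id)
  diff2 <- setdiff(transformed$gene_id, untransformed$gene_id)
  if (length(diff1) || length(diff2)) {
    abort(paste0(
      "Call sets cover different gene universes. Only untransformed: ",
      paste(diff1, collapse = ", "), "; only transformed: ",
      paste(diff2, collapse = ", ")
    ))
  }
  full_join(
    select(as_tibble(untransformed), "gene_id",
           coefficient_untransformed = "coefficient", sig_u = "is_interactor"),
    select(as_tibble(transformed), "gene_id",
           coefficient_transformed = "coefficient", sig_t = "is_interactor"),
    by = "gene_id"
  ) %>%
    mutate(
      class = factor(
        case_when(
          .data$sig_t & !.data$sig_u ~ "unique",
          .data$sig_t & .data$sig_u &
            .data$coefficient_transformed < .data$coefficient_untransformed ~ "enhanced",
          .data$sig_t & .data$sig_u ~ "shared_unchanged",
          TRUE ~ "none"
        ),
        levels = c("enhanced", "unique", "shared_unchanged", "none")
      ),
      untransformed_only = .data$sig_u & !.data$sig_t
    ) %>%
    select("gene_id", "class", "coefficient_untransformed",
           "coefficient_transformed", "untransformed_only")
}

#' Export interaction calls as an edge list
#'
#' Simple (gene, background, coefficient, class) edge list consumable by
#' graph tools; only significant interactors are emitted.
#'
#' @param calls Output of [call_interactions()].
#' @param background Label of the sensitized background (defaults to the
#'   test condition recorded in `calls`).
#' @export
interaction_edges <- function(calls, background = NULL) {
  background <- background %||% unique(calls$test)
  calls %>%
    filter(.data$is_interactor) %>%
    mutate(background = background) %>%
    select("gene_id", "background", "coefficient", "wald_p")
}
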