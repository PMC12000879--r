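#' Percent relative abundance of modified peptide forms
#'
#' For every (sample, replicate, peptide) group and each channel, the %RA of
#' a form is its area divided by the summed areas of all observed forms of
#' that peptide, times 100. The light channel is the sample, the heavy
#' channel the spiked-in labelled internal standard; their ratio
#' `lh_ratio = ra_light / ra_heavy` is the standard-referenced quantity used
#' downstream. Forms with zero heavy %RA get a missing ratio, and a group
#' whose areas are all zero in a channel is flagged undetected (missing %RA,
#' never zeros).
#'
#' @param areas Long tibble: `sample_id`, `replicate`, `peptide_id`,
#'   `form_id`, `area_light`, `area_heavy`.
#' @return Tibble with class `ern_ptm_quant`: the input keys plus
#'   `ra_light`, `ra_heavy`, `lh_ratio`.
#' @export
quantify_ptm <- function(areas) {
  req <- c("sample_id", "replicate", "peptide_id", "form_id", "area_light", "area_heavy")
  missing_cols <- setdiff(req, names(areas))
  if (length(missing_cols)) abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  if (any(areas$area_light < 0 | areas$area_heavy < 0, na.rm = TRUE)) {
    abort("Areas must be non-negative.")
  }
  out <- areas %>%
    group_by(.data$sample_id, .data$replicate, .data$peptide_id) %>%
    mutate(
      ra_light = relative_abundance(.data$area_light),
      ra_heavy = relative_abundance(.data$area_heavy)
    ) %>%
    ungroup() %>%
    mutate(lh_ratio = lh_ratio(.data$ra_light, .data$ra_heavy))
  class(out) <- unique(c("ern_ptm_quant", class(out)))
  out
}

#' @rdname quantify_ptm
#' @param form_areas Numeric areas of all forms of one peptide in one
#'   channel/replicate.
#' @return `relative_abundance()`: %RA values summing to 100, or all-NA when
#'   every area is zero (undetected group).
#' @export
relative_abundance <- function(form_areas) {
  total <- sum(form_areas)
  if (is.na(total) || total <= 0) return(rep(NA_real_, length(form_areas)))
  100 * form_areas / total
}

#' @rdname quantify_ptm
#' @param ra_light,ra_heavy %RA values of the two channels.
#' @return `lh_ratio()`: `ra_light / ra_heavy`, missing (NA) wherever
#'   `ra_heavy` is 0 or missing.
#' @export
lh_ratio <- function(ra_light, ra_heavy) {
  ifelse(is.na(ra_heavy) | ra_heavy == 0, NA_real_, ra_light / ra_heavy)
}

#' Differential histone-PTM calling against a reference sample
#'
#' For each peptide form, per-replicate log2 L/H ratios are expressed
#' relative to the mean of the reference sample's replicates; the mean of
#' these relative values is the form's log2 fold change. Significance comes
#' from a two-sided two-sample t-test (pooled by default, Welch optional) on
#' the log2 L/H ratios. A form is `up` iff `log2fc > upper` and
#' `p < p_threshold`, `down` iff `log2fc < lower` and `p < p_threshold`
#' (all strict); forms missing in any replicate of either sample are
#' `undetected`. The default interval (-0.41, 0.58) is the published
#' >1.5-fold boundary, kept as printed including its asymmetry.
#'
#' @param quant An `ern_ptm_quant` tibble covering reference and test
#'   samples.
#' @param reference Reference sample label (default `"WT"`).
#' @param lower,upper Strict log2 fold-change boundaries of the unchanged
#'   region (defaults -0.41 and 0.58).
#' @param p_threshold Strict P cutoff (default 0.01).
#' @param var_equal Pooled (TRUE, default) or Welch t-test.
#' @return Tibble with class `ern_ptm_calls`: one row per
#'   (sample, peptide, form) for non-reference samples with `mean_log2fc`,
#'   `p_value`, `call` (up/down/unchanged/undetected) and the thresholds.
#' @export
differential_ptm <- function(quant, reference = "WT", lower = -0.41,
                             upper = 0.58, p_threshold = 0.01,
                             var_equal = TRUE) {
  if (!reference %in% quant$sample_id) abort("`reference` sample not present.")
  ref <- quant %>%
    filter(.data$sample_id == reference) %>%
    group_by(.data$peptide_id, .data$form_id) %>%
    summarise(
      ref_log2 = list(log2(.data$lh_ratio)),
      ref_mean_log2 = mean(log2(.data$lh_ratio)),  # NA if any replicate missing
      .groups = "drop"
    )

  out <- quant %>%
    filter(.data$sample_id != reference) %>%
    group_by(.data$sample_id, .data$peptide_id, .data$form_id) %>%
    summarise(test_log2 = list(log2(.data$lh_ratio)), .groups = "drop") %>%
    left_join(ref, by = c("peptide_id", "form_id")) %>%
    mutate(purrr::map2(.data$test_log2, .data$ref_log2, ptm_form_test,
                       var_equal = var_equal) %>% bind_rows()) %>%
    mutate(
      mean_log2fc = .data$test_mean - .data$ref_mean_log2,
      call = factor(
        case_when(
          .data$undetected ~ "undetected",
          .data$mean_log2fc > upper & .data$p_value < p_threshold ~ "up",
          .data$mean_log2fc < lower & .data$p_value < p_threshold ~ "down",
          TRUE ~ "unchanged"
        ),
        levels = c("up", "down", "unchanged", "undetected")
      ),
      lower = lower, upper = upper, p_threshold = p_threshold
    ) %>%
    select("sample_id", "peptide_id", "form_id", "mean_log2fc", "p_value",
           "call", "lower", "upper", "p_threshold")
  class(out) <- unique(c("ern_ptm_calls", class(out)))
  out
}

# per-form two-sample t on log2 L/H values; missing replicates => undetected
ptm_form_test <- function(test_log2, ref_log2, var_equal = TRUE) {
  undetected <- is.null(ref_log2) || anyNA(test_log2) || anyNA(ref_log2) ||
    length(test_log2) < 2 || length(ref_log2) < 2
  if (undetected) {
    return(tibble(test_mean = mean(test_log2), p_value = NA_real_, undetected = TRUE))
  }
  if (sd(test_log2) == 0 && sd(ref_log2) == 0) {
    p <- if (mean(test_log2) == mean(ref_log2)) 1 else 0
  } else {
    p <- stats::t.test(test_log2, ref_log2, var.equal = var_equal)$p.value
  }
  tibble(test_mean = mean(test_log2), p_value = p, undetected = FALSE)
}
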