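#' Functional-class enrichment of a dispensability status
#'
#' Tests whether a call level (e.g. indispensable, or fully dispensable) is
#' homogeneously distributed across functional classes: one global chi-square
#' test of homogeneity on the status-by-class contingency table
#' (df = classes - 1; 7 df for the eight-class library), plus per-class
#' log2(observed / expected) ratios. Because expected counts are
#' proportional to class size, the ratio is identical whether computed on
#' proportions or on raw counts; both columns are returned.
#'
#' @param calls An `ern_dispensability` tibble.
#' @param library The `ern_library` supplying `functional_class`.
#' @param status Call level tested (default `"indispensable"`).
#' @return A list with class `ern_enrichment`: `by_class` tibble
#'   (`functional_class`, `n_genes`, `observed`, `expected`,
#'   `observed_prop`, `expected_prop`, `log2_ratio`) and `test` tibble
#'   (`chi2_stat`, `df`, `p_value`).
#' @export
class_enrichment <- function(calls, library,
                             status = c("indispensable", "fully_dispensable",
                                        "partially_dispensable")) {
  status <- match.arg(status)
  library <- validate_library(library)
  ann <- calls %>%
    inner_join(select(library, "gene_id", "functional_class"), by = "gene_id")
  if (any(is.na(ann$functional_class))) abort("Every called gene needs a functional class.")

  by_class <- ann %>%
    group_by(.data$functional_class) %>%
    summarise(n_genes = n(), observed = sum(.data$call == status), .groups = "drop")
  empty <- by_class$functional_class[by_class$n_genes == 0]
  if (length(empty)) {
    warn(paste0("Classes with zero members excluded: ", paste(empty, collapse = ", ")))
    by_class <- filter(by_class, .data$n_genes > 0)
  }
  if (nrow(by_class) < 2) abort("Need >= 2 functional classes for an enrichment test.")

  overall_rate <- sum(by_class$observed) / sum(by_class$n_genes)
  by_class <- by_class %>%
    mutate(
      expected = .data$n_genes * overall_rate,
      observed_prop = .data$observed / .data$n_genes,
      expected_prop = overall_rate,
      log2_ratio = ifelse(.data$observed == 0, -Inf,
                          log2(.data$observed / .data$expected))
    )

  tab <- rbind(by_class$observed, by_class$n_genes - by_class$observed)
  if (overall_rate %in% c(0, 1)) {
    test <- tibble(chi2_stat = 0, df = nrow(by_class) - 1L, p_value = 1)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    test <- tibble(chi2_stat = unname(ct$statistic), df = unname(ct$parameter),
                   p_value = unname(ct$p.value))
  }
  structure(list(by_class = by_class, test = test, status = status),
            class = "ern_enrichment")
}

#' Paralogue-status enrichment among indispensable genes
#'
#' 2x2 table (has paralogue x indispensable) tested by a plain two-tailed
#' chi-square (df = 1, no continuity correction by default, matching the
#' published test; set `yates = TRUE` for the corrected variant), with
#' log2(observed / expected) counts of indispensable genes in each
#' paralogue-status group. A group with zero observed indispensable genes
#' yields `log2_ratio = NA` flagged in `depleted_to_zero`.
#'
#' @inheritParams class_enrichment
#' @param status Call level tested (default `"indispensable"`).
#' @param yates Apply Yates continuity correction (default FALSE).
#' @return List with class `ern_enrichment`: `by_group` tibble and `test`.
#' @export
paralogue_enrichment <- function(calls, library, status = "indispensable",
                                 yates = FALSE) {
  library <- validate_library(library)
  ann <- calls %>%
    inner_join(select(library, "gene_id", "has_paralogue"), by = "gene_id")
  if (any(is.na(ann$has_paralogue))) abort("Paralogue annotation missing for some called genes.")

  by_group <- ann %>%
    mutate(group = ifelse(.data$has_paralogue, "paralogue", "singleton")) %>%
    group_by(.data$group) %>%
    summarise(n_genes = n(), observed = sum(.data$call == status), .groups = "drop")
  if (nrow(by_group) < 2 || any(by_group$n_genes == 0)) {
    abort("Degenerate 2x2 table: both paralogue-status groups must be populated.")
  }
  overall_rate <- sum(by_group$observed) / sum(by_group$n_genes)
  if (overall_rate %in% c(0, 1)) abort("Degenerate 2x2 table: status column is empty or full.")

  by_group <- by_group %>%
    mutate(
      expected = .data$n_genes * overall_rate,
      log2_ratio = ifelse(.data$observed == 0, NA_real_,
                          log2(.data$observed / .data$expected)),
      depleted_to_zero = .data$observed == 0
    )
  tab <- rbind(by_group$observed, by_group$n_genes - by_group$observed)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  structure(
    list(
      by_group = by_group,
      test = tibble(chi2_stat = unname(ct$statistic), df = unname(ct$parameter),
                    p_value = unname(ct$p.value)),
      status = status
    ),
    class = "ern_enrichment"
  )
}

#' Concordance of fitness landscapes between two cell lines
#'
#' Pearson correlation of per-gene mean fitness scores over the shared gene
#' universe, plus the overlap of dispensable gene sets: the fraction of the
#' query line's dispensable genes ("dispensable" = not indispensable, i.e.
#' fully + partially) that are also dispensable in the other line.
#'
#' @param scores_a,scores_b `ern_fitness` tibbles for the two lines
#'   (target rows used).
#' @param calls_a,calls_b Matching `ern_dispensability` tibbles; line b is
#'   the query for the overlap fraction.
#' @return One-row tibble: `pearson_r`, `p_value`, `n_genes`,
#'   `dispensable_overlap_fraction`.
#' @export
cross_line_concordance <- function(scores_a, scores_b, calls_a, calls_b) {
  shared <- inner_join(
    scores_a %>% filter(!.data$is_control) %>% select("gene_id", score_a = "mean_score"),
    scores_b %>% filter(!.data$is_control) %>% select("gene_id", score_b = "mean_score"),
    by = "gene_id"
  )
  if (nrow(shared) < 3) abort("Need >= 3 shared genes.")
  if (sd(shared$score_a) == 0 || sd(shared$score_b) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(shared$score_a, shared$score_b, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  disp_a <- calls_a$gene_id[calls_a$call != "indispensable"]
  disp_b <- calls_b$gene_id[calls_b$call != "indispensable"]
  overlap <- if (length(disp_b)) length(intersect(disp_b, disp_a)) / length(disp_b) else NA_real_
  tibble(pearson_r = r, p_value = p, n_genes = nrow(shared),
         dispensable_overlap_fraction = overlap)
}

#' @export
print.ern_enrichment <- function(x, ...) {
  cat("Enrichment of status '", x$status, "'\n", sep = "")
  print(x[[intersect(c("by_class", "by_group"), names(x))[1]]])
  cat(sprintf("chi2 = %.4g on %d df, P = %.3g\n",
              x$test$chi2_stat, x$test$df, x$test$p_value))
  invisible(x)
}
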