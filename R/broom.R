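#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-gene summaries of screen results
#'
#' Broom-style accessors: `tidy()` returns one row per gene with
#' standardized column names (`estimate`, `std.error`, `statistic`,
#' `p.value`), `glance()` a one-row model-level summary.
#'
#' @param x An `ern_fitness`, `ern_interactions` or `ern_interaction_calls`
#'   object.
#' @param ... Unused.
#' @name ern_tidiers
NULL

#' @rdname ern_tidiers
#' @export
tidy.ern_fitness <- function(x, ...) {
  x %>%
    filter(!.data$is_control) %>%
    select("gene_id", "condition", estimate = "mean_score", std.error = "sem")
}

#' @rdname ern_tidiers
#' @export
tidy.ern_interactions <- function(x, ...) {
  select(as_tibble(x), "gene_id", estimate = "coefficient",
         std.error = "std_error", statistic = "statistic", p.value = "wald_p")
}

#' @rdname ern_tidiers
#' @export
tidy.ern_interaction_calls <- function(x, ...) {
  select(as_tibble(x), "gene_id", estimate = "coefficient",
         std.error = "std_error", statistic = "statistic",
         p.value = "wald_p", "is_interactor")
}

#' @rdname ern_tidiers
#' @export
glance.ern_interactions <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    reference = unique(x$reference),
    test = unique(x$test),
    median_std_error = median(x$std_error),
    n_degenerate = sum(x$degenerate)
  )
}

#' @rdname ern_tidiers
#' @export
glance.ern_interaction_calls <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_interactors = sum(x$is_interactor),
    n_negative = sum(x$is_interactor & x$coefficient < 0),
    p_threshold = unique(x$p_threshold),
    coef_threshold = unique(x$coef_threshold)
  )
}

#' @rdname ern_tidiers
#' @export
glance.ern_dispensability <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_fully_dispensable = sum(x$call == "fully_dispensable"),
    n_partially_dispensable = sum(x$call == "partially_dispensable"),
    n_indispensable = sum(x$call == "indispensable"),
    prop_indispensable = mean(x$call == "indispensable")
  )
}
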