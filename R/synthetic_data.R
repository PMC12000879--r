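#' Planted true effects for a simulated screen
#'
#' Bundles the generative truth that [simulate_screen()] plants and that the
#' analysis should recover: a per-gene fitness effect (log2 scale, 0 for
#' neutral, negative for deleterious) and an optional per-(gene, condition)
#' interaction effect added only in that background condition. The
#' negative-control gene is forced to exactly 0.
#'
#' @param library An `ern_library` tibble; every gene gets a fitness effect.
#' @param fitness Optional tibble `gene_id`, `fitness_effect`; missing genes
#'   default to 0.
#' @param interaction Optional tibble `gene_id`, `condition`,
#'   `interaction_effect`.
#' @return A list with class `ern_true_effects` and elements `fitness` and
#'   `interaction` (tibbles).
#' @export
true_effects <- function(library, fitness = NULL, interaction = NULL) {
  library <- validate_library(library)
  base <- tibble(gene_id = library$gene_id, fitness_effect = 0)
  if (!is.null(fitness)) {
    stopifnot(all(c("gene_id", "fitness_effect") %in% names(fitness)))
    bad <- setdiff(fitness$gene_id, library$gene_id)
    if (length(bad)) abort(paste0("Unknown genes in fitness effects: ", paste(bad, collapse = ", ")))
    base <- base %>%
      left_join(fitness, by = "gene_id", suffix = c("", ".new")) %>%
      mutate(fitness_effect = dplyr::coalesce(.data$fitness_effect.new, .data$fitness_effect)) %>%
      select("gene_id", "fitness_effect")
  }
  ctrl <- library$gene_id[library$is_negative_control]
  base$fitness_effect[base$gene_id %in% ctrl] <- 0
  if (!all(is.finite(base$fitness_effect))) abort("Fitness effects must be finite.")

  inter <- interaction %||%
    tibble(gene_id = character(), condition = character(), interaction_effect = double())
  stopifnot(all(c("gene_id", "condition", "interaction_effect") %in% names(inter)))
  inter <- as_tibble(inter) %>% filter(!.data$gene_id %in% ctrl)
  if (!all(is.finite(inter$interaction_effect))) abort("Interaction effects must be finite.")

  structure(list(fitness = base, interaction = inter), class = "ern_true_effects")
}

#' Draw a random set of true effects emulating a regulator knockout screen
#'
#' Defaults reflect the landscape seen in somatic-cell regulator screens:
#' most knockouts are neutral, a minority (`partial_fraction`) mildly
#' deleterious and a small set (`indispensable_fraction`) strongly
#' deleterious; an optional subset of genes carries a synthetic-sick
#' interaction with the non-reference condition.
#'
#' @inheritParams true_effects
#' @param indispensable_fraction Fraction of targets with strong fitness
#'   effects (default 0.12).
#' @param partial_fraction Fraction with mild effects (default 0.20).
#' @param strong_range,mild_range Uniform ranges (log2) for the two groups.
#' @param interacting_fraction Fraction of targets given an interaction
#'   effect in `interaction_condition` (default 0).
#' @param interaction_effect Planted interaction effect (default -0.6).
#' @param interaction_condition Condition label carrying the interaction.
#' @param seed Integer seed.
#' @export
simulate_true_effects <- function(library,
                                  indispensable_fraction = 0.12,
                                  partial_fraction = 0.20,
                                  strong_range = c(-3, -1),
                                  mild_range = c(-0.6, -0.15),
                                  interacting_fraction = 0,
                                  interaction_effect = -0.6,
                                  interaction_condition = "KO",
                                  seed = NULL) {
  library <- validate_library(library)
  targets <- library$gene_id[!library$is_negative_control]
  draw <- function() {
    n <- length(targets)
    n_strong <- round(indispensable_fraction * n)
    n_mild <- round(partial_fraction * n)
    shuffled <- sample(targets)
    eff <- tibble(
      gene_id = shuffled,
      fitness_effect = c(
        stats::runif(n_strong, strong_range[1], strong_range[2]),
        stats::runif(n_mild, mild_range[1], mild_range[2]),
        rep(0, n - n_strong - n_mild)
      )
    )
    inter <- NULL
    if (interacting_fraction > 0) {
      n_int <- round(interacting_fraction * n)
      inter <- tibble(
        gene_id = sample(targets, n_int),
        condition = interaction_condition,
        interaction_effect = interaction_effect
      )
    }
    true_effects(library, fitness = eff, interaction = inter)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulation settings for the arrayed screen generator
#'
#' @param plate_baseline Log2-count intercept, recycled over plates or a
#'   named vector by `plate_id`. Default 10 (~1000 cells/well at endpoint).
#' @param noise_sd Replicate noise sd on the log2 scale (default 0.15).
#' @param n_replicates Replicates per condition (default 3).
#' @param conditions Background-genotype labels; the first is the reference.
#' @param ko_escape_fraction Fraction of unedited cells in a knockout
#'   population (default 0.3, i.e. ~70% edited). Used as the default mixture
#'   weight in [simulate_if_intensities()] and by the optional
#'   `apply_ko_escape` attenuation of [simulate_screen()].
#' @param seed Integer seed.
#' @export
screen_sim_config <- function(plate_baseline = 10, noise_sd = 0.15,
                              n_replicates = 3, conditions = c("WT", "KO"),
                              ko_escape_fraction = 0.3, seed = NULL) {
  stopifnot(noise_sd >= 0, n_replicates >= 1, length(conditions) >= 1,
            ko_escape_fraction >= 0, ko_escape_fraction <= 1)
  structure(
    list(plate_baseline = plate_baseline, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates), conditions = conditions,
         ko_escape_fraction = ko_escape_fraction, seed = seed),
    class = "ern_sim_config"
  )
}

#' Simulate a per-well cell-count screen table
#'
#' For every well, condition and replicate, draws
#' `cell_count = 2^(plate_baseline + fitness_effect + interaction_effect + e)`
#' with `e ~ Normal(0, noise_sd)` on the log2 scale, i.e. multiplicative
#' noise on counts. The plate baseline is shared by all wells of a plate
#' within a condition, which is exactly the systematic effect the
#' negative-control normalization must cancel. Counts are left as reals so
#' that the noiseless pipeline is exact; set `integer_counts = TRUE` for
#' rounded realism.
#'
#' @param library,layout Library and plate layout covering it.
#' @param effects An `ern_true_effects` object; every gene in the layout must
#'   have a fitness effect.
#' @param config An [screen_sim_config()].
#' @param apply_ko_escape Attenuate planted effects for the unedited-cell
#'   fraction (default FALSE; see the methods vignette).
#' @param integer_counts Round counts to integers (default FALSE).
#' @return A screen tibble: `plate_id`, `well`, `gene_id`, `condition`,
#'   `replicate`, `cell_count`.
#' @export
simulate_screen <- function(library, layout, effects,
                            config = screen_sim_config(),
                            apply_ko_escape = FALSE,
                            integer_counts = FALSE) {
  library <- validate_library(library)
  layout <- validate_layout(layout)
  stopifnot(inherits(effects, "ern_true_effects"), inherits(config, "ern_sim_config"))
  missing_eff <- setdiff(layout$gene_id, effects$fitness$gene_id)
  if (length(missing_eff)) {
    abort(paste0("Layout genes absent from effects: ", paste(missing_eff, collapse = ", ")))
  }

  plates <- unique(layout$plate_id)
  baseline <- config$plate_baseline
  if (is.null(names(baseline))) {
    baseline <- setNames(rep_len(baseline, length(plates)), plates)
  }
  if (!all(plates %in% names(baseline))) abort("plate_baseline must cover every plate.")

  grid <- tidyr::expand_grid(
    layout,
    condition = config$conditions,
    replicate = seq_len(config$n_replicates)
  ) %>%
    left_join(effects$fitness, by = "gene_id") %>%
    left_join(effects$interaction, by = c("gene_id", "condition")) %>%
    mutate(
      interaction_effect = tidyr::replace_na(.data$interaction_effect, 0),
      total_effect = .data$fitness_effect + .data$interaction_effect
    )

  if (apply_ko_escape && config$ko_escape_fraction > 0) {
    f <- config$ko_escape_fraction
    grid <- grid %>%
      mutate(total_effect = ifelse(
        .data$is_control, 0,
        log2((1 - f) * 2^.data$total_effect + f)
      ))
  }

  draw <- function() stats::rnorm(nrow(grid), 0, config$noise_sd)
  eps <- if (config$noise_sd == 0) {
    rep(0, nrow(grid))
  } else if (is.null(config$seed)) draw() else with_seed(config$seed, draw())

  out <- grid %>%
    mutate(cell_count = 2^(unname(baseline[.data$plate_id]) + .data$total_effect + eps)) %>%
    select("plate_id", "well", "gene_id", "condition", "replicate", "cell_count")
  if (integer_counts) out$cell_count <- round(out$cell_count)
  validate_screen(out)
}

#' Simulate SILAC peptide areas with planted fold changes
#'
#' Generates light/heavy chromatographic areas for every modification form of
#' each peptide. Heavy areas follow the fixed internal-standard composition
#' (`true_ra`); light areas follow `true_ra` modulated by per-sample fold
#' changes. Because modification states of one peptide interconvert, a fold
#' change on one form is absorbed by a balance form (default `"unmod"`, else
#' the largest form without a planted fold) so the peptide's total abundance
#' is conserved -- with `noise_cv = 0` the downstream log2 L/H ratio relative
#' to the reference then equals `log2(fold)` exactly.
#'
#' @param true_ra Named list: peptide -> named numeric of reference %RA per
#'   form, each summing to 100 (+-1e-6).
#' @param fold_changes Named list: sample -> named list/vector
#'   peptide -> c(form = fold). Samples without entries are reference-like.
#' @param samples Character vector of sample labels; the first is taken as
#'   the reference when omitted from `fold_changes`.
#' @param total_abundance Total light area per peptide (arbitrary units).
#' @param heavy_abundance Total heavy (internal standard) area per peptide.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise on each area (default 0.1).
#' @param n_replicates Replicates per sample (default 3).
#' @param seed Integer seed.
#' @return Long tibble: `sample_id`, `replicate`, `peptide_id`, `form_id`,
#'   `area_light`, `area_heavy`.
#' @export
simulate_peptide_areas <- function(true_ra,
                                   fold_changes = list(),
                                   samples = c("WT", "KO"),
                                   total_abundance = 1e6,
                                   heavy_abundance = 1e6,
                                   noise_cv = 0.1,
                                   n_replicates = 3,
                                   seed = NULL) {
  stopifnot(is.list(true_ra), length(true_ra) >= 1, noise_cv >= 0, n_replicates >= 1)
  for (pep in names(true_ra)) {
    if (abs(sum(true_ra[[pep]]) - 100) > 1e-6) {
      abort(sprintf("Reference %%RA for peptide '%s' must sum to 100.", pep))
    }
  }
  bad_samples <- setdiff(names(fold_changes), samples)
  if (length(bad_samples)) abort(paste0("fold_changes for unknown samples: ", paste(bad_samples, collapse = ", ")))

  light_ra_for <- function(sample, pep) {
    ra <- true_ra[[pep]]
    fc <- fold_changes[[sample]][[pep]]
    if (is.null(fc)) return(ra)
    unknown <- setdiff(names(fc), names(ra))
    if (length(unknown)) abort(paste0("Fold change on unknown forms: ", paste(unknown, collapse = ", ")))
    new <- ra
    new[names(fc)] <- ra[names(fc)] * fc
    free <- setdiff(names(ra), names(fc))
    if (!length(free)) abort("Every form carries a fold change; no balance form can conserve total abundance.")
    balance <- if ("unmod" %in% free) "unmod" else free[which.max(ra[free])]
    new[balance] <- new[balance] + (sum(ra) - sum(new))
    if (new[balance] < 0) {
      abort(sprintf("Planted folds on peptide '%s' exceed the balance form's share.", pep))
    }
    new
  }

  grid <- tidyr::expand_grid(
    sample_id = samples,
    replicate = seq_len(n_replicates),
    peptide_id = names(true_ra)
  )
  rows <- purrr::pmap(grid, function(sample_id, replicate, peptide_id) {
    ra_h <- true_ra[[peptide_id]]
    ra_l <- light_ra_for(sample_id, peptide_id)
    tibble(
      sample_id = sample_id, replicate = replicate, peptide_id = peptide_id,
      form_id = names(ra_h),
      area_light = total_abundance * ra_l / 100,
      area_heavy = heavy_abundance * ra_h / 100
    )
  }) %>% bind_rows()

  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noisy <- function() {
      rows$area_light <<- rows$area_light * stats::rlnorm(nrow(rows), -sdlog^2 / 2, sdlog)
      rows$area_heavy <<- rows$area_heavy * stats::rlnorm(nrow(rows), -sdlog^2 / 2, sdlog)
    }
    if (is.null(seed)) noisy() else with_seed(seed, noisy())
  }
  rows
}

#' Simulate single-cell immunofluorescence intensities
#'
#' Two-component lognormal mixture modelling a knockout population: a
#' `ko_fraction` of edited, low-signal cells and the remaining KO-escape
#' cells at control-like intensity.
#'
#' @param n_cells Number of cells (> 0).
#' @param ko_fraction Mixture weight of the low component in \[0, 1\].
#' @param mu_low,mu_high Log-scale means of the two components
#'   (`mu_low < mu_high`).
#' @param sigma Log-scale sd shared by the components.
#' @param population_id Label stored in the output.
#' @param seed Integer seed.
#' @return Tibble: `population_id`, `cell_id`, `intensity`.
#' @export
simulate_if_intensities <- function(n_cells, ko_fraction, mu_low, mu_high,
                                    sigma = 0.3, population_id = "pop",
                                    seed = NULL) {
  if (n_cells <= 0) abort("`n_cells` must be positive.")
  stopifnot(ko_fraction >= 0, ko_fraction <= 1, mu_low < mu_high, sigma >= 0)
  draw <- function() {
    low <- stats::runif(n_cells) < ko_fraction
    stats::rlnorm(n_cells, meanlog = ifelse(low, mu_low, mu_high), sdlog = sigma)
  }
  intensity <- if (is.null(seed)) draw() else with_seed(seed, draw())
  tibble(population_id = population_id, cell_id = seq_len(n_cells), intensity = intensity)
}

#' Simulate log-linear growth curves
#'
#' Per replicate, `log2(signal) = intercept + slope * time + noise`; the
#' output carries raw `signal` so it matches the confluence/count tables the
#' slope test consumes.
#'
#' @param slopes Named numeric: condition -> slope (per hour, log2 scale).
#' @param timepoints Strictly increasing times in hours; at least two must
#'   fall inside `window`.
#' @param noise_sd Log2-scale noise sd (default 0).
#' @param n_replicates Replicates per condition (default 6).
#' @param intercept Log2 signal at time 0 (default 0).
#' @param window Closed analysis window checked for coverage (default 24-48 h).
#' @param seed Integer seed.
#' @return Tibble: `condition`, `replicate`, `time`, `signal`.
#' @export
simulate_growth_curves <- function(slopes, timepoints, noise_sd = 0,
                                   n_replicates = 6, intercept = 0,
                                   window = c(24, 48), seed = NULL) {
  stopifnot(length(slopes) >= 1, !is.null(names(slopes)), noise_sd >= 0)
  if (is.unsorted(timepoints, strictly = TRUE)) abort("`timepoints` must be strictly increasing.")
  if (sum(timepoints >= window[1] & timepoints <= window[2]) < 2) {
    abort(sprintf("Need at least 2 timepoints within the %g-%g h window.", window[1], window[2]))
  }
  grid <- tidyr::expand_grid(
    condition = names(slopes),
    replicate = seq_len(n_replicates),
    time = timepoints
  )
  draw <- function() stats::rnorm(nrow(grid), 0, noise_sd)
  eps <- if (noise_sd == 0) rep(0, nrow(grid)) else if (is.null(seed)) draw() else with_seed(seed, draw())
  grid %>%
    mutate(signal = 2^(intercept + unname(slopes[.data$condition]) * .data$time + eps))
}
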