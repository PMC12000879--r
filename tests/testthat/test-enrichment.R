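# small helper: dispensability-call tibble from a named vector gene -> call
mk_calls <- function(calls) {
  tibble::tibble(
    gene_id = names(calls), condition = "WT", mean_score = 0,
    call = factor(calls, levels = c("fully_dispensable", "partially_dispensable",
                                    "indispensable")),
    control_min = -0.1, control_max = 0.1, half_max = -1
  )
}

# library with explicit classes / paralogue flags
mk_library <- function(classes, has_para = NULL) {
  n <- length(classes)
  has_para <- has_para %||% rep(FALSE, n)
  partner <- ifelse(has_para, "P", NA_character_)
  validate_library(tibble::tibble(
    gene_id = names(classes) %||% sprintf("g%d", seq_len(n)),
    functional_class = unname(classes),
    has_paralogue = has_para,
    paralogue_partner = partner,
    expression_tpm = NA_real_,
    is_negative_control = FALSE
  ))
}
`%||%` <- rlang::`%||%`

test_that("exact homogeneity gives zero chi-square and flat ratios", {
  classes <- setNames(rep(c("A", "B", "C", "D"), each = 10),
                      sprintf("g%d", 1:40))
  lib <- mk_library(classes)
  # 2 indispensable in every class of 10: perfectly uniform
  call_vec <- rep("fully_dispensable", 40)
  names(call_vec) <- names(classes)
  for (cl in c("A", "B", "C", "D")) {
    call_vec[which(classes == cl)[1:2]] <- "indispensable"
  }
  res <- class_enrichment(mk_calls(call_vec), lib)
  expect_equal(res$test$chi2_stat, 0, tolerance = 1e-12)
  expect_equal(res$test$p_value, 1)
  expect_true(all(abs(res$by_class$log2_ratio) < 1e-12))
})

test_that("eight classes give a 7-df test", {
  lib <- build_default_library(n_targets = 80, paralogue_fraction = 0, seed = 1)
  calls <- mk_calls(setNames(
    rep(c("indispensable", "fully_dispensable"), c(10, 70)),
    lib$gene_id[!lib$is_negative_control]
  ))
  res <- class_enrichment(calls, lib)
  expect_equal(res$test$df, 7)
})

test_that("two-class enrichment matches the hand-built contingency oracle", {
  classes <- setNames(rep(c("A", "B"), each = 20), sprintf("g%d", 1:40))
  lib <- mk_library(classes)
  call_vec <- rep("fully_dispensable", 40)
  names(call_vec) <- names(classes)
  call_vec[1:10] <- "indispensable"  # class A: 10/20, class B: 0/20
  res <- class_enrichment(mk_calls(call_vec), lib)

  expect_equal(res$test$chi2_stat, chisq_oracle(c(10, 0), c(20, 20)),
               tolerance = 1e-12)
  expect_equal(res$test$df, 1)
  # expected = 20 * 10/40 = 5 in each class; ratios log2(10/5) and -Inf
  a <- res$by_class[res$by_class$functional_class == "A", ]
  b <- res$by_class[res$by_class$functional_class == "B", ]
  expect_equal(a$expected, 5)
  expect_equal(a$log2_ratio, 1)
  expect_equal(b$log2_ratio, -Inf)
  # conservation and sign agreement
  expect_equal(sum(res$by_class$expected), sum(res$by_class$observed))
  expect_true(all(sign(res$by_class$log2_ratio) ==
                    sign(res$by_class$observed - res$by_class$expected)))
})

test_that("chi-square statistic is invariant to category order", {
  classes <- setNames(rep(c("A", "B", "C"), times = c(12, 8, 20)),
                      sprintf("g%d", 1:40))
  lib <- mk_library(classes)
  call_vec <- setNames(rep("fully_dispensable", 40), names(classes))
  call_vec[c(1:5, 13:14, 21)] <- "indispensable"
  res1 <- class_enrichment(mk_calls(call_vec), lib)
  shuffle <- withr::with_seed(1, sample(names(call_vec)))
  res2 <- class_enrichment(mk_calls(call_vec[shuffle]), lib)
  expect_equal(res1$test$chi2_stat, res2$test$chi2_stat, tolerance = 1e-12)
})

test_that("paralogue enrichment matches the direct 2x2 oracle", {
  lib <- mk_library(setNames(rep("A", 200), sprintf("g%d", 1:200)),
                    has_para = rep(c(TRUE, FALSE), each = 100))
  call_vec <- setNames(rep("fully_dispensable", 200), lib$gene_id)
  call_vec[1:2] <- "indispensable"      # paralogue group: 2/100
  call_vec[101:110] <- "indispensable"  # singleton group: 10/100
  res <- paralogue_enrichment(mk_calls(call_vec), lib)

  expect_equal(res$test$chi2_stat, chisq_oracle(c(2, 10), c(100, 100)),
               tolerance = 1e-12)
  expect_equal(res$test$df, 1)
  para <- res$by_group[res$by_group$group == "paralogue", ]
  single <- res$by_group[res$by_group$group == "singleton", ]
  expect_equal(para$log2_ratio, log2(2 / 6))    # expected = 100 * 12/200 = 6
  expect_equal(single$log2_ratio, log2(10 / 6))
  # yates variant matches stats::chisq.test with correction
  tab <- rbind(c(2, 10), c(98, 90))
  res_y <- paralogue_enrichment(mk_calls(call_vec), lib, yates = TRUE)
  expect_equal(res_y$test$chi2_stat,
               unname(stats::chisq.test(tab, correct = TRUE)$statistic),
               tolerance = 1e-10)
})

test_that("total depletion of one group is reported missing, not -Inf", {
  lib <- mk_library(setNames(rep("A", 40), sprintf("g%d", 1:40)),
                    has_para = rep(c(TRUE, FALSE), each = 20))
  call_vec <- setNames(rep("fully_dispensable", 40), lib$gene_id)
  call_vec[21:26] <- "indispensable"  # all indispensable genes are singletons
  res <- paralogue_enrichment(mk_calls(call_vec), lib)
  para <- res$by_group[res$by_group$group == "paralogue", ]
  single <- res$by_group[res$by_group$group == "singleton", ]
  expect_true(is.na(para$log2_ratio))
  expect_true(para$depleted_to_zero)
  expect_gt(single$log2_ratio, 0)
})

test_that("cross-line concordance handles identity, anti-identity and attenuation", {
  mk_scores <- function(scores) {
    tibble::tibble(
      plate_id = "P1", well = "B2", gene_id = names(scores), condition = "WT",
      is_control = FALSE, mean_score = unname(scores), sem = 0, n_reps = 3
    )
  }
  s <- setNames(c(-2, -1, 0, 0.2, -0.5), sprintf("g%d", 1:5))
  calls <- mk_calls(setNames(rep("fully_dispensable", 5), names(s)))

  same <- cross_line_concordance(mk_scores(s), mk_scores(s), calls, calls)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$dispensable_overlap_fraction, 1)

  anti <- cross_line_concordance(mk_scores(s), mk_scores(-s), calls, calls)
  expect_equal(anti$pearson_r, -1)

  const <- cross_line_concordance(mk_scores(s * 0), mk_scores(s), calls, calls)
  expect_true(is.na(const$pearson_r))

  # attenuation: shared effects + independent noise in each line's mean score
  withr::with_seed(77, {
    n <- 400; sigma <- 0.1; n_rep <- 3
    effect <- rnorm(n, -0.5, 0.6)
    names(effect) <- sprintf("g%d", 1:n)
    a <- effect + rnorm(n, 0, sigma / sqrt(n_rep))
    b <- effect + rnorm(n, 0, sigma / sqrt(n_rep))
    names(a) <- names(b) <- names(effect)
    big_calls <- mk_calls(setNames(rep("fully_dispensable", n), names(effect)))
    res <- cross_line_concordance(mk_scores(a), mk_scores(b), big_calls, big_calls)
    predicted <- var(effect) / (var(effect) + sigma^2 / n_rep)
    expect_equal(res$pearson_r, predicted, tolerance = 0.02)
    expect_lt(res$p_value, 1e-4)
  })
})
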