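test_that("case frequency sums carrier counts over cases sequenced", {
  expect_equal(round(case_frequency(104L, 6179), 3), 0.017)
  expect_equal(case_frequency(integer(0), 100), 0)
  expect_equal(case_frequency(c(2L, 3L), 100), 0.05)
  expect_error(case_frequency(5L, 0), "positive")
  expect_warning(f <- case_frequency(c(80L, 30L), 100), "capped")
  expect_equal(f, 1)
})

test_that("case excess is a signed difference, never clipped", {
  expect_equal(case_excess(0.02, 0.005), 0.015)
  expect_equal(case_excess(0.01, 0.01), 0)
  expect_equal(case_excess(0.005, 0.02), -0.015)
})

test_that("Fisher's exact test reproduces known two-sided p-values", {
  expect_equal(fisher_exact(1, 1, 1, 1), 1)
  expect_equal(fisher_exact(5, 0, 0, 5), 2 / 252)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)), 2 / 252)
  expect_warning(p <- fisher_exact(0, 5, 0, 5), "degenerate")
  expect_equal(p, 1)
})

test_that("Fisher p agrees with stats::fisher.test and the enumeration oracle", {
  set.seed(11)
  for (k in 1:60) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p_pkg <- fisher_exact(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(p_pkg, fisher.test(tab)$p.value, tolerance = 1e-12)
    expect_equal(p_pkg, enum_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1],
                                      tab[2, 2]), tolerance = 1e-12)
  }
})

test_that("odds ratio uses the cross-product with Woolf interval", {
  expect_equal(unname(odds_ratio_ci(10, 90, 10, 90)["or"]), 1)
  expect_equal(unname(odds_ratio_ci(104, 6075, 3, 60703)["or"]),
               (104 * 60703) / (6075 * 3))
  expect_equal(round(unname(odds_ratio_ci(104, 6075, 3, 60703)["or"]), 1),
               346.4)
  # Haldane-Anscombe correction with a zero cell
  expect_equal(unname(odds_ratio_ci(0, 100, 5, 995)["or"]),
               (0.5 * 995.5) / (100.5 * 5.5))
  expect_error(odds_ratio_ci(0, 0, 5, 995), "arm")
  ci <- odds_ratio_ci(20, 80, 10, 90)
  expect_lte(ci["lo"], ci["or"])
  expect_gte(ci["hi"], ci["or"])
})

test_that("OR and EF intervals nest with confidence level", {
  ci90 <- odds_ratio_ci(20, 80, 10, 90, conf.level = 0.90)
  ci99 <- odds_ratio_ci(20, 80, 10, 90, conf.level = 0.99)
  expect_lt(ci99["lo"], ci90["lo"])
  expect_gt(ci99["hi"], ci90["hi"])
  ef90 <- etiological_fraction(ci90)
  ef99 <- etiological_fraction(ci99)
  expect_lte(ef99["lo"], ef90["lo"])
  expect_gte(ef99["hi"], ef90["hi"])
})

test_that("etiological fraction is (OR-1)/OR floored at zero", {
  expect_equal(etiological_fraction(1), 0)
  expect_equal(etiological_fraction(2), 0.5)
  expect_equal(etiological_fraction(0.8), 0)  # lower CI bound floors at 0
  expect_error(etiological_fraction(0), "OR")
  expect_error(etiological_fraction(-2), "OR")
  # strictly increasing on a grid, EF(1) = 0, approaching 1 for huge OR
  grid <- c(1, 1.5, 2, 5, 12, 100, 1e6)
  ef <- etiological_fraction(grid)
  expect_true(all(diff(ef) > 0))
  expect_equal(ef[1], 0)
  expect_gt(ef[length(ef)], 0.999)
})

test_that("Bonferroni thresholds follow panel size", {
  expect_equal(bonferroni_threshold(0.05, 20), 0.0025)
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("Wilson interval matches the score-test route and known values", {
  ci <- binomial_ci(104, 6179)
  expect_equal(round(100 * ci[["lo"]], 1), 1.4)
  expect_equal(round(100 * ci[["hi"]], 1), 2.0)
  # independent route: score interval from prop.test without continuity
  pt <- prop.test(104, 6179, correct = FALSE)$conf.int
  expect_equal(unname(ci), as.numeric(pt), tolerance = 1e-10)
  expect_equal(binomial_ci(0, 100)[["lo"]], 0)
  ci50 <- binomial_ci(50, 100)
  expect_equal(unname(ci50[["lo"]] + ci50[["hi"]]) / 2, 0.5, tolerance = 1e-6)
})

test_that("predicted pathogenic count floors negative excess at zero", {
  expect_equal(predicted_pathogenic(0.015, 1000), 15)
  expect_equal(predicted_pathogenic(-0.002, 1000), 0)
  expect_equal(predicted_pathogenic(0, 500), 0)
})

test_that("gene_burden partitions carriers across classes and fills all fields", {
  sim <- simulate_cohorts(
    list(synthetic_gene_spec("G1", pathogenic_fraction = 0.08),
         synthetic_gene_spec("G2")),
    n_cases = 1000, n_ref = 20000, seed = 3)
  fit <- suppressWarnings(gene_burden(sim$cases, sim$reference, sim$panel))
  res <- fit$results
  expect_s3_class(fit, "gene_burden")
  expect_equal(nrow(res), 6L)  # 2 genes x 3 classes
  for (g in c("G1", "G2")) {
    r <- res[res$gene == g, ]
    expect_equal(r$case_carriers[r$variant_class == "ALL"],
                 r$case_carriers[r$variant_class == "TRUNCATING"] +
                   r$case_carriers[r$variant_class == "NONTRUNCATING"])
  }
  expect_true(all(res$case_excess == res$case_freq - res$ref_freq))
  expect_true(all(res$or_lo <= res$or_point & res$or_point <= res$or_hi))
  expect_true(all(res$ef_point == pmax(0, (res$or_point - 1) / res$or_point)))
  expect_false(anyNA(res$fisher_p))
})

test_that("a case gene missing from the panel is a hard failure", {
  sim <- simulate_cohorts(list(synthetic_gene_spec("G1")),
                          n_cases = 200, n_ref = 2000, seed = 5)
  panel <- sim$panel
  panel$gene <- "OTHER"
  expect_error(gene_burden(sim$cases, sim$reference, panel), "G1")
})

test_that("null genes show near-zero excess and EF near zero", {
  # background identical in cases and reference, no pathogenic injection
  sims <- lapply(1:30, function(s)
    simulate_cohorts(list(synthetic_gene_spec("G", background_rate = 0.02)),
                     n_cases = 1000, n_ref = 20000, seed = 1000 + s))
  excess <- vapply(sims, function(sim) {
    fit <- suppressWarnings(gene_burden(sim$cases, sim$reference, sim$panel))
    fit$results$case_excess[fit$results$variant_class == "ALL"]
  }, numeric(1))
  # mean excess within binomial sampling error of zero
  se <- sqrt(0.02 * 0.98 / 1000 / length(sims))
  expect_lt(abs(mean(excess)), 4 * se)
})

test_that("a true OR of 12 is recovered within its own confidence interval", {
  covered <- vapply(1:25, function(s) {
    pf <- pathogenic_fraction_for_ef(11 / 12, background_rate = 0.01)
    sim <- simulate_cohorts(
      list(synthetic_gene_spec("G", pathogenic_fraction = pf)),
      n_cases = 2000, n_ref = 50000, seed = 2000 + s)
    fit <- suppressWarnings(gene_burden(sim$cases, sim$reference, sim$panel))
    r <- fit$results[fit$results$variant_class == "ALL", ]
    true_or <- sim$truth$true_or
    r$or_lo <= true_or && true_or <= r$or_hi
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
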