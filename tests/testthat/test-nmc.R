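test_that("position normalisation scales, sorts and deduplicates", {
  expect_equal(normalize_positions(c(10, 20), 100), c(0.1, 0.2))
  expect_equal(normalize_positions(c(10, 10, 20), 100), c(0.1, 0.2))
  expect_equal(normalize_positions(c(20, 10), 100), c(0.1, 0.2))
  expect_error(normalize_positions(0, 100), "1")
  expect_error(normalize_positions(101, 100), "protein_length")
})

test_that("pair p-values match the Beta closed forms", {
  expect_equal(nmc_pair_pvalue(1, 2, 2, 0.1), 1 - (1 - 0.1)^2)
  expect_equal(nmc_pair_pvalue(2, 3, 3, 0.05), 1 - (1 - 0.05)^3)
  expect_equal(nmc_pair_pvalue(2, 3, 3, 0.05), 0.142625)
  expect_error(nmc_pair_pvalue(2, 2, 3, 0.1), "i < j")
  expect_error(nmc_pair_pvalue(1, 2, 2, 1.5), "gap")
})

test_that("adjacent-pair p equals 1-(1-g)^n to near machine precision", {
  set.seed(9)
  for (k in 1:50) {
    n <- sample(3:60, 1)
    i <- sample(n - 1L, 1)
    g <- runif(1)
    expect_equal(nmc_pair_pvalue(i, i + 1L, n, g), 1 - (1 - g)^n,
                 tolerance = 1e-12)
  }
})

test_that("pair p is monotone nondecreasing in the gap", {
  gaps <- seq(0, 1, by = 0.05)
  for (cfg in list(c(1, 2, 5), c(2, 6, 10), c(3, 9, 40))) {
    p <- nmc_pair_pvalue(cfg[1], cfg[2], cfg[3], gaps)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("evenly spaced positions yield no significant cluster", {
  scan <- nmc_scan(c(25, 50, 75), 100)
  expect_s3_class(scan, "nmc_scan")
  expect_equal(nrow(scan$clusters), 0L)
  # adjacent-pair p for gap 0.25 with n = 3 is 1 - 0.75^3
  adj <- scan$pairs[scan$pairs$i == 1 & scan$pairs$j == 2, ]
  expect_equal(adj$p_value, 1 - 0.75^3)
})

test_that("scan output is invariant to input ordering and clusters disjoint", {
  set.seed(21)
  pos <- c(sample(180:940, 25), sample(1:1935, 6))
  a <- nmc_scan(pos, 1935)
  b <- nmc_scan(rev(pos), 1935)
  expect_equal(a$clusters, b$clusters)
  expect_equal(a$pairs, b$pairs)
  cl <- a$clusters
  if (nrow(cl) > 1) {
    expect_true(all(cl$start_residue[-1] > cl$end_residue[-nrow(cl)]))
  }
  expect_true(all(cl$q_value >= cl$p_value))
})

test_that("an implanted cluster is detected and overlaps the true interval", {
  hits <- vapply(1:40, function(s) {
    set.seed(300 + s)
    pos <- unique(c(sample(180:940, 30), sample(1:1935, 5)))
    scan <- nmc_scan(pos, 1935)
    cl <- scan$clusters
    nrow(cl) > 0 && any(cl$start_residue <= 940 & cl$end_residue >= 180)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("scan on a single position warns and returns no clusters", {
  expect_warning(scan <- nmc_scan(10, 100), "fewer than 2")
  expect_equal(nrow(scan$clusters), 0L)
})

test_that("cluster-restricted EF over the whole protein equals the gene result", {
  sim <- simulate_cohorts(
    list(synthetic_gene_spec("G", protein_length = 1000,
                             pathogenic_fraction = 0.06,
                             pathogenic_class_mix = c(NONTRUNCATING = 1),
                             cluster_interval = c(100, 400))),
    n_cases = 1500, n_ref = 30000, seed = 17)
  fit <- suppressWarnings(gene_burden(sim$cases, sim$reference, sim$panel))
  full <- fit$results[fit$results$variant_class == "NONTRUNCATING", ]
  restricted <- suppressWarnings(
    cluster_ef(sim$cases, sim$reference, "G", c(1L, 1000L), n_cases = 1500))
  expect_equal(restricted$ef_point, full$ef_point, tolerance = 1e-10)
  expect_equal(restricted$n_ref_effective, full$n_ref_effective)
  expect_equal(restricted$case_carriers, full$case_carriers)
})

test_that("EF inside the pathogenic interval exceeds EF in its complement", {
  sim <- simulate_cohorts(
    list(synthetic_gene_spec("G", protein_length = 1000,
                             pathogenic_fraction = 0.08,
                             pathogenic_class_mix = c(NONTRUNCATING = 1),
                             cluster_interval = c(100, 400))),
    n_cases = 1500, n_ref = 30000, seed = 23)
  inside <- suppressWarnings(
    cluster_ef(sim$cases, sim$reference, "G", c(100L, 400L), n_cases = 1500))
  outside <- suppressWarnings(
    cluster_ef(sim$cases, sim$reference, "G", c(401L, 1000L), n_cases = 1500))
  expect_gt(inside$ef_point, outside$ef_point)
})

test_that("an interval with no case variants is flagged undefined", {
  cases <- data.frame(disease = "D", gene = "G", variant_id = "v1",
                      consequence = "missense_variant", protein_pos = 500L,
                      carrier_count = 3L, reported_class = NA_character_,
                      stringsAsFactors = FALSE)
  reference <- data.frame(gene = "G", variant_id = "r1",
                          consequence = "missense_variant",
                          protein_pos = 600L, ac = 1L, an = 50000L,
                          stringsAsFactors = FALSE)
  expect_warning(
    row <- cluster_ef(cases, reference, "G", c(1L, 100L), n_cases = 1000),
    "undefined")
  expect_true(is.na(row$ef_point))
})
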