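test_that("identical seeds give byte-identical outputs", {
  specs <- list(synthetic_gene_spec("G1", pathogenic_fraction = 0.05,
                                    cluster_interval = c(100, 500)),
                synthetic_gene_spec("G2"))
  s1 <- simulate_cohorts(specs, n_cases = 500, n_ref = 5000, seed = 42)
  s2 <- simulate_cohorts(specs, n_cases = 500, n_ref = 5000, seed = 42)
  expect_identical(s1, s2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohorts(s1, d1); p2 <- write_cohorts(s2, d2)
  for (k in seq_along(p1))
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  s3 <- simulate_cohorts(specs, n_cases = 500, n_ref = 5000, seed = 43)
  expect_false(identical(s1$cases, s3$cases))
})

test_that("a seed is mandatory", {
  expect_error(simulate_cohorts(list(synthetic_gene_spec("G")),
                                n_cases = 10, n_ref = 10), "seed")
})

test_that("realized carriers in the truth equal emitted carrier sums", {
  sim <- simulate_cohorts(
    list(synthetic_gene_spec("G1", pathogenic_fraction = 0.1),
         synthetic_gene_spec("G2", background_rate = 0.02)),
    n_cases = 800, n_ref = 8000, seed = 7)
  for (g in c("G1", "G2")) {
    tr <- sim$truth[sim$truth$gene == g, ]
    expect_equal(sum(sim$cases$carrier_count[sim$cases$gene == g]),
                 tr$realized_benign_case_carriers +
                   tr$realized_pathogenic_carriers)
    expect_equal(sum(sim$reference$ac[sim$reference$gene == g]),
                 tr$realized_benign_ref_carriers)
  }
})

test_that("emitted tables round-trip through the package readers", {
  sim <- simulate_cohorts(list(synthetic_gene_spec("G1")),
                          n_cases = 300, n_ref = 3000, seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_cohorts(sim, dir)
  expect_equal(read_case_table(paths["cases"]), sim$cases)
  expect_equal(read_reference_table(paths["reference"]), sim$reference)
  expect_equal(read_panel_table(paths["panel"]), sim$panel)
})

test_that("coverage model: complete genotyping and linear scaling", {
  set.seed(1)
  full <- coverage_model_uniform(1)(10, 5000)
  expect_true(all(full == 10000L))
  half <- coverage_model_uniform(0.5)(10, 5000)
  expect_true(all(half == 5000L))
  # jittered model: mean AN within 1% of the target over many sites
  jit <- coverage_model_uniform(0.9, jitter = 0.1)(1000, 5000)
  expect_lt(abs(mean(jit) - 0.9 * 10000) / (0.9 * 10000), 0.01)
})

test_that("true EF bookkeeping matches the generative rates", {
  spec <- synthetic_gene_spec("G", background_rate = 0.01,
                              pathogenic_fraction = 0.1)
  sim <- simulate_cohorts(list(spec), n_cases = 100, n_ref = 1000, seed = 2)
  tr <- sim$truth
  p_case <- 1 - (1 - 0.1) * (1 - 0.01)
  or <- (p_case / (1 - p_case)) / (0.01 / 0.99)
  expect_equal(tr$true_or, or)
  expect_equal(tr$true_ef, (or - 1) / or)
})

test_that("pathogenic_fraction_for_ef inverts the generative model", {
  for (ef in c(0.2, 0.5, 0.9)) {
    pf <- pathogenic_fraction_for_ef(ef, background_rate = 0.01)
    sim <- simulate_cohorts(
      list(synthetic_gene_spec("G", pathogenic_fraction = pf)),
      n_cases = 10, n_ref = 10, seed = 1)
    expect_equal(sim$truth$true_ef, ef, tolerance = 1e-12)
  }
})

test_that("a concentrated allelic spectrum triggers the self-filter warning", {
  spec <- synthetic_gene_spec("G", background_rate = 0.2, pool_size = 5,
                              zipf_exponent = 2)
  expect_warning(simulate_cohorts(list(spec), n_cases = 50, n_ref = 500,
                                  seed = 1),
                 "self-filter")
})

test_that("pathogenic missense positions stay inside the cluster interval", {
  sim <- simulate_cohorts(
    list(synthetic_gene_spec("G", protein_length = 1000,
                             pathogenic_fraction = 0.3,
                             pathogenic_class_mix = c(NONTRUNCATING = 1),
                             cluster_interval = c(200, 300))),
    n_cases = 500, n_ref = 500, seed = 31)
  path <- sim$cases[grepl(":p", sim$cases$variant_id, fixed = TRUE), ]
  expect_gt(nrow(path), 0)
  expect_true(all(path$protein_pos >= 200 & path$protein_pos <= 300))
})
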