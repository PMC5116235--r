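#' Specification of one synthetic gene
#'
#' Encodes the generative assumptions of the burden model: rare benign
#' variation arises at the same per-individual rate in cases and reference
#' (\code{background_rate}); pathogenic variants occur only in cases, in a
#' fraction \code{pathogenic_fraction} of them, optionally with missense
#' positions confined to a residue interval (a mutation hotspot). Benign
#' alleles are drawn from a long-tailed (Zipf-like) allelic spectrum, so a
#' few recurrent alleles and many singletons arise — individually rare,
#' collectively common.
#'
#' @param gene Gene symbol.
#' @param protein_length Canonical protein length in residues.
#' @param background_rate Per-individual probability of carrying a rare
#'   benign protein-altering variant in this gene (default 0.01, typical of
#'   large sarcomeric genes).
#' @param pathogenic_fraction Proportion of cases carrying a causal variant
#'   in this gene (default 0).
#' @param pathogenic_class_mix Named proportions over
#'   \code{c("TRUNCATING", "NONTRUNCATING")} for causal variants.
#' @param benign_class_mix Same, for benign variants (rare benign variation
#'   is overwhelmingly missense).
#' @param cluster_interval Optional residue interval \code{c(a, b)} holding
#'   all pathogenic missense positions; NULL means uniform over the protein.
#' @param zipf_exponent Exponent of the benign allelic spectrum (rank
#'   probability proportional to rank^-s); smaller values flatten the
#'   spectrum towards private alleles.
#' @param pool_size Number of distinct possible benign alleles; NULL scales
#'   it with the expected carrier count so the spectrum stays long-tailed.
#' @return An object of class \code{"synthetic_gene_spec"}.
#' @export
synthetic_gene_spec <- function(gene, protein_length = 1500,
                                background_rate = 0.01,
                                pathogenic_fraction = 0,
                                pathogenic_class_mix = c(TRUNCATING = 0.25,
                                                         NONTRUNCATING = 0.75),
                                benign_class_mix = c(TRUNCATING = 0.05,
                                                     NONTRUNCATING = 0.95),
                                cluster_interval = NULL,
                                zipf_exponent = 0.5,
                                pool_size = NULL) {
  stopifnot(background_rate >= 0, pathogenic_fraction >= 0,
            pathogenic_fraction <= 1, protein_length >= 1)
  norm_mix <- function(m) {
    stopifnot(all(names(m) %in% c("TRUNCATING", "NONTRUNCATING")), all(m >= 0))
    full <- c(TRUNCATING = 0, NONTRUNCATING = 0)
    full[names(m)] <- m
    if (sum(full) == 0) stop("class mix sums to zero", call. = FALSE)
    full / sum(full)
  }
  if (!is.null(cluster_interval)) {
    stopifnot(length(cluster_interval) == 2L,
              cluster_interval[1] >= 1,
              cluster_interval[2] <= protein_length,
              cluster_interval[1] <= cluster_interval[2])
  }
  structure(list(gene = gene, protein_length = as.integer(protein_length),
                 background_rate = background_rate,
                 pathogenic_fraction = pathogenic_fraction,
                 pathogenic_class_mix = norm_mix(pathogenic_class_mix),
                 benign_class_mix = norm_mix(benign_class_mix),
                 cluster_interval = cluster_interval,
                 zipf_exponent = zipf_exponent, pool_size = pool_size),
            class = "synthetic_gene_spec")
}

#' Uniform coverage model for reference allele numbers
#'
#' Returns a generator of per-site total allele numbers (AN). Each site is
#' genotyped in a fraction of the reference cohort drawn uniformly around
#' \code{depth_fraction}; \code{depth_fraction = 1} with zero jitter
#' reproduces complete genotyping (AN = 2 N at every site).
#'
#' @param depth_fraction Mean fraction of the cohort genotyped per site.
#' @param jitter Half-width of the uniform fluctuation around
#'   \code{depth_fraction} (default 0).
#' @return Function \code{(n_sites, n_ref) -> integer AN vector}.
#' @export
coverage_model_uniform <- function(depth_fraction = 1, jitter = 0) {
  stopifnot(depth_fraction > 0, depth_fraction <= 1, jitter >= 0)
  function(n_sites, n_ref) {
    f <- depth_fraction + stats::runif(n_sites, -jitter, jitter)
    f <- pmin(pmax(f, 0.01), 1)
    as.integer(round(2 * n_ref * f))
  }
}

# consequence term for a class draw
.draw_consequence <- function(class_vec) {
  trunc_terms <- c("frameshift_variant", "stop_gained",
                   "splice_donor_variant", "splice_acceptor_variant")
  out <- character(length(class_vec))
  nt <- class_vec == "NONTRUNCATING"
  out[nt] <- "missense_variant"
  out[!nt] <- sample(trunc_terms, sum(!nt), replace = TRUE,
                     prob = c(0.45, 0.4, 0.075, 0.075))
  out
}

# fixed benign allele pool for one gene: id, consequence, position, and
# Zipf sampling weights
.benign_pool <- function(spec, n_total, rare_maf_threshold) {
  expected_carriers <- n_total * spec$background_rate
  M <- spec$pool_size
  if (is.null(M)) M <- max(2000L, ceiling(20 * expected_carriers))
  ranks <- seq_len(M)
  w <- ranks^(-spec$zipf_exponent)
  prob <- w / sum(w)
  # expected MAF of the most recurrent allele under the spectrum
  top_maf <- spec$background_rate * prob[1L] / 2
  if (top_maf >= rare_maf_threshold)
    warning("gene ", spec$gene, ": background rate and allelic spectrum ",
            "imply a top-allele MAF of ", signif(top_maf, 2),
            " >= rare threshold; such alleles will self-filter",
            call. = FALSE)
  cls <- sample(names(spec$benign_class_mix), M, replace = TRUE,
                prob = spec$benign_class_mix)
  data.frame(variant_id = paste0(spec$gene, ":b", ranks),
             consequence = .draw_consequence(cls),
             protein_pos = sample.int(spec$protein_length, M, replace = TRUE),
             prob = prob, stringsAsFactors = FALSE)
}

# smaller recurrent pool for pathogenic alleles (cases only); missense
# positions confined to the cluster interval when given
.pathogenic_pool <- function(spec, size = 200L) {
  ranks <- seq_len(size)
  w <- ranks^(-1)
  cls <- sample(names(spec$pathogenic_class_mix), size, replace = TRUE,
                prob = spec$pathogenic_class_mix)
  cons <- .draw_consequence(cls)
  int <- if (is.null(spec$cluster_interval)) c(1L, spec$protein_length)
         else spec$cluster_interval
  pos <- integer(size)
  miss <- cons == "missense_variant"
  pos[miss] <- int[1] + sample.int(int[2] - int[1] + 1L, sum(miss),
                                   replace = TRUE) - 1L
  pos[!miss] <- sample.int(spec$protein_length, sum(!miss), replace = TRUE)
  data.frame(variant_id = paste0(spec$gene, ":p", ranks),
             consequence = cons, protein_pos = pos, prob = w / sum(w),
             stringsAsFactors = FALSE)
}

#' Simulate case and reference cohorts with known ground truth
#'
#' Generates, for each gene specification, a summary-level case variant
#' table, a reference site table with coverage-dependent allele numbers, a
#' panel table, and a ground-truth record — everything needed to run the
#' full burden pipeline against known answers. Benign carriers are drawn as
#' Bernoulli(\code{background_rate}) per individual on both sides and
#' assigned alleles from a shared long-tailed spectrum; pathogenic carriers
#' (cases only, one causal variant each) are drawn with probability
#' \code{pathogenic_fraction}. Identical seeds give identical outputs.
#'
#' @param specs List of \code{\link{synthetic_gene_spec}} objects (a single
#'   spec is accepted).
#' @param n_cases Number of cases sequenced per gene.
#' @param n_ref Nominal reference cohort size (individuals).
#' @param coverage Coverage model, e.g. \code{\link{coverage_model_uniform}}.
#' @param seed Integer seed (mandatory: reproducibility is part of the
#'   contract).
#' @param disease Disease label for the simulated panel.
#' @param rare_maf_threshold Threshold used only to warn when the benign
#'   spectrum would concentrate mass above it.
#' @return List with \code{cases}, \code{reference}, \code{panel} (data
#'   frames in the package's input dialects) and \code{truth}: per gene, the
#'   generative rates, realized carrier counts, implied true odds ratio and
#'   true etiological fraction, and the cluster interval.
#' @export
simulate_cohorts <- function(specs, n_cases, n_ref,
                             coverage = coverage_model_uniform(1),
                             seed, disease = "SIM",
                             rare_maf_threshold = 1e-4) {
  if (inherits(specs, "synthetic_gene_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "synthetic_gene_spec")))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(as.integer(seed))

  case_rows <- list(); ref_rows <- list(); truth_rows <- list()
  for (spec in specs) {
    pool <- .benign_pool(spec, n_cases + n_ref, rare_maf_threshold)

    n_benign_case <- stats::rbinom(1L, n_cases, min(spec$background_rate, 1))
    n_benign_ref <- stats::rbinom(1L, n_ref, min(spec$background_rate, 1))
    bc <- sample.int(nrow(pool), n_benign_case, replace = TRUE,
                     prob = pool$prob)
    br <- sample.int(nrow(pool), n_benign_ref, replace = TRUE,
                     prob = pool$prob)

    n_path <- stats::rbinom(1L, n_cases, spec$pathogenic_fraction)
    ppool <- .pathogenic_pool(spec)
    pc <- if (n_path > 0) sample.int(nrow(ppool), n_path, replace = TRUE,
                                     prob = ppool$prob) else integer(0)

    case_counts <- c(table(bc))
    path_counts <- c(table(pc))
    gene_cases <- rbind(
      if (length(case_counts))
        data.frame(disease = disease, gene = spec$gene,
                   variant_id = pool$variant_id[as.integer(names(case_counts))],
                   consequence = pool$consequence[as.integer(names(case_counts))],
                   protein_pos = pool$protein_pos[as.integer(names(case_counts))],
                   carrier_count = as.integer(case_counts),
                   reported_class = NA_character_,
                   stringsAsFactors = FALSE),
      if (length(path_counts))
        data.frame(disease = disease, gene = spec$gene,
                   variant_id = ppool$variant_id[as.integer(names(path_counts))],
                   consequence = ppool$consequence[as.integer(names(path_counts))],
                   protein_pos = ppool$protein_pos[as.integer(names(path_counts))],
                   carrier_count = as.integer(path_counts),
                   reported_class = NA_character_,
                   stringsAsFactors = FALSE))

    ref_counts <- c(table(br))
    gene_ref <- if (length(ref_counts)) {
      an <- coverage(length(ref_counts), n_ref)
      ac <- as.integer(ref_counts)
      an <- pmax(an, ac)  # a site cannot show more alleles than genotyped
      data.frame(gene = spec$gene,
                 variant_id = pool$variant_id[as.integer(names(ref_counts))],
                 consequence = pool$consequence[as.integer(names(ref_counts))],
                 protein_pos = pool$protein_pos[as.integer(names(ref_counts))],
                 ac = ac, an = an, stringsAsFactors = FALSE)
    }

    p_ref <- min(spec$background_rate, 1)
    p_case <- 1 - (1 - spec$pathogenic_fraction) * (1 - p_ref)
    true_or <- if (p_ref > 0 && p_case < 1)
      (p_case / (1 - p_case)) / (p_ref / (1 - p_ref)) else Inf
    truth_rows[[spec$gene]] <- data.frame(
      gene = spec$gene, protein_length = spec$protein_length,
      background_rate = spec$background_rate,
      pathogenic_fraction = spec$pathogenic_fraction,
      realized_benign_case_carriers = n_benign_case,
      realized_pathogenic_carriers = n_path,
      realized_benign_ref_carriers = n_benign_ref,
      true_or = true_or,
      true_ef = if (is.finite(true_or)) max(0, (true_or - 1) / true_or) else 1,
      cluster_start = if (is.null(spec$cluster_interval)) NA_integer_
                      else spec$cluster_interval[1],
      cluster_end = if (is.null(spec$cluster_interval)) NA_integer_
                    else spec$cluster_interval[2],
      stringsAsFactors = FALSE)

    case_rows[[spec$gene]] <- gene_cases
    ref_rows[[spec$gene]] <- gene_ref
  }

  cases <- do.call(rbind, case_rows)
  if (is.null(cases))
    cases <- data.frame(disease = character(0), gene = character(0),
                        variant_id = character(0), consequence = character(0),
                        protein_pos = integer(0), carrier_count = integer(0),
                        reported_class = character(0))
  reference <- do.call(rbind, ref_rows)
  if (is.null(reference))
    reference <- data.frame(gene = character(0), variant_id = character(0),
                            consequence = character(0),
                            protein_pos = integer(0),
                            ac = integer(0), an = integer(0))
  panel <- data.frame(
    disease = disease,
    gene = vapply(specs, `[[`, character(1), "gene"),
    n_cases = n_cases,
    protein_length = vapply(specs, `[[`, integer(1), "protein_length"),
    transcript_id = NA_character_, stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth_rows)
  rownames(cases) <- rownames(reference) <- rownames(truth) <- NULL
  list(cases = cases, reference = reference, panel = panel, truth = truth)
}

#' Pathogenic fraction giving a target etiological fraction
#'
#' Inverts the generative model of \code{\link{simulate_cohorts}}: given the
#' benign background carrier rate, returns the pathogenic case fraction at
#' which the population-level odds ratio implies the requested etiological
#' fraction.
#'
#' @param ef Target etiological fraction in [0, 1).
#' @param background_rate Benign carrier rate per individual.
#' @return Pathogenic fraction in [0, 1).
#' @export
pathogenic_fraction_for_ef <- function(ef, background_rate) {
  stopifnot(ef >= 0, ef < 1, background_rate > 0, background_rate < 1)
  or <- 1 / (1 - ef)
  odds_case <- or * background_rate / (1 - background_rate)
  p_case <- odds_case / (1 + odds_case)
  1 - (1 - p_case) / (1 - background_rate)
}

#' Write simulated cohorts to disk
#'
#' Emits the three input tables in the package's TSV dialects plus the
#' ground truth as JSON. Identical simulations produce byte-identical files.
#'
#' @param sim Result of \code{\link{simulate_cohorts}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_cohorts <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cases = file.path(dir, "cases.tsv"),
             reference = file.path(dir, "reference.tsv"),
             panel = file.path(dir, "panel.tsv"),
             truth = file.path(dir, "truth.json"))
  write_case_table(sim$cases, paths["cases"])
  utils::write.table(sim$reference, paths["reference"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(sim$panel, paths["panel"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  jsonlite::write_json(sim$truth, paths["truth"], digits = NA, pretty = TRUE)
  invisible(paths)
}
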