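#' Case carrier frequency for one gene and variant class
#'
#' Proportion of cases carrying a retained rare variant: the sum of
#' per-variant carrier counts divided by the number of cases sequenced for
#' the gene. With summary-level inputs, cases carrying two qualifying
#' variants cannot be resolved, so the sum is capped at \code{n_cases} with
#' a warning when the cap binds (negligible at observed frequencies).
#'
#' @param carrier_counts Integer vector of per-variant carrier counts.
#' @param n_cases Number of cases sequenced (> 0).
#' @return Carrier proportion in [0, 1].
#' @export
case_frequency <- function(carrier_counts, n_cases) {
  if (length(n_cases) != 1L || !is.finite(n_cases) || n_cases <= 0)
    stop("n_cases must be a single positive number", call. = FALSE)
  total <- sum(carrier_counts)
  if (total > n_cases) {
    warning("summed carrier counts (", total, ") exceed n_cases (", n_cases,
            "); capped", call. = FALSE)
    total <- n_cases
  }
  total / n_cases
}

#' Case excess
#'
#' The proportion of cases with a qualifying rare variant minus the
#' corresponding reference proportion. Under the assumption that rare benign
#' variation is equally frequent in cases and reference, this estimates the
#' proportion of cases explained by (putatively causal) variants in the
#' gene. Never clipped here; a negative excess is meaningful sampling noise.
#'
#' @param case_freq,ref_freq Proportions in [0, 1].
#' @return \code{case_freq - ref_freq}.
#' @export
case_excess <- function(case_freq, ref_freq) {
  stopifnot(all(case_freq >= 0 & case_freq <= 1),
            all(ref_freq >= 0 & ref_freq <= 1))
  case_freq - ref_freq
}

# two-sided Fisher p for one table by hypergeometric summation over the
# support of a at fixed margins; relative tolerance as in the classical
# implementation so ties at the observed probability are included
.fisher_p1 <- function(a, b, c, d) {
  R1 <- a + b; R2 <- c + d; C1 <- a + c
  if (R1 == 0 || R2 == 0 || C1 == 0 || (b + d) == 0) {
    warning("degenerate margin in 2x2 table; p = 1", call. = FALSE)
    return(1)
  }
  lo <- max(0L, C1 - R2); hi <- min(C1, R1)
  xs <- lo:hi
  pmf <- stats::dhyper(xs, R1, R2, C1)
  p_obs <- pmf[match(a, xs)]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}

#' Two-sided Fisher's exact test on a 2x2 carrier table
#'
#' Tests whether rare-variant carriers are over-represented in cases
#' relative to the reference population. The two-sided p-value sums the
#' hypergeometric probabilities of all tables (at fixed margins) no more
#' probable than the observed one. Non-integer cells (possible after
#' coverage adjustment of reference denominators) are rounded to the
#' nearest integer, as the exact test requires counts.
#'
#' @param a Case carriers (or a 2x2 matrix \code{rbind(c(a, b), c(c, d))},
#'   in which case \code{b}, \code{c}, \code{d} are ignored).
#' @param b Case non-carriers.
#' @param c Reference carriers.
#' @param d Reference non-carriers.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_exact(5, 0, 0, 5)  # 2/252
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  stopifnot(length(a) == length(b), length(b) == length(c),
            length(c) == length(d))
  a <- round(a); b <- round(b); c <- round(c); d <- round(d)
  if (any(c(a, b, c, d) < 0)) stop("negative cell in 2x2 table", call. = FALSE)
  if (length(a) == 1L) return(.fisher_p1(a, b, c, d))
  mapply(.fisher_p1, a, b, c, d)
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio \code{(a d) / (b c)} with the Woolf log-normal
#' interval \code{exp(log OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))}. When any
#' cell is zero, the Haldane-Anscombe correction (0.5 added to every cell)
#' is applied to both the point estimate and the interval.
#'
#' @param a,b,c,d Cells of the 2x2 table (case carriers, case non-carriers,
#'   reference carriers, reference non-carriers); may be non-integer after
#'   coverage adjustment.
#' @param conf.level Confidence level (default 0.95).
#' @return Named numeric vector \code{c(or, lo, hi)}.
#' @export
odds_ratio_ci <- function(a, b, c, d, conf.level = 0.95) {
  if ((a + b) <= 0 || (c + d) <= 0)
    stop("odds ratio undefined: an empty study arm", call. = FALSE)
  if (any(c(a, b, c, d) < 0)) stop("negative cell in 2x2 table", call. = FALSE)
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se))
}

#' Etiological fraction from an odds ratio
#'
#' \code{EF = (OR - 1) / OR}, floored at 0: the estimated probability that a
#' qualifying rare variant found in an affected carrier actually caused the
#' disease (the attributable fraction among the exposed). Applied to the OR
#' point estimate and both CI bounds; the transform is monotone, so bounds
#' map to bounds.
#'
#' @param or Odds ratio(s), > 0.
#' @return \code{pmax(0, (or - 1) / or)}, same length as \code{or}.
#' @examples
#' etiological_fraction(c(1, 2, 12))
#' @export
etiological_fraction <- function(or) {
  if (any(!is.finite(or) | or <= 0))
    stop("etiological fraction requires finite OR > 0", call. = FALSE)
  ef <- (or - 1) / or
  ef[ef < 0] <- 0
  ef
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise error control over the genes tested for one disease panel: a
#' gene is flagged significant iff its Fisher p-value is at most
#' \code{alpha / m}.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of genes tested for the disease panel.
#' @return \code{alpha / m}.
#' @examples
#' bonferroni_threshold(0.05, 20)  # 0.0025 for a 20-gene panel
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1)
  if (any(m < 1)) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes (carriers).
#' @param n Number of trials (cases), >= 1.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector \code{c(lo, hi)}, both in [0, 1].
#' @examples
#' binomial_ci(104, 6179)  # 0.0139-0.0204, i.e. 1.4\%-2.0\%
#' @export
binomial_ci <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Predicted number of pathogenic-variant carriers in a cohort
#'
#' The case excess times the cohort size: the expected number of cases whose
#' qualifying variant is causal, used to benchmark variant counts reported
#' as pathogenic by research studies.
#'
#' @param excess Case excess (proportion difference).
#' @param n_cases Cohort size (> 0).
#' @return \code{max(0, excess) * n_cases} (real-valued).
#' @export
predicted_pathogenic <- function(excess, n_cases) {
  if (any(n_cases <= 0)) stop("n_cases must be > 0", call. = FALSE)
  pmax(0, excess) * n_cases
}

# one GeneBurdenResult row; case/ref inputs already filtered to the
# gene x class of interest
.burden_row <- function(disease, gene, variant_class, case_rows, ref_rows,
                        n_cases, fallback_an, alpha = 0.05, m = 1L,
                        conf.level = 0.95) {
  refsum <- summarize_reference_gene(ref_rows, fallback_an = fallback_an)
  n_eff <- refsum$n_ref_effective
  case_freq <- case_frequency(case_rows$carrier_count, n_cases)
  ref_freq <- refsum$carrier_freq

  a <- case_freq * n_cases            # case carriers (after cap)
  b <- n_cases - a
  c <- ref_freq * n_eff               # reference carriers (coverage-adjusted)
  d <- n_eff - c

  p <- fisher_exact(a, b, c, d)
  orci <- odds_ratio_ci(a, b, c, d, conf.level = conf.level)
  ef <- etiological_fraction(orci)
  ci <- binomial_ci(round(a), n_cases, level = conf.level)
  excess <- case_excess(case_freq, ref_freq)

  data.frame(
    disease = disease, gene = gene, variant_class = variant_class,
    n_cases = n_cases, n_ref_effective = n_eff,
    n_case_variants = nrow(case_rows), n_ref_sites = refsum$n_sites,
    case_carriers = a, ref_carriers = c,
    case_freq = case_freq, case_freq_lo = unname(ci["lo"]),
    case_freq_hi = unname(ci["hi"]),
    ref_freq = ref_freq, case_excess = excess,
    fisher_p = p, significant = p <= bonferroni_threshold(alpha, m),
    or_point = unname(orci["or"]), or_lo = unname(orci["lo"]),
    or_hi = unname(orci["hi"]),
    ef_point = unname(ef[1]), ef_lo = unname(ef[2]), ef_hi = unname(ef[3]),
    predicted_pathogenic = predicted_pathogenic(excess, n_cases),
    ref_fallback_an = refsum$used_fallback,
    stringsAsFactors = FALSE
  )
}

#' Fit per-gene rare-variant burden comparisons
#'
#' The central model fit: for every gene of a disease panel, and for each
#' variant class (\code{ALL} protein-altering, \code{TRUNCATING},
#' \code{NONTRUNCATING}), compares the carrier frequency of rare variants in
#' cases against a coverage-adjusted reference population. Produces case
#' excess, a two-sided Fisher's exact test with Bonferroni family-wise
#' control over the panel's genes, the odds ratio with Woolf confidence
#' interval, the etiological fraction, a Wilson interval on the case carrier
#' proportion, and the predicted number of pathogenic-variant carriers.
#'
#' Inputs are summary tables (see \link{tables}); the rare-variant filter
#' (\code{\link{filter_rare}}) is applied internally. Reference carrier
#' totals keep their coverage-adjusted (non-integer) values for the effect
#' estimates and are rounded only for the exact test. Genes of the panel
#' with no retained reference site in a class fall back to the gene-level
#' median AN as denominator (flagged in the \code{ref_fallback_an} column);
#' a gene observed in cases but missing from the panel is an error.
#'
#' @param cases Case variant table.
#' @param reference Reference site table.
#' @param panel Panel definition table.
#' @param disease Optional disease label(s) to restrict to (default: all
#'   diseases in the panel).
#' @param config A \code{\link{frequency_config}}.
#' @param alpha Family-wise error rate for the Bonferroni flag (default 0.05).
#' @param conf.level Confidence level for OR/EF/proportion intervals.
#' @return An object of class \code{"gene_burden"}: a list with elements
#'   \code{results} (one row per gene x class), \code{config}, \code{alpha},
#'   \code{m} (genes tested per disease), and \code{call}. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{plot},
#'   \code{as.data.frame}.
#' @examples
#' sim <- simulate_cohorts(
#'   list(synthetic_gene_spec("GENE1", pathogenic_fraction = 0.05)),
#'   n_cases = 500, n_ref = 5000, seed = 1)
#' fit <- gene_burden(sim$cases, sim$reference, sim$panel)
#' summary(fit)
#' @export
gene_burden <- function(cases, reference, panel, disease = NULL,
                        config = frequency_config(), alpha = 0.05,
                        conf.level = 0.95) {
  cl <- match.call()
  if (!is.null(disease)) {
    panel <- panel[panel$disease %in% disease, , drop = FALSE]
    cases <- cases[cases$disease %in% disease, , drop = FALSE]
    if (nrow(panel) == 0L)
      stop("no panel entries for disease(s): ",
           paste(disease, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(unique(paste(cases$disease, cases$gene)),
                    paste(panel$disease, panel$gene))
  if (length(orphan))
    stop("gene(s) present in cases but missing from panel: ",
         paste(orphan, collapse = "; "), call. = FALSE)

  filt <- filter_rare(cases, reference, config)
  fcase <- filt$cases
  fref <- filt$reference

  m_by_disease <- table(panel$disease)
  rows <- vector("list", nrow(panel) * 3L)
  k <- 0L
  for (i in seq_len(nrow(panel))) {
    dis <- panel$disease[i]; gene <- panel$gene[i]
    n_cases <- panel$n_cases[i]
    m <- as.integer(m_by_disease[[dis]])
    gene_all_an <- reference$an[reference$gene == gene]
    fallback <- if (length(gene_all_an)) stats::median(gene_all_an) else NULL
    gcase <- fcase[fcase$disease == dis & fcase$gene == gene, , drop = FALSE]
    gref <- fref[fref$gene == gene, , drop = FALSE]
    for (vc in c("ALL", variant_classes())) {
      cc <- if (vc == "ALL") gcase else gcase[gcase$variant_class == vc, , drop = FALSE]
      rr <- if (vc == "ALL") gref else gref[gref$variant_class == vc, , drop = FALSE]
      k <- k + 1L
      rows[[k]] <- .burden_row(dis, gene, vc, cc, rr, n_cases,
                               fallback_an = fallback, alpha = alpha, m = m,
                               conf.level = conf.level)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(list(results = res, config = config, alpha = alpha,
                 conf.level = conf.level,
                 m = as.list(m_by_disease), call = cl),
            class = "gene_burden")
}
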