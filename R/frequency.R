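#' Frequency filter configuration
#'
#' Holds the allele-frequency thresholds of the rare-variant filter. Variants
#' at reference minor allele frequency (MAF) at or above
#' \code{rare_maf_threshold} are not plausible highly penetrant dominant
#' alleles and are removed from burden testing; variants above
#' \code{polymorphism_threshold} are outright polymorphisms (relevant to the
#' reported-variant audit). Under \code{assume_het} every allele counts one
#' carrier; at MAF below 1e-4 homozygotes are vanishingly rare, so the
#' approximation is essentially exact.
#'
#' @param rare_maf_threshold Rare-variant MAF cutoff (default 1e-4).
#' @param polymorphism_threshold Polymorphism MAF cutoff (default 1e-2).
#' @param assume_het Treat each alternate allele as one carrier (default TRUE).
#' @return An object of class \code{"frequency_config"}.
#' @export
frequency_config <- function(rare_maf_threshold = 1e-4,
                             polymorphism_threshold = 1e-2,
                             assume_het = TRUE) {
  stopifnot(is.numeric(rare_maf_threshold), is.numeric(polymorphism_threshold))
  if (!(rare_maf_threshold > 0 && rare_maf_threshold < polymorphism_threshold &&
        polymorphism_threshold < 1))
    stop("need 0 < rare_maf_threshold < polymorphism_threshold < 1",
         call. = FALSE)
  structure(list(rare_maf_threshold = rare_maf_threshold,
                 polymorphism_threshold = polymorphism_threshold,
                 assume_het = isTRUE(assume_het)),
            class = "frequency_config")
}

#' Minor allele frequency from allele counts
#'
#' @param ac Alternate allele count(s), 0 <= ac <= an.
#' @param an Total alleles genotyped, > 0.
#' @return \code{ac / an}.
#' @examples
#' compute_maf(3, 121412)   # 2.47e-5, i.e. 2.5e-5 at two significant figures
#' @export
compute_maf <- function(ac, an) {
  if (any(an <= 0)) stop("undefined frequency: AN must be > 0", call. = FALSE)
  if (any(ac < 0) || any(ac > an)) stop("need 0 <= AC <= AN", call. = FALSE)
  ac / an
}

#' Apply the rare protein-altering variant filter
#'
#' Retains, on both the case and the reference side, exactly the variants
#' whose reference MAF is below \code{config$rare_maf_threshold} and whose
#' consequence classifies as TRUNCATING or NONTRUNCATING. The same frequency
#' criterion on both sides keeps the benign background symmetric. Case
#' variants absent from the reference have frequency 0 and always pass:
#' absence in tens of thousands of reference samples cannot justify
#' exclusion.
#'
#' @param cases Case table (\code{\link{read_case_table}}).
#' @param reference Reference table (\code{\link{read_reference_table}}).
#' @param config A \code{\link{frequency_config}}.
#' @return List with elements \code{cases} and \code{reference}: the retained
#'   rows, each with an added \code{variant_class} column (and \code{ref_maf}
#'   on the case side).
#' @export
filter_rare <- function(cases, reference, config = frequency_config()) {
  stopifnot(inherits(config, "frequency_config"))
  ref_maf_by_id <- if (nrow(reference))
    stats::setNames(compute_maf(reference$ac, reference$an), reference$variant_id)
  else stats::setNames(numeric(0), character(0))

  ref_class <- classify_consequence(reference$consequence)
  ref_keep <- ref_class != "EXCLUDED" &
    compute_maf(reference$ac, pmax(reference$an, 1L)) < config$rare_maf_threshold
  ref_out <- reference[ref_keep, , drop = FALSE]
  ref_out$variant_class <- ref_class[ref_keep]

  case_maf <- ref_maf_by_id[cases$variant_id]
  case_maf[is.na(case_maf)] <- 0
  case_class <- classify_consequence(cases$consequence)
  case_keep <- case_class != "EXCLUDED" & case_maf < config$rare_maf_threshold
  case_out <- cases[case_keep, , drop = FALSE]
  case_out$variant_class <- case_class[case_keep]
  case_out$ref_maf <- unname(case_maf[case_keep])

  rownames(case_out) <- rownames(ref_out) <- NULL
  list(cases = case_out, reference = ref_out)
}

#' Coverage-adjusted reference summary for one gene and variant class
#'
#' Aggregates retained reference sites of one gene/class into the quantities
#' entering the burden comparison: the summed allele count, the mean of the
#' per-site total alleles (the coverage-adjusted denominator on the allele
#' scale), and the effective number of reference individuals
#' \code{mean_an / 2}. Sites covered in every sample have
#' \code{an = 2 * N}, so complete genotyping recovers the nominal cohort
#' size; incomplete coverage shrinks it.
#'
#' When a gene/class has no retained sites, \code{fallback_an} (typically
#' the median AN over all sites of the gene) supplies the denominator and
#' the summary is flagged.
#'
#' @param sites Retained reference rows for one gene and one class.
#' @param fallback_an Gene-level AN to use when \code{sites} is empty.
#' @return List with \code{sum_ac}, \code{mean_an}, \code{n_ref_effective},
#'   \code{carrier_freq} (carrier proportion of individuals, assuming one
#'   carrier per allele, capped at 1), \code{n_sites}, \code{used_fallback}.
#' @export
summarize_reference_gene <- function(sites, fallback_an = NULL) {
  if (is.null(sites) || nrow(sites) == 0L) {
    if (is.null(fallback_an) || !is.finite(fallback_an) || fallback_an <= 0)
      stop("no retained reference sites and no gene-level fallback AN ",
           "available", call. = FALSE)
    return(list(sum_ac = 0, mean_an = as.numeric(fallback_an),
                n_ref_effective = fallback_an / 2, carrier_freq = 0,
                n_sites = 0L, used_fallback = TRUE))
  }
  sum_ac <- sum(sites$ac)
  mean_an <- mean(sites$an)
  n_eff <- mean_an / 2
  carriers <- min(sum_ac, n_eff)  # one carrier per allele, capped
  list(sum_ac = sum_ac, mean_an = mean_an, n_ref_effective = n_eff,
       carrier_freq = carriers / n_eff, n_sites = nrow(sites),
       used_fallback = FALSE)
}
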