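#' Frequency status of a previously reported pathogenic variant
#'
#' Places each reported disease-causing variant into one of four mutually
#' exclusive statuses by its reference-population MAF:
#' \describe{
#'   \item{ABSENT}{not observed in the reference population}
#'   \item{PRESENT_RARE}{observed, MAF at or below the rare threshold —
#'     compatible with a penetrant dominant allele}
#'   \item{EXCEEDS_RARE_THRESHOLD}{MAF above the rare threshold but at or
#'     below the polymorphism threshold — a frequency incompatible with
#'     causation of a penetrant Mendelian disease}
#'   \item{POLYMORPHISM_EXCLUDED}{MAF above the polymorphism threshold —
#'     removed from analysis outright}
#' }
#'
#' @param maf Reference MAF per variant; NA when absent from the reference.
#' @param config A \code{\link{frequency_config}}.
#' @return Character vector of statuses, same length as \code{maf}.
#' @export
classify_reported <- function(maf, config = frequency_config()) {
  stopifnot(inherits(config, "frequency_config"))
  out <- rep("ABSENT", length(maf))
  present <- !is.na(maf) & maf > 0
  out[present & maf <= config$rare_maf_threshold] <- "PRESENT_RARE"
  out[present & maf > config$rare_maf_threshold &
        maf <= config$polymorphism_threshold] <- "EXCEEDS_RARE_THRESHOLD"
  out[present & maf > config$polymorphism_threshold] <- "POLYMORPHISM_EXCLUDED"
  out
}

#' Audit reported pathogenic variants against reference frequencies
#'
#' Re-examines lists of variants previously reported as disease-causing
#' (e.g. literature-curated DM / DM? entries) in the light of a large
#' reference population: how many are observed at all, how many at a
#' frequency incompatible with penetrant disease, and what cumulative
#' fraction of reference individuals carries at least one reported variant
#' (approximated by the capped sum of allele counts — individual-level
#' de-duplication is not possible from summary data).
#'
#' @param reported Reported-variant table
#'   (\code{\link{read_reported_table}}).
#' @param reference Reference site table
#'   (\code{\link{read_reference_table}}).
#' @param config A \code{\link{frequency_config}}.
#' @return An object of class \code{"variant_audit"}: list with
#'   \code{variants} (per-variant status table) and \code{summary} (per
#'   disease: \code{n_reported}, \code{n_observed},
#'   \code{prop_observed} — observed at any frequency, after polymorphism
#'   exclusion —, \code{n_above_rare}, \code{prop_above_rare},
#'   \code{cumulative_carrier_freq}).
#' @export
audit_reported <- function(reported, reference,
                           config = frequency_config()) {
  stopifnot(inherits(config, "frequency_config"))
  idx <- match(reported$variant_id, reference$variant_id)
  ac <- reference$ac[idx]
  an <- reference$an[idx]
  maf <- ifelse(is.na(idx) | ac == 0, NA_real_, ac / an)
  status <- classify_reported(maf, config)
  variants <- cbind(reported,
                    data.frame(reference_ac = ac, reference_an = an,
                               reference_maf = maf, status = status,
                               stringsAsFactors = FALSE))

  per_disease <- lapply(split(variants, variants$disease), function(v) {
    kept <- v[v$status != "POLYMORPHISM_EXCLUDED", , drop = FALSE]
    n <- nrow(kept)
    observed <- kept$status %in% c("PRESENT_RARE", "EXCEEDS_RARE_THRESHOLD")
    n_eff <- if (any(observed)) mean(kept$reference_an[observed]) / 2 else NA_real_
    carriers <- if (any(observed)) min(sum(kept$reference_ac[observed]), n_eff)
                else 0
    data.frame(
      disease = v$disease[1], n_reported = n,
      n_polymorphism_excluded = sum(v$status == "POLYMORPHISM_EXCLUDED"),
      n_observed = sum(observed),
      prop_observed = if (n > 0) sum(observed) / n else 0,
      n_above_rare = sum(kept$status == "EXCEEDS_RARE_THRESHOLD"),
      prop_above_rare = if (n > 0)
        sum(kept$status == "EXCEEDS_RARE_THRESHOLD") / n else 0,
      cumulative_carrier_freq = if (is.na(n_eff) || n_eff == 0) 0
                                else carriers / n_eff,
      stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, per_disease)
  rownames(summary) <- NULL
  structure(list(variants = variants, summary = summary, config = config),
            class = "variant_audit")
}

#' @export
print.variant_audit <- function(x, ...) {
  cat("Reported-variant frequency audit\n")
  cat("  rare MAF threshold:", format(x$config$rare_maf_threshold),
      " polymorphism threshold:", format(x$config$polymorphism_threshold),
      "\n")
  s <- x$summary
  s$prop_observed <- round(s$prop_observed, 3)
  s$prop_above_rare <- round(s$prop_above_rare, 3)
  s$cumulative_carrier_freq <- round(s$cumulative_carrier_freq, 3)
  print.data.frame(s, row.names = FALSE)
  invisible(x)
}
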