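#' @name tables
#' @title Input tables: cases, reference sites, panel, reported variants
#'
#' @description
#' All inputs are summary-level, UTF-8, tab-separated tables with a mandatory
#' header row; lines starting with \code{#} are comments.
#'
#' \strong{Case table} (one row per distinct variant observed in a disease
#' cohort): columns \code{disease}, \code{gene}, \code{variant_id},
#' \code{consequence}, \code{carrier_count} (number of cases carrying the
#' variant), optional \code{protein_pos} (1-based residue) and
#' \code{reported_class} (P / LP / VUS / unclassified).
#'
#' \strong{Reference table} (one row per site/alt in the reference
#' population): columns \code{gene}, \code{variant_id}, \code{consequence},
#' \code{ac} (alternate allele count), \code{an} (total alleles genotyped at
#' the site), optional \code{protein_pos}. Alternatively a sites-only VCF
#' with INFO fields \code{AC} (per alt) and \code{AN}; see
#' \code{\link{read_reference_table}}.
#'
#' \strong{Panel table}: columns \code{disease}, \code{gene}, \code{n_cases}
#' (cases sequenced for that gene), \code{protein_length} (residues of the
#' canonical transcript), optional \code{transcript_id}.
#'
#' \strong{Reported-variant table} (for the audit): columns \code{disease},
#' \code{gene}, \code{variant_id}, \code{reported_tag} (DM or DM?).
NULL

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = TRUE,
                    na.strings = c("NA", ""))
}

# all-NA or zero-row columns are read as logical; pin string columns so
# empty tables round-trip with stable types
.as_chr <- function(df, cols) {
  for (col in intersect(cols, names(df))) df[[col]] <- as.character(df[[col]])
  df
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing required column(s) in '", basename(path), "': ",
         paste(missing, collapse = ", "), call. = FALSE)
}

.check_integerish <- function(x, name, path) {
  xn <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(xn) & !is.na(x) | (!is.na(xn) & xn != round(xn)))
  if (length(bad))
    stop("non-integer ", name, " in '", basename(path), "' at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  as.integer(round(xn))
}

#' Read a case variant table
#'
#' @param path Path to a tab-separated case table (see \link{tables}).
#' @return A \code{data.frame} with columns \code{disease}, \code{gene},
#'   \code{variant_id}, \code{consequence}, \code{protein_pos} (integer, NA
#'   when absent), \code{carrier_count}, \code{reported_class}.
#' @export
read_case_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("disease", "gene", "variant_id", "consequence",
                         "carrier_count"), path)
  df <- .as_chr(df, c("disease", "gene", "variant_id", "consequence",
                      "reported_class"))
  df$carrier_count <- .check_integerish(df$carrier_count, "carrier_count", path)
  bad <- which(df$carrier_count < 1L)
  if (length(bad))
    stop("carrier_count must be >= 1; violated at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (is.null(df$protein_pos)) df$protein_pos <- NA_integer_
  df$protein_pos <- .check_integerish(df$protein_pos, "protein_pos", path)
  if (any(df$protein_pos < 1L, na.rm = TRUE))
    stop("protein_pos must be >= 1 (1-based residues)", call. = FALSE)
  if (is.null(df$reported_class)) df$reported_class <- NA_character_
  known <- c("P", "LP", "VUS", "unclassified")
  odd <- setdiff(unique(df$reported_class[!is.na(df$reported_class)]), known)
  if (length(odd))
    warning("unrecognised reported_class value(s): ",
            paste(odd, collapse = ", "), call. = FALSE)
  df[c("disease", "gene", "variant_id", "consequence", "protein_pos",
       "carrier_count", "reported_class")]
}

#' Write a case variant table
#'
#' Inverse of \code{\link{read_case_table}}; a round trip preserves all
#' field values.
#'
#' @param cases Data frame as returned by \code{read_case_table}.
#' @param path Output path.
#' @export
write_case_table <- function(cases, path) {
  utils::write.table(cases, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a reference population site table
#'
#' Ingests per-site reference summaries carrying alternate allele counts
#' (AC) and total genotyped alleles (AN), either from a TSV or from a
#' sites-only VCF. For VCF input only PASS-filter records are retained
#' (dropped records are reported), and multiallelic records are decomposed
#' into one row per alternate allele using the per-alt AC. Gene, consequence
#' and protein position are taken from INFO fields \code{GENE}, \code{CSQ}
#' and \code{PPOS} when present.
#'
#' @param path Path to the table.
#' @param format \code{"tsv"} or \code{"vcf_sites"}.
#' @return Data frame with columns \code{gene}, \code{variant_id},
#'   \code{consequence}, \code{protein_pos}, \code{ac}, \code{an}.
#' @export
read_reference_table <- function(path, format = c("tsv", "vcf_sites")) {
  format <- match.arg(format)
  df <- if (format == "tsv") .read_reference_tsv(path) else .read_reference_vcf(path)
  if (any(df$an <= 0L))
    stop("reference site with AN <= 0", call. = FALSE)
  if (any(df$ac > df$an))
    stop("reference site with AC > AN (allele count exceeds alleles genotyped)",
         call. = FALSE)
  if (any(df$ac < 0L))
    stop("negative AC in reference table", call. = FALSE)
  odd_an <- df$an %% 2L != 0L
  if (any(odd_an))
    warning(sum(odd_an), " reference site(s) with odd AN (expected even for ",
            "diploid chromosomes)", call. = FALSE)
  df
}

.read_reference_tsv <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("gene", "variant_id", "consequence", "ac", "an"), path)
  df <- .as_chr(df, c("gene", "variant_id", "consequence"))
  df$ac <- .check_integerish(df$ac, "ac", path)
  df$an <- .check_integerish(df$an, "an", path)
  if (is.null(df$protein_pos)) df$protein_pos <- NA_integer_
  df$protein_pos <- .check_integerish(df$protein_pos, "protein_pos", path)
  df[c("gene", "variant_id", "consequence", "protein_pos", "ac", "an")]
}

.read_reference_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF reference tables requires the 'vcfR' package",
         call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.null(dim(fix))) t(fix) else fix
  filt <- fix[, "FILTER"]
  keep <- is.na(filt) | filt %in% c("PASS", ".")
  if (any(!keep))
    message(sum(!keep), " non-PASS VCF record(s) dropped")
  info_field <- function(key) vcfR::extract.info(v, element = key)
  ac_raw <- info_field("AC")
  an_raw <- info_field("AN")
  gene   <- info_field("GENE")
  csq    <- info_field("CSQ")
  ppos   <- info_field("PPOS")
  if (all(is.na(an_raw))) stop("VCF is missing the AN INFO field", call. = FALSE)

  rows <- lapply(which(keep), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    acs  <- suppressWarnings(as.integer(strsplit(ac_raw[i], ",", fixed = TRUE)[[1L]]))
    if (length(acs) != length(alts))
      stop("VCF record ", fix[i, "CHROM"], ":", fix[i, "POS"],
           " has ", length(alts), " ALT allele(s) but ", length(acs),
           " AC value(s)", call. = FALSE)
    an <- suppressWarnings(as.integer(an_raw[i]))
    if (is.na(an))
      stop("VCF record ", fix[i, "CHROM"], ":", fix[i, "POS"],
           " is missing AN", call. = FALSE)
    data.frame(
      gene = if (is.na(gene[i])) NA_character_ else gene[i],
      variant_id = paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alts,
                         sep = ":"),
      consequence = if (length(csq) && !is.na(csq[i])) csq[i] else NA_character_,
      protein_pos = if (length(ppos) && !is.na(ppos[i]))
        suppressWarnings(as.integer(ppos[i])) else NA_integer_,
      ac = acs, an = an,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), variant_id = character(0),
                      consequence = character(0), protein_pos = integer(0),
                      ac = integer(0), an = integer(0))
  rownames(out) <- NULL
  out
}

#' Read a panel definition table
#'
#' @param path Path to a tab-separated panel table (see \link{tables}).
#' @return Data frame with columns \code{disease}, \code{gene},
#'   \code{n_cases}, \code{protein_length}, \code{transcript_id}.
#' @export
read_panel_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("disease", "gene", "n_cases", "protein_length"), path)
  df <- .as_chr(df, c("disease", "gene", "transcript_id"))
  df$n_cases <- .check_integerish(df$n_cases, "n_cases", path)
  df$protein_length <- .check_integerish(df$protein_length, "protein_length", path)
  if (any(df$n_cases <= 0L)) stop("n_cases must be > 0", call. = FALSE)
  if (any(df$protein_length <= 0L)) stop("protein_length must be > 0", call. = FALSE)
  if (is.null(df$transcript_id)) df$transcript_id <- NA_character_
  if (anyDuplicated(df[c("disease", "gene")]))
    stop("duplicate disease/gene entries in panel table", call. = FALSE)
  df[c("disease", "gene", "n_cases", "protein_length", "transcript_id")]
}

#' Read a reported-pathogenic variant table
#'
#' Lists variants previously reported as disease-causing (e.g. literature
#' curation tags DM / DM?), for the frequency audit.
#'
#' @param path Path to a tab-separated reported-variant table.
#' @param tags Which curation tags to admit (default both DM and DM?).
#' @return Data frame with columns \code{disease}, \code{gene},
#'   \code{variant_id}, \code{reported_tag}.
#' @export
read_reported_table <- function(path, tags = c("DM", "DM?")) {
  df <- .read_tsv(path)
  .require_columns(df, c("disease", "gene", "variant_id", "reported_tag"), path)
  df <- .as_chr(df, c("disease", "gene", "variant_id", "reported_tag"))
  df <- df[df$reported_tag %in% tags, , drop = FALSE]
  rownames(df) <- NULL
  df[c("disease", "gene", "variant_id", "reported_tag")]
}
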