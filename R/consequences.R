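#' Variant consequence vocabulary and burden classes
#'
#' Rare-variant burden comparisons consider only likely protein-altering
#' variants on the designated canonical transcript, split into two classes:
#' \emph{truncating} (frameshift, nonsense/stop-gained, essential splice
#' donor/acceptor, i.e. the first and last two bases of each intron) and
#' \emph{nontruncating} (missense and in-frame insertions/deletions).
#' Everything else (synonymous, deeper intronic, UTR, ...) is excluded from
#' burden testing.
#'
#' Sequence Ontology terms are canonical; a small alias table admits legacy
#' spellings ("nonsense", "stop gained", ...).
#'
#' @name consequence-classes
NULL

# canonical SO term -> burden class
.CONSEQUENCE_CLASS <- c(
  frameshift_variant       = "TRUNCATING",
  stop_gained              = "TRUNCATING",
  splice_donor_variant     = "TRUNCATING",
  splice_acceptor_variant  = "TRUNCATING",
  missense_variant         = "NONTRUNCATING",
  inframe_insertion        = "NONTRUNCATING",
  inframe_deletion         = "NONTRUNCATING"
)

# legacy / free-text spellings -> canonical SO term
.CONSEQUENCE_ALIASES <- c(
  "frameshift"            = "frameshift_variant",
  "nonsense"              = "stop_gained",
  "stop gained"           = "stop_gained",
  "stopgain"              = "stop_gained",
  "splice_donor"          = "splice_donor_variant",
  "splice donor"          = "splice_donor_variant",
  "splice_acceptor"       = "splice_acceptor_variant",
  "splice acceptor"       = "splice_acceptor_variant",
  "missense"              = "missense_variant",
  "inframe insertion"     = "inframe_insertion",
  "in-frame insertion"    = "inframe_insertion",
  "inframe deletion"      = "inframe_deletion",
  "in-frame deletion"     = "inframe_deletion"
)

# terms we recognise as valid but excluded from burden classes (no warning)
.CONSEQUENCE_KNOWN_EXCLUDED <- c(
  "synonymous_variant", "synonymous", "intron_variant", "intronic",
  "5_prime_utr_variant", "3_prime_utr_variant", "utr",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant",
  "splice_region_variant", "stop_retained_variant", "start_retained_variant",
  "non_coding_transcript_variant"
)

#' Full consequence vocabulary recognised by the package
#'
#' @return Character vector of all consequence terms (canonical Sequence
#'   Ontology terms, their accepted aliases, and recognised excluded terms).
#' @export
consequence_vocabulary <- function() {
  unique(c(names(.CONSEQUENCE_CLASS), names(.CONSEQUENCE_ALIASES),
           .CONSEQUENCE_KNOWN_EXCLUDED))
}

#' Classify a variant consequence term into a burden class
#'
#' Maps each consequence term to exactly one of \code{"TRUNCATING"},
#' \code{"NONTRUNCATING"} or \code{"EXCLUDED"}. Unknown or empty terms are
#' classified \code{"EXCLUDED"} with a warning so they can never leak
#' silently into a burden class.
#'
#' Intronic terms of the form \code{"intronic_+k"} / \code{"intronic_-k"}
#' (offset from the nearest exon boundary) classify as truncating for
#' |k| <= 2 (essential splice site) and excluded otherwise.
#'
#' @param term Character vector of consequence terms.
#' @return Character vector, same length, of burden classes.
#' @examples
#' classify_consequence(c("frameshift", "missense", "synonymous"))
#' @export
classify_consequence <- function(term) {
  if (length(term) == 0L) return(character(0))
  term_chr <- trimws(tolower(as.character(term)))
  out <- character(length(term_chr))

  canon <- ifelse(term_chr %in% names(.CONSEQUENCE_ALIASES),
                  .CONSEQUENCE_ALIASES[term_chr], term_chr)
  cls <- .CONSEQUENCE_CLASS[canon]
  out[!is.na(cls)] <- cls[!is.na(cls)]

  todo <- is.na(cls)
  if (any(todo)) {
    # intronic offsets: first/last two intron bases are essential splice sites
    m <- regmatches(term_chr[todo],
                    regexec("^intronic_([+-])([0-9]+)$", term_chr[todo]))
    off <- vapply(m, function(g) if (length(g) == 3L) as.integer(g[3L]) else NA_integer_,
                  integer(1))
    is_intronic_offset <- !is.na(off)
    cls2 <- rep(NA_character_, sum(todo))
    cls2[is_intronic_offset & off <= 2L] <- "TRUNCATING"
    cls2[is_intronic_offset & off > 2L]  <- "EXCLUDED"
    known_excl <- term_chr[todo] %in% .CONSEQUENCE_KNOWN_EXCLUDED
    cls2[is.na(cls2) & known_excl] <- "EXCLUDED"
    unknown <- is.na(cls2)
    if (any(unknown)) {
      bad <- unique(term_chr[todo][unknown])
      bad[bad == ""] <- "<empty>"
      warning("unknown consequence term(s) classified EXCLUDED: ",
              paste(bad, collapse = ", "), call. = FALSE)
      cls2[unknown] <- "EXCLUDED"
    }
    out[todo] <- cls2
  }
  unname(out)
}

#' Burden variant classes
#'
#' @return Character vector \code{c("TRUNCATING", "NONTRUNCATING")}, the two
#'   protein-altering classes tested (plus their union \code{"ALL"} in
#'   results).
#' @export
variant_classes <- function() c("TRUNCATING", "NONTRUNCATING")
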