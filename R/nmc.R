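#' Normalize protein residue positions for the order-statistic model
#'
#' Scales 1-based residue indices onto (0, 1] by the protein length and
#' collapses duplicates: distinct substitutions at one residue carry no
#' spacing information, and the continuous order-statistic model degenerates
#' at zero gaps.
#'
#' @param positions Integer vector of residue positions (1-based).
#' @param protein_length Protein length L in residues.
#' @return Sorted unique values \code{positions / L} in (0, 1].
#' @export
normalize_positions <- function(positions, protein_length) {
  stopifnot(length(protein_length) == 1L, protein_length >= 1)
  if (any(positions < 1 | positions > protein_length))
    stop("residue positions must lie in [1, protein_length]", call. = FALSE)
  sort(unique(positions)) / protein_length
}

#' Beta order-statistic p-value for a pair of mutation positions
#'
#' Under the null that n mutation positions are uniform on the protein, the
#' spacing between the i-th and j-th order statistics follows
#' Beta(j - i, n - j + i + 1). The p-value is that Beta CDF at the observed
#' (normalized) gap: a small value means the two positions are closer than
#' uniformity predicts, i.e. clustering.
#'
#' @param i,j Order indices, 1 <= i < j <= n.
#' @param n Total number of (distinct) positions.
#' @param gap Observed normalized spacing x_(j) - x_(i), in [0, 1].
#' @return Lower-tail Beta CDF at \code{gap}.
#' @examples
#' nmc_pair_pvalue(1, 2, 2, 0.1)  # 1 - (1 - 0.1)^2 = 0.19
#' @export
nmc_pair_pvalue <- function(i, j, n, gap) {
  if (any(i < 1 | j <= i | j > n)) stop("need 1 <= i < j <= n", call. = FALSE)
  if (any(gap < 0 | gap > 1)) stop("gap must lie in [0, 1]", call. = FALSE)
  stats::pbeta(gap, j - i, n - j + i + 1)
}

#' Nonrandom mutation clustering scan over protein positions
#'
#' Scans the distinct residue positions of rare missense variants for
#' segments more densely mutated than expected under positional uniformity.
#' Every pair of order statistics is tested with
#' \code{\link{nmc_pair_pvalue}}; Benjamini-Hochberg FDR control is applied
#' across all n(n-1)/2 pairs; significant pairs are mapped back to residue
#' intervals and overlapping intervals are merged into maximal clusters.
#'
#' @param positions Residue positions (1-based) of distinct variants.
#' @param protein_length Protein length in residues.
#' @param fdr_threshold FDR level q for calling a pair significant
#'   (default 0.05).
#' @param gene,cohort Optional labels, carried into the result.
#' @return An object of class \code{"nmc_scan"}: list with
#'   \code{clusters} (data frame: \code{start_residue}, \code{end_residue},
#'   \code{n_in_cluster}, \code{p_value} = minimum pair p inside the merged
#'   interval, \code{q_value} = its BH-adjusted value), \code{pairs} (all
#'   pair tests), \code{n}, \code{protein_length}, \code{fdr_threshold},
#'   \code{gene}, \code{cohort}.
#' @export
nmc_scan <- function(positions, protein_length, fdr_threshold = 0.05,
                     gene = NULL, cohort = NULL) {
  pos <- sort(unique(positions))
  empty <- data.frame(start_residue = integer(0), end_residue = integer(0),
                      n_in_cluster = integer(0), p_value = numeric(0),
                      q_value = numeric(0))
  if (length(pos) < 2L) {
    warning("fewer than 2 distinct positions; no scan performed",
            call. = FALSE)
    return(structure(list(clusters = empty, pairs = NULL, n = length(pos),
                          protein_length = protein_length,
                          fdr_threshold = fdr_threshold,
                          gene = gene, cohort = cohort),
                     class = "nmc_scan"))
  }
  x <- normalize_positions(pos, protein_length)
  n <- length(x)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  gap <- x[j] - x[i]
  p <- nmc_pair_pvalue(i, j, n, gap)
  q <- stats::p.adjust(p, method = "BH")
  pairs <- data.frame(i = i, j = j,
                      start_residue = pos[i], end_residue = pos[j],
                      gap = gap, p_value = p, q_value = q)
  sig <- pairs[pairs$q_value <= fdr_threshold, , drop = FALSE]
  clusters <- if (nrow(sig) == 0L) empty else .merge_intervals(sig, pos)
  structure(list(clusters = clusters, pairs = pairs, n = n,
                 protein_length = protein_length,
                 fdr_threshold = fdr_threshold, gene = gene, cohort = cohort),
            class = "nmc_scan")
}

# merge overlapping significant pair intervals into maximal clusters
.merge_intervals <- function(sig, pos) {
  sig <- sig[order(sig$start_residue, sig$end_residue), , drop = FALSE]
  starts <- sig$start_residue; ends <- sig$end_residue
  grp <- integer(nrow(sig)); g <- 1L; grp[1L] <- g
  cur_end <- ends[1L]
  for (k in seq_len(nrow(sig))[-1L]) {
    if (starts[k] <= cur_end) {
      grp[k] <- g
      cur_end <- max(cur_end, ends[k])
    } else {
      g <- g + 1L; grp[k] <- g; cur_end <- ends[k]
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(sig)), grp), function(rows) {
    s <- min(starts[rows]); e <- max(ends[rows])
    best <- rows[which.min(sig$p_value[rows])]
    data.frame(start_residue = s, end_residue = e,
               n_in_cluster = sum(pos >= s & pos <= e),
               p_value = sig$p_value[best], q_value = sig$q_value[best])
  }))
  rownames(out) <- NULL
  out[order(out$start_residue), , drop = FALSE]
}

#' @export
print.nmc_scan <- function(x, ...) {
  cat("Nonrandom mutation clustering scan\n")
  if (!is.null(x$gene)) cat("  gene:", x$gene,
                            if (!is.null(x$cohort)) paste0("(", x$cohort, ")"),
                            "\n")
  cat("  distinct positions:", x$n, " protein length:", x$protein_length, "\n")
  cat("  FDR threshold q <=", x$fdr_threshold, "\n")
  if (nrow(x$clusters) == 0L) {
    cat("  no significant clusters\n")
  } else {
    cat("  clusters:\n")
    print.data.frame(
      within(x$clusters, {p_value <- signif(p_value, 3)
                          q_value <- signif(q_value, 3)}),
      row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.nmc_scan <- function(x, ...) {
  if (is.null(x$pairs)) stop("nothing to plot: no scan performed")
  pos <- sort(unique(c(x$pairs$start_residue, x$pairs$end_residue)))
  graphics::plot(NA, xlim = c(1, x$protein_length), ylim = c(0, 1.2),
                 xlab = "protein residue", ylab = "", yaxt = "n",
                 main = if (!is.null(x$gene)) x$gene else "", ...)
  graphics::segments(pos, 0, pos, 0.6, col = grDevices::grey(0.4))
  if (nrow(x$clusters)) {
    graphics::rect(x$clusters$start_residue, 0.8,
                   x$clusters$end_residue, 1.1,
                   col = grDevices::adjustcolor("orange", 0.6), border = NA)
  }
  invisible(x)
}

#' Cluster-restricted etiological fraction
#'
#' Recomputes the nontruncating burden comparison of one gene using only
#' variants whose protein position lies inside a residue interval
#' (typically a cluster from \code{\link{nmc_scan}}), keeping the
#' gene-level denominators: the same number of cases and the same
#' coverage-adjusted effective reference size as the unrestricted
#' nontruncating comparison. Positional restriction therefore changes only
#' the carrier counts, so an interval covering the whole protein reproduces
#' the unrestricted result.
#'
#' @param cases Case variant table.
#' @param reference Reference site table.
#' @param gene Gene symbol.
#' @param interval Length-2 integer vector \code{c(start, end)}, residues,
#'   inclusive.
#' @param n_cases Number of cases sequenced for the gene.
#' @param config A \code{\link{frequency_config}}.
#' @param alpha,m,conf.level As in \code{\link{gene_burden}}.
#' @return A one-row data frame in the \code{gene_burden} result layout
#'   (variant_class \code{"NONTRUNCATING[start-end]"}), or, when no case
#'   variant falls inside the interval, the same row with \code{NA} effect
#'   estimates and a warning (EF undefined).
#' @export
cluster_ef <- function(cases, reference, gene, interval, n_cases,
                       config = frequency_config(), alpha = 0.05, m = 1L,
                       conf.level = 0.95) {
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  filt <- filter_rare(cases[cases$gene == gene, , drop = FALSE],
                      reference[reference$gene == gene, , drop = FALSE],
                      config)
  gcase <- filt$cases[filt$cases$variant_class == "NONTRUNCATING", , drop = FALSE]
  gref <- filt$reference[filt$reference$variant_class == "NONTRUNCATING", , drop = FALSE]
  if (anyNA(gcase$protein_pos) || anyNA(gref$protein_pos))
    warning("nontruncating variant(s) without protein_pos excluded from ",
            "positional restriction", call. = FALSE)

  # gene-level denominator: fixed across intervals
  gene_all_an <- reference$an[reference$gene == gene]
  fallback <- if (length(gene_all_an)) stats::median(gene_all_an) else NULL
  refsum <- summarize_reference_gene(gref, fallback_an = fallback)
  n_eff <- refsum$n_ref_effective

  in_int <- function(p) !is.na(p) & p >= interval[1] & p <= interval[2]
  ccase <- gcase[in_int(gcase$protein_pos), , drop = FALSE]
  cref <- gref[in_int(gref$protein_pos), , drop = FALSE]
  label <- sprintf("NONTRUNCATING[%d-%d]", interval[1], interval[2])

  if (nrow(ccase) == 0L) {
    warning("no case variants inside [", interval[1], ", ", interval[2],
            "]; EF undefined", call. = FALSE)
    return(data.frame(disease = unique(c(cases$disease, NA))[1], gene = gene,
                      variant_class = label, n_cases = n_cases,
                      n_ref_effective = n_eff, case_carriers = 0,
                      ref_carriers = min(sum(cref$ac), n_eff),
                      case_freq = 0, ref_freq = NA_real_,
                      case_excess = NA_real_, fisher_p = NA_real_,
                      significant = NA, or_point = NA_real_,
                      or_lo = NA_real_, or_hi = NA_real_,
                      ef_point = NA_real_, ef_lo = NA_real_, ef_hi = NA_real_,
                      predicted_pathogenic = NA_real_,
                      stringsAsFactors = FALSE))
  }

  a <- min(sum(ccase$carrier_count), n_cases)
  b <- n_cases - a
  c <- min(sum(cref$ac), n_eff)
  d <- n_eff - c
  p <- fisher_exact(a, b, c, d)
  orci <- odds_ratio_ci(a, b, c, d, conf.level = conf.level)
  ef <- etiological_fraction(orci)
  excess <- case_excess(a / n_cases, c / n_eff)
  data.frame(disease = ccase$disease[1], gene = gene, variant_class = label,
             n_cases = n_cases, n_ref_effective = n_eff,
             case_carriers = a, ref_carriers = c,
             case_freq = a / n_cases, ref_freq = c / n_eff,
             case_excess = excess, fisher_p = p,
             significant = p <= bonferroni_threshold(alpha, m),
             or_point = unname(orci["or"]), or_lo = unname(orci["lo"]),
             or_hi = unname(orci["hi"]),
             ef_point = unname(ef[1]), ef_lo = unname(ef[2]),
             ef_hi = unname(ef[3]),
             predicted_pathogenic = predicted_pathogenic(excess, n_cases),
             stringsAsFactors = FALSE)
}
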