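#' @export
print.gene_burden <- function(x, ...) {
  res <- x$results
  cat("Rare-variant burden fit\n")
  cat("  diseases:", paste(names(x$m), collapse = ", "), "\n")
  cat("  genes tested:",
      paste(sprintf("%s (m = %d)", names(x$m), unlist(x$m)), collapse = ", "),
      "\n")
  cat("  rare MAF threshold:", format(x$config$rare_maf_threshold), "\n")
  nsig <- sum(res$significant[res$variant_class == "ALL"])
  cat("  significant genes (ALL class, Bonferroni ", format(x$alpha), "): ",
      nsig, " / ", sum(res$variant_class == "ALL"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gene_burden <- function(object, variant_class = "ALL", ...) {
  res <- object$results
  res <- res[res$variant_class %in% variant_class, , drop = FALSE]
  out <- res[order(res$disease, -res$case_excess),
             c("disease", "gene", "variant_class", "n_cases",
               "case_freq", "ref_freq", "case_excess", "fisher_p",
               "significant", "or_point", "or_lo", "or_hi",
               "ef_point", "ef_lo", "ef_hi")]
  rownames(out) <- NULL
  structure(list(table = out, alpha = object$alpha, m = object$m),
            class = "summary.gene_burden")
}

#' @export
print.summary.gene_burden <- function(x, digits = 3, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print.data.frame(tab, row.names = FALSE)
  thr <- vapply(x$m, function(m) bonferroni_threshold(x$alpha, m), numeric(1))
  cat("Bonferroni thresholds: ",
      paste(sprintf("%s p <= %.4g", names(x$m), thr), collapse = "; "),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.gene_burden <- function(x, ...) x$results

#' Effect estimates from a burden fit
#'
#' @param object A \code{\link{gene_burden}} fit.
#' @param ... Unused.
#' @return Matrix with one row per gene x class (rownames
#'   \code{disease:gene:class}) and columns \code{or}, \code{or_lo},
#'   \code{or_hi}, \code{ef}, \code{ef_lo}, \code{ef_hi}.
#' @export
coef.gene_burden <- function(object, ...) {
  res <- object$results
  out <- as.matrix(res[c("or_point", "or_lo", "or_hi",
                         "ef_point", "ef_lo", "ef_hi")])
  colnames(out) <- c("or", "or_lo", "or_hi", "ef", "ef_lo", "ef_hi")
  rownames(out) <- paste(res$disease, res$gene, res$variant_class, sep = ":")
  out
}

#' Genetic-landscape plot of a burden fit
#'
#' Case excess (contribution of the gene to the disease) against etiological
#' fraction (interpretability of a variant found in a case), one point per
#' gene, for a chosen variant class. Significant genes are filled.
#'
#' @param x A \code{\link{gene_burden}} fit.
#' @param variant_class Which class to plot (default \code{"ALL"}).
#' @param ... Passed to \code{plot}.
#' @export
plot.gene_burden <- function(x, variant_class = "ALL", ...) {
  res <- x$results[x$results$variant_class == variant_class, , drop = FALSE]
  graphics::plot(res$ef_point, pmax(0, res$case_excess),
                 xlab = "etiological fraction",
                 ylab = "case excess (proportion of cases)",
                 xlim = c(0, 1),
                 pch = ifelse(res$significant, 19, 1), ...)
  graphics::text(res$ef_point, pmax(0, res$case_excess), labels = res$gene,
                 pos = 3, cex = 0.7)
  invisible(x)
}
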