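#' Run the full burden pipeline on input tables
#'
#' End-to-end orchestration: reads the case, reference and panel tables,
#' applies the rare-variant filter, fits the per-gene burden comparisons,
#' and (optionally) runs the mutation-clustering scan for requested genes
#' and the reported-variant audit. Writes, under \code{out_dir}: the burden
#' results as TSV and as a machine-readable JSON "atlas" keyed by
#' disease/gene/class, optional cluster and audit TSVs, and a run manifest
#' recording the configuration and input checksums so a run can be replayed
#' and verified. Reruns on identical inputs produce identical outputs. Any
#' stage failure aborts with a stage-named error and partial outputs are
#' removed.
#'
#' Etiological fraction and case excess are emitted both as fractions and as
#' x100 percentage columns.
#'
#' @param case_path,reference_path,panel_path Input table paths.
#' @param out_dir Output directory (created).
#' @param reference_format \code{"tsv"} or \code{"vcf_sites"}.
#' @param disease Optional disease restriction.
#' @param config A \code{\link{frequency_config}}.
#' @param alpha Family-wise error rate.
#' @param cluster_genes Character vector of genes to scan for missense
#'   clusters (default none).
#' @param reported_path Optional reported-variant table for the audit.
#' @param fdr_threshold FDR threshold for the cluster scan.
#' @return Invisibly, a list with the fitted \code{\link{gene_burden}}
#'   object, any \code{\link{nmc_scan}} results, any
#'   \code{\link{audit_reported}} result, and the manifest.
#' @export
run_pipeline <- function(case_path, reference_path, panel_path, out_dir,
                         reference_format = "tsv", disease = NULL,
                         config = frequency_config(), alpha = 0.05,
                         cluster_genes = character(0), reported_path = NULL,
                         fdr_threshold = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written), add = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  cases <- stage("variant_io", read_case_table(case_path))
  reference <- stage("variant_io",
                     read_reference_table(reference_path, reference_format))
  panel <- stage("variant_io", read_panel_table(panel_path))

  fit <- stage("burden",
               gene_burden(cases, reference, panel, disease = disease,
                           config = config, alpha = alpha))
  res <- fit$results
  res$case_excess_pct <- res$case_excess * 100
  res$ef_pct <- res$ef_point * 100

  burden_tsv <- file.path(out_dir, "burden.tsv")
  utils::write.table(res, burden_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  written <- c(written, burden_tsv)

  atlas <- lapply(split(res, paste(res$disease, res$gene, res$variant_class,
                                   sep = "/")),
                  function(r) as.list(r[1, ]))
  atlas_json <- file.path(out_dir, "burden.json")
  jsonlite::write_json(atlas, atlas_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, atlas_json)

  scans <- NULL
  if (length(cluster_genes)) {
    scans <- stage("clustering", {
      filt <- filter_rare(cases, reference, config)
      lapply(stats::setNames(cluster_genes, cluster_genes), function(g) {
        L <- panel$protein_length[match(g, panel$gene)]
        if (is.na(L)) stop("gene '", g, "' not in panel")
        pos <- filt$cases$protein_pos[filt$cases$gene == g &
                 filt$cases$variant_class == "NONTRUNCATING"]
        nmc_scan(pos[!is.na(pos)], L, fdr_threshold = fdr_threshold,
                 gene = g, cohort = "cases")
      })
    })
    cl <- do.call(rbind, lapply(scans, function(s)
      if (nrow(s$clusters)) cbind(gene = s$gene, s$clusters)))
    cluster_tsv <- file.path(out_dir, "clusters.tsv")
    utils::write.table(
      if (is.null(cl)) data.frame(gene = character(0),
                                  start_residue = integer(0),
                                  end_residue = integer(0),
                                  n_in_cluster = integer(0),
                                  p_value = numeric(0), q_value = numeric(0))
      else cl,
      cluster_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, cluster_tsv)
  }

  audit <- NULL
  if (!is.null(reported_path)) {
    audit <- stage("audit", {
      reported <- read_reported_table(reported_path)
      audit_reported(reported, reference, config)
    })
    audit_tsv <- file.path(out_dir, "audit_summary.tsv")
    utils::write.table(audit$summary, audit_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    variants_tsv <- file.path(out_dir, "audit_variants.tsv")
    utils::write.table(audit$variants, variants_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    written <- c(written, audit_tsv, variants_tsv)
  }

  inputs <- c(cases = unname(case_path), reference = unname(reference_path),
              panel = unname(panel_path),
              if (!is.null(reported_path)) c(reported = unname(reported_path)))
  manifest <- list(
    package = "geneburden",
    version = as.character(utils::packageVersion("geneburden")),
    inputs = as.list(inputs),
    input_md5 = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                        names(inputs))),
    reference_format = reference_format,
    disease = disease,
    config = unclass(config),
    alpha = alpha,
    cluster_genes = cluster_genes,
    fdr_threshold = fdr_threshold,
    outputs = written)
  manifest_json <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  written <- c(written, manifest_json)

  ok <- TRUE
  invisible(list(burden = fit, scans = scans, audit = audit,
                 manifest = manifest, outputs = written))
}
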