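# in-code fixtures shared across test files

make_case_df <- function() {
  data.frame(
    disease = "HCM",
    gene = c("MYH7", "MYH7", "MYBPC3"),
    variant_id = c("14:100:A:G", "14:200:C:T", "11:300:G:A"),
    consequence = c("missense_variant", "stop_gained", "frameshift_variant"),
    protein_pos = c(403L, 723L, 502L),
    carrier_count = c(4L, 1L, 2L),
    reported_class = c("P", "VUS", "LP"),
    stringsAsFactors = FALSE)
}

make_ref_df <- function() {
  data.frame(
    gene = c("MYH7", "MYH7", "MYBPC3"),
    variant_id = c("14:100:A:G", "14:900:T:C", "11:310:C:G"),
    consequence = c("missense_variant", "missense_variant",
                    "missense_variant"),
    protein_pos = c(403L, 1500L, 512L),
    ac = c(3L, 2L, 1L),
    an = c(121412L, 120000L, 119000L),
    stringsAsFactors = FALSE)
}

make_panel_df <- function() {
  data.frame(
    disease = "HCM", gene = c("MYH7", "MYBPC3"),
    n_cases = c(6179L, 6179L), protein_length = c(1935L, 1274L),
    transcript_id = NA_character_, stringsAsFactors = FALSE)
}

write_tsv_tmp <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

# independent two-sided Fisher p by full hypergeometric enumeration with
# log-binomial arithmetic (no dhyper); used as oracle against the package
enum_fisher_p <- function(a, b, c, d) {
  R1 <- a + b; R2 <- c + d; C1 <- a + c
  lo <- max(0, C1 - R2); hi <- min(C1, R1)
  xs <- lo:hi
  lp <- lchoose(R1, xs) + lchoose(R2, C1 - xs) - lchoose(R1 + R2, C1)
  pmf <- exp(lp)
  p_obs <- pmf[match(a, xs)]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}
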