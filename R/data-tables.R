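#' Bundled GTEx cohort sample table
#'
#' The example cohort used throughout the documentation: sample counts for
#' ten GTEx body sites across four tissues (artery, brain, lung, skeletal
#' muscle).
#'
#' @return data frame with columns `tissue`, `body_site`, `n_samples`.
#' @export
cohort_table <- function() {
  read.delim(system.file("extdata", "gtex_cohort_samples.tsv",
                         package = "rnaeditr"), stringsAsFactors = FALSE)
}

#' Bundled differential recoding site table
#'
#' Statistically significant differentially edited recoding sites between
#' tibial artery and cerebellum (GTEx). Delta editing follows the
#' group-2-minus-group-1 convention with groups ordered (artery,
#' cerebellum): negative values are artery-high sites. Raw Mann-Whitney p
#' and Benjamini-Hochberg adjusted p are included.
#'
#' @return data frame with columns `site`, `gene`, `aa_change`,
#'   `delta_editing`, `pval_mw`, `padj_bh`.
#' @export
recoding_site_table <- function() {
  read.delim(system.file("extdata", "artery_cerebellum_recoding_sites.tsv",
                         package = "rnaeditr"), stringsAsFactors = FALSE)
}
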