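#' Published pairwise Bayes factors
#'
#' The pairwise group-comparison statistics printed for the
#' shift-proportion and peak-velocity/amplitude outcomes in the study
#' this package emulates: chi-square, p, b, SE, BF10, BF01 and marginal
#' f2 for each group contrast.  Rows whose BF was only reported as a
#' bound (BF10 > 500, BF01 < 0.01) carry the bound value with
#' `bf10_bound`/`bf01_bound` set to `"gt"`/`"lt"`.  Used as a consistency
#' check on the BF10/BF01 reciprocal identity.
#'
#' @return Data.frame with one row per published comparison.
#' @export
published_bayes_factors <- function() {
  path <- system.file("extdata", "pairwise_bayes_factors.csv",
                      package = "gazeorient")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
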