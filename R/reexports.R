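#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`

utils::globalVariables(c(
  ".bin", "bin", "bin_lo", "bin_hi", "bin_lo_kb", "bin_hi_kb", "chrom",
  "animal", "animal_id", "coefficient", "density", "distance_mbp", "f",
  "f_roh", "kb", "kb_avg", "length_kb", "lo", "hi", "ma", "mb", "maf",
  "mean_r2", "mean_signed_r", "mid", "n_het", "n_pairs", "n_segments",
  "n_snps", "ne", "nseg", "nsnp", "PC1", "PC2", "population", "pos_bp",
  "r", "r2", "signed_r", "signed_r_a", "signed_r_b", "start_bp", "end_bp",
  "threshold", "total_roh_bp", "generations_ago", "surviving_markers",
  "surviving_animals", "p", "he", "ho", "marker_id"))
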