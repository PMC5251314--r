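#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg expectation `n * (p^2, 2pq, q^2)`, with the
#' allele frequency `p` estimated from the same counts. No continuity
#' correction. A monomorphic marker (p of 0 or 1) cannot be tested and
#' returns `chi2 = 0, p_value = 1` by convention.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (vectorised).
#' @return Tibble with columns `chi2` and `p_value`.
#' @export
#' @examples
#' hwe_chisq_test(25, 50, 25)  # exact HWE proportions: chi2 = 0
#' hwe_chisq_test(50, 0, 50)   # no heterozygotes: chi2 = 100
hwe_chisq_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(n == 0))
    stop("counts must be >= 0 with positive total", call. = FALSE)
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  mono <- p == 0 | p == 1
  e_AA <- n * p^2
  e_Aa <- n * 2 * p * q
  e_aa <- n * q^2
  chi2 <- ifelse(mono, 0,
                 (n_AA - e_AA)^2 / e_AA + (n_Aa - e_Aa)^2 / e_Aa +
                   (n_aa - e_aa)^2 / e_aa)
  pval <- ifelse(mono, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  tibble::tibble(chi2 = chi2, p_value = pval)
}

#' Per-marker QC statistics
#' @keywords internal
marker_qc_stats <- function(panel) {
  dos <- panel$dosages
  n_nonmiss <- unname(colSums(!is.na(dos)))
  n_AA <- unname(colSums(dos == 2L, na.rm = TRUE))
  n_Aa <- unname(colSums(dos == 1L, na.rm = TRUE))
  n_aa <- unname(colSums(dos == 0L, na.rm = TRUE))
  p <- ifelse(n_nonmiss > 0, (2 * n_AA + n_Aa) / (2 * n_nonmiss), NA_real_)
  hwe_p <- rep(1, ncol(dos))
  ok <- n_nonmiss > 0
  if (any(ok))
    hwe_p[ok] <- hwe_chisq_test(n_AA[ok], n_Aa[ok], n_aa[ok])$p_value
  tibble::tibble(
    marker_id = panel$map$marker_id,
    call_rate = n_nonmiss / nrow(dos),
    p = p,
    maf = pmin(p, 1 - p),
    hwe_p = hwe_p
  )
}

#' Apply genotype quality control
#'
#' Four sequential criteria: animals with call rate below `animal_cr_min`
#' are removed first; then markers are tested, each attributed to the first
#' criterion it fails in the fixed order MAF, SNP call rate,
#' Hardy-Weinberg. All frequencies use non-missing calls only. When a panel
#' spans several populations, run QC on each population separately
#' (see [split_panel()]); [run_pipeline()] does this.
#'
#' @param panel A [genotype_panel()].
#' @param snp_cr_min Minimum SNP call rate (default 0.90).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param hwe_p_min Minimum Hardy-Weinberg chi-square p-value
#'   (default 1e-6).
#' @param animal_cr_min Minimum per-animal call rate (default 0.90).
#' @return List with elements `panel` (the filtered [genotype_panel()]) and
#'   `report`, a tibble of class `qc_report` with per-criterion excluded
#'   counts, surviving ids and the thresholds used.
#' @export
apply_qc <- function(panel, snp_cr_min = 0.90, maf_min = 0.05,
                     hwe_p_min = 1e-6, animal_cr_min = 0.90) {
  if (n_markers(panel) == 0L || n_animals(panel) == 0L)
    stop("empty panel", call. = FALSE)
  animal_cr <- rowMeans(!is.na(panel$dosages))
  keep_animals <- animal_cr >= animal_cr_min
  n_animals_excluded <- sum(!keep_animals)
  p1 <- if (all(keep_animals)) panel else
    subset_panel(panel, animals = which(keep_animals))

  st <- marker_qc_stats(p1)
  fail_maf <- !is.na(st$maf) & st$maf < maf_min | is.na(st$maf)
  fail_cr <- !fail_maf & st$call_rate < snp_cr_min
  fail_hwe <- !fail_maf & !fail_cr & st$hwe_p < hwe_p_min
  keep <- !(fail_maf | fail_cr | fail_hwe)
  if (!any(keep))
    warning("all markers removed by QC", call. = FALSE)
  out <- subset_panel(p1, markers = which(keep))
  report <- tibble::tibble(
    n_markers_in = n_markers(panel),
    n_animals_in = n_animals(panel),
    excluded_maf = sum(fail_maf),
    excluded_snp_call_rate = sum(fail_cr),
    excluded_hwe = sum(fail_hwe),
    excluded_animals = n_animals_excluded,
    n_markers_out = sum(keep),
    n_animals_out = n_animals(out),
    maf_min = maf_min, snp_cr_min = snp_cr_min, hwe_p_min = hwe_p_min,
    animal_cr_min = animal_cr_min,
    surviving_markers = list(out$map$marker_id),
    surviving_animals = list(out$animals$animal_id)
  )
  class(report) <- c("qc_report", class(report))
  list(panel = out, report = report)
}

#' Screen for putatively misplaced SNPs
#'
#' A SNP placed at the wrong map position betrays itself by strong linkage
#' disequilibrium with physically distant markers combined with weak LD
#' with its mapped neighbours. For each marker this computes the fraction
#' of same-chromosome pairs farther than `d_far_mbp` whose r-squared is at
#' least `r2_high` (`far_high_ld_fraction`) and the mean r-squared with up
#' to 10 nearest markers within `d_near_mbp` (`near_mean_r2`); a marker is
#' flagged when the first is at least `far_fraction_min` and the second at
#' most `near_r2_max`. Chromosomes with a single marker are skipped.
#'
#' @param panel A post-QC [genotype_panel()].
#' @param d_far_mbp,d_near_mbp Distance thresholds in Mbp (defaults 10, 1).
#' @param r2_high Far-pair r-squared threshold (default 0.3).
#' @param far_fraction_min Flagging threshold on the far fraction
#'   (default 0.05).
#' @param near_r2_max Flagging threshold on the near mean (default 0.1).
#' @return Tibble with one row per screened marker: `marker_id`, `chrom`,
#'   `pos_bp`, `far_high_ld_fraction`, `near_mean_r2`, `flagged`.
#' @export
detect_misplaced_snps <- function(panel, d_far_mbp = 10, d_near_mbp = 1,
                                  r2_high = 0.3, far_fraction_min = 0.05,
                                  near_r2_max = 0.1) {
  chroms <- unique(panel$map$chrom)
  res <- purrr::map_dfr(chroms, function(ch) {
    idx <- which(panel$map$chrom == ch)
    if (length(idx) < 2L) return(tibble::tibble())
    sub <- subset_panel(panel, markers = idx)
    r2m <- ld_r2_matrix(sub$dosages)
    pos <- sub$map$pos_bp
    dmat <- abs(outer(pos, pos, "-")) / 1e6
    L <- length(idx)
    purrr::map_dfr(seq_len(L), function(i) {
      far <- which(dmat[i, ] > d_far_mbp)
      far_frac <- if (length(far) == 0L) 0 else
        mean(r2m[i, far] >= r2_high, na.rm = TRUE)
      if (is.nan(far_frac)) far_frac <- 0
      near <- setdiff(which(dmat[i, ] <= d_near_mbp & dmat[i, ] > 0), i)
      if (length(near) > 10L)
        near <- near[order(dmat[i, near])][1:10]
      near_r2 <- if (length(near) == 0L) NA_real_ else
        mean(r2m[i, near], na.rm = TRUE)
      tibble::tibble(
        marker_id = sub$map$marker_id[i], chrom = ch,
        pos_bp = pos[i],
        far_high_ld_fraction = far_frac,
        near_mean_r2 = near_r2,
        flagged = isTRUE(far_frac >= far_fraction_min &&
                           !is.na(near_r2) && near_r2 <= near_r2_max))
    })
  })
  res
}
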