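#' Composite linkage disequilibrium for one marker pair
#'
#' Estimates gametic disequilibrium directly from unphased diploid
#' genotypes, so no haplotype phasing is required. With dosages `x`, `y`
#' counting the counted alleles A and B over the `N` animals non-missing at
#' both markers,
#' \deqn{D = \frac{N}{N-1}\left[\frac{4N_{AABB} + 2(N_{AABb}+N_{AaBB}) +
#'   N_{AaBb}}{2N} - 2 f(A) f(B)\right],}
#' \deqn{r^2 = \frac{D^2}{f(A)f(a)f(B)f(b)},}
#' and the signed phase correlation is `sign(D) * sqrt(r2)` (with
#' `sign(0)` taken as +1). The double-homozygote-weighted joint count in
#' the bracket equals `sum(x * y)`, which is how it is computed. The
#' `N/(N-1)` small-sample factor can push the raw `r2` ratio above 1 on
#' tiny or degenerate samples; it is clamped at 1 so the signed transform
#' stays defined, and the clamp is reported.
#'
#' @param dosages_a,dosages_b Integer dosage vectors of equal length
#'   (values 0/1/2, `NA` missing).
#' @return One-row tibble: `D`, `r2`, `signed_r`, `n_animals`, `clamped`,
#'   `ok` (FALSE with a `reason` when the pair is unusable: fewer than two
#'   complete observations or a marker monomorphic among them).
#' @export
#' @examples
#' composite_ld_pair(c(2, 1, 1, 0), c(2, 2, 1, 1))
composite_ld_pair <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b))
  use <- !is.na(dosages_a) & !is.na(dosages_b)
  x <- as.numeric(dosages_a[use])
  y <- as.numeric(dosages_b[use])
  n <- length(x)
  bad <- function(reason) tibble::tibble(
    D = NA_real_, r2 = NA_real_, signed_r = NA_real_, n_animals = n,
    clamped = FALSE, ok = FALSE, reason = reason)
  if (n < 2L) return(bad("fewer than 2 complete observations"))
  fA <- sum(x) / (2 * n)
  fB <- sum(y) / (2 * n)
  if (fA <= 0 || fA >= 1) return(bad("marker a monomorphic"))
  if (fB <= 0 || fB >= 1) return(bad("marker b monomorphic"))
  D <- n / (n - 1) * (sum(x * y) / (2 * n) - 2 * fA * fB)
  raw <- D^2 / (fA * (1 - fA) * fB * (1 - fB))
  clamped <- raw > 1
  r2 <- min(raw, 1)
  sgn <- if (D < 0) -1 else 1
  tibble::tibble(D = D, r2 = r2, signed_r = sgn * sqrt(r2), n_animals = n,
                 clamped = clamped, ok = TRUE, reason = NA_character_)
}

#' All-pairs composite LD within one dosage matrix
#'
#' Matrix-form evaluation of [composite_ld_pair()] for every column pair,
#' handling missing data with per-pair complete observations via crossprod
#' identities. Returns the pieces needed by [ld_scan()].
#'
#' @param dos Animals-by-markers dosage matrix.
#' @return List of matrices `D`, `r2`, `n`, `ok`, `clamped`.
#' @keywords internal
ld_pair_matrices <- function(dos) {
  X <- dos
  storage.mode(X) <- "double"
  M <- 1 - is.na(X) * 1
  X0 <- X
  X0[is.na(X0)] <- 0
  N <- crossprod(M)            # complete pairs per marker pair
  SX <- crossprod(X0, M)       # sum of x over pairs complete with each j
  SXY <- crossprod(X0)         # sum x*y over complete pairs
  pA <- SX / (2 * N)           # freq of marker i's counted allele, pairwise
  pB <- t(pA)
  D <- N / (N - 1) * (SXY / (2 * N) - 2 * pA * pB)
  denom <- pA * (1 - pA) * pB * (1 - pB)
  raw <- D^2 / denom
  ok <- N >= 2 & pA > 0 & pA < 1 & pB > 0 & pB < 1
  clamped <- ok & !is.na(raw) & raw > 1
  r2 <- pmin(raw, 1)
  D[!ok] <- NA_real_
  r2[!ok] <- NA_real_
  list(D = D, r2 = r2, n = N, ok = ok, clamped = clamped)
}

#' r-squared matrix for one chromosome's dosages
#' @keywords internal
ld_r2_matrix <- function(dos) {
  m <- ld_pair_matrices(dos)
  r2 <- m$r2
  diag(r2) <- NA_real_
  r2
}

#' Scan within-chromosome marker pairs for composite LD
#'
#' Computes [composite_ld_pair()] for every same-chromosome marker pair up
#' to `max_distance_mbp` apart (or only map-consecutive pairs when
#' `adjacent_only`), in deterministic (chromosome, left marker, right
#' marker) order. Pairs that cannot be evaluated (monomorphic among the
#' complete observations, or fewer than two of them) are dropped; their
#' count is available as `attr(records, "n_skipped")`.
#'
#' @param panel A post-QC [genotype_panel()] (map sorted by construction).
#' @param max_distance_mbp Maximum pair distance in Mbp (default 5).
#' @param adjacent_only Only consecutive-marker pairs (default FALSE).
#' @return Tibble of class `ld_records`: `chrom`, `id_a`, `id_b`, `bp_a`,
#'   `bp_b`, `distance_mbp`, `D`, `r2`, `signed_r`, `n_animals`,
#'   `adjacent`.
#' @export
ld_scan <- function(panel, max_distance_mbp = 5, adjacent_only = FALSE) {
  chroms <- unique(panel$map$chrom)
  n_skipped <- 0L
  recs <- purrr::map_dfr(chroms, function(ch) {
    idx <- which(panel$map$chrom == ch)
    if (length(idx) < 2L) return(tibble::tibble())
    pos <- panel$map$pos_bp[idx]
    ids <- panel$map$marker_id[idx]
    L <- length(idx)
    ii <- rep(seq_len(L - 1L), times = (L - 1L):1L)
    jj <- unlist(lapply(seq_len(L - 1L), function(i) (i + 1L):L))
    if (adjacent_only) {
      keep <- jj == ii + 1L
      ii <- ii[keep]; jj <- jj[keep]
    }
    d <- (pos[jj] - pos[ii]) / 1e6
    keep <- d <= max_distance_mbp
    ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
    if (length(ii) == 0L) return(tibble::tibble())
    mats <- ld_pair_matrices(panel$dosages[, idx, drop = FALSE])
    lin <- cbind(ii, jj)
    ok <- mats$ok[lin]
    n_skipped <<- n_skipped + sum(!ok)
    tibble::tibble(
      chrom = ch,
      id_a = ids[ii], id_b = ids[jj],
      bp_a = pos[ii], bp_b = pos[jj],
      distance_mbp = d,
      D = mats$D[lin], r2 = mats$r2[lin],
      signed_r = ifelse(mats$D[lin] < 0, -1, 1) * sqrt(mats$r2[lin]),
      n_animals = mats$n[lin],
      adjacent = jj == ii + 1L
    )[ok, ]
  })
  attr(recs, "n_skipped") <- n_skipped
  class(recs) <- c("ld_records", class(recs))
  recs
}

#' Distance classes used for LD-level tables
#'
#' The default class bounds (Mbp): 0-0.01, 0.01-0.05, 0.05-0.10, 0.10-0.50,
#' 0.50-1.00, 1-2, 2-3, 3-4, 4-5, all half-open `[lo, hi)`.
#' @return Tibble with `lo`, `hi` columns in Mbp.
#' @export
ld_distance_classes <- function() {
  tibble::tibble(
    lo = c(0, 0.01, 0.05, 0.10, 0.50, 1, 2, 3, 4),
    hi = c(0.01, 0.05, 0.10, 0.50, 1, 2, 3, 4, 5))
}

#' Summarise LD records into decay bins, distance classes and useful-LD
#' fractions
#'
#' Three views of a set of pairwise LD records: fine distance bins of width
#' `bin_width_mbp` anchored at 0 (the decay curve), coarser distance-class
#' means, and — over the map-adjacent pairs — the fraction with r-squared
#' at or above each `useful_thresholds` value. All bins are half-open
#' `[lo, hi)`; empty bins are omitted.
#'
#' @param records An `ld_records` tibble from [ld_scan()].
#' @param bin_width_mbp Decay-curve bin width in Mbp (default 0.01).
#' @param distance_classes Tibble of `lo`/`hi` bounds
#'   (default [ld_distance_classes()]).
#' @param useful_thresholds Numeric thresholds for the adjacent-pair
#'   useful-LD fractions (default `c(0.2, 0.3)`).
#' @return List of class `ld_summary` with tibbles `bins` (`bin_lo`,
#'   `bin_hi`, `mean_r2`, `mean_signed_r`, `n_pairs`), `classes` (`lo`,
#'   `hi`, `mean_r2`, `n_pairs`) and `useful` (`threshold`, `fraction`,
#'   `n_adjacent`).
#' @export
summarize_ld <- function(records, bin_width_mbp = 0.01,
                         distance_classes = ld_distance_classes(),
                         useful_thresholds = c(0.2, 0.3)) {
  if (nrow(records) == 0L) stop("no LD records", call. = FALSE)
  bin <- floor(records$distance_mbp / bin_width_mbp)
  bins <- records |>
    dplyr::mutate(.bin = bin) |>
    dplyr::group_by(.bin) |>
    dplyr::summarise(mean_r2 = mean(r2), mean_signed_r = mean(signed_r),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin_lo = .bin * bin_width_mbp,
                  bin_hi = (.bin + 1) * bin_width_mbp) |>
    dplyr::select(bin_lo, bin_hi, mean_r2, mean_signed_r, n_pairs) |>
    dplyr::arrange(bin_lo)
  classes <- purrr::pmap_dfr(distance_classes, function(lo, hi) {
    sel <- records$distance_mbp >= lo & records$distance_mbp < hi
    if (!any(sel)) return(tibble::tibble())
    tibble::tibble(lo = lo, hi = hi, mean_r2 = mean(records$r2[sel]),
                   n_pairs = sum(sel))
  })
  adj <- records[records$adjacent, , drop = FALSE]
  useful <- tibble::tibble(
    threshold = useful_thresholds,
    fraction = vapply(useful_thresholds,
                      function(t) if (nrow(adj)) mean(adj$r2 >= t) else NA_real_,
                      numeric(1)),
    n_adjacent = nrow(adj))
  structure(list(bins = bins, classes = classes, useful = useful),
            class = "ld_summary")
}

#' @export
print.ld_summary <- function(x, ...) {
  cat("<ld_summary>\n")
  cat(sprintf("  decay bins: %d non-empty\n", nrow(x$bins)))
  if (nrow(x$classes)) {
    cat("  class means (Mbp -> mean r2):\n")
    for (i in seq_len(nrow(x$classes)))
      cat(sprintf("    %.2f-%.2f  %.3f  (n=%d)\n", x$classes$lo[i],
                  x$classes$hi[i], x$classes$mean_r2[i], x$classes$n_pairs[i]))
  }
  if (all(!is.na(x$useful$fraction)))
    cat(sprintf("  adjacent pairs with r2 >= %.2f: %.1f%%\n",
                x$useful$threshold, 100 * x$useful$fraction), sep = "")
  invisible(x)
}
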