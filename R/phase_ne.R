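#' Persistence of gametic phase between two populations
#'
#' The signed phase correlation `signed_r = sign(D) * sqrt(r2)` of a
#' marker pair encodes which allele combinations travel together. For two
#' populations whose panels share the same counted-allele coding, phase
#' persistence at a distance is the Pearson correlation, across the marker
#' pairs shared by both record sets within a distance bin, between the two
#' populations' signed r values. High values mean marker-QTL phases
#' transfer between the populations. Bins are half-open `[lo, hi)`
#' anchored at 0; bins with fewer than 3 shared pairs are omitted.
#'
#' Shared allele coding is a precondition: recoding one population's
#' counted alleles flips the sign of its signed r pair-by-pair and turns a
#' perfect correlation into -1. Panels exported from the same simulation
#' or read from files with a common allele policy satisfy it.
#'
#' The default correlates pair-level signed r within each bin. The
#' alternative reading — one overall Pearson correlation between the two
#' populations' bin-mean signed r curves — is available as
#' `method = "bin_means"` and returns a single row.
#'
#' @param records_a,records_b `ld_records` from [ld_scan()] on panels with
#'   a shared counted-allele coding.
#' @param bin_width_mbp Bin width in Mbp (default 0.05).
#' @param method `"pairwise"` (default) or `"bin_means"`.
#' @return Tibble of class `phase_persistence`: `bin_lo`, `bin_hi`, `r`,
#'   `n_pairs` (for `"bin_means"`: one row, `n_pairs` = number of bins).
#' @export
phase_persistence <- function(records_a, records_b, bin_width_mbp = 0.05,
                              method = c("pairwise", "bin_means")) {
  method <- match.arg(method)
  m <- dplyr::inner_join(
    tibble::as_tibble(records_a)[c("chrom", "id_a", "id_b", "distance_mbp",
                                   "signed_r")],
    tibble::as_tibble(records_b)[c("chrom", "id_a", "id_b", "signed_r")],
    by = c("chrom", "id_a", "id_b"), suffix = c("_a", "_b"))
  if (nrow(m) == 0L) {
    warning("no shared marker pairs", call. = FALSE)
    out <- tibble::tibble(bin_lo = numeric(), bin_hi = numeric(),
                          r = numeric(), n_pairs = integer())
    class(out) <- c("phase_persistence", class(out))
    return(out)
  }
  m$bin <- floor(m$distance_mbp / bin_width_mbp)
  if (method == "pairwise") {
    out <- m |>
      dplyr::group_by(bin) |>
      dplyr::summarise(
        r = if (dplyr::n() >= 3) stats::cor(signed_r_a, signed_r_b)
            else NA_real_,
        n_pairs = dplyr::n(), .groups = "drop") |>
      dplyr::filter(n_pairs >= 3) |>
      dplyr::mutate(bin_lo = bin * bin_width_mbp,
                    bin_hi = (bin + 1) * bin_width_mbp) |>
      dplyr::select(bin_lo, bin_hi, r, n_pairs)
  } else {
    means <- m |>
      dplyr::group_by(bin) |>
      dplyr::summarise(ma = mean(signed_r_a), mb = mean(signed_r_b),
                       .groups = "drop")
    out <- tibble::tibble(bin_lo = min(means$bin) * bin_width_mbp,
                          bin_hi = (max(means$bin) + 1) * bin_width_mbp,
                          r = stats::cor(means$ma, means$mb),
                          n_pairs = nrow(means))
  }
  class(out) <- c("phase_persistence", class(out))
  out
}

#' Invert Sved's expectation for effective population size
#'
#' Under drift-recombination equilibrium without mutation,
#' `E(r2) = 1 / (1 + 4 Ne c)` for loci `c` Morgans apart, so
#' `Ne = (1 / r2 - 1) / (4 c)`; the estimate at distance `c` reflects the
#' effective size `T = 1 / (2 c)` generations ago.
#'
#' @param mean_r2 Mean r-squared in a distance bin, in (0, 1).
#' @param c_morgans Bin-centre recombination distance in Morgans, > 0.
#' @return Numeric Ne (vectorised).
#' @export
#' @examples
#' sved_ne(0.2, 0.01)   # (5 - 1) / 0.04 = 100, at T = 50 generations
sved_ne <- function(mean_r2, c_morgans) {
  stopifnot(all(c_morgans > 0))
  ifelse(mean_r2 > 0 & mean_r2 < 1,
         (1 / mean_r2 - 1) / (4 * c_morgans), NA_real_)
}

#' LD-based effective population size trajectory
#'
#' Bins pairwise r-squared by physical distance on a two-resolution grid —
#' windows of half-width 0.05 Mbp at centres every 0.10 Mbp from 0.05 to
#' 10 Mbp, then every 0.5 Mbp out to 20 Mbp — converts each centre to
#' Morgans via `cm_per_mbp`, and inverts Sved's expectation per bin
#' ([sved_ne()]). Each bin dates its estimate at `T = 1/(2c)` generations
#' ago. Bins with fewer than `min_pairs` records or mean r-squared outside
#' (0, 1) are omitted. No sample-size correction of r-squared is applied
#' by default; `r2_adjust_n` subtracts `1/N` (the chord-sample bias term)
#' before inversion if wanted.
#'
#' @param records `ld_records` from [ld_scan()] (run with
#'   `max_distance_mbp` = 20 to populate the far grid).
#' @param near_step_mbp,near_max_mbp,far_step_mbp,far_max_mbp Grid layout
#'   in Mbp (defaults 0.10 to 10, then 0.5 to 20).
#' @param half_width_mbp Window half-width (default 0.05; windows are
#'   half-open `[centre - hw, centre + hw)`).
#' @param cm_per_mbp Map scaling, cM per Mbp (default 1).
#' @param min_pairs Minimum records per bin (default 10).
#' @param r2_adjust_n Subtract `1/N` from mean r-squared before inversion
#'   (default FALSE).
#' @return Tibble of class `ne_trajectory`: `c_morgans`, `generations_ago`
#'   (`T`), `mean_r2`, `n_pairs`, `ne`, ordered by increasing `T`.
#' @export
estimate_ne <- function(records, near_step_mbp = 0.10, near_max_mbp = 10,
                        far_step_mbp = 0.5, far_max_mbp = 20,
                        half_width_mbp = 0.05, cm_per_mbp = 1,
                        min_pairs = 10, r2_adjust_n = FALSE) {
  centers <- c(seq(near_step_mbp, near_max_mbp, by = near_step_mbp),
               seq(near_max_mbp + far_step_mbp, far_max_mbp,
                   by = far_step_mbp))
  eps <- 1e-9  # snap window edges (Mbp): guards binary representation of the grid
  rows <- purrr::map_dfr(centers, function(ct) {
    sel <- records$distance_mbp - (ct - half_width_mbp) >= -eps &
      records$distance_mbp - (ct + half_width_mbp) < -eps
    n <- sum(sel)
    if (n < min_pairs) return(tibble::tibble())
    r2 <- mean(records$r2[sel])
    if (r2_adjust_n) r2 <- r2 - 1 / mean(records$n_animals[sel])
    if (is.na(r2) || r2 <= 0 || r2 >= 1) return(tibble::tibble())
    c_m <- ct * cm_per_mbp / 100
    tibble::tibble(c_morgans = c_m, generations_ago = 1 / (2 * c_m),
                   mean_r2 = r2, n_pairs = n,
                   ne = sved_ne(r2, c_m))
  })
  if (nrow(rows) == 0L) {
    warning("no usable distance bins for Ne estimation", call. = FALSE)
    rows <- tibble::tibble(c_morgans = numeric(), generations_ago = numeric(),
                           mean_r2 = numeric(), n_pairs = integer(),
                           ne = numeric())
  }
  rows <- dplyr::arrange(rows, generations_ago)
  class(rows) <- c("ne_trajectory", class(rows))
  rows
}
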