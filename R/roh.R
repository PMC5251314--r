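#' Detect runs of homozygosity
#'
#' A run of homozygosity is a maximal within-chromosome marker interval
#' whose genotypes contain at least `min_snps` markers, at most `max_het`
#' heterozygous calls and at most `max_missing` missing calls, and whose
#' first and last markers are homozygous non-missing. "Maximal" means not
#' contained in any larger interval satisfying the same constraints; the
#' detector performs a left-to-right two-pointer scan whose output equals
#' exhaustive maximal-interval enumeration. This is a direct application
#' of the segment rules rather than a sliding-window heuristic, which is
#' recorded in `attr(, "method")` to explain numeric differences from
#' window-based tools.
#'
#' @param panel A post-QC [genotype_panel()] (autosomes).
#' @param min_snps Minimum markers per run (default 40).
#' @param max_het Maximum heterozygous calls per run (default 1).
#' @param max_missing Maximum missing calls per run (default 2).
#' @return Tibble of class `roh_segments`: `animal_id`, `population`,
#'   `chrom`, `start_bp`, `end_bp`, `n_snps`, `n_het`, `n_missing`,
#'   `length_kb`. Empty (zero-row) results are valid.
#' @export
detect_roh <- function(panel, min_snps = 40, max_het = 1, max_missing = 2) {
  chroms <- unique(panel$map$chrom)
  res <- purrr::map_dfr(seq_len(n_animals(panel)), function(a) {
    purrr::map_dfr(chroms, function(ch) {
      idx <- which(panel$map$chrom == ch)
      g <- panel$dosages[a, idx]
      runs <- maximal_homozygous_runs(g, min_snps, max_het, max_missing)
      if (nrow(runs) == 0L) return(tibble::tibble())
      pos <- panel$map$pos_bp[idx]
      tibble::tibble(
        animal_id = panel$animals$animal_id[a],
        population = panel$animals$population[a],
        chrom = ch,
        start_bp = pos[runs$start], end_bp = pos[runs$end],
        n_snps = runs$end - runs$start + 1L,
        n_het = runs$n_het, n_missing = runs$n_missing,
        length_kb = (pos[runs$end] - pos[runs$start]) / 1000)
    })
  })
  if (nrow(res) == 0L)
    res <- tibble::tibble(animal_id = character(), population = character(),
                          chrom = integer(), start_bp = integer(),
                          end_bp = integer(), n_snps = integer(),
                          n_het = integer(), n_missing = integer(),
                          length_kb = numeric())
  attr(res, "method") <- "maximal-run scan"
  class(res) <- c("roh_segments", class(res))
  res
}

#' Maximal constrained homozygous runs in one genotype vector
#'
#' Two-pointer scan over a single chromosome's dosages: for every
#' homozygous non-missing left endpoint, the furthest right endpoint that
#' is homozygous non-missing with the interval's het/missing counts within
#' budget; intervals contained in an earlier one are dropped, then the
#' `min_snps` filter applies. Containment cannot hide a long interval
#' inside a short one, so filtering after maximality is equivalent to
#' filtering within the enumeration.
#'
#' @param g Integer dosage vector (0/1/2/NA).
#' @return Tibble: `start`, `end` (marker indices), `n_het`, `n_missing`.
#' @keywords internal
maximal_homozygous_runs <- function(g, min_snps, max_het, max_missing) {
  L <- length(g)
  is_het <- !is.na(g) & g == 1L
  is_mis <- is.na(g)
  is_hom <- !is_het & !is_mis
  ches <- cumsum(is_het)
  cmis <- cumsum(is_mis)
  cnt <- function(cum, l, r) cum[r] - if (l > 1L) cum[l - 1L] else 0L
  hom_idx <- which(is_hom)
  starts <- integer(0); ends <- integer(0)
  best_r <- 0L
  r <- 0L
  for (l in hom_idx) {
    if (r < l) r <- l
    # extend r to the furthest homozygous endpoint with budget intact
    repeat {
      nxt <- r + 1L
      if (nxt > L) break
      # furthest homozygous position r2 > r reachable keeping counts ok
      # advance one homozygous endpoint at a time
      cand <- nxt
      while (cand <= L && !is_hom[cand]) cand <- cand + 1L
      if (cand > L) break
      if (cnt(ches, l, cand) <= max_het && cnt(cmis, l, cand) <= max_missing)
        r <- cand
      else break
    }
    if (r >= l && cnt(ches, l, r) <= max_het && cnt(cmis, l, r) <= max_missing) {
      if (r > best_r) {
        starts <- c(starts, l); ends <- c(ends, r)
        best_r <- r
      }
    }
  }
  keep <- (ends - starts + 1L) >= min_snps
  tibble::tibble(start = starts[keep], end = ends[keep],
                 n_het = vapply(which(keep), function(k)
                   cnt(ches, starts[k], ends[k]), integer(1)),
                 n_missing = vapply(which(keep), function(k)
                   cnt(cmis, starts[k], ends[k]), integer(1)))
}

#' ROH-based inbreeding coefficient
#'
#' `F_ROH` is the summed physical length of an animal's ROH segments
#' divided by the total autosomal map length covered by SNPs (sum over
#' chromosomes of last-SNP minus first-SNP position).
#'
#' @param segments ROH segments from [detect_roh()].
#' @param map The marker map the segments were detected on.
#' @return Tibble: `animal_id`, `f_roh`, `total_roh_bp`. Animals absent
#'   from `segments` are not listed; treat them as `f_roh = 0` (see
#'   [inbreeding_table()] which fills panel animals).
#' @export
f_roh <- function(segments, map) {
  if (nrow(map) == 0L) stop("empty map", call. = FALSE)
  genome_bp <- map |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(span = max(pos_bp) - min(pos_bp), .groups = "drop")
  total <- sum(genome_bp$span)
  if (total <= 0) stop("map spans zero length", call. = FALSE)
  segments |>
    dplyr::group_by(animal_id) |>
    dplyr::summarise(total_roh_bp = sum(end_bp - start_bp),
                     .groups = "drop") |>
    dplyr::mutate(f_roh = total_roh_bp / total) |>
    dplyr::select(animal_id, f_roh, total_roh_bp)
}

#' Summarise runs of homozygosity
#'
#' Per-animal counts and lengths (NSEG, total KB, mean segment KB, mean
#' SNPs per segment, density = mean kb per SNP within runs), their
#' per-population means and SDs, and a segment-length histogram.
#'
#' @param segments ROH segments from [detect_roh()].
#' @param panel The panel they were detected on (provides the animal
#'   roster, so ROH-free animals appear with NSEG 0).
#' @param length_breaks_kb Histogram bin edges in kb (default
#'   `c(0, 1000, 2000, 4000, 8000, 16000, Inf)`).
#' @return List of class `roh_summary`: tibbles `animals` (`animal_id`,
#'   `population`, `nseg`, `kb`, `kb_avg`, `nsnp`, `density`),
#'   `populations` (means and SDs of those), `histogram` (`population`,
#'   `bin_lo_kb`, `bin_hi_kb`, `n_segments`).
#' @export
summarize_roh <- function(segments, panel,
                          length_breaks_kb = c(0, 1000, 2000, 4000, 8000,
                                               16000, Inf)) {
  roster <- panel$animals[c("animal_id", "population")]
  per_an <- segments |>
    dplyr::group_by(animal_id) |>
    dplyr::summarise(nseg = dplyr::n(), kb = sum(length_kb),
                     kb_avg = mean(length_kb), nsnp = mean(n_snps),
                     .groups = "drop") |>
    dplyr::mutate(density = kb_avg / nsnp)
  animals <- roster |>
    dplyr::left_join(per_an, by = "animal_id") |>
    dplyr::mutate(nseg = dplyr::coalesce(nseg, 0L),
                  kb = dplyr::coalesce(kb, 0))
  populations <- animals |>
    dplyr::group_by(population) |>
    dplyr::summarise(
      nseg_mean = mean(nseg), nseg_sd = stats::sd(nseg),
      kb_mean = mean(kb), kb_sd = stats::sd(kb),
      kb_avg_mean = mean(kb_avg, na.rm = TRUE),
      kb_avg_sd = stats::sd(kb_avg[!is.na(kb_avg)]),
      nsnp_mean = mean(nsnp, na.rm = TRUE),
      density_mean = mean(density, na.rm = TRUE),
      n_animals = dplyr::n(), .groups = "drop")
  histogram <- if (nrow(segments)) {
    segments |>
      dplyr::mutate(bin = cut(length_kb, breaks = length_breaks_kb,
                              right = FALSE)) |>
      dplyr::group_by(population, bin) |>
      dplyr::summarise(n_segments = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(
        bin_lo_kb = length_breaks_kb[as.integer(bin)],
        bin_hi_kb = length_breaks_kb[as.integer(bin) + 1L]) |>
      dplyr::select(population, bin_lo_kb, bin_hi_kb, n_segments)
  } else tibble::tibble(population = character(), bin_lo_kb = numeric(),
                        bin_hi_kb = numeric(), n_segments = integer())
  structure(list(animals = animals, populations = populations,
                 histogram = histogram), class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat("<roh_summary>\n")
  print(x$populations)
  invisible(x)
}
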