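#' Excess-homozygosity inbreeding coefficient
#'
#' For animal dosages `c_i` and counted-allele frequencies `p_i`,
#' \deqn{F_{EH} = \frac{1}{m} \sum_i \left[1 - \frac{c_i (2 - c_i)}
#'   {2 p_i (1 - p_i)}\right]}
#' over the animal's non-missing markers (`m` is that non-missing count).
#' Markers with `p` of 0 or 1 are excluded. A fully heterozygous animal at
#' `p = 0.5` everywhere gives -1; a fully homozygous one gives +1.
#'
#' @param panel A [genotype_panel()].
#' @param freqs [allele_stats()] computed on the same panel, or reference
#'   (e.g. base-population) frequencies for the same markers; defaults to
#'   the panel's own.
#' @return Tibble: `animal_id`, `population`, `f_eh`, `n_markers_used`
#'   (`f_eh` is `NA` when no marker is usable).
#' @export
f_excess_homozygosity <- function(panel, freqs = allele_stats(panel)) {
  p <- match_freqs(panel, freqs)
  use <- !is.na(p) & p > 0 & p < 1
  dos <- panel$dosages[, use, drop = FALSE]
  p <- p[use]
  het_exp <- 2 * p * (1 - p)
  term <- 1 - sweep(dos * (2 - dos), 2, het_exp, "/")
  m <- unname(rowSums(!is.na(term)))
  f <- ifelse(m > 0, unname(rowSums(term, na.rm = TRUE)) / m, NA_real_)
  tibble::tibble(animal_id = panel$animals$animal_id,
                 population = panel$animals$population,
                 f_eh = f, n_markers_used = m)
}

#' VanRaden inbreeding coefficient
#'
#' \deqn{F_{VR} = \frac{\sum_i (c_i - 2 p_i)^2}{2 \sum_i p_i (1 - p_i)} - 1}
#' over the animal's non-missing markers. On a panel without missing calls
#' this equals the diagonal of the VanRaden genomic relationship matrix
#' minus 1 (see [build_grm()]); with missing calls the per-animal sums run
#' over the observed markers only.
#'
#' @inheritParams f_excess_homozygosity
#' @return Tibble: `animal_id`, `population`, `f_vr`, `n_markers_used`.
#' @export
f_vanraden <- function(panel, freqs = allele_stats(panel)) {
  p <- match_freqs(panel, freqs)
  use <- !is.na(p) & p > 0 & p < 1
  dos <- panel$dosages[, use, drop = FALSE]
  p <- p[use]
  dev2 <- sweep(dos, 2, 2 * p, "-")^2
  obs <- !is.na(dos)
  num <- unname(rowSums(dev2, na.rm = TRUE))
  den <- unname(2 * (obs %*% (p * (1 - p)))[, 1])
  f <- ifelse(den > 0, num / den - 1, NA_real_)
  tibble::tibble(animal_id = panel$animals$animal_id,
                 population = panel$animals$population,
                 f_vr = f, n_markers_used = unname(rowSums(obs)))
}

match_freqs <- function(panel, freqs) {
  stopifnot(inherits(freqs, "data.frame"),
            all(c("marker_id", "p") %in% names(freqs)))
  p <- freqs$p[match(panel$map$marker_id, freqs$marker_id)]
  if (all(is.na(p))) stop("no matching marker frequencies", call. = FALSE)
  p
}

#' Pedigree inbreeding coefficient (Wright's F)
#'
#' Computes every animal's inbreeding coefficient by the recursive tabular
#' method on the numerator relationship matrix: with animals in
#' parents-first order, `A[i,j] = (A[j,sire_i] + A[j,dam_i]) / 2` and
#' `A[i,i] = 1 + A[sire_i, dam_i] / 2`; `F = A[i,i] - 1`. Founders and
#' animals with an unknown parent get 0. This is numerically identical to
#' indirect-method implementations used for large pedigrees; the method
#' name is recorded in `attr(, "method")`.
#'
#' @param ped A pedigree from [read_pedigree()] / [as_pedigree()].
#' @return Tibble: `animal`, `f_ped`, with `attr(, "method") = "tabular"`.
#' @export
f_pedigree <- function(ped) {
  ped <- if (inherits(ped, "pedigree")) ped else as_pedigree(ped)
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      A[j, i] <- A[i, j] <- (as_ + ad_) / 2
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else A[s, d] / 2
  }
  out <- tibble::tibble(animal = id, f_ped = diag(A) - 1)
  attr(out, "method") <- "tabular"
  out
}

#' Assemble the per-animal inbreeding table
#'
#' Joins the four coefficients — excess homozygosity, VanRaden, ROH-based
#' and pedigree-based — for the panel's animals. Components whose inputs
#' are not supplied are filled with `NA`.
#'
#' @param panel A [genotype_panel()].
#' @param freqs Optional [allele_stats()] (defaults to the panel's own).
#' @param segments Optional ROH segments from [detect_roh()]; computed
#'   from the panel when `NULL` and `roh = TRUE`.
#' @param ped Optional pedigree for `f_ped`.
#' @param roh Compute F_ROH (default TRUE).
#' @param ... Passed to [detect_roh()].
#' @return Tibble of class `inbreeding_table`: `animal_id`, `population`,
#'   `f_eh`, `f_vr`, `f_roh`, `f_ped`.
#' @export
inbreeding_table <- function(panel, freqs = allele_stats(panel),
                             segments = NULL, ped = NULL, roh = TRUE, ...) {
  out <- f_excess_homozygosity(panel, freqs)[c("animal_id", "population",
                                               "f_eh")]
  out$f_vr <- f_vanraden(panel, freqs)$f_vr
  if (roh) {
    if (is.null(segments)) segments <- detect_roh(panel, ...)
    fr <- f_roh(segments, panel$map)
    out$f_roh <- fr$f_roh[match(out$animal_id, fr$animal_id)]
  } else out$f_roh <- NA_real_
  if (!is.null(ped)) {
    fp <- f_pedigree(ped)
    out$f_ped <- fp$f_ped[match(out$animal_id, fp$animal)]
  } else out$f_ped <- NA_real_
  class(out) <- c("inbreeding_table", class(out))
  out
}

#' Per-population summary of inbreeding coefficients
#'
#' @param table An [inbreeding_table()].
#' @return Tibble: `population`, `coefficient`, `mean`, `sd`, `min`, `max`,
#'   `n`.
#' @export
summarize_inbreeding <- function(table) {
  table |>
    tidyr::pivot_longer(dplyr::all_of(c("f_eh", "f_vr", "f_roh", "f_ped")),
                        names_to = "coefficient", values_to = "f") |>
    dplyr::filter(!is.na(f)) |>
    dplyr::group_by(population, coefficient) |>
    dplyr::summarise(mean = mean(f), sd = stats::sd(f), min = min(f),
                     max = max(f), n = dplyr::n(), .groups = "drop")
}

#' Pearson correlations among inbreeding coefficients
#'
#' Pairwise Pearson correlations among the four coefficients within each
#' population, on complete cases. A coefficient with zero variance in a
#' population (all F_PED of an F1 cross are exactly 0, for instance) has
#' no defined correlation; it is reported as 0 with `degenerate = TRUE`.
#'
#' @param table An [inbreeding_table()] with at least 3 complete-case
#'   animals per population.
#' @return Tibble: `population`, `coef_a`, `coef_b`, `r`, `n`,
#'   `degenerate`.
#' @export
inbreeding_correlations <- function(table) {
  coefs <- c("f_eh", "f_vr", "f_roh", "f_ped")
  present <- coefs[vapply(coefs, function(cc) any(!is.na(table[[cc]])),
                          logical(1))]
  purrr::map_dfr(split(table, table$population), function(tab) {
    cc <- tab[stats::complete.cases(tab[present]), present, drop = FALSE]
    if (nrow(cc) < 3L) return(tibble::tibble())
    pairs <- utils::combn(present, 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- cc[[pairs[1, k]]]; b <- cc[[pairs[2, k]]]
      degen <- stats::sd(a) == 0 || stats::sd(b) == 0
      tibble::tibble(
        population = tab$population[1],
        coef_a = pairs[1, k], coef_b = pairs[2, k],
        r = if (degen) 0 else stats::cor(a, b),
        n = nrow(cc), degenerate = degen)
    })
  })
}
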