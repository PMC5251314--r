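#' Per-marker allele statistics
#'
#' For each marker: the counted-allele frequency `p` on non-missing calls,
#' minor allele frequency `maf = min(p, 1 - p)`, observed heterozygosity
#' `ho` (fraction of non-missing calls that are heterozygous) and expected
#' heterozygosity `he = 2 p (1 - p)`. Markers with every call missing get
#' `NA` statistics and are excluded from panel means.
#'
#' @param panel A [genotype_panel()].
#' @return Tibble of class `allele_stats`: `marker_id`, `chrom`, `pos_bp`,
#'   `n_called`, `p`, `maf`, `ho`, `he`.
#' @export
allele_stats <- function(panel) {
  if (n_markers(panel) == 0L) stop("empty panel", call. = FALSE)
  dos <- panel$dosages
  n_called <- unname(colSums(!is.na(dos)))
  p <- ifelse(n_called > 0,
              unname(colSums(dos, na.rm = TRUE)) / (2 * n_called),
              NA_real_)
  ho <- ifelse(n_called > 0,
               unname(colSums(dos == 1L, na.rm = TRUE)) / n_called,
               NA_real_)
  out <- tibble::tibble(
    marker_id = panel$map$marker_id,
    chrom = panel$map$chrom,
    pos_bp = panel$map$pos_bp,
    n_called = n_called,
    p = p,
    maf = pmin(p, 1 - p),
    ho = ho,
    he = 2 * p * (1 - p)
  )
  class(out) <- c("allele_stats", class(out))
  out
}

#' Pairwise identity-by-state genetic distance
#'
#' For each animal pair, over the `N` loci non-missing in both: `IBS2` is
#' the number of identical genotypes (dosage difference 0), `IBS1` the
#' number sharing exactly one allele (dosage difference 1), and the
#' allele-sharing proportion is `D_ST = (IBS2 + 0.5 * IBS1) / N`. The
#' genetic distance is `D = 1 - D_ST`. Pairs with no jointly non-missing
#' loci get `NA`.
#'
#' @param panel A [genotype_panel()] with at least 2 animals.
#' @return A symmetric distance matrix of class `ibs_distance` (animals in
#'   rows/columns, diagonal 0) with the panel's animal table in
#'   `attr(, "animals")`.
#' @export
ibs_distance <- function(panel) {
  if (n_animals(panel) < 2L) stop("need >= 2 animals", call. = FALSE)
  X <- panel$dosages
  storage.mode(X) <- "double"
  M <- 1 - is.na(X) * 1
  X0 <- X
  X0[is.na(X0)] <- 0
  # |x - y| over complete loci via sum x^2 + y^2 - 2xy restricted to
  # jointly observed loci, split by difference size:
  N <- tcrossprod(M)
  Sxy <- tcrossprod(X0)
  Sx2 <- tcrossprod(X0^2, M)
  # sum (x-y)^2 over complete loci; diff in {0,1,2} so
  # #(|diff|=2) = (S2 - S1)/... use S1 = sum|diff| via |d| = d^2 - 2*(d^2==4)?
  S2 <- Sx2 + t(Sx2) - 2 * Sxy            # sum of squared differences
  # squared diff 4 <=> opposite homozygotes: count via indicator products
  A2 <- (X0 == 2) * M                      # hom counted, observed
  A0 <- (X0 == 0) * M                      # hom other, observed
  opp <- tcrossprod(A2, A0) + tcrossprod(A0, A2)  # #loci |diff| = 2
  ibs1 <- S2 - 4 * opp                     # #loci |diff| = 1
  ibs2 <- N - ibs1 - opp
  dst <- (ibs2 + 0.5 * ibs1) / N
  D <- 1 - dst
  D[N == 0] <- NA_real_
  diag(D) <- 0
  dimnames(D) <- list(panel$animals$animal_id, panel$animals$animal_id)
  attr(D, "animals") <- panel$animals
  class(D) <- c("ibs_distance", class(D))
  D
}

#' @export
tidy.ibs_distance <- function(x, ...) {
  ids <- rownames(x)
  n <- length(ids)
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  tibble::tibble(animal_a = ids[ii], animal_b = ids[jj],
                 distance = unclass(x)[cbind(ii, jj)])
}

#' Per-population genetic diversity summary
#'
#' Mean and SD of expected/observed heterozygosity and MAF over post-QC
#' markers (unweighted marker means), plus the mean off-diagonal
#' identity-by-state allele sharing `D_ST` and genetic distance `D` within
#' each population.
#'
#' @param panel A [genotype_panel()]; populations taken from its animal
#'   table.
#' @return Tibble with one row per population: `population`, `n_animals`,
#'   `n_markers`, `he_mean`, `he_sd`, `ho_mean`, `ho_sd`, `maf_mean`,
#'   `maf_sd`, `dst_mean`, `d_mean`.
#' @export
diversity_summary <- function(panel) {
  pops <- split_panel(panel, "population")
  purrr::imap_dfr(pops, function(p, name) {
    st <- allele_stats(p)
    st <- st[!is.na(st$p), ]
    if (n_animals(p) >= 2) {
      D <- ibs_distance(p)
      off <- unclass(D)[upper.tri(D)]
      d_mean <- mean(off, na.rm = TRUE)
    } else d_mean <- NA_real_
    tibble::tibble(
      population = name,
      n_animals = n_animals(p), n_markers = nrow(st),
      he_mean = mean(st$he), he_sd = stats::sd(st$he),
      ho_mean = mean(st$ho), ho_sd = stats::sd(st$ho),
      maf_mean = mean(st$maf), maf_sd = stats::sd(st$maf),
      dst_mean = 1 - d_mean, d_mean = d_mean)
  })
}
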