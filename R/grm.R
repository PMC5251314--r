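#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_i * (1 - p_i)))` where `Z` is the dosage matrix
#' column-centred by `2 p_i` over polymorphic markers. Missing dosages are
#' imputed at `2 p_i` (a zero-contribution entry of `Z`, the standard
#' VanRaden convention). On a complete panel `diag(G) - 1` equals the
#' VanRaden inbreeding coefficient of [f_vanraden()].
#'
#' @param panel A post-QC [genotype_panel()].
#' @param freqs [allele_stats()] for the same markers (defaults to the
#'   panel's own).
#' @return An animals-by-animals matrix of class `grm` with attributes
#'   `n_markers`, `animals` (the panel's animal table).
#' @export
build_grm <- function(panel, freqs = allele_stats(panel)) {
  p <- match_freqs(panel, freqs)
  use <- !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("no polymorphic markers", call. = FALSE)
  dos <- panel$dosages[, use, drop = FALSE]
  storage.mode(dos) <- "double"
  p <- p[use]
  Z <- sweep(dos, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(panel$animals$animal_id, panel$animals$animal_id)
  attr(G, "n_markers") <- sum(use)
  attr(G, "animals") <- panel$animals
  class(G) <- c("grm", class(G))
  G
}

#' Principal components of the genomic relationship matrix
#'
#' Eigendecomposition of the double-centred GRM (`H G H` with
#' `H = I - 11'/n`), the standard population-structure projection. Scores
#' are eigenvectors scaled by the square root of their eigenvalues;
#' variance fractions are eigenvalues over the sum of positive
#' eigenvalues. Requested components beyond the matrix rank are dropped
#' with a message.
#'
#' @param grm A [build_grm()] result.
#' @param k Number of components (default 2).
#' @return Object of class `grm_pca`: list with `scores` (tibble
#'   `animal_id`, `population`, `PC1`..), `variance_fraction`,
#'   `eigenvalues`.
#' @export
principal_components <- function(grm, k = 2) {
  n <- nrow(grm)
  stopifnot(k >= 1, k <= n)
  G <- unclass(grm)
  Gc <- sweep(G, 1, rowMeans(G))
  Gc <- sweep(Gc, 2, colMeans(Gc))
  eg <- eigen(Gc, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-12
  rank_ <- sum(pos)
  if (k > rank_) {
    message("requested ", k, " components but rank is ", rank_,
            "; truncating")
    k <- rank_
  }
  if (k == 0L) stop("degenerate GRM: no positive eigenvalues", call. = FALSE)
  lam <- eg$values[seq_len(k)]
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  colnames(scores) <- paste0("PC", seq_len(k))
  animals <- attr(grm, "animals")
  out <- list(
    scores = dplyr::bind_cols(
      tibble::tibble(animal_id = animals$animal_id,
                     population = animals$population),
      tibble::as_tibble(scores)),
    variance_fraction = lam / sum(eg$values[pos]),
    eigenvalues = eg$values)
  class(out) <- "grm_pca"
  out
}

#' @export
print.grm_pca <- function(x, ...) {
  k <- length(x$variance_fraction)
  cat(sprintf("<grm_pca> %d components, variance fractions: %s\n", k,
              paste(sprintf("%.2f%%", 100 * x$variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.grm_pca <- function(x, ...) x$scores

#' @export
glance.grm_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$variance_fraction),
    variance_fraction_total = sum(x$variance_fraction),
    pc1_fraction = x$variance_fraction[1],
    pc2_fraction = if (length(x$variance_fraction) >= 2)
      x$variance_fraction[2] else NA_real_)
}
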