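# Fixture with known violations: 50 animals, 12 markers of which
# 3 fail MAF < 0.05, 2 fail call rate < 0.90, 1 fails HWE at p < 1e-6,
# 6 are clean. Built deterministically from genotype counts.
qc_fixture <- function() {
  n <- 50
  col_from_counts <- function(n0, n1, n2, n_miss = 0) {
    c(rep(0L, n0), rep(1L, n1), rep(2L, n2), rep(NA_integer_, n_miss))
  }
  cols <- list(
    maf1 = col_from_counts(50, 0, 0),          # monomorphic, MAF 0
    maf2 = col_from_counts(49, 1, 0),          # MAF 0.01
    maf3 = col_from_counts(48, 2, 0),          # MAF 0.02
    cr1 = col_from_counts(20, 14, 10, 6),      # call rate 44/50 = 0.88
    cr2 = col_from_counts(14, 20, 10, 6),      # call rate 0.88
    hwe1 = col_from_counts(25, 0, 25),         # chi2 = 100, p ~ 1.5e-23
    ok1 = col_from_counts(13, 24, 13),
    ok2 = col_from_counts(18, 24, 8),
    ok3 = col_from_counts(8, 24, 18),
    ok4 = col_from_counts(12, 26, 12),
    ok5 = col_from_counts(20, 22, 8),
    ok6 = col_from_counts(10, 25, 15))
  # spread the missing calls of cr1/cr2 over distinct animals so every
  # animal keeps call rate >= 11/12
  dos <- matrix(NA_integer_, n, 12)
  for (j in seq_along(cols)) {
    v <- cols[[j]]
    miss <- is.na(v)
    if (any(miss)) {
      slots <- if (j == 4) 1:6 else 7:12
      vv <- rep(NA_integer_, n)
      vv[-slots] <- v[!miss]
      v <- vv
    }
    dos[, j] <- v
  }
  map <- tibble::tibble(marker_id = names(cols), chrom = 1L,
                        pos_bp = seq_len(12) * 1000L)
  animals <- tibble::tibble(animal_id = sprintf("a%02d", 1:n),
                            population = "P1", herd = "H1")
  genotype_panel(dos, map, animals)
}


string_panel <- function(g, spacing_bp = 10000L) {
  g <- as.integer(g)
  map <- tibble::tibble(marker_id = sprintf("m%03d", seq_along(g)),
                        chrom = 1L, pos_bp = seq_along(g) * spacing_bp)
  an <- tibble::tibble(animal_id = "a1", population = "P")
  genotype_panel(matrix(g, 1), map, an)
}

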