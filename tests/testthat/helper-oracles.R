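# Independent oracles used to cross-check the package's implementations.
# Each one is written from the definition, against a different code path
# than the function it checks.

# Composite LD via explicit 3x3 genotype contingency table.
ld_pair_table_oracle <- function(x, y) {
  use <- !is.na(x) & !is.na(y)
  x <- x[use]; y <- y[use]
  n <- length(x)
  tab <- table(factor(x, 0:2), factor(y, 0:2))
  fA <- (2 * sum(tab["2", ]) + sum(tab["1", ])) / (2 * n)
  fB <- (2 * sum(tab[, "2"]) + sum(tab[, "1"])) / (2 * n)
  D <- n / (n - 1) *
    ((4 * tab["2", "2"] + 2 * (tab["2", "1"] + tab["1", "2"]) +
        tab["1", "1"]) / (2 * n) - 2 * fA * fB)
  raw <- D^2 / (fA * (1 - fA) * fB * (1 - fB))
  list(D = as.numeric(D), r2 = min(as.numeric(raw), 1))
}

# All maximal homozygous-run intervals by exhaustive enumeration:
# every (l, r) with homozygous non-missing endpoints and het/missing
# counts within budget is enumerated; intervals contained in another
# valid interval are discarded; then the min_snps filter applies.
roh_bruteforce <- function(g, min_snps = 40, max_het = 1, max_missing = 2) {
  L <- length(g)
  is_het <- !is.na(g) & g == 1L
  is_mis <- is.na(g)
  is_hom <- !is_het & !is_mis
  ch <- c(0L, cumsum(is_het))
  cm <- c(0L, cumsum(is_mis))
  hom <- which(is_hom)
  lmax <- integer(0)  # per left endpoint, the largest valid right endpoint
  ls <- integer(0)
  for (l in hom) {
    r <- hom[hom >= l]
    ok <- (ch[r + 1L] - ch[l]) <= max_het & (cm[r + 1L] - cm[l]) <= max_missing
    if (!any(ok)) next
    ls <- c(ls, l)
    lmax <- c(lmax, max(r[ok]))
  }
  if (!length(ls)) return(cbind(start = integer(0), end = integer(0)))
  # an interval is maximal iff no valid interval with l' <= l has r' >= r
  keep <- lmax > cummax(c(0L, lmax))[seq_along(lmax)]
  res <- cbind(start = ls[keep], end = lmax[keep])
  res[res[, 2] - res[, 1] + 1L >= min_snps, , drop = FALSE]
}

# Wright's inbreeding coefficient by common-ancestor path counting.
# ped: tibble with animal, sire, dam (NA = unknown).
f_path_oracle <- function(ped, animal) {
  sire_of <- stats::setNames(ped$sire, ped$animal)
  dam_of <- stats::setNames(ped$dam, ped$animal)
  parents <- function(a) {
    p <- c(sire_of[[a]], dam_of[[a]])
    p[!is.na(p)]
  }
  # all upward paths starting at a (each path a character vector)
  paths_up <- function(a) {
    out <- list(a)
    for (p in parents(a))
      out <- c(out, lapply(paths_up(p), function(pp) c(a, pp)))
    out
  }
  f_of <- function(a) {
    s <- sire_of[[a]]; d <- dam_of[[a]]
    if (is.na(s) || is.na(d)) return(0)
    ps <- paths_up(s)
    pd <- paths_up(d)
    f <- 0
    for (p1 in ps) for (p2 in pd) {
      anc <- p1[length(p1)]
      if (p2[length(p2)] != anc) next
      # paths must share only the common ancestor
      if (length(intersect(p1[-length(p1)], p2[-length(p2)])) > 0) next
      if (anc %in% p1[-length(p1)] || anc %in% p2[-length(p2)]) next
      n1 <- length(p1) - 1L
      n2 <- length(p2) - 1L
      f <- f + 0.5^(n1 + n2 + 1) * (1 + f_of(anc))
    }
    f
  }
  f_of(animal)
}

# Every pedigree topology on n ordered animals: animal i's sire and dam
# each chosen from {unknown, 1, ..., i-1}, distinct when both known.
enumerate_pedigrees <- function(n) {
  choices <- lapply(seq_len(n), function(i) {
    opts <- expand.grid(s = 0:(i - 1), d = 0:(i - 1))
    opts[opts$s == 0 | opts$d == 0 | opts$s != opts$d, , drop = FALSE]
  })
  grids <- expand.grid(lapply(choices, function(df) seq_len(nrow(df))))
  lapply(seq_len(nrow(grids)), function(k) {
    s <- vapply(seq_len(n), function(i) choices[[i]]$s[grids[k, i]], 0)
    d <- vapply(seq_len(n), function(i) choices[[i]]$d[grids[k, i]], 0)
    tibble::tibble(
      animal = as.character(seq_len(n)),
      sire = ifelse(s == 0, NA_character_, as.character(s)),
      dam = ifelse(d == 0, NA_character_, as.character(d)),
      population = NA_character_)
  })
}

# random ordered pedigree on n animals (parents precede offspring)
random_pedigree <- function(n, p_founder = 0.3) {
  s <- d <- rep(NA_character_, n)
  for (i in 2:n) {
    if (stats::runif(1) < p_founder) next
    pool <- seq_len(i - 1)
    if (length(pool) == 1L) {
      s[i] <- "1"
    } else {
      pick <- sample(pool, 2)
      s[i] <- as.character(pick[1]); d[i] <- as.character(pick[2])
    }
  }
  tibble::tibble(animal = as.character(seq_len(n)), sire = s, dam = d,
                 population = NA_character_)
}

# quick random panel builder (no missing calls unless asked)
random_panel <- function(n_animals, n_markers, n_chrom = 1,
                         miss_rate = 0, maf_range = c(0.1, 0.5),
                         population = "P1", id_prefix = "a") {
  p <- stats::runif(n_markers, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n_animals * n_markers, 2,
                              rep(p, each = n_animals)),
                n_animals, n_markers)
  if (miss_rate > 0)
    dos[stats::runif(length(dos)) < miss_rate] <- NA_integer_
  chrom <- rep(seq_len(n_chrom), length.out = n_markers)
  pos <- unlist(lapply(seq_len(n_chrom), function(ch)
    seq_len(sum(chrom == ch)) * 50000L))
  map <- tibble::tibble(
    marker_id = sprintf("m%04d", seq_len(n_markers)),
    chrom = sort(chrom), pos_bp = pos)
  animals <- tibble::tibble(
    animal_id = sprintf("%s%03d", id_prefix, seq_len(n_animals)),
    population = population, herd = "H1")
  genotype_panel(dos, map, animals)
}

# pre-sorted pedigree without the igraph validation round-trip (the
# enumeration helpers always emit parents-first order)
as_sorted_pedigree <- function(ped) {
  structure(ped, class = c("pedigree", class(tibble::tibble())))
}
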