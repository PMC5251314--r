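test_that("identical seeds give bitwise-identical simulations", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_cm = 50,
                    n_markers = 100, ne = 30, burn_in_generations = 10,
                    seed = 91)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$panel$dosages, b$panel$dosages)
  expect_identical(tibble::as_tibble(a$pedigree),
                   tibble::as_tibble(b$pedigree))
})

test_that("config validation rejects bad trajectories and ranges", {
  expect_error(sim_config(ne_trajectory = data.frame(generation = 2, n = 10),
                          burn_in_generations = 5), "generation 1")
  expect_error(sim_config(ne_trajectory = data.frame(generation = c(1, 99),
                                                     n = c(10, 10)),
                          burn_in_generations = 5), "beyond the burn-in")
  expect_error(sim_config(init_maf_range = c(0, 0.5)))
  expect_error(sim_config(n_markers = 1))
})

test_that("a declining-size trajectory is honoured in the census", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_cm = 20,
                    n_markers = 50, burn_in_generations = 6,
                    ne_trajectory = data.frame(generation = c(1, 4),
                                               n = c(40, 12)),
                    seed = 92)
  sim <- simulate_population(cfg)
  expect_equal(n_animals(sim$panel), 12)
})

test_that("without recombination offspring chromosomes are exact parental copies", {
  # near-zero genetic length: no crossovers can occur; check transmission
  # through an F1 cross where parent genotypes are observable
  pa <- simulate_population(sim_config(
    n_chromosomes = 1, chrom_length_cm = 1e-6, n_markers = 50, ne = 20,
    burn_in_generations = 3, seed = 93, cm_per_mbp = 1e-8, label = "PA"))
  pb <- simulate_population(sim_config(
    n_chromosomes = 1, chrom_length_cm = 1e-6, n_markers = 50, ne = 20,
    burn_in_generations = 3, seed = 94, cm_per_mbp = 1e-8, label = "PB"))
  f1 <- make_f1(pa, pb, 1000)
  ped <- tibble::as_tibble(f1$pedigree)
  ped <- ped[ped$population == "F1", ]
  ped <- ped[match(f1$panel$animals$animal_id, ped$animal), ]  # panel row order
  sire_dos <- pa$panel$dosages[ped$sire, , drop = FALSE]
  dam_dos <- pb$panel$dosages[ped$dam, , drop = FALSE]
  off <- f1$panel$dosages
  # transmissible bounds: each parent passes 1 allele copy
  lower <- (sire_dos == 2L) + (dam_dos == 2L)
  upper <- (sire_dos >= 1L) + (dam_dos >= 1L)
  expect_true(all(off >= lower & off <= upper))
  # Mendelian 1:2:1 at the marker with the most double-heterozygous matings
  dd <- (sire_dos == 1L) & (dam_dos == 1L)
  j <- which.max(colSums(dd))
  counts <- table(factor(off[dd[, j], j], levels = 0:2))
  expect_gt(sum(counts), 100)
  p <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.01)
})

test_that("allele-frequency drift variance matches p(1-p)/(2N)", {
  sim <- simulate_population(sim_config(
    n_chromosomes = 1, chrom_length_cm = 100, n_markers = 500, ne = 100,
    burn_in_generations = 1, init_maf_range = c(0.3, 0.5), seed = 95))
  p0 <- sim$truth$founder_freq[[1]]
  p1 <- colMeans(sim$panel$dosages) / 2
  drift_var <- mean((p1 - p0)^2)
  expected <- mean(p0 * (1 - p0)) / (2 * 100)
  expect_lt(abs(drift_var - expected) / expected, 0.2)
})

test_that("LD at Sved equilibrium: tightly linked mean r2 near 1/(1+4Nec)", {
  sim <- simulate_population(sim_config(
    n_chromosomes = 4, chrom_length_cm = 100, n_markers = 100, ne = 100,
    burn_in_generations = 150, seed = 96))
  recs <- ld_scan(sim$panel, max_distance_mbp = 1.01, adjacent_only = TRUE)
  # adjacent spacing 1 cM -> c = 0.01 M, E(r2) = 1/5
  got <- mean(recs$r2)
  expect_lt(abs(got - 0.2) / 0.2, 0.3)
})

test_that("drift raises r2 between tightly linked loci when recombination is off", {
  early <- simulate_population(sim_config(
    n_chromosomes = 1, chrom_length_cm = 1e-6, n_markers = 40, ne = 50,
    burn_in_generations = 5, init_maf_range = c(0.3, 0.5), seed = 97,
    cm_per_mbp = 1e-8))
  late <- simulate_population(sim_config(
    n_chromosomes = 1, chrom_length_cm = 1e-6, n_markers = 40, ne = 50,
    burn_in_generations = 60, init_maf_range = c(0.3, 0.5), seed = 97,
    cm_per_mbp = 1e-8))
  r2_of <- function(s) {
    r <- ld_scan(s$panel, max_distance_mbp = 1e9)
    mean(r$r2)
  }
  expect_gt(r2_of(late), r2_of(early))
})

test_that("the exported pedigree is Mendelian-consistent with the panel", {
  sim <- simulate_population(sim_config(
    n_chromosomes = 1, chrom_length_cm = 30, n_markers = 80, ne = 25,
    burn_in_generations = 8, pedigree_depth = 8, seed = 98))
  ped <- tibble::as_tibble(sim$pedigree)
  # final generation's parents are one generation up; their genotypes are
  # not exported, so check structural consistency instead: parents exist,
  # depth covers the request, no cycles (as_pedigree validated already)
  final_ids <- sim$panel$animals$animal_id
  expect_true(all(final_ids %in% ped$animal))
  parents <- ped[match(final_ids, ped$animal), ]
  expect_true(all(!is.na(parents$sire) & !is.na(parents$dam)))
  expect_true(all(parents$sire %in% ped$animal))
  gens <- unique(sub("^.*_g(\\d+)_.*$", "\\1", ped$animal))
  expect_gte(length(gens), 8)
})

test_that("zero-generation splits are identical and diverge with time", {
  base <- simulate_population(sim_config(
    n_chromosomes = 1, chrom_length_cm = 30, n_markers = 150, ne = 60,
    burn_in_generations = 30, seed = 99, label = "B"))
  same <- split_populations(base, 0, labels = c("S1", "S2"))
  expect_identical(unname(same[[1]]$panel$dosages),
                   unname(same[[2]]$panel$dosages))
  pp <- phase_persistence(ld_scan(same[[1]]$panel, max_distance_mbp = 2),
                          ld_scan(same[[2]]$panel, max_distance_mbp = 2))
  expect_true(all(abs(pp$r - 1) < 1e-12))
  apart <- split_populations(base, 40, labels = c("S1", "S2"))
  expect_false(identical(unname(apart[[1]]$panel$dosages),
                         unname(apart[[2]]$panel$dosages)))
})

test_that("F1 crosses have outbred pedigrees and elevated heterozygosity", {
  base <- simulate_population(sim_config(
    n_chromosomes = 2, chrom_length_cm = 40, n_markers = 150, ne = 40,
    burn_in_generations = 30, seed = 100, label = "B"))
  lines <- split_populations(base, 60, labels = c("L1", "L2"))
  f1 <- make_f1(lines[[1]], lines[[2]], 40)
  fp <- f_pedigree(f1$pedigree)
  f1_ids <- f1$panel$animals$animal_id
  expect_equal(fp$f_ped[match(f1_ids, fp$animal)], rep(0, 40))
  het <- function(p) mean(p$dosages == 1L)
  expect_gte(het(f1$panel), max(het(lines[[1]]$panel),
                                het(lines[[2]]$panel)))
  expect_error(make_f1(base, simulate_population(sim_config(
    n_chromosomes = 1, chrom_length_cm = 40, n_markers = 10, ne = 10,
    burn_in_generations = 2, seed = 1, label = "Z")), 5),
    "incompatible")
})
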