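test_that("composite LD matches hand evaluation of the estimator", {
  r <- composite_ld_pair(c(2, 1, 1, 0), c(2, 2, 1, 1))
  # f(A) = 0.5, f(B) = 0.75, weighted joint count 7/(2N) = 7/8,
  # D = (4/3)(0.875 - 0.75) = 1/6; r2 = D^2 / (0.5*0.5*0.75*0.25)
  expect_equal(r$D, 1 / 6)
  expect_equal(r$r2, (1 / 36) / 0.046875)
  expect_equal(r$signed_r, sqrt((1 / 36) / 0.046875))
  oracle <- ld_pair_table_oracle(c(2, 1, 1, 0), c(2, 2, 1, 1))
  expect_equal(r$D, oracle$D, tolerance = 1e-14)
  expect_equal(r$r2, oracle$r2, tolerance = 1e-14)
})

test_that("the small-sample factor can push r2 past 1 and is clamped", {
  x <- c(2, 1, 1, 0)
  r <- composite_ld_pair(x, x)
  # uncorrected D would be 0.25 (r2 = 1); N/(N-1) makes D = 1/3
  expect_equal(r$D, 1 / 3)
  expect_equal(r$r2, 1)
  expect_true(r$clamped)
  expect_equal(r$signed_r, 1)
})

test_that("composite LD is symmetric and signs behave", {
  set.seed(71)
  for (i in 1:25) {
    x <- sample(0:2, 20, replace = TRUE)
    y <- sample(0:2, 20, replace = TRUE)
    a <- composite_ld_pair(x, y)
    b <- composite_ld_pair(y, x)
    expect_equal(a$D, b$D)
    expect_equal(a$r2, b$r2)
    if (isTRUE(a$ok)) {
      expect_equal(a$signed_r^2, a$r2, tolerance = 1e-12)
      # recoding one marker's counted allele flips the sign only
      fl <- composite_ld_pair(x, 2 - y)
      if (isTRUE(fl$ok)) {
        expect_equal(fl$r2, a$r2, tolerance = 1e-12)
        expect_equal(fl$D, -a$D, tolerance = 1e-12)
      }
    }
  }
})

test_that("degenerate pairs are refused with a reason", {
  r <- composite_ld_pair(c(0, 0, 0, 0), c(0, 1, 2, 1))
  expect_false(r$ok)
  expect_match(r$reason, "monomorphic")
  r <- composite_ld_pair(c(0, NA, NA, NA), c(0, 1, 2, 1))
  expect_false(r$ok)
  expect_match(r$reason, "fewer than 2")
})

test_that("independent markers in a large sample show near-zero r2", {
  set.seed(72)
  n <- 1000
  mean_r2 <- mean(replicate(30, {
    composite_ld_pair(stats::rbinom(n, 2, 0.3), stats::rbinom(n, 2, 0.4))$r2
  }))
  expect_lt(mean_r2, 0.02)
})

test_that("the matrix scan agrees with the scalar estimator pair by pair", {
  set.seed(73)
  panel <- random_panel(30, 40, n_chrom = 2, miss_rate = 0.08)
  recs <- ld_scan(panel, max_distance_mbp = 100)
  expect_gt(nrow(recs), 100)
  idx <- sample(nrow(recs), 50)
  for (k in idx) {
    a <- panel$dosages[, recs$id_a[k]]
    b <- panel$dosages[, recs$id_b[k]]
    ref <- composite_ld_pair(a, b)
    expect_equal(recs$D[k], ref$D, tolerance = 1e-12)
    expect_equal(recs$r2[k], ref$r2, tolerance = 1e-12)
    expect_equal(recs$signed_r[k], ref$signed_r, tolerance = 1e-12)
    expect_equal(recs$n_animals[k], ref$n_animals)
  }
})

test_that("scan combinatorics: pair counts, adjacency, distance cutoffs", {
  set.seed(70)
  panel <- random_panel(20, 5, maf_range = c(0.3, 0.5))
  expect_equal(nrow(ld_scan(panel, max_distance_mbp = 5)), 10)
  expect_equal(nrow(ld_scan(panel, max_distance_mbp = 5,
                            adjacent_only = TRUE)), 4)
  expect_equal(nrow(ld_scan(panel, max_distance_mbp = 0.02)), 0)
  panel3 <- random_panel(20, 3)
  expect_equal(nrow(ld_scan(panel3, max_distance_mbp = 5)), 3)
  # deterministic ordering
  recs <- ld_scan(panel, max_distance_mbp = 5)
  expect_equal(recs, recs[order(recs$chrom, recs$id_a, recs$id_b), ])
})

test_that("LD summaries bin, class and threshold correctly", {
  recs <- tibble::tibble(
    chrom = 1L, id_a = paste0("m", 1:4), id_b = paste0("n", 1:4),
    bp_a = 1L, bp_b = 1L,
    distance_mbp = c(0.005, 0.02, 0.02, 0.3),
    D = 0.1, r2 = c(0.5, 0.1, 0.3, 0.5), signed_r = 0.5,
    n_animals = 10, adjacent = c(TRUE, TRUE, FALSE, FALSE))
  class(recs) <- c("ld_records", class(recs))
  s <- summarize_ld(recs)
  # class [0.01, 0.05) holds the two middle records: mean 0.2
  cls <- s$classes
  expect_equal(cls$mean_r2[cls$lo == 0.01], 0.2)
  expect_equal(cls$n_pairs[cls$lo == 0.01], 2)
  # adjacent useful fractions over the two adjacent records (0.5, 0.1)
  expect_equal(s$useful$fraction[s$useful$threshold == 0.2], 0.5)
  expect_equal(s$useful$fraction[s$useful$threshold == 0.3], 0.5)
  # constant input gives constant bins
  const <- dplyr::mutate(recs, r2 = 0.5)
  class(const) <- class(recs)
  s2 <- summarize_ld(const)
  expect_true(all(s2$bins$mean_r2 == 0.5))
  expect_true(all(s2$useful$fraction == 1))
})

test_that("LD decays with distance in a constant-size population", {
  sim <- simulate_population(sim_config(
    n_chromosomes = 4, chrom_length_cm = 100, n_markers = 200, ne = 100,
    burn_in_generations = 100, seed = 74, label = "DECAY"))
  s <- summarize_ld(ld_scan(sim$panel, max_distance_mbp = 5))
  mr <- s$classes$mean_r2
  # non-increasing across distance classes, allowing one sampling inversion
  expect_lte(sum(diff(mr) > 0), 1)
})
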