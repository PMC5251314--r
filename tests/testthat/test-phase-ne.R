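test_that("a population against itself has phase correlation 1 in every bin", {
  set.seed(81)
  panel <- random_panel(40, 60)
  recs <- ld_scan(panel, max_distance_mbp = 3)
  pp <- phase_persistence(recs, recs)
  expect_gt(nrow(pp), 0)
  expect_true(all(abs(pp$r - 1) < 1e-12))
})

test_that("recoding one marker of each pair flips phase persistence to -1", {
  set.seed(82)
  panel <- random_panel(40, 60)
  # recode every other marker's counted allele; each adjacent pair then has
  # exactly one recoded member, so its D (hence signed r) changes sign
  dos <- panel$dosages
  odd <- seq(1, ncol(dos), by = 2)
  dos[, odd] <- 2L - dos[, odd]
  flipped <- genotype_panel(dos, panel$map, panel$animals)
  ra <- ld_scan(panel, max_distance_mbp = 3, adjacent_only = TRUE)
  rb <- ld_scan(flipped, max_distance_mbp = 3, adjacent_only = TRUE)
  pp <- phase_persistence(ra, rb)
  expect_gt(nrow(pp), 0)
  expect_true(all(abs(pp$r + 1) < 1e-12))
})

test_that("phase persistence is symmetric in its two populations", {
  set.seed(83)
  pa <- random_panel(30, 50)
  pb <- genotype_panel(pa$dosages[sample(30), ], pa$map, pa$animals)
  ra <- ld_scan(pa, max_distance_mbp = 3)
  rb <- ld_scan(pb, max_distance_mbp = 3)
  expect_equal(phase_persistence(ra, rb)$r, phase_persistence(rb, ra)$r)
})

test_that("the bin-means reading returns a single overall correlation", {
  set.seed(84)
  panel <- random_panel(30, 50)
  recs <- ld_scan(panel, max_distance_mbp = 3)
  pp <- phase_persistence(recs, recs, method = "bin_means")
  expect_equal(nrow(pp), 1)
  expect_equal(pp$r, 1)
})

test_that("no shared pairs warns and returns an empty result", {
  set.seed(85)
  pa <- random_panel(20, 30)
  pb <- random_panel(20, 30)
  pb$map$marker_id <- paste0("other_", pb$map$marker_id)
  ra <- ld_scan(pa, max_distance_mbp = 3)
  rb <- ld_scan(pb, max_distance_mbp = 3)
  expect_warning(pp <- phase_persistence(ra, rb), "no shared")
  expect_equal(nrow(pp), 0)
})

test_that("Sved inversion closed forms and exact round-trip", {
  expect_equal(sved_ne(0.2, 0.01), 100)
  expect_equal(sved_ne(0.5, 0.0025), 100)
  for (ne in c(50, 100, 500))
    for (cm in c(0.001, 0.01, 0.1))
      expect_equal(sved_ne(1 / (1 + 4 * ne * cm), cm), ne)
  expect_true(is.na(sved_ne(1, 0.01)))
  expect_true(is.na(sved_ne(0, 0.01)))
})

test_that("synthetic records following Sved's expectation recover Ne through the full path", {
  ne_true <- 120
  centers <- seq(0.1, 10, by = 0.1)
  recs <- purrr::map_dfr(centers, function(ct) {
    tibble::tibble(chrom = 1L, id_a = paste0("a", ct), id_b = paste0("b", ct),
                   bp_a = 1L, bp_b = 1L, distance_mbp = ct,
                   D = 0.1, r2 = 1 / (1 + 4 * ne_true * ct / 100),
                   signed_r = 0.1, n_animals = 50,
                   adjacent = FALSE)
  })
  recs <- recs[rep(seq_len(nrow(recs)), each = 10), ]  # meet min_pairs
  class(recs) <- c("ld_records", class(recs))
  traj <- estimate_ne(recs)
  expect_gt(nrow(traj), 50)
  expect_equal(traj$ne, rep(ne_true, nrow(traj)), tolerance = 1e-12)
  # T decreases as c grows and equals 1/(2c)
  expect_equal(traj$generations_ago, 1 / (2 * traj$c_morgans))
  expect_true(all(diff(traj$generations_ago[order(traj$c_morgans)]) < 0))
})

test_that("bins are half-open center +/- 0.05 windows with pair and r2 guards", {
  mk <- function(d, r2, n = 20) {
    out <- tibble::tibble(chrom = 1L, id_a = "a", id_b = "b", bp_a = 1L,
                          bp_b = 1L, distance_mbp = d, D = 0.1, r2 = r2,
                          signed_r = 0.1, n_animals = 50, adjacent = FALSE)
    out[rep(1, n), ]
  }
  # a record at exactly centre + 0.05 falls in the next window
  recs <- dplyr::bind_rows(mk(0.15, 0.4), mk(0.349999, 0.2))
  class(recs) <- c("ld_records", class(recs))
  traj <- estimate_ne(recs)
  expect_equal(traj$mean_r2[abs(traj$c_morgans - 0.002) < 1e-9], 0.4)
  expect_equal(traj$mean_r2[abs(traj$c_morgans - 0.003) < 1e-9], 0.2)
  # r2 of exactly 1 and sparse bins are omitted
  recs2 <- dplyr::bind_rows(mk(0.15, 1), mk(0.55, 0.3, n = 5))
  class(recs2) <- c("ld_records", class(recs2))
  expect_warning(traj2 <- estimate_ne(recs2), "no usable")
  expect_equal(nrow(traj2), 0)
})

test_that("sample-size adjustment of r2 is available but off by default", {
  recs <- tibble::tibble(chrom = 1L, id_a = "a", id_b = "b", bp_a = 1L,
                         bp_b = 1L, distance_mbp = 1.0, D = 0.1, r2 = 0.21,
                         signed_r = 0.1, n_animals = 100, adjacent = FALSE)
  recs <- recs[rep(1, 20), ]
  class(recs) <- c("ld_records", class(recs))
  plain <- estimate_ne(recs)
  adj <- estimate_ne(recs, r2_adjust_n = TRUE)
  expect_equal(plain$mean_r2, 0.21)
  expect_equal(adj$mean_r2, 0.20)
  expect_gt(adj$ne, plain$ne)
})
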