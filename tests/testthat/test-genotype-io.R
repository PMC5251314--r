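test_that("PED/MAP parsing codes dosages by the minor allele and handles missing calls", {
  tmp <- withr::local_tempdir()
  # 4 animals, 2 markers; marker m1 minor allele A, marker m2 balanced (tie)
  writeLines(c(
    "1 snp1 0 100",
    "1 snp2 0 200"), file.path(tmp, "toy.map"))
  writeLines(c(
    "P1 a1 0 0 0 -9 A A  C C",
    "P1 a2 0 0 0 -9 A G  C T",
    "P1 a3 0 0 0 -9 G G  T C",
    "P1 a4 0 0 0 -9 0 0  T T"), file.path(tmp, "toy.ped"))
  panel <- read_plink_text(file.path(tmp, "toy.ped"), file.path(tmp, "toy.map"))
  # snp1 alleles: A count 3, G count 3 of 6 -> tie, lexicographic minor = A
  expect_equal(unname(panel$dosages[, "snp1"]), c(2L, 1L, 0L, NA))
  # snp2: C x4, T x4 -> tie, minor = C
  expect_equal(unname(panel$dosages[, "snp2"]), c(2L, 1L, 1L, 0L))
  expect_equal(panel$counted_allele, c("A", "C"))
  expect_equal(panel$animals$population, rep("P1", 4))
})

test_that("malformed PED/MAP lines are rejected with a line number", {
  tmp <- withr::local_tempdir()
  writeLines(c("1 snp1 0 100", "1 snp1 0 200"), file.path(tmp, "dup.map"))
  writeLines("P1 a1 0 0 0 -9 A A A A", file.path(tmp, "dup.ped"))
  expect_error(read_plink_text(file.path(tmp, "dup.ped"),
                               file.path(tmp, "dup.map")),
               "duplicate marker id")
  writeLines("1 snp1 0 100", file.path(tmp, "bad.map"))
  writeLines(c("P1 a1 0 0 0 -9 A A", "P1 a2 0 0 0 -9 A"),
             file.path(tmp, "bad.ped"))
  expect_error(read_plink_text(file.path(tmp, "bad.ped"),
                               file.path(tmp, "bad.map")), "line 2")
  writeLines(c("P1 a1 0 0 0 -9 A A", "P1 a2 0 0 0 -9 C G"),
             file.path(tmp, "tri.ped"))
  writeLines("1 snp1 0 100", file.path(tmp, "tri.map"))
  expect_error(read_plink_text(file.path(tmp, "tri.ped"),
                               file.path(tmp, "tri.map")),
               "more than 2 alleles")
})

test_that("write then read round-trips panels exactly", {
  tmp <- withr::local_tempdir()
  set.seed(42)
  for (rep in 1:3) {
    panel <- random_panel(20, 50, n_chrom = 2, miss_rate = 0.05)
    # the minor-allele policy defines the dosage coding, so flip any
    # column whose counted allele drifted above 0.5 by sampling (exact
    # ties resolve to the written counted letter, which sorts first)
    p_hat <- colMeans(panel$dosages, na.rm = TRUE) / 2
    flip <- !is.na(p_hat) & p_hat > 0.5
    dos <- panel$dosages
    dos[, flip] <- 2L - dos[, flip]
    panel <- genotype_panel(dos, panel$map, panel$animals)
    prefix <- file.path(tmp, paste0("rt", rep))
    write_plink_text(panel, prefix)
    back <- read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
    expect_equal(unname(back$dosages), unname(panel$dosages))
    expect_equal(back$map, panel$map)
    expect_equal(back$animals, panel$animals)
  }
  # dosage 1 writes the counted and alternate letters
  one <- genotype_panel(matrix(1L, 1, 1),
                        tibble::tibble(marker_id = "m1", chrom = 1L,
                                       pos_bp = 100L),
                        tibble::tibble(animal_id = "a1", population = "P"))
  write_plink_text(one, file.path(tmp, "one"))
  line <- readLines(file.path(tmp, "one.ped"))
  expect_match(line, "A B$")
  # refuse an empty panel
  empty <- subset_panel(one, animals = integer(0))
  expect_error(write_plink_text(empty, file.path(tmp, "empty")),
               "no animals")
})

test_that("counted plus alternate dosages sum to 2 on non-missing calls", {
  set.seed(7)
  panel <- random_panel(15, 30, miss_rate = 0.1)
  flipped <- 2L - panel$dosages
  s <- panel$dosages + flipped
  expect_true(all(s[!is.na(s)] == 2L))
})

test_that("pedigree reading validates structure and orders parents first", {
  tmp <- withr::local_tempdir()
  writeLines(c("animal\tsire\tdam", "C\tA\tB", "A\t0\t0", "B\t0\t0"),
             file.path(tmp, "ped.tsv"))
  ped <- read_pedigree(file.path(tmp, "ped.tsv"))
  expect_equal(nrow(ped), 3)
  expect_lt(which(ped$animal == "A"), which(ped$animal == "C"))
  expect_true(all(is.na(ped$sire[ped$animal %in% c("A", "B")])))

  writeLines(c("animal,sire,dam", "X,X,0"), file.path(tmp, "self.csv"))
  expect_error(read_pedigree(file.path(tmp, "self.csv")), "cycle.*X")

  writeLines(c("animal sire dam", "A B 0", "B A 0"),
             file.path(tmp, "loop.txt"))
  expect_error(read_pedigree(file.path(tmp, "loop.txt")), "cycle")
})

test_that("large random pedigrees round-trip through write and read", {
  tmp <- withr::local_tempdir()
  set.seed(99)
  gens <- 10
  per_gen <- 100
  ids <- outer(seq_len(per_gen), seq_len(gens),
               function(i, g) sprintf("g%02d_%03d", g, i))
  rows <- list(tibble::tibble(animal = ids[, 1], sire = NA_character_,
                              dam = NA_character_,
                              population = "SIM"))
  for (g in 2:gens) {
    s <- sample(ids[, g - 1], per_gen, replace = TRUE)
    d <- sample(ids[, g - 1], per_gen, replace = TRUE)
    rows[[g]] <- tibble::tibble(animal = ids[, g], sire = s, dam = d,
                                population = "SIM")
  }
  ped <- as_pedigree(dplyr::bind_rows(rows))
  path <- file.path(tmp, "big.tsv")
  write_pedigree(ped, path)
  back <- read_pedigree(path)
  expect_setequal(back$animal, ped$animal)
  m <- match(ped$animal, back$animal)
  expect_equal(back$sire[m], ped$sire)
  expect_equal(back$dam[m], ped$dam)
})
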