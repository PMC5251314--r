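#' Read a genotype panel from PLINK text files
#'
#' Parses the whitespace-delimited PED/MAP dialect: the MAP file has four
#' columns (chromosome, marker id, genetic position, bp position) and each
#' PED row has six leading columns (family, individual, sire, dam, sex,
#' phenotype) followed by two allele columns per marker. Missing calls are
#' coded `0 0`. The family column is taken as the population label; a herd
#' label may be appended to it as `population:herd`.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param allele_policy Which allele becomes the counted allele of the
#'   dosage coding. `"minor"` (default): the sample-wide minor allele, ties
#'   broken lexicographically. `"first_listed"`: the first non-missing
#'   allele encountered in file order for that marker.
#' @return A [genotype_panel()].
#' @export
read_plink_text <- function(ped_path, map_path,
                            allele_policy = c("minor", "first_listed")) {
  allele_policy <- match.arg(allele_policy)
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path, call. = FALSE)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path, call. = FALSE)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "\\s+")
  bad <- which(lengths(map_tok) != 4L)
  if (length(bad))
    stop(sprintf("MAP parse error at line %d: expected 4 fields", bad[1]),
         call. = FALSE)
  map <- tibble::tibble(
    marker_id = vapply(map_tok, `[`, "", 2L),
    chrom = as.integer(vapply(map_tok, `[`, "", 1L)),
    pos_bp = as.integer(vapply(map_tok, `[`, "", 4L))
  )
  if (anyNA(map$chrom) || anyNA(map$pos_bp))
    stop("MAP parse error: non-numeric chromosome or position", call. = FALSE)
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker id in MAP: ",
         map$marker_id[anyDuplicated(map$marker_id)], call. = FALSE)
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  if (n == 0L) stop("PED file has no records", call. = FALSE)
  ped_tok <- strsplit(trimws(ped_lines), "\\s+")
  bad <- which(lengths(ped_tok) != 6L + 2L * m)
  if (length(bad))
    stop(sprintf("PED parse error at line %d: expected %d fields, got %d",
                 bad[1], 6L + 2L * m, lengths(ped_tok)[bad[1]]),
         call. = FALSE)
  tok <- matrix(unlist(ped_tok), nrow = n, byrow = TRUE)
  fam <- tok[, 1L]
  pop <- sub(":.*$", "", fam)
  herd <- ifelse(grepl(":", fam), sub("^[^:]*:", "", fam), "H1")
  animals <- tibble::tibble(animal_id = tok[, 2L], population = pop,
                            herd = herd)

  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  a1[a1 == "0"] <- NA_character_
  a2[a2 == "0"] <- NA_character_
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop(sprintf("PED parse error at line %d: half-missing genotype",
                 which(rowSums(half) > 0)[1]), call. = FALSE)

  counted <- character(m)
  other <- character(m)
  dos <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    alleles <- c(a1[, j], a2[, j])
    obs <- alleles[!is.na(alleles)]
    lev <- sort(unique(obs))
    if (length(lev) > 2L)
      stop("more than 2 alleles at marker ", map$marker_id[j], call. = FALSE)
    if (length(lev) == 0L) lev <- c("A", "B")
    if (length(lev) == 1L) lev <- c(lev, setdiff(c("A", "B"), lev)[1])
    cnt <- if (allele_policy == "minor") {
      f1 <- sum(obs == lev[1]) / length(obs)
      # minor allele; exact tie broken lexicographically (lev is sorted)
      if (f1 <= 0.5) lev[1] else lev[2]
    } else {
      obs[1]
    }
    oth <- setdiff(lev, cnt)[1]
    counted[j] <- cnt
    other[j] <- oth
    dos[, j] <- (a1[, j] == cnt) + (a2[, j] == cnt)
  }
  genotype_panel(dos, map, animals, counted, other)
}

#' Write a genotype panel as PLINK text files
#'
#' Inverse of [read_plink_text()]: emits `<out_prefix>.ped` and
#' `<out_prefix>.map`. The counted allele is written with its stored letter
#' (default `"A"`), the alternate with its own (default `"B"`); missing
#' calls become `0 0`. The family column carries `population:herd`.
#'
#' @param panel A [genotype_panel()].
#' @param out_prefix Output path prefix.
#' @return Invisibly, a named character vector with `ped` and `map` paths.
#' @export
write_plink_text <- function(panel, out_prefix) {
  if (n_animals(panel) == 0L)
    stop("refusing to write a panel with no animals", call. = FALSE)
  ped_path <- paste0(out_prefix, ".ped")
  map_path <- paste0(out_prefix, ".map")
  map_df <- panel$map
  readr::write_tsv(
    tibble::tibble(chrom = map_df$chrom, marker_id = map_df$marker_id,
                   cm = map_df$pos_bp / 1e6, pos_bp = map_df$pos_bp),
    map_path, col_names = FALSE)

  dos <- panel$dosages
  m <- ncol(dos)
  a_cnt <- panel$counted_allele
  a_oth <- panel$other_allele
  lines <- vapply(seq_len(nrow(dos)), function(i) {
    g <- dos[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, a_cnt, a_oth))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, a_cnt, a_oth))
    paste(c(paste0(panel$animals$population[i], ":", panel$animals$herd[i]),
            panel$animals$animal_id[i], "0", "0", "0", "-9",
            as.vector(rbind(a1, a2))), collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a pedigree file
#'
#' Expects delimited text (tab, comma or whitespace) with a header and at
#' least three columns: animal, sire, dam, optionally population. Unknown
#' parents are coded `0`, `NA` or an empty field. The pedigree is validated
#' to be acyclic and returned in a topological (parents-before-offspring)
#' order.
#'
#' @param path Path to the pedigree file.
#' @return A tibble of class `pedigree` with columns `animal`, `sire`,
#'   `dam`, `population` (unknown parents as `NA`), topologically sorted.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else " "
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          strip.white = TRUE, colClasses = "character")
  if (ncol(df) < 3L)
    stop("pedigree needs at least 3 columns (animal, sire, dam)",
         call. = FALSE)
  ped <- tibble::tibble(
    animal = df[[1L]], sire = df[[2L]], dam = df[[3L]],
    population = if (ncol(df) >= 4L) df[[4L]] else NA_character_)
  as_pedigree(ped)
}

#' Coerce a data frame to a validated, topologically sorted pedigree
#'
#' @param ped Data frame with columns `animal`, `sire`, `dam` and optional
#'   `population`; unknown parents as `0`, `""` or `NA`.
#' @return Tibble of class `pedigree`, parents before offspring.
#' @export
as_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  if (!"population" %in% names(ped)) ped$population <- NA_character_
  null_code <- function(x) ifelse(is.na(x) | x == "0" | x == "", NA, as.character(x))
  ped$animal <- as.character(ped$animal)
  ped$sire <- null_code(ped$sire)
  ped$dam <- null_code(ped$dam)
  if (anyDuplicated(ped$animal))
    stop("duplicate animal in pedigree: ",
         ped$animal[anyDuplicated(ped$animal)], call. = FALSE)
  self <- which(ped$animal == ped$sire | ped$animal == ped$dam)
  if (length(self))
    stop("pedigree cycle: animal ", ped$animal[self[1]],
         " is its own parent", call. = FALSE)
  # implicit founders: parents never listed as animals
  founders <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(founders))
    ped <- dplyr::bind_rows(
      tibble::tibble(animal = founders, sire = NA_character_,
                     dam = NA_character_, population = NA_character_), ped)
  edges <- dplyr::bind_rows(
    tibble::tibble(from = ped$sire, to = ped$animal),
    tibble::tibble(from = ped$dam, to = ped$animal))
  edges <- edges[!is.na(edges$from), ]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = ped$animal)
  if (!igraph::is_dag(g)) {
    cyc <- ped$animal[1]
    # name one animal on a cycle for the error message
    comp <- igraph::components(g, mode = "strong")
    big <- which(comp$csize > 1)[1]
    cyc <- names(comp$membership)[comp$membership == big][1]
    stop("pedigree contains a cycle involving animal ", cyc, call. = FALSE)
  }
  ord <- names(igraph::topo_sort(g, mode = "out"))
  ped <- ped[match(ord, ped$animal), ]
  class(ped) <- c("pedigree", class(ped))
  ped
}

#' Write a pedigree as TSV
#' @param ped A pedigree tibble (see [read_pedigree()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  out <- tibble::as_tibble(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  readr::write_tsv(out, path)
  invisible(path)
}
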