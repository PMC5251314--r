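#' Construct a genotype panel
#'
#' A genotype panel is the substrate of every statistic in this package: a
#' set of diploid animals genotyped at biallelic SNPs with a physical marker
#' map. Dosages count copies of the *counted* allele per marker (0, 1, 2 or
#' `NA` for a missing call), so a dosage of 1 is a heterozygote regardless of
#' which allele is counted.
#'
#' @param dosages Integer matrix, animals in rows and markers in columns,
#'   values in `{0, 1, 2, NA}`.
#' @param map Data frame with columns `marker_id` (unique), `chrom`
#'   (positive integer label; pig autosomes are 1..18) and `pos_bp`
#'   (1-based physical position). Markers are re-sorted by chromosome then
#'   position, and the dosage columns follow.
#' @param animals Data frame with columns `animal_id` (unique) and
#'   `population` (non-empty label); an optional `herd` column defaults to
#'   `"H1"`.
#' @param counted_allele,other_allele Optional character vectors (one letter
#'   per marker) recording the allele identities behind the dosage coding;
#'   default `"A"`/`"B"`.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `map` (tibble), `animals` (tibble), `counted_allele`,
#'   `other_allele`.
#' @export
genotype_panel <- function(dosages, map, animals,
                           counted_allele = NULL, other_allele = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  map <- tibble::as_tibble(map)
  animals <- tibble::as_tibble(animals)
  if (!all(c("marker_id", "chrom", "pos_bp") %in% names(map)))
    stop("map must have columns marker_id, chrom, pos_bp", call. = FALSE)
  if (!all(c("animal_id", "population") %in% names(animals)))
    stop("animals must have columns animal_id, population", call. = FALSE)
  if (!"herd" %in% names(animals)) animals$herd <- "H1"
  if (nrow(map) != ncol(dosages))
    stop("map rows must match dosage columns", call. = FALSE)
  if (nrow(animals) != nrow(dosages))
    stop("animal rows must match dosage rows", call. = FALSE)
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker ids", call. = FALSE)
  if (anyDuplicated(animals$animal_id))
    stop("duplicate animal ids", call. = FALSE)
  if (any(is.na(animals$population)) || any(animals$population == ""))
    stop("population labels must be non-empty", call. = FALSE)
  if (any(map$pos_bp < 1)) stop("pos_bp must be >= 1", call. = FALSE)
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be in {0, 1, 2, NA}", call. = FALSE)
  m <- nrow(map)
  if (is.null(counted_allele)) counted_allele <- rep("A", m)
  if (is.null(other_allele)) other_allele <- rep("B", m)

  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  counted_allele <- counted_allele[ord]
  other_allele <- other_allele[ord]
  dup_pos <- duplicated(map[, c("chrom", "pos_bp")])
  if (any(dup_pos))
    stop("markers must have distinct positions within a chromosome",
         call. = FALSE)
  dimnames(dosages) <- list(animals$animal_id, map$marker_id)

  structure(
    list(dosages = dosages, map = map, animals = animals,
         counted_allele = counted_allele, other_allele = other_allele),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d animals x %d markers on %d chromosome(s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom))))
  pops <- table(x$animals$population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of animals / markers in a panel
#' @param panel A [genotype_panel()].
#' @return Integer count.
#' @export
n_animals <- function(panel) nrow(panel$dosages)

#' @rdname n_animals
#' @export
n_markers <- function(panel) ncol(panel$dosages)

#' Subset a genotype panel
#'
#' @param panel A [genotype_panel()].
#' @param animals,markers Logical, integer or character index into animals
#'   (ids) or markers (marker ids); `NULL` keeps all.
#' @return A new `genotype_panel`.
#' @export
subset_panel <- function(panel, animals = NULL, markers = NULL) {
  ai <- seq_len(n_animals(panel))
  mi <- seq_len(n_markers(panel))
  if (!is.null(animals)) {
    ai <- if (is.character(animals))
      match(animals, panel$animals$animal_id) else ai[animals]
    if (anyNA(ai)) stop("unknown animal id", call. = FALSE)
  }
  if (!is.null(markers)) {
    mi <- if (is.character(markers))
      match(markers, panel$map$marker_id) else mi[markers]
    if (anyNA(mi)) stop("unknown marker id", call. = FALSE)
  }
  genotype_panel(panel$dosages[ai, mi, drop = FALSE],
                 panel$map[mi, , drop = FALSE],
                 panel$animals[ai, , drop = FALSE],
                 panel$counted_allele[mi], panel$other_allele[mi])
}

#' Split a panel by population (or herd)
#'
#' @param panel A [genotype_panel()].
#' @param by Grouping column of the animal table, `"population"` or
#'   `"herd"`.
#' @return Named list of `genotype_panel` objects, one per group level.
#' @export
split_panel <- function(panel, by = "population") {
  stopifnot(by %in% names(panel$animals))
  groups <- split(seq_len(n_animals(panel)), panel$animals[[by]])
  lapply(groups, function(idx) subset_panel(panel, animals = idx))
}

#' Marker distances in Mbp
#'
#' @param pos_a,pos_b Physical positions in bp.
#' @return `abs(pos_a - pos_b) / 1e6`.
#' @keywords internal
mbp_distance <- function(pos_a, pos_b) abs(pos_a - pos_b) / 1e6
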