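#' Configuration for the forward Wright-Fisher simulator
#'
#' Describes a diploid monoecious random-mating population (selfing
#' excluded, discrete non-overlapping generations, no mutation, no
#' selection) evolving on a multi-chromosome SNP map. Recombination
#' follows the Haldane model: each gamete receives
#' `Poisson(length_cm / 100)` crossovers at uniform genetic positions, no
#' interference. Markers are equally spaced in genetic distance and
#' physical positions follow `1 cM = cm_per_mbp^-1 Mbp`. Founders are
#' initialised at linkage equilibrium with counted-allele frequencies
#' drawn uniformly from `init_maf_range`; the burn-in generations then
#' build the LD a real population of that effective size would carry.
#' Under this mating scheme the effective size equals the census size.
#'
#' @param n_chromosomes Number of chromosomes (default 2).
#' @param chrom_length_cm Genetic length per chromosome in cM
#'   (default 100).
#' @param n_markers Markers per chromosome (default 250).
#' @param ne Constant diploid population size (default 100); ignored when
#'   `ne_trajectory` is given.
#' @param ne_trajectory Optional tibble/data.frame with columns
#'   `generation` (1-based, within the burn-in) and `n`: the census size
#'   used from that generation on. Must start at generation 1.
#' @param burn_in_generations Generations simulated before sampling
#'   (default 100).
#' @param n_sampled Animals exported from the final generation (default
#'   all).
#' @param init_maf_range Range for founder counted-allele frequencies
#'   (default `c(0.1, 0.5)`).
#' @param cm_per_mbp Map scaling (default 1, the usual livestock
#'   assumption).
#' @param pedigree_depth Generations of pedigree exported (default 5).
#' @param seed Integer RNG seed; required for a reproducible run.
#' @param label Population label for animal ids (default `"POP"`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length_cm = 100,
                       n_markers = 250, ne = 100, ne_trajectory = NULL,
                       burn_in_generations = 100, n_sampled = NULL,
                       init_maf_range = c(0.1, 0.5), cm_per_mbp = 1,
                       pedigree_depth = 5, seed = 1, label = "POP") {
  stopifnot(n_chromosomes >= 1, chrom_length_cm > 0, n_markers >= 2,
            ne >= 2, burn_in_generations >= 1,
            init_maf_range[1] > 0, init_maf_range[2] < 1,
            init_maf_range[1] <= init_maf_range[2], cm_per_mbp > 0)
  if (!is.null(ne_trajectory)) {
    ne_trajectory <- tibble::as_tibble(ne_trajectory)
    stopifnot(all(c("generation", "n") %in% names(ne_trajectory)))
    if (min(ne_trajectory$generation) != 1L)
      stop("ne_trajectory must define generation 1", call. = FALSE)
    if (max(ne_trajectory$generation) > burn_in_generations)
      stop("ne_trajectory references generations beyond the burn-in",
           call. = FALSE)
    if (any(ne_trajectory$n < 2))
      stop("population sizes must be >= 2", call. = FALSE)
  }
  structure(list(
    n_chromosomes = n_chromosomes, chrom_length_cm = chrom_length_cm,
    n_markers = n_markers, ne = ne, ne_trajectory = ne_trajectory,
    burn_in_generations = burn_in_generations, n_sampled = n_sampled,
    init_maf_range = init_maf_range, cm_per_mbp = cm_per_mbp,
    pedigree_depth = pedigree_depth, seed = seed, label = label),
    class = "sim_config")
}

# census size at a given burn-in generation
census_at <- function(config, gen) {
  if (is.null(config$ne_trajectory)) return(config$ne)
  tr <- config$ne_trajectory
  tr$n[max(which(tr$generation <= gen))]
}

# one gamete per parent: recombine the parent's two haplotypes
make_gametes <- function(H, parents, gpos_cm, len_cm) {
  n <- length(parents)
  L <- length(gpos_cm)
  k <- stats::rpois(n, len_cm / 100)
  start <- sample.int(2L, n, replace = TRUE) - 1L
  phase <- matrix(start, n, L)
  for (j in which(k > 0L)) {
    bp <- sort(stats::runif(k[j], 0, len_cm))
    phase[j, ] <- (start[j] + findInterval(gpos_cm, bp)) %% 2L
  }
  hap_row <- 2L * (parents - 1L) + 1L + phase
  matrix(H[cbind(as.vector(hap_row), rep(seq_len(L), each = n))], n, L)
}

wf_generation <- function(haps, gpos, len_cm, n_next) {
  n_cur <- nrow(haps[[1]]) / 2L
  sire <- sample.int(n_cur, n_next, replace = TRUE)
  shift <- if (n_cur > 1L) sample.int(n_cur - 1L, n_next, replace = TRUE)
           else integer(n_next)
  dam <- 1L + (sire - 1L + shift) %% n_cur
  new_haps <- lapply(seq_along(haps), function(ci) {
    h1 <- make_gametes(haps[[ci]], sire, gpos[[ci]], len_cm)
    h2 <- make_gametes(haps[[ci]], dam, gpos[[ci]], len_cm)
    out <- matrix(0L, 2L * n_next, ncol(h1))
    out[seq(1L, 2L * n_next, by = 2L), ] <- h1
    out[seq(2L, 2L * n_next, by = 2L), ] <- h2
    out
  })
  list(haps = new_haps, sire = sire, dam = dam)
}

state_to_panel <- function(state, config, which_animals, animal_ids) {
  dos <- do.call(cbind, lapply(state$haps, function(H) {
    H[2L * which_animals - 1L, , drop = FALSE] +
      H[2L * which_animals, , drop = FALSE]
  }))
  map <- purrr::map_dfr(seq_len(config$n_chromosomes), function(ci) {
    g <- state$gpos[[ci]]
    tibble::tibble(
      marker_id = sprintf("c%dm%04d", ci, seq_along(g)),
      chrom = ci,
      pos_bp = as.integer(round(g / config$cm_per_mbp * 1e6)))
  })
  animals <- tibble::tibble(animal_id = animal_ids,
                            population = config$label, herd = "H1")
  genotype_panel(dos, map, animals)
}

finish_sim <- function(state, config) {
  n_final <- nrow(state$haps[[1]]) / 2L
  ids_final <- state$ped_ids[[length(state$ped_ids)]]
  take <- if (is.null(config$n_sampled) || config$n_sampled >= n_final)
    seq_len(n_final) else sort(sample.int(n_final, config$n_sampled))
  panel <- state_to_panel(state, config, take, ids_final[take])

  depth <- min(config$pedigree_depth, length(state$ped_ids))
  gens <- seq(length(state$ped_ids) - depth + 1L, length(state$ped_ids))
  ped <- purrr::map_dfr(gens, function(g) {
    ids <- state$ped_ids[[g]]
    if (g == gens[1] || is.null(state$ped_parents[[g]]))
      tibble::tibble(animal = ids, sire = NA_character_,
                     dam = NA_character_, population = config$label)
    else {
      prev <- state$ped_ids[[g - 1L]]
      tibble::tibble(animal = ids,
                     sire = prev[state$ped_parents[[g]]$sire],
                     dam = prev[state$ped_parents[[g]]$dam],
                     population = config$label)
    }
  })
  structure(list(panel = panel, pedigree = as_pedigree(ped),
                 state = state, config = config,
                 truth = list(config = config,
                              founder_freq = state$founder_freq)),
            class = "sim_population")
}

#' Simulate a population forward in time
#'
#' Runs the Wright-Fisher model of [sim_config()]: founders at linkage
#' equilibrium, `burn_in_generations` of random mating with recombination,
#' then the final generation (optionally subsampled) exported as a
#' [genotype_panel()] together with the pedigree of the last
#' `pedigree_depth` generations. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_population`: list with `panel`,
#'   `pedigree`, `config`, `truth` (config echo and realised founder
#'   allele frequencies) and the internal haplotype `state` (used by
#'   [split_populations()] and [make_f1()]).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_markers
  spacing <- config$chrom_length_cm / L
  gpos <- replicate(config$n_chromosomes,
                    (seq_len(L) - 0.5) * spacing, simplify = FALSE)
  n0 <- census_at(config, 1L)
  haps <- vector("list", config$n_chromosomes)
  founder_freq <- vector("list", config$n_chromosomes)
  for (ci in seq_len(config$n_chromosomes)) {
    q <- stats::runif(L, config$init_maf_range[1], config$init_maf_range[2])
    H <- matrix(stats::rbinom(2L * n0 * L, 1L, rep(q, each = 2L * n0)),
                2L * n0, L)
    haps[[ci]] <- H
    founder_freq[[ci]] <- colMeans(H)
  }
  state <- list(haps = haps, gpos = gpos, founder_freq = founder_freq,
                ped_ids = list(sprintf("%s_g0_%04d", config$label,
                                       seq_len(n0))),
                ped_parents = list(NULL))
  for (g in seq_len(config$burn_in_generations)) {
    n_next <- census_at(config, g)
    gen <- wf_generation(state$haps, state$gpos, config$chrom_length_cm,
                         n_next)
    state$haps <- gen$haps
    state$ped_ids <- c(state$ped_ids,
                       list(sprintf("%s_g%d_%04d", config$label, g,
                                    seq_len(n_next))))
    state$ped_parents <- c(state$ped_parents,
                           list(list(sire = gen$sire, dam = gen$dam)))
  }
  finish_sim(state, config)
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> '%s': %d animals x %d markers after %d generations\n",
              x$config$label, n_animals(x$panel), n_markers(x$panel),
              x$config$burn_in_generations))
  invisible(x)
}

#' Split a simulated population into two diverging copies
#'
#' Duplicates the parent simulation's final haplotype state and evolves
#' the two copies independently for `generations_after_split` further
#' generations (0 gives two identical samples). Marker map and allele
#' coding are shared by construction, so the panels are directly
#' comparable for phase-persistence analysis.
#'
#' @param parent A [simulate_population()] result.
#' @param generations_after_split Generations each copy evolves
#'   independently (>= 0).
#' @param labels Population labels of the two copies (default `"A"`,
#'   `"B"`).
#' @return List of two `sim_population` objects.
#' @export
split_populations <- function(parent, generations_after_split,
                              labels = c("A", "B")) {
  stopifnot(inherits(parent, "sim_population"),
            generations_after_split >= 0, length(labels) == 2)
  purrr::map(1:2, function(side) {
    cfg <- parent$config
    cfg$label <- labels[side]
    state <- parent$state
    n_cur <- nrow(state$haps[[1]]) / 2L
    state$ped_ids <- list(sprintf("%s_g0_%04d", cfg$label, seq_len(n_cur)))
    state$ped_parents <- list(NULL)
    g <- 0L
    while (g < generations_after_split) {
      g <- g + 1L
      n_next <- nrow(state$haps[[1]]) / 2L
      gen <- wf_generation(state$haps, state$gpos, cfg$chrom_length_cm,
                           n_next)
      state$haps <- gen$haps
      state$ped_ids <- c(state$ped_ids,
                         list(sprintf("%s_g%d_%04d", cfg$label, g,
                                      seq_len(n_next))))
      state$ped_parents <- c(state$ped_parents,
                             list(list(sire = gen$sire, dam = gen$dam)))
    }
    finish_sim(state, cfg)
  })
}

#' Cross two simulated populations into an F1
#'
#' Each F1 offspring takes one gamete from a random animal of the final
#' generation of `pop_a` and one from `pop_b`; the pedigree records the
#' cross, so every F1 animal has pedigree inbreeding 0 (its parents share
#' no recorded ancestor).
#'
#' @param pop_a,pop_b `sim_population` objects sharing a marker map.
#' @param n_offspring Number of F1 animals.
#' @param label Population label (default `"F1"`).
#' @return A list of class `sim_population` with the F1 `panel` and a
#'   `pedigree` covering both parent lines and the cross.
#' @export
make_f1 <- function(pop_a, pop_b, n_offspring, label = "F1") {
  same_map <- identical(pop_a$panel$map[c("chrom", "pos_bp")],
                        pop_b$panel$map[c("chrom", "pos_bp")])
  if (!same_map) stop("incompatible marker maps", call. = FALSE)
  cfg <- pop_a$config
  cfg$label <- label
  na_ <- nrow(pop_a$state$haps[[1]]) / 2L
  nb_ <- nrow(pop_b$state$haps[[1]]) / 2L
  sire <- sample.int(na_, n_offspring, replace = TRUE)
  dam <- sample.int(nb_, n_offspring, replace = TRUE)
  haps <- lapply(seq_along(pop_a$state$haps), function(ci) {
    h1 <- make_gametes(pop_a$state$haps[[ci]], sire, pop_a$state$gpos[[ci]],
                       cfg$chrom_length_cm)
    h2 <- make_gametes(pop_b$state$haps[[ci]], dam, pop_b$state$gpos[[ci]],
                       cfg$chrom_length_cm)
    out <- matrix(0L, 2L * n_offspring, ncol(h1))
    out[seq(1L, 2L * n_offspring, by = 2L), ] <- h1
    out[seq(2L, 2L * n_offspring, by = 2L), ] <- h2
    out
  })
  ids <- sprintf("%s_%04d", label, seq_len(n_offspring))
  state <- list(haps = haps, gpos = pop_a$state$gpos,
                founder_freq = pop_a$state$founder_freq,
                ped_ids = list(ids), ped_parents = list(NULL))
  panel <- state_to_panel(state, cfg, seq_len(n_offspring), ids)
  ped_a <- tibble::as_tibble(pop_a$pedigree)
  ped_b <- tibble::as_tibble(pop_b$pedigree)
  a_final <- pop_a$state$ped_ids[[length(pop_a$state$ped_ids)]]
  b_final <- pop_b$state$ped_ids[[length(pop_b$state$ped_ids)]]
  ped_f1 <- tibble::tibble(animal = ids, sire = a_final[sire],
                           dam = b_final[dam], population = label)
  pedigree <- as_pedigree(dplyr::bind_rows(ped_a, ped_b, ped_f1))
  structure(list(panel = panel, pedigree = pedigree, state = state,
                 config = cfg, truth = list(config = cfg)),
            class = "sim_population")
}
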