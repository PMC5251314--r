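#' Build a run configuration
#'
#' Collects the knobs of the end-to-end analysis: input paths (or a
#' [sim_config()] to generate the panel), QC thresholds, LD distances and
#' bin widths, ROH rules, output directory and seed. Defaults mirror the
#' package-wide defaults of the individual stages.
#'
#' @param ped_path,map_path PLINK text inputs (ignored when `simulate` is
#'   given).
#' @param pedigree_path Optional pedigree file for F_PED.
#' @param simulate Optional [sim_config()]; when present the panel is
#'   simulated instead of read. A list of `sim_config`s produces one
#'   population each.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for any randomness in the run.
#' @param qc Named list of [apply_qc()] thresholds.
#' @param ld_max_decay_mbp Max pair distance for the decay scan
#'   (default 5).
#' @param ld_max_ne_mbp Max pair distance for the Ne scan (default 20).
#' @param ld_bin_width_mbp Decay bin width (default 0.01).
#' @param phase_bin_width_mbp Phase-persistence bin width (default 0.05).
#' @param roh Named list of [detect_roh()] rules.
#' @param misplaced_screen Run [detect_misplaced_snps()] (default TRUE).
#' @param k_pc Number of principal components (default 2).
#' @return A list of class `run_config`.
#' @export
run_config <- function(ped_path = NULL, map_path = NULL,
                       pedigree_path = NULL, simulate = NULL,
                       out_dir = tempfile("ldphase_run_"), seed = 1,
                       qc = list(), ld_max_decay_mbp = 5,
                       ld_max_ne_mbp = 20, ld_bin_width_mbp = 0.01,
                       phase_bin_width_mbp = 0.05, roh = list(),
                       misplaced_screen = TRUE, k_pc = 2) {
  if (is.null(simulate) && (is.null(ped_path) || is.null(map_path)))
    stop("either input paths or a simulate config are required",
         call. = FALSE)
  structure(list(ped_path = ped_path, map_path = map_path,
                 pedigree_path = pedigree_path, simulate = simulate,
                 out_dir = out_dir, seed = seed, qc = qc,
                 ld_max_decay_mbp = ld_max_decay_mbp,
                 ld_max_ne_mbp = ld_max_ne_mbp,
                 ld_bin_width_mbp = ld_bin_width_mbp,
                 phase_bin_width_mbp = phase_bin_width_mbp, roh = roh,
                 misplaced_screen = misplaced_screen, k_pc = k_pc),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys match the arguments of [run_config()]; a `simulate` key
#' holds [sim_config()] arguments (or a list of them under `populations`).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate <- if (!is.null(y$simulate$populations))
      lapply(y$simulate$populations, function(s) do.call(sim_config, s))
    else do.call(sim_config, y$simulate)
  }
  do.call(run_config, y)
}

#' Built-in demo configuration
#'
#' A small three-population synthetic study (two diverged purebred lines
#' plus their F1) on 2 chromosomes of 500 markers, sized to run end to end
#' in well under five minutes.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return A `run_config` whose `simulate` element is handled specially by
#'   [run_pipeline()] (split + cross).
#' @export
demo_config <- function(seed = 1, out_dir = tempfile("ldphase_demo_")) {
  cfg <- run_config(
    simulate = list(
      base = sim_config(n_chromosomes = 2, chrom_length_cm = 50,
                        n_markers = 500, ne = 100,
                        burn_in_generations = 80, seed = seed,
                        label = "LINE1"),
      split_generations = 30,
      labels = c("LINE1", "LINE2"),
      n_f1 = 40),
    out_dir = out_dir, seed = seed)
  cfg$demo <- TRUE
  cfg
}

write_stage <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  readr::write_tsv(tibble::as_tibble(df), path)
  path
}

#' Run the full analysis pipeline
#'
#' Per population: quality control, misplaced-SNP screen, diversity
#' summary, inbreeding coefficients and their correlations, runs of
#' homozygosity, GRM and principal components, LD decay with distance
#' classes and useful-LD fractions, and the Sved Ne trajectory. Per
#' population pair: phase persistence on the shared post-QC markers
#' (records are computed per population on its own surviving markers; the
#' pair analysis uses their intersection, which keeps allele coding
#' identical because all populations come from one jointly coded panel).
#' Every table is written as TSV under `config$out_dir` and listed with
#' its MD5 checksum in `manifest.json`; identical inputs, config and seed
#' give identical checksums.
#'
#' @param config A [run_config()] or [demo_config()].
#' @return Invisibly, the manifest as a tibble (`artifact`, `path`,
#'   `md5`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  ped <- NULL
  if (!is.null(config$simulate)) {
    if (isTRUE(config$demo) ||
        (is.list(config$simulate) && !is.null(config$simulate$base))) {
      sims <- demo_populations(config$simulate)
    } else if (inherits(config$simulate, "sim_config")) {
      sims <- list(simulate_population(config$simulate))
    } else {
      sims <- lapply(config$simulate, simulate_population)
    }
    panels <- lapply(sims, function(s) s$panel)
    names(panels) <- vapply(panels, function(p) p$animals$population[1], "")
    ped <- as_pedigree(dplyr::bind_rows(
      lapply(sims, function(s) tibble::as_tibble(s$pedigree))) |>
        dplyr::distinct(animal, .keep_all = TRUE))
  } else {
    panel <- read_plink_text(config$ped_path, config$map_path)
    panels <- split_panel(panel, "population")
    if (!is.null(config$pedigree_path))
      ped <- read_pedigree(config$pedigree_path)
  }

  artifacts <- character(0)
  add <- function(df, name) {
    p <- write_stage(df, config$out_dir, name)
    artifacts[[name]] <<- p
    artifacts <<- artifacts
  }

  clean <- list()
  records5 <- list()
  records20 <- list()
  inb_all <- list()
  for (pop in names(panels)) {
    qc <- do.call(apply_qc, c(list(panels[[pop]]), config$qc))
    add(dplyr::select(qc$report, -surviving_markers, -surviving_animals),
        paste0("qc_", pop))
    pp <- qc$panel
    clean[[pop]] <- pp
    if (config$misplaced_screen) {
      mis <- detect_misplaced_snps(pp)
      add(mis, paste0("misplaced_", pop))
      if (any(mis$flagged))
        pp <- subset_panel(pp,
                          markers = setdiff(pp$map$marker_id,
                                            mis$marker_id[mis$flagged]))
      clean[[pop]] <- pp
    }
    segs <- do.call(detect_roh, c(list(pp), config$roh))
    add(segs, paste0("roh_segments_", pop))
    rs <- summarize_roh(segs, pp)
    add(rs$animals, paste0("roh_animals_", pop))
    add(rs$histogram, paste0("roh_histogram_", pop))
    inb <- inbreeding_table(pp, segments = segs, ped = ped)
    inb$f_roh[is.na(inb$f_roh)] <- 0
    inb_all[[pop]] <- inb
    add(inb, paste0("inbreeding_", pop))
    r5 <- ld_scan(pp, max_distance_mbp = config$ld_max_decay_mbp)
    records5[[pop]] <- r5
    ls_ <- summarize_ld(r5, bin_width_mbp = config$ld_bin_width_mbp)
    add(ls_$bins, paste0("ld_decay_", pop))
    add(ls_$classes, paste0("ld_classes_", pop))
    add(ls_$useful, paste0("ld_useful_", pop))
    r20 <- ld_scan(pp, max_distance_mbp = config$ld_max_ne_mbp)
    records20[[pop]] <- r20
    ne <- estimate_ne(r20)
    add(ne, paste0("ne_trajectory_", pop))
  }

  div <- purrr::map_dfr(clean, diversity_summary)
  add(div, "diversity")
  inb_tab <- dplyr::bind_rows(inb_all)
  add(summarize_inbreeding(inb_tab), "inbreeding_summary")
  add(inbreeding_correlations(inb_tab), "inbreeding_correlations")

  joint <- join_panels(clean)
  if (n_animals(joint) >= 3 && n_markers(joint) >= 2) {
    grm <- build_grm(joint)
    pcs <- principal_components(grm, k = min(config$k_pc,
                                             n_animals(joint) - 1L))
    add(pcs$scores, "pca_scores")
    add(tibble::tibble(component = seq_along(pcs$variance_fraction),
                       variance_fraction = pcs$variance_fraction),
        "pca_variance")
  }

  pops <- names(panels)
  if (length(pops) >= 2) {
    pairs <- utils::combn(pops, 2)
    phase <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      pp <- phase_persistence(records5[[a]], records5[[b]],
                              bin_width_mbp = config$phase_bin_width_mbp)
      if (nrow(pp) == 0L) return(tibble::tibble())
      dplyr::mutate(tibble::as_tibble(pp), pop_a = a, pop_b = b,
                    .before = 1)
    })
    add(phase, "phase_persistence")
  }

  manifest <- tibble::tibble(
    artifact = names(artifacts),
    path = unname(artifacts),
    md5 = unname(tools::md5sum(unname(artifacts))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}

# demo topology: one base line, split into two, plus an F1 cross
demo_populations <- function(sim) {
  base <- simulate_population(sim$base)
  halves <- split_populations(base, sim$split_generations,
                              labels = sim$labels)
  f1 <- make_f1(halves[[1]], halves[[2]], sim$n_f1)
  list(halves[[1]], halves[[2]], f1)
}

# stack per-population panels that share a marker map superset
join_panels <- function(panels) {
  common <- Reduce(intersect, lapply(panels, function(p) p$map$marker_id))
  if (length(common) < 2L) stop("no common markers across populations",
                                call. = FALSE)
  parts <- lapply(panels, function(p) subset_panel(p, markers = common))
  dos <- do.call(rbind, lapply(parts, function(p) p$dosages))
  animals <- dplyr::bind_rows(lapply(parts, function(p) p$animals))
  genotype_panel(dos, parts[[1]]$map, animals,
                 parts[[1]]$counted_allele, parts[[1]]$other_allele)
}
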