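# End-to-end orchestration: simulate -> assign -> detect SSRs -> call SNPs
# -> design markers -> two-point map, with a reproducible run manifest.
# The R functions themselves are the command-line surface: each stage is an
# exported function, and scripts/acceptance.R shows the scripted entry point.

#' Build a pipeline configuration
#'
#' Collects the simulation configuration, every stage threshold and the
#' stage toggles into one validated object. Thresholds default to the
#' design rules of the marker pipeline: 80\% / 100 bp homolog assignment,
#' 90\% SNP comparison floor, 50 bp flanks (101 bp window), depth >= 7,
#' quality >= 40, MISA SSR minima 10/6/5/5/5/5, LOD 6.0 grouping.
#'
#' @param sim a [simulation_config()] object (the input data regime).
#' @param out_dir output directory for stage files (`NULL` = no files).
#' @param min_assign_identity,min_assign_length homolog assignment rule.
#' @param min_pair_identity SNP comparison identity floor.
#' @param flank flank length (window is `2 * flank + 1`).
#' @param min_depth,min_quality SNP depth/quality criterion.
#' @param ssr_minima per-class SSR minimum repeat counts (unit lengths 1-6).
#' @param lod_threshold,alpha linkage grouping LOD and distortion alpha.
#' @param ril_n,ril_generation RIL validation population size/generation.
#' @param stages character vector of stages to run, a subset of
#'   `c("ssr", "snp", "marker", "map")` (simulation always runs).
#' @param seed integer master seed (overrides `sim$seed`).
#' @return a `transmark_pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            out_dir = NULL,
                            min_assign_identity = 0.80,
                            min_assign_length = 100L,
                            min_pair_identity = 0.90,
                            flank = 50L, min_depth = 7L, min_quality = 40L,
                            ssr_minima = c(10L, 6L, 5L, 5L, 5L, 5L),
                            lod_threshold = 6.0, alpha = 0.01,
                            ril_n = 93L, ril_generation = 7L,
                            stages = c("ssr", "snp", "marker", "map"),
                            seed = NULL) {
  stopifnot(inherits(sim, "transmark_config"),
            min_assign_identity > 0, min_assign_identity <= 1,
            min_pair_identity > 0, min_pair_identity <= 1,
            flank >= 1, min_depth >= 0, min_quality >= 0,
            length(ssr_minima) == 6L, lod_threshold >= 0,
            alpha > 0, alpha < 1)
  bad <- setdiff(stages, c("ssr", "snp", "marker", "map"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(seed)) {
    sim$seed <- as.integer(seed)
  }
  cfg <- list(sim = sim, out_dir = out_dir,
              min_assign_identity = min_assign_identity,
              min_assign_length = as.integer(min_assign_length),
              min_pair_identity = min_pair_identity,
              flank = as.integer(flank), min_depth = as.integer(min_depth),
              min_quality = as.integer(min_quality),
              ssr_minima = as.integer(ssr_minima),
              lod_threshold = lod_threshold, alpha = alpha,
              ril_n = as.integer(ril_n),
              ril_generation = as.integer(ril_generation),
              stages = stages, seed = sim$seed)
  class(cfg) <- "transmark_pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with fields matching [pipeline_config()] arguments
#'   (`sim` holds [simulation_config()] arguments).
#' @return a `transmark_pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- raw$sim
  if (!is.null(sim_args$ssr_spec)) {
    sim_args$ssr_spec <- lapply(sim_args$ssr_spec, function(e) {
      list(motif = e$motif, counts = unlist(e$counts))
    })
  }
  sim <- do.call(simulation_config, if (is.null(sim_args)) list() else sim_args)
  raw$sim <- sim
  do.call(pipeline_config, raw)
}

#' Run the marker-design pipeline end to end
#'
#' Simulates the configured data bundle, assigns contigs to gene models,
#' detects and compares SSRs, calls and filters SNPs, runs the
#' three-criteria marker cascade, and validates accepted markers on a
#' simulated RIL population with two-point linkage utilities. Stage
#' results are written to `out_dir` (when set) and summarised in a run
#' manifest sufficient to reproduce the run (config echo, seed, per-stage
#' record counts, funnel, output paths).
#'
#' @param config a [pipeline_config()] object.
#' @param quiet suppress progress messages (default `TRUE`).
#' @return list with `manifest` and the in-memory stage results (`bundle`,
#'   `groups`, `copy_summary`, `ssr`, `snp`, `cascade`, `map`).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "transmark_pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir
  paths <- character(0)
  emit <- function(writer, obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    p <- file.path(out_dir, name)
    writer(obj, p)
    paths[[name]] <<- p
    invisible(p)
  }

  say("stage simulate: %d families", config$sim$n_single + config$sim$n_two +
        config$sim$n_three)
  bundle <- simulate_bundle(config$sim)
  emit(write_fasta, bundle$ref$gene_models, "gene_models.fasta")
  emit(write_fasta, bundle$ref$genomic, "genomic.fasta")
  emit(write_fasta, bundle$contigs, "contigs.fasta")
  emit(write_paralog_table, bundle$ref$paralog_table, "paralogs.tsv")
  emit(write_depth_table, bundle$depth, "depth.tsv")

  contig_lines <- setNames(bundle$contig_info$line, bundle$contig_info$contig_id)
  counts <- list(
    n_gene_models = length(bundle$ref$gene_models),
    n_contigs = length(bundle$contigs),
    n_planted_snps = nrow(bundle$truth$snp_sites),
    n_expected_markers = length(bundle$truth$expected_marker_ids))

  results <- list(bundle = bundle)

  cascade <- NULL
  if (any(c("snp", "marker", "map") %in% config$stages)) {
    say("stage assign/call/design: %d contigs", length(bundle$contigs))
    cascade <- run_cascade(
      bundle$contigs, bundle$ref$gene_models, bundle$ref$genomic,
      bundle$depth, bundle$ref$paralog_table, contig_lines,
      min_pair_identity = config$min_pair_identity, flank = config$flank,
      min_depth = config$min_depth, min_quality = config$min_quality,
      min_assign_identity = config$min_assign_identity,
      min_assign_length = config$min_assign_length)
    results$groups <- cascade$groups
    results$copy_summary <- summarize_copy_classes(cascade$groups,
                                                   bundle$ref$paralog_table)
    counts$n_assigned <- nrow(cascade$groups)
    counts$n_unassigned <- length(cascade$unassigned)
    if ("snp" %in% config$stages) {
      flt <- filter_snps(cascade$candidates,
                         min_depth = config$min_depth,
                         min_quality = config$min_quality)
      results$snp <- list(
        filtered = flt,
        partition = partition_by_copy_class(flt$sites,
                                            bundle$ref$paralog_table),
        presence = per_gene_snp_presence(flt$sites, cascade$groups))
      counts$n_snps_called <- nrow(cascade$candidates)
      counts$n_snps_retained <- nrow(flt$sites)
      emit(write_snp_table, flt$sites, "snps.tsv")
    }
    if ("marker" %in% config$stages) {
      results$cascade <- cascade
      counts$funnel <- setNames(cascade$funnel$n_genes, cascade$funnel$stage)
      counts$n_markers <- nrow(cascade$markers)
      emit(write_assay_table, cascade$markers, "markers.tsv")
    }
  }

  if ("ssr" %in% config$stages) {
    say("stage ssr")
    line_seqs <- c(list(ref = bundle$ref$gene_models),
                   lapply(bundle$lines, `[[`, "alleles"))
    loci_by_line <- lapply(line_seqs, detect_ssrs,
                           minima = config$ssr_minima,
                           flank_len = config$flank)
    results$ssr <- list(loci = loci_by_line,
                        sharing = if (length(loci_by_line) >= 2L)
                          summarize_ssr_sharing(loci_by_line,
                                                flank_len = config$flank)
                        else NULL)
    counts$n_ssr_loci <- sum(vapply(loci_by_line, nrow, integer(1)))
    emit(write_ssr_table, do.call(rbind, loci_by_line), "ssrs.tsv")
  }

  if ("map" %in% config$stages && !is.null(cascade) &&
      nrow(cascade$markers) >= 2L) {
    say("stage map: %d markers", nrow(cascade$markers))
    # validation map: accepted markers spread over 10 linkage groups
    mk <- cascade$markers$marker_id
    n_groups <- min(10L, length(mk))
    grp <- rep(seq_len(n_groups), length.out = length(mk))
    grp <- sort(grp)
    map <- do.call(rbind, lapply(split(mk, grp), function(ids) {
      data.frame(marker_id = ids, pos_cm = seq(0, by = 5, length.out = length(ids)))
    }))
    map$group <- rep(seq_len(n_groups), table(grp))
    map <- map[c("marker_id", "group", "pos_cm")]
    pop <- simulate_ril_population(map, n_individuals = config$ril_n,
                                   generation = config$ril_generation,
                                   seed = config$seed + 77L)
    tp <- two_point_scan(pop$genotypes, generation = config$ril_generation)
    grouping <- group_markers(tp, lod_threshold = config$lod_threshold,
                              markers = map$marker_id)
    distortion <- apply(pop$genotypes, 1L, function(calls) {
      test_segregation_distortion(calls, alpha = config$alpha)$distorted
    })
    results$map <- list(map = map, population = pop, two_point = tp,
                        groups = grouping, n_distorted = sum(distortion))
    counts$n_linkage_groups <- length(unique(grouping$group))
    counts$n_distorted_markers <- sum(distortion)
  }

  manifest <- list(
    package = "transmark",
    schema_version = 1L,
    seed = config$seed,
    stages = config$stages,
    config = config[setdiff(names(config), c("sim", "out_dir"))],
    sim_config = unclass(config$sim)[setdiff(names(config$sim), "ssr_spec")],
    counts = counts,
    outputs = as.list(paths))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  results$manifest <- manifest
  results
}
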