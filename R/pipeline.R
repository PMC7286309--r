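#' Pipeline configuration
#'
#' Collects every stage parameter with the defaults used throughout:
#' DAGchainer-style chaining with a maximum match distance of 25 genes and a
#' 20-pair block floor, quota-align-style merging at 50 genes, a 5 Mb
#' chromosome filter, Ks usability ceiling of 2, the 20-gene sub-block floor
#' with the block-G exception, and the 50-gene adjacency gap. Unknown keys
#' are rejected.
#'
#' @param max_gap chaining gap, genes (default 25).
#' @param min_pairs minimum anchors per block (default 20).
#' @param gap_penalty chaining gap penalty per rank unit (default 0.2).
#' @param merge_dist block merge distance, genes (default 50).
#' @param min_chrom_len chromosome length filter, bp (default 5e6).
#' @param ks_max Ks usability ceiling (default 2).
#' @param ks_cut manual ortholog/paralog boundary; `NULL` estimates it from
#'   the Ks density (see [estimate_ks_modes()]).
#' @param overlap_frac redundant-block overlap fraction (default 0.5).
#' @param min_subblock sub-block size floor, anchors (default 20).
#' @param allow_small GB labels exempt from the floor (default `"G"`).
#' @param adjacency_max_gap adjacency gap, genes (default 50).
#' @param adjacency_mode `"lenient"` or `"strict"` (see
#'   [extract_adjacencies()]).
#' @param seed integer; recorded for provenance.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(max_gap = 25, min_pairs = 20, gap_penalty = 0.2,
                            merge_dist = 50, min_chrom_len = 5e6, ks_max = 2,
                            ks_cut = NULL, overlap_frac = 0.5,
                            min_subblock = 20, allow_small = "G",
                            adjacency_max_gap = 50,
                            adjacency_mode = c("lenient", "strict"),
                            seed = 1L) {
  adjacency_mode <- match.arg(adjacency_mode)
  cfg <- list(max_gap = max_gap, min_pairs = min_pairs,
              gap_penalty = gap_penalty, merge_dist = merge_dist,
              min_chrom_len = min_chrom_len, ks_max = ks_max,
              ks_cut = ks_cut, overlap_frac = overlap_frac,
              min_subblock = min_subblock, allow_small = allow_small,
              adjacency_max_gap = adjacency_max_gap,
              adjacency_mode = adjacency_mode, seed = as.integer(seed))
  stopifnot(cfg$max_gap >= 1, cfg$min_pairs >= 1, cfg$merge_dist >= 0,
            cfg$min_chrom_len >= 0, cfg$ks_max > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are a hard
#' error.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Run the full genomic-block pipeline for one or more query genomes
#'
#' Stages, in order, per query genome against the reference carrying the GB
#' table: load -> chain -> merge -> Ks classify -> deduplicate -> project to
#' a painted karyotype; then across genomes: adjacency extraction, shared
#' derived associations, and (when candidate topologies are supplied) Fitch
#' parsimony ranking. Each stage writes its table under `outdir` along with
#' a per-stage log and an echo of the effective configuration; the run is a
#' pure function of (inputs, config).
#'
#' @param inputs list with elements: `ref_annotation` (path or
#'   `genome_annotation` of the reference genome), `annotations` (named list
#'   of query annotation paths/objects), `anchors` (named list, one anchor
#'   table path/data.frame per query, query gene in column `gene_a`,
#'   reference gene in `gene_b`), `gb_table` (path or data.frame),
#'   optionally `trees` (newick path or `multiPhylo`).
#' @param config a `pipeline_config`.
#' @param outdir output directory.
#' @return (invisibly) list with `blocks`, `modes`, `maps`, `adjacencies`,
#'   `shared`, `ranking` (NULL when < 2 taxa or no trees), `log`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "pipeline.log")
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("FAILED at stage %s: %s", name, conditionMessage(e))
      writeLines(log_lines, logf)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  load_ann <- function(x, id = NULL) {
    if (inherits(x, "genome_annotation")) x else
      read_annotation(x, min_chrom_len = config$min_chrom_len, genome_id = id)
  }
  ref_ann <- stage("load", load_ann(inputs$ref_annotation, "REF"))
  gb <- stage("load", {
    if (is.character(inputs$gb_table)) read_gb_table(inputs$gb_table, ref_ann)
    else gb_table(inputs$gb_table, ref_ann)
  })
  say("load: reference '%s' with %d genes; GB table with %d blocks",
      ref_ann$genome_id, nrow(ref_ann$genes), nrow(gb))

  taxa <- names(inputs$annotations)
  all_blocks <- list(); maps <- list(); modes_by_taxon <- list()
  for (tx in taxa) {
    ann <- stage("load", load_ann(inputs$annotations[[tx]], tx))
    anc <- stage("load", {
      x <- inputs$anchors[[tx]]
      if (is.character(x)) read_anchors(x, ann, ref_ann, ks_max = config$ks_max)
      else anchor_table(x, ann, ref_ann, ks_max = config$ks_max)
    })
    say("load[%s]: %d genes, %d anchors", tx, nrow(ann$genes), nrow(anc))

    blocks <- stage("chain", chain_anchors(
      anc, ann, ref_ann, max_gap = config$max_gap,
      min_pairs = config$min_pairs, gap_penalty = config$gap_penalty))
    say("chain[%s]: %d blocks, %d anchors chained", tx, length(blocks),
        sum(vapply(blocks, `[[`, integer(1), "n_pairs")))

    blocks <- stage("merge", merge_blocks(blocks, config$merge_dist))
    say("merge[%s]: %d blocks after merging", tx, length(blocks))

    modes <- stage("classify", {
      if (!is.null(config$ks_cut)) ks_modes(cut = config$ks_cut,
                                            ks_max = config$ks_max)
      else estimate_ks_modes(anc, ks_max = config$ks_max)
    })
    blocks <- stage("classify", classify_blocks(blocks, modes))
    say("classify[%s]: cut %.3f -> %d ortholog, %d WGD-paralog, %d unclassified",
        tx, modes$cut,
        sum(vapply(blocks, `[[`, character(1), "origin") == "ORTHOLOG"),
        sum(vapply(blocks, `[[`, character(1), "origin") == "WGD_PARALOG"),
        sum(vapply(blocks, `[[`, character(1), "origin") == "UNCLASSIFIED"))

    blocks <- stage("dedup", deduplicate_blocks(blocks, config$overlap_frac))
    say("dedup[%s]: %d retained ortholog blocks", tx,
        sum(vapply(blocks, function(b)
          b$origin == "ORTHOLOG" && !b$discarded, logical(1))))

    map <- stage("project", suppressMessages(build_gb_map(
      blocks, gb, ann, min_subblock = config$min_subblock,
      allow_small = config$allow_small)))
    say("project[%s]: %d sub-blocks (%d inverted) on %d chromosomes", tx,
        nrow(map$subblocks), sum(map$subblocks$inverted),
        length(unique(map$subblocks$chrom)))

    utils::write.table(blocks_summary(blocks),
                       file.path(outdir, paste0("blocks_", tx, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gb_map(map, file.path(outdir, paste0("gb_map_", tx, ".tsv")))
    all_blocks[[tx]] <- blocks
    maps[[tx]] <- map
    modes_by_taxon[[tx]] <- modes
  }

  ref_adj <- extract_adjacencies(gb_reference_map(gb),
                                 max_gap_genes = config$adjacency_max_gap,
                                 mode = config$adjacency_mode)
  adjacencies <- lapply(maps, extract_adjacencies,
                        max_gap_genes = config$adjacency_max_gap,
                        mode = config$adjacency_mode)
  shared <- NULL; ranking <- NULL
  if (length(maps) >= 2) {
    shared <- stage("adjacency", shared_derived_adjacencies(
      maps, ref_adj, max_gap_genes = config$adjacency_max_gap,
      mode = config$adjacency_mode))
    say("adjacency: %d derived adjacencies, %d shared by >= 2 taxa",
        nrow(shared), sum(shared$shared))
    utils::write.table(shared, file.path(outdir, "shared_adjacencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(inputs$trees)) {
      ranking <- stage("phylo", {
        m <- adjacency_character_matrix(shared)
        rank_topologies(m, inputs$trees)
      })
      say("phylo: best topology '%s' with score %d",
          ranking$tree[1], ranking$score[1])
      utils::write.table(ranking, file.path(outdir, "topology_ranking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  writeLines(log_lines, logf)
  invisible(list(blocks = all_blocks, modes = modes_by_taxon, maps = maps,
                 adjacencies = adjacencies, shared = shared,
                 ranking = ranking, log = log_lines))
}
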