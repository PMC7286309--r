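#' Compare a detected painted karyotype against a ground-truth map
#'
#' Three recovery measures for simulation benchmarks: the fraction of true
#' sub-block boundaries with a detected boundary within `tol` genes on the
#' same chromosome; the fraction of true adjacencies (at `max_gap_genes`)
#' present in the detected adjacency set; and agreement of inversion flags
#' between each true fragment and the detected fragment overlapping it
#' most.
#'
#' @param map detected `gb_map`.
#' @param truth ground-truth `gb_map` (e.g. [true_gb_map()] at the
#'   pipeline's detection floor).
#' @param tol boundary tolerance in genes (default 25).
#' @param max_gap_genes adjacency gap used on both maps (default 50).
#' @return list: `boundary_recovery`, `adjacency_recovery`,
#'   `inversion_flag_agreement`, `inversion_flags_ok`, `n_boundaries`,
#'   `n_adjacencies`.
#' @export
recovery_stats <- function(map, truth, tol = 25, max_gap_genes = 50) {
  tb <- truth$subblocks; db <- map$subblocks
  hits <- 0L; tot <- 0L
  for (i in seq_len(nrow(tb))) {
    d <- db[db$chrom == tb$chrom[i], , drop = FALSE]
    for (b in c(tb$rank_start[i], tb$rank_end[i])) {
      tot <- tot + 1L
      if (nrow(d) &&
          min(abs(c(d$rank_start, d$rank_end) - b)) <= tol) hits <- hits + 1L
    }
  }
  ta <- extract_adjacencies(truth, max_gap_genes = max_gap_genes)
  da <- extract_adjacencies(map, max_gap_genes = max_gap_genes)
  adj_rec <- if (nrow(ta)) mean(ta$key %in% da$key) else 1

  flag_ok <- logical(0)
  for (i in seq_len(nrow(tb))) {
    d <- db[db$chrom == tb$chrom[i], , drop = FALSE]
    if (!nrow(d)) next
    ov <- pmin(d$rank_end, tb$rank_end[i]) - pmax(d$rank_start,
                                                  tb$rank_start[i]) + 1
    if (max(ov) <= 0) next
    flag_ok <- c(flag_ok, d$inverted[which.max(ov)] == tb$inverted[i])
  }
  agree <- if (length(flag_ok)) mean(flag_ok) else 1
  list(boundary_recovery = if (tot) hits / tot else 1,
       adjacency_recovery = adj_rec,
       inversion_flag_agreement = agree,
       inversion_flags_ok = agree == 1,
       n_boundaries = tot, n_adjacencies = nrow(ta))
}

#' Simulated backbone-phylogeny scenario with ancestral block associations
#'
#' Builds the evolutionary scenario in which three non-ACK block
#' associations are part of the family-ancestral genome (planted on the
#' root stem as translocations that insert GBs W, U and R into foreign
#' junctions), are retained by the two earliest-diverging analogues
#' (Aethionema and Arabis) and are subsequently lost — each lineage moving
#' the inserted segment somewhere else — in the lineage III/E, I/A and II/B
#' analogues. Each leaf is then chained, classified and painted against the
#' ancestral reference, giving the painted maps, the ancestral adjacency
#' reference and the two candidate backbone topologies (Arabideae diverging
#' early vs nested within lineage II) to be ranked by Fitch parsimony.
#'
#' @param genes_per_gb genes per genomic block (default 60).
#' @param seed simulator seed.
#' @return list: `sim`, `maps` (named per taxon), `ref_adj`, `topologies`
#'   (named: `Arabideae_early`, `Arabideae_within_II`), `shared`.
#' @export
scenario_dataset <- function(genes_per_gb = 60, seed = 1) {
  g <- genes_per_gb
  tr <- function(branch, chrom, start, end, dest_chrom, dest_pos) {
    list(branch = branch, type = "translocation", chrom = chrom,
         start = start, end = end, dest_chrom = dest_chrom,
         dest_pos = dest_pos, invert = FALSE)
  }
  events <- list(
    # ancestral associations: A-W-B on AK1, I-U-J on AK4, D-R-E on AK2
    tr("root", "AK8", g + 1, 2 * g, "AK1", g),
    tr("root", "AK7", 2 * g + 1, 3 * g, "AK4", g),
    tr("root", "AK6", 3 * g + 1, 4 * g, "AK2", g),
    # independent losses: each late lineage moves the inserted segments
    # to lineage-specific positions
    tr("linIII", "AK1", g + 1, 2 * g, "AK3", g %/% 2),
    tr("linIII", "AK4", g + 1, 2 * g, "AK3", 2 * g + g %/% 2),
    tr("linIII", "AK2", g + 1, 2 * g, "AK3", 4 * g + g %/% 2),
    tr("linI", "AK1", g + 1, 2 * g, "AK5", g %/% 3),
    tr("linI", "AK4", g + 1, 2 * g, "AK5", g + g %/% 2),
    tr("linI", "AK2", g + 1, 2 * g, "AK5", 2 * g + g %/% 2),
    tr("linII", "AK1", g + 1, 2 * g, "AK6", g %/% 3),
    tr("linII", "AK4", g + 1, 2 * g, "AK6", g + g %/% 3),
    tr("linII", "AK2", g + 1, 2 * g, "AK6", 2 * g + g %/% 3))
  cfg <- sim_config(genes_per_gb = g, wgd_enabled = FALSE, loss_prob = 0,
                    events = events, seed = seed)
  sim <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  maps <- list()
  for (tx in cfg$tree$tip.label) {
    anc <- anchor_table(sim$anchors[[paste0(tx, "|REF")]])
    blocks <- classify_blocks(
      merge_blocks(chain_anchors(anc, sim$annotations[[tx]],
                                 sim$annotations$REF)),
      ks_modes(cut = 1.0))
    blocks <- deduplicate_blocks(blocks)
    maps[[tx]] <- suppressMessages(
      build_gb_map(blocks, sim$ancestor$gb, sim$annotations[[tx]]))
  }
  ref_adj <- extract_adjacencies(gb_reference_map(sim$ancestor$gb))
  topologies <- list(
    Arabideae_early = ape::read.tree(
      text = "(Aeth,(Arab,(linIII,(linI,linII))));"),
    Arabideae_within_II = ape::read.tree(
      text = "(Aeth,(linIII,(linI,(linII,Arab))));"))
  shared <- shared_derived_adjacencies(maps, ref_adj)
  list(sim = sim, maps = maps, ref_adj = ref_adj, topologies = topologies,
       shared = shared)
}
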