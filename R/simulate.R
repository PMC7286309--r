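#' Configuration for the synthetic genome-evolution simulator
#'
#' The simulator emulates the data-generating process the analysis assumes:
#' an ancestral karyotype partitioned into labelled genomic blocks, a
#' whole-genome duplication (the At-alpha analogue) whose paralog Ks sits in
#' a higher mode than ortholog Ks, biased fractionation of the duplicated
#' copies, and lineage-specific inversions / translocations / fissions /
#' fusions along a given tree. All randomness flows from `seed`; per-branch
#' substreams are derived deterministically from branch names, so a fixed
#' seed gives byte-identical outputs.
#'
#' The default karyotype is the 8-chromosome ancestral crucifer karyotype
#' with its 22 blocks (A..X, K-L and M-N merged) in their ancestral order.
#' Pairwise ortholog Ks mode grows with tree path length (`ks_rate` per unit
#' length; the default 0.385 puts two depth-1 leaves at 0.77) and the
#' paralog mode rides `wgd_ks_excess` above it (default 0.6, reproducing the
#' observed 0.77 vs 1.37 and 0.41 vs 1.01 ortholog/paralog pairs).
#'
#' @param tree newick string or `ape::phylo` with branch lengths; leaves
#'   named.
#' @param gb_labels named list: AK chromosome -> ordered GB labels.
#' @param genes_per_gb genes per genomic block (default 100).
#' @param gene_slot_bp bp of sequence per gene slot (default 30000, so a
#'   200-gene chromosome exceeds the 5 Mb chromosome filter).
#' @param gene_len_bp length of each gene (default 2000).
#' @param wgd_enabled apply a WGD shared by all taxa (default `TRUE`).
#' @param wgd_ks_excess paralog Ks mode minus ortholog Ks mode (default 0.6).
#' @param ks_rate ortholog Ks mode per unit of tree path length.
#' @param ks_logsd log-scale standard deviation of all Ks draws (default 0.2).
#' @param loss_prob probability a duplicated gene pair loses one copy in a
#'   leaf lineage (default 0.7).
#' @param copy_bias probability the lost copy comes from the lineage's
#'   non-dominant subgenome (default 0.7); dominant subgenomes alternate
#'   across leaves, so different lineages preferentially retain different
#'   copies.
#' @param event_counts named list: branch (child node or leaf name) ->
#'   named counts among `inversion`, `translocation`, `fission`, `fusion`.
#' @param events list of explicit planted events, each a list with `branch`
#'   (a leaf or internal node name, or `"root"` to modify the shared
#'   ancestral state before the walk),
#'   `type`, `chrom` (name), 1-based gene positions `start`, `end`, and for
#'   translocations `dest_chrom`, `dest_pos` (0 = before first gene),
#'   `invert`. Applied before that branch's random events.
#' @param seed integer master seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(tree = "(Aeth:1,(Arab:0.6,(linIII:0.4,(linI:0.2,linII:0.2):0.2):0.2):0.4);",
                       gb_labels = list(
                         AK1 = c("A", "B", "C"), AK2 = c("D", "E"),
                         AK3 = c("F", "G", "H"), AK4 = c("I", "J"),
                         AK5 = c("K-L", "M-N"), AK6 = c("O", "P", "Q", "R"),
                         AK7 = c("S", "T", "U"), AK8 = c("V", "W", "X")),
                       genes_per_gb = 100, gene_slot_bp = 30000,
                       gene_len_bp = 2000,
                       wgd_enabled = TRUE, wgd_ks_excess = 0.6,
                       ks_rate = 0.385, ks_logsd = 0.2,
                       loss_prob = 0.7, copy_bias = 0.7,
                       event_counts = list(), events = list(), seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            genes_per_gb >= 1, ks_logsd > 0,
            loss_prob >= 0, loss_prob <= 1, copy_bias >= 0, copy_bias <= 1)
  if (is.null(tree$node.label) || !all(nzchar(tree$node.label))) {
    tree$node.label <- paste0("N", seq_len(tree$Nnode))
  }
  structure(list(tree = tree, gb_labels = gb_labels,
                 genes_per_gb = genes_per_gb, gene_slot_bp = gene_slot_bp,
                 gene_len_bp = gene_len_bp, wgd_enabled = wgd_enabled,
                 wgd_ks_excess = wgd_ks_excess, ks_rate = ks_rate,
                 ks_logsd = ks_logsd, loss_prob = loss_prob,
                 copy_bias = copy_bias, event_counts = event_counts,
                 events = events, seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-branch / per-purpose substream seed (< 2^31)
.sub_seed <- function(seed, name) {
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 1048573
  as.integer((as.numeric(seed) * 1048583 + h * 7919 + 17) %% 2147483629)
}

#' Simulate the ancestral karyotype
#'
#' Lays out `genes_per_gb` genes per genomic block contiguously along the
#' ancestral chromosomes, and derives the GB definition table (first and
#' last gene id of each block). The GB intervals partition every chromosome
#' with no gaps. Deterministic: no random draws are involved.
#'
#' @param config a `sim_config`.
#' @return list with `genome` (internal representation), `ann`
#'   (`genome_annotation` of the ancestor, genome_id `"REF"`) and `gb`
#'   (rank-resolved GB table).
#' @export
simulate_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- list()
  gid <- 0L
  gb_rows <- list()
  for (ch in names(config$gb_labels)) {
    rows <- list()
    for (lb in config$gb_labels[[ch]]) {
      ids <- sprintf("g%05d", gid + seq_len(config$genes_per_gb))
      gid <- gid + config$genes_per_gb
      rows[[lb]] <- data.frame(anc_id = ids, subgenome = 1L, gb_label = lb,
                               strand = "+", stringsAsFactors = FALSE)
      gb_rows[[lb]] <- data.frame(label = lb, ak_chrom = ch,
                                  ref_start_gene = ids[1],
                                  ref_end_gene = ids[length(ids)],
                                  stringsAsFactors = FALSE)
    }
    chrom <- do.call(rbind, rows)
    chrom$anc_rank <- seq_len(nrow(chrom)) - 1L
    rownames(chrom) <- NULL
    genome[[ch]] <- chrom
  }
  ann <- .genome_to_annotation(genome, "REF", config, ref_ids = TRUE)
  gb <- gb_table(do.call(rbind, gb_rows), ref_ann = ann)
  list(genome = genome, ann = ann, gb = gb)
}

# lay the evolved gene order out on bp coordinates and rank it.
# chrom_len_genes carries each chromosome's pre-fractionation gene count:
# gene loss leaves the DNA (and so the chromosome length) in place
.genome_to_annotation <- function(genome, genome_id, config, ref_ids = FALSE,
                                  chrom_len_genes = NULL) {
  slot <- config$gene_slot_bp; glen <- config$gene_len_bp
  genes <- list(); chroms <- list()
  for (ch in names(genome)) {
    g <- genome[[ch]]
    if (!nrow(g)) next
    k <- seq_len(nrow(g)) - 1L
    genes[[ch]] <- data.frame(
      gene_id = if (ref_ids) g$anc_id else
        sprintf("%s_%s_s%d", genome_id, g$anc_id, g$subgenome),
      chrom = ch, start = k * slot + 1000, end = k * slot + 1000 + glen,
      strand = g$strand, stringsAsFactors = FALSE)
    n_len <- if (!is.null(chrom_len_genes) && ch %in% names(chrom_len_genes))
      chrom_len_genes[[ch]] else nrow(g)
    chroms[[ch]] <- data.frame(chrom = ch,
                               length = n_len * slot + 10000,
                               stringsAsFactors = FALSE)
  }
  genome_annotation(genome_id, do.call(rbind, chroms), do.call(rbind, genes))
}

.apply_wgd <- function(genome) {
  dup <- lapply(genome, function(g) { g$subgenome <- 2L; g })
  names(dup) <- paste0(names(genome), "b")
  c(genome, dup)
}

# --- rearrangement events on the internal genome representation ---------

.ev_inversion <- function(genome, chrom, start, end) {
  g <- genome[[chrom]]
  seg <- g[start:end, , drop = FALSE]
  seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  seg$strand <- ifelse(seg$strand == "+", "-", "+")
  genome[[chrom]] <- rbind(
    if (start > 1) g[1:(start - 1), , drop = FALSE],
    seg,
    if (end < nrow(g)) g[(end + 1):nrow(g), , drop = FALSE])
  genome
}

.ev_translocation <- function(genome, chrom, start, end, dest_chrom, dest_pos,
                              invert = FALSE) {
  g <- genome[[chrom]]
  seg <- g[start:end, , drop = FALSE]
  if (invert) {
    seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    seg$strand <- ifelse(seg$strand == "+", "-", "+")
  }
  rest <- g[-(start:end), , drop = FALSE]
  genome[[chrom]] <- rest
  d <- genome[[dest_chrom]]
  genome[[dest_chrom]] <- rbind(
    if (dest_pos > 0) d[seq_len(dest_pos), , drop = FALSE],
    seg,
    if (dest_pos < nrow(d)) d[(dest_pos + 1):nrow(d), , drop = FALSE])
  genome
}

.ev_fission <- function(genome, chrom, cut) {
  g <- genome[[chrom]]
  genome[[paste0(chrom, ".1")]] <- g[seq_len(cut), , drop = FALSE]
  genome[[paste0(chrom, ".2")]] <- g[(cut + 1):nrow(g), , drop = FALSE]
  genome[[chrom]] <- NULL
  genome
}

.ev_fusion <- function(genome, chrom1, chrom2, invert2 = FALSE) {
  g2 <- genome[[chrom2]]
  if (invert2) {
    g2 <- g2[rev(seq_len(nrow(g2))), , drop = FALSE]
    g2$strand <- ifelse(g2$strand == "+", "-", "+")
  }
  genome[[paste0(chrom1, "+", chrom2)]] <- rbind(genome[[chrom1]], g2)
  genome[[chrom1]] <- NULL
  genome[[chrom2]] <- NULL
  genome
}

.pick_chrom <- function(genome, min_genes = 1) {
  sizes <- vapply(genome, nrow, integer(1))
  ok <- names(sizes)[sizes >= min_genes]
  if (!length(ok)) return(NULL)
  # breakpoints uniform in rank space: weight chromosomes by gene count
  sample(ok, 1, prob = sizes[ok])
}

.random_event <- function(genome, type, max_retry = 100) {
  for (try in seq_len(max_retry)) {
    if (type == "inversion") {
      ch <- .pick_chrom(genome, 2)
      if (is.null(ch)) next
      n <- nrow(genome[[ch]])
      cut <- sort(sample.int(n, 2))
      return(list(type = type, chrom = ch, start = cut[1], end = cut[2]))
    }
    if (type == "translocation") {
      ch <- .pick_chrom(genome, 2)
      if (is.null(ch)) next
      n <- nrow(genome[[ch]])
      cut <- sort(sample.int(n, 2))
      if (cut[2] - cut[1] + 1 >= n) next  # keep the donor chromosome alive
      others <- setdiff(names(genome), ch)
      if (!length(others)) next
      dest <- sample(others, 1)
      dpos <- sample.int(nrow(genome[[dest]]) + 1, 1) - 1L
      return(list(type = type, chrom = ch, start = cut[1], end = cut[2],
                  dest_chrom = dest, dest_pos = dpos,
                  invert = stats::runif(1) < 0.5))
    }
    if (type == "fission") {
      ch <- .pick_chrom(genome, 2)
      if (is.null(ch)) next
      return(list(type = type, chrom = ch,
                  cut = sample.int(nrow(genome[[ch]]) - 1, 1)))
    }
    if (type == "fusion") {
      if (length(genome) < 2) next
      pair <- sample(names(genome), 2)
      return(list(type = type, chrom1 = pair[1], chrom2 = pair[2],
                  invert2 = stats::runif(1) < 0.5))
    }
  }
  stop("could not draw a feasible ", type, " after ", max_retry, " tries")
}

.apply_event <- function(genome, ev) {
  switch(ev$type,
         inversion = .ev_inversion(genome, ev$chrom, ev$start, ev$end),
         translocation = .ev_translocation(genome, ev$chrom, ev$start, ev$end,
                                           ev$dest_chrom, ev$dest_pos,
                                           isTRUE(ev$invert)),
         fission = .ev_fission(genome, ev$chrom, ev$cut),
         fusion = .ev_fusion(genome, ev$chrom1, ev$chrom2, isTRUE(ev$invert2)),
         stop("unknown event type: ", ev$type))
}

.event_row <- function(branch, ev) {
  data.frame(branch = branch, type = ev$type,
             chrom = if (!is.null(ev$chrom)) ev$chrom else ev$chrom1,
             start = if (!is.null(ev$start)) ev$start else
               if (!is.null(ev$cut)) ev$cut else NA_integer_,
             end = if (!is.null(ev$end)) ev$end else NA_integer_,
             dest_chrom = if (!is.null(ev$dest_chrom)) ev$dest_chrom else
               if (!is.null(ev$chrom2)) ev$chrom2 else NA_character_,
             dest_pos = if (!is.null(ev$dest_pos)) ev$dest_pos else NA_integer_,
             invert = isTRUE(ev$invert) || isTRUE(ev$invert2),
             stringsAsFactors = FALSE)
}

#' Evolve the ancestral genome along the tree
#'
#' Applies the WGD (duplicating every chromosome into a second subgenome),
#' then walks the tree from the root, applying each branch's planted and
#' random rearrangement events to a copy of the parent genome; at the
#' leaves, biased fractionation removes one copy of duplicated genes. Leaf
#' annotations, anchor tables (leaf vs the ancestral reference `REF` and all
#' leaf pairs, with Ks drawn from the configured log-normal modes and the
#' true origin recorded per pair) and a complete ground-truth record (event
#' log, per-taxon true sub-block maps, true adjacency sets) are returned.
#'
#' @param ancestor output of [simulate_ancestor()].
#' @param config the `sim_config`.
#' @return a `genome_sim` list: `config`, `tree`, `ancestor`, `annotations`
#'   (named, including `REF`), `genomes` (internal per-leaf state),
#'   `anchors` (named `"A|B"`), `truth` (`events`, `dominant_subgenome`).
#' @export
evolve_along_tree <- function(ancestor, config) {
  tree <- config$tree
  ntip <- length(tree$tip.label)
  node_name <- c(tree$tip.label, tree$node.label)
  root <- ntip + 1L

  genome0 <- ancestor$genome
  if (config$wgd_enabled) genome0 <- .apply_wgd(genome0)

  events <- list()
  # events planted on the root stem shape the family-ancestral state
  # shared by every taxon (the reference genome is not affected)
  for (ev in config$events) {
    if (!identical(ev$branch, "root")) next
    genome0 <- .apply_event(genome0, ev)
    events[[length(events) + 1]] <- .event_row("root", ev)
  }
  states <- list(); states[[node_name[root]]] <- genome0
  # preorder edge walk: parents are always visited before their children
  edges <- tree$edge[rev(ape::postorder(tree)), , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    par <- node_name[edges[i, 1]]; child <- node_name[edges[i, 2]]
    genome <- states[[par]]
    for (ev in config$events) {
      if (!identical(ev$branch, child)) next
      genome <- .apply_event(genome, ev)
      events[[length(events) + 1]] <- .event_row(child, ev)
    }
    counts <- config$event_counts[[child]]
    if (!is.null(counts) && sum(counts) > 0) {
      set.seed(.sub_seed(config$seed, paste0("branch:", child)))
      for (type in c("inversion", "translocation", "fission", "fusion")) {
        k <- if (type %in% names(counts)) counts[[type]] else 0
        if (is.na(k)) k <- 0
        for (r in seq_len(k)) {
          ev <- .random_event(genome, type)
          genome <- .apply_event(genome, ev)
          events[[length(events) + 1]] <- .event_row(child, ev)
        }
      }
    }
    states[[child]] <- genome
  }

  # biased fractionation at the leaves; dominant subgenome alternates
  prefrac_counts <- lapply(states[tree$tip.label], function(g)
    vapply(g, nrow, integer(1)))
  dominant <- stats::setNames(rep_len(c(1L, 2L), ntip), tree$tip.label)
  if (config$wgd_enabled && config$loss_prob > 0) {
    for (tx in tree$tip.label) {
      set.seed(.sub_seed(config$seed, paste0("fractionation:", tx)))
      genome <- states[[tx]]
      all_ids <- unlist(lapply(genome, `[[`, "anc_id"), use.names = FALSE)
      all_sub <- unlist(lapply(genome, `[[`, "subgenome"), use.names = FALSE)
      dup_ids <- intersect(all_ids[all_sub == 1L], all_ids[all_sub == 2L])
      lose <- dup_ids[stats::runif(length(dup_ids)) < config$loss_prob]
      # which copy dies: the non-dominant one with prob copy_bias
      nondom <- ifelse(stats::runif(length(lose)) < config$copy_bias,
                       3L - dominant[tx], dominant[tx])
      kill <- paste(lose, nondom)
      states[[tx]] <- lapply(genome, function(g) {
        g[!(paste(g$anc_id, g$subgenome) %in% kill), , drop = FALSE]
      })
    }
  }

  annotations <- list(REF = ancestor$ann)
  for (tx in tree$tip.label) {
    annotations[[tx]] <- .genome_to_annotation(
      states[[tx]], tx, config, chrom_len_genes = prefrac_counts[[tx]])
  }

  depth <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  names(depth) <- tree$tip.label
  dmat <- ape::cophenetic.phylo(tree)

  anchors <- list()
  for (tx in tree$tip.label) {
    anchors[[paste(tx, "REF", sep = "|")]] <-
      .make_anchors_vs_ref(states[[tx]], tx, depth[tx], config)
  }
  tips <- tree$tip.label
  if (ntip >= 2) {
    for (i in seq_len(ntip - 1)) for (j in (i + 1):ntip) {
      anchors[[paste(tips[i], tips[j], sep = "|")]] <-
        .make_anchors_leaf_pair(states[[tips[i]]], states[[tips[j]]],
                                tips[i], tips[j], dmat[tips[i], tips[j]],
                                config)
    }
  }

  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(), type = character(), chrom = character(),
               start = integer(), end = integer(), dest_chrom = character(),
               dest_pos = integer(), invert = logical(),
               stringsAsFactors = FALSE)
  structure(list(config = config, tree = tree, ancestor = ancestor,
                 genomes = states[tree$tip.label], annotations = annotations,
                 anchors = anchors,
                 truth = list(events = ev_df, dominant_subgenome = dominant)),
            class = "genome_sim")
}

.ks_draw <- function(n, mode, logsd) {
  # log-normal parameterised by its mode: mode = exp(meanlog - sd^2)
  stats::rlnorm(n, meanlog = log(mode) + logsd^2, sdlog = logsd)
}

.flatten_genome <- function(genome) {
  g <- do.call(rbind, genome)
  rownames(g) <- NULL
  g
}

.make_anchors_vs_ref <- function(genome, taxon, depth, config) {
  g <- .flatten_genome(genome)
  set.seed(.sub_seed(config$seed, paste0("ks:", taxon, "|REF")))
  ortho_mode <- max(config$ks_rate * depth, 0.02)
  gene_a <- sprintf("%s_%s_s%d", taxon, g$anc_id, g$subgenome)
  is_par <- g$subgenome == 2L
  ks <- numeric(nrow(g))
  ks[!is_par] <- .ks_draw(sum(!is_par), ortho_mode, config$ks_logsd)
  if (any(is_par)) {
    ks[is_par] <- .ks_draw(sum(is_par), ortho_mode + config$wgd_ks_excess,
                           config$ks_logsd)
  }
  data.frame(gene_a = gene_a, gene_b = g$anc_id, ks = ks, score = NA_real_,
             true_origin = ifelse(is_par, "WGD_PARALOG", "ORTHOLOG"),
             stringsAsFactors = FALSE)
}

.make_anchors_leaf_pair <- function(gen1, gen2, tx1, tx2, path_len, config) {
  g1 <- .flatten_genome(gen1); g2 <- .flatten_genome(gen2)
  set.seed(.sub_seed(config$seed, paste0("ks:", tx1, "|", tx2)))
  m <- merge(g1[c("anc_id", "subgenome")], g2[c("anc_id", "subgenome")],
             by = "anc_id", suffixes = c("_1", "_2"))
  if (!nrow(m)) return(NULL)
  m <- m[order(m$anc_id, m$subgenome_1, m$subgenome_2), , drop = FALSE]
  is_par <- m$subgenome_1 != m$subgenome_2
  ortho_mode <- max(config$ks_rate * path_len, 0.02)
  ks <- numeric(nrow(m))
  ks[!is_par] <- .ks_draw(sum(!is_par), ortho_mode, config$ks_logsd)
  if (any(is_par)) {
    ks[is_par] <- .ks_draw(sum(is_par), ortho_mode + config$wgd_ks_excess,
                           config$ks_logsd)
  }
  data.frame(
    gene_a = sprintf("%s_%s_s%d", tx1, m$anc_id, m$subgenome_1),
    gene_b = sprintf("%s_%s_s%d", tx2, m$anc_id, m$subgenome_2),
    ks = ks, score = NA_real_,
    true_origin = ifelse(is_par, "WGD_PARALOG", "ORTHOLOG"),
    stringsAsFactors = FALSE)
}

#' Ground-truth painted karyotype of a simulated taxon
#'
#' Reads the true sub-block structure straight off the simulated gene order:
#' maximal runs of genes with the same GB label, the same subgenome and a
#' consistent ancestral-rank direction form the true sub-blocks; a
#' descending run is a true inversion. Fragments are indexed by ancestral
#' start position exactly as [build_gb_map()] numbers detected fragments.
#'
#' `min_fragment` sets the resolution: recovery benchmarks use the
#' pipeline's detection floor (20 genes, with the same `allow_small`
#' exemption the projector applies) so that truth and detection are
#' compared at the same scale. At that floored resolution, breaks the
#' method cannot see are collapsed: two same-label, same-direction runs
#' separated only by a dropped sub-floor fragment or by an ancestral-rank
#' jump within `merge_tol` (the quota-align merge distance) are rejoined,
#' exactly as chaining plus merging rejoins them. `min_fragment = 1` gives
#' the full-resolution truth with every breakpoint.
#'
#' @param sim a `genome_sim`.
#' @param taxon leaf name.
#' @param min_fragment drop true fragments with fewer genes (default 1).
#' @param subgenome which subgenome's fragments constitute the truth
#'   (default 1, the copy orthologous to the reference); `NULL` keeps both.
#' @param jump_max largest ancestral-rank step still treated as within-run
#'   (default 25, the chaining gap); larger jumps mark true breakpoints.
#' @param allow_small labels exempt from `min_fragment` (default `"G"`,
#'   matching the projector).
#' @param merge_tol rank tolerance for collapsing sub-resolution breaks in
#'   the floored truth (default 50, the merge distance).
#' @return a `gb_map`.
#' @export
true_gb_map <- function(sim, taxon, min_fragment = 1, subgenome = 1L,
                        jump_max = 25, allow_small = "G", merge_tol = 50) {
  stopifnot(inherits(sim, "genome_sim"))
  genome <- sim$genomes[[taxon]]
  if (is.null(genome)) stop("unknown taxon: ", taxon)
  slot <- sim$config$gene_slot_bp; glen <- sim$config$gene_len_bp
  rows <- list()
  for (ch in names(genome)) {
    g <- genome[[ch]]
    if (!nrow(g)) next
    g$final_rank <- seq_len(nrow(g)) - 1L
    # greedy run scan: a run extends while the GB label and subgenome stay
    # constant, the ancestral-rank step is at most jump_max in magnitude
    # (fractionation punches small holes; rearrangement breakpoints jump
    # far) and its sign agrees with the run's direction
    run <- integer(nrow(g))
    run[1] <- 1L
    dirn <- 0L
    for (i in seq_len(nrow(g))[-1]) {
      d <- g$anc_rank[i] - g$anc_rank[i - 1]
      same <- g$gb_label[i] == g$gb_label[i - 1] &&
        g$subgenome[i] == g$subgenome[i - 1] && abs(d) <= jump_max &&
        (dirn == 0L || sign(d) == dirn)
      if (same) {
        run[i] <- run[i - 1]
        if (dirn == 0L) dirn <- sign(d)
      } else {
        run[i] <- run[i - 1] + 1L
        dirn <- 0L
      }
    }
    for (r in unique(run)) {
      s <- g[run == r, , drop = FALSE]
      if (!is.null(subgenome) && s$subgenome[1] != subgenome) next
      if (nrow(s) < min_fragment && !(s$gb_label[1] %in% allow_small)) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, rank_start = min(s$final_rank),
        rank_end = max(s$final_rank),
        bp_start = min(s$final_rank) * slot + 1000,
        bp_end = max(s$final_rank) * slot + 1000 + glen,
        gb_label = s$gb_label[1], index = NA_integer_,
        inverted = nrow(s) >= 2 && s$anc_rank[2] < s$anc_rank[1],
        n_genes = nrow(s),
        ref_start_rank = min(s$anc_rank), ref_end_rank = max(s$anc_rank),
        stringsAsFactors = FALSE)
    }
  }
  sb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), rank_start = integer(),
               rank_end = integer(), bp_start = numeric(), bp_end = numeric(),
               gb_label = character(), index = integer(), inverted = logical(),
               n_genes = integer(), ref_start_rank = integer(),
               ref_end_rank = integer(), stringsAsFactors = FALSE)
  if (min_fragment > 1) sb <- .collapse_subresolution(sb, merge_tol)
  for (lb in unique(sb$gb_label)) {
    ix <- which(sb$gb_label == lb)
    sb$index[ix[order(sb$ref_start_rank[ix])]] <- seq_along(ix)
  }
  new_gb_map(taxon, sb)
}

# rejoin floored-truth fragments split only by sub-resolution breaks: same
# label and direction, nearby in both query rank and ancestral rank
.collapse_subresolution <- function(sb, merge_tol) {
  if (nrow(sb) < 2) return(sb)
  sb <- sb[order(sb$chrom, sb$rank_start), , drop = FALSE]
  i <- 1L
  while (i < nrow(sb)) {
    a <- sb[i, ]; b <- sb[i + 1, ]
    ref_gap <- if (a$inverted) a$ref_start_rank - b$ref_end_rank
    else b$ref_start_rank - a$ref_end_rank
    if (a$chrom == b$chrom && a$gb_label == b$gb_label &&
        a$inverted == b$inverted &&
        b$rank_start - a$rank_end - 1 <= merge_tol &&
        abs(ref_gap) <= merge_tol) {
      sb$rank_end[i] <- b$rank_end
      sb$bp_end[i] <- b$bp_end
      sb$n_genes[i] <- a$n_genes + b$n_genes
      sb$ref_start_rank[i] <- min(a$ref_start_rank, b$ref_start_rank)
      sb$ref_end_rank[i] <- max(a$ref_end_rank, b$ref_end_rank)
      sb <- sb[-(i + 1), , drop = FALSE]
    } else i <- i + 1L
  }
  rownames(sb) <- NULL
  sb
}

#' Write a simulated dataset to disk
#'
#' Emits, under `outdir`: one GFF3 per taxon (including the ancestral
#' reference `REF`), one anchors TSV per genome pair (with Ks, and the true
#' pair origin in a trailing column readers ignore), the GB definition
#' table, ground-truth tables (event log, per-taxon true sub-block maps),
#' and a YAML echo of the configuration. Everything re-loads through the
#' package readers; output is byte-identical under a fixed seed.
#'
#' @param sim a `genome_sim`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
emit_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  for (tx in names(sim$annotations)) {
    .write_gff3(sim$annotations[[tx]], file.path(outdir, paste0(tx, ".gff3")))
  }
  for (pair in names(sim$anchors)) {
    df <- sim$anchors[[pair]]
    fn <- file.path(outdir, paste0("anchors_", gsub("\\|", "_", pair), ".tsv"))
    utils::write.table(
      data.frame(gene_a = df$gene_a, gene_b = df$gene_b,
                 ks = sprintf("%.6f", df$ks), score = ".",
                 true_origin = df$true_origin, stringsAsFactors = FALSE),
      fn, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  gb <- sim$ancestor$gb
  utils::write.table(gb[c("label", "ak_chrom", "ref_start_gene",
                          "ref_end_gene")],
                     file.path(outdir, "gb_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$events, file.path(outdir, "truth", "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (tx in names(sim$genomes)) {
    write_gb_map(true_gb_map(sim, tx),
                 file.path(outdir, "truth", paste0(tx, "_true_map.tsv")))
  }
  cfg <- sim$config
  cfg$tree <- ape::write.tree(cfg$tree)
  yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), c("events"))],
                   file.path(outdir, "config.yaml"))
  invisible(outdir)
}

.write_gff3 <- function(ann, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(ann$chromosomes))) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              ann$chromosomes$chrom[i],
                              as.integer(ann$chromosomes$length[i])))
  }
  g <- ann$genes
  lines <- c(lines, sprintf(
    "%s\tackpaint-sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
    g$chrom, as.integer(g$start + 1), as.integer(g$end), g$strand,
    g$gene_id, g$gene_id))
  writeLines(lines, path)
  invisible(path)
}
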