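# In-code fixtures and independent oracles shared across the test files.

# single- or multi-chromosome annotation with one gene per rank
toy_ann <- function(n, genome_id = "Q", chrom = "c1", start0 = 0) {
  chroms <- data.frame(chrom = chrom,
                       length = rep(n * 10 + 100, length(chrom)))
  genes <- do.call(rbind, lapply(chrom, function(ch) data.frame(
    gene_id = sprintf("%s_%s_g%03d", genome_id, ch, seq_len(n)),
    chrom = ch, start = start0 + (seq_len(n) - 1) * 10,
    end = start0 + (seq_len(n) - 1) * 10 + 5,
    strand = "+", stringsAsFactors = FALSE)))
  genome_annotation(genome_id, chroms, genes)
}

# anchors joining rank ra on ann_a's chrom_a to rank rb on ann_b's chrom_b
anchors_from_ranks <- function(ann_a, ann_b, ra, rb, ks = NA_real_,
                               chrom_a = ann_a$genes$chrom[1],
                               chrom_b = ann_b$genes$chrom[1]) {
  ga <- ann_a$genes; gb <- ann_b$genes
  data.frame(
    gene_a = ga$gene_id[match(paste(chrom_a, ra), paste(ga$chrom, ga$rank))],
    gene_b = gb$gene_id[match(paste(chrom_b, rb), paste(gb$chrom, gb$rank))],
    ks = rep_len(ks, length(ra)), score = NA_real_,
    ks_usable = rep_len(!is.na(ks) & ks < 2, length(ra)),
    stringsAsFactors = FALSE)
}

# exhaustive chaining oracle: best score over all monotone, gap-feasible
# anchor subsets (chains), both orientations, by explicit enumeration
brute_best_chain_score <- function(ra, rb, w, max_gap, gap_penalty) {
  n <- length(ra)
  best <- -Inf
  for (ori in c(1, -1)) {
    rbo <- ori * rb
    ord <- order(ra, rbo)
    ras <- ra[ord]; rbs <- rbo[ord]; ws <- w[ord]
    rec <- function(last, score) {
      best <<- max(best, score)
      for (j in seq_len(n)) {
        if (ras[j] > ras[last] && rbs[j] > rbs[last] &&
            ras[j] - ras[last] <= max_gap && rbs[j] - rbs[last] <= max_gap) {
          gc <- gap_penalty * (max(ras[j] - ras[last], rbs[j] - rbs[last]) - 1)
          rec(j, score + ws[j] - gc)
        }
      }
    }
    for (i in seq_len(n)) rec(i, ws[i])
  }
  best
}

# exhaustive Fitch oracle: minimum mismatching edges over all 0/1
# assignments to internal nodes and missing-state leaves
brute_fitch_char <- function(tree, states) {
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  fixed <- rep(NA_integer_, nnode)
  fixed[seq_len(ntip)] <- states[tree$tip.label]
  free <- which(is.na(fixed))
  best <- Inf
  for (mask in 0:(2^length(free) - 1)) {
    s <- fixed
    s[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1), 1)
    ch <- sum(s[tree$edge[, 1]] != s[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

brute_fitch_score <- function(tree, m) {
  sum(vapply(seq_len(ncol(m)), function(j) {
    brute_fitch_char(tree, stats::setNames(m[, j], rownames(m)))
  }, numeric(1)))
}

# random chaining instance in a small rank box
random_instance <- function(n, box = 30) {
  ra <- sample.int(box, n)
  rb <- sample.int(box, n)
  keep <- !duplicated(ra) & !duplicated(rb)
  data.frame(ra = ra[keep], rb = rb[keep], w = 1)
}

# build a classified ortholog syntenic_block directly from rank pairs
make_block <- function(ann_a, ann_b, ra, rb, ks = 0.5, id = "B0001",
                       origin = "ORTHOLOG",
                       chrom_a = ann_a$genes$chrom[1],
                       chrom_b = ann_b$genes$chrom[1]) {
  an <- anchors_from_ranks(ann_a, ann_b, ra, rb, ks, chrom_a, chrom_b)
  an$ra <- ra; an$rb <- rb; an$weight <- 1
  ori <- if (length(ra) >= 2 && rb[which.max(ra)] < rb[which.min(ra)]) -1L else 1L
  ackpaint:::new_syntenic_block(id, chrom_a, chrom_b, ori,
                                an[c("gene_a", "gene_b", "ks", "weight",
                                     "ra", "rb")],
                                origin = origin)
}

# 22-block ancestral fixture shared by projection / adjacency tests
small_sim <- function(genes_per_gb = 30, seed = 1, ...) {
  cfg <- sim_config(genes_per_gb = genes_per_gb, seed = seed, ...)
  anc <- simulate_ancestor(cfg)
  list(cfg = cfg, anc = anc)
}
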