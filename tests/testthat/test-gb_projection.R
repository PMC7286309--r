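# brute-force interval-intersection oracle: expected fragment extents are the
# ranges of anchors falling inside each GB interval
brute_fragments <- function(block, gb) {
  out <- list()
  for (i in seq_len(nrow(gb))) {
    if (gb$ref_chrom[i] != block$chrom_b) next
    hit <- block$anchors$rb >= gb$ref_start_rank[i] &
      block$anchors$rb <= gb$ref_end_rank[i]
    if (!any(hit)) next
    out[[gb$label[i]]] <- c(min(block$anchors$ra[hit]),
                            max(block$anchors$ra[hit]))
  }
  out
}

test_that("a block covering one GB projects to a single upright fragment", {
  s <- small_sim()
  ref <- s$anc$ann
  ann_q <- toy_ann(40, "Q")
  # GB H occupies ranks 60..89 of AK3 in the 30-genes-per-GB ancestor
  b <- make_block(ann_q, ref, 0:29, 60:89, chrom_b = "AK3")
  fr <- project_block(b, s$anc$gb)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$gb_label, "H")
  expect_false(fr$inverted)
  expect_equal(c(fr$rank_start, fr$rank_end), c(0, 29))
})

test_that("the size floor spares only labels in the allow-small set", {
  s <- small_sim()
  ref <- s$anc$ann
  ann_q <- toy_ann(40, "Q")
  # six anchors inside GB G (ranks 30..59 of AK3)
  b <- make_block(ann_q, ref, 0:5, 35:40, chrom_b = "AK3")
  with_g <- suppressMessages(project_block(b, s$anc$gb, min_subblock = 20,
                                           allow_small = "G"))
  expect_equal(with_g$gb_label, "G")
  expect_equal(with_g$n_genes, 6)
  without <- suppressMessages(project_block(b, s$anc$gb, min_subblock = 20,
                                            allow_small = character()))
  expect_equal(nrow(without), 0)
})

test_that("a reversed block split at a GB boundary yields two inverted fragments", {
  s <- small_sim()
  ref <- s$anc$ann
  ann_q <- toy_ann(80, "Q")
  # antisense block spanning the F|G boundary on AK3 (F = 0..29, G = 30..59)
  rb <- 49:10
  b <- make_block(ann_q, ref, 0:39, rb, chrom_b = "AK3")
  fr <- suppressMessages(project_block(b, s$anc$gb, min_subblock = 5,
                                       allow_small = character()))
  expect_setequal(fr$gb_label, c("F", "G"))
  expect_true(all(fr$inverted))
  oracle <- brute_fragments(b, s$anc$gb)
  for (lb in names(oracle)) {
    expect_equal(c(fr$rank_start[fr$gb_label == lb],
                   fr$rank_end[fr$gb_label == lb]), oracle[[lb]])
  }
})

test_that("an unrearranged genome paints back to the exact ancestral map", {
  cfg <- sim_config(genes_per_gb = 30, wgd_enabled = FALSE, loss_prob = 0,
                    seed = 3)
  sim <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  anc <- anchor_table(sim$anchors[["Aeth|REF"]])
  blocks <- classify_blocks(
    merge_blocks(chain_anchors(anc, sim$annotations$Aeth,
                               sim$annotations$REF)),
    ks_modes(cut = 1.0))
  map <- build_gb_map(blocks, sim$ancestor$gb, sim$annotations$Aeth)
  sb <- map$subblocks
  expect_equal(nrow(sb), 22)
  expect_setequal(sb$gb_label, sim$ancestor$gb$label)
  expect_true(all(sb$index == 1L))
  expect_false(any(sb$inverted))
})

test_that("fragments of one GB are numbered 1..k along the ancestral chromosome", {
  s <- small_sim(genes_per_gb = 80)
  ref <- s$anc$ann
  ann_q <- toy_ann(20, "Q", chrom = paste0("q", 1:8))
  # eight 10-anchor pieces of GB A (AK1 ranks 0..79) scattered over
  # chromosomes in an order unrelated to their ancestral order
  piece_of <- c(5, 2, 8, 1, 7, 3, 6, 4)  # ancestral piece carried by q_i
  blocks <- lapply(1:8, function(i) {
    rb0 <- (piece_of[i] - 1) * 10
    make_block(ann_q, ref, 0:9, rb0 + 0:9, id = sprintf("B%04d", i),
               chrom_a = paste0("q", i), chrom_b = "AK1")
  })
  map <- build_gb_map(blocks, s$anc$gb, ann_q, min_subblock = 5)
  sb <- map$subblocks
  expect_equal(nrow(sb), 8)
  expect_true(all(sb$gb_label == "A"))
  # index follows ancestral start order, whatever chromosome the piece is on
  expect_equal(sb$index[match(paste0("q", 1:8), sb$chrom)], piece_of)
})

test_that("a planted inversion inside one GB becomes an inverted sub-block", {
  cfg <- sim_config(genes_per_gb = 100, wgd_enabled = FALSE, loss_prob = 0,
                    events = list(list(branch = "Aeth", type = "inversion",
                                       chrom = "AK2", start = 31, end = 70)),
                    seed = 9)
  sim <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  anc <- anchor_table(sim$anchors[["Aeth|REF"]])
  blocks <- classify_blocks(
    merge_blocks(chain_anchors(anc, sim$annotations$Aeth,
                               sim$annotations$REF)),
    ks_modes(cut = 1.0))
  map <- suppressMessages(
    build_gb_map(blocks, sim$ancestor$gb, sim$annotations$Aeth))
  sb <- map$subblocks
  inv <- sb[sb$inverted, , drop = FALSE]
  expect_equal(nrow(inv), 1)
  expect_equal(inv$gb_label, "D")        # AK2 ranks 30..69 lie inside GB D
  expect_equal(c(inv$rank_start, inv$rank_end), c(30, 69))
  # inversion flag agrees with the sign of the query/reference rank
  # correlation of the fragment's anchors (independent oracle)
  qg <- sim$annotations$Aeth$genes
  rg <- sim$annotations$REF$genes
  ra <- qg$rank[match(anc$gene_a, qg$gene_id)]
  rb <- rg$rank[match(anc$gene_b, rg$gene_id)]
  for (i in seq_len(nrow(sb))) {
    if (sb$chrom[i] != "AK2") next
    in_frag <- qg$chrom[match(anc$gene_a, qg$gene_id)] == sb$chrom[i] &
      ra >= sb$rank_start[i] & ra <= sb$rank_end[i]
    rho <- stats::cor(ra[in_frag], rb[in_frag], method = "spearman")
    expect_equal(sb$inverted[i], rho < 0)
  }
  # and matches the simulator's ground truth at full resolution
  tm <- true_gb_map(sim, "Aeth")
  expect_equal(sum(tm$subblocks$inverted), 1)
  expect_equal(tm$subblocks$rank_start[tm$subblocks$inverted], 30)
})

test_that("every chained anchor of a retained block is painted or accounted for", {
  cfg <- sim_config(genes_per_gb = 50, wgd_enabled = FALSE, loss_prob = 0,
                    event_counts = list(Aeth = c(inversion = 4,
                                                 translocation = 2)),
                    seed = 21)
  sim <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  anc <- anchor_table(sim$anchors[["Aeth|REF"]])
  blocks <- classify_blocks(
    merge_blocks(chain_anchors(anc, sim$annotations$Aeth,
                               sim$annotations$REF)),
    ks_modes(cut = 1.0))
  keep <- Filter(function(b) b$origin == "ORTHOLOG" && !b$discarded, blocks)
  frags <- do.call(rbind, lapply(keep, function(b)
    suppressMessages(project_block(b, sim$ancestor$gb, min_subblock = 1))))
  # with no size floor, fragments of each block partition its anchors
  expect_equal(sum(frags$n_genes),
               sum(vapply(keep, `[[`, integer(1), "n_pairs")))
})

test_that("the reference map is the identity painting of the GB table", {
  s <- small_sim()
  m <- gb_reference_map(s$anc$gb)
  expect_equal(nrow(m$subblocks), 22)
  expect_true(all(m$subblocks$index == 1L))
  expect_false(any(m$subblocks$inverted))
  expect_equal(sort(unique(m$subblocks$chrom)), paste0("AK", 1:8))
})
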