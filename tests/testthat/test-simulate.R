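test_that("the ancestor lays out the configured karyotype exactly", {
  cfg <- sim_config(genes_per_gb = 100, seed = 1)
  anc <- simulate_ancestor(cfg)
  expect_equal(nrow(anc$gb), 22)
  expect_equal(nrow(anc$ann$genes), 2200)
  expect_equal(nrow(anc$ann$chromosomes), 8)

  # GB intervals partition every chromosome with no gaps (interval sweep)
  for (ch in unique(anc$gb$ref_chrom)) {
    g <- anc$gb[anc$gb$ref_chrom == ch, ]
    g <- g[order(g$ref_start_rank), ]
    expect_equal(g$ref_start_rank[1], 0)
    if (nrow(g) > 1) {
      expect_equal(g$ref_start_rank[-1], g$ref_end_rank[-nrow(g)] + 1)
    }
    n_chr <- sum(anc$ann$genes$chrom == ch)
    expect_equal(g$ref_end_rank[nrow(g)], n_chr - 1)
  }

  expect_identical(simulate_ancestor(cfg)$ann$genes, anc$ann$genes)
})

test_that("identity evolution returns the ancestor at every leaf", {
  cfg <- sim_config(genes_per_gb = 20, wgd_enabled = FALSE, loss_prob = 0,
                    seed = 2)
  sim <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  for (tx in cfg$tree$tip.label) {
    g <- sim$annotations[[tx]]$genes
    expect_equal(nrow(g), nrow(sim$annotations$REF$genes))
    expect_equal(g$rank, sim$annotations$REF$genes$rank)
  }
  expect_equal(nrow(sim$truth$events), 0)
  for (a in sim$anchors) expect_true(all(a$true_origin == "ORTHOLOG"))
})

test_that("a WGD with full retention doubles every gene with separated Ks modes", {
  cfg <- sim_config(genes_per_gb = 25, wgd_enabled = TRUE, loss_prob = 0,
                    wgd_ks_excess = 0.6, seed = 4)
  sim <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  n_anc <- nrow(sim$annotations$REF$genes)
  expect_equal(nrow(sim$annotations$Aeth$genes), 2 * n_anc)

  a <- sim$anchors[["Aeth|Arab"]]
  expect_setequal(unique(a$true_origin), c("ORTHOLOG", "WGD_PARALOG"))
  # each ancestral gene yields 2 ortholog and 2 paralog pairs
  expect_equal(sum(a$true_origin == "ORTHOLOG"), 2 * n_anc)
  expect_equal(sum(a$true_origin == "WGD_PARALOG"), 2 * n_anc)
  # paralog Ks rides the configured excess above the ortholog mode
  med_o <- median(a$ks[a$true_origin == "ORTHOLOG"])
  med_p <- median(a$ks[a$true_origin == "WGD_PARALOG"])
  expect_gt(med_p - med_o, 0.4)
})

test_that("event bookkeeping matches the true sub-block map", {
  cfg <- sim_config(genes_per_gb = 100, wgd_enabled = FALSE, loss_prob = 0,
                    event_counts = list(Arab = c(inversion = 10)), seed = 8)
  sim <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  ev <- sim$truth$events
  expect_equal(nrow(ev), 10)
  expect_true(all(ev$type == "inversion"))
  expect_true(all(ev$branch == "Arab"))
  # untouched taxa keep the ancestral 22-fragment map
  tm0 <- true_gb_map(sim, "Aeth")
  expect_equal(nrow(tm0$subblocks), 22)
  expect_false(any(tm0$subblocks$inverted))
  # the rearranged taxon has strictly more fragments, with inversions
  tm <- true_gb_map(sim, "Arab")
  expect_gt(nrow(tm$subblocks), 22)
  expect_gt(sum(tm$subblocks$inverted), 0)
})

test_that("a single planted inversion splits exactly one GB into three runs", {
  cfg <- sim_config(genes_per_gb = 60, wgd_enabled = FALSE, loss_prob = 0,
                    events = list(list(branch = "linI", type = "inversion",
                                       chrom = "AK4", start = 11, end = 40)),
                    seed = 10)
  sim <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  tm <- true_gb_map(sim, "linI")
  expect_equal(nrow(tm$subblocks), 24)   # 22 + 2 extra pieces of GB I
  ii <- tm$subblocks[tm$subblocks$gb_label == "I", ]
  expect_equal(nrow(ii), 3)
  expect_equal(ii$index, 1:3)
  expect_equal(ii$inverted, c(FALSE, TRUE, FALSE))
  expect_equal(ii$rank_start, c(0, 10, 40))
})

test_that("opposite fractionation bias leaves paralog pairs denser than orthologs", {
  cfg <- sim_config(genes_per_gb = 60, wgd_enabled = TRUE, loss_prob = 0.7,
                    copy_bias = 0.8, seed = 12)
  sim <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  # Aeth retains subgenome 1, Arab subgenome 2 (alternating dominance)
  expect_equal(unname(sim$truth$dominant_subgenome[c("Aeth", "Arab")]),
               c(1L, 2L))
  a <- sim$anchors[["Aeth|Arab"]]
  expect_gt(sum(a$true_origin == "WGD_PARALOG"),
            sum(a$true_origin == "ORTHOLOG"))
})

test_that("fissions and fusions reshape the karyotype and stay recoverable", {
  cfg <- sim_config(genes_per_gb = 50, wgd_enabled = FALSE, loss_prob = 0,
                    event_counts = list(linII = c(fission = 2, fusion = 1)),
                    seed = 14)
  sim <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  expect_equal(nrow(sim$annotations$linII$chromosomes), 9)  # 8 + 2 - 1
  # gene content is conserved
  expect_equal(nrow(sim$annotations$linII$genes),
               nrow(sim$annotations$REF$genes))
})

test_that("emitted datasets reload identically and are seed-deterministic", {
  cfg <- sim_config(tree = "(A:1,(B:0.5,C:0.5):0.5);", genes_per_gb = 20,
                    wgd_enabled = FALSE, loss_prob = 0,
                    event_counts = list(B = c(inversion = 2)), seed = 16)
  sim <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  d1 <- file.path(tempfile(), "run1")
  emit_dataset(sim, d1)
  expect_length(list.files(d1, pattern = "\\.gff3$"), 4)   # REF + 3 taxa
  expect_length(list.files(d1, pattern = "^anchors_"), 6)  # 3 vs REF + 3 pairs

  # round trip through the package readers
  ann_b <- read_annotation(file.path(d1, "B.gff3"), min_chrom_len = 0,
                           genome_id = "B")
  expect_equal(ann_b$genes$gene_id, sim$annotations$B$genes$gene_id)
  expect_equal(ann_b$genes$rank, sim$annotations$B$genes$rank)
  ref <- read_annotation(file.path(d1, "REF.gff3"), min_chrom_len = 0,
                         genome_id = "REF")
  gb <- read_gb_table(file.path(d1, "gb_table.tsv"), ref)
  expect_equal(gb$ref_start_rank, sim$ancestor$gb$ref_start_rank)
  tm <- read_gb_map(file.path(d1, "truth", "B_true_map.tsv"))
  expect_equal(tm$subblocks, true_gb_map(sim, "B")$subblocks)

  # byte-identical re-emission under the same seed
  sim2 <- evolve_along_tree(simulate_ancestor(cfg), cfg)
  d2 <- file.path(tempfile(), "run2")
  emit_dataset(sim2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)), label = f)
  }
})
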