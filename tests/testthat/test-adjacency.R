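# hand-built painted map: sub-blocks in listed order on one chromosome
map_from_spec <- function(genome_id, chrom, labels, indices, inverted,
                          size = 30, gap = 0) {
  n <- length(labels)
  start <- (seq_len(n) - 1) * (size + gap)
  sb <- data.frame(chrom = rep_len(chrom, n), rank_start = start,
                   rank_end = start + size - 1,
                   bp_start = NA_real_, bp_end = NA_real_,
                   gb_label = labels, index = as.integer(indices),
                   inverted = inverted, n_genes = size,
                   ref_start_rank = (as.integer(indices) - 1L) * size,
                   ref_end_rank = as.integer(indices) * size - 1L,
                   stringsAsFactors = FALSE)
  ackpaint:::new_gb_map(genome_id, sb)
}

test_that("consecutive sub-blocks yield adjacencies joining facing extremities", {
  m <- map_from_spec("t1", "LG5", c("J", "V", "O"), c(1, 2, 1),
                     c(FALSE, FALSE, FALSE))
  adj <- extract_adjacencies(m)
  expect_setequal(adj$key, c("J:tail--V:head", "O:head--V:tail"))

  # strict mode keeps fragment indices
  adj_s <- extract_adjacencies(m, mode = "strict")
  expect_setequal(adj_s$key, c("J1:tail--V2:head", "O1:head--V2:tail"))

  # inversion of the middle block swaps its facing extremities
  mi <- map_from_spec("t1", "LG5", c("J", "V", "O"), c(1, 2, 1),
                      c(FALSE, TRUE, FALSE))
  expect_setequal(extract_adjacencies(mi)$key,
                  c("J:tail--V:tail", "O:head--V:head"))

  # single sub-block: nothing to join
  expect_equal(nrow(extract_adjacencies(
    map_from_spec("t1", "LG1", "A", 1, FALSE))), 0)

  # a large unassigned gap suppresses the adjacency
  mg <- map_from_spec("t1", "LG5", c("J", "V"), c(1, 1), c(FALSE, FALSE),
                      gap = 60)
  expect_equal(nrow(extract_adjacencies(mg, max_gap_genes = 50)), 0)
  expect_equal(nrow(extract_adjacencies(mg, max_gap_genes = 60)), 1)
})

test_that("the identity-painted reference reproduces the ancestral adjacencies", {
  s <- small_sim()
  adj <- extract_adjacencies(gb_reference_map(s$anc$gb))
  # one adjacency per within-chromosome consecutive GB pair: 22 - 8
  expect_equal(nrow(adj), 14)
  expect_true("A:tail--B:head" %in% adj$key)
  expect_true("G:tail--H:head" %in% adj$key)
})

test_that("shared derived adjacencies equal brute-force set algebra", {
  ref <- map_from_spec("ACK", "AK1", c("A", "B", "C"), c(1, 1, 1), rep(FALSE, 3))
  ref_adj <- extract_adjacencies(ref)

  m1 <- map_from_spec("tx1", "c1", c("U", "B", "A"), c(3, 5, 1),
                      c(FALSE, FALSE, FALSE))
  m2 <- map_from_spec("tx2", "c1", c("U", "B", "C"), c(3, 5, 1),
                      c(FALSE, FALSE, FALSE))
  m3 <- map_from_spec("tx3", "c1", c("A", "B", "C"), c(1, 1, 1),
                      c(FALSE, FALSE, FALSE))
  out <- shared_derived_adjacencies(list(m1, m2, m3), ref_adj)

  # brute force: union of per-map sets minus the reference, shared = in >= 2
  sets <- lapply(list(m1, m2, m3), function(m) extract_adjacencies(m)$key)
  derived <- setdiff(Reduce(union, sets), ref_adj$key)
  shared <- derived[vapply(derived, function(k)
    sum(vapply(sets, function(s) k %in% s, logical(1))) >= 2, logical(1))]
  expect_setequal(out$key, derived)
  expect_setequal(out$key[out$shared], shared)
  expect_true("B:head--U:tail" %in% out$key[out$shared])

  # taxon-specific adjacencies stay in the table but are not shared
  only1 <- out[out$key == "A:head--B:tail", ]
  expect_false(only1$shared)
  expect_true(only1$tx1)
  expect_false(only1$tx2)

  # symmetric in map order
  out_perm <- shared_derived_adjacencies(list(m3, m1, m2), ref_adj)
  expect_equal(out_perm$key, out$key)
  expect_equal(out_perm$shared, out$shared)
})

test_that("Fitch scores match exhaustive small-parsimony enumeration", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  taxa <- c("Aeth", "Arab", "linIII", "linI", "linII")
  trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = taxa)
  expect_length(trees, 15)
  for (rep in 1:8) {
    m <- matrix(sample(0:1, 5 * 6, replace = TRUE), nrow = 5,
                dimnames = list(taxa, paste0("ch", 1:6)))
    if (rep > 6) m[sample(length(m), 3)] <- NA  # missing entries are free
    for (k in sample(15, 4)) {
      tr <- trees[[k]]   # [[ expands the shared tip labels of a multiPhylo
      expect_equal(fitch_score(tr, m), brute_fitch_score(tr, m))
    }
    # independent library cross-check on complete matrices
    if (!anyNA(m)) {
      pd <- phangorn::phyDat(m, type = "USER", levels = c(0, 1))
      tr <- trees[[sample(15, 1)]]
      expect_equal(fitch_score(tr, m),
                   as.integer(phangorn::parsimony(tr, pd)))
    }
  }
})

test_that("Fitch scoring is invariant under re-rooting and checks taxa", {
  set.seed(33)
  taxa <- paste0("t", 1:6)
  tr <- ape::rtree(6, tip.label = taxa, rooted = FALSE)
  m <- matrix(sample(0:1, 6 * 5, replace = TRUE), nrow = 6,
              dimnames = list(taxa, paste0("c", 1:5)))
  base <- fitch_score(tr, m)
  for (og in taxa[-1]) {
    expect_equal(fitch_score(ape::root(tr, outgroup = og,
                                       resolve.root = TRUE), m), base)
  }
  expect_equal(fitch_score(tr, m[, 0, drop = FALSE]), 0L)
  expect_equal(fitch_score(tr, matrix(0L, 6, 3,
                                      dimnames = list(taxa, paste0("z", 1:3)))),
               0L)
  expect_error(fitch_score(ape::rtree(4, tip.label = taxa[1:4]), m),
               "taxon sets differ")
})

test_that("topology ranking is ascending with stable, reported ties", {
  taxa <- c("Aeth", "Arab", "linIII", "linI", "linII")
  # characters present exactly in {Aeth, Arab}
  m <- matrix(0L, 5, 3, dimnames = list(taxa, paste0("adj", 1:3)))
  m[c("Aeth", "Arab"), ] <- 1L
  t_early <- ape::read.tree(text = "(Aeth,(Arab,(linIII,(linI,linII))));")
  t_nested <- ape::read.tree(text = "(Aeth,(linIII,(linI,(linII,Arab))));")
  r <- rank_topologies(m, list(early = t_early, nested = t_nested))
  expect_equal(r$tree, c("early", "nested"))
  expect_equal(r$score, c(3L, 6L))
  expect_true(all(diff(r$score) >= 0))

  # identical topologies tie and keep input order
  r2 <- rank_topologies(m, list(a = t_early, b = t_early))
  expect_equal(r2$tree, c("a", "b"))
  expect_equal(r2$rank, c(1L, 1L))
})
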