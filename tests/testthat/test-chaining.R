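test_that("a perfect diagonal chains into one forward block", {
  ann_a <- toy_ann(30, "A"); ann_b <- toy_ann(30, "B")
  anc <- anchors_from_ranks(ann_a, ann_b, 0:29, 0:29, ks = 0.5)
  blocks <- chain_anchors(anc, ann_a, ann_b, min_pairs = 20)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$n_pairs, 30)
  expect_equal(blocks[[1]]$orientation, 1L)
  expect_equal(blocks[[1]]$span_a, c(0, 29))

  # antiparallel diagonal gives a reverse block
  anc_rev <- anchors_from_ranks(ann_a, ann_b, 0:29, 29:0, ks = 0.5)
  rev_blocks <- chain_anchors(anc_rev, ann_a, ann_b, min_pairs = 20)
  expect_length(rev_blocks, 1)
  expect_equal(rev_blocks[[1]]$orientation, -1L)
})

test_that("the minimum-pair floor is sharp at 20 collinear anchors", {
  ann_a <- toy_ann(25, "A"); ann_b <- toy_ann(25, "B")
  anc <- anchors_from_ranks(ann_a, ann_b, 0:18, 0:18, ks = 0.5)
  expect_length(chain_anchors(anc, ann_a, ann_b, min_pairs = 20), 0)
  expect_length(chain_anchors(anc, ann_a, ann_b, min_pairs = 19), 1)
})

test_that("DP chain score matches exhaustive enumeration on random instances", {
  set.seed(101)
  for (i in 1:60) {
    inst <- random_instance(sample(3:12, 1))
    max_gap <- sample(c(3, 8, 25), 1)
    ann_a <- toy_ann(31, "A"); ann_b <- toy_ann(31, "B")
    anc <- anchors_from_ranks(ann_a, ann_b, inst$ra - 1, inst$rb - 1, ks = 0.5)
    blocks <- chain_anchors(anc, ann_a, ann_b, max_gap = max_gap,
                            min_pairs = 1, gap_penalty = 0.2)
    blocks <- Filter(function(b) b$n_pairs >= 2, blocks)
    dp_best <- if (length(blocks)) {
      max(vapply(blocks, function(b) {
        ra <- b$anchors$ra
        rbo <- b$orientation * b$anchors$rb
        sum(b$anchors$weight) -
          0.2 * sum(pmax(diff(ra), diff(rbo)) - 1)
      }, numeric(1)))
    } else NA_real_
    oracle <- brute_best_chain_score(inst$ra, inst$rb, inst$w, max_gap, 0.2)
    if (!is.na(dp_best)) {
      # the first extracted chain is the global best
      expect_equal(max(dp_best), oracle, tolerance = 1e-9)
    } else {
      # nothing chained: no multi-anchor chain can beat a singleton
      expect_lte(oracle, max(inst$w))
    }
  }
})

test_that("no anchor is used twice and thresholds act monotonically", {
  set.seed(202)
  ann_a <- toy_ann(80, "A"); ann_b <- toy_ann(80, "B")
  for (rep in 1:20) {
    ra <- sample(0:79, 50); rb <- sample(0:79, 50)
    anc <- anchors_from_ranks(ann_a, ann_b, ra, rb, ks = 0.5)
    b2 <- chain_anchors(anc, ann_a, ann_b, max_gap = 10, min_pairs = 2)
    used <- unlist(lapply(b2, function(b) b$anchors$gene_a))
    expect_false(any(duplicated(used)))
    expect_lte(length(used), nrow(anc))

    # raising min_pairs never increases the block count
    b4 <- chain_anchors(anc, ann_a, ann_b, max_gap = 10, min_pairs = 4)
    expect_lte(length(b4), length(b2))
    # raising max_gap never loses chained anchors
    wide <- chain_anchors(anc, ann_a, ann_b, max_gap = 20, min_pairs = 2)
    expect_gte(sum(vapply(wide, `[[`, integer(1), "n_pairs")),
               sum(vapply(b2, `[[`, integer(1), "n_pairs")))
  }
})

test_that("block merging respects distance, orientation and collinearity", {
  ann_a <- toy_ann(200, "A"); ann_b <- toy_ann(200, "B")
  mkb <- function(ra0, rb0, n = 21, dir = 1) {
    rb <- if (dir > 0) rb0 + 0:(n - 1) else rb0 - 0:(n - 1)
    make_block(ann_a, ann_b, ra0 + 0:(n - 1), rb)
  }
  # separation 40 on both genomes -> merged
  two <- list(mkb(0, 0), mkb(60, 60))   # ends at 20, starts at 60: sep 40
  m <- merge_blocks(two, merge_dist = 50)
  expect_length(m, 1)
  expect_equal(m[[1]]$n_pairs, 42)
  expect_true(ackpaint:::.is_monotone(m[[1]]$anchors$ra, m[[1]]$anchors$rb, 1))

  # separation 51 on genome A -> not merged
  two51 <- list(mkb(0, 0), mkb(71, 60))
  expect_length(merge_blocks(two51, merge_dist = 50), 2)
  # boundary case: separation exactly 50 merges
  two50 <- list(mkb(0, 0), mkb(70, 60))
  expect_length(merge_blocks(two50, merge_dist = 50), 1)

  # orientation mismatch never merges, even overlapping
  mixed <- list(mkb(0, 0), make_block(ann_a, ann_b, 10 + 0:20, 40 - 0:20))
  expect_length(merge_blocks(mixed, merge_dist = 50), 2)
})

test_that("merging reaches an order-independent fixpoint", {
  ann_a <- toy_ann(400, "A"); ann_b <- toy_ann(400, "B")
  set.seed(7)
  blocks <- lapply(1:6, function(i) {
    o <- (i - 1) * 60
    make_block(ann_a, ann_b, o + 0:20, o + 0:20, id = sprintf("B%04d", i))
  })
  ref <- merge_blocks(blocks, merge_dist = 50)
  expect_length(ref, 1)   # chained end to end at 39-gene separations
  expect_identical(blocks_summary(merge_blocks(ref, merge_dist = 50)),
                   blocks_summary(ref))
  for (i in 1:5) {
    perm <- sample(blocks)
    expect_identical(blocks_summary(merge_blocks(perm, merge_dist = 50)),
                     blocks_summary(ref))
  }
})

test_that("manual merging ignores distance but enforces collinearity", {
  ann_a <- toy_ann(400, "A"); ann_b <- toy_ann(400, "B")
  b1 <- make_block(ann_a, ann_b, 0:20, 0:20, id = "B0001")
  b2 <- make_block(ann_a, ann_b, 140:160, 140:160, id = "B0002")
  # 120 ranks apart: automatic merging refuses, manual merging succeeds
  expect_length(merge_blocks(list(b1, b2), merge_dist = 50), 2)
  m <- manual_merge(list(b1, b2), c("B0001", "B0002"))
  expect_equal(m$n_pairs, 42)
  expect_match(m$provenance, "manual")

  expect_identical(manual_merge(list(b1, b2), "B0002"), b2)

  b3 <- make_block(ann_a, ann_b, 140:160, 160:140, id = "B0003")
  expect_error(manual_merge(list(b1, b3), c("B0001", "B0003")), "orientation")
  b4 <- make_block(ann_a, ann_b, 10:30, 150:170, id = "B0004")
  expect_error(manual_merge(list(b1, b4), c("B0001", "B0004")), "collinear")
  expect_error(manual_merge(list(b1), "missing"), "unknown block id")
})
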