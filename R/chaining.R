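#' Chain anchor pairs into collinear syntenic blocks
#'
#' Dynamic-programming collinearity chaining in gene-rank space, DAGchainer
#' style: within each chromosome pair, anchors form a DAG where an edge joins
#' two anchors if both rank coordinates increase (rank_b decreases for
#' antisense chains) by at most `max_gap`. The best-scoring chain (anchor
#' weights minus gap penalties) is extracted, its anchors removed, and the
#' search repeated until no chain of at least two anchors remains; chains
#' with fewer than `min_pairs` anchors are then discarded. Both orientations
#' are searched; every anchor ends up in at most one block.
#'
#' Chain score is `sum(weight) - gap_penalty * sum(g)` with per-step gap
#' `g = max(delta_rank_a, delta_rank_b) - 1`, so perfectly consecutive
#' anchors cost nothing and a maximal 25-rank jump costs 4.8 at the default
#' penalty. Anchor weight is the `score` column when present, else 1.
#'
#' @param anchors anchor table (see [anchor_table()]).
#' @param ann_a,ann_b `genome_annotation`s for the query (a) and reference
#'   (b) genomes.
#' @param max_gap maximum rank distance between consecutive anchors of a
#'   chain, in genes (default 25).
#' @param min_pairs minimum anchors per retained block (default 20).
#' @param gap_penalty score penalty per skipped rank unit (default 0.2).
#' @return list of `syntenic_block` objects.
#' @export
chain_anchors <- function(anchors, ann_a, ann_b, max_gap = 25, min_pairs = 20,
                          gap_penalty = 0.2) {
  stopifnot(max_gap >= 1, min_pairs >= 1)
  if (!nrow(anchors)) return(list())
  ga <- ann_a$genes; gb <- ann_b$genes
  ia <- match(anchors$gene_a, ga$gene_id)
  ib <- match(anchors$gene_b, gb$gene_id)
  ok <- !is.na(ia) & !is.na(ib)
  if (any(!ok)) {
    warning(sum(!ok), " anchor(s) not resolvable against the annotations; dropped")
  }
  a <- data.frame(gene_a = anchors$gene_a[ok], gene_b = anchors$gene_b[ok],
                  ks = anchors$ks[ok],
                  weight = ifelse(is.na(anchors$score[ok]), 1, anchors$score[ok]),
                  chrom_a = ga$chrom[ia[ok]], chrom_b = gb$chrom[ib[ok]],
                  ra = ga$rank[ia[ok]], rb = gb$rank[ib[ok]],
                  stringsAsFactors = FALSE)
  if (!nrow(a)) return(list())
  a <- a[order(a$chrom_a, a$chrom_b, a$ra, a$rb), , drop = FALSE]
  a$grp <- paste(a$chrom_a, a$chrom_b, sep = "\r")
  groups <- split(seq_len(nrow(a)), a$grp)
  groups <- groups[order(names(groups))]

  alive <- rep(TRUE, nrow(a))
  # per-(group, orientation) cached best chain; invalidated on extraction
  cache <- new.env(parent = emptyenv())
  best_in <- function(gname, ori) {
    key <- paste(gname, ori)
    if (!is.null(cache[[key]])) return(cache[[key]])
    idx <- groups[[gname]]
    idx <- idx[alive[idx]]
    res <- .best_chain(a$ra[idx], a$rb[idx], a$weight[idx], ori,
                       max_gap, gap_penalty)
    if (!is.null(res)) res$idx <- idx[res$members]
    cache[[key]] <- if (is.null(res)) list(score = -Inf) else res
    cache[[key]]
  }

  blocks <- list()
  repeat {
    cand <- NULL
    for (gname in names(groups)) {
      for (ori in c(1L, -1L)) {
        b <- best_in(gname, ori)
        if (is.infinite(b$score)) next
        b$ori <- ori; b$grp <- gname
        if (is.null(cand) || .chain_better(b, cand)) cand <- b
      }
    }
    if (is.null(cand) || length(cand$idx) < 2) break
    alive[cand$idx] <- FALSE
    rm(list = ls(cache)[startsWith(ls(cache), paste0(cand$grp, " "))],
       envir = cache)
    ch <- a[cand$idx, , drop = FALSE]
    blocks[[length(blocks) + 1]] <- new_syntenic_block(
      block_id = sprintf("B%04d", length(blocks) + 1),
      chrom_a = ch$chrom_a[1], chrom_b = ch$chrom_b[1],
      orientation = cand$ori, anchors = ch)
  }
  Filter(function(b) b$n_pairs >= min_pairs, blocks)
}

# best chain by DP over one chromosome pair; ra sorted ascending on entry.
# Returns list(score, members (positions into input vectors), start_ra, start_rb)
# or NULL when no anchor.
.best_chain <- function(ra, rb, w, orientation, max_gap, gap_penalty) {
  n <- length(ra)
  if (!n) return(NULL)
  rbo <- if (orientation > 0) rb else -rb
  ord <- order(ra, rbo)
  ra <- ra[ord]; rbo <- rbo[ord]; w <- w[ord]
  dp <- w
  parent <- rep(0L, n)
  lo <- 1L
  for (i in seq_len(n)) {
    while (ra[lo] < ra[i] - max_gap) lo <- lo + 1L
    if (lo < i) {
      j <- lo:(i - 1L)
      feas <- ra[j] < ra[i] & rbo[j] < rbo[i] & (rbo[i] - rbo[j]) <= max_gap
      if (any(feas)) {
        j <- j[feas]
        cand <- dp[j] - gap_penalty * (pmax(ra[i] - ra[j], rbo[i] - rbo[j]) - 1)
        k <- which.max(cand)
        if (cand[k] > 0) {
          dp[i] <- w[i] + cand[k]
          parent[i] <- j[k]
        }
      }
    }
  }
  ends <- which(dp == max(dp))
  chains <- lapply(ends, function(e) {
    m <- integer(0)
    while (e > 0L) { m <- c(e, m); e <- parent[e] }
    m
  })
  starts_ra <- vapply(chains, function(m) ra[m[1]], numeric(1))
  starts_rb <- vapply(chains, function(m) abs(rbo[m[1]]), numeric(1))
  pick <- order(starts_ra, starts_rb)[1]
  list(score = max(dp), members = ord[chains[[pick]]],
       start_ra = starts_ra[pick], start_rb = starts_rb[pick])
}

# deterministic preference between candidate chains across groups
.chain_better <- function(x, y) {
  if (x$score != y$score) return(x$score > y$score)
  if (x$start_ra != y$start_ra) return(x$start_ra < y$start_ra)
  if (x$start_rb != y$start_rb) return(x$start_rb < y$start_rb)
  if (x$grp != y$grp) return(x$grp < y$grp)
  x$ori > y$ori
}

new_syntenic_block <- function(block_id, chrom_a, chrom_b, orientation,
                               anchors, origin = "UNCLASSIFIED",
                               discarded = FALSE, provenance = "chained") {
  anchors <- anchors[order(anchors$ra), , drop = FALSE]
  rownames(anchors) <- NULL
  structure(list(
    block_id = block_id, chrom_a = chrom_a, chrom_b = chrom_b,
    orientation = as.integer(orientation),
    anchors = anchors[c("gene_a", "gene_b", "ks", "weight", "ra", "rb")],
    span_a = range(anchors$ra), span_b = range(anchors$rb),
    n_pairs = nrow(anchors),
    median_ks = .median_ks(anchors$ks), mean_ks = .mean_ks(anchors$ks),
    origin = origin, discarded = discarded, provenance = provenance
  ), class = "syntenic_block")
}

.median_ks <- function(ks, ks_max = 2) {
  u <- ks[!is.na(ks) & ks < ks_max]
  if (!length(u)) NA_real_ else stats::median(u)
}
.mean_ks <- function(ks, ks_max = 2) {
  u <- ks[!is.na(ks) & ks < ks_max]
  if (!length(u)) NA_real_ else mean(u)
}

#' @export
print.syntenic_block <- function(x, ...) {
  cat(sprintf(
    "syntenic_block %s: %s[%d..%d] ~ %s[%d..%d] %s, %d pairs, median Ks %s, %s%s\n",
    x$block_id, x$chrom_a, x$span_a[1], x$span_a[2],
    x$chrom_b, x$span_b[1], x$span_b[2],
    if (x$orientation > 0) "+" else "-", x$n_pairs,
    ifelse(is.na(x$median_ks), "NA", sprintf("%.3f", x$median_ks)),
    x$origin, if (x$discarded) " (discarded)" else ""))
  invisible(x)
}

#' Summarise a list of syntenic blocks as a data.frame
#'
#' @param blocks list of `syntenic_block`s.
#' @return data.frame with one row per block.
#' @export
blocks_summary <- function(blocks) {
  if (!length(blocks)) {
    return(data.frame(block_id = character(), chrom_a = character(),
                      chrom_b = character(), start_a = integer(),
                      end_a = integer(), start_b = integer(),
                      end_b = integer(), orientation = integer(),
                      n_pairs = integer(), median_ks = numeric(),
                      mean_ks = numeric(), origin = character(),
                      discarded = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(blocks, function(b) data.frame(
    block_id = b$block_id, chrom_a = b$chrom_a, chrom_b = b$chrom_b,
    start_a = b$span_a[1], end_a = b$span_a[2],
    start_b = b$span_b[1], end_b = b$span_b[2],
    orientation = b$orientation, n_pairs = b$n_pairs,
    median_ks = b$median_ks, mean_ks = b$mean_ks,
    origin = b$origin, discarded = b$discarded, stringsAsFactors = FALSE)))
}

#' Merge nearby collinear blocks (quota-align style)
#'
#' Two blocks merge iff they lie on the same chromosome pair, share
#' orientation, their rank spans are separated by at most `merge_dist` genes
#' on both genomes, and the pooled anchors are still strictly collinear.
#' Merging repeats to fixpoint; the result is independent of input order.
#'
#' @param blocks list of `syntenic_block`s.
#' @param merge_dist maximum separation in genes (default 50).
#' @return list of `syntenic_block`s after merging.
#' @export
merge_blocks <- function(blocks, merge_dist = 50) {
  if (length(blocks) < 2) return(blocks)
  key <- vapply(blocks, function(b)
    paste(b$chrom_a, b$chrom_b, b$orientation), character(1))
  start_a <- vapply(blocks, function(b) b$span_a[1], numeric(1))
  ids <- vapply(blocks, function(b) b$block_id, character(1))
  blocks <- blocks[order(key, start_a, ids)]
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < length(blocks)) {
      j <- i + 1L
      while (j <= length(blocks)) {
        m <- .try_merge(blocks[[i]], blocks[[j]], merge_dist)
        if (!is.null(m)) {
          blocks[[i]] <- m
          blocks[[j]] <- NULL
          merged_any <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  blocks
}

.try_merge <- function(b1, b2, merge_dist) {
  if (b1$chrom_a != b2$chrom_a || b1$chrom_b != b2$chrom_b ||
      b1$orientation != b2$orientation) return(NULL)
  sep <- function(s1, s2) max(s1[1], s2[1]) - min(s1[2], s2[2])
  if (sep(b1$span_a, b2$span_a) > merge_dist) return(NULL)
  if (sep(b1$span_b, b2$span_b) > merge_dist) return(NULL)
  u <- rbind(b1$anchors, b2$anchors)
  u <- u[order(u$ra), , drop = FALSE]
  if (!.is_monotone(u$ra, u$rb, b1$orientation)) return(NULL)
  new_syntenic_block(block_id = b1$block_id, chrom_a = b1$chrom_a,
                     chrom_b = b1$chrom_b, orientation = b1$orientation,
                     anchors = u,
                     provenance = paste("merged", b1$block_id, b2$block_id))
}

.is_monotone <- function(ra, rb, orientation) {
  if (length(ra) < 2) return(TRUE)
  all(diff(ra) > 0) && all(orientation * diff(rb) > 0)
}

#' Manually merge named blocks regardless of distance
#'
#' Covers the hand-curation step used when fragments of one genomic block
#' are too far apart for automatic merging: the named blocks must share
#' chromosome pair and orientation and their pooled anchors must remain
#' strictly collinear, but no distance limit applies. A provenance note
#' records the merge.
#'
#' @param blocks list of `syntenic_block`s.
#' @param block_ids ids of the blocks to merge (one id returns that block
#'   unchanged).
#' @return a single merged `syntenic_block`.
#' @export
manual_merge <- function(blocks, block_ids) {
  ids <- vapply(blocks, function(b) b$block_id, character(1))
  hit <- match(block_ids, ids)
  if (anyNA(hit)) stop("unknown block id: ",
                       paste(block_ids[is.na(hit)], collapse = ", "))
  sel <- blocks[hit]
  if (length(sel) == 1) return(sel[[1]])
  ori <- unique(vapply(sel, `[[`, integer(1), "orientation"))
  ca <- unique(vapply(sel, `[[`, character(1), "chrom_a"))
  cb <- unique(vapply(sel, `[[`, character(1), "chrom_b"))
  if (length(ori) > 1) stop("manual_merge: blocks have mixed orientations")
  if (length(ca) > 1 || length(cb) > 1) {
    stop("manual_merge: blocks lie on different chromosome pairs")
  }
  u <- do.call(rbind, lapply(sel, `[[`, "anchors"))
  u <- u[order(u$ra), , drop = FALSE]
  if (!.is_monotone(u$ra, u$rb, ori)) {
    stop("manual_merge: pooled anchors are not collinear")
  }
  new_syntenic_block(block_id = sel[[1]]$block_id, chrom_a = ca, chrom_b = cb,
                     orientation = ori, anchors = u,
                     origin = sel[[1]]$origin,
                     provenance = paste("manual merge of",
                                        paste(block_ids, collapse = "+")))
}
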