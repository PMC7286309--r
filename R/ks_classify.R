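#' Median Ks of a syntenic block
#'
#' Median over the block's anchors with a present Ks below `ks_max`; `NA`
#' when no anchor has a usable Ks. Ks values of 2 and above are excluded
#' because Ks is only approximately linear with time below 2.
#'
#' @param block a `syntenic_block`.
#' @param ks_max usability ceiling (default 2).
#' @return numeric median or `NA`.
#' @export
block_median_ks <- function(block, ks_max = 2) {
  stopifnot(block$n_pairs >= 1)
  .median_ks(block$anchors$ks, ks_max)
}

#' Estimate ortholog and WGD Ks modes from anchor Ks values
#'
#' Kernel-density estimation (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth) on usable Ks values below `ks_max`. The two highest local
#' maxima are reported as the ortholog (lower) and WGD-paralog (higher)
#' modes, and the classification cut is placed at the density minimum
#' between them. With a unimodal density the cut is undefined (`NA`) and a
#' manual cut must be supplied downstream. In pairwise species comparisons
#' the ortholog and paralog peaks can sit close together (lineage-specific
#' substitutions shift both), which is why the cut is estimated explicitly
#' rather than assumed.
#'
#' @param anchors anchor table with a `ks` column.
#' @param ks_max ceiling for usable Ks (default 2).
#' @param bw kernel bandwidth passed to [stats::density()] (default
#'   `"nrd0"`, Silverman's rule).
#' @return a `ks_modes` list: `ortholog_mode`, `wgd_mode`, `cut`, `ks_max`,
#'   `bw`, `n_used`. For a unimodal density `wgd_mode` and `cut` are `NA`.
#' @export
estimate_ks_modes <- function(anchors, ks_max = 2, bw = "nrd0") {
  ks <- anchors$ks
  ks <- ks[!is.na(ks) & ks < ks_max & ks > 0]
  if (length(ks) < 100) {
    stop("estimate_ks_modes needs at least 100 usable Ks values; got ",
         length(ks))
  }
  if (stats::sd(ks) < 1e-3) {
    # effectively a point mass: unimodal by construction
    return(structure(list(ortholog_mode = stats::median(ks),
                          wgd_mode = NA_real_, cut = NA_real_,
                          ks_max = ks_max, bw = NA_real_,
                          n_used = length(ks)), class = "ks_modes"))
  }
  d <- stats::density(ks, bw = bw, from = 0, to = ks_max, n = 1024)
  y <- d$y
  peak <- which(diff(sign(diff(y))) == -2) + 1
  # ignore shoulder ripples well below the dominant peak
  peak <- peak[y[peak] >= 0.05 * max(y[peak])]
  if (!length(peak)) peak <- which.max(y)
  if (length(peak) == 1) {
    return(structure(list(ortholog_mode = d$x[peak], wgd_mode = NA_real_,
                          cut = NA_real_, ks_max = ks_max, bw = d$bw,
                          n_used = length(ks)), class = "ks_modes"))
  }
  top2 <- peak[order(y[peak], decreasing = TRUE)[1:2]]
  top2 <- sort(top2)
  between <- seq(top2[1], top2[2])
  cut_i <- between[which.min(y[between])]
  structure(list(ortholog_mode = d$x[top2[1]], wgd_mode = d$x[top2[2]],
                 cut = d$x[cut_i], ks_max = ks_max, bw = d$bw,
                 n_used = length(ks)),
            class = "ks_modes")
}

#' Manually specified Ks modes / classification cut
#'
#' @param cut classification boundary between ortholog and WGD-paralog
#'   median Ks.
#' @param ortholog_mode,wgd_mode optional mode locations for reporting.
#' @param ks_max usability ceiling (default 2).
#' @return a `ks_modes` list.
#' @export
ks_modes <- function(cut, ortholog_mode = NA_real_, wgd_mode = NA_real_,
                     ks_max = 2) {
  stopifnot(is.numeric(cut), cut > 0, cut < ks_max)
  structure(list(ortholog_mode = ortholog_mode, wgd_mode = wgd_mode,
                 cut = cut, ks_max = ks_max, bw = NA_real_, n_used = NA_integer_),
            class = "ks_modes")
}

#' @export
print.ks_modes <- function(x, ...) {
  cat(sprintf("ks_modes: ortholog %.3f | cut %s | WGD %s (ks_max %.2f, n %s)\n",
              x$ortholog_mode,
              ifelse(is.na(x$cut), "undefined", sprintf("%.3f", x$cut)),
              ifelse(is.na(x$wgd_mode), "NA", sprintf("%.3f", x$wgd_mode)),
              x$ks_max, x$n_used))
  invisible(x)
}

#' Classify blocks as orthologous or WGD-derived by median Ks
#'
#' Blocks with median Ks below the cut are orthologs; blocks with median Ks
#' at or above the cut (the boundary goes to the paralog side) are
#' WGD-derived paralogs and are marked discarded for karyotype projection.
#' Blocks without a usable median stay unclassified but are retained.
#'
#' @param blocks list of `syntenic_block`s.
#' @param modes a `ks_modes` with a defined `cut`.
#' @return the blocks with `origin`/`discarded` set.
#' @export
classify_blocks <- function(blocks, modes) {
  stopifnot(inherits(modes, "ks_modes"))
  if (is.na(modes$cut)) {
    stop("classify_blocks: undefined Ks cut; supply ks_modes(cut = ...)")
  }
  lapply(blocks, function(b) {
    m <- block_median_ks(b, modes$ks_max)
    b$median_ks <- m
    if (is.na(m)) {
      b$origin <- "UNCLASSIFIED"
    } else if (m < modes$cut) {
      b$origin <- "ORTHOLOG"
    } else {
      b$origin <- "WGD_PARALOG"
      b$discarded <- TRUE
    }
    b
  })
}

#' Remove redundant blocks covering the same ancestral region
#'
#' Among ortholog-classified blocks sharing at least `overlap_frac` of the
#' smaller block's reference genes (on the same reference chromosome), only
#' the block with the lowest median Ks keeps its ortholog
#' status; the others are re-marked discarded. The survivor set equals the
#' closure of the pairwise lower-Ks rule and is independent of input order.
#'
#' @param blocks list of `syntenic_block`s (reference genome = genome b).
#' @param overlap_frac minimum overlap as a fraction of the shorter span
#'   (default 0.5).
#' @return the blocks, redundant copies marked discarded.
#' @export
deduplicate_blocks <- function(blocks, overlap_frac = 0.5) {
  idx <- which(vapply(blocks, function(b)
    identical(b$origin, "ORTHOLOG") && !b$discarded, logical(1)))
  if (length(idx) < 2) return(blocks)
  med <- vapply(blocks[idx], `[[`, numeric(1), "median_ks")
  ids <- vapply(blocks[idx], `[[`, character(1), "block_id")
  ord <- idx[order(med, ids)]  # best (lowest Ks) first; id breaks exact ties
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (k in kept) {
      if (.ref_overlap(blocks[[i]], blocks[[k]]) >= overlap_frac) {
        clash <- TRUE
        break
      }
    }
    if (clash) {
      blocks[[i]]$discarded <- TRUE
      blocks[[i]]$provenance <- paste(blocks[[i]]$provenance,
                                      "| dedup: higher-Ks duplicate")
    } else kept <- c(kept, i)
  }
  blocks
}

# fraction of the smaller block's reference genes also covered by the other
# block. Shared genes, not span intersection: a within-block inversion chain
# sits inside the flanking chain's span but covers disjoint reference genes
# and must not be treated as a redundant copy.
.ref_overlap <- function(b1, b2) {
  if (b1$chrom_b != b2$chrom_b) return(0)
  length(intersect(b1$anchors$rb, b2$anchors$rb)) /
    min(b1$n_pairs, b2$n_pairs)
}

#' Histogram of anchor Ks values by block origin class
#'
#' Bins usable Ks values of chained anchors, labelled by the origin class of
#' the containing block (unchained anchors are labelled `UNCHAINED`), the
#' table behind a Ks histogram coloured by ortholog/paralog class.
#'
#' @param anchors anchor table.
#' @param blocks list of `syntenic_block`s.
#' @param ks_max ceiling (default 2); `binwidth` bin width (default 0.05).
#' @param binwidth histogram bin width.
#' @return data.frame `bin_lo`, `bin_hi`, `class`, `count`.
#' @export
ks_histogram <- function(anchors, blocks, ks_max = 2, binwidth = 0.05) {
  cls <- rep("UNCHAINED", nrow(anchors))
  key <- paste(anchors$gene_a, anchors$gene_b)
  for (b in blocks) {
    cls[key %in% paste(b$anchors$gene_a, b$anchors$gene_b)] <- b$origin
  }
  use <- !is.na(anchors$ks) & anchors$ks < ks_max
  ks <- anchors$ks[use]; cls <- cls[use]
  br <- seq(0, ks_max, by = binwidth)
  bin <- cut(ks, br, include.lowest = TRUE, right = FALSE)
  tab <- as.data.frame(table(bin = bin, class = cls), stringsAsFactors = FALSE)
  i <- match(tab$bin, levels(bin))
  data.frame(bin_lo = br[i], bin_hi = br[i + 1], class = tab$class,
             count = tab$Freq, stringsAsFactors = FALSE)
}
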