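#' Split an ortholog block at genomic-block boundaries
#'
#' Projects one ortholog syntenic block onto the reference GB definition
#' table: the block is cut at every GB interval boundary its reference span
#' crosses, each piece takes the GB label of its interval, and pieces with
#' fewer than `min_subblock` anchors are dropped unless their label is in
#' `allow_small` (the classic exception is block G, detectable with only six
#' genes). Anchors outside every GB interval form `unassigned` fragments.
#'
#' A fragment is called inverted when its anchors run antisense to the GB's
#' reference direction: the call is the sign of the Spearman correlation
#' between query and reference ranks; fragments with |rho| < 0.5 are flagged
#' ambiguous and reported not inverted.
#'
#' @param block a `syntenic_block` with `origin == "ORTHOLOG"`; the
#'   reference genome is side b.
#' @param gb GB table resolved against the reference annotation (see
#'   [read_gb_table()]).
#' @param min_subblock minimum anchors per retained fragment (default 20).
#' @param allow_small GB labels exempt from the size floor (default `"G"`).
#' @return data.frame of fragments: `block_id`, `gb_label`, `chrom`,
#'   `rank_start`, `rank_end`, `n_genes`, `inverted`, `ambiguous`,
#'   `ref_start_rank`, `ref_end_rank`, plus a list column `anchors` holding
#'   each fragment's (ra, rb) anchor coordinates.
#' @export
project_block <- function(block, gb, min_subblock = 20, allow_small = "G") {
  stopifnot(inherits(block, "syntenic_block"))
  if (!identical(block$origin, "ORTHOLOG") || block$discarded) {
    stop("project_block expects a retained ORTHOLOG block; got ",
         block$origin, if (block$discarded) " (discarded)")
  }
  if (is.null(gb$ref_start_rank)) {
    stop("GB table must be rank-resolved against the reference annotation")
  }
  an <- block$anchors
  lab <- rep("unassigned", nrow(an))
  on_chr <- which(gb$ref_chrom == block$chrom_b)
  for (i in on_chr) {
    hit <- an$rb >= gb$ref_start_rank[i] & an$rb <= gb$ref_end_rank[i]
    lab[hit] <- gb$label[i]
  }
  groups <- split(seq_len(nrow(an)), lab)
  out <- do.call(rbind, lapply(names(groups), function(lb) {
    .fragment_row(block$block_id, block$chrom_a, block$orientation,
                  an[groups[[lb]], c("ra", "rb"), drop = FALSE], lb)
  }))
  keep <- out$n_genes >= min_subblock | out$gb_label %in% allow_small
  if (any(!keep)) {
    message(sum(!keep), " sub-threshold fragment(s) of block ",
            block$block_id, " dropped (",
            paste(out$gb_label[!keep], collapse = ", "), ")")
  }
  out <- out[keep, , drop = FALSE]
  if (any(out$gb_label == "unassigned")) {
    message("block ", block$block_id,
            " has anchors outside every GB interval (unassigned fragment)")
  }
  out <- out[order(out$rank_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.fragment_row <- function(block_id, chrom, ori_fallback, sub, label) {
  rho <- if (nrow(sub) >= 2 && stats::sd(sub$rb) > 0) {
    suppressWarnings(stats::cor(sub$ra, sub$rb, method = "spearman"))
  } else NA_real_
  if (is.na(rho)) rho <- ori_fallback
  df <- data.frame(block_id = block_id, gb_label = label, chrom = chrom,
                   rank_start = min(sub$ra), rank_end = max(sub$ra),
                   n_genes = nrow(sub),
                   inverted = abs(rho) >= 0.5 && rho < 0,
                   ambiguous = abs(rho) < 0.5,
                   ref_start_rank = min(sub$rb), ref_end_rank = max(sub$rb),
                   stringsAsFactors = FALSE)
  df$anchors <- I(list(sub[order(sub$ra), , drop = FALSE]))
  df
}

#' Build a painted karyotype (GB map) from classified blocks
#'
#' Projects all retained ortholog blocks (see [project_block()]), resolves
#' query-side conflicts, numbers the fragments of each GB 1..k by their
#' reference (ACK) start positions — so e.g. `F4` is the fourth piece of GB
#' F counted along the ancestral chromosome — and orders sub-blocks along
#' each query chromosome. Direction of blocks is given relative to the
#' ancestral karyotype via the inversion flag.
#'
#' Two kinds of query-side span overlap are distinguished. When two
#' fragments place anchors in the same query interval (double painting,
#' e.g. an undeduplicated redundant block), the larger fragment wins and the
#' conflict is logged. When one fragment's span merely brackets another
#' without occupying it — the typical signature of a within-block inversion,
#' whose antisense anchors form their own chain inside a gap of the
#' flanking chain — the bracketing fragment is split around the inner one,
#' so the painted chromosome is a tiling of sub-blocks.
#'
#' @param blocks list of classified `syntenic_block`s.
#' @param gb rank-resolved GB table.
#' @param ann_query query `genome_annotation` (for bp spans).
#' @param min_subblock,allow_small passed to [project_block()] and applied
#'   again to split pieces.
#' @return a `gb_map`.
#' @export
build_gb_map <- function(blocks, gb, ann_query, min_subblock = 20,
                         allow_small = "G") {
  use <- Filter(function(b) identical(b$origin, "ORTHOLOG") && !b$discarded,
                blocks)
  frags <- do.call(rbind, lapply(use, project_block, gb = gb,
                                 min_subblock = min_subblock,
                                 allow_small = allow_small))
  if (!is.null(frags) && nrow(frags)) {
    n_un <- sum(frags$gb_label == "unassigned")
    if (n_un) message(n_un, " unassigned fragment(s) excluded from the GB map")
    frags <- frags[frags$gb_label != "unassigned", , drop = FALSE]
  }
  if (is.null(frags) || !nrow(frags)) {
    return(new_gb_map(ann_query$genome_id, data.frame()))
  }
  frags <- .resolve_overlaps(frags, min_subblock, allow_small)

  # ACK-relative numbering: order fragments of a GB by reference start
  frags$index <- NA_integer_
  for (lb in unique(frags$gb_label)) {
    ix <- which(frags$gb_label == lb)
    frags$index[ix[order(frags$ref_start_rank[ix])]] <- seq_along(ix)
  }

  g <- ann_query$genes
  bp_of <- function(chrom, rank, field) {
    i <- match(paste(chrom, rank), paste(g$chrom, g$rank))
    g[[field]][i]
  }
  frags$bp_start <- bp_of(frags$chrom, frags$rank_start, "start")
  frags$bp_end <- bp_of(frags$chrom, frags$rank_end, "end")
  new_gb_map(ann_query$genome_id, frags[c(
    "chrom", "rank_start", "rank_end", "bp_start", "bp_end", "gb_label",
    "index", "inverted", "n_genes", "ref_start_rank", "ref_end_rank")])
}

# query-side conflict resolution over the pooled fragment table
.resolve_overlaps <- function(frags, min_subblock, allow_small) {
  repeat {
    n <- nrow(frags)
    ord <- order(frags$chrom, frags$rank_start, -frags$n_genes)
    frags <- frags[ord, , drop = FALSE]
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      if (i >= nrow(frags)) break
      j <- i + 1
      while (j <= nrow(frags) && frags$chrom[j] == frags$chrom[i] &&
             frags$rank_start[j] <= frags$rank_end[i]) {
        ai <- frags$anchors[[i]]; aj <- frags$anchors[[j]]
        lo <- max(frags$rank_start[i], frags$rank_start[j])
        hi <- min(frags$rank_end[i], frags$rank_end[j])
        # occupancy of the shared interval, as a fraction of each fragment's
        # anchors: both high = double painting; one-sided = a chain that
        # tunnelled through or brackets the other fragment
        frac_i <- sum(ai$ra >= lo & ai$ra <= hi) / nrow(ai)
        frac_j <- sum(aj$ra >= lo & aj$ra <= hi) / nrow(aj)
        if (min(frac_i, frac_j) > 0.25) {
          # double painting: larger fragment wins
          drop <- if (frags$n_genes[i] >= frags$n_genes[j]) j else i
          message("overlapping fragments on ", frags$chrom[i], ": dropping ",
                  frags$gb_label[drop], " (", frags$n_genes[drop],
                  " genes) in favour of the larger fragment")
          frags <- frags[-drop, , drop = FALSE]
          changed <- TRUE
          if (drop == i) break
        } else {
          # split the sparse (bracketing) fragment around the dense one;
          # its stray anchors inside the shared interval are dropped
          outer <- if (frac_i <= frac_j) i else j
          inner <- if (frac_i <= frac_j) j else i
          ao <- frags$anchors[[outer]]
          left <- ao[ao$ra < frags$rank_start[inner], , drop = FALSE]
          right <- ao[ao$ra > frags$rank_end[inner], , drop = FALSE]
          pieces <- Filter(function(p) nrow(p) > 0, list(left, right))
          pieces <- lapply(pieces, function(p) {
            .fragment_row(frags$block_id[outer], frags$chrom[outer],
                          if (frags$inverted[outer]) -1 else 1, p,
                          frags$gb_label[outer])
          })
          keep_piece <- vapply(pieces, function(p)
            p$n_genes >= min_subblock || p$gb_label %in% allow_small,
            logical(1))
          frags <- rbind(frags[-outer, , drop = FALSE],
                         do.call(rbind, pieces[keep_piece]))
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  rownames(frags) <- NULL
  frags
}

#' The reference karyotype painted with its own GB table
#'
#' Builds the identity `gb_map` of the ancestral karyotype: one sub-block
#' per GB, index 1, none inverted, on the ancestral (AK) chromosomes in
#' table order. Its adjacency set (see [extract_adjacencies()]) is the
#' ancestral adjacency reference against which derived associations are
#' called.
#'
#' @param gb GB table (rank-resolved tables use their reference ranks;
#'   otherwise synthetic contiguous spans are assigned in table order).
#' @return a `gb_map` with `genome_id = "ACK"`.
#' @export
gb_reference_map <- function(gb) {
  resolved <- !is.null(gb$ref_start_rank)
  sb <- data.frame(chrom = gb$ak_chrom, gb_label = gb$label,
                   index = 1L, inverted = FALSE, stringsAsFactors = FALSE)
  if (resolved) {
    sb$rank_start <- gb$ref_start_rank
    sb$rank_end <- gb$ref_end_rank
  } else {
    # synthetic contiguous spans in table order within each AK chromosome
    sb$rank_start <- NA_integer_; sb$rank_end <- NA_integer_
    for (ch in unique(sb$chrom)) {
      ix <- which(sb$chrom == ch)
      sb$rank_start[ix] <- (seq_along(ix) - 1L) * 2L
      sb$rank_end[ix] <- (seq_along(ix) - 1L) * 2L + 1L
    }
  }
  sb$n_genes <- sb$rank_end - sb$rank_start + 1L
  sb$bp_start <- NA_real_; sb$bp_end <- NA_real_
  sb$ref_start_rank <- sb$rank_start; sb$ref_end_rank <- sb$rank_end
  new_gb_map("ACK", sb)
}

#' Per-GB fragment count summary of a painted karyotype
#'
#' @param map a `gb_map`.
#' @return data.frame `gb_label`, `n_fragments`, `n_inverted`, `n_genes`.
#' @export
gb_fragment_summary <- function(map) {
  sb <- map$subblocks
  if (!nrow(sb)) {
    return(data.frame(gb_label = character(), n_fragments = integer(),
                      n_inverted = integer(), n_genes = integer()))
  }
  out <- do.call(rbind, lapply(split(sb, sb$gb_label), function(s) data.frame(
    gb_label = s$gb_label[1], n_fragments = nrow(s),
    n_inverted = sum(s$inverted), n_genes = sum(s$n_genes),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$gb_label), , drop = FALSE]
}
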