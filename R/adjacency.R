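#' Extract block-adjacency characters from a painted karyotype
#'
#' For every pair of consecutive sub-blocks on a chromosome separated by at
#' most `max_gap_genes` unassigned genes, emits one adjacency joining the
#' facing block extremities. A non-inverted sub-block exposes its GB `tail`
#' (ancestral end) on its right side and its `head` on its left; inversion
#' swaps them. Endpoint tokens are normalised lexicographically so each
#' adjacency has a unique representation.
#'
#' In `lenient` mode fragment indices are ignored (`J:tail--V:head`);
#' `strict` mode keeps the fragment index (`J1:tail--V2:head`), so
#' associations built from different pieces of the same GBs are
#' distinguished — associations with the same labels but different internal
#' block borders can have independent origins.
#'
#' @param map a `gb_map`.
#' @param max_gap_genes maximum number of intervening unassigned genes
#'   (default 50, the merge distance).
#' @param mode `"lenient"` (GB-extremity resolution, default) or `"strict"`
#'   (fragment-index resolution).
#' @return data.frame with one row per distinct adjacency: `key`, `e1`,
#'   `e2`, `chrom`, `gap`, `ref_bk1`, `ref_bk2` (reference ranks of the two
#'   facing breakpoints).
#' @export
extract_adjacencies <- function(map, max_gap_genes = 50,
                                mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  sb <- map$subblocks
  empty <- data.frame(key = character(), e1 = character(), e2 = character(),
                      chrom = character(), gap = integer(),
                      ref_bk1 = numeric(), ref_bk2 = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(sb) < 2) return(empty)
  rows <- list()
  for (ch in unique(sb$chrom)) {
    s <- sb[sb$chrom == ch, , drop = FALSE]
    s <- s[order(s$rank_start), , drop = FALSE]
    if (nrow(s) < 2) next
    for (i in seq_len(nrow(s) - 1)) {
      gap <- s$rank_start[i + 1] - s$rank_end[i] - 1L
      if (gap > max_gap_genes) next
      lab <- function(k) if (mode == "strict")
        paste0(s$gb_label[k], s$index[k]) else s$gb_label[k]
      e_left <- paste0(lab(i), ":", if (s$inverted[i]) "head" else "tail")
      e_right <- paste0(lab(i + 1), ":", if (s$inverted[i + 1]) "tail" else "head")
      bk_left <- if (s$inverted[i]) s$ref_start_rank[i] else s$ref_end_rank[i]
      bk_right <- if (s$inverted[i + 1]) s$ref_end_rank[i + 1] else
        s$ref_start_rank[i + 1]
      if (e_left <= e_right) {
        e1 <- e_left; e2 <- e_right; b1 <- bk_left; b2 <- bk_right
      } else {
        e1 <- e_right; e2 <- e_left; b1 <- bk_right; b2 <- bk_left
      }
      rows[[length(rows) + 1]] <- data.frame(
        key = paste(e1, e2, sep = "--"), e1 = e1, e2 = e2, chrom = ch,
        gap = gap, ref_bk1 = b1, ref_bk2 = b2, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adjacencies shared across genomes but absent from the ancestral karyotype
#'
#' Extracts adjacency sets from each painted karyotype, removes every
#' adjacency present in the reference (ancestral) set, and tabulates
#' per-taxon presence. Adjacencies observed in at least two taxa are flagged
#' `shared` — the shared derived associations usable as phylogenetic
#' characters. The output is symmetric in the order of the input maps.
#'
#' @param maps list of `gb_map`s (names default to their `genome_id`s).
#' @param reference_adjacencies adjacency data.frame from
#'   [extract_adjacencies()] (e.g. of [gb_reference_map()]) or a character
#'   vector of keys.
#' @param max_gap_genes,mode passed to [extract_adjacencies()].
#' @return data.frame: `key`, `e1`, `e2`, one logical column per taxon,
#'   `n_taxa`, `shared`.
#' @export
shared_derived_adjacencies <- function(maps, reference_adjacencies,
                                       max_gap_genes = 50,
                                       mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  stopifnot(length(maps) >= 2)
  taxa <- names(maps)
  if (is.null(taxa)) {
    taxa <- vapply(maps, `[[`, character(1), "genome_id")
    names(maps) <- taxa
  }
  ref_keys <- if (is.data.frame(reference_adjacencies))
    reference_adjacencies$key else as.character(reference_adjacencies)
  sets <- lapply(maps, extract_adjacencies, max_gap_genes = max_gap_genes,
                 mode = mode)
  all_keys <- sort(unique(unlist(lapply(sets, `[[`, "key"))))
  derived <- setdiff(all_keys, ref_keys)
  pres <- vapply(sets, function(s) derived %in% s$key,
                 logical(length(derived)))
  pres <- matrix(pres, nrow = length(derived),
                 dimnames = list(derived, taxa))
  parts <- strsplit(derived, "--", fixed = TRUE)
  out <- data.frame(key = derived,
                    e1 = vapply(parts, `[`, character(1), 1),
                    e2 = vapply(parts, `[`, character(1), 2),
                    stringsAsFactors = FALSE)
  for (tx in taxa) out[[tx]] <- pres[, tx]
  out$n_taxa <- rowSums(pres)
  out$shared <- out$n_taxa >= 2
  rownames(out) <- NULL
  out[order(out$key), , drop = FALSE]
}

#' Binary character matrix from shared derived adjacencies
#'
#' @param shared output of [shared_derived_adjacencies()].
#' @param shared_only keep only characters present in >= 2 taxa (default
#'   `TRUE`).
#' @return integer matrix, taxa in rows, adjacency characters in columns;
#'   no all-zero columns. Cells may be set to `NA` afterwards to mark an
#'   adjacency unobservable in an incompletely assembled genome (Fitch
#'   treats `NA` as free).
#' @export
adjacency_character_matrix <- function(shared, shared_only = TRUE) {
  taxa <- setdiff(names(shared),
                  c("key", "e1", "e2", "n_taxa", "shared"))
  if (shared_only) shared <- shared[shared$shared, , drop = FALSE]
  m <- t(vapply(taxa, function(tx) as.integer(shared[[tx]]),
                integer(nrow(shared))))
  dimnames(m) <- list(taxa, shared$key)
  m <- m[, colSums(m, na.rm = TRUE) > 0, drop = FALSE]
  m
}

#' Fitch small-parsimony score of a binary character matrix on a topology
#'
#' Sum over characters of the minimum number of state changes on the tree
#' (Fitch set-intersection algorithm). `NA` cells are free: the leaf may
#' take either state at no cost. Unrooted trees are rooted at an arbitrary
#' leaf first; the score is invariant under re-rooting.
#'
#' @param topology an `ape::phylo`; must be binary (after rooting).
#' @param matrix taxa-by-characters matrix of 0/1/NA; rownames are taxa and
#'   must match the tree's tip labels as a set.
#' @return integer parsimony score.
#' @export
fitch_score <- function(topology, matrix) {
  stopifnot(inherits(topology, "phylo"))
  taxa <- rownames(matrix)
  extra <- setdiff(topology$tip.label, taxa)
  miss <- setdiff(taxa, topology$tip.label)
  if (length(extra) || length(miss)) {
    stop("taxon sets differ; tree-only: {",
         paste(extra, collapse = ", "), "}, matrix-only: {",
         paste(miss, collapse = ", "), "}")
  }
  tr <- topology
  if (!ape::is.rooted(tr)) {
    tr <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
  }
  if (!ape::is.binary(tr)) {
    stop("fitch_score requires a binary topology")
  }
  tr <- stats::reorder(tr, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  if (!ncol(matrix)) return(0L)

  total <- 0L
  leafset <- matrix(3L, nrow = ntip, ncol = ncol(matrix))
  mm <- matrix[tr$tip.label, , drop = FALSE]
  leafset[!is.na(mm) & mm == 0] <- 1L
  leafset[!is.na(mm) & mm == 1] <- 2L
  for (ch in seq_len(ncol(matrix))) {
    state <- integer(nnode)
    state[seq_len(ntip)] <- leafset[, ch]
    changes <- 0L
    for (i in seq_len(nrow(tr$edge))) {
      # postorder edges: fold child sets into the parent
      par <- tr$edge[i, 1]; child <- tr$edge[i, 2]
      if (state[par] == 0L) {
        state[par] <- state[child]
      } else {
        inter <- bitwAnd(state[par], state[child])
        if (inter == 0L) {
          state[par] <- bitwOr(state[par], state[child])
          changes <- changes + 1L
        } else state[par] <- inter
      }
    }
    total <- total + changes
  }
  total
}

#' Score and rank candidate topologies by Fitch parsimony
#'
#' @param matrix binary character matrix (taxa x characters).
#' @param topologies a `multiPhylo`, list of `phylo`, or path to a newick
#'   file.
#' @return data.frame `tree`, `score`, `rank`, ordered by ascending score
#'   (ties keep input order and share a rank); the sorted trees are attached
#'   as attribute `"trees"`.
#' @export
rank_topologies <- function(matrix, topologies) {
  if (is.character(topologies) && length(topologies) == 1) {
    topologies <- ape::read.tree(topologies)
  }
  if (inherits(topologies, "phylo")) topologies <- list(topologies)
  stopifnot(length(topologies) >= 2)
  labs <- names(topologies)
  if (is.null(labs)) labs <- paste0("tree", seq_along(topologies))
  scores <- vapply(topologies, fitch_score, integer(1), matrix = matrix)
  ord <- order(scores)  # stable: ties keep input order
  out <- data.frame(tree = labs[ord], score = scores[ord],
                    rank = match(scores[ord], sort(unique(scores))),
                    stringsAsFactors = FALSE)
  attr(out, "trees") <- topologies[ord]
  out
}
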