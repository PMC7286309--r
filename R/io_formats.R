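#' Read a genome annotation and rank its genes
#'
#' Parses gene features from a GFF3 or BED6 file into a `genome_annotation`:
#' per-chromosome gene tables with a 0-based rank (order index along the
#' chromosome in start order), the coordinate system used by all chaining and
#' merging distances. Chromosomes shorter than `min_chrom_len` are dropped,
#' mirroring the minimum-chromosome-length filter used to restrict synteny
#' searches to assembled chromosomes (default 5 Mb).
#'
#' Coordinates are stored 0-based half-open. GFF3 (1-based closed) is
#' converted on read; BED is native. Chromosome lengths come from
#' `##sequence-region` pragmas when present, otherwise from the maximal gene
#' end observed.
#'
#' @param path GFF3 or BED file.
#' @param format `"GFF3"` or `"BED"`; guessed from the file extension when
#'   `NULL`.
#' @param min_chrom_len minimum chromosome length in bp; chromosomes below it
#'   are discarded before ranking.
#' @param genome_id label for the genome; defaults to the file stem.
#' @return a `genome_annotation`: list with `genome_id`, `chromosomes`
#'   (data.frame `chrom`, `length`) and `genes` (data.frame `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `rank`).
#' @export
read_annotation <- function(path, format = NULL, min_chrom_len = 5e6,
                            genome_id = NULL) {
  stopifnot(file.exists(path), min_chrom_len >= 0)
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
  }
  format <- match.arg(toupper(format), c("GFF3", "BED"))
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gff3?|bed)$", "", basename(path), ignore.case = TRUE)
  }

  seqlens <- NULL
  if (format == "GFF3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == "gene"]
    ids <- as.character(gr$ID)
    if (anyNA(ids)) stop("GFF3 gene feature without ID attribute in ", path)
    genes <- data.frame(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
    seqlens <- .read_sequence_region_pragmas(path)
  } else {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(bed) < 4) stop("BED file needs at least 4 columns (BED6): ", path)
    genes <- data.frame(
      gene_id = as.character(bed[[4]]),
      chrom = as.character(bed[[1]]),
      start = as.integer(bed[[2]]),
      end = as.integer(bed[[3]]),
      strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "+",
      stringsAsFactors = FALSE
    )
  }
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"

  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  if (any(genes$start >= genes$end)) {
    bad <- genes$gene_id[genes$start >= genes$end][1]
    stop("gene with start >= end: ", bad)
  }

  obs_len <- tapply(genes$end, genes$chrom, max)
  chroms <- data.frame(chrom = names(obs_len),
                       length = as.numeric(obs_len),
                       stringsAsFactors = FALSE)
  if (!is.null(seqlens) && length(seqlens)) {
    hit <- match(chroms$chrom, names(seqlens))
    chroms$length[!is.na(hit)] <- seqlens[hit[!is.na(hit)]]
    extra <- setdiff(names(seqlens), chroms$chrom)
    if (length(extra)) {
      chroms <- rbind(chroms, data.frame(chrom = extra,
                                         length = as.numeric(seqlens[extra])))
    }
  }
  chroms <- chroms[order(chroms$chrom), , drop = FALSE]

  keep <- chroms$chrom[chroms$length >= min_chrom_len]
  if (!length(keep)) {
    stop("no chromosome reaches min_chrom_len = ", min_chrom_len, " bp in ", path)
  }
  chroms <- chroms[chroms$chrom %in% keep, , drop = FALSE]
  genes <- genes[genes$chrom %in% keep, , drop = FALSE]
  genome_annotation(genome_id, chroms, genes)
}

.read_sequence_region_pragmas <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[startsWith(ln, "##sequence-region")]
  if (!length(ln)) return(NULL)
  parts <- strsplit(trimws(ln), "[ \t]+")
  lens <- vapply(parts, function(p) as.numeric(p[4]), numeric(1))
  names(lens) <- vapply(parts, function(p) p[2], character(1))
  lens
}

#' Construct a genome annotation from in-memory tables
#'
#' Ranks genes by start within each chromosome (0-based, a bijection onto
#' `0..n-1` per chromosome) and validates invariants.
#'
#' @param genome_id genome label.
#' @param chromosomes data.frame with `chrom`, `length` (bp).
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open bp).
#' @return a `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, chromosomes, genes) {
  stopifnot(!anyDuplicated(genes$gene_id), all(genes$start < genes$end),
            all(genes$chrom %in% chromosomes$chrom))
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  genes$rank <- stats::ave(genes$start, genes$chrom,
                           FUN = function(x) seq_along(x) - 1L)
  genes$rank <- as.integer(genes$rank)
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id,
                 chromosomes = chromosomes,
                 genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation '%s': %d genes on %d chromosomes\n",
              x$genome_id, nrow(x$genes), nrow(x$chromosomes)))
  invisible(x)
}

#' Read an anchor table of homologous gene pairs
#'
#' Reads a TSV with columns `gene_a`, `gene_b` and optional `ks`, `score`
#' ('.' or empty = missing), the shape of a SynMap/DAGchainer anchor export.
#' Pairs with Ks at or above `ks_max` are retained but flagged unusable for
#' Ks-mode estimation (Ks is only approximately linear with time below 2).
#' When annotations are supplied, pairs are oriented so `gene_a` belongs to
#' `ann_a`, unresolvable rows are skipped with a warning, and exact
#' duplicates are collapsed.
#'
#' @param path TSV file; a header line naming `gene_a` is detected and
#'   honoured, otherwise columns are positional.
#' @param ann_a,ann_b optional `genome_annotation`s used to resolve and
#'   orient the pairs.
#' @param ks_max usability ceiling for Ks (default 2).
#' @return data.frame `gene_a`, `gene_b`, `ks`, `score`, `ks_usable`.
#' @export
read_anchors <- function(path, ann_a = NULL, ann_b = NULL, ks_max = 2) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           na.strings = c("NA", ".", ""), fill = TRUE)
  if (nrow(raw) && identical(tolower(as.character(raw[1, 1])), "gene_a")) {
    raw <- raw[-1, , drop = FALSE]
  }
  anchors <- data.frame(
    gene_a = as.character(raw[[1]]),
    gene_b = as.character(raw[[2]]),
    ks = if (ncol(raw) >= 3) suppressWarnings(as.numeric(raw[[3]])) else NA_real_,
    score = if (ncol(raw) >= 4) suppressWarnings(as.numeric(raw[[4]])) else NA_real_,
    stringsAsFactors = FALSE
  )
  anchor_table(anchors, ann_a = ann_a, ann_b = ann_b, ks_max = ks_max)
}

#' Validate, orient and flag an in-memory anchor table
#'
#' @inheritParams read_anchors
#' @param anchors data.frame with `gene_a`, `gene_b` and optional `ks`,
#'   `score`.
#' @return data.frame with `ks_usable` flag added.
#' @export
anchor_table <- function(anchors, ann_a = NULL, ann_b = NULL, ks_max = 2) {
  anchors <- as.data.frame(anchors, stringsAsFactors = FALSE)
  if (is.null(anchors$ks)) anchors$ks <- NA_real_
  if (is.null(anchors$score)) anchors$score <- NA_real_
  if (any(!is.na(anchors$ks) & anchors$ks < 0)) stop("negative ks in anchor table")
  if (!is.null(ann_a) && !is.null(ann_b)) {
    in_a <- anchors$gene_a %in% ann_a$genes$gene_id
    in_b <- anchors$gene_b %in% ann_b$genes$gene_id
    flip <- !in_a & anchors$gene_b %in% ann_a$genes$gene_id &
      anchors$gene_a %in% ann_b$genes$gene_id
    if (any(flip)) {
      tmp <- anchors$gene_a[flip]
      anchors$gene_a[flip] <- anchors$gene_b[flip]
      anchors$gene_b[flip] <- tmp
      in_a <- anchors$gene_a %in% ann_a$genes$gene_id
      in_b <- anchors$gene_b %in% ann_b$genes$gene_id
    }
    bad <- !(in_a & in_b)
    if (any(bad)) {
      warning(sum(bad), " anchor row(s) reference unknown genes; skipped")
      anchors <- anchors[!bad, , drop = FALSE]
    }
  }
  anchors <- anchors[!duplicated(anchors[c("gene_a", "gene_b")]), , drop = FALSE]
  anchors$ks_usable <- !is.na(anchors$ks) & anchors$ks < ks_max
  rownames(anchors) <- NULL
  anchors
}

#' Read a genomic-block (GB) definition table
#'
#' The table maps GB labels (A..X, possibly merged labels such as "K-L") to
#' intervals on the reference genome, delimited by reference gene ids — the
#' ancestral-crucifer-karyotype building blocks. When a reference annotation
#' is given, gene ids are resolved to rank intervals and overlap between
#' distinct labels is rejected.
#'
#' @param path TSV with columns `label`, `ak_chrom`, `ref_start_gene`,
#'   `ref_end_gene` (header optional).
#' @param ref_ann optional reference `genome_annotation` for rank resolution.
#' @return data.frame of GB definitions, with `ref_chrom`, `ref_start_rank`,
#'   `ref_end_rank` added when resolved (ranks inclusive).
#' @export
read_gb_table <- function(path, ref_ann = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(as.character(raw[1, 1])), "label")) {
    raw <- raw[-1, , drop = FALSE]
  }
  gb <- data.frame(label = as.character(raw[[1]]),
                   ak_chrom = as.character(raw[[2]]),
                   ref_start_gene = as.character(raw[[3]]),
                   ref_end_gene = as.character(raw[[4]]),
                   stringsAsFactors = FALSE)
  gb_table(gb, ref_ann = ref_ann)
}

#' Validate (and resolve) an in-memory GB definition table
#'
#' @param gb data.frame with `label`, `ak_chrom`, `ref_start_gene`,
#'   `ref_end_gene`.
#' @param ref_ann optional reference `genome_annotation`.
#' @return validated data.frame, rank-resolved when `ref_ann` is given.
#' @export
gb_table <- function(gb, ref_ann = NULL) {
  gb <- as.data.frame(gb, stringsAsFactors = FALSE)
  if (anyDuplicated(gb$label)) {
    stop("duplicate GB label: ", gb$label[duplicated(gb$label)][1])
  }
  if (!is.null(ref_ann)) {
    g <- ref_ann$genes
    i1 <- match(gb$ref_start_gene, g$gene_id)
    i2 <- match(gb$ref_end_gene, g$gene_id)
    if (anyNA(i1) || anyNA(i2)) {
      miss <- unique(c(gb$ref_start_gene[is.na(i1)], gb$ref_end_gene[is.na(i2)]))
      stop("GB table references unknown reference genes: ",
           paste(miss, collapse = ", "))
    }
    if (any(g$chrom[i1] != g$chrom[i2])) {
      stop("GB interval spans two reference chromosomes: ",
           gb$label[g$chrom[i1] != g$chrom[i2]][1])
    }
    gb$ref_chrom <- g$chrom[i1]
    gb$ref_start_rank <- pmin(g$rank[i1], g$rank[i2])
    gb$ref_end_rank <- pmax(g$rank[i1], g$rank[i2])
    # distinct labels must not overlap on the reference
    for (ch in unique(gb$ref_chrom)) {
      sub <- gb[gb$ref_chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$ref_start_rank), , drop = FALSE]
      if (nrow(sub) > 1) {
        ov <- which(sub$ref_start_rank[-1] <= sub$ref_end_rank[-nrow(sub)])
        if (length(ov)) {
          stop("overlapping GB intervals on ", ch, ": ",
               sub$label[ov[1]], " and ", sub$label[ov[1] + 1])
        }
      }
    }
  }
  rownames(gb) <- NULL
  gb
}

#' Write a painted genomic-block map to TSV
#'
#' One row per sub-block: query chromosome, rank span, bp span, GB label with
#' fragment index, inversion flag, gene count and reference rank span. Rows
#' are in chromosome order, then position. Round-trips losslessly through
#' [read_gb_map()].
#'
#' @param map a `gb_map` (see [build_gb_map()]).
#' @param path output TSV path.
#' @export
write_gb_map <- function(map, path) {
  stopifnot(inherits(map, "gb_map"))
  sb <- map$subblocks
  out <- data.frame(genome_id = rep(map$genome_id, nrow(sb)),
                    chrom = sb$chrom,
                    rank_start = sb$rank_start, rank_end = sb$rank_end,
                    bp_start = sb$bp_start, bp_end = sb$bp_end,
                    gb_label = sb$gb_label, index = sb$index,
                    inverted = sb$inverted, n_genes = sb$n_genes,
                    ref_start_rank = sb$ref_start_rank,
                    ref_end_rank = sb$ref_end_rank,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a painted genomic-block map written by [write_gb_map()]
#'
#' @param path TSV path.
#' @return a `gb_map`.
#' @export
read_gb_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(genome_id = "character",
                                         chrom = "character",
                                         gb_label = "character"))
  gid <- if (nrow(df)) df$genome_id[1] else NA_character_
  sb <- df[setdiff(names(df), "genome_id")]
  new_gb_map(gid, sb)
}

new_gb_map <- function(genome_id, subblocks) {
  cols <- c("chrom", "rank_start", "rank_end", "bp_start", "bp_end",
            "gb_label", "index", "inverted", "n_genes",
            "ref_start_rank", "ref_end_rank")
  if (!nrow(subblocks)) {
    subblocks <- as.data.frame(stats::setNames(
      list(character(), integer(), integer(), numeric(), numeric(),
           character(), integer(), logical(), integer(), integer(), integer()),
      cols))
  }
  subblocks <- subblocks[order(subblocks$chrom, subblocks$rank_start), cols,
                         drop = FALSE]
  rownames(subblocks) <- NULL
  structure(list(genome_id = genome_id, subblocks = subblocks),
            class = "gb_map")
}

#' @export
print.gb_map <- function(x, ...) {
  cat(sprintf("gb_map '%s': %d sub-blocks on %d chromosomes (%d inverted)\n",
              x$genome_id, nrow(x$subblocks),
              length(unique(x$subblocks$chrom)), sum(x$subblocks$inverted)))
  invisible(x)
}

#' Write a syntenic dotplot as SVG
#'
#' One glyph per anchor at its (rank_a, rank_b) position in concatenated
#' whole-genome rank coordinates, coloured by the origin class of the block
#' containing the anchor (orthologs purple, WGD-derived paralogs blue,
#' unchained anchors grey), the colouring used to tell apart orthologous and
#' At-alpha-derived regions on a synteny dotplot.
#'
#' @param anchors anchor table (see [anchor_table()]).
#' @param blocks list of `syntenic_block`s, or `NULL`.
#' @param ann_a,ann_b `genome_annotation`s for the two axes.
#' @param path output SVG path.
#' @param width,height canvas size in px.
#' @export
write_dotplot <- function(anchors, blocks, ann_a, ann_b, path,
                          width = 800, height = 800) {
  ga <- ann_a$genes; gb <- ann_b$genes
  # concatenated rank coordinate with per-chromosome offsets
  off_a <- .chrom_offsets(ga); off_b <- .chrom_offsets(gb)
  ia <- match(anchors$gene_a, ga$gene_id)
  ib <- match(anchors$gene_b, gb$gene_id)
  ok <- !is.na(ia) & !is.na(ib)
  x <- ga$rank[ia[ok]] + off_a[ga$chrom[ia[ok]]]
  y <- gb$rank[ib[ok]] + off_b[gb$chrom[ib[ok]]]
  col <- rep("#b0b0b0", sum(ok))
  if (!is.null(blocks)) {
    key <- paste(anchors$gene_a[ok], anchors$gene_b[ok])
    for (blk in blocks) {
      cls <- switch(blk$origin, ORTHOLOG = "#7b3294", WGD_PARALOG = "#2c7bb6",
                    UNCLASSIFIED = "#fdae61", "#b0b0b0")
      hit <- key %in% paste(blk$anchors$gene_a, blk$anchors$gene_b)
      col[hit] <- cls
    }
  }
  tot_a <- max(c(off_a + tapply(ga$rank, ga$chrom, max)[names(off_a)], 1))
  tot_b <- max(c(off_b + tapply(gb$rank, gb$chrom, max)[names(off_b)], 1))
  pad <- 40
  sx <- function(v) pad + v / max(tot_a, 1) * (width - 2 * pad)
  sy <- function(v) height - pad - v / max(tot_b, 1) * (height - 2 * pad)
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height),
    sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="white" stroke="black"/>',
            pad, pad, width - 2 * pad, height - 2 * pad),
    sprintf('<text x="%d" y="%d" font-size="12">%s</text>',
            pad, height - 10, ann_a$genome_id),
    sprintf('<text x="12" y="%d" font-size="12" transform="rotate(-90 12 %d)">%s</text>',
            pad + 10, pad + 10, ann_b$genome_id))
  if (length(x)) {
    lines <- c(lines, sprintf(
      '<circle class="anchor" cx="%.1f" cy="%.1f" r="1.5" fill="%s"/>',
      sx(x), sy(y), col))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

.chrom_offsets <- function(genes) {
  n <- tapply(genes$rank, genes$chrom, max) + 1
  chroms <- sort(names(n))
  off <- cumsum(c(0, as.numeric(n[chroms])[-length(chroms)]))
  names(off) <- chroms
  off
}
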