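#' Normalize loop strengths by library depth
#'
#' Divides each loop's mated-PE count by the library's total cis-far unique
#' valid pairs and rescales, giving reads per `scale` cis-far pairs
#' (default 1e8, i.e. reads per 100 M). Rank order of counts is preserved.
#'
#' @param library a [loop_library()].
#' @param scale rescaling constant (default 1e8).
#' @return named numeric vector, loop id -> normalized strength.
#' @export
normalize_strength <- function(library, scale = 1e8) {
  stopifnot_scalar_number(scale, "scale", min = .Machine$double.xmin)
  out <- library$loops$count / library$cis_far_total * scale
  names(out) <- library$loops$id
  out
}

#' Match loops between two libraries
#'
#' A loop of library A is "common" if some loop of library B overlaps it at
#' both anchors (left anchor with left anchor and right with right, at
#' least 1 bp each, same chromosome); otherwise it is specific to A. A
#' one-anchor match is not a match. The classification is computed for both
#' libraries.
#'
#' @param lib_a,lib_b [loop_library()] objects (canonical anchor order).
#' @param min_bp minimum anchor overlap in bp (default 1).
#' @return list with named character vectors `a` and `b` (loop id ->
#'   "common" / "specific_A" / "specific_B") and `pairs`, a data.frame of
#'   matched id pairs.
#' @export
match_loops <- function(lib_a, lib_b, min_bp = 1L) {
  la <- lib_a$loops; lb <- lib_b$loops
  pairs <- matched_loop_pairs(la, lb, min_bp = min_bp)
  a_class <- ifelse(la$id %in% pairs$id_a, "common", "specific_A")
  b_class <- ifelse(lb$id %in% pairs$id_b, "common", "specific_B")
  names(a_class) <- la$id
  names(b_class) <- lb$id
  list(a = a_class, b = b_class, pairs = pairs)
}

# both-anchor overlap pairs between two loop tables
matched_loop_pairs <- function(la, lb, min_bp = 1L) {
  if (!nrow(la) || !nrow(lb)) {
    return(data.frame(id_a = character(), id_b = character()))
  }
  h1 <- overlap_pairs(
    data.frame(chrom = la$chrom, start = la$start1, end = la$end1),
    data.frame(chrom = lb$chrom, start = lb$start1, end = lb$end1),
    min_bp = min_bp
  )
  h2 <- overlap_pairs(
    data.frame(chrom = la$chrom, start = la$start2, end = la$end2),
    data.frame(chrom = lb$chrom, start = lb$start2, end = lb$end2),
    min_bp = min_bp
  )
  both <- merge(h1, h2, by = c("query", "subject"))
  data.frame(id_a = la$id[both$query], id_b = lb$id[both$subject],
             stringsAsFactors = FALSE)
}

#' H3K27ac status of loop anchors
#'
#' Classifies each loop by whether its anchors overlap H3K27ac peaks:
#' `"+/+"` (both anchors), `"-/+"` (exactly one; unordered), `"-/-"`
#' (neither).
#'
#' @param library a [loop_library()].
#' @param k27_peaks H3K27ac peak data frame.
#' @return named character vector, loop id -> status.
#' @export
k27_status <- function(library, k27_peaks) {
  l <- library$loops
  a_pos <- overlaps_any(
    data.frame(chrom = l$chrom, start = l$start1, end = l$end1), k27_peaks)
  b_pos <- overlaps_any(
    data.frame(chrom = l$chrom, start = l$start2, end = l$end2), k27_peaks)
  n_pos <- a_pos + b_pos
  out <- c("-/-", "-/+", "+/+")[n_pos + 1L]
  names(out) <- l$id
  out
}

#' Gene density inside loops
#'
#' Counts gene TSSs strictly inside the open interval between a loop's two
#' anchor midpoints and normalizes by that distance in Mb, yielding genes
#' per Mb per loop.
#'
#' @param library a [loop_library()].
#' @param genes gene-model data frame (`gene_id`, `chrom`, `tss`).
#' @return named numeric vector, loop id -> genes per Mb.
#' @export
gene_density <- function(library, genes) {
  l <- library$loops
  mid_a <- interval_mid(l$start1, l$end1)
  mid_b <- interval_mid(l$start2, l$end2)
  dist <- mid_b - mid_a
  if (any(dist <= 0)) stop("loop midpoint distance must be positive", call. = FALSE)
  counts <- vapply(seq_len(nrow(l)), function(i) {
    sum(genes$chrom == l$chrom[i] & genes$tss > mid_a[i] & genes$tss < mid_b[i])
  }, numeric(1))
  out <- counts / (dist / 1e6)
  names(out) <- l$id
  out
}

#' Assign genes to anchors by TSS proximity
#'
#' A gene is assigned to an anchor when its TSS lies within the anchor
#' interval expanded by `window` bp on both sides (default 3 kb).
#'
#' @param anchors interval data frame (`chrom`, `start`, `end`).
#' @param genes gene-model data frame.
#' @param window expansion in bp (default 3000).
#' @return list of character vectors, one per anchor row, of assigned gene
#'   ids.
#' @export
annotate_anchor_genes <- function(anchors, genes, window = 3000) {
  stopifnot_scalar_number(window, "window", min = 0)
  anchors <- validate_intervals(anchors, "anchor")
  expanded <- data.frame(chrom = anchors$chrom,
                         start = pmax(0, anchors$start - window),
                         end = anchors$end + window)
  tss_iv <- data.frame(chrom = genes$chrom, start = genes$tss,
                       end = genes$tss + 1)
  hits <- overlap_pairs(expanded, tss_iv)
  out <- rep(list(character()), nrow(anchors))
  if (nrow(hits)) {
    sp <- split(genes$gene_id[hits$subject], hits$query)
    out[as.integer(names(sp))] <- lapply(sp, unique)
  }
  out
}

#' Promoter-anchored loop strength per gene
#'
#' For each gene, sums the normalized strengths of loops having at least one
#' anchor whose `window`-expanded interval contains the gene's TSS. A loop
#' anchoring a TSS with both anchors is counted once. Genes with no
#' anchoring loop map to 0.
#'
#' @param genes gene-model data frame.
#' @param library a [loop_library()].
#' @param window TSS window in bp (default 3000).
#' @param scale normalization scale passed to [normalize_strength()].
#' @return named numeric vector, gene_id -> total normalized strength.
#' @export
promoter_loop_strength <- function(genes, library, window = 3000,
                                   scale = 1e8) {
  norm <- normalize_strength(library, scale = scale)
  l <- library$loops
  tss_iv <- data.frame(chrom = genes$chrom, start = genes$tss,
                       end = genes$tss + 1)
  hit_gene_loop <- function(side_start, side_end) {
    anchors <- data.frame(chrom = l$chrom,
                          start = pmax(0, side_start - window),
                          end = side_end + window)
    h <- overlap_pairs(tss_iv, anchors)
    data.frame(gene = h$query, loop = h$subject)
  }
  hits <- unique(rbind(hit_gene_loop(l$start1, l$end1),
                       hit_gene_loop(l$start2, l$end2)))
  out <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  if (nrow(hits)) {
    sums <- tapply(norm[hits$loop], hits$gene, sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
    names(out) <- genes$gene_id
  }
  out
}

#' Annotate a loop library
#'
#' Convenience wrapper combining normalized strength, strength class
#' (strong = more than `strong_threshold` mated-PE reads), H3K27ac anchor
#' status, gene density, and — when a second library is given — the
#' common/specific match class.
#'
#' @param library a [loop_library()].
#' @param k27_peaks H3K27ac peaks (optional).
#' @param genes gene models (optional).
#' @param other second library for matching (optional).
#' @param strong_threshold raw-count threshold for "strong" loops
#'   (default 10).
#' @param scale normalization scale.
#' @return data.frame: the loop table plus annotation columns.
#' @export
annotate_loops <- function(library, k27_peaks = NULL, genes = NULL,
                           other = NULL, strong_threshold = 10, scale = 1e8) {
  out <- library$loops
  out$norm_strength <- as.numeric(normalize_strength(library, scale = scale))
  out$strength_class <- ifelse(out$count > strong_threshold, "strong", "weak")
  out$distance <- loop_distance(out)
  if (!is.null(k27_peaks)) {
    out$k27_status <- as.character(k27_status(library, k27_peaks))
  }
  if (!is.null(genes)) {
    out$gene_density <- as.numeric(gene_density(library, genes))
  }
  if (!is.null(other)) {
    out$match_class <- as.character(match_loops(library, other)$a)
  }
  out
}
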