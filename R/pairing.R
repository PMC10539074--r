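#' Assign genes to boundary regions
#'
#' A gene belongs to a boundary region when their intervals overlap by at
#' least one base; because regions on a chromosome are disjoint after
#' merging, a gene that overlaps two regions (possible only at region
#' gaps; intervals are half-open) is assigned to the region with the
#' larger overlap, ties to the leftmost.
#'
#' @param regions boundary regions from [expand_and_merge()] (one species)
#' @param genes gene table from [extract_proteins()] (same species)
#' @return data.frame `boundary_id`, `gene_id`
#' @export
genes_in_boundary <- function(regions, genes) {
  if (nrow(regions) == 0 || nrow(genes) == 0)
    return(empty_df(boundary_id = character(0), gene_id = character(0)))
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start + 1, genes$end))
  r <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1, regions$end))
  ov <- GenomicRanges::findOverlaps(g, r, minoverlap = 1L)
  if (length(ov) == 0)
    return(empty_df(boundary_id = character(0), gene_id = character(0)))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(g)[qh],
                                          IRanges::ranges(r)[sh]))
  o <- order(qh, -w, sh)
  keep <- !duplicated(qh[o])
  df <- data.frame(boundary_id = regions$boundary_id[sh[o][keep]],
                   gene_id = genes$gene_id[qh[o][keep]],
                   stringsAsFactors = FALSE)
  df[order(df$boundary_id, df$gene_id), , drop = FALSE]
}

#' Boundary pairs supported by syntenic gene anchors
#'
#' For every anchored gene pair whose two genes fall inside boundary
#' regions of their respective species, the enclosing boundaries form a
#' conserved pair. The pair weight accumulates, over supporting anchors,
#' the summed gene lengths `(end_a - start_a) + (end_b - start_b)`.
#'
#' @param assign_a,assign_b gene-to-boundary assignments from
#'   [genes_in_boundary()] for species A and B
#' @param anchor_index gene index from [block_anchor_index()]
#' @param genes_a,genes_b gene tables (for gene lengths)
#' @return data.frame of pairs: `boundary_a`, `boundary_b`, `species_a`,
#'   `species_b`, `evidence` (`"synteny"`), `weight`
#' @export
pairs_from_synteny <- function(assign_a, assign_b, anchor_index,
                               genes_a, genes_b) {
  empty <- empty_pairs()
  if (nrow(anchor_index) == 0 || nrow(assign_a) == 0 || nrow(assign_b) == 0)
    return(empty)
  sp_a <- species_of(genes_a$gene_id[1])
  idx <- anchor_index[species_of(anchor_index$gene) == sp_a, , drop = FALSE]
  m <- merge(idx, assign_a, by.x = "gene", by.y = "gene_id")
  names(m)[names(m) == "boundary_id"] <- "boundary_a"
  m <- merge(m, assign_b, by.x = "partner", by.y = "gene_id")
  names(m)[names(m) == "boundary_id"] <- "boundary_b"
  if (nrow(m) == 0) return(empty)
  len_a <- genes_a$end - genes_a$start
  len_b <- genes_b$end - genes_b$start
  m$w <- len_a[match(m$gene, genes_a$gene_id)] +
    len_b[match(m$partner, genes_b$gene_id)]
  agg <- stats::aggregate(list(weight = m$w),
                          by = list(boundary_a = m$boundary_a,
                                    boundary_b = m$boundary_b), FUN = sum)
  data.frame(boundary_a = agg$boundary_a, boundary_b = agg$boundary_b,
             species_a = sp_a, species_b = species_of(genes_b$gene_id[1]),
             evidence = "synteny", weight = agg$weight,
             stringsAsFactors = FALSE)
}

#' Boundary pairs supported by sequence alignment
#'
#' A (length-filtered) alignment hit whose target interval overlaps a
#' target-species boundary region by at least `min_overlap` bp links the
#' query boundary to that target boundary; the pair weight accumulates
#' the aligned lengths of supporting hits.
#'
#' @param hits filtered hits from [filter_hits()] (queries from species A,
#'   target species B)
#' @param boundaries_target boundary regions of the target species
#' @param min_overlap minimum hit/region overlap in bp (default 1)
#' @return data.frame of pairs with `evidence = "sequence"`
#' @export
pairs_from_sequence <- function(hits, boundaries_target, min_overlap = 1) {
  empty <- empty_pairs()
  if (nrow(hits) == 0 || nrow(boundaries_target) == 0) return(empty)
  h <- GenomicRanges::GRanges(hits$target_chrom,
                              IRanges::IRanges(hits$target_start + 1,
                                               hits$target_end))
  r <- GenomicRanges::GRanges(boundaries_target$chrom,
                              IRanges::IRanges(boundaries_target$start + 1,
                                               boundaries_target$end))
  ov <- GenomicRanges::findOverlaps(h, r, minoverlap = as.integer(min_overlap))
  if (length(ov) == 0) return(empty)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  df <- data.frame(boundary_a = hits$boundary_id[qh],
                   boundary_b = boundaries_target$boundary_id[sh],
                   w = hits$length[qh], stringsAsFactors = FALSE)
  df <- df[species_of(df$boundary_a) != species_of(df$boundary_b), ,
           drop = FALSE]
  if (nrow(df) == 0) return(empty)
  agg <- stats::aggregate(list(weight = df$w),
                          by = list(boundary_a = df$boundary_a,
                                    boundary_b = df$boundary_b), FUN = sum)
  data.frame(boundary_a = agg$boundary_a, boundary_b = agg$boundary_b,
             species_a = species_of(agg$boundary_a),
             species_b = species_of(agg$boundary_b),
             evidence = "sequence", weight = agg$weight,
             stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  empty_df(boundary_a = character(0), boundary_b = character(0),
           species_a = character(0), species_b = character(0),
           evidence = character(0), weight = numeric(0))
}

# canonicalise a pair table to the unordered orientation
# (boundary_a < boundary_b) and merge duplicate keys with `fun`
merge_pairs <- function(parts, fun) {
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0, parts)
  if (!length(parts)) return(empty_pairs())
  all <- do.call(rbind, parts)
  if (any(all$weight <= 0)) stop("pair weight must be > 0")
  if (any(species_of(all$boundary_a) == species_of(all$boundary_b)))
    stop("self-species pair encountered")
  flip <- all$boundary_a > all$boundary_b
  ba <- ifelse(flip, all$boundary_b, all$boundary_a)
  bb <- ifelse(flip, all$boundary_a, all$boundary_b)
  key <- paste(ba, bb, sep = "\r")
  w <- tapply(all$weight, key, fun)
  ev <- tapply(all$evidence, key, function(e) {
    u <- sort(unique(e))
    if (length(u) > 1) "both" else u
  })
  keys <- sort(names(w))
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  data.frame(boundary_a = ab[, 1], boundary_b = ab[, 2],
             species_a = species_of(ab[, 1]),
             species_b = species_of(ab[, 2]),
             evidence = as.character(ev[keys]),
             weight = as.numeric(w[keys]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Integrate synteny and sequence evidence into undirected boundary pairs
#'
#' Pairs are keyed by the unordered boundary pair. The sequence channel is
#' run in both directions (A as query against B, and B against A); the two
#' directional weights for the same unordered pair are symmetrised by
#' keeping the larger one, since conservation is an undirected relation.
#' The synteny channel is direction-free. When both channels report the
#' same unordered pair the evidence label becomes `"both"` and the channel
#' weights add.
#'
#' @param synteny_pairs pairs from [pairs_from_synteny()] (or NULL)
#' @param sequence_fwd,sequence_rev directional pair tables from
#'   [pairs_from_sequence()] (either may be NULL)
#' @return undirected pair table with `boundary_a` < `boundary_b`
#'   lexicographically
#' @export
integrate_pairs <- function(synteny_pairs = NULL, sequence_fwd = NULL,
                            sequence_rev = NULL) {
  seq_und <- merge_pairs(list(sequence_fwd, sequence_rev), max)
  merge_pairs(list(merge_pairs(list(synteny_pairs), sum), seq_und), sum)
}
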