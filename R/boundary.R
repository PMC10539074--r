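#' TAD edge positions per chromosome
#'
#' Every TAD contributes its start and its end as a boundary edge; shared
#' edges of abutting TADs are de-duplicated.
#'
#' @param tads data.frame from [read_tads()] (single species)
#' @return data.frame `chrom`, `pos` (sorted, unique per chromosome)
#' @export
edges_from_tads <- function(tads) {
  stopifnot(length(unique(tads$species)) <= 1)
  if (nrow(tads) == 0)
    return(empty_df(chrom = character(0), pos = numeric(0)))
  e <- rbind(data.frame(chrom = tads$chrom, pos = tads$start),
             data.frame(chrom = tads$chrom, pos = tads$end))
  e <- unique(e)
  e <- e[order(e$chrom, e$pos), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Expand TAD edges into merged boundary regions
#'
#' Each edge `e` becomes the window `[e - radius, e + radius)`, clipped to
#' the chromosome; overlapping or abutting windows are merged into their
#' union (one contiguous boundary zone), and ids are assigned left to
#' right per chromosome. `source_edges` records how many edges were merged
#' into a region.
#'
#' @param edges data.frame `chrom`, `pos` from [edges_from_tads()]
#' @param radius half-width of the boundary window in bp (> 0)
#' @param chrom_len named vector of chromosome lengths
#' @param species_id species identifier used in the `boundary_id`
#' @return data.frame of boundary regions: `boundary_id`, `species`,
#'   `chrom`, `start`, `end`, `source_edges`; disjoint (gap >= 1 bp) and
#'   sorted within each chromosome
#' @export
expand_and_merge <- function(edges, radius, chrom_len, species_id) {
  if (radius <= 0) stop("radius must be > 0")
  if (nrow(edges) == 0)
    return(empty_df(boundary_id = character(0), species = character(0),
                    chrom = character(0), start = numeric(0),
                    end = numeric(0), source_edges = integer(0)))
  if (any(!edges$chrom %in% names(chrom_len)))
    stop("edge on unknown chromosome")
  if (any(edges$pos < 0 | edges$pos > chrom_len[edges$chrom]))
    stop("edge position outside chromosome")
  out <- lapply(split(edges, edges$chrom), function(e) {
    clen <- chrom_len[[e$chrom[1]]]
    s <- pmax(0, e$pos - radius)
    en <- pmin(clen, e$pos + radius)
    keep <- en > s
    ir <- IRanges::IRanges(start = s[keep] + 1L, end = en[keep])
    red <- IRanges::reduce(ir)  # merges overlapping and abutting
    n_src <- IRanges::countOverlaps(red, ir, type = "any")
    data.frame(chrom = e$chrom[1],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               source_edges = as.integer(n_src),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  tok <- split_prefixed_id(res$chrom)$token
  ord <- stats::ave(seq_len(nrow(res)), res$chrom, FUN = seq_along)
  res <- cbind(
    data.frame(boundary_id = paste0(species_id, "|", tok, ":b",
                                    sprintf("%04d", ord)),
               species = species_id, stringsAsFactors = FALSE),
    res)
  rownames(res) <- NULL
  res
}

#' Boundary regions for one species
#'
#' Convenience wrapper: TAD intervals to edges to merged regions.
#'
#' @inheritParams expand_and_merge
#' @param tads data.frame from [read_tads()]
#' @param genome `tc_genome`
#' @param radius boundary half-width in bp (default 20000)
#' @return see [expand_and_merge()]
#' @export
boundaries_for_species <- function(tads, genome, radius = 20000) {
  expand_and_merge(edges_from_tads(tads), radius, genome$lengths,
                   genome$species)
}

#' Extract boundary-region sequences
#'
#' Forward-strand slices of the genome, one per region, named by
#' `boundary_id`.
#'
#' @param regions boundary regions from [expand_and_merge()]
#' @param genome `tc_genome`
#' @return `DNAStringSet`
#' @export
boundary_sequences <- function(regions, genome) {
  if (nrow(regions) == 0) return(Biostrings::DNAStringSet())
  if (any(!regions$chrom %in% names(genome$seqs)))
    stop("region on unknown chromosome")
  if (any(regions$start < 0 | regions$end > genome$lengths[regions$chrom]))
    stop("boundary region outside chromosome")
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(regions)), function(i)
    as.character(Biostrings::subseq(genome$seqs[[regions$chrom[i]]],
                                    start = regions$start[i] + 1L,
                                    end = regions$end[i])), character(1)))
  names(seqs) <- regions$boundary_id
  seqs
}

#' Write boundary regions as BED
#'
#' Columns: chrom (cleaned), start, end, boundary_id, source_edges.
#'
#' @param regions boundary regions
#' @param path output path
#' @export
write_boundary_bed <- function(regions, path) {
  bed <- regions[, c("chrom", "start", "end", "boundary_id", "source_edges")]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
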