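#' MinHash sketch of a genome
#'
#' Hashes every canonical k-mer (lexicographic minimum of a window and its
#' reverse complement) with a deterministic 53-bit hash and keeps the
#' `sketch_size` smallest distinct values across all chromosomes. k-mers
#' containing non-ACGT characters are skipped.
#'
#' @param genome a `tc_genome`, a `DNAStringSet`, or a character vector of
#'   sequences
#' @param k k-mer size, between 11 and 31 (default 21)
#' @param sketch_size sketch capacity, at least 100 (default 1000)
#' @return a `tc_sketch` list: `species`, `k`, `sketch_size`, `hashes`
#'   (sorted ascending, unique)
#' @export
sketch_genome <- function(genome, k = 21, sketch_size = 1000) {
  if (k < 11 || k > 31) stop("k must be in [11, 31]")
  if (sketch_size < 100) stop("sketch_size must be >= 100")
  species <- NA_character_
  if (inherits(genome, "tc_genome")) {
    species <- genome$species
    seqs <- as.character(genome$seqs)
  } else if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else seqs <- as.character(genome)
  if (max(nchar(seqs)) < k) stop("genome shorter than k")
  h <- minhash_sketch_cpp(seqs, as.integer(k), as.integer(sketch_size))
  structure(list(species = species, k = k, sketch_size = sketch_size,
                 hashes = h), class = "tc_sketch")
}

#' @export
print.tc_sketch <- function(x, ...) {
  cat("MinHash sketch [", x$species, "]: k=", x$k, ", ",
      length(x$hashes), "/", x$sketch_size, " hashes\n", sep = "")
  invisible(x)
}

#' Mash distance between two sketches
#'
#' Jaccard similarity `j` is estimated from the merged bottom sketch (the
#' fraction of the `sketch_size` smallest hashes of the union present in
#' both sketches), then converted to the Mash distance
#' `d = -(1/k) * log(2 j / (1 + j))`. `j = 0` saturates at `d = 1`;
#' identical sketches give `d = 0`.
#'
#' @param sk_a,sk_b sketches from [sketch_genome()] with equal `k`
#' @return distance (non-negative scalar)
#' @export
mash_distance <- function(sk_a, sk_b) {
  if (sk_a$k != sk_b$k) stop("sketches have different k")
  u <- sort(unique(c(sk_a$hashes, sk_b$hashes)))
  s <- min(max(sk_a$sketch_size, sk_b$sketch_size), length(u))
  bottom <- u[seq_len(s)]
  shared <- sum(bottom %in% sk_a$hashes & bottom %in% sk_b$hashes)
  j <- shared / s
  if (j <= 0) return(1.0)
  if (j >= 1) return(0.0)
  max(0, -(1 / sk_a$k) * log(2 * j / (1 + j)))
}

#' Choose an alignment stringency preset from a Mash distance
#'
#' Near-identical genomes are aligned under the strict `asm5` preset,
#' moderately diverged genomes under `asm10`, and distant genomes under
#' the relaxed `asm20` preset. Thresholds follow the presets' documented
#' divergence bands (about 1%, 5% and 10%) measured on the Mash scale, and
#' can be overridden.
#'
#' @param distance Mash distance (>= 0)
#' @param thresholds two cut points, `asm5` upper bound then `asm10`
#'   upper bound (default `c(0.01, 0.1)`)
#' @return `"asm5"`, `"asm10"` or `"asm20"`
#' @export
select_preset <- function(distance, thresholds = c(0.01, 0.1)) {
  if (any(distance < 0)) stop("distance must be non-negative")
  ifelse(distance <= thresholds[1], "asm5",
         ifelse(distance <= thresholds[2], "asm10", "asm20"))
}

# minimum anchor-coverage identity per preset, on the builtin aligner's
# scale (fraction of the query span covered by exact 15-mer anchors; a
# conservative lower bound on true identity)
preset_min_identity <- function(preset) {
  switch(preset, asm5 = 0.8, asm10 = 0.5, asm20 = 0.3,
         stop("unknown preset: ", preset))
}

#' Align boundary sequences to a target genome
#'
#' Builtin backend: exact-match k-mer anchors (k = 15) between each query
#' and each target chromosome are grouped per (query, chromosome, strand)
#' into diagonal bands, split where the target gap exceeds `chain_gap`,
#' and each group with at least `min_anchors` anchors becomes one hit.
#' Identity is estimated as the fraction of the query span covered by
#' anchors; the preset sets the minimum identity (asm5 strictest). The
#' external backend parses PAF records produced by a whole-genome aligner.
#'
#' @param boundary_seqs named `DNAStringSet` of boundary sequences (names
#'   are boundary ids)
#' @param target_genome `tc_genome` of the target species
#' @param preset `"asm5"`, `"asm10"` or `"asm20"` (see [select_preset()])
#' @param backend `"builtin"` or `"external"`
#' @param k anchor k-mer size (builtin; default 15)
#' @param chain_gap largest target gap joined into one hit, bp
#'   (default 2000)
#' @param band_width diagonal tolerance when banding anchors, bp
#'   (default 500)
#' @param min_anchors minimum distinct anchor start positions per
#'   reported hit (default 2)
#' @param min_span minimum target span of a hit in bp (default 200);
#'   suppresses coincidental isolated k-mer matches
#' @param max_occ k-mers seen more often than this in a target chromosome
#'   are skipped as repeats (default 50)
#' @param paf_path PAF file path (external backend)
#' @return data.frame of hits: `boundary_id`, `target_species`,
#'   `target_chrom`, `target_start`, `target_end` (0-based half-open),
#'   `length` (target span, bp), `identity`, `strand`
#' @export
align_boundaries <- function(boundary_seqs, target_genome, preset = "asm10",
                             backend = "builtin", k = 15, chain_gap = 2000,
                             band_width = 500, min_anchors = 2,
                             min_span = 200, max_occ = 50,
                             paf_path = NULL) {
  empty <- empty_df(boundary_id = character(0), target_species = character(0),
                    target_chrom = character(0), target_start = numeric(0),
                    target_end = numeric(0), length = numeric(0),
                    identity = numeric(0), strand = character(0))
  if (backend == "external") {
    if (is.null(paf_path) || !file.exists(paf_path))
      stop("external alignment backend requires an existing PAF file")
    return(read_paf_hits(paf_path, target_genome))
  }
  if (backend != "builtin") stop("unknown backend: ", backend)
  if (length(boundary_seqs) == 0) return(empty)
  if (is.null(names(boundary_seqs)) || any(!nzchar(names(boundary_seqs))))
    stop("boundary sequences must be named by boundary_id")
  min_ident <- preset_min_identity(preset)
  qnames <- names(boundary_seqs)
  qseqs <- as.character(boundary_seqs)
  hits <- list()
  for (chrom in names(target_genome$seqs)) {
    anchors <- kmer_anchor_hits(qseqs,
                                as.character(target_genome$seqs[[chrom]]),
                                as.integer(k), as.integer(max_occ))
    if (nrow(anchors) == 0) next
    anchors$diag <- ifelse(anchors$strand == 1,
                           anchors$tpos - anchors$qpos,
                           anchors$tpos + anchors$qpos)
    for (grp in split(anchors,
                      list(anchors$query, anchors$strand), drop = TRUE)) {
      grp <- grp[order(grp$diag, grp$tpos), , drop = FALSE]
      band <- cumsum(c(1, diff(grp$diag) > band_width))
      for (bid in unique(band)) {
        sub <- grp[band == bid, , drop = FALSE]
        sub <- sub[order(sub$tpos), , drop = FALSE]
        piece <- cumsum(c(1, diff(sub$tpos) > chain_gap))
        for (pid in unique(piece)) {
          a <- sub[piece == pid, , drop = FALSE]
          if (length(unique(a$qpos)) < min_anchors) next
          if (max(a$tpos) + k - min(a$tpos) < min_span) next
          qcov <- sum(IRanges::width(IRanges::reduce(
            IRanges::IRanges(start = a$qpos + 1L, width = k))))
          qspan <- max(a$qpos) + k - min(a$qpos)
          ident <- qcov / qspan
          if (ident < min_ident) next
          qi <- a$query[1]
          hits[[length(hits) + 1L]] <- data.frame(
            boundary_id = qnames[qi],
            target_species = target_genome$species,
            target_chrom = chrom,
            target_start = min(a$tpos),
            target_end = max(a$tpos) + k,
            length = max(a$tpos) + k - min(a$tpos),
            identity = ident,
            strand = if (a$strand[1] == 1) "+" else "-",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) return(empty)
  res <- do.call(rbind, hits)
  res <- res[order(res$boundary_id, res$target_chrom, res$target_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# PAF adapter for an external aligner's output
read_paf_hits <- function(paf_path, target_genome) {
  p <- utils::read.table(paf_path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, fill = TRUE)
  data.frame(boundary_id = p[[1]],
             target_species = target_genome$species,
             target_chrom = clean_chrom_name(p[[6]], target_genome$species),
             target_start = as.numeric(p[[8]]),
             target_end = as.numeric(p[[9]]),
             length = as.numeric(p[[9]]) - as.numeric(p[[8]]),
             identity = as.numeric(p[[10]]) / pmax(1, as.numeric(p[[11]])),
             strand = p[[5]], stringsAsFactors = FALSE)
}

#' Drop short alignment hits
#'
#' Retains hits whose aligned length is strictly greater than `min_len`
#' (default 2000 bp), preserving input order. Idempotent.
#'
#' @param hits data.frame from [align_boundaries()]
#' @param min_len length cutoff in bp (default 2000)
#' @return filtered data.frame
#' @export
filter_hits <- function(hits, min_len = 2000) {
  if (min_len < 0) stop("min_len must be >= 0")
  hits[hits$length > min_len, , drop = FALSE]
}
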