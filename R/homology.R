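#' Homologous protein pairs between two species
#'
#' The builtin backend seeds candidate pairs by shared amino-acid k-mers
#' (k = 5) and scores each candidate with a local Smith-Waterman alignment
#' under BLOSUM62 (gap open 11, extend 1). Pairs scoring at least
#' `min_score` are kept; per gene only the best `max_hits` partners
#' survive, ties broken by the lexicographically smallest partner id. Each
#' unordered pair is reported once. The external backend reads a tabular
#' hits file (`query target bitscore`) produced by any search tool.
#'
#' @param genes_a,genes_b gene tables from [extract_proteins()] for two
#'   different species
#' @param backend `"builtin"` or `"external"`
#' @param min_score minimum alignment score (default 50)
#' @param max_hits best partners retained per gene (default 5)
#' @param min_seed_kmers shared 5-mers required to score a candidate pair
#'   (builtin backend; default 2)
#' @param hits_path path to external tabular hits (external backend)
#' @return data.frame of anchor pairs: `gene_a`, `gene_b`, `score`
#' @export
protein_homologs <- function(genes_a, genes_b, backend = "builtin",
                             min_score = 50, max_hits = 5,
                             min_seed_kmers = 2, hits_path = NULL) {
  sp_a <- unique(species_of(genes_a$gene_id))
  sp_b <- unique(species_of(genes_b$gene_id))
  if (length(sp_a) != 1 || length(sp_b) != 1 || sp_a == sp_b)
    stop("protein_homologs needs gene sets from two distinct species")
  if (backend == "external") {
    if (is.null(hits_path) || !file.exists(hits_path))
      stop("external homology backend requires an existing hits file ",
           "(run your search tool and pass hits_path)")
    h <- utils::read.table(hits_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    cand <- data.frame(gene_a = h[[1]], gene_b = h[[2]],
                       score = as.numeric(h[[3]]),
                       stringsAsFactors = FALSE)
  } else if (backend == "builtin") {
    cand <- seed_candidates(genes_a, genes_b, k = 5,
                            min_shared = min_seed_kmers)
    if (nrow(cand) == 0)
      return(empty_df(gene_a = character(0), gene_b = character(0),
                      score = numeric(0)))
    pa <- stats::setNames(genes_a$protein, genes_a$gene_id)
    pb <- stats::setNames(genes_b$protein, genes_b$gene_id)
    cand$score <- sw_scores(pa[cand$gene_a], pb[cand$gene_b])
  } else stop("unknown backend: ", backend)

  cand <- cand[cand$score >= min_score, , drop = FALSE]
  if (nrow(cand) == 0)
    return(empty_df(gene_a = character(0), gene_b = character(0),
                    score = numeric(0)))
  # canonical unordered orientation: species of genes_a on the left
  cand <- unique(cand)
  cand <- top_partners(cand, "gene_a", "gene_b", max_hits)
  cand <- top_partners(cand, "gene_b", "gene_a", max_hits)
  cand <- cand[order(cand$gene_a, cand$gene_b), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# keep, per value of `key`, the max_hits best rows by score
# (ties by partner id)
top_partners <- function(df, key, partner, max_hits) {
  keep <- unlist(lapply(split(seq_len(nrow(df)), df[[key]]), function(ix) {
    o <- order(-df$score[ix], df[[partner]][ix])
    ix[o][seq_len(min(max_hits, length(ix)))]
  }), use.names = FALSE)
  df[sort(keep), , drop = FALSE]
}

# candidate pairs sharing at least min_shared distinct amino-acid k-mers
seed_candidates <- function(genes_a, genes_b, k = 5, min_shared = 2) {
  idx <- function(g) {
    n <- nchar(g$protein)
    keep <- which(n >= k)
    if (!length(keep))
      return(empty_df(kmer = character(0), id = character(0)))
    km <- lapply(keep, function(i) {
      s <- g$protein[i]
      unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
    })
    data.frame(kmer = unlist(km),
               id = rep(g$gene_id[keep], lengths(km)),
               stringsAsFactors = FALSE)
  }
  ia <- idx(genes_a)
  ib <- idx(genes_b)
  m <- merge(ia, ib, by = "kmer", suffixes = c("_a", "_b"))
  if (nrow(m) == 0)
    return(empty_df(gene_a = character(0), gene_b = character(0)))
  cnt <- stats::aggregate(list(n = m$kmer),
                          by = list(gene_a = m$id_a, gene_b = m$id_b),
                          FUN = length)
  cnt <- cnt[cnt$n >= min_shared, c("gene_a", "gene_b"), drop = FALSE]
  rownames(cnt) <- NULL
  cnt
}

# vectorised local-alignment scores for paired protein strings
sw_scores <- function(prot_a, prot_b) {
  if (length(prot_a) == 0) return(numeric(0))
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  mat <- get("BLOSUM62", envir = data_env)
  a <- Biostrings::AAStringSet(prot_a)
  b <- Biostrings::AAStringSet(prot_b)
  as.numeric(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE))
}

#' Chain anchor pairs into collinear synteny blocks
#'
#' Single-pass dynamic programme over anchors sorted by the rank of their
#' side-A gene: an anchor j extends anchor i when
#' `0 < rank_a(j) - rank_a(i) <= gap_max` and
#' `0 < |rank_b(j) - rank_b(i)| <= gap_max` with a sign consistent across
#' the chain (increasing = `same` orientation, decreasing = `inverted`).
#' Chain score is the anchor count. Maximal chains are extracted greedily,
#' best score first (ties by leftmost side-A start); anchors and genes of
#' an emitted block are removed before the next extraction, so every gene
#' belongs to at most one block.
#'
#' @param anchors anchor pairs from [protein_homologs()]
#' @param genes_a,genes_b gene tables providing `chrom` and `rank`
#' @param gap_max largest allowed rank gap inside a chain (default 25)
#' @param min_block_anchors minimum anchors per emitted block (default 4)
#' @return data.frame of blocks: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_anchors`, plus an `anchors` list-column holding,
#'   per block, a data.frame (`gene_a`, `gene_b`, `rank_a`, `rank_b`)
#' @export
chain_collinear <- function(anchors, genes_a, genes_b, gap_max = 25,
                            min_block_anchors = 4) {
  empty <- data.frame(block_id = character(0), chrom_a = character(0),
                      chrom_b = character(0), orientation = character(0),
                      n_anchors = integer(0), stringsAsFactors = FALSE)
  empty$anchors <- list()
  if (nrow(anchors) == 0) return(empty)

  ga <- genes_a[match(anchors$gene_a, genes_a$gene_id), ]
  gb <- genes_b[match(anchors$gene_b, genes_b$gene_id), ]
  tab <- data.frame(gene_a = anchors$gene_a, gene_b = anchors$gene_b,
                    chrom_a = ga$chrom, chrom_b = gb$chrom,
                    rank_a = ga$rank, rank_b = gb$rank,
                    stringsAsFactors = FALSE)
  sp_a <- species_of(tab$gene_a[1])
  blocks <- list()
  bn <- 0L
  for (key in sort(unique(paste(tab$chrom_a, tab$chrom_b, sep = "\r")))) {
    part <- tab[paste(tab$chrom_a, tab$chrom_b, sep = "\r") == key, ,
                drop = FALSE]
    repeat {
      best <- best_chain(part, gap_max)
      if (is.null(best) || length(best$idx) < min_block_anchors) break
      bn <- bn + 1L
      sel <- part[best$idx, , drop = FALSE]
      blk <- data.frame(block_id = paste0(sp_a, ":blk", sprintf("%04d", bn)),
                        chrom_a = sel$chrom_a[1], chrom_b = sel$chrom_b[1],
                        orientation = best$orientation,
                        n_anchors = nrow(sel), stringsAsFactors = FALSE)
      blk$anchors <- list(sel[, c("gene_a", "gene_b", "rank_a", "rank_b")])
      blocks[[bn]] <- blk
      # remove anchors touching the emitted block's genes
      part <- part[!(part$gene_a %in% sel$gene_a |
                       part$gene_b %in% sel$gene_b), , drop = FALSE]
      if (nrow(part) == 0) break
    }
  }
  if (!length(blocks)) return(empty)
  res <- do.call(rbind, blocks)
  rownames(res) <- NULL
  res
}

# best chain within one chromosome-pair anchor set: DP over anchors sorted
# by (rank_a, rank_b), one pass per orientation sign
best_chain <- function(part, gap_max) {
  n <- nrow(part)
  if (n == 0) return(NULL)
  o <- order(part$rank_a, part$rank_b)
  ra <- part$rank_a[o]
  rb <- part$rank_b[o]
  best <- NULL
  for (sgn in c(1, -1)) {
    len <- rep(1L, n)
    prev <- rep(NA_integer_, n)
    for (j in seq_len(n)) {
      for (i in seq_len(j - 1L)) {
        da <- ra[j] - ra[i]
        if (da <= 0 || da > gap_max) next
        db <- sgn * (rb[j] - rb[i])
        if (db <= 0 || db > gap_max) next
        if (len[i] + 1L > len[j]) {
          len[j] <- len[i] + 1L
          prev[j] <- i
        }
      }
    }
    jbest <- which(len == max(len))
    # tie-break: leftmost chain start (smallest rank_a of the chain head)
    heads <- vapply(jbest, function(j) {
      while (!is.na(prev[j])) j <- prev[j]
      ra[j]
    }, numeric(1))
    j <- jbest[order(heads, jbest)][1]
    chain <- integer(0)
    jj <- j
    repeat {
      chain <- c(jj, chain)
      if (is.na(prev[jj])) break
      jj <- prev[jj]
    }
    cand <- list(idx = o[chain],
                 orientation = if (sgn == 1) "same" else "inverted",
                 score = len[j], head = ra[chain[1]])
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$head < best$head))
      best <- cand
  }
  best
}

#' Invert synteny blocks into a gene-to-block index
#'
#' @param blocks blocks from [chain_collinear()]
#' @return data.frame `gene`, `partner`, `block_id` with one row per
#'   anchored gene (both sides indexed)
#' @export
block_anchor_index <- function(blocks) {
  if (nrow(blocks) == 0)
    return(empty_df(gene = character(0), partner = character(0),
                    block_id = character(0)))
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    a <- blocks$anchors[[i]]
    rbind(data.frame(gene = a$gene_a, partner = a$gene_b,
                     block_id = blocks$block_id[i], stringsAsFactors = FALSE),
          data.frame(gene = a$gene_b, partner = a$gene_a,
                     block_id = blocks$block_id[i], stringsAsFactors = FALSE))
  })
  idx <- do.call(rbind, rows)
  if (anyDuplicated(idx$gene) &&
      any(tapply(idx$block_id, idx$gene, function(b) length(unique(b))) > 1))
    stop("internal error: a gene appears in two blocks")
  rownames(idx) <- NULL
  idx
}
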