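# Independent reference implementations used as oracles. These are kept
# deliberately naive (per-base bitmaps, quadratic scans, plain recursion)
# and share no code with the package internals they check.

# union of expanded edge windows as a per-base bitmap
bitmap_union <- function(edges, radius, chrom_len) {
  bits <- logical(chrom_len)
  for (e in edges) {
    lo <- max(0, e - radius)
    hi <- min(chrom_len, e + radius)
    if (hi > lo) bits[(lo + 1):hi] <- TRUE
  }
  bits
}

# intervals (0-based half-open) covered by a bitmap
bitmap_intervals <- function(bits) {
  r <- rle(bits)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  data.frame(start = starts[r$values], end = ends[r$values])
}

# quadratic interval-overlap scan: gene i overlaps region j by >= 1 bp
overlap_scan <- function(genes, regions) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    best <- NULL
    best_w <- 0
    for (j in seq_len(nrow(regions))) {
      if (genes$chrom[i] != regions$chrom[j]) next
      w <- min(genes$end[i], regions$end[j]) -
        max(genes$start[i], regions$start[j])
      if (w >= 1 && w > best_w) {
        best <- j
        best_w <- w
      }
    }
    if (!is.null(best))
      out[[length(out) + 1]] <- data.frame(
        boundary_id = regions$boundary_id[best],
        gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(boundary_id = character(0), gene_id = character(0)))
  do.call(rbind, out)
}

# exhaustive best-chain search over anchors (rank_a, rank_b): plain
# recursion over chain extensions under the stated gap/sign rules;
# returns the maximum chain length and the smallest head rank_a among
# maximum chains
max_chain_oracle <- function(ra, rb, gap_max) {
  n <- length(ra)
  if (n == 0) return(list(score = 0, head = NA))
  best_from <- function(i, sgn, memo) {
    key <- paste(i, sgn)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- 1
    for (j in seq_len(n)) {
      da <- ra[j] - ra[i]
      db <- sgn * (rb[j] - rb[i])
      if (da > 0 && da <= gap_max && db > 0 && db <= gap_max)
        best <- max(best, 1 + best_from(j, sgn, memo)$score)
      memo[[key]] <- list(score = best)
    }
    memo[[key]] <- list(score = best)
    memo[[key]]
  }
  memo <- new.env()
  scores <- vapply(seq_len(n), function(i)
    max(best_from(i, 1, memo)$score, best_from(i, -1, memo)$score),
    numeric(1))
  smax <- max(scores)
  list(score = smax, head = min(ra[scores == smax]))
}

# validity of one chain under the collinearity rules
chain_is_valid <- function(ra, rb, gap_max) {
  if (length(ra) == 1) return(TRUE)
  da <- diff(ra)
  db <- diff(rb)
  all(da > 0 & da <= gap_max) &&
    (all(db > 0 & db <= gap_max) || all(-db > 0 & -db <= gap_max))
}

# straightforward dense-matrix MCL reference: explicit loops, same
# parameters and attractor-overlap interpretation as documented
ref_mcl <- function(adj, inflation = 2, max_iter = 100, prune = 1e-5) {
  n <- nrow(adj)
  for (v in seq_len(n)) adj[v, v] <- max(max(adj[, v]), 1)
  norm_cols <- function(m) {
    for (v in seq_len(ncol(m))) {
      s <- sum(m[, v])
      if (s == 0) m[v, v] <- s <- 1
      m[, v] <- m[, v] / s
    }
    m
  }
  M <- norm_cols(adj)
  for (iter in seq_len(max_iter)) {
    nxt <- (M %*% M)^inflation
    nxt[nxt < prune] <- 0
    nxt <- norm_cols(nxt)
    if (max(abs(nxt - M)) < 1e-8) {
      M <- nxt
      break
    }
    M <- nxt
  }
  # group nodes that share mass in an attractor row
  g <- igraph::make_empty_graph(n, directed = FALSE)
  for (a in which(diag(M) > prune)) {
    mem <- which(M[a, ] > prune)
    for (m in mem) g <- igraph::add_edges(g, c(a, m))
  }
  for (v in seq_len(n)) {
    rows <- which(M[, v] > prune)
    if (length(rows)) g <- igraph::add_edges(g, c(rows[1], v))
  }
  igraph::components(g)$membership
}

# partitions equal up to relabelling
same_partition <- function(p1, p2) {
  length(p1) == length(p2) &&
    all(outer(p1, p1, "==") == outer(p2, p2, "=="))
}

# standard-code translation via an independent codon-table lookup
translate_oracle <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(cds) %/% 3
  if (n == 0) return("")
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- ifelse(grepl("[^ACGT]", codons), "X",
               unname(code[codons]))
  aa[is.na(aa)] <- "X"
  p <- paste(aa, collapse = "")
  sub("\\*$", "", p)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
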