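# Small programmatic fixtures shared across tests.

write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]])))
  writeLines(lines, path)
  path
}

# one-exon gene rows -> GFF3 (genes: data.frame id, start0, end0, strand)
write_gff3 <- function(genes, chrom, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines,
      sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              chrom, g$start0 + 1, g$end0, g$strand, g$id),
      sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              chrom, g$start0 + 1, g$end0, g$strand, g$id, g$id),
      sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c;Parent=%s.t1",
              chrom, g$start0 + 1, g$end0, g$strand, g$id, g$id))
  }
  writeLines(lines, path)
  path
}

# a fabricated sketch with chosen hash values
fake_sketch <- function(hashes, k = 21, sketch_size = length(hashes)) {
  structure(list(species = "x", k = k, sketch_size = sketch_size,
                 hashes = sort(unique(hashes))), class = "tc_sketch")
}

# minimal gene table for pairing/homology tests
gene_row <- function(id, chrom, start, end, rank, protein = "M",
                     strand = "+") {
  data.frame(gene_id = id, chrom = chrom, start = start, end = end,
             strand = strand, rank = rank, protein = protein,
             stringsAsFactors = FALSE)
}

# boundary-region table row
region_row <- function(id, species, chrom, start, end, source_edges = 1) {
  data.frame(boundary_id = id, species = species, chrom = chrom,
             start = start, end = end, source_edges = source_edges,
             stringsAsFactors = FALSE)
}

# random protein string
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

nodes_df <- function(ids) {
  data.frame(boundary_id = ids,
             species = vapply(strsplit(ids, "|", fixed = TRUE), `[`,
                              character(1), 1),
             chrom = "c", start = 0, end = 1, source_edges = 1L,
             stringsAsFactors = FALSE)
}

pair_df <- function(a, b, w = 1) {
  data.frame(boundary_a = a, boundary_b = b,
             species_a = sub("\\|.*", "", a),
             species_b = sub("\\|.*", "", b),
             evidence = "sequence", weight = w, stringsAsFactors = FALSE)
}

# tc_graph straight from an adjacency matrix (unit species per node)
graph_from_adj <- function(adj) {
  ids <- paste0("s", seq_len(nrow(adj)), "|b")
  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  pairs <- pair_df(ids[edges[, 1]], ids[edges[, 2]],
                   adj[edges])
  build_graph(nodes_df(ids), pairs)
}

# small two-species clade used by pipeline smoke tests (fast to build)
small_clade <- function(dir, seed = 7, n_species = 2) {
  generate_clade(sim_params(
    n_species = n_species, genome_length = 600000, n_genes = 60,
    n_tads = 10, sub_rate = 0.01, n_inversions = 1,
    n_translocations = 0, n_duplications = 1, p_gain = 0.1,
    p_loss = 0, seed = seed), dir = dir)
}
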