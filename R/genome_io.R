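#' Load a species manifest
#'
#' A manifest lists, per species, the genome FASTA, the GFF3 annotation and
#' the TAD interval file. Two dialects are accepted: a TSV with header
#' `species fasta gff tad [radius]`, or a YAML file with a top-level
#' `species:` list whose entries carry `id`, `fasta`, `gff`, `tad` and an
#' optional `radius`. Relative paths are resolved against the manifest's
#' own directory. The optional radius column overrides the global boundary
#' radius for that species only.
#'
#' @param path path to the manifest file (`.tsv`/`.txt` or `.yml`/`.yaml`)
#' @param check_files verify that every referenced file exists (default TRUE)
#' @return an object of class `tc_manifest`: a data.frame with one row per
#'   species and columns `species`, `fasta`, `gff`, `tad`, `radius`
#'   (NA where not set)
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  base <- dirname(normalizePath(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    sp <- y$species
    if (is.null(sp)) stop("YAML manifest needs a top-level 'species' list")
    m <- do.call(rbind, lapply(sp, function(e) {
      data.frame(species = as.character(e$id),
                 fasta = as.character(e$fasta),
                 gff = as.character(e$gff),
                 tad = as.character(e$tad),
                 radius = if (is.null(e$radius)) NA_real_ else as.numeric(e$radius),
                 stringsAsFactors = FALSE)
    }))
  } else {
    m <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
    need <- c("species", "fasta", "gff", "tad")
    miss <- setdiff(need, names(m))
    if (length(miss))
      stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
    if (!"radius" %in% names(m)) m$radius <- NA_real_
    m <- m[, c(need, "radius")]
    m$radius <- as.numeric(m$radius)
  }
  validate_manifest(m, base = base, check_files = check_files)
}

validate_manifest <- function(m, base = ".", check_files = TRUE) {
  if (nrow(m) < 1) stop("manifest has no species")
  bad <- grepl("[|[:space:]]", m$species) | nchar(m$species) == 0
  if (any(bad))
    stop("species_id must be non-empty without whitespace or '|': ",
         paste(m$species[bad], collapse = ", "))
  dup <- duplicated(m$species)
  if (any(dup))
    stop("duplicate species_id in manifest: ",
         paste(unique(m$species[dup]), collapse = ", "))
  resolve <- function(p) ifelse(grepl("^(/|~)", p), p, file.path(base, p))
  for (col in c("fasta", "gff", "tad")) {
    m[[col]] <- resolve(m[[col]])
    if (check_files) {
      missing <- !file.exists(m[[col]])
      if (any(missing))
        stop("missing ", col, " file for species ",
             paste(m$species[missing], collapse = ", "), ": ",
             paste(m[[col]][missing], collapse = ", "))
    }
  }
  if (any(!is.na(m$radius) & m$radius <= 0))
    stop("per-species radius must be positive")
  rownames(m) <- NULL
  class(m) <- c("tc_manifest", "data.frame")
  m
}

#' @export
print.tc_manifest <- function(x, ...) {
  cat("Species manifest:", nrow(x), "species\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a manifest back to TSV
#'
#' Inverse of [load_manifest()] for the TSV dialect; the radius column is
#' only written when at least one species sets it.
#'
#' @param manifest a `tc_manifest`
#' @param path output path
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  if (all(is.na(df$radius))) df$radius <- NULL
  write_tsv(df, path)
}

#' Clean a raw sequence header into a species-prefixed chromosome name
#'
#' Keeps the first whitespace-delimited token of a FASTA header and
#' prefixes it with the species identifier, giving globally unique
#' chromosome names of the form `"hs|chr1"`.
#'
#' @param raw_name raw header(s)
#' @param species_id species identifier (no whitespace, no `|`)
#' @return cleaned name(s)
#' @export
#' @examples
#' clean_chrom_name("chr1 primary assembly", "hs")
clean_chrom_name <- function(raw_name, species_id) {
  stopifnot(length(species_id) == 1, !grepl("[|[:space:]]", species_id),
            nzchar(species_id))
  tok <- sub("[[:space:]].*$", "", trimws(raw_name))
  if (any(!nzchar(tok))) stop("empty chromosome token after cleaning")
  paste0(species_id, "|", tok)
}

#' Read and index a genome FASTA
#'
#' Loads all sequences, cleans their names with [clean_chrom_name()] and
#' records lengths.
#'
#' @param fasta_path genome FASTA
#' @param species_id species identifier used as name prefix
#' @return a `tc_genome` list: `species`, `seqs` (a `DNAStringSet` with
#'   cleaned names), `lengths` (named integer vector)
#' @export
read_genome <- function(fasta_path, species_id) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- clean_chrom_name(names(seqs), species_id)
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names after cleaning in ", fasta_path)
  if (any(Biostrings::width(seqs) == 0))
    stop("zero-length sequence in ", fasta_path)
  structure(list(species = species_id, seqs = seqs,
                 lengths = stats::setNames(Biostrings::width(seqs),
                                           names(seqs))),
            class = "tc_genome")
}

#' @export
print.tc_genome <- function(x, ...) {
  cat("Genome [", x$species, "]: ", length(x$seqs), " sequence(s), ",
      format(sum(as.numeric(x$lengths)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Extract one representative protein per gene from a genome + GFF3
#'
#' Walks the gene -> mRNA -> CDS hierarchy of a GFF3 file, picks the
#' representative isoform per gene (largest summed CDS length, ties broken
#' by the lexicographically smallest mRNA id), concatenates its CDS in
#' transcription order, reverse-complements minus-strand genes and
#' translates with the standard code. A trailing stop codon is removed;
#' internal stops are kept (reported via a message) so that pseudogenised
#' fixtures still yield searchable products. Codons containing N translate
#' to `X`. Genes without CDS, or with CDS outside the chromosome, are
#' skipped with a warning.
#'
#' All coordinates in the result are 0-based half-open; GFF3's 1-based
#' inclusive convention is converted on read.
#'
#' @param genome a `tc_genome` from [read_genome()]
#' @param gff_path GFF3 annotation path (chromosome names must match the
#'   raw FASTA headers' first token)
#' @return data.frame of gene models: `gene_id` (species-prefixed),
#'   `chrom` (cleaned), `start`, `end`, `strand`, `rank` (0-based ordinal
#'   along the chromosome by start), `protein`
#' @export
extract_proteins <- function(genome, gff_path) {
  sp <- genome$species
  gr <- rtracklayer::import(gff_path, format = "gff3")
  typ <- tolower(as.character(gr$type))
  is_gene <- typ == "gene"
  is_mrna <- typ %in% c("mrna", "transcript")
  is_cds <- typ == "cds"
  if (!any(is_gene) || !any(is_cds))
    stop("GFF3 lacks gene/CDS features: ", gff_path)

  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) as.character(v[[1]]) else NA_character_, character(1))

  genes <- gr[is_gene]
  mrna <- gr[is_mrna]
  cds <- gr[is_cds]
  mrna_parent <- first_parent(mrna$Parent)
  cds_parent <- first_parent(cds$Parent)

  cds_by_mrna <- split(seq_along(cds), cds_parent)
  mrna_ids <- as.character(mrna$ID)

  out <- vector("list", length(genes))
  skipped <- character(0)
  n_internal_stop <- 0L

  for (i in seq_along(genes)) {
    gid <- as.character(genes$ID[i])
    chrom_raw <- as.character(GenomicRanges::seqnames(genes)[i])
    chrom <- clean_chrom_name(chrom_raw, sp)
    if (!chrom %in% names(genome$seqs)) {
      skipped <- c(skipped, gid)
      next
    }
    clen <- genome$lengths[[chrom]]
    kids <- mrna_ids[mrna_parent == gid]
    kids <- kids[kids %in% names(cds_by_mrna)]
    if (!length(kids)) {
      skipped <- c(skipped, gid)
      next
    }
    # representative isoform: longest summed CDS, tie -> smallest mRNA id
    lens <- vapply(kids, function(m)
      sum(GenomicRanges::width(cds[cds_by_mrna[[m]]])), numeric(1))
    kids <- sort(kids[lens == max(lens)])
    rep_id <- kids[1]
    cpart <- cds[cds_by_mrna[[rep_id]]]
    st <- as.character(GenomicRanges::strand(cpart)[1])
    if (!st %in% c("+", "-")) st <- "+"
    cpart <- cpart[order(GenomicRanges::start(cpart))]
    s0 <- GenomicRanges::start(cpart) - 1L  # to 0-based half-open
    e0 <- GenomicRanges::end(cpart)
    if (any(s0 < 0) || any(e0 > clen)) {
      warning("CDS outside chromosome for gene ", gid, "; skipped")
      skipped <- c(skipped, gid)
      next
    }
    pieces <- Biostrings::DNAStringSet(genome$seqs[[chrom]],
                                       start = s0 + 1L, end = e0)
    dna <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
    if (st == "-") dna <- Biostrings::reverseComplement(dna)
    prot <- translate_cds(as.character(dna))
    if (!nzchar(prot)) {
      skipped <- c(skipped, gid)
      next
    }
    if (grepl("*", prot, fixed = TRUE)) n_internal_stop <- n_internal_stop + 1L
    gstart <- min(s0)
    gend <- max(e0)
    out[[i]] <- data.frame(
      gene_id = paste0(sp, "|", gid), chrom = chrom,
      start = gstart, end = gend, strand = st,
      protein = prot, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(length(skipped), " gene(s) skipped (no usable CDS): ",
            paste(utils::head(skipped, 5), collapse = ", "))
  if (n_internal_stop > 0)
    message(n_internal_stop, " protein(s) contain internal stop codons")
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    return(empty_df(gene_id = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0),
                    strand = character(0), rank = integer(0),
                    protein = character(0)))
  res <- res[order(res$chrom, res$start, res$gene_id), , drop = FALSE]
  res$rank <- NA_integer_
  for (ch in unique(res$chrom)) {
    ix <- which(res$chrom == ch)
    res$rank[ix[order(res$start[ix], res$gene_id[ix])]] <-
      seq_along(ix) - 1L
  }
  rownames(res) <- NULL
  res[, c("gene_id", "chrom", "start", "end", "strand", "rank", "protein")]
}

#' Translate a CDS nucleotide string with the standard code
#'
#' Codons containing characters other than A/C/G/T translate to `X`;
#' a trailing stop is dropped; an incomplete final codon is ignored.
#'
#' @param cds nucleotide string (already in coding orientation)
#' @return amino-acid string
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  cds <- substr(cds, 1L, 3L * n)
  if (grepl("[^ACGT]", cds)) {
    codons <- substring(cds, seq(1L, 3L * n, by = 3L), seq(3L, 3L * n, by = 3L))
    ok <- !grepl("[^ACGT]", codons)
    aa <- rep("X", n)
    if (any(ok)) {
      aa[ok] <- vapply(codons[ok], function(cd)
        as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                           no.init.codon = TRUE)),
        character(1))
    }
    prot <- paste(aa, collapse = "")
  } else {
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                               no.init.codon = TRUE))
  }
  sub("\\*$", "", prot)
}

#' Read TAD intervals from a BED-like file
#'
#' Expects at least three columns (chrom, start, end; 0-based half-open);
#' extra columns are ignored. Chromosome names are cleaned and
#' species-prefixed. Rows with `end <= start` raise an error naming the
#' offending line.
#'
#' @param tad_path BED path
#' @param genome `tc_genome` used to validate chromosome names and bounds
#' @return data.frame `species`, `chrom`, `start`, `end`
#' @export
read_tads <- function(tad_path, genome) {
  raw <- utils::read.table(tad_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 3) stop("TAD file needs >= 3 columns: ", tad_path)
  df <- data.frame(species = genome$species,
                   chrom = clean_chrom_name(raw[[1]], genome$species),
                   start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]]),
                   stringsAsFactors = FALSE)
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("TAD file ", tad_path, ": end <= start at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  unknown <- !df$chrom %in% names(genome$seqs)
  if (any(unknown))
    stop("TAD file references unknown chromosome(s): ",
         paste(unique(df$chrom[unknown]), collapse = ", "))
  over <- df$end > genome$lengths[df$chrom] | df$start < 0
  if (any(over))
    stop("TAD interval outside chromosome at line(s) ",
         paste(utils::head(which(over), 5), collapse = ", "))
  df
}
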