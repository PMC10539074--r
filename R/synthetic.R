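#' Parameters for the synthetic clade generator
#'
#' The generator simulates an ancestor genome with uniformly spaced genes
#' and a contiguous run of TADs, then evolves each species independently
#' along a star phylogeny: nucleotide substitutions, inversions,
#' translocations and duplications of whole-TAD segments (breakpoints
#' never split genes), and TAD-boundary gain/loss. Every TAD edge traces
#' to a ground-truth record.
#'
#' Scale defaults describe a desk-sized clade: 2 Mb genomes carrying 200
#' genes (900 bp single-exon CDS every 10 kb) and 40 TADs of 45 kb tiling
#' the interval from 100 kb to 1.9 Mb. `boundary_radius` is the boundary
#' half-width written into the generated manifest; 5 kb is proportionate
#' to the 45 kb simulated TADs. Gained boundaries are implanted at a
#' species-specific offset inside a TAD, placed so that boundary regions
#' of different species never overlap homologous coordinates (guaranteed
#' for up to 3 species).
#'
#' @param n_species number of species (2-6; offsets guarantee clean
#'   species-specific gains for up to 3)
#' @param genome_length ancestor chromosome length, bp
#' @param n_genes gene count (uniform 10 kb spacing must fit)
#' @param n_tads TAD count (45 kb each, tiled from 100 kb)
#' @param sub_rate per-branch substitution probability per bp
#' @param n_inversions,n_translocations,n_duplications rearrangement
#'   counts applied independently to each species
#' @param p_gain per-TAD probability of gaining a species-specific
#'   boundary
#' @param p_loss per-edge probability of losing an internal boundary
#' @param seed RNG seed; identical params + seed give byte-identical
#'   output
#' @param boundary_radius boundary half-width recorded in the manifest, bp
#' @return a list of class `tc_sim_params`
#' @export
sim_params <- function(n_species = 3, genome_length = 2e6, n_genes = 200,
                       n_tads = 40, sub_rate = 0.02, n_inversions = 2,
                       n_translocations = 1, n_duplications = 1,
                       p_gain = 0.1, p_loss = 0.05, seed = 42,
                       boundary_radius = 5000) {
  p <- list(n_species = n_species, genome_length = genome_length,
            n_genes = n_genes, n_tads = n_tads, sub_rate = sub_rate,
            n_inversions = n_inversions,
            n_translocations = n_translocations,
            n_duplications = n_duplications, p_gain = p_gain,
            p_loss = p_loss, seed = seed,
            boundary_radius = boundary_radius)
  stopifnot(p$n_species >= 1, p$n_species <= 6,
            p$sub_rate >= 0, p$sub_rate <= 1,
            p$p_gain >= 0, p$p_gain <= 1, p$p_loss >= 0, p$p_loss <= 1,
            p$n_inversions >= 0, p$n_translocations >= 0,
            p$n_duplications >= 0)
  if (p$n_genes * 10000 > p$genome_length)
    stop("genes x spacing exceed genome length")
  if (100000 + p$n_tads * 45000 > p$genome_length)
    stop("TAD run exceeds genome length")
  class(p) <- "tc_sim_params"
  p
}

# ---- coordinate remapping through rearrangements ------------------------

#' Remap an interval through a list of rearrangements
#'
#' Applies inversions, translocations and duplications in order to
#' 0-based half-open coordinates. A duplication yields both copies. An
#' interval spanning a breakpoint is assigned to its larger fragment
#' (reported via a message). Each rearrangement is a list with `type`
#' (`"inv"`, `"trans"`, `"dup"`), breakpoints `a` < `b`, and for
#' translocation/duplication an insertion point `c` outside `[a, b]`.
#'
#' @param interval numeric `c(start, end)`, 0-based half-open
#' @param ops list of rearrangement records
#' @return matrix with columns `start`, `end`; one row per image
#' @export
remap_interval <- function(interval, ops) {
  cur <- matrix(interval, ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  for (op in ops) {
    nxt <- list()
    for (r in seq_len(nrow(cur)))
      nxt[[r]] <- remap_interval_one(cur[r, ], op)
    cur <- do.call(rbind, nxt)
  }
  cur
}

# largest fragment of [s,e) after cutting at the sorted cut points
larger_fragment <- function(s, e, cuts) {
  cuts <- sort(unique(c(s, cuts[cuts > s & cuts < e], e)))
  w <- diff(cuts)
  i <- which.max(w)
  message("interval [", s, ",", e, ") spans a breakpoint; keeping ",
          "fragment [", cuts[i], ",", cuts[i + 1], ")")
  c(cuts[i], cuts[i + 1])
}

remap_interval_one <- function(iv, op) {
  s <- iv[[1]]; e <- iv[[2]]
  a <- op$a; b <- op$b; len <- b - a
  if (op$type == "inv") {
    if (e <= a || s >= b)
      return(matrix(c(s, e), 1, dimnames = list(NULL, c("start", "end"))))
    if (s >= a && e <= b)
      return(matrix(c(a + b - e, a + b - s), 1,
                    dimnames = list(NULL, c("start", "end"))))
    f <- larger_fragment(s, e, c(a, b))
    return(remap_interval_one(f, op))
  }
  cpr <- if (op$c >= b) op$c - len else op$c  # insertion pos after removal
  if (op$type == "trans") {
    if (s >= a && e <= b) {  # moves with the segment
      ns <- cpr + (s - a)
      return(matrix(c(ns, ns + (e - s)), 1,
                    dimnames = list(NULL, c("start", "end"))))
    }
    if (e > a && s < b || (s < op$c && e > op$c)) {
      f <- larger_fragment(s, e, c(a, b, op$c))
      return(remap_interval_one(f, op))
    }
    q <- if (s >= b) s - len else s
    shift <- if (q >= cpr) len else 0
    return(matrix(c(q + shift, q + shift + (e - s)), 1,
                  dimnames = list(NULL, c("start", "end"))))
  }
  if (op$type == "dup") {
    spans_c <- s < op$c && e > op$c
    inside <- s >= a && e <= b
    partial <- !inside && e > a && s < b
    if (partial || spans_c) {
      f <- larger_fragment(s, e, c(a, b, op$c))
      return(remap_interval_one(f, op))
    }
    shift <- if (s >= op$c) len else 0
    out <- matrix(c(s + shift, e + shift), 1,
                  dimnames = list(NULL, c("start", "end")))
    if (inside) {
      cs <- op$c + (s - a)
      out <- rbind(out, c(cs, cs + (e - s)))
    }
    return(out)
  }
  stop("unknown rearrangement type: ", op$type)
}

# remap a breakpoint of a LATER rearrangement: the position of the
# non-moved material at a cut point. Unlike remap_point, a point equal to
# a previous segment end follows the flanking material (excision
# junction / original copy), never the moved or duplicated segment.
remap_breakpoint <- function(p, ops) {
  x <- p
  for (op in ops) {
    a <- op$a; b <- op$b; len <- b - a
    if (op$type == "inv") {
      if (x > a && x < b) x <- a + b - x
    } else if (op$type == "trans") {
      cpr <- if (op$c >= b) op$c - len else op$c
      if (x > a && x < b)
        stop("breakpoint inside a previously moved segment")
      q <- if (x >= b) x - len else x
      x <- q + if (q > cpr) len else 0
    } else if (op$type == "dup") {
      x <- x + if (x > op$c) len else 0
    }
  }
  x
}

# remap a cut point (edge position); duplication may return two images
remap_point <- function(p, ops) {
  cur <- p
  for (op in ops) {
    a <- op$a; b <- op$b; len <- b - a
    nxt <- numeric(0)
    for (x in cur) {
      if (op$type == "inv") {
        nxt <- c(nxt, if (x > a && x < b) a + b - x else x)
      } else if (op$type == "trans") {
        cpr <- if (op$c >= b) op$c - len else op$c
        if (x >= a && x <= b) nxt <- c(nxt, cpr + (x - a))
        else {
          q <- if (x > b) x - len else x
          nxt <- c(nxt, q + if (q > cpr) len else 0)
        }
      } else if (op$type == "dup") {
        base <- x + if (x > op$c) len else 0
        nxt <- c(nxt, base)
        if (x >= a && x <= b) nxt <- c(nxt, op$c + (x - a))
      } else stop("unknown rearrangement type")
    }
    cur <- nxt
  }
  unique(cur)
}

# ---- sequence helpers ---------------------------------------------------

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

apply_op_seq <- function(s, op) {
  n <- nchar(s)
  a <- op$a; b <- op$b
  seg <- substr(s, a + 1, b)
  if (op$type == "inv")
    return(paste0(substr(s, 1, a), revcomp_str(seg), substr(s, b + 1, n)))
  if (op$type == "trans") {
    rest <- paste0(substr(s, 1, a), substr(s, b + 1, n))
    cpr <- if (op$c >= b) op$c - (b - a) else op$c
    return(paste0(substr(rest, 1, cpr), seg,
                  substr(rest, cpr + 1, nchar(rest))))
  }
  if (op$type == "dup")
    return(paste0(substr(s, 1, op$c), seg, substr(s, op$c + 1, n)))
  stop("unknown rearrangement type")
}

random_cds <- function(n_codons) {
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1, paste, collapse = "")
  body <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(body, n_codons - 2, replace = TRUE),
                      collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  nmut <- stats::rbinom(1, n, rate)
  if (nmut == 0) return(s)
  pos <- sample.int(n, nmut)
  bases <- c("A", "C", "G", "T")
  cur <- match(v[pos], bases)
  v[pos] <- bases[((cur - 1 + sample.int(3, nmut, replace = TRUE)) %% 4) + 1]
  paste(v, collapse = "")
}

# ---- the generator ------------------------------------------------------

#' Generate a synthetic clade with ground-truth boundary labels
#'
#' Simulates the ancestor, evolves each species (see [sim_params()]) and
#' writes per-species FASTA, GFF3 and TAD BED files plus a manifest TSV
#' and a ground-truth TSV into `dir`.
#'
#' Rearrangement breakpoints are drawn on a 5 kb grid aligned with TAD
#' edges, so segments move whole TADs and never split genes;
#' translocations and duplications insert their segment into the interior
#' of a separate host TAD. Gains are implanted at a species-specific
#' offset inside TADs that are not rearrangement hosts. Gained and lost
#' boundaries, and every image of every ancestral edge (duplications give
#' two), are recorded in the truth table.
#'
#' @param params a `tc_sim_params` from [sim_params()]
#' @param dir output directory (created if needed)
#' @return list with `manifest` (a `tc_manifest`), `truth` (data.frame
#'   `edge_id`, `type` in `ancestral`/`gained`, `species`, `pos`),
#'   `params`, and `dir`
#' @export
generate_clade <- function(params = sim_params(), dir = tempfile("clade")) {
  stopifnot(inherits(params, "tc_sim_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(params$seed)
  L <- params$genome_length
  tad_len <- 45000
  tad0 <- 100000
  edges_anc <- tad0 + tad_len * (0:params$n_tads)
  n_sp <- params$n_species
  species <- paste0("sp", seq_len(n_sp))

  # ancestor genome with genes written in
  anc <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  gene_len <- 900
  genes <- data.frame(
    id = sprintf("g%04d", seq_len(params$n_genes)),
    start = (seq_len(params$n_genes) - 1) * 10000 + 3000,
    stringsAsFactors = FALSE)
  genes$end <- genes$start + gene_len
  genes$strand <- sample(c("+", "-"), params$n_genes, replace = TRUE)
  for (i in seq_len(nrow(genes))) {
    cds <- random_cds(gene_len / 3)
    if (genes$strand[i] == "-") cds <- revcomp_str(cds)
    substr(anc, genes$start[i] + 1, genes$end[i]) <- cds
  }

  # species-specific gain offsets inside a TAD, >= 10.5 kb from both TAD
  # edges and pairwise separated so 5 kb boundary regions never overlap
  # across species at homologous coordinates (clean for n_species <= 3)
  gain_off <- if (n_sp == 1) 22500 else
    round((10500 + (seq_len(n_sp) - 1) * 24000 / (n_sp - 1)) / 500) * 500

  truth <- list()
  manifest_rows <- list()

  # choose every species' rearrangement plan first: gains must avoid TADs
  # that host an insertion in ANY species, or a gained region could
  # overlap homologous coordinates of another species' insertion junction
  plans <- vector("list", n_sp)
  hosts_all <- integer(0)
  for (si in seq_len(n_sp)) {
    used <- integer(0)
    pick_run <- function(len) {
      for (try in 1:200) {
        s0 <- sample(2:(params$n_tads - len), 1)
        idx <- s0:(s0 + len - 1)
        if (!any(idx %in% used)) {
          used <<- c(used, idx)
          return(idx)
        }
      }
      stop("cannot place rearrangement segment; too many for n_tads")
    }
    plan <- list()
    for (k in seq_len(params$n_inversions))
      plan[[length(plan) + 1]] <- list(type = "inv",
                                       run = pick_run(sample(2:4, 1)))
    for (k in seq_len(params$n_translocations)) {
      run <- pick_run(sample(1:2, 1))
      host <- pick_run(1)
      hosts_all <- union(hosts_all, host)
      plan[[length(plan) + 1]] <- list(type = "trans", run = run,
                                       host = host)
    }
    for (k in seq_len(params$n_duplications)) {
      run <- pick_run(1)
      host <- pick_run(1)
      hosts_all <- union(hosts_all, host)
      plan[[length(plan) + 1]] <- list(type = "dup", run = run, host = host)
    }
    plans[[si]] <- plan
  }

  for (si in seq_len(n_sp)) {
    sp <- species[si]
    g <- mutate_seq(anc, params$sub_rate)
    sp_genes <- genes
    plan <- plans[[si]]

    # gains and losses decided in ancestral coordinates
    internal <- 2:params$n_tads  # internal ancestral edge indices
    lost <- internal[stats::runif(length(internal)) < params$p_loss]
    gain_ok <- setdiff(seq_len(params$n_tads), hosts_all)
    gained_tads <- gain_ok[stats::runif(length(gain_ok)) < params$p_gain]
    gain_pos_anc <- edges_anc[gained_tads] + gain_off[si]

    # apply rearrangements sequentially; breakpoints are ancestral
    # positions remapped through the ops already applied
    ops <- list()
    cur_pt <- function(p) remap_breakpoint(p, ops)
    for (pl in plan) {
      A <- edges_anc[pl$run[1]]
      B <- edges_anc[pl$run[length(pl$run)] + 1]
      op <- list(type = pl$type, a = cur_pt(A), b = cur_pt(B))
      if (pl$type != "inv") {
        Cc <- edges_anc[pl$host] + 17500  # host TAD interior, off-grid
        op$c <- cur_pt(Cc)
      }
      ops[[length(ops) + 1]] <- op
      g <- apply_op_seq(g, op)
    }

    # remap genes (duplication may copy them)
    rows <- lapply(seq_len(nrow(sp_genes)), function(i) {
      iv <- remap_interval(c(sp_genes$start[i], sp_genes$end[i]), ops)
      strand <- sp_genes$strand[i]
      # inversion containment flips strand; detect by checking whether the
      # original midpoint ended up mirrored an odd number of times
      st <- strand_after_ops(c(sp_genes$start[i], sp_genes$end[i]), ops)
      data.frame(id = if (nrow(iv) == 1) sp_genes$id[i] else
        paste0(sp_genes$id[i], c("", letters[seq_len(nrow(iv) - 1)])),
        start = iv[, "start"], end = iv[, "end"],
        strand = st, stringsAsFactors = FALSE)
    })
    sp_genes <- do.call(rbind, rows)

    # remap boundary edges. An inversion junction carries the outer flank
    # of one end edge and the mirrored inner flank of the other, so each
    # end edge of an inverted segment descends to both junction positions.
    src_pos <- as.list(edges_anc)
    for (pl in plan) {
      if (pl$type != "inv") next
      i <- pl$run[1]
      j <- pl$run[length(pl$run)] + 1
      src_pos[[i]] <- c(src_pos[[i]], edges_anc[j])
      src_pos[[j]] <- c(src_pos[[j]], edges_anc[i])
    }
    kept <- setdiff(seq_along(edges_anc), lost)
    for (ei in kept) {
      imgs <- unique(unlist(lapply(src_pos[[ei]], remap_point, ops = ops)))
      for (p in imgs)
        truth[[length(truth) + 1]] <- data.frame(
          edge_id = sprintf("anc_e%02d", ei - 1), type = "ancestral",
          species = sp, pos = p, stringsAsFactors = FALSE)
    }
    for (k in seq_along(gain_pos_anc)) {
      imgs <- remap_point(gain_pos_anc[k], ops)
      for (p in imgs)
        truth[[length(truth) + 1]] <- data.frame(
          edge_id = sprintf("gain_%s_%02d", sp, k), type = "gained",
          species = sp, pos = p, stringsAsFactors = FALSE)
    }

    # emit files
    sp_truth <- do.call(rbind, truth[vapply(truth, function(t)
      t$species == sp, logical(1))])
    edge_pos <- sort(unique(sp_truth$pos))
    tads <- data.frame(chrom = "chr1",
                       start = utils::head(edge_pos, -1),
                       end = utils::tail(edge_pos, -1))
    fa <- file.path(dir, paste0(sp, ".fa"))
    writeLines(c(paste0(">chr1 ", sp, " synthetic chromosome"),
                 substring(g, seq(1, nchar(g), 70),
                           pmin(seq(70, nchar(g) + 69, 70), nchar(g)))),
               fa)
    gff <- file.path(dir, paste0(sp, ".gff3"))
    write_sim_gff3(sp_genes, "chr1", gff)
    bed <- file.path(dir, paste0(sp, ".bed"))
    utils::write.table(tads, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    manifest_rows[[si]] <- data.frame(
      species = sp, fasta = fa, gff = gff, tad = bed,
      radius = params$boundary_radius, stringsAsFactors = FALSE)
  }

  manifest <- validate_manifest(do.call(rbind, manifest_rows))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  write_tsv(truth, file.path(dir, "truth.tsv"))
  list(manifest = manifest, truth = truth, params = params, dir = dir)
}

# net strand flip for an interval fully inside/outside each inversion
strand_after_ops <- function(iv, ops) {
  flips <- 0L
  cur <- matrix(iv, ncol = 2)
  for (op in ops) {
    if (op$type == "inv" && cur[1, 1] >= op$a && cur[1, 2] <= op$b)
      flips <- flips + 1L
    cur <- remap_interval_one(cur[1, ], op)
  }
  if (flips %% 2 == 1) "-" else "+"
}

write_sim_gff3 <- function(genes, chrom, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    gid <- genes$id[i]
    s1 <- genes$start[i] + 1  # to 1-based inclusive
    e1 <- genes$end[i]
    st <- genes$strand[i]
    lines <- c(lines,
      paste(chrom, "tcsim", "gene", s1, e1, ".", st, ".",
            paste0("ID=", gid), sep = "\t"),
      paste(chrom, "tcsim", "mRNA", s1, e1, ".", st, ".",
            paste0("ID=", gid, ".t1;Parent=", gid), sep = "\t"),
      paste(chrom, "tcsim", "CDS", s1, e1, ".", st, "0",
            paste0("ID=", gid, ".cds;Parent=", gid, ".t1"), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Map ground-truth edge positions to pipeline boundary ids
#'
#' Each truth record's position is located inside the boundary region
#' that contains it (positions are always covered, since regions are the
#' radius-expansion of the very same edges).
#'
#' @param truth truth table from [generate_clade()]
#' @param boundaries row-bound boundary regions of all species
#' @return truth with a `boundary_id` column added
#' @export
truth_boundaries <- function(truth, boundaries) {
  truth$boundary_id <- NA_character_
  for (sp in unique(truth$species)) {
    b <- boundaries[boundaries$species == sp, , drop = FALSE]
    ti <- which(truth$species == sp)
    hit <- vapply(truth$pos[ti], function(p) {
      j <- which(b$start <= p & p < b$end)
      if (length(j) >= 1) b$boundary_id[j[1]] else NA_character_
    }, character(1))
    truth$boundary_id[ti] <- hit
  }
  truth
}

#' Score pipeline output against the generator's ground truth
#'
#' A truth group (ancestral edge) is pan-conserved when every species
#' retains at least one descendant boundary. Such a group counts as
#' recovered when a single conserved-class cluster contains at least one
#' of its descendant boundaries from every species. An implanted gained
#' boundary counts as correctly labelled when its boundary sits in a
#' specific-class cluster.
#'
#' @param truth truth table with `boundary_id` (see [truth_boundaries()])
#' @param membership cluster membership from [mcl_cluster()]
#' @param clusters classified clusters from [classify_clusters()]
#' @param species all species in the run
#' @return list: `n_pan`, `n_pan_recovered`, `pan_recovery`,
#'   `n_gained`, `n_gained_specific`, `gained_specific_rate`
#' @export
evaluate_recovery <- function(truth, membership, clusters, species) {
  cl_of <- stats::setNames(membership$cluster_id, membership$boundary_id)
  class_of <- stats::setNames(clusters$class, clusters$cluster_id)
  anc <- truth[truth$type == "ancestral" & !is.na(truth$boundary_id), ]
  pan_ids <- names(which(tapply(anc$species, anc$edge_id, function(s)
    length(unique(s))) == length(species)))
  rec <- vapply(pan_ids, function(eid) {
    rows <- anc[anc$edge_id == eid, ]
    cl <- cl_of[rows$boundary_id]
    # clusters holding >= 1 member of every species for this group
    ok <- vapply(unique(cl), function(cc)
      length(unique(rows$species[cl == cc])) == length(species) &&
        identical(unname(class_of[cc]), "conserved"), logical(1))
    any(ok)
  }, logical(1))
  gain <- truth[truth$type == "gained" & !is.na(truth$boundary_id), ]
  gain_groups <- unique(gain[, c("edge_id", "species")])
  gspec <- vapply(seq_len(nrow(gain_groups)), function(i) {
    rows <- gain[gain$edge_id == gain_groups$edge_id[i], ]
    all(class_of[cl_of[rows$boundary_id]] == "specific")
  }, logical(1))
  list(n_pan = length(pan_ids), n_pan_recovered = sum(rec),
       pan_recovery = if (length(pan_ids)) mean(rec) else NA_real_,
       n_gained = nrow(gain_groups), n_gained_specific = sum(gspec),
       gained_specific_rate = if (nrow(gain_groups)) mean(gspec)
       else NA_real_)
}
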