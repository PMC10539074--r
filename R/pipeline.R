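#' Run the full boundary-conservation pipeline
#'
#' Executes the stages in order: (1) per-species preprocessing (genome
#' and annotation read, protein extraction, TAD edge merging, boundary
#' sequence extraction), (2) genome sketching and alignment-preset
#' selection, (3) per-species-pair evidence collection (collinear gene
#' anchors and boundary-sequence alignment) integrated into undirected
#' weighted boundary pairs, (4) boundary-graph construction, MCL
#' clustering, classification and profile export.
#'
#' Each stage caches its result under `outdir/cache/` keyed by a hash of
#' the configuration; rerunning with an unchanged configuration reuses
#' the caches and reproduces byte-identical outputs.
#'
#' @param manifest a `tc_manifest` from [load_manifest()] (>= 2 species)
#' @param outdir output directory
#' @param radius boundary half-width in bp (default 20000); a manifest
#'   `radius` column overrides it per species
#' @param min_align_len alignment length filter in bp (default 2000,
#'   strict inequality)
#' @param inflation MCL inflation (default 2)
#' @param conserved_min_species species needed for the conserved class
#'   (default: all)
#' @param backend_homology,backend_align `"builtin"` or `"external"`
#' @param min_overlap minimum hit/boundary overlap in bp (default 1)
#' @param log_weights log-scale edge weights before clustering
#' @param seed RNG seed (logged and set; builtin backends are themselves
#'   deterministic)
#' @param resume reuse stage caches when the configuration is unchanged
#'   (default TRUE)
#' @param verbose print stage progress
#' @return an object of class `tc_run`; see [summary.tc_run()]
#' @export
run_pipeline <- function(manifest, outdir, radius = 20000,
                         min_align_len = 2000, inflation = 2,
                         conserved_min_species = NULL,
                         backend_homology = "builtin",
                         backend_align = "builtin", min_overlap = 1,
                         log_weights = FALSE, seed = 1, resume = TRUE,
                         verbose = TRUE) {
  if (nrow(manifest) < 2)
    stop("cross-species analysis needs at least 2 species")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "cache"), showWarnings = FALSE)
  species <- manifest$species
  conserved_min_species <- conserved_min_species %||% length(species)
  config <- list(manifest = as.data.frame(manifest), radius = radius,
                 min_align_len = min_align_len, inflation = inflation,
                 conserved_min_species = conserved_min_species,
                 backend_homology = backend_homology,
                 backend_align = backend_align, min_overlap = min_overlap,
                 log_weights = log_weights, seed = seed)
  hash <- config_hash(config)
  jsonlite::write_json(c(config["manifest"], config[-1],
                         list(config_hash = hash)),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  set.seed(seed)
  say <- function(...) if (verbose) message("[tadcons] ", ...)
  say("run configuration hash: ", hash, " (seed ", seed, ")")

  stage <- function(name, fun) {
    cache <- file.path(outdir, "cache", paste0(name, ".rds"))
    if (resume && file.exists(cache)) {
      obj <- readRDS(cache)
      if (identical(obj$hash, hash)) {
        say("stage ", name, ": reused cache")
        return(obj$value)
      }
    }
    say("stage ", name, ": running")
    value <- withCallingHandlers(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    saveRDS(list(hash = hash, value = value), cache)
    value
  }

  prep <- stage("preprocess", function() {
    out <- list()
    for (i in seq_len(nrow(manifest))) {
      sp <- manifest$species[i]
      say("  preprocess ", sp)
      genome <- read_genome(manifest$fasta[i], sp)
      genes <- suppressWarnings(extract_proteins(genome, manifest$gff[i]))
      tads <- read_tads(manifest$tad[i], genome)
      r <- if (!is.na(manifest$radius[i])) manifest$radius[i] else radius
      bounds <- boundaries_for_species(tads, genome, radius = r)
      bseq <- boundary_sequences(bounds, genome)
      write_boundary_bed(bounds,
                         file.path(outdir, paste0(sp, ".boundaries.bed")))
      Biostrings::writeXStringSet(bseq,
        file.path(outdir, paste0(sp, ".boundaries.fa")))
      out[[sp]] <- list(genome = genome, genes = genes, tads = tads,
                        boundaries = bounds, bseq = bseq,
                        assign = genes_in_boundary(bounds, genes))
    }
    out
  })

  dist <- stage("distance", function() {
    sketches <- lapply(prep, function(p) sketch_genome(p$genome))
    d <- matrix(0, length(species), length(species),
                dimnames = list(species, species))
    for (a in species) for (b in species) if (a < b) {
      d[a, b] <- d[b, a] <- mash_distance(sketches[[a]], sketches[[b]])
    }
    d
  })

  pairs <- stage("pairs", function() {
    acc <- list()
    for (ia in seq_along(species)) for (ib in seq_along(species)) {
      if (ia >= ib) next
      a <- species[ia]; b <- species[ib]
      say("  pairing ", a, " vs ", b)
      anchors <- protein_homologs(prep[[a]]$genes, prep[[b]]$genes,
                                  backend = backend_homology)
      blocks <- chain_collinear(anchors, prep[[a]]$genes, prep[[b]]$genes)
      idx <- block_anchor_index(blocks)
      syn <- pairs_from_synteny(prep[[a]]$assign, prep[[b]]$assign, idx,
                                prep[[a]]$genes, prep[[b]]$genes)
      preset <- select_preset(dist[a, b])
      say("    mash d=", signif(dist[a, b], 3), " preset=", preset,
          "; synteny anchors=", nrow(anchors), " blocks=", nrow(blocks))
      hits_ab <- filter_hits(align_boundaries(prep[[a]]$bseq,
        prep[[b]]$genome, preset = preset, backend = backend_align),
        min_align_len)
      hits_ba <- filter_hits(align_boundaries(prep[[b]]$bseq,
        prep[[a]]$genome, preset = preset, backend = backend_align),
        min_align_len)
      seq_ab <- pairs_from_sequence(hits_ab, prep[[b]]$boundaries,
                                    min_overlap)
      seq_ba <- pairs_from_sequence(hits_ba, prep[[a]]$boundaries,
                                    min_overlap)
      acc[[paste(a, b)]] <- integrate_pairs(syn, seq_ab, seq_ba)
    }
    res <- do.call(rbind, acc)
    rownames(res) <- NULL
    res
  })
  write_tsv(pairs, file.path(outdir, "pairs.tsv"))

  clus <- stage("cluster", function() {
    all_bounds <- do.call(rbind, lapply(prep, `[[`, "boundaries"))
    graph <- build_graph(all_bounds, pairs, log_weights = log_weights)
    write_abc(graph, file.path(outdir, "graph.abc"))
    membership <- mcl_cluster(graph, inflation = inflation)
    clusters <- classify_clusters(membership, species,
                                  conserved_min_species)
    profile <- profile_matrix(membership, clusters, species)
    list(graph = graph, membership = membership, clusters = clusters,
         profile = profile)
  })
  memb <- merge(clus$membership, clus$clusters[, c("cluster_id", "class")],
                by = "cluster_id")
  memb <- memb[order(memb$cluster_id, memb$boundary_id), ]
  write_tsv(memb, file.path(outdir, "clusters.tsv"))
  write_profile(clus$profile, file.path(outdir, "profile.tsv"))

  summary_tab <- list(
    species = species,
    n_boundaries = vapply(prep, function(p) nrow(p$boundaries),
                          numeric(1)),
    n_pairs = nrow(pairs),
    pairs_by_evidence = as.list(table(pairs$evidence)),
    n_clusters = nrow(clus$clusters),
    clusters_by_class = as.list(table(clus$clusters$class)),
    boundaries_by_class = as.list(tapply(memb$boundary_id, memb$class,
                                         length)),
    config_hash = hash, seed = seed)
  jsonlite::write_json(summary_tab, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  res <- list(outdir = outdir, config = config,
              boundaries = lapply(prep, `[[`, "boundaries"),
              genes = lapply(prep, `[[`, "genes"),
              distances = dist, pairs = pairs, graph = clus$graph,
              membership = clus$membership, clusters = clus$clusters,
              profile = clus$profile, summary = summary_tab)
  class(res) <- "tc_run"
  res
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.tc_run <- function(x, ...) {
  cat("tadcons run (", length(x$summary$species), " species: ",
      paste(x$summary$species, collapse = ", "), ")\n", sep = "")
  cat("  boundaries:",
      paste(paste0(x$summary$species, "=", x$summary$n_boundaries),
            collapse = " "), "\n")
  cat("  pairs:", x$summary$n_pairs, "(",
      paste(names(x$summary$pairs_by_evidence),
            unlist(x$summary$pairs_by_evidence), collapse = ", "), ")\n")
  cat("  clusters:", x$summary$n_clusters, "(",
      paste(names(x$summary$clusters_by_class),
            unlist(x$summary$clusters_by_class), collapse = ", "), ")\n")
  cat("  outputs in:", x$outdir, "\n")
  invisible(x)
}

#' Summarise a pipeline run
#'
#' @param object a `tc_run`
#' @param ... unused
#' @return the run's summary list (per-species boundary counts, pair
#'   counts by evidence, cluster counts by class)
#' @export
summary.tc_run <- function(object, ...) {
  object$summary
}

#' Export the phylogenomic profile and optionally draw the heatmap
#'
#' Writes the cluster-by-species profile TSV and, when the `pheatmap`
#' package is available, renders a clustered heatmap of boundary counts
#' (colour intensity = conservation strength). The TSV is always written;
#' a missing plotting package only produces a warning.
#'
#' @param run a `tc_run` (or a profile matrix from [profile_matrix()])
#' @param path output TSV path
#' @param plot_path optional PNG path for the heatmap
#' @return `path`, invisibly
#' @export
export_heatmap_table <- function(run, path, plot_path = NULL) {
  profile <- if (inherits(run, "tc_run")) run$profile else run
  write_profile(profile, path)
  if (!is.null(plot_path)) {
    if (!requireNamespace("pheatmap", quietly = TRUE)) {
      warning("package 'pheatmap' not available; profile TSV written, ",
              "heatmap skipped")
    } else if (nrow(profile) >= 2 && ncol(profile) >= 2) {
      grDevices::png(plot_path, width = 900, height = 1200, res = 120)
      pheatmap::pheatmap(unclass(profile)[, , drop = FALSE],
                         cluster_cols = FALSE,
                         show_rownames = nrow(profile) <= 60,
                         main = "TAD boundary conservation profile")
      grDevices::dev.off()
    }
  }
  invisible(path)
}
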