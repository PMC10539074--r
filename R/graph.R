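#' Build the multi-species boundary graph
#'
#' Nodes are all boundary regions across species (including unpaired
#' ones, which later become singleton species-specific clusters); edges
#' are the integrated undirected boundary pairs, weighted in bp.
#'
#' @param all_boundaries data.frame row-binding every species' boundary
#'   regions
#' @param pairs integrated pairs from [integrate_pairs()]
#' @param log_weights log-scale the bp weights as `log1p(weight)` before
#'   clustering (default FALSE); raw bp spans several orders of magnitude
#' @return a `tc_graph` list: `nodes` (data.frame with `boundary_id`,
#'   `species`), `edges` (data.frame `from`, `to`, `weight`)
#' @export
build_graph <- function(all_boundaries, pairs, log_weights = FALSE) {
  if (anyDuplicated(all_boundaries$boundary_id))
    stop("boundary ids are not globally unique")
  nodes <- all_boundaries[, c("boundary_id", "species")]
  unknown <- !(pairs$boundary_a %in% nodes$boundary_id &
                 pairs$boundary_b %in% nodes$boundary_id)
  if (any(unknown))
    stop("pair references unknown boundary: ",
         paste(utils::head(unique(c(pairs$boundary_a, pairs$boundary_b)[
           rep(unknown, 2)]), 3), collapse = ", "))
  if (any(pairs$boundary_a == pairs$boundary_b)) stop("self-loop pair")
  w <- pairs$weight
  if (any(w <= 0)) stop("edge weight must be > 0")
  if (log_weights) w <- log1p(w)
  edges <- data.frame(from = pairs$boundary_a, to = pairs$boundary_b,
                      weight = w, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "tc_graph")
}

#' @export
print.tc_graph <- function(x, ...) {
  cat("Boundary graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write a graph as an ABC edge list
#'
#' `node node weight` per line, the interchange format of the canonical
#' MCL tool; isolated nodes are appended as zero-weight self-lines so the
#' node set round-trips.
#'
#' @param graph a `tc_graph`
#' @param path output path
#' @export
write_abc <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(graph$edges))
    writeLines(paste(graph$edges$from, graph$edges$to,
                     format(graph$edges$weight, scientific = FALSE,
                            trim = TRUE)), con)
  iso <- setdiff(graph$nodes$boundary_id,
                 c(graph$edges$from, graph$edges$to))
  if (length(iso)) writeLines(paste(iso, iso, "0"), con)
  invisible(path)
}

#' Markov clustering of the boundary graph
#'
#' Standard MCL on the weighted adjacency matrix. Self-loops are added
#' with the maximum incident edge weight per node (at least 1) to damp
#' odd-cycle parity effects. The column-stochastic matrix is iterated
#' through expansion (matrix self-product) and inflation (entrywise power
#' followed by column renormalisation), pruning entries below
#' `prune_threshold` and renormalising, until the largest column change
#' drops below 1e-8 or `max_iter` is reached. Clusters are the connected
#' components of the attractor-overlap graph: each attractor row (node
#' with positive diagonal mass) groups the nodes it retains mass on;
#' overlapping groups merge. Every node lands in exactly one cluster.
#'
#' @param graph a `tc_graph` from [build_graph()]
#' @param inflation inflation exponent, > 1 (default 2)
#' @param max_iter iteration cap (default 100)
#' @param prune_threshold entries below this are zeroed each iteration
#'   (default 1e-5)
#' @return data.frame of memberships: `cluster_id`, `boundary_id`,
#'   `species`
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100,
                        prune_threshold = 1e-5) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (max_iter < 1) stop("max_iter must be >= 1")
  ids <- graph$nodes$boundary_id
  n <- length(ids)
  if (n == 0)
    return(empty_df(cluster_id = character(0), boundary_id = character(0),
                    species = character(0)))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, ids)
    j <- match(graph$edges$to, ids)
    A[cbind(i, j)] <- A[cbind(i, j)] + graph$edges$weight
    A[cbind(j, i)] <- A[cbind(i, j)]
  }
  loop <- pmax(apply(A, 2, max), 1)
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < prune_threshold] <- 0      # prune
    cs <- colSums(M2)
    dead <- cs == 0
    if (any(dead)) {                   # guard: re-seed an emptied column
      M2[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-8) break
  }
  membership <- mcl_interpret(M, prune_threshold)
  data.frame(cluster_id = paste0("c", sprintf("%04d", membership)),
             boundary_id = ids,
             species = graph$nodes$species, stringsAsFactors = FALSE)
}

# attractor-overlap interpretation of a converged MCL matrix:
# components of the bipartite attractor-row / retained-node structure
mcl_interpret <- function(M, tol) {
  n <- nrow(M)
  attractors <- which(diag(M) > tol)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  for (a in attractors) {
    members <- which(M[a, ] > tol)
    for (m in members) union2(a, m)
  }
  # a non-attractor node keeps mass on attractor rows of its column
  for (jj in seq_len(n)) {
    rows <- which(M[, jj] > tol)
    if (length(rows)) union2(rows[1], jj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Classify clusters by species membership
#'
#' A cluster is `conserved` when it contains boundaries from at least
#' `conserved_min_species` species (default: every species in the
#' manifest), `specific` when exactly one species is present, and
#' `partial` otherwise.
#'
#' @param membership data.frame from [mcl_cluster()]
#' @param species character vector of all manifest species
#' @param conserved_min_species species count needed for the conserved
#'   class (default `length(species)`)
#' @return data.frame of clusters: `cluster_id`, `n_members`,
#'   `n_species`, `species_set` (comma-joined), `class`
#' @export
classify_clusters <- function(membership, species,
                              conserved_min_species = length(species)) {
  if (nrow(membership) == 0)
    return(empty_df(cluster_id = character(0), n_members = integer(0),
                    n_species = integer(0), species_set = character(0),
                    class = character(0)))
  sp <- split(membership$species, membership$cluster_id)
  df <- data.frame(cluster_id = names(sp),
                   n_members = lengths(sp),
                   n_species = vapply(sp, function(s)
                     length(unique(s)), integer(1)),
                   species_set = vapply(sp, function(s)
                     paste(sort(unique(s)), collapse = ","), character(1)),
                   stringsAsFactors = FALSE)
  df$class <- ifelse(df$n_species >= conserved_min_species, "conserved",
                     ifelse(df$n_species == 1, "specific", "partial"))
  rownames(df) <- NULL
  df[order(df$cluster_id), , drop = FALSE]
}

#' Cluster-by-species phylogenomic profile matrix
#'
#' Rows are clusters, columns are species, cells count member boundaries.
#' Rows are ordered by (class: conserved, partial, specific), then
#' descending species presence, then descending size.
#'
#' @param membership data.frame from [mcl_cluster()]
#' @param clusters classified clusters from [classify_clusters()]
#' @param species all manifest species (column order)
#' @return integer matrix with cluster ids as row names, plus attribute
#'   `class` (row classes)
#' @export
profile_matrix <- function(membership, clusters, species) {
  m <- matrix(0L, nrow = nrow(clusters), ncol = length(species),
              dimnames = list(clusters$cluster_id, species))
  if (nrow(membership)) {
    t <- table(membership$cluster_id, membership$species)
    m[rownames(t), colnames(t)] <- as.integer(t)
  }
  cls <- factor(clusters$class, levels = c("conserved", "partial", "specific"))
  o <- order(cls, -clusters$n_species, -clusters$n_members,
             clusters$cluster_id)
  m <- m[o, , drop = FALSE]
  attr(m, "class_by_row") <- clusters$class[o]
  m
}

#' Write a profile matrix as TSV
#'
#' First column `cluster_id`, second `class`, then one count column per
#' species; header always written, even for an empty profile.
#'
#' @param profile matrix from [profile_matrix()]
#' @param path output path
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(cluster_id = rownames(profile) %||% character(0),
                   class = attr(profile, "class_by_row") %||% character(0),
                   stringsAsFactors = FALSE)
  mat <- as.data.frame(unclass(profile)[, , drop = FALSE])
  if (nrow(df) == 0) {
    mat <- as.data.frame(matrix(integer(0), 0, ncol(profile),
                                dimnames = list(NULL, colnames(profile))))
  }
  write_tsv(cbind(df, mat), path)
  invisible(path)
}
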