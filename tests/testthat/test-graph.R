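test_that("graph construction keeps isolated nodes and validates pairs", {
  nodes <- nodes_df(c("a|b1", "b|b1", "c|b1"))
  g <- build_graph(nodes, pair_df("a|b1", "b|b1", 10))
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 1)

  g0 <- build_graph(nodes, pair_df("a|b1", "b|b1", 10)[0, ])
  expect_equal(nrow(g0$edges), 0)

  expect_error(build_graph(nodes, pair_df("a|b1", "b|zz", 1)), "unknown")
  expect_error(build_graph(nodes, pair_df("a|b1", "b|b1", 0)), "weight")
})

test_that("two disjoint triangles give exactly two clusters of three", {
  adj <- matrix(0, 6, 6)
  tri <- rbind(c(1, 2), c(2, 3), c(1, 3))
  for (r in 1:3) {
    adj[tri[r, 1], tri[r, 2]] <- adj[tri[r, 2], tri[r, 1]] <- 1
    adj[tri[r, 1] + 3, tri[r, 2] + 3] <- adj[tri[r, 2] + 3, tri[r, 1] + 3] <- 1
  }
  m <- mcl_cluster(graph_from_adj(adj))
  expect_equal(length(unique(m$cluster_id)), 2)
  expect_equal(as.integer(sort(table(m$cluster_id))), c(3L, 3L))
  expect_equal(length(unique(m$cluster_id[1:3])), 1)
})

test_that("an isolated node becomes a singleton cluster", {
  g <- build_graph(nodes_df(c("a|b1")), pair_df("x", "y")[0, ])
  m <- mcl_cluster(g)
  expect_equal(nrow(m), 1)
})

test_that("clustering matches an independent dense MCL reference", {
  set.seed(61)
  for (trial in 1:8) {
    n <- sample(12:50, 1)
    k <- sample(2:4, 1)  # planted communities
    com <- sample(k, n, replace = TRUE)
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p <- if (com[i] == com[j]) 0.6 else 0.03
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- sample(1:5, 1)
    }
    got <- mcl_cluster(graph_from_adj(adj))
    ref <- ref_mcl(adj)
    expect_true(same_partition(as.integer(factor(got$cluster_id)), ref))
  }
})

test_that("the partition is invariant to node relabelling", {
  set.seed(71)
  n <- 15
  adj <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (runif(1) < 0.3) adj[i, j] <- adj[j, i] <- sample(1:9, 1)
  base <- mcl_cluster(graph_from_adj(adj))
  perm <- sample(n)
  permuted <- mcl_cluster(graph_from_adj(adj[perm, perm]))
  expect_true(same_partition(
    as.integer(factor(base$cluster_id))[perm],
    as.integer(factor(permuted$cluster_id))))
})

test_that("raising inflation never reduces the cluster count", {
  set.seed(83)
  for (trial in 1:6) {
    n <- sample(10:30, 1)
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.25) adj[i, j] <- adj[j, i] <- sample(1:5, 1)
    g <- graph_from_adj(adj)
    k_lo <- length(unique(mcl_cluster(g, inflation = 1.5)$cluster_id))
    k_hi <- length(unique(mcl_cluster(g, inflation = 4)$cluster_id))
    expect_gte(k_hi, k_lo)
  }
})

test_that("cluster classes follow the species-presence definition", {
  m <- data.frame(cluster_id = c("c1", "c1", "c1", "c2", "c3", "c3"),
                  boundary_id = paste0("b", 1:6),
                  species = c("hs", "mm", "gg", "hs", "mm", "gg"),
                  stringsAsFactors = FALSE)
  cl <- classify_clusters(m, c("hs", "mm", "gg"))
  expect_equal(cl$class[cl$cluster_id == "c1"], "conserved")
  expect_equal(cl$class[cl$cluster_id == "c2"], "specific")
  expect_equal(cl$class[cl$cluster_id == "c3"], "partial")

  # relaxed conserved threshold
  cl2 <- classify_clusters(m, c("hs", "mm", "gg"),
                           conserved_min_species = 2)
  expect_equal(cl2$class[cl2$cluster_id == "c3"], "conserved")
})

test_that("profile rows and columns sum to cluster sizes and species totals", {
  set.seed(91)
  sp <- c("hs", "mm", "gg")
  m <- data.frame(cluster_id = sprintf("c%02d", sample(1:8, 60, TRUE)),
                  boundary_id = paste0("b", 1:60),
                  species = sample(sp, 60, TRUE), stringsAsFactors = FALSE)
  cl <- classify_clusters(m, sp)
  pr <- profile_matrix(m, cl, sp)
  expect_equal(sort(rowSums(pr)), sort(unname(
    tapply(m$boundary_id, m$cluster_id, length))), ignore_attr = TRUE)
  expect_equal(colSums(pr)[sp], table(m$species)[sp], ignore_attr = TRUE)
  expect_equal(unname(rowSums(pr)),
               cl$n_members[match(rownames(pr), cl$cluster_id)])

  d <- withr::local_tempdir()
  write_profile(pr, file.path(d, "p.tsv"))
  back <- read.table(file.path(d, "p.tsv"), sep = "\t", header = TRUE)
  expect_equal(nrow(back), nrow(pr))
  expect_equal(as.matrix(back[, sp]), unclass(pr)[, sp],
               ignore_attr = TRUE)
})
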