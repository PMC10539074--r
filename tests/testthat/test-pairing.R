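test_that("gene-to-boundary assignment respects half-open overlap", {
  r <- region_row("s|c1:b0001", "s", "s|c1", 0, 20000)
  g1 <- gene_row("s|g1", "s|c1", 5000, 7000, 0)
  expect_equal(genes_in_boundary(r, g1)$boundary_id, "s|c1:b0001")
  g2 <- gene_row("s|g2", "s|c1", 20000, 25000, 1)
  expect_equal(nrow(genes_in_boundary(r, g2)), 0)
})

test_that("gene assignment matches a quadratic overlap scan", {
  set.seed(37)
  for (trial in 1:10) {
    edges <- data.frame(chrom = "s|c",
                        pos = sort(sample(0:100000, sample(3:20, 1))))
    regions <- expand_and_merge(edges, sample(1000:8000, 1),
                                c("s|c" = 100000), "s")
    st <- sample(0:98000, 40)
    genes <- do.call(rbind, lapply(seq_along(st), function(i)
      gene_row(sprintf("s|g%02d", i), "s|c", st[i],
               st[i] + sample(200:3000, 1), i - 1)))
    got <- genes_in_boundary(regions, genes)
    ref <- overlap_scan(genes, regions)
    got <- got[order(got$gene_id), ]
    ref <- ref[order(ref$gene_id), ]
    expect_equal(got$gene_id, ref$gene_id)
    expect_equal(got$boundary_id, ref$boundary_id)
  }
})

test_that("synteny pairs accumulate summed gene lengths", {
  ga <- gene_row("a|g1", "a|c1", 1000, 2200, 0)   # length 1200
  gb <- gene_row("b|g1", "b|c1", 5000, 6500, 0)   # length 1500
  idx <- data.frame(gene = c("a|g1", "b|g1"), partner = c("b|g1", "a|g1"),
                    block_id = "a:blk0001", stringsAsFactors = FALSE)
  aa <- data.frame(boundary_id = "a|c1:b0001", gene_id = "a|g1")
  ab <- data.frame(boundary_id = "b|c1:b0001", gene_id = "b|g1")
  p <- pairs_from_synteny(aa, ab, idx, ga, gb)
  expect_equal(nrow(p), 1)
  expect_equal(p$weight, 2700)
  expect_equal(p$evidence, "synteny")

  # anchored genes outside any region: no pair
  p0 <- pairs_from_synteny(aa[0, ], ab[0, ], idx, ga, gb)
  expect_equal(nrow(p0), 0)
})

test_that("multi-anchor synteny weights equal a brute-force accumulation", {
  set.seed(51)
  n <- 20
  ga <- do.call(rbind, lapply(1:n, function(i)
    gene_row(sprintf("a|g%02d", i), "a|c1", i * 5000,
             i * 5000 + sample(500:2500, 1), i - 1)))
  gb <- do.call(rbind, lapply(1:n, function(i)
    gene_row(sprintf("b|g%02d", i), "b|c1", i * 5000,
             i * 5000 + sample(500:2500, 1), i - 1)))
  idx <- data.frame(gene = c(ga$gene_id, gb$gene_id),
                    partner = c(gb$gene_id, ga$gene_id),
                    block_id = "a:blk0001", stringsAsFactors = FALSE)
  aa <- data.frame(boundary_id = sprintf("a|c1:b%04d", rep(1:4, each = 5)),
                   gene_id = ga$gene_id, stringsAsFactors = FALSE)
  ab <- data.frame(boundary_id = sprintf("b|c1:b%04d", rep(1:5, each = 4)),
                   gene_id = gb$gene_id, stringsAsFactors = FALSE)
  p <- pairs_from_synteny(aa, ab, idx, ga, gb)
  # brute force over all anchor pairs
  ref <- list()
  for (i in 1:n) {
    ba <- aa$boundary_id[aa$gene_id == ga$gene_id[i]]
    bb <- ab$boundary_id[ab$gene_id == gb$gene_id[i]]
    key <- paste(ba, bb)
    w <- (ga$end[i] - ga$start[i]) + (gb$end[i] - gb$start[i])
    ref[[key]] <- (ref[[key]] %||% 0) + w
  }
  expect_equal(nrow(p), length(ref))
  got <- setNames(p$weight, paste(p$boundary_a, p$boundary_b))
  expect_equal(got[names(ref)], unlist(ref)[names(ref)],
               ignore_attr = FALSE)
})

test_that("sequence pairs require region overlap and sum aligned lengths", {
  bt <- region_row("b|c1:b0001", "b", "b|c1", 50000, 60000)
  hit <- data.frame(boundary_id = "a|c1:b0001", target_species = "b",
                    target_chrom = "b|c1", target_start = 52000,
                    target_end = 55000, length = 3000, identity = 0.9,
                    strand = "+", stringsAsFactors = FALSE)
  p <- pairs_from_sequence(hit, bt)
  expect_equal(p$weight, 3000)
  expect_equal(p$evidence, "sequence")

  miss <- transform(hit, target_start = 70000, target_end = 73000)
  expect_equal(nrow(pairs_from_sequence(miss, bt)), 0)
})

test_that("integration unions channels, sums weights, max-merges directions", {
  syn <- data.frame(boundary_a = "a|c1:b0001", boundary_b = "b|c1:b0001",
                    species_a = "a", species_b = "b",
                    evidence = "synteny", weight = 2700,
                    stringsAsFactors = FALSE)
  seq_ab <- transform(syn, evidence = "sequence", weight = 3000)
  out <- integrate_pairs(syn, seq_ab, NULL)
  expect_equal(out$evidence, "both")
  expect_equal(out$weight, 5700)

  # disjoint channel outputs concatenate
  seq2 <- data.frame(boundary_a = "b|c1:b0002", boundary_b = "a|c1:b0002",
                     species_a = "b", species_b = "a",
                     evidence = "sequence", weight = 2500,
                     stringsAsFactors = FALSE)
  out2 <- integrate_pairs(syn, seq2, NULL)
  expect_equal(nrow(out2), 2)
  expect_true(all(out2$boundary_a < out2$boundary_b))

  # asymmetric directional sequence runs: larger weight wins
  fwd <- seq_ab
  rev <- data.frame(boundary_a = "b|c1:b0001", boundary_b = "a|c1:b0001",
                    species_a = "b", species_b = "a",
                    evidence = "sequence", weight = 4400,
                    stringsAsFactors = FALSE)
  out3 <- integrate_pairs(NULL, fwd, rev)
  expect_equal(out3$weight, 4400)
  out4 <- integrate_pairs(syn, fwd, rev)
  expect_equal(out4$weight, 2700 + 4400)
  expect_equal(out4$evidence, "both")

  bad <- transform(syn, boundary_b = "a|c1:b0009", species_b = "a")
  expect_error(integrate_pairs(bad, NULL, NULL), "self-species")
})
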