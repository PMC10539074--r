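test_that("sketching is deterministic and matches exhaustive canonical hashing", {
  set.seed(13)
  g <- random_dna(10000)
  s1 <- sketch_genome(g, k = 15, sketch_size = 100000)
  s2 <- sketch_genome(g, k = 15, sketch_size = 100000)
  expect_identical(s1$hashes, s2$hashes)

  # unbounded sketch == set of hashes of all canonical k-mers
  k <- 15
  kmers <- substring(g, 1:(nchar(g) - k + 1), k:nchar(g))
  canon <- pmin(kmers, vapply(kmers, revcomp, character(1)))
  ref <- sort(unique(vapply(unique(canon), function(km)
    tadcons:::kmer_hash_values(km, k), numeric(1))))
  expect_equal(s1$hashes, ref)

  # degenerate single-k-mer genome
  s3 <- sketch_genome(strrep("A", 12), k = 11, sketch_size = 100)
  expect_length(s3$hashes, 1)

  expect_error(sketch_genome("ACGT", k = 11, sketch_size = 100), "shorter")
  expect_error(sketch_genome(g, k = 5, sketch_size = 100), "k must")
})

test_that("mash distance follows the Jaccard formula and its limits", {
  a <- fake_sketch(1:1000, k = 21)
  expect_equal(mash_distance(a, a), 0)
  b <- fake_sketch(2001:3000, k = 21)
  expect_equal(mash_distance(a, b), 1.0)

  # constructed overlap: bottom-1000 of the union shares 500
  c5 <- fake_sketch(c(1:500, 5001:5500), k = 21, sketch_size = 1000)
  d5 <- fake_sketch(c(1:500, 9001:9500), k = 21, sketch_size = 1000)
  j <- 0.5
  expect_equal(mash_distance(c5, d5), -(1 / 21) * log(2 * j / (1 + j)))

  expect_error(mash_distance(a, fake_sketch(1:1000, k = 15)),
               "different k")

  # symmetry and monotone decrease in j
  expect_equal(mash_distance(c5, d5), mash_distance(d5, c5))
  j_grid <- c(0.1, 0.25, 0.5, 0.9)
  d_grid <- -(1 / 21) * log(2 * j_grid / (1 + j_grid))
  expect_true(all(diff(d_grid) < 0))
})

test_that("preset selection honours the divergence bands", {
  expect_equal(select_preset(0), "asm5")
  expect_equal(select_preset(0.01), "asm5")
  expect_equal(select_preset(0.05), "asm10")
  expect_equal(select_preset(0.3), "asm20")
  expect_error(select_preset(-0.1), "non-negative")
})

test_that("the builtin aligner finds exact, mutated and reverse-strand copies", {
  set.seed(29)
  query <- random_dna(3000)
  target_seq <- paste0(random_dna(20000), query, random_dna(20000))
  d <- withr::local_tempdir()
  genome <- read_genome(write_fasta(list(c1 = target_seq),
                                    file.path(d, "t.fa")), "tg")
  q <- Biostrings::DNAStringSet(query)
  names(q) <- "qs|c1:b0001"
  hits <- align_boundaries(q, genome, preset = "asm10")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$target_start, 20000)
  expect_equal(hits$target_end, 23000)

  # reverse strand: same interval, strand '-'
  genome_rc <- read_genome(write_fasta(list(c1 = revcomp(target_seq)),
                                       file.path(d, "rc.fa")), "tg")
  hits_rc <- align_boundaries(q, genome_rc, preset = "asm10")
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$target_start, nchar(target_seq) - 23000)

  # unrelated target: no hits
  genome_bad <- read_genome(write_fasta(list(c1 = random_dna(40000)),
                                        file.path(d, "b.fa")), "tg")
  expect_equal(nrow(align_boundaries(q, genome_bad, preset = "asm10")), 0)
})

test_that("a 2% mutated planted boundary is recovered over >= 80% of its length", {
  set.seed(41)
  for (trial in 1:20) {
    query <- random_dna(4000)
    mutated <- strsplit(query, "")[[1]]
    pos <- sample(4000, 80)  # 2%
    bases <- c("A", "C", "G", "T")
    mutated[pos] <- bases[((match(mutated[pos], bases) - 1 +
                             sample(3, 80, TRUE)) %% 4) + 1]
    target <- paste0(random_dna(10000), paste(mutated, collapse = ""),
                     random_dna(10000))
    d <- withr::local_tempdir()
    genome <- read_genome(write_fasta(list(c1 = target),
                                      file.path(d, "t.fa")), "tg")
    q <- Biostrings::DNAStringSet(query)
    names(q) <- "qs|c1:b0001"
    hits <- align_boundaries(q, genome, preset = "asm20")
    expect_gte(max(c(0, hits$length)), 0.8 * 4000)
  }
})

test_that("the length filter keeps strictly longer hits only, in order", {
  h <- data.frame(boundary_id = c("a", "b", "c"),
                  length = c(2001, 2000, 5000))
  f <- filter_hits(h)
  expect_equal(f$boundary_id, c("a", "c"))
  expect_identical(filter_hits(f), f)  # idempotent
  expect_equal(nrow(filter_hits(h[0, ])), 0)

  set.seed(2)
  lens <- sample(0:5000, 100, replace = TRUE)
  hh <- data.frame(boundary_id = as.character(1:100), length = lens)
  expect_equal(nrow(filter_hits(hh)), sum(lens > 2000))
  expect_equal(filter_hits(hh)$length, lens[lens > 2000])
})
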