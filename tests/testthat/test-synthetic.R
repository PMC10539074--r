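test_that("interval remapping handles inversion, translocation, duplication", {
  inv <- list(type = "inv", a = 100, b = 200)
  expect_equal(unname(remap_interval(c(10, 50), list(inv))[1, ]),
               c(10, 50))
  # wholly inside: mirrored about a+b
  expect_equal(unname(remap_interval(c(120, 140), list(inv))[1, ]),
               c(160, 180))
  # per-base mirror oracle: base at p maps to a+b-1-p
  for (p in c(100, 133, 199)) {
    img <- remap_interval(c(p, p + 1), list(inv))
    expect_equal(unname(img[1, ]), c(100 + 200 - 1 - p, 100 + 200 - p))
  }

  tr <- list(type = "trans", a = 100, b = 200, c = 400)
  expect_equal(unname(remap_interval(c(120, 140), list(tr))[1, ]),
               c(320, 340))              # moved to insertion site
  expect_equal(unname(remap_interval(c(250, 260), list(tr))[1, ]),
               c(150, 160))              # shifted left past the excision
  expect_equal(unname(remap_interval(c(420, 430), list(tr))[1, ]),
               c(420, 430))              # right of everything: net zero

  dup <- list(type = "dup", a = 100, b = 200, c = 400)
  img <- remap_interval(c(120, 140), list(dup))
  expect_equal(nrow(img), 2)             # both copies
  expect_equal(unname(img[1, ]), c(120, 140))
  expect_equal(unname(img[2, ]), c(420, 440))

  # spanning a breakpoint: larger fragment kept, with a message
  expect_message(res <- remap_interval(c(90, 130), list(inv)),
                 "larger|fragment|breakpoint")
  expect_equal(unname(res[1, "end"] - res[1, "start"]), 30)
})

test_that("sequence edits agree with coordinate remapping", {
  set.seed(3)
  s <- random_dna(500)
  for (op in list(list(type = "inv", a = 100, b = 200),
                  list(type = "trans", a = 100, b = 200, c = 400),
                  list(type = "dup", a = 100, b = 200, c = 400))) {
    s2 <- tadcons:::apply_op_seq(s, op)
    # an interval far from all breakpoints carries its sequence along
    iv <- c(250, 280)
    img <- remap_interval(iv, list(op))
    for (r in seq_len(nrow(img)))
      expect_equal(substr(s2, img[r, 1] + 1, img[r, 2]),
                   substr(s, iv[1] + 1, iv[2]))
    # the moved segment itself
    seg <- c(110, 150)
    img2 <- remap_interval(seg, list(op))
    want <- substr(s, seg[1] + 1, seg[2])
    if (op$type == "inv") want <- revcomp(want)
    for (r in seq_len(nrow(img2)))
      expect_equal(substr(s2, img2[r, 1] + 1, img2[r, 2]), want)
  }
})

test_that("identical parameters and seed reproduce byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- small_clade(d1, seed = 99)
  c2 <- small_clade(d2, seed = 99)
  for (f in c("sp1.fa", "sp1.gff3", "sp1.bed", "sp2.fa", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  expect_false(identical(
    readLines(file.path(d1, "sp1.fa")),
    readLines(small_clade(withr::local_tempdir(), seed = 100)$dir |>
                file.path("sp1.fa"))))
})

test_that("zero-rate evolution reproduces the ancestor in every species", {
  d <- withr::local_tempdir()
  cl <- generate_clade(sim_params(
    n_species = 2, genome_length = 600000, n_genes = 60, n_tads = 10,
    sub_rate = 0, n_inversions = 0, n_translocations = 0,
    n_duplications = 0, p_gain = 0, p_loss = 0, seed = 5), dir = d)
  s1 <- readLines(file.path(d, "sp1.fa"))[-1]
  s2 <- readLines(file.path(d, "sp2.fa"))[-1]
  expect_identical(s1, s2)
  # truth maps every ancestral edge 1:1 in both species
  tt <- cl$truth
  expect_true(all(tt$type == "ancestral"))
  expect_equal(as.integer(table(tt$species)), c(11L, 11L))
  expect_identical(tt$pos[tt$species == "sp1"],
                   tt$pos[tt$species == "sp2"])
})

test_that("a lone inversion keeps every edge, remapped, in the truth table", {
  d <- withr::local_tempdir()
  cl <- generate_clade(sim_params(
    n_species = 2, genome_length = 600000, n_genes = 60, n_tads = 10,
    sub_rate = 0, n_inversions = 1, n_translocations = 0,
    n_duplications = 0, p_gain = 0, p_loss = 0, seed = 8), dir = d)
  tt <- cl$truth
  for (sp in c("sp1", "sp2")) {
    present <- unique(tt$edge_id[tt$species == sp])
    expect_setequal(present, sprintf("anc_e%02d", 0:10))
    # every image is a real TAD edge of the emitted BED
    bed <- read.table(file.path(d, paste0(sp, ".bed")), sep = "\t")
    edges <- sort(unique(c(bed[[2]], bed[[3]])))
    expect_true(all(tt$pos[tt$species == sp] %in% edges))
  }
})

test_that("a duplication yields a one-to-many truth record", {
  d <- withr::local_tempdir()
  cl <- generate_clade(sim_params(
    n_species = 2, genome_length = 600000, n_genes = 60, n_tads = 10,
    sub_rate = 0, n_inversions = 0, n_translocations = 0,
    n_duplications = 1, p_gain = 0, p_loss = 0, seed = 13), dir = d)
  tt <- cl$truth
  multi <- tapply(tt$pos, paste(tt$edge_id, tt$species), length)
  expect_true(any(multi == 2))
})
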