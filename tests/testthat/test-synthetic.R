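# Synthetic generators: reproducibility, stated class structure, and the
# class-contrast / length-matching invariants.

test_that("gen_random_string is uniform, seeded and validated", {
  expect_equal(gen_random_string(4, 1, seed = 123), "aaaa")
  expect_identical(gen_random_string(50, 3, seed = 7),
                   gen_random_string(50, 3, seed = 7))
  s <- gen_random_string(1e4, 2, seed = 1)
  frac_a <- mean(strsplit(s, "")[[1]] == "a")
  expect_lt(abs(frac_a - 0.5), 0.02)
  expect_error(gen_random_string(0, 2, seed = 1), "invalid-argument")
  expect_error(gen_random_string(5, 0, seed = 1), "invalid-argument")
})

test_that("gen_modular_string executes the join process as stated", {
  r <- gen_modular_string(1, 1, 0.5, seed = 99)
  expect_equal(r$string, "aa")
  expect_equal(r$pathway_length, 1L)
  # full reuse of the newest object doubles each step
  r3 <- gen_modular_string(3, 1, 1.0, seed = 0)
  expect_equal(r3$string, "aaaaaaaa")
  expect_equal(r3$pathway_length, 3L)
  expect_identical(gen_modular_string(5, 2, 0.7, seed = 11),
                   gen_modular_string(5, 2, 0.7, seed = 11))
})

test_that("the construction pathway witnesses the assembly index bound", {
  for (seed in 1:15) {
    r <- gen_modular_string(n_joins = 4, alphabet_size = 2, reuse_bias = 0.6,
                            seed = seed)
    expect_lte(assembly_index_exact(r$string)$index, r$pathway_length)
  }
})

test_that("gen_peak_matrix realises both class structures", {
  m <- gen_peak_matrix(4, 8, "modular", n_templates = 1, flip_noise = 0,
                       density = 0.5, seed = 3)
  expect_true(all(m %in% c(0L, 1L)))
  for (r in 2:4) expect_equal(m[r, ], m[1, ])
  mr <- gen_peak_matrix(64, 64, "random", density = 0.5, seed = 5)
  expect_lt(abs(mean(mr) - 0.5), 0.05)
  expect_error(gen_peak_matrix(4, 8, "modular", n_templates = 9, seed = 1),
               "invalid-argument")
  expect_identical(gen_peak_matrix(16, 16, "random", seed = 2),
                   gen_peak_matrix(16, 16, "random", seed = 2))
  # noiseless modular matrices compress better than random ones
  for (seed in 1:5) {
    mm <- gen_peak_matrix(16, 16, "modular", n_templates = 2, flip_noise = 0,
                          density = 0.5, seed = seed)
    rr <- gen_peak_matrix(16, 16, "random", density = 0.5, seed = seed + 100)
    pm <- lz78_parse(matrix_to_sequence(mm, "binary"))$phrase_count
    pr <- lz78_parse(matrix_to_sequence(rr, "binary"))$phrase_count
    expect_lt(pm, pr)
  }
})

test_that("gen_molecule produces the stated topologies", {
  poly <- gen_molecule("polymer", n_atoms = 6, monomer_size = 2, seed = 0)
  expect_equal(length(poly$atoms), 6L)
  expect_gte(nrow(poly$bonds), 5L)
  expect_true(molcomplexity:::.mol_connected(poly))
  tree <- gen_molecule("random_tree", n_atoms = 10, seed = 2)
  expect_equal(nrow(tree$bonds), 9L) # tree property
  expect_true(molcomplexity:::.mol_connected(tree))
  expect_error(gen_molecule("polymer", n_atoms = 7, monomer_size = 2, seed = 1),
               "invalid-argument")
  expect_identical(gen_molecule("random_tree", n_atoms = 8, seed = 5),
                   gen_molecule("random_tree", n_atoms = 8, seed = 5))
})

test_that("polymer distance matrices compress better than random trees", {
  # averaged over 20 seeds at 16 atoms (4 tetramer units). For very short
  # chains with tiny monomers the RLE direction can invert: chain
  # distances are gradients, and the polymer's redundancy is periodicity,
  # which LZ78 sees at every size but RLE only via the digit cap.
  runs <- function(mol) {
    rle_encode(matrix_to_sequence(bond_distance_matrix(mol)))$run_count
  }
  phrases <- function(mol) {
    lz78_parse(matrix_to_sequence(bond_distance_matrix(mol)))$phrase_count
  }
  n <- 16L
  poly <- lapply(1:20, function(s) gen_molecule("polymer", n, 4L, seed = s))
  tree <- lapply(1:20, function(s) gen_molecule("random_tree", n, seed = s))
  expect_lte(mean(sapply(poly, runs)), mean(sapply(tree, runs)))
  expect_lt(mean(sapply(poly, phrases)), mean(sapply(tree, phrases)))
})

test_that("modular class beats random class on mean LZ78 phrase count", {
  # class-contrast invariant at generator defaults (n_joins = 12),
  # length-matched controls, 50 seeds
  pm <- numeric(50); pr <- numeric(50)
  for (seed in 1:50) {
    ms <- gen_modular_string(seed = seed)
    rs <- gen_random_string(nchar(ms$string), 4L, seed = seed + 1000L)
    pm[seed] <- lz78_parse(ms$string)$phrase_count
    pr[seed] <- lz78_parse(rs)$phrase_count
  }
  expect_lt(mean(pm), mean(pr))
})

test_that("the corpus is length-matched, reproducible and disk-stable", {
  corpus <- gen_string_corpus(n_per_class = 12, seed = 31)
  expect_equal(nrow(corpus), 24L)
  lens <- nchar(corpus$string)
  expect_true(all(lens >= 8 & lens <= 16))
  mod <- corpus[corpus$class == "modular", ]
  rnd <- corpus[corpus$class == "random", ]
  expect_equal(nchar(mod$string), nchar(rnd$string)) # paired lengths
  expect_identical(corpus, gen_string_corpus(n_per_class = 12, seed = 31))

  dir <- tempfile("corpus")
  write_corpus(corpus, dir)
  expect_true(file.exists(file.path(dir, "groups.csv")))
  back <- read_corpus(dir)
  expect_identical(back$string, corpus$string)
  expect_identical(back$class, corpus$class)
})
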