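# Encodings: ASCII-to-binary, matrix flattening, MOL V2000 round trips
# and bond distance matrices.

test_that("ascii_to_bits uses fixed 8-bit codes and inverts exactly", {
  expect_equal(ascii_to_bits("A"), "01000001")
  expect_equal(ascii_to_bits(""), "")
  expect_equal(ascii_to_bits("AB"), "0100000101000010")
  expect_error(ascii_to_bits("abéc"), "index 3")
  set.seed(201)
  for (i in 1:30) {
    s <- paste(sample(c(letters, LETTERS, 0:9, "(", ")", "-", "/"),
                      sample(0:40, 1), replace = TRUE), collapse = "")
    bits <- ascii_to_bits(s)
    expect_equal(nchar(bits), 8L * nchar(s))
    expect_identical(bits_to_ascii(bits), s)
  }
})

test_that("matrix_to_sequence flattens row-major with capping/threshold", {
  expect_equal(matrix_to_sequence(matrix(c(0, 1, 1, 0), 2, byrow = TRUE)),
               "0110")
  expect_equal(
    matrix_to_sequence(matrix(c(0, 3, 2, 0), 2, byrow = TRUE),
                       mode = "binary", threshold = 2),
    "0110")
  expect_equal(matrix_to_sequence(matrix(0, 3, 2)), "000000")
  # row-major means rows are contiguous
  expect_equal(matrix_to_sequence(matrix(0:3, 2, 2, byrow = TRUE)), "0123")
  # entries cap at 9 in digits mode
  expect_equal(matrix_to_sequence(matrix(c(8, 12), 1, 2)), "89")
  expect_error(matrix_to_sequence(matrix(c(-1, 0), 1, 2)), "non-negative")
})

test_that("bond distances match path/cycle geometry and a BFS oracle", {
  path3 <- molecule_graph(c("A", "B", "C"),
                          data.frame(from = c(1L, 2L), to = c(2L, 3L),
                                     order = 1L))
  expect_equal(bond_distance_matrix(path3),
               matrix(c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L, 0L), 3))
  pair <- molecule_graph(c("A", "B"),
                         data.frame(from = 1L, to = 2L, order = 1L))
  expect_equal(bond_distance_matrix(pair), matrix(c(0L, 1L, 1L, 0L), 2))
  cyc4 <- molecule_graph(rep("C", 4),
                         data.frame(from = c(1L, 2L, 3L, 4L),
                                    to = c(2L, 3L, 4L, 1L), order = 1L))
  d4 <- bond_distance_matrix(cyc4)
  expect_true(all(d4[upper.tri(d4)] %in% c(1L, 2L)))
  # BFS oracle on random trees and the cycle, up to 12 atoms
  expect_equal(d4, oracle_bfs_distances(cyc4))
  for (seed in 1:10) {
    mol <- gen_molecule("random_tree", n_atoms = sample(2:12, 1), seed = seed)
    d <- bond_distance_matrix(mol)
    expect_equal(d, oracle_bfs_distances(mol))
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0L))
  }
})

test_that("relabelling changes the flattened distance sequence unless it is an automorphism", {
  edges4 <- cbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 1L))
  seq_of <- function(perm) {
    e <- matrix(perm[edges4], ncol = 2)
    m <- molecule_graph(rep("C", 4),
                        data.frame(from = e[, 1], to = e[, 2], order = 1L))
    matrix_to_sequence(bond_distance_matrix(m))
  }
  base <- seq_of(1:4)
  expect_identical(seq_of(c(1L, 4L, 3L, 2L)), base) # reflection: automorphism
  expect_identical(seq_of(c(2L, 3L, 4L, 1L)), base) # rotation: automorphism
  # swapping one adjacent pair is not an automorphism of the 4-cycle
  expect_false(identical(seq_of(c(1L, 3L, 2L, 4L)), base))
})

test_that("MOL V2000 files round-trip and malformed files give line errors", {
  mol <- molecule_graph(c("C", "C"),
                        data.frame(from = 1L, to = 2L, order = 1L))
  path <- tempfile(fileext = ".mol")
  write_molfile(mol, path)
  back <- read_molfile(path)
  expect_identical(back$atoms, mol$atoms)
  expect_equal(back$bonds$from, mol$bonds$from)
  expect_equal(back$bonds$to, mol$bonds$to)
  # richer molecule
  mol2 <- gen_molecule("polymer", n_atoms = 8L, monomer_size = 2L, seed = 4)
  write_molfile(mol2, path)
  back2 <- read_molfile(path)
  expect_identical(back2$atoms, mol2$atoms)
  expect_equal(bond_distance_matrix(back2), bond_distance_matrix(mol2))

  # V2000 is 1-based: a bond naming atom 0 is a parse error
  bad <- c("name", "", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 2L, 1L),
           sprintf("%10.4f%10.4f%10.4f %-3s 0  0", 0, 0, 0, "C"),
           sprintf("%10.4f%10.4f%10.4f %-3s 0  0", 0, 0, 0, "C"),
           sprintf("%3d%3d%3d  0", 0L, 2L, 1L), "M  END")
  f <- tempfile(fileext = ".mol")
  writeLines(bad, f)
  expect_error(read_molfile(f), "parse-error")
  # malformed counts line
  writeLines(c("x", "", "", "  x  y", "M  END"), f)
  expect_error(read_molfile(f), "line 4")
  # disconnected graph rejected on load
  disc <- c("name", "", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 3L, 1L),
            rep(sprintf("%10.4f%10.4f%10.4f %-3s 0  0", 0, 0, 0, "C"), 3),
            sprintf("%3d%3d%3d  0", 1L, 2L, 1L), "M  END")
  writeLines(disc, f)
  expect_error(read_molfile(f), "disconnected")
})

test_that("disconnected graphs are rejected by the distance matrix", {
  mol <- molecule_graph(c("C", "C", "C"),
                        data.frame(from = 1L, to = 2L, order = 1L),
                        check_connected = FALSE)
  expect_error(bond_distance_matrix(mol), "disconnected")
})

test_that("sequence_to_binary is fixed-width and leaves binary alone", {
  expect_identical(sequence_to_binary("0110"), "0110")
  b <- sequence_to_binary("abca")
  expect_equal(nchar(b), 8L) # 4 symbols x 2 bits
  expect_identical(sequence_to_binary("abca"), b)
})
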