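# Seeded synthetic corpora: modular ("biotic-like") vs random
# ("abiotic-like") strings, binarised peak matrices, and molecule graphs.
# Every generator is a pure function of its arguments including the seed;
# substreams are derived with the splittable scheme in utils.R so that
# one corpus-level seed drives everything reproducibly.

#' Random (incompressible) string
#'
#' I.i.d. uniform symbols over the first `alphabet_size` lower-case
#' letters: the "abiotic" null model against which modular strings are
#' compared.
#'
#' @param length Positive integer string length.
#' @param alphabet_size Number of symbols (1..26).
#' @param seed Integer seed; identical arguments reproduce the string.
#' @return A character string.
#' @export
gen_random_string <- function(length, alphabet_size, seed) {
  length <- .assert_count(length, "length")
  alphabet_size <- .assert_count(alphabet_size, "alphabet_size")
  if (alphabet_size > 26L) .stopf("invalid-argument: alphabet_size > 26")
  .with_stream(seed, 0L, {
    .collapse(sample(letters[seq_len(alphabet_size)], length, replace = TRUE))
  })
}

#' Modular (assembly-pathway) string
#'
#' Mirrors an assembly pathway: the pool starts with the single symbols;
#' each of the `n_joins` steps concatenates two existing objects, each
#' operand independently being the most recently built object with
#' probability `reuse_bias` and otherwise a uniform draw from the pool.
#' The last object built is returned. By construction the string's exact
#' assembly index is at most `n_joins`.
#'
#' @param n_joins Number of join steps (the pathway length).
#' @param alphabet_size Number of basis symbols.
#' @param reuse_bias Probability of picking the newest object as operand.
#' @param seed Integer seed.
#' @return List with `string` and `pathway_length` (= `n_joins`).
#' @export
gen_modular_string <- function(n_joins = 12L, alphabet_size = 4L,
                               reuse_bias = 0.8, seed = 1L) {
  n_joins <- .assert_count(n_joins, "n_joins")
  alphabet_size <- .assert_count(alphabet_size, "alphabet_size")
  reuse_bias <- .assert_prob(reuse_bias, "reuse_bias")
  .with_stream(seed, 1L, {
    pool <- as.list(letters[seq_len(alphabet_size)])
    newest <- NULL
    pick <- function() {
      if (!is.null(newest) && stats::runif(1) < reuse_bias) return(newest)
      pool[[sample.int(length(pool), 1L)]]
    }
    for (k in seq_len(n_joins)) {
      left <- pick(); right <- pick()
      newest <- paste0(left, right)
      pool[[length(pool) + 1L]] <- newest
    }
    list(string = newest, pathway_length = n_joins)
  })
}

#' Binarised peak matrix
#'
#' Emulates the statistical structure of binarised MS2 peak matrices.
#' Class `"random"` has i.i.d. Bernoulli(`density`) entries; class
#' `"modular"` draws each row from one of `n_templates` Bernoulli
#' template rows and then flips each bit independently with probability
#' `flip_noise`.
#'
#' @param rows,cols Matrix dimensions.
#' @param class_label `"modular"` or `"random"`.
#' @param n_templates Number of template rows (modular class).
#' @param flip_noise Per-bit flip probability after template assignment.
#' @param density Bernoulli density of entries / templates.
#' @param seed Integer seed.
#' @return A 0/1 integer matrix.
#' @export
gen_peak_matrix <- function(rows, cols, class_label = c("modular", "random"),
                            n_templates = 2L, flip_noise = 0.02,
                            density = 0.5, seed = 1L) {
  rows <- .assert_count(rows, "rows")
  cols <- .assert_count(cols, "cols")
  class_label <- match.arg(class_label)
  flip_noise <- .assert_prob(flip_noise, "flip_noise")
  density <- .assert_prob(density, "density")
  if (class_label == "modular") {
    n_templates <- .assert_count(n_templates, "n_templates")
    if (n_templates > rows) {
      .stopf("invalid-argument: n_templates (%d) > rows (%d)", n_templates, rows)
    }
  }
  .with_stream(seed, 2L, {
    if (class_label == "random") {
      m <- matrix(stats::rbinom(rows * cols, 1L, density), rows, cols)
    } else {
      templates <- matrix(stats::rbinom(n_templates * cols, 1L, density),
                          n_templates, cols)
      assign_row <- if (n_templates == 1L) rep(1L, rows) else
        sample.int(n_templates, rows, replace = TRUE)
      m <- templates[assign_row, , drop = FALSE]
      if (flip_noise > 0) {
        flips <- matrix(stats::rbinom(rows * cols, 1L, flip_noise), rows, cols)
        m <- (m + flips) %% 2L
      }
    }
    storage.mode(m) <- "integer"
    m
  })
}

# Decode a Pruefer sequence into the edge list of a labelled tree on n
# nodes; uniform Pruefer sequences give uniform labelled trees.
.prufer_tree <- function(pr, n) {
  if (n == 2L) return(cbind(1L, 2L))
  deg <- tabulate(pr, n) + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(pr)) {
    leaf <- which(deg == 1L)[1L]
    edges[i, ] <- c(leaf, pr[i])
    deg[leaf] <- deg[leaf] - 1L
    deg[pr[i]] <- deg[pr[i]] - 1L
  }
  last <- which(deg == 1L)
  edges[n - 1L, ] <- last[1:2]
  edges
}

#' Synthetic molecule graph
#'
#' `"polymer"`: a fixed random monomer of `monomer_size` atoms (a random
#' labelled tree with elements drawn from \{C, N, O, S\}) repeated in a
#' chain, consecutive copies linked by one bond — a modular, repetitive
#' topology. `"random_tree"`: a uniform random labelled tree on
#' `n_atoms` atoms via a Pruefer sequence.
#'
#' @param class_label `"polymer"` or `"random_tree"`.
#' @param n_atoms Total atom count (>= 2; for polymers a multiple of
#'   `monomer_size`).
#' @param monomer_size Atoms per monomer unit.
#' @param seed Integer seed.
#' @return A [molecule_graph()].
#' @export
gen_molecule <- function(class_label = c("polymer", "random_tree"),
                         n_atoms, monomer_size = 2L, seed = 1L) {
  class_label <- match.arg(class_label)
  n_atoms <- .assert_count(n_atoms, "n_atoms", min = 2L)
  elements <- c("C", "N", "O", "S")
  eprob <- c(0.7, 0.1, 0.15, 0.05)
  .with_stream(seed, 3L, {
    if (class_label == "random_tree") {
      pr <- if (n_atoms > 2L) sample.int(n_atoms, n_atoms - 2L, replace = TRUE)
            else integer(0)
      edges <- .prufer_tree(pr, n_atoms)
      atoms <- sample(elements, n_atoms, replace = TRUE, prob = eprob)
    } else {
      monomer_size <- .assert_count(monomer_size, "monomer_size")
      if (n_atoms %% monomer_size != 0L) {
        .stopf("invalid-argument: monomer_size must divide n_atoms")
      }
      k <- n_atoms %/% monomer_size
      mono_atoms <- sample(elements, monomer_size, replace = TRUE, prob = eprob)
      mono_edges <- if (monomer_size >= 2L) {
        pr <- if (monomer_size > 2L)
          sample.int(monomer_size, monomer_size - 2L, replace = TRUE)
        else integer(0)
        .prufer_tree(pr, monomer_size)
      } else matrix(0L, 0L, 2L)
      atoms <- rep(mono_atoms, k)
      edges <- matrix(0L, 0L, 2L)
      for (copy in seq_len(k)) {
        off <- (copy - 1L) * monomer_size
        if (nrow(mono_edges)) edges <- rbind(edges, mono_edges + off)
        if (copy > 1L) {
          # link last atom of previous copy to first atom of this copy
          edges <- rbind(edges, c(off, off + 1L))
        }
      }
    }
    molecule_graph(atoms,
                   data.frame(from = edges[, 1L], to = edges[, 2L],
                              order = 1L))
  })
}

#' Length-matched modular vs random string corpus
#'
#' The default corpus behind the class-separation analysis: for each of
#' `n_per_class` objects, a modular string is generated first (join count
#' drawn uniformly from `join_range`, regenerated until its length falls
#' inside `length_range`) and then paired with a random string of
#' identical length, so complexity differences are never artifacts of
#' length.
#'
#' @param n_per_class Objects per class.
#' @param alphabet_size Alphabet size (default 4; with a binary alphabet
#'   frequency-based measures such as Huffman coding degenerate to a
#'   constant — see the methods vignette).
#' @param reuse_bias Reuse bias of [gen_modular_string()].
#' @param length_range Inclusive length bounds for every string.
#' @param join_range Range of join counts sampled per modular string.
#' @param seed Corpus seed (default 42).
#' @return Data frame with `object_id`, `class` (`"modular"`/`"random"`)
#'   and `string`.
#' @export
gen_string_corpus <- function(n_per_class = 100L, alphabet_size = 4L,
                              reuse_bias = 0.8, length_range = c(8L, 16L),
                              join_range = c(3L, 8L), seed = 42L) {
  n_per_class <- .assert_count(n_per_class, "n_per_class")
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2])
  ids <- character(0); cls <- character(0); strs <- character(0)
  for (i in seq_len(n_per_class)) {
    attempt <- 0L
    repeat {
      nj <- .with_stream(seed, 10000L + i * 100L + attempt,
                         sample(seq(join_range[1], join_range[2]), 1L))
      ms <- gen_modular_string(nj, alphabet_size, reuse_bias,
                               seed = .derive_seed(seed, 20000L + i * 100L + attempt))
      len <- nchar(ms$string)
      if (len >= length_range[1] && len <= length_range[2]) break
      attempt <- attempt + 1L
      if (attempt > 500L) .stopf("could not hit length_range for object %d", i)
    }
    rs <- gen_random_string(nchar(ms$string), alphabet_size,
                            seed = .derive_seed(seed, 30000L + i))
    ids <- c(ids, sprintf("mod_%03d", i), sprintf("rnd_%03d", i))
    cls <- c(cls, "modular", "random")
    strs <- c(strs, ms$string, rs)
  }
  data.frame(object_id = ids, class = cls, string = strs,
             stringsAsFactors = FALSE)
}

#' Write a synthetic corpus to disk
#'
#' Writes one plain-text `.seq` file per string plus a `groups.csv`
#' manifest (`object_id`, `class_label`).
#'
#' @param corpus Data frame from [gen_string_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(corpus))) {
    writeLines(corpus$string[i],
               file.path(dir, paste0(corpus$object_id[i], ".seq")))
  }
  manifest <- data.frame(object_id = corpus$object_id,
                         class_label = corpus$class)
  utils::write.csv(manifest, file.path(dir, "groups.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#' @param dir Directory containing `.seq` files and `groups.csv`.
#' @return Data frame with `object_id`, `class`, `string`.
#' @export
read_corpus <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "groups.csv"),
                              stringsAsFactors = FALSE)
  strings <- vapply(manifest$object_id, function(id) {
    readLines(file.path(dir, paste0(id, ".seq")), warn = FALSE)[1L]
  }, character(1))
  data.frame(object_id = manifest$object_id, class = manifest$class_label,
             string = unname(strings), stringsAsFactors = FALSE)
}
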