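# Conversion of molecular inputs (identifier text, connection tables,
# peak matrices) into 1D sequences consumed by the complexity measures.

#' ASCII text to fixed 8-bit binary
#'
#' Encodes each character as its 8-bit ASCII code, the treatment applied
#' to identifier strings before binary complexity measures. The encoding
#' is injective and inverted exactly by [bits_to_ascii()].
#'
#' @param text A character string of 7-bit ASCII characters.
#' @return A 0/1 string of length `8 * nchar(text)`.
#' @examples
#' ascii_to_bits("A") # "01000001"
#' @export
ascii_to_bits <- function(text) {
  .assert_string(text, "text")
  if (nchar(text) == 0L) return("")
  codes <- utf8ToInt(text)
  bad <- which(is.na(codes) | codes > 127L)
  if (length(bad)) {
    .stopf("encoding-error: non-ASCII character at index %d", bad[1L])
  }
  bits <- vapply(codes, function(k) {
    .collapse(rev(as.integer(intToBits(k))[1:8]))
  }, character(1))
  .collapse(bits)
}

#' Decode 8-bit ASCII binary back to text
#' @param bits A 0/1 string whose length is a multiple of 8.
#' @return The decoded text.
#' @export
bits_to_ascii <- function(bits) {
  .assert_string(bits, "bits")
  n <- nchar(bits)
  if (n == 0L) return("")
  if (n %% 8L != 0L) .stopf("bit string length %d is not a multiple of 8", n)
  starts <- seq(1L, n, by = 8L)
  codes <- strtoi(substring(bits, starts, starts + 7L), base = 2L)
  intToUtf8(codes)
}

#' Flatten a matrix into a sequence
#'
#' Row-major flattening of the whole matrix (including the diagonal and
#' the symmetric duplicate, so symmetry stays detectable as redundancy).
#' In `"digits"` mode entries must be non-negative integers and are
#' capped at 9 so each entry is one symbol; in `"binary"` mode entries
#' are thresholded (`entry >= threshold` maps to 1).
#'
#' @param m A numeric matrix.
#' @param mode `"digits"` or `"binary"`.
#' @param threshold Threshold for binary mode (default 1).
#' @return A character string of length `nrow(m) * ncol(m)`.
#' @examples
#' matrix_to_sequence(matrix(c(0, 1, 1, 0), 2, byrow = TRUE)) # "0110"
#' @export
matrix_to_sequence <- function(m, mode = c("digits", "binary"), threshold = 1) {
  mode <- match.arg(mode)
  if (!is.matrix(m) || !is.numeric(m)) .stopf("`m` must be a numeric matrix")
  if (mode == "digits") {
    if (any(m < 0) || any(m != round(m))) {
      .stopf("digits mode requires non-negative integer entries")
    }
    v <- pmin(as.vector(t(m)), 9)
  } else {
    v <- as.integer(as.vector(t(m)) >= threshold)
  }
  .collapse(as.character(v))
}

#' Map an arbitrary sequence onto a binary alphabet
#'
#' Symbols already in \{0,1\} pass through unchanged; otherwise each
#' symbol of the (sorted) alphabet is replaced by its index written in
#' fixed-width binary, the minimal width that distinguishes all symbols.
#' Used to feed non-binary sequences to the CTM/BDM measure.
#'
#' @param s A non-empty character string.
#' @return A 0/1 string.
#' @export
sequence_to_binary <- function(s) {
  .assert_string(s, allow_empty = FALSE)
  ch <- .chars(s)
  ab <- sort(unique(ch))
  if (all(ab %in% c("0", "1"))) return(s)
  width <- max(1L, ceiling(log2(length(ab))))
  codes <- vapply(seq_along(ab) - 1L, function(k) {
    .collapse(rev(as.integer(intToBits(k))[seq_len(width)]))
  }, character(1))
  names(codes) <- ab
  .collapse(codes[ch])
}

# ---------------------------------------------------------------------------
# Molecule graphs and MOL V2000 connection tables

#' Construct a molecule graph
#'
#' @param atoms Character vector of element labels.
#' @param bonds Data frame with integer columns `from`, `to`, `order`
#'   (1-based atom indices).
#' @param check_connected Require the bond graph to be connected.
#' @return An object of class `MoleculeGraph`.
#' @export
molecule_graph <- function(atoms, bonds, check_connected = TRUE) {
  if (!is.character(atoms) || length(atoms) < 1L) {
    .stopf("invalid-argument: `atoms` must be a non-empty character vector")
  }
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0L) {
    need <- c("from", "to", "order")
    if (!all(need %in% names(bonds))) {
      .stopf("`bonds` needs columns from, to, order")
    }
    n <- length(atoms)
    if (any(bonds$from < 1L | bonds$from > n | bonds$to < 1L | bonds$to > n)) {
      .stopf("invalid-argument: bond atom index out of range 1..%d", n)
    }
    if (any(bonds$from == bonds$to)) .stopf("invalid-argument: self-bond")
  } else {
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  }
  mol <- structure(list(atoms = atoms, bonds = bonds), class = "MoleculeGraph")
  if (check_connected && !.mol_connected(mol)) {
    .stopf("invalid-argument: molecule graph is disconnected")
  }
  mol
}

.mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    mol$bonds[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = seq_along(mol$atoms))
  )
}

.mol_connected <- function(mol) {
  if (length(mol$atoms) == 1L) return(TRUE)
  if (nrow(mol$bonds) == 0L) return(FALSE)
  igraph::components(.mol_igraph(mol))$no == 1L
}

#' @export
print.MoleculeGraph <- function(x, ...) {
  cat(sprintf("MoleculeGraph: %d atoms (%s), %d bonds\n",
              length(x$atoms),
              paste(utils::head(x$atoms, 8L), collapse = ""),
              nrow(x$bonds)))
  invisible(x)
}

#' Bond (graph) distance matrix
#'
#' Entry (i, j) is the number of bonds on the shortest path between atoms
#' i and j. The graph must be connected (no infinite distances).
#'
#' @param mol A [molecule_graph()].
#' @return A symmetric integer matrix with zero diagonal.
#' @export
bond_distance_matrix <- function(mol) {
  if (!inherits(mol, "MoleculeGraph")) .stopf("`mol` must be a MoleculeGraph")
  if (!.mol_connected(mol)) .stopf("invalid-input: disconnected molecule graph")
  if (length(mol$atoms) == 1L) return(matrix(0L, 1L, 1L))
  d <- igraph::distances(.mol_igraph(mol))
  d <- d[order(as.integer(rownames(d))), order(as.integer(colnames(d)))]
  dimnames(d) <- NULL
  storage.mode(d) <- "integer"
  d
}

#' Read a MOL/SDF V2000 connection table
#'
#' Coordinates are read and ignored; only the topology matters. Atom
#' indices are 1-based on disk (the V2000 convention) and kept 1-based
#' internally, the natural R convention.
#'
#' @param path Path to a MOL V2000 file.
#' @return A [molecule_graph()].
#' @export
read_molfile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) .stopf("parse-error at line %d: truncated file", length(lines))
  counts <- lines[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || is.na(nb) || na < 1L || nb < 0L) {
    .stopf("parse-error at line 4: malformed counts line '%s'", counts)
  }
  if (length(lines) < 4L + na + nb) {
    .stopf("parse-error at line %d: expected %d atom and %d bond lines",
           length(lines), na, nb)
  }
  atoms <- character(na)
  for (i in seq_len(na)) {
    ln <- lines[4L + i]
    ln <- formatC(ln, width = 34L, flag = "-")
    el <- trimws(substr(ln, 32L, 34L))
    if (!nzchar(el)) .stopf("parse-error at line %d: missing element symbol", 4L + i)
    atoms[i] <- el
  }
  from <- integer(nb); to <- integer(nb); ord <- integer(nb)
  for (i in seq_len(nb)) {
    ln <- lines[4L + na + i]
    a1 <- suppressWarnings(as.integer(substr(ln, 1L, 3L)))
    a2 <- suppressWarnings(as.integer(substr(ln, 4L, 6L)))
    bo <- suppressWarnings(as.integer(substr(ln, 7L, 9L)))
    if (is.na(a1) || is.na(a2)) {
      .stopf("parse-error at line %d: malformed bond line", 4L + na + i)
    }
    if (a1 < 1L || a1 > na || a2 < 1L || a2 > na) {
      .stopf("parse-error at line %d: bond atom index out of range", 4L + na + i)
    }
    if (a1 == a2) .stopf("parse-error at line %d: self-bond", 4L + na + i)
    from[i] <- a1; to[i] <- a2; ord[i] <- if (is.na(bo)) 1L else bo
  }
  tryCatch(
    molecule_graph(atoms, data.frame(from = from, to = to, order = ord)),
    error = function(e) .stopf("parse-error: %s", conditionMessage(e))
  )
}

#' Write a molecule graph as MOL V2000
#'
#' Coordinates are written as zeros (topology only).
#'
#' @param mol A [molecule_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molfile <- function(mol, path) {
  if (!inherits(mol, "MoleculeGraph")) .stopf("`mol` must be a MoleculeGraph")
  na <- length(mol$atoms); nb <- nrow(mol$bonds)
  header <- c("generated", "", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, mol$atoms)
  bond_lines <- if (nb > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$from, mol$bonds$to, mol$bonds$order)
  } else character(0)
  writeLines(c(header, counts, atom_lines, bond_lines, "M  END"), path)
  invisible(path)
}
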