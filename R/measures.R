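# Statistical coding / compression complexity estimators.
#
# Each estimator returns its natural size proxy plus enough detail to
# decode again, so losslessness is testable. The scalar reported to the
# analysis stage per measure is: entropy = bits per block, RLE =
# encoded_length, Huffman = total_bits, LZ78 = phrase_count, LZW =
# code_count, LZ77 = triple_count (see `complexity_scalar()`).

#' Empirical block Shannon entropy
#'
#' Splits `s` into non-overlapping blocks of length `block` (a trailing
#' remainder shorter than `block` is discarded) and returns the empirical
#' entropy of the block distribution in bits per block.
#'
#' @param s A character string.
#' @param block Positive integer block length.
#' @return Entropy in bits per block (0 for a constant sequence).
#' @examples
#' shannon_entropy("0101", block = 1) # 1 bit
#' @export
shannon_entropy <- function(s, block = 1L) {
  .assert_string(s, allow_empty = FALSE)
  block <- .assert_count(block, "block")
  n <- nchar(s)
  if (n < block) .stopf("undefined-input: sequence shorter than one block")
  nb <- n %/% block
  starts <- (seq_len(nb) - 1L) * block + 1L
  blocks <- substring(s, starts, starts + block - 1L)
  p <- as.numeric(table(blocks)) / nb
  -sum(p * log2(p))
}

#' Run-length encoding
#'
#' Replaces maximal runs of a repeated symbol with (symbol, count) pairs.
#' The count is always written, including 1, so the encoding is
#' unambiguous. `encoded_length` is the total character cost:
#' one character for the symbol plus the decimal digits of the count.
#'
#' @param s A character string (may be empty).
#' @return A list with `runs` (data.frame of `symbol`, `count`),
#'   `encoded` (the literal encoded string), `encoded_length` and
#'   `run_count`.
#' @seealso [rle_decode()]
#' @examples
#' rle_encode("AAAABBB")$encoded # "A4B3"
#' @export
rle_encode <- function(s) {
  .assert_string(s)
  ch <- .chars(s)
  if (length(ch) == 0L) {
    return(list(runs = data.frame(symbol = character(0), count = integer(0)),
                encoded = "", encoded_length = 0L, run_count = 0L))
  }
  r <- rle(ch)
  runs <- data.frame(symbol = r$values, count = r$lengths,
                     stringsAsFactors = FALSE)
  list(runs = runs,
       encoded = .collapse(paste0(r$values, r$lengths)),
       encoded_length = sum(1L + nchar(as.character(r$lengths))),
       run_count = nrow(runs))
}

#' Decode a run-length encoding
#'
#' @param runs The `runs` data.frame produced by [rle_encode()].
#' @return The original string.
#' @export
rle_decode <- function(runs) {
  if (nrow(runs) == 0L) return("")
  .collapse(rep(runs$symbol, runs$count))
}

# Canonical Huffman tree with deterministic tie-breaking: always merge
# the two nodes with smallest (weight, creation index); leaves are
# created first, in symbol order, so ties resolve to the smallest symbol.
.huffman_code <- function(freq) {
  syms <- names(freq)
  k <- length(syms)
  if (k == 1L) return(stats::setNames("0", syms))
  nodes <- vector("list", 2L * k - 1L)
  for (i in seq_len(k)) {
    nodes[[i]] <- list(weight = as.numeric(freq[[i]]), created = i,
                       leaf = TRUE, symbol = syms[i])
  }
  active <- seq_len(k)
  counter <- k
  while (length(active) > 1L) {
    w <- vapply(nodes[active], `[[`, numeric(1), "weight")
    cr <- vapply(nodes[active], `[[`, numeric(1), "created")
    ord <- order(w, cr)
    a <- active[ord[1L]]; b <- active[ord[2L]]
    counter <- counter + 1L
    nodes[[counter]] <- list(weight = nodes[[a]]$weight + nodes[[b]]$weight,
                             created = counter, leaf = FALSE,
                             left = a, right = b)
    active <- c(setdiff(active, c(a, b)), counter)
  }
  code <- character(0)
  walk <- function(i, prefix) {
    nd <- nodes[[i]]
    if (nd$leaf) {
      code[[nd$symbol]] <<- prefix
    } else {
      walk(nd$left, paste0(prefix, "0"))
      walk(nd$right, paste0(prefix, "1"))
    }
  }
  walk(active, "")
  code[order(names(code))]
}

#' Huffman coding cost
#'
#' Builds a minimum-redundancy prefix code from the symbol frequencies of
#' `s` and reports the total encoded size in bits. For a single-symbol
#' alphabet the codeword has length 1 by convention (a code must emit
#' something per symbol), so `total_bits = nchar(s)`.
#'
#' @param s Non-empty character string.
#' @return A list with `total_bits`, `code` (named character vector of
#'   bitstrings) and `freq`.
#' @seealso [huffman_encode()], [huffman_decode()]
#' @examples
#' huffman_bits("AABC")$total_bits # 6
#' @export
huffman_bits <- function(s) {
  .assert_string(s, allow_empty = FALSE)
  ch <- .chars(s)
  freq <- table(ch)
  freq <- freq[order(names(freq))]
  code <- .huffman_code(freq)
  total <- sum(as.numeric(freq) * nchar(code[names(freq)]))
  list(total_bits = as.integer(total), code = code,
       freq = stats::setNames(as.integer(freq), names(freq)))
}

#' Encode a string with its Huffman code
#' @param s Non-empty character string.
#' @return List with `bits` (the 0/1 string) and `code`.
#' @export
huffman_encode <- function(s) {
  hb <- huffman_bits(s)
  ch <- .chars(s)
  list(bits = .collapse(hb$code[ch]), code = hb$code)
}

#' Decode a Huffman bitstream
#' @param bits A string of 0/1 characters.
#' @param code Named character vector mapping symbol to bitstring.
#' @return The decoded string.
#' @export
huffman_decode <- function(bits, code) {
  inv <- stats::setNames(names(code), code)
  out <- character(0)
  cur <- ""
  for (b in .chars(bits)) {
    cur <- paste0(cur, b)
    hit <- inv[cur]
    if (!is.na(hit)) {
      out <- c(out, hit)
      cur <- ""
    }
  }
  if (nzchar(cur)) .stopf("huffman_decode: dangling bits '%s'", cur)
  .collapse(out)
}

#' LZ78 incremental parsing
#'
#' Factors `s` into phrases, each being the longest previously seen
#' phrase extended by one symbol. All phrases are distinct except
#' possibly the last (which may be an exact repeat when the input ends
#' mid-phrase).
#'
#' @param s A character string (may be empty).
#' @return List with `phrases` (character vector, concatenating to `s`)
#'   and `phrase_count`.
#' @examples
#' lz78_parse("abab")$phrases # "a" "b" "ab"
#' @export
lz78_parse <- function(s) {
  .assert_string(s)
  ch <- .chars(s)
  dict <- new.env(parent = emptyenv(), hash = TRUE)
  phrases <- character(0)
  w <- ""
  for (c in ch) {
    wc <- paste0(w, c)
    if (exists(wc, envir = dict, inherits = FALSE)) {
      w <- wc
    } else {
      phrases <- c(phrases, wc)
      assign(wc, TRUE, envir = dict)
      w <- ""
    }
  }
  if (nzchar(w)) phrases <- c(phrases, w)
  list(phrases = phrases, phrase_count = length(phrases))
}

#' Reassemble an LZ78 parse
#' @param phrases Character vector of phrases.
#' @return The original string.
#' @export
lz78_decode <- function(phrases) .collapse(phrases)

#' LZW compression
#'
#' Standard LZW with the dictionary initialised to the sorted alphabet of
#' `s`. Codes index the dictionary (1-based).
#'
#' @param s Non-empty character string.
#' @return List with `codes` (integer vector), `code_count`, `dict_size`
#'   (final dictionary size) and `alphabet` (the initial dictionary).
#' @seealso [lzw_decompress()]
#' @examples
#' lzw_compress("ABABAB")$code_count # 4
#' @export
lzw_compress <- function(s) {
  .assert_string(s, allow_empty = FALSE)
  ch <- .chars(s)
  alphabet <- sort(unique(ch))
  dict <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(alphabet)) assign(alphabet[i], i, envir = dict)
  nextcode <- length(alphabet) + 1L
  codes <- integer(0)
  w <- ""
  for (c in ch) {
    wc <- paste0(w, c)
    if (exists(wc, envir = dict, inherits = FALSE)) {
      w <- wc
    } else {
      codes <- c(codes, get(w, envir = dict))
      assign(wc, nextcode, envir = dict)
      nextcode <- nextcode + 1L
      w <- c
    }
  }
  codes <- c(codes, get(w, envir = dict))
  list(codes = codes, code_count = length(codes),
       dict_size = nextcode - 1L, alphabet = alphabet)
}

#' Decompress an LZW code stream
#' @param codes Integer vector from [lzw_compress()].
#' @param alphabet The initial dictionary (sorted character vector).
#' @return The original string.
#' @export
lzw_decompress <- function(codes, alphabet) {
  if (length(codes) == 0L) return("")
  dict <- as.list(alphabet)
  w <- dict[[codes[1L]]]
  out <- w
  for (code in codes[-1L]) {
    entry <- if (code <= length(dict)) {
      dict[[code]]
    } else if (code == length(dict) + 1L) {
      paste0(w, substr(w, 1L, 1L)) # the just-about-to-be-added phrase
    } else {
      .stopf("lzw_decompress: invalid code %d", code)
    }
    out <- paste0(out, entry)
    dict[[length(dict) + 1L]] <- paste0(w, substr(entry, 1L, 1L))
    w <- entry
  }
  out
}

#' LZ77 greedy factorisation
#'
#' Greedy longest-match parsing into (offset, length, next-symbol)
#' triples. Self-overlapping matches are allowed (offset < length) and
#' the window is unbounded by default. Among equally long matches the
#' smallest offset wins. A literal is `(0, 0, symbol)`; when a match
#' consumes the string to its end the next symbol is `NA`.
#'
#' @param s A character string (may be empty).
#' @param window Maximum look-back distance (default `Inf`).
#' @return List with `triples` (data.frame `offset`, `length`, `next_sym`)
#'   and `triple_count`.
#' @seealso [lz77_reconstruct()]
#' @export
lz77_parse <- function(s, window = Inf) {
  .assert_string(s)
  ch <- .chars(s)
  n <- length(ch)
  offset <- integer(0); len <- integer(0); nxt <- character(0)
  i <- 1L
  while (i <= n) {
    best_len <- 0L; best_off <- 0L
    if (i > 1L) {
      L <- n - i + 1L
      lo <- max(1L, as.integer(max(1, i - window)))
      for (j in (i - 1L):lo) { # descending j = ascending offset
        if (ch[j] != ch[i]) next
        m <- ch[j:(j + L - 1L)] == ch[i:(i + L - 1L)]
        bad <- which(!m)
        l <- if (length(bad)) bad[1L] - 1L else L
        if (l > best_len) {
          best_len <- l
          best_off <- i - j
          if (l == L) break
        }
      }
    }
    if (best_len == 0L) {
      offset <- c(offset, 0L); len <- c(len, 0L); nxt <- c(nxt, ch[i])
      i <- i + 1L
    } else {
      nx <- if (i + best_len <= n) ch[i + best_len] else NA_character_
      offset <- c(offset, best_off); len <- c(len, best_len); nxt <- c(nxt, nx)
      i <- i + best_len + 1L
    }
  }
  triples <- data.frame(offset = offset, length = len, next_sym = nxt,
                        stringsAsFactors = FALSE)
  list(triples = triples, triple_count = nrow(triples))
}

#' Reconstruct a string from LZ77 triples
#' @param triples Data frame from [lz77_parse()].
#' @return The original string.
#' @export
lz77_reconstruct <- function(triples) {
  out <- character(0)
  for (r in seq_len(nrow(triples))) {
    off <- triples$offset[r]; l <- triples$length[r]
    if (l > 0L) {
      for (t in seq_len(l)) { # char-by-char so self-overlap copies work
        out <- c(out, out[length(out) - off + 1L])
      }
    }
    if (!is.na(triples$next_sym[r])) out <- c(out, triples$next_sym[r])
  }
  .collapse(out)
}

#' Scalar complexity value for the analysis stage
#'
#' Maps each measure to its natural size proxy: `entropy` = bits per
#' block, `rle` = encoded length in characters, `huffman` = total bits,
#' `lz77` = triple count, `lz78` = phrase count, `lzw` = code count,
#' `assembly` = assembly index (exact when `nchar(s) <= max_len`, greedy
#' beyond), `bdm` = Block Decomposition Method value in bits.
#'
#' @param s Non-empty character string.
#' @param measure One of `"entropy"`, `"rle"`, `"huffman"`, `"lz77"`,
#'   `"lz78"`, `"lzw"`, `"assembly"`, `"bdm"`.
#' @param ctm_table A [build_ctm_table()] table (required for `"bdm"`).
#' @param block Block length: entropy blocks (default 1) and BDM blocks
#'   (default 4, compatible with the exhaustive 2-state table).
#' @param max_len Longest string for which the exact assembly search runs.
#' @return A single non-negative number.
#' @export
complexity_scalar <- function(s, measure, ctm_table = NULL, block = NULL,
                              max_len = 20L) {
  .assert_string(s, allow_empty = FALSE)
  switch(measure,
    entropy  = shannon_entropy(s, block = if (is.null(block)) 1L else block),
    rle      = rle_encode(s)$encoded_length,
    huffman  = huffman_bits(s)$total_bits,
    lz77     = lz77_parse(s)$triple_count,
    lz78     = lz78_parse(s)$phrase_count,
    lzw      = lzw_compress(s)$code_count,
    assembly = {
      if (nchar(s) <= max_len) assembly_index_exact(s, max_len = max_len)$index
      else assembly_index_greedy(s)$index
    },
    bdm = {
      if (is.null(ctm_table)) .stopf("bdm requires `ctm_table`")
      b <- sequence_to_binary(s)
      bdm(b, ctm_table, block_length = if (is.null(block)) 4L else block)$value
    },
    .stopf("unknown measure '%s'", measure)
  )
}
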