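# Reduced-scale Coding Theorem Method (CTM) and Block Decomposition
# Method (BDM).
#
# CTM approximates the algorithmic probability of a short binary string
# s as D(s) = (halting machines outputting s) / (halting machines), over
# an exhaustive enumeration of small 2-symbol Turing machines in the
# busy-beaver formalism, and reports CTM(s) = -log2 D(s) bits. BDM
# extends the table to longer sequences by summing, over the distinct
# non-overlapping blocks of a sequence, CTM(block) + log2(multiplicity).

# steps the busy beaver needs for n in 1..3; exhaustive enumeration
# requires max_steps at or above this so that every halting machine halts
.BB_STEPS <- c(1L, 6L, 21L)

.ctm_cache <- new.env(parent = emptyenv())

#' Build a CTM table by Turing machine enumeration
#'
#' Enumerates the `(4n+2)^(2n)` two-symbol, `n`-state Turing machines
#' (an extra halt state; a halting transition writes a symbol and stops)
#' of the standard busy-beaver formalism, runs each from a tape of blank
#' 0s for at most `max_steps` steps, and records the contiguous visited
#' tape segment of each halting machine as its output. To restore the
#' 0/1 exchange symmetry that a one-sided blank convention breaks, each
#' output is counted together with its complement — exactly equivalent
#' to running the full enumeration on blank-0 and blank-1 tapes (the
#' machine set is closed under the symbol-exchange map). The table maps
#' each output string to `-log2` of its output frequency.
#'
#' @param states Number of states (1, 2 or 3 for exhaustive mode).
#' @param max_steps Step budget per machine (default 107; must be at
#'   least the busy-beaver step bound in exhaustive mode).
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param n_sample Number of machines to sample (sampled mode).
#' @param seed Seed for sampled mode.
#' @param chunk_size Machines simulated per vectorised chunk.
#' @return A `CTMTable`: list with `entries` (named numeric, bits) and
#'   `meta`.
#' @export
build_ctm_table <- function(states = 2L, max_steps = 107L,
                            mode = c("exhaustive", "sampled"),
                            n_sample = NULL, seed = NULL,
                            chunk_size = 50000L) {
  states <- .assert_count(states, "states")
  max_steps <- .assert_count(max_steps, "max_steps")
  mode <- match.arg(mode)
  base <- 4L * states + 2L
  total <- base^(2L * states)
  if (mode == "exhaustive") {
    if (states > 3L) {
      .stopf("exhaustive enumeration refuses states > 3 (combinatorial blowup)")
    }
    if (max_steps < .BB_STEPS[states]) {
      .stopf("exhaustive mode needs max_steps >= %d for %d states",
             .BB_STEPS[states], states)
    }
    idx_all <- NULL # all machines, chunked below
  } else {
    if (is.null(n_sample) || is.null(seed)) {
      .stopf("sampled mode requires `n_sample` and `seed`")
    }
    n_sample <- .assert_count(n_sample, "n_sample")
    idx_all <- .with_stream(seed, 4L, {
      sample(total, min(n_sample, total)) - 1
    })
  }

  n_machines <- if (is.null(idx_all)) total else length(idx_all)
  outputs <- character(0)
  done <- 0
  while (done < n_machines) {
    m <- min(chunk_size, n_machines - done)
    idx <- if (is.null(idx_all)) done + seq_len(m) - 1 else idx_all[done + seq_len(m)]
    outputs <- c(outputs, .run_tm_chunk(idx, states, max_steps))
    done <- done + m
  }

  # symmetrise: count each output and its 0<->1 complement
  outputs_sym <- c(outputs, chartr("01", "10", outputs))
  counts <- table(outputs_sym)
  halted <- length(outputs)
  entries <- -log2(as.numeric(counts) / (2 * halted))
  names(entries) <- names(counts)

  structure(list(
    entries = entries,
    meta = list(states = states, symbols = 2L, max_steps = max_steps,
                machines_total = total, machines_halted = halted,
                method = if (is.null(idx_all)) "exhaustive" else "sampled")
  ), class = "CTMTable")
}

# Vectorised simulation of one chunk of machines from blank-0 tape.
# Transition codes 0..(4n+1) per (state, read symbol): code < 4n encodes
# (write = code %% 2, move = code %/% 2 %% 2 [0 left, 1 right],
#  next = code %/% 4 + 1); code >= 4n halts writing (code - 4n).
.run_tm_chunk <- function(idx, states, max_steps) {
  m <- length(idx)
  base <- 4L * states + 2L
  npairs <- 2L * states
  trans <- matrix(0L, m, npairs)
  d <- idx
  for (p in seq_len(npairs)) {
    trans[, p] <- as.integer(d %% base)
    d <- d %/% base
  }
  width <- 2L * max_steps + 3L
  center <- max_steps + 2L
  tape <- matrix(0L, m, width)
  pos <- rep(center, m)
  minpos <- pos; maxpos <- pos
  state <- rep(1L, m)
  active <- rep(TRUE, m)
  halted <- rep(FALSE, m)
  for (step in seq_len(max_steps)) {
    act <- which(active)
    if (!length(act)) break
    sym <- tape[cbind(act, pos[act])]
    code <- trans[cbind(act, (state[act] - 1L) * 2L + sym + 1L)]
    is_halt <- code >= 4L * states
    if (any(is_halt)) {
      h <- act[is_halt]
      tape[cbind(h, pos[h])] <- code[is_halt] - 4L * states
      active[h] <- FALSE
      halted[h] <- TRUE
    }
    if (any(!is_halt)) {
      a <- act[!is_halt]
      cd <- code[!is_halt]
      tape[cbind(a, pos[a])] <- cd %% 2L
      mv <- ifelse((cd %/% 2L) %% 2L == 1L, 1L, -1L)
      pos[a] <- pos[a] + mv
      minpos[a] <- pmin(minpos[a], pos[a])
      maxpos[a] <- pmax(maxpos[a], pos[a])
      state[a] <- cd %/% 4L + 1L
    }
  }
  hs <- which(halted)
  vapply(hs, function(r) {
    paste0(tape[r, minpos[r]:maxpos[r]], collapse = "")
  }, character(1))
}

#' @export
print.CTMTable <- function(x, ...) {
  cat(sprintf("CTMTable (%s): %d entries, states = %d, halted = %s of %s machines\n",
              x$meta$method, length(x$entries), x$meta$states,
              format(x$meta$machines_halted, big.mark = ","),
              format(x$meta$machines_total, big.mark = ",")))
  invisible(x)
}

#' CTM value of a string
#' @param table A `CTMTable`.
#' @param s Binary string.
#' @return CTM value in bits, or `NA` if `s` is not in the table.
#' @export
ctm_value <- function(table, s) {
  v <- table$entries[s]
  unname(v)
}

# memoised default table used by the pipeline and tests
.default_ctm_table <- function(states = 2L) {
  key <- sprintf("exh_%d", states)
  if (is.null(.ctm_cache[[key]])) {
    .ctm_cache[[key]] <- build_ctm_table(states = states)
  }
  .ctm_cache[[key]]
}

#' Block Decomposition Method
#'
#' Splits the binary sequence into non-overlapping blocks of
#' `block_length` (a trailing remainder is discarded) and returns the sum
#' over distinct blocks of `CTM(block) + log2(multiplicity)`. Blocks
#' absent from the table are scored with the near-maximal surrogate
#' `block_length + 1` bits and counted in `missing_blocks`, so reduced
#' tables never silently deflate the value.
#'
#' @param s Binary (0/1) character string.
#' @param table A `CTMTable` covering strings at least `block_length`
#'   long.
#' @param block_length Block size (default 8; use 4 with the exhaustive
#'   2-state table, whose longest output has length 4).
#' @return A `BDMValue`: list with `value` (bits), `block_length`,
#'   `boundary_policy`, `missing_blocks`.
#' @export
bdm <- function(s, table, block_length = 8L) {
  .assert_string(s, allow_empty = FALSE)
  if (!inherits(table, "CTMTable")) .stopf("`table` must be a CTMTable")
  block_length <- .assert_count(block_length, "block_length")
  ch <- .chars(s)
  if (!all(ch %in% c("0", "1"))) .stopf("bdm requires a binary sequence")
  maxcov <- max(nchar(names(table$entries)))
  if (block_length > maxcov) {
    .stopf("block_length %d exceeds longest table string (%d)",
           block_length, maxcov)
  }
  nb <- nchar(s) %/% block_length
  if (nb < 1L) .stopf("undefined-input: sequence shorter than one block")
  starts <- (seq_len(nb) - 1L) * block_length + 1L
  blocks <- substring(s, starts, starts + block_length - 1L)
  tab <- table(blocks)
  vals <- table$entries[names(tab)]
  missing <- sum(is.na(vals))
  vals[is.na(vals)] <- block_length + 1
  structure(list(value = sum(vals + log2(as.numeric(tab))),
                 block_length = block_length,
                 boundary_policy = "discard-trailing",
                 missing_blocks = as.integer(missing)),
            class = "BDMValue")
}

#' @export
print.BDMValue <- function(x, ...) {
  cat(sprintf("BDM = %.4f bits (block %d, %d missing block(s), %s)\n",
              x$value, x$block_length, x$missing_blocks, x$boundary_policy))
  invisible(x)
}

#' Save a CTM table as CSV
#'
#' Writes a `#meta` header line carrying the provenance metadata and then
#' `string,ctm_bits` rows.
#'
#' @param table A `CTMTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_ctm_table <- function(table, path) {
  meta <- table$meta
  hdr <- sprintf("#meta states=%d symbols=%d max_steps=%d machines_total=%.0f machines_halted=%.0f method=%s",
                 meta$states, meta$symbols, meta$max_steps,
                 meta$machines_total, meta$machines_halted, meta$method)
  keys <- names(table$entries)[order(nchar(names(table$entries)),
                                     names(table$entries))]
  rows <- sprintf("%s,%.12g", keys, table$entries[keys])
  writeLines(c(hdr, "string,ctm_bits", rows), path)
  invisible(path)
}

#' Load a CTM table from CSV
#'
#' Accepts externally published CTM tables in `string,ctm_bits` form
#' (optionally with a `#meta` first line). Strings must be binary and
#' unique, values positive. The loaded table's method is `"loaded"`.
#'
#' @param path Path to a CSV file.
#' @return A `CTMTable`.
#' @export
load_ctm_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list(states = NA_integer_, symbols = 2L, max_steps = NA_integer_,
               machines_total = NA_real_, machines_halted = NA_real_,
               method = "loaded")
  offset <- 0L
  if (length(lines) && startsWith(lines[1L], "#meta")) {
    kv <- strsplit(trimws(sub("^#meta", "", lines[1L])), "\\s+")[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2L && parts[1] %in% names(meta) && parts[1] != "method") {
        meta[[parts[1]]] <- as.numeric(parts[2])
      }
    }
    offset <- 1L
  }
  if (length(lines) > offset && grepl("^string\\s*,", lines[offset + 1L])) {
    offset <- offset + 1L
  }
  rows <- lines[seq.int(offset + 1L, length.out = length(lines) - offset)]
  rows <- rows[nzchar(trimws(rows))]
  if (!length(rows)) .stopf("parse-error: empty CTM table")
  keys <- character(length(rows)); vals <- numeric(length(rows))
  for (i in seq_along(rows)) {
    parts <- strsplit(rows[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L) .stopf("parse-error at row %d: expected 2 fields", i)
    key <- trimws(parts[1]); val <- suppressWarnings(as.numeric(parts[2]))
    if (!grepl("^[01]+$", key)) {
      .stopf("parse-error at row %d: non-binary string '%s'", i, key)
    }
    if (is.na(val) || val <= 0) {
      .stopf("parse-error at row %d: non-positive value", i)
    }
    keys[i] <- key; vals[i] <- val
  }
  if (anyDuplicated(keys)) {
    .stopf("parse-error at row %d: duplicate string '%s'",
           which(duplicated(keys))[1L], keys[duplicated(keys)][1L])
  }
  structure(list(entries = stats::setNames(vals, keys), meta = meta),
            class = "CTMTable")
}
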