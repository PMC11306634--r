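# The assembly index for sequences: exact minimal assembly pathway by
# search, a greedy longest-repeat upper bound, and analytic bounds.
#
# Join model: binary concatenation of previously available objects. The
# basis is the set of distinct symbols of the target (free, not counted
# as steps); every product of a valid pathway is a contiguous substring
# of the target, and the index is the number of join steps.

.assembly_result <- function(index, steps, method, is_exact) {
  pathway <- if (is.null(steps) || nrow(steps) == 0L) {
    data.frame(left = character(0), right = character(0),
               product = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(left = steps[, 1L], right = steps[, 2L], product = steps[, 3L],
               stringsAsFactors = FALSE)
  }
  structure(list(index = as.integer(index), pathway = pathway,
                 method = method, is_exact = is_exact),
            class = "AssemblyResult")
}

#' @export
print.AssemblyResult <- function(x, ...) {
  cat(sprintf("AssemblyResult: index = %d (%s%s), %d pathway step(s)\n",
              x$index, x$method, if (x$is_exact) ", exact" else "",
              nrow(x$pathway)))
  invisible(x)
}

#' Exact assembly index of a string
#'
#' Global minimum number of join steps over all assembly pathways, found
#' by iterative deepening over the pathway length with memoised canonical
#' states; the search space is restricted to substrings of `s` (every
#' node of a concatenation tree for `s` is one). The returned pathway is
#' a witness realising the minimum.
#'
#' @param s Non-empty character string, at most `max_len` characters.
#' @param max_len Refusal threshold (default 20): beyond it the search
#'   cost grows super-exponentially, use [assembly_index_greedy()] or
#'   [assembly_bounds()] instead.
#' @return An `AssemblyResult` with `is_exact = TRUE`.
#' @examples
#' assembly_index_exact("AAAA")$index # 2
#' @export
assembly_index_exact <- function(s, max_len = 20L) {
  .assert_string(s, allow_empty = FALSE)
  if (nchar(s) > max_len) {
    .stopf(paste0("string length %d exceeds max_len = %d; use ",
                  "assembly_index_greedy() or assembly_bounds() instead"),
           nchar(s), max_len)
  }
  cap <- min(assembly_index_greedy(s)$index, assembly_bounds(s)$lz78_upper)
  res <- .assembly_exact_cpp(s, as.integer(cap))
  .assembly_result(res$index, res$steps, "exact", TRUE)
}

# Greedy left-to-right longest-match cover of `x` by built objects and
# single symbols; returns the parts.
.greedy_cover <- function(x, built) {
  parts <- character(0)
  pos <- 1L
  n <- nchar(x)
  objs <- built[order(-nchar(built))]
  while (pos <= n) {
    hit <- NA_character_
    for (b in objs) {
      lb <- nchar(b)
      if (pos + lb - 1L <= n && substr(x, pos, pos + lb - 1L) == b) {
        hit <- b
        break
      }
    }
    if (is.na(hit)) hit <- substr(x, pos, pos)
    parts <- c(parts, hit)
    pos <- pos + nchar(hit)
  }
  parts
}

# Longest proper substring of x (length >= 2) with at least two
# non-overlapping occurrences in x; leftmost among ties.
.longest_repeat <- function(x) {
  n <- nchar(x)
  for (L in seq.int(n %/% 2L, 2L)) {
    if (L < 2L) break
    for (st in seq_len(n - L + 1L)) {
      cand <- substr(x, st, st + L - 1L)
      count <- 0L
      pos <- 1L
      while (pos + L - 1L <= n) {
        if (substr(x, pos, pos + L - 1L) == cand) {
          count <- count + 1L
          pos <- pos + L
        } else {
          pos <- pos + 1L
        }
      }
      if (count >= 2L) return(cand)
    }
  }
  NA_character_
}

#' Greedy assembly index upper bound
#'
#' Recursive longest-repeat scheme: to build an object, find its longest
#' repeated substring (at least two non-overlapping occurrences; leftmost
#' among equally long candidates), build that once — recursively, so
#' nested repeats are also reused — and then assemble the object as a
#' left-associated chain over the greedy longest-match cover by the
#' objects built so far. Always an upper bound on the exact index, with a
#' valid witness pathway.
#'
#' @param s Non-empty character string.
#' @return An `AssemblyResult` with `is_exact = FALSE`.
#' @export
assembly_index_greedy <- function(s) {
  .assert_string(s, allow_empty = FALSE)
  if (nchar(s) == 1L) return(.assembly_result(0L, NULL, "greedy", FALSE))
  built <- character(0)
  steps <- matrix(character(0), 0L, 3L)
  build_chain <- function(target) {
    # join the greedy cover of `target` left to right, recording steps
    parts <- .greedy_cover(target, built)
    acc <- parts[1L]
    for (p in parts[-1L]) {
      prod <- paste0(acc, p)
      steps <<- rbind(steps, c(acc, p, prod))
      if (nchar(prod) > 1L && !(prod %in% built)) built <<- c(built, prod)
      acc <- prod
    }
    invisible(NULL)
  }
  build_obj <- function(x) {
    if (nchar(x) == 1L || x %in% built) return(invisible(NULL))
    t <- .longest_repeat(x)
    if (!is.na(t)) build_obj(t)
    build_chain(x)
    invisible(NULL)
  }
  build_obj(s)
  .assembly_result(nrow(steps), steps, "greedy", FALSE)
}

#' Analytic assembly index bounds
#'
#' `lower` is the doubling limit `ceil(log2(nchar(s)))`: each join can at
#' most double the longest object built so far. `lz78_upper` is
#' constructive: every LZ78 phrase is its prefix phrase plus one symbol
#' (one join per distinct multi-symbol phrase), and the phrases are then
#' joined left to right.
#'
#' @param s Non-empty character string.
#' @return List with `lower` and `lz78_upper`.
#' @export
assembly_bounds <- function(s) {
  .assert_string(s, allow_empty = FALSE)
  n <- nchar(s)
  lower <- as.integer(ceiling(log2(n) - 1e-12))
  p <- lz78_parse(s)
  k <- p$phrase_count
  multi <- unique(p$phrases[nchar(p$phrases) > 1L])
  lz78_upper <- as.integer(length(multi) + max(0L, k - 1L))
  list(lower = lower, lz78_upper = lz78_upper)
}

#' Brute-force assembly index (reference implementation)
#'
#' An intentionally simple breadth-first search over sets of built
#' substrings, with no pruning beyond the substring closure that defines
#' the state space. Exponential; intended as an independent check of
#' [assembly_index_exact()] on short strings.
#'
#' @param s Non-empty character string (keep it short).
#' @return The minimal number of joins (integer).
#' @export
assembly_index_bfs <- function(s) {
  .assert_string(s, allow_empty = FALSE)
  .assembly_oracle_cpp(s)
}

#' Replay an assembly pathway
#'
#' Checks that every operand of every step is a single symbol of the
#' target's alphabet or the product of an earlier step, that every
#' product is a contiguous substring of the target, and that the last
#' product equals the target.
#'
#' @param pathway Data frame with columns `left`, `right`, `product`.
#' @param target The target string.
#' @return `TRUE` (invisibly) if valid; otherwise an error.
#' @export
validate_pathway <- function(pathway, target) {
  alphabet <- unique(.chars(target))
  if (nchar(target) == 1L && nrow(pathway) == 0L) return(invisible(TRUE))
  if (nrow(pathway) == 0L) .stopf("empty pathway for multi-symbol target")
  available <- alphabet
  for (i in seq_len(nrow(pathway))) {
    l <- pathway$left[i]; r <- pathway$right[i]; p <- pathway$product[i]
    if (!(l %in% available)) .stopf("step %d: operand '%s' not available", i, l)
    if (!(r %in% available)) .stopf("step %d: operand '%s' not available", i, r)
    if (paste0(l, r) != p) .stopf("step %d: %s + %s != %s", i, l, r, p)
    if (!grepl(p, target, fixed = TRUE)) {
      .stopf("step %d: product '%s' is not a substring of the target", i, p)
    }
    available <- c(available, p)
  }
  if (pathway$product[nrow(pathway)] != target) {
    .stopf("last product does not equal the target")
  }
  invisible(TRUE)
}
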