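# Independent oracles used by the test suite. These deliberately take
# different computational routes from the package implementations.

# Minimum total encoded bits over all prefix-free codes with non-empty
# codewords, by exhaustive enumeration of merge orders (every full binary
# code tree arises from some order of pairwise merges; its cost is the
# sum of the merged weights). For a single symbol the shortest non-empty
# codeword has length 1, so the minimum is the total frequency.
oracle_min_prefix_bits <- function(s) {
  freq <- as.numeric(table(strsplit(s, "")[[1]]))
  if (length(freq) == 1L) return(sum(freq))
  rec <- function(w) {
    if (length(w) == 1L) return(0)
    best <- Inf
    for (i in seq_len(length(w) - 1L)) {
      for (j in seq.int(i + 1L, length(w))) {
        merged <- w[i] + w[j]
        best <- min(best, merged + rec(c(w[-c(i, j)], merged)))
      }
    }
    best
  }
  rec(freq)
}

# Pearson r and one-tailed p through R's own machinery.
oracle_pearson <- function(x, y) {
  ct <- stats::cor.test(x, y, alternative = "greater", method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# AUC by exhaustive enumeration of cross-pairs, ties half-weighted.
# Group 2 vs group 1, matching separation()'s orientation.
oracle_auc <- function(g1, g2) {
  wins <- 0
  for (a in g1) for (b in g2) wins <- wins + (b > a) + 0.5 * (b == a)
  wins / (length(g1) * length(g2))
}

# All-pairs shortest bond paths by plain breadth-first search.
oracle_bfs_distances <- function(mol) {
  n <- length(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(NA_integer_, n, n)
  for (src in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[src] <- 0L
    queue <- src
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    d[src, ] <- dist
  }
  d
}

# Independent pathway replayer: tracks the multiset of available objects
# and re-derives each product by literal concatenation.
oracle_replay_pathway <- function(pathway, target) {
  avail <- unique(strsplit(target, "")[[1]])
  if (nrow(pathway) == 0L) return(nchar(target) == 1L)
  for (i in seq_len(nrow(pathway))) {
    if (!(pathway$left[i] %in% avail)) return(FALSE)
    if (!(pathway$right[i] %in% avail)) return(FALSE)
    if (paste0(pathway$left[i], pathway$right[i]) != pathway$product[i]) {
      return(FALSE)
    }
    avail <- c(avail, pathway$product[i])
  }
  pathway$product[nrow(pathway)] == target
}

# Seeded random test string.
rand_string <- function(len, alphabet_size = 2L) {
  if (len == 0L) return("")
  paste(sample(letters[seq_len(alphabet_size)], len, replace = TRUE),
        collapse = "")
}
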