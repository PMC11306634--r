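# internal helpers shared across modules

.chars <- function(s) {
  if (nchar(s) == 0L) return(character(0))
  strsplit(s, "", fixed = TRUE)[[1]]
}

.collapse <- function(x) paste0(x, collapse = "")

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.assert_string <- function(s, name = "s", allow_empty = TRUE) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    .stopf("`%s` must be a single character string", name)
  }
  if (!allow_empty && nchar(s) == 0L) {
    .stopf("undefined-input: `%s` must be non-empty", name)
  }
  invisible(s)
}

.assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    .stopf("invalid-argument: `%s` must be an integer >= %d", name, min)
  }
  as.integer(x)
}

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    .stopf("invalid-argument: `%s` must be a probability in [0, 1]", name)
  }
  as.numeric(x)
}

# Splittable seeding: one integer seed plus a stream index gives an
# independent substream; all constants keep intermediates exactly
# representable as doubles and the result below 2^31.
.derive_seed <- function(seed, stream = 0L) {
  seed <- .assert_count(seed, "seed", min = -2147483647)
  as.integer(((abs(seed) %% 65011) * 33029 +
                (abs(stream) %% 262139) * 7919 + 17) %% 2147483587)
}

.with_stream <- function(seed, stream, code) {
  withr::with_seed(.derive_seed(seed, stream), code)
}
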