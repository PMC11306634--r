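# Analysis stage: per-object complexity profiles, pairwise Pearson
# correlations with one-tailed p-values, and rank-based two-group
# separation (AUC / Cliff's delta plus per-group median and IQR).

#' Pearson correlation with a one-tailed p-value
#'
#' Product-moment correlation; the p-value comes from the t statistic
#' \code{r * sqrt((n - 2) / (1 - r^2))} against a Student t distribution with
#' `n - 2` degrees of freedom. The tested direction is positive
#' correlation (`alternative = "greater"`, the default); a two-sided
#' p-value is available by flag. P-values are uncorrected.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @param alternative `"greater"` (upper tail, default) or `"two.sided"`.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_one_tailed <- function(x, y, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3L) .stopf("insufficient-data: need n >= 3")
  if (anyNA(x) || anyNA(y)) .stopf("x and y must be complete")
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) {
    .stopf("degenerate-input: constant vector has no defined correlation")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
  r <- max(-1, min(1, r))
  tstat <- if (abs(r) == 1) Inf * sign(r) else r * sqrt((n - 2) / (1 - r^2))
  p <- if (alternative == "greater") {
    stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  p <- max(p, .Machine$double.xmin) # p in (0, 1]
  list(r = r, p = p, n = n)
}

#' Two-group separation statistics
#'
#' AUC is the Mann-Whitney U statistic divided by `n1 * n2` (ties counted
#' one half): the probability that a random member of the second group
#' exceeds a random member of the first. Cliff's delta is `2 * AUC - 1`.
#' Medians and interquartile ranges are reported per group because the
#' underlying comparisons argue via medians and ranges, not a single
#' statistic.
#'
#' @param values Numeric vector.
#' @param labels Vector with exactly two distinct labels; the first
#'   level (sorted order, or factor level order) is the reference group.
#' @return List with `groups`, `median`, `iqr`, `n`, `auc`,
#'   `cliffs_delta`.
#' @export
separation <- function(values, labels) {
  if (length(values) != length(labels)) .stopf("lengths differ")
  f <- factor(labels)
  if (nlevels(f) != 2L) .stopf("invalid-input: exactly two groups required")
  g1 <- values[f == levels(f)[1L]]
  g2 <- values[f == levels(f)[2L]]
  if (!length(g1) || !length(g2)) .stopf("invalid-input: empty group")
  r <- rank(c(g1, g2)) # midranks handle ties at half weight
  n1 <- length(g1); n2 <- length(g2)
  u2 <- sum(r[(n1 + 1L):(n1 + n2)]) - n2 * (n2 + 1) / 2
  auc <- u2 / (n1 * n2)
  list(groups = levels(f),
       median = c(stats::median(g1), stats::median(g2)),
       iqr = c(stats::quantile(g1, 0.75) - stats::quantile(g1, 0.25),
               stats::quantile(g2, 0.75) - stats::quantile(g2, 0.25)),
       n = c(n1, n2),
       auc = unname(auc),
       cliffs_delta = unname(2 * auc - 1))
}

#' Validate and construct a tidy results table
#'
#' Records are `(object_id, group, representation, measure, value)`; the
#' key `(object_id, representation, measure)` must be unique and all
#' values finite.
#'
#' @param records A data.frame with the five columns above.
#' @return The validated data.frame (class `ResultsTable`).
#' @export
results_table <- function(records) {
  need <- c("object_id", "group", "representation", "measure", "value")
  if (!all(need %in% names(records))) {
    .stopf("records need columns: %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(records$value))) .stopf("non-finite value in records")
  key <- paste(records$object_id, records$representation, records$measure)
  if (anyDuplicated(key)) {
    .stopf("duplicate (object_id, representation, measure) record")
  }
  class(records) <- c("ResultsTable", "data.frame")
  records
}

.rt_wide <- function(rt, representation) {
  sub <- rt[rt$representation == representation, , drop = FALSE]
  if (!nrow(sub)) .stopf("no records for representation '%s'", representation)
  objects <- unique(sub$object_id)
  measures <- sort(unique(sub$measure))
  wide <- matrix(NA_real_, length(objects), length(measures),
                 dimnames = list(objects, measures))
  wide[cbind(match(sub$object_id, objects), match(sub$measure, measures))] <-
    sub$value
  wide
}

#' Pairwise correlation report for one representation
#'
#' All measure pairs once, pairwise-complete: objects missing either
#' measure of a pair are dropped for that pair and the drop count is
#' reported in the `dropped` column (and via a message).
#'
#' @param rt A [results_table()].
#' @param representation Representation to analyse.
#' @param alternative Passed to [pearson_one_tailed()].
#' @return Data frame with `measure_a`, `measure_b`, `r`, `p_one_tailed`,
#'   `n`, `dropped`.
#' @export
correlation_matrix <- function(rt, representation,
                               alternative = "greater") {
  wide <- .rt_wide(rt, representation)
  measures <- colnames(wide)
  if (length(measures) < 2L) .stopf("insufficient-data: need >= 2 measures")
  complete <- sum(stats::complete.cases(wide))
  if (complete < 3L) {
    .stopf("insufficient-data: %d object(s) with complete profiles", complete)
  }
  out <- NULL
  total_dropped <- 0L
  for (i in seq_along(measures)[-length(measures)]) {
    for (j in seq.int(i + 1L, length(measures))) {
      ok <- is.finite(wide[, i]) & is.finite(wide[, j])
      dropped <- sum(!ok)
      total_dropped <- total_dropped + dropped
      if (sum(ok) < 3L) {
        .stopf("insufficient-data for pair %s / %s", measures[i], measures[j])
      }
      pr <- pearson_one_tailed(wide[ok, i], wide[ok, j],
                               alternative = alternative)
      out <- rbind(out, data.frame(measure_a = measures[i],
                                   measure_b = measures[j],
                                   r = pr$r, p_one_tailed = pr$p,
                                   n = pr$n, dropped = dropped,
                                   stringsAsFactors = FALSE))
    }
  }
  if (total_dropped > 0L) {
    message(sprintf("correlation_matrix: %d pairwise-incomplete drops",
                    total_dropped))
  }
  out
}

#' Per-measure separation report
#'
#' @param rt A [results_table()].
#' @param representation Representation to analyse.
#' @return Data frame with one row per measure: group medians and IQRs,
#'   `auc` and `cliffs_delta`.
#' @export
separation_report <- function(rt, representation) {
  wide <- .rt_wide(rt, representation)
  sub <- rt[rt$representation == representation, , drop = FALSE]
  grp <- sub$group[match(rownames(wide), sub$object_id)]
  f <- factor(grp)
  if (nlevels(f) != 2L) .stopf("invalid-input: exactly two groups required")
  out <- NULL
  for (m in colnames(wide)) {
    ok <- is.finite(wide[, m])
    s <- separation(wide[ok, m], grp[ok])
    out <- rbind(out, data.frame(
      measure = m,
      group_a = s$groups[1L], group_b = s$groups[2L],
      median_a = s$median[1L], median_b = s$median[2L],
      iqr_a = s$iqr[1L], iqr_b = s$iqr[2L],
      n_a = s$n[1L], n_b = s$n[2L],
      auc = s$auc, cliffs_delta = s$cliffs_delta,
      stringsAsFactors = FALSE))
  }
  out
}

.default_config <- function() {
  list(kind = "strings", n_per_class = 100L, alphabet_size = 4L,
       reuse_bias = 0.8, length_range = c(8L, 16L), join_range = c(3L, 8L),
       representation = "raw-text",
       measures = c("entropy", "rle", "huffman", "lz77", "lz78", "lzw",
                    "assembly"),
       bdm_block = 4L, seed = 42L)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates (or loads) a corpus, computes the configured measures on the
#' chosen representation, and produces the tidy results table, the
#' correlation report and the separation report, together with a run
#' manifest embedding the config and seed for exact reruns.
#'
#' @param config A named list (missing fields take defaults; see
#'   `Details`) or a path to a JSON config file. Fields: `n_per_class`,
#'   `alphabet_size`, `reuse_bias`, `length_range`, `join_range`,
#'   `representation` (`"raw-text"` or `"ascii-binary"`), `measures`
#'   (any of entropy, rle, huffman, lz77, lz78, lzw, assembly, bdm),
#'   `bdm_block`, `seed`. An optional `external_ma` data.frame
#'   (`object_id`, `MA`) merges externally supplied assembly values as
#'   measure `"MA"`; unknown object ids are reported, never silently
#'   dropped.
#' @param out_dir Optional output directory for `results.csv`,
#'   `correlations.csv`, `separation.csv` and `manifest.json`.
#' @param corpus Optional pre-built corpus data frame (overrides
#'   generation).
#' @return List with `results`, `correlations`, `separation`, `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, corpus = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(.default_config(), config)
  external_ma <- cfg$external_ma
  cfg$external_ma <- NULL

  if (is.null(corpus)) {
    corpus <- gen_string_corpus(n_per_class = cfg$n_per_class,
                                alphabet_size = cfg$alphabet_size,
                                reuse_bias = cfg$reuse_bias,
                                length_range = cfg$length_range,
                                join_range = cfg$join_range,
                                seed = cfg$seed)
  }

  ctm_table <- if ("bdm" %in% cfg$measures) .default_ctm_table(2L) else NULL
  records <- NULL
  for (i in seq_len(nrow(corpus))) {
    s <- corpus$string[i]
    if (cfg$representation == "ascii-binary") s <- ascii_to_bits(s)
    for (m in cfg$measures) {
      v <- complexity_scalar(s, m, ctm_table = ctm_table,
                             block = if (m == "bdm") cfg$bdm_block else NULL)
      records <- rbind(records, data.frame(
        object_id = corpus$object_id[i], group = corpus$class[i],
        representation = cfg$representation, measure = m, value = v,
        stringsAsFactors = FALSE))
    }
  }

  if (!is.null(external_ma)) {
    external_ma <- as.data.frame(external_ma)
    unknown <- setdiff(external_ma$object_id, corpus$object_id)
    if (length(unknown)) {
      warning(sprintf("external MA column: %d unknown object_id(s): %s",
                      length(unknown),
                      paste(utils::head(unknown, 5L), collapse = ", ")))
    }
    known <- external_ma[external_ma$object_id %in% corpus$object_id, ,
                         drop = FALSE]
    if (nrow(known)) {
      records <- rbind(records, data.frame(
        object_id = known$object_id,
        group = corpus$class[match(known$object_id, corpus$object_id)],
        representation = cfg$representation, measure = "MA",
        value = known$MA, stringsAsFactors = FALSE))
    }
  }

  rt <- results_table(records)
  correlations <- correlation_matrix(rt, cfg$representation)
  sep <- NULL
  if (length(unique(rt$group)) == 2L) {
    sep <- separation_report(rt, cfg$representation)
  } else {
    warning("separation report omitted: need exactly two groups")
  }
  manifest <- list(config = cfg, seed = cfg$seed,
                   n_objects = nrow(corpus),
                   package = "molcomplexity",
                   version = as.character(utils::packageVersion("molcomplexity")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rt, file.path(out_dir, "results.csv"), row.names = FALSE)
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    if (!is.null(sep)) {
      utils::write.csv(sep, file.path(out_dir, "separation.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(results = rt, correlations = correlations, separation = sep,
       manifest = manifest)
}
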