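# Statistics stage: Pearson with one-tailed p, rank-based separation,
# correlation/separation reports and pipeline plumbing.

test_that("pearson_one_tailed matches closed-form values and R's oracle", {
  expect_equal(pearson_one_tailed(1:4, 1:4)$r, 1)
  expect_equal(pearson_one_tailed(1:4, -(1:4))$r, -1)
  pr <- pearson_one_tailed(c(1, 2, 3), c(1, 2, 4))
  or <- oracle_pearson(c(1, 2, 3), c(1, 2, 4))
  expect_equal(pr$r, or$r, tolerance = 1e-12)
  expect_equal(pr$p, or$p, tolerance = 1e-12)
  set.seed(501)
  for (i in 1:60) {
    n <- sample(3:25, 1)
    x <- rnorm(n); y <- rnorm(n)
    pr <- pearson_one_tailed(x, y)
    or <- oracle_pearson(x, y)
    expect_equal(pr$r, or$r, tolerance = 1e-12)
    expect_equal(pr$p, or$p, tolerance = 1e-12)
    pr2 <- pearson_one_tailed(x, y, alternative = "two.sided")
    ct2 <- stats::cor.test(x, y)$p.value
    expect_equal(pr2$p, ct2, tolerance = 1e-12)
  }
  expect_error(pearson_one_tailed(rep(1, 5), 1:5), "degenerate-input")
  expect_error(pearson_one_tailed(1:2, 1:2), "insufficient-data")
  # p stays in (0, 1] even at |r| = 1
  expect_gt(pearson_one_tailed(1:4, 1:4)$p, 0)
})

test_that("separation reproduces exhaustive cross-pair AUC", {
  s <- separation(c(1, 2, 9, 10), c("a", "a", "b", "b"))
  expect_equal(s$auc, 1)
  same <- separation(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$auc, 0.5)
  s2 <- separation(c(1, 3, 5, 2, 4, 6), rep(c("a", "b"), each = 3))
  expect_equal(s2$auc, oracle_auc(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(s2$auc, (s2$cliffs_delta + 1) / 2)
  # relabelling flips the AUC
  s3 <- separation(c(1, 3, 5, 2, 4, 6), rep(c("b", "a"), each = 3))
  expect_equal(s3$auc, 1 - s2$auc)
  set.seed(502)
  for (i in 1:30) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    g1 <- sample(1:6, n1, TRUE); g2 <- sample(1:6, n2, TRUE)
    s <- separation(c(g1, g2), rep(c("a", "b"), c(n1, n2)))
    expect_equal(s$auc, oracle_auc(g1, g2))
  }
  expect_error(separation(1:3, c("a", "a", "a")), "two groups")
})

test_that("correlation_matrix covers all pairs with pairwise deletion", {
  rt <- results_table(data.frame(
    object_id = rep(sprintf("o%02d", 1:10), each = 3),
    group = "g",
    representation = "raw-text",
    measure = rep(c("m1", "m2", "m3"), 10),
    value = c(rbind(1:10, 1:10, 10:1))))
  cm <- correlation_matrix(rt, "raw-text")
  expect_equal(nrow(cm), 3L)
  expect_equal(cm$r[cm$measure_a == "m1" & cm$measure_b == "m2"], 1)
  expect_equal(cm$r[cm$measure_a == "m1" & cm$measure_b == "m3"], -1)
  # missing values are dropped pairwise-complete and counted
  rt2 <- rt[-c(2, 5), ] # drop m2 for two objects
  cm2 <- suppressMessages(correlation_matrix(results_table(rt2), "raw-text"))
  expect_equal(cm2$n[cm2$measure_a == "m1" & cm2$measure_b == "m2"], 8L)
  expect_equal(cm2$dropped[cm2$measure_a == "m1" & cm2$measure_b == "m2"], 2L)
  # too few complete objects
  rt3 <- results_table(data.frame(
    object_id = c("a", "a", "b", "b"), group = "g",
    representation = "raw-text", measure = rep(c("m1", "m2"), 2),
    value = c(1, 2, 3, 4)))
  expect_error(correlation_matrix(rt3, "raw-text"), "insufficient-data")
})

test_that("results_table enforces uniqueness and finiteness", {
  bad <- data.frame(object_id = c("a", "a"), group = "g",
                    representation = "r", measure = "m", value = c(1, 2))
  expect_error(results_table(bad), "duplicate")
  bad2 <- data.frame(object_id = c("a", "b"), group = "g",
                     representation = "r", measure = "m", value = c(1, NaN))
  expect_error(results_table(bad2), "finite")
})

test_that("run_pipeline is deterministic and writes stable outputs", {
  cfg <- list(n_per_class = 6L, measures = c("rle", "lz78", "lzw"),
              seed = 7L)
  d1 <- tempfile("run1"); d2 <- tempfile("run2")
  r1 <- run_pipeline(cfg, out_dir = d1)
  r2 <- run_pipeline(cfg, out_dir = d2)
  for (f in c("results.csv", "correlations.csv", "separation.csv",
              "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_equal(sort(unique(r1$results$measure)), c("lz78", "lzw", "rle"))
  expect_equal(nrow(r1$results), 12L * 3L)
  # config can come from a JSON file
  cfile <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfile, auto_unbox = TRUE)
  r3 <- run_pipeline(cfile)
  expect_identical(r3$results$value, r1$results$value)
})

test_that("external MA columns join the correlation report", {
  cfg <- list(n_per_class = 6L, measures = c("rle", "lz78"), seed = 7L)
  corpus <- gen_string_corpus(n_per_class = 6L, seed = 7L)
  ma <- data.frame(object_id = c(corpus$object_id, "ghost"),
                   MA = c(seq_len(nrow(corpus)), 99))
  expect_warning(
    res <- run_pipeline(c(cfg, list(external_ma = ma)), corpus = corpus),
    "unknown object_id")
  expect_true("MA" %in% res$results$measure)
  expect_true(any(res$correlations$measure_a == "MA" |
                    res$correlations$measure_b == "MA"))
})

test_that("a single-group corpus omits the separation report with a warning", {
  corpus <- gen_string_corpus(n_per_class = 4L, seed = 3L)
  corpus <- corpus[corpus$class == "modular", ]
  expect_warning(
    res <- run_pipeline(list(measures = c("rle", "lz78"), seed = 3L),
                        corpus = corpus),
    "two groups")
  expect_null(res$separation)
})
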