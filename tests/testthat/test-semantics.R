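test_that("tokenization lowercases, strips punctuation, drops stop-words", {
  expect_equal(preprocess_list("Koira, kissa!"), c("koira", "kissa"))
  expect_equal(preprocess_list("ja se on", stopwords = c("ja", "se", "on")),
               character())
  expect_equal(preprocess_list("Talo talo"), c("talo", "talo"))
  expect_equal(preprocess_list(""), character())
  expect_equal(preprocess_list(NA_character_), character())
})

test_that("list vectors are embedding sums with OOV tokens discarded", {
  emb <- toy_embeddings()
  one <- list_vector("koira", emb)
  expect_equal(one$vector, c(1, 0, 0))
  two <- list_vector(c("koira", "kissa"), emb)
  expect_equal(two$vector, c(1, 1, 0))
  mixed <- list_vector(c("koira", "xyzzy"), emb)
  expect_equal(mixed$vector, c(1, 0, 0))
  expect_equal(mixed$n_oov, 1L)
  none <- list_vector(c("foo", "bar"), emb)
  expect_true(none$missing)
  expect_null(none$vector)
  # repetition contributes twice to the sum
  dup <- list_vector(c("talo", "talo"), emb)
  expect_equal(dup$vector, c(0, 0, 2))
})

test_that("cosine similarity: hand values, range, scale invariance", {
  v <- c(0.3, -1.2, 4)
  expect_equal(cosine_similarity(v, v), 1, tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2),
               tolerance = 1e-12)
  set.seed(30)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    cs <- cosine_similarity(a, b)
    expect_equal(cs, naive_cosine(a, b), tolerance = 1e-12)
    expect_lte(abs(cs), 1 + 1e-12)
    expect_equal(cosine_similarity(3.7 * a, b), cs, tolerance = 1e-12)
  }
})

test_that("within-group cosines exclude missing vectors and need two", {
  vs <- list(c(1, 0), NULL, c(1, 1))
  expect_equal(within_group_cosines(vs), 1 / sqrt(2), tolerance = 1e-12)
  expect_null(within_group_cosines(list(c(1, 0), NULL)))
})

test_that("adding a duplicated word pulls other cosines toward that word", {
  emb <- toy_embeddings()
  base <- list_vector(c("koira", "kissa"), emb)$vector
  more <- list_vector(c("koira", "kissa", "koira"), emb)$vector
  target <- list_vector("koira", emb)$vector
  expect_equal(cosine_similarity(more, more), 1, tolerance = 1e-12)
  expect_gt(cosine_similarity(more, target), cosine_similarity(base, target))
})

test_that("segment permutation test handles degenerate and strong cases", {
  res <- segment_permutation_test(rep(0.5, 5), rep(0.5, 6),
                                  n_permutations = 200, seed = 1)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_perm, 1)
  set.seed(31)
  res <- segment_permutation_test(rnorm(20, 0.6, 0.05), rnorm(20, 0.3, 0.05),
                                  n_permutations = 5000, seed = 2)
  expect_lt(res$p_perm, 0.001)
  expect_equal(res$direction, "A")
})

test_that("pair-level test is exact for exchangeable cosine values", {
  set.seed(32)
  hits <- vapply(1:400, function(i) {
    a <- rnorm(12, 0.4, 0.1); b <- rnorm(10, 0.4, 0.1)
    segment_permutation_test(a, b, n_permutations = 400,
                             seed = 1000 + i)$p_perm <= 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.02 + 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("participant-relabeling test matches a direct recomputation", {
  set.seed(33)
  d <- 6
  va <- lapply(1:5, function(i) rnorm(d))
  vb <- lapply(1:4, function(i) rnorm(d))
  res <- segment_permutation_test_subjects(va, vb, n_permutations = 300,
                                           seed = 3)
  cos_a <- within_group_cosines(va)
  cos_b <- within_group_cosines(vb)
  t_direct <- (mean(cos_a) - mean(cos_b)) /
    sqrt(var(cos_a) / length(cos_a) + var(cos_b) / length(cos_b))
  expect_equal(res$t_statistic, t_direct, tolerance = 1e-10)
  expect_equal(res$n_pairs_A, 10)
  expect_equal(res$n_pairs_B, 6)
})

test_that("participant relabeling is calibrated under exchangeability", {
  set.seed(34)
  hits <- vapply(1:300, function(i) {
    vs <- lapply(1:16, function(j) rnorm(8) + c(2, rep(0, 7)))
    segment_permutation_test_subjects(vs[1:8], vs[9:16],
                                      n_permutations = 300,
                                      seed = 2000 + i)$p_perm <= 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.02 + 2 * sqrt(0.05 * 0.95 / 300))
})

test_that("FDR over segments flags exactly the right hand-built case", {
  res <- data.frame(segment = 1:101,
                    p_perm = c(0.0001, rep(1, 100)),
                    direction = c("A", rep("none", 100)),
                    testable = TRUE)
  out <- fdr_over_segments(res, q = 0.05)
  expect_equal(which(out$flagged), 1L)
  expect_equal(unname(attr(out, "counts")["A_higher"]), 1L)
  none <- fdr_over_segments(transform(res, p_perm = 1), q = 0.05)
  expect_false(any(none$flagged))
})

test_that("word-count contrast reproduces the printed percent difference", {
  res <- word_count_contrast(18724, 12536)
  expect_equal(res$percent_difference, (18724 - 12536) / 18724 * 100,
               tolerance = 1e-12)
  expect_equal(round(res$percent_difference), 33)
  expect_equal(word_count_contrast(c(5, 5), c(5, 5))$percent_difference, 0)
  expect_equal(word_count_contrast(c(5, 5), c(5, 5))$p_value, 1)
  # strictly positive paired differences put the signed-rank statistic at
  # its extreme (all ranks positive; the negative-rank sum is 0)
  res <- word_count_contrast(c(10, 12, 14, 16), c(5, 6, 7, 8))
  expect_equal(res$statistic, 4 * 5 / 2)
  expect_equal(res$higher_group, "A")
})

test_that("embedding tables round-trip through the plain-text format", {
  emb <- toy_embeddings()
  f <- tempfile(fileext = ".txt")
  write_embeddings(emb, f)
  back <- read_embeddings(f)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-7)
  expect_equal(embedding_coverage(emb, c("koira", "nope")), 0.5)
})
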