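#' Word-embedding table
#'
#' A plain lookup from word to a fixed-dimension semantic vector. The
#' analysis core never trains embeddings; any provider can be plugged in
#' by constructing this table (the study-scale reference used a skip-gram
#' model with 500 dimensions, window 10, minimum count 50, 5 passes --
#' recorded here as conventional defaults in `metadata`).
#'
#' @param vectors numeric matrix, one row per word, with rownames.
#' @param metadata optional list of provenance/training metadata.
#' @return An `embedding_table`.
#' @export
embedding_table <- function(vectors, metadata = list()) {
  vectors <- as.matrix(vectors)
  if (is.null(rownames(vectors))) stop("`vectors` must have word rownames")
  if (any(!is.finite(vectors))) stop("embedding vectors must be finite")
  structure(list(vectors = vectors, dim = ncol(vectors), metadata = metadata),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d words, %d dimensions\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Read / write a plain-text embedding table
#'
#' One word per line: the token followed by its whitespace-separated
#' vector components.
#'
#' @param path file path.
#' @return [read_embeddings()]: an [embedding_table()].
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  words <- vapply(parts, `[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]),
                   numeric(length(parts[[1]]) - 1L)))
  rownames(vecs) <- words
  embedding_table(vecs)
}

#' @rdname read_embeddings
#' @param emb an [embedding_table()].
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_table"))
  lines <- paste(rownames(emb$vectors),
                 apply(emb$vectors, 1, function(v)
                   paste(format(v, digits = 8, trim = TRUE, scientific = FALSE),
                         collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Fraction of tokens covered by the embedding vocabulary
#' @param emb an [embedding_table()].
#' @param tokens character vector of tokens.
#' @return proportion of tokens found in the vocabulary.
#' @export
embedding_coverage <- function(emb, tokens) {
  if (length(tokens) == 0) return(NA_real_)
  mean(tokens %in% rownames(emb$vectors))
}

#' Tokenize a free-association response
#'
#' Lowercases, strips punctuation and digits-adjacent separators, splits
#' on whitespace and removes stop-words. Duplicates are kept: the list
#' vector is a sum, so a repeated word intentionally contributes twice.
#' Spelling correction is assumed to have happened upstream.
#'
#' @param raw_text character scalar (possibly empty or `NA`).
#' @param stopwords character vector of tokens to drop.
#' @return character vector of tokens (possibly empty).
#' @export
preprocess_list <- function(raw_text, stopwords = character()) {
  if (is.na(raw_text) || !nzchar(raw_text)) return(character())
  x <- tolower(raw_text)
  x <- gsub("[^[:alnum:]]+", " ", x)
  tokens <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  tokens[!tokens %in% stopwords]
}

#' Semantic vector of a word list
#'
#' The vector sum of the embeddings of all in-vocabulary tokens.
#' Out-of-vocabulary tokens are discarded and counted; a list with no
#' usable tokens yields a flagged missing vector (not an error).
#'
#' @param tokens character vector of tokens.
#' @param emb an [embedding_table()].
#' @return list with `vector` (numeric, or `NULL` when missing),
#'   `n_used`, `n_oov`, `missing`.
#' @export
list_vector <- function(tokens, emb) {
  stopifnot(inherits(emb, "embedding_table"))
  inv <- tokens %in% rownames(emb$vectors)
  n_used <- sum(inv)
  if (n_used == 0)
    return(list(vector = NULL, n_used = 0L, n_oov = length(tokens),
                missing = TRUE))
  v <- colSums(emb$vectors[tokens[inv], , drop = FALSE])
  list(vector = as.numeric(v), n_used = n_used,
       n_oov = length(tokens) - n_used, missing = FALSE)
}

#' Cosine similarity of two vectors
#' @param a,b numeric vectors of equal length.
#' @return inner product divided by the product of norms; `NA` if either
#'   vector has zero norm.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Within-group pairwise cosine similarities for one segment
#'
#' Cosine similarity for every unordered pair of participants with a
#' non-missing list vector. Fewer than 2 usable vectors marks the segment
#' untestable for that group (`NULL`).
#'
#' @param vectors list of numeric vectors (entries may be `NULL` for
#'   participants with no usable words).
#' @return numeric vector of pairwise cosines, or `NULL` if untestable.
#' @export
within_group_cosines <- function(vectors) {
  usable <- Filter(Negate(is.null), vectors)
  n <- length(usable)
  if (n < 2) return(NULL)
  cmb <- combn(n, 2)
  vapply(seq_len(ncol(cmb)), function(p)
    cosine_similarity(usable[[cmb[1, p]]], usable[[cmb[2, p]]]), numeric(1))
}

# Welch (or pooled) two-sample t; degenerate zero-variance cases give 0
# when the means agree and +/-Inf otherwise.
two_sample_t <- function(a, b, var_equal = FALSE) {
  nA <- length(a); nB <- length(b)
  num <- mean(a) - mean(b)
  den <- if (var_equal) {
    sp2 <- ((nA - 1) * var(a) + (nB - 1) * var(b)) / (nA + nB - 2)
    sqrt(sp2 * (1 / nA + 1 / nB))
  } else {
    sqrt(var(a) / nA + var(b) / nB)
  }
  if (!is.finite(den) || den == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / den
}

#' Permutation t-test comparing two sets of pairwise cosines
#'
#' Two-tailed nonparametric t-test: the observed two-sample t statistic
#' (Welch by default) on the two groups' pairwise cosine similarities is
#' compared against its distribution under random exchange of cosine
#' values between the groups (pair-level exchange, mirroring the imaging
#' contrast). `p = (#\{|t_perm| >= |t_obs|\} + 1) / (P + 1)`.
#'
#' Pair-level exchange treats the pooled cosines as exchangeable, which
#' they are not when pairs share a participant: a participant whose list
#' vector sits closer to the segment topic raises every cosine they take
#' part in. This test is therefore anti-conservative in the presence of
#' participant effects; [segment_permutation_test_subjects()] relabels
#' participants instead and is the calibrated default of
#' [semantic_similarity_analysis()].
#'
#' @param cos_A,cos_B numeric vectors of within-group pairwise cosines.
#' @param n_permutations number of permutations (default 50000).
#' @param seed RNG seed.
#' @param var_equal use the pooled-variance t instead of Welch.
#' @return list with `t_statistic`, `p_perm`, `direction` (`"A"` or `"B"`
#'   for the more coherent group, `"none"` on a tie), `n_pairs_A`,
#'   `n_pairs_B`.
#' @export
segment_permutation_test <- function(cos_A, cos_B, n_permutations = 50000,
                                     seed = 1L, var_equal = FALSE) {
  nA <- length(cos_A); nB <- length(cos_B)
  if (nA < 2 || nB < 2) stop("need at least 2 cosine values per group")
  t_obs <- two_sample_t(cos_A, cos_B, var_equal)
  pool <- c(cos_A, cos_B)
  n <- nA + nB
  set.seed(seed)
  idx <- vapply(seq_len(n_permutations), function(i) sample.int(n, nA),
                integer(nA))
  xa <- matrix(pool[idx], nA, n_permutations)
  sA <- colSums(xa); ssA <- colSums(xa^2)
  sT <- sum(pool); ssT <- sum(pool^2)
  mA <- sA / nA; mB <- (sT - sA) / nB
  vA <- (ssA - nA * mA^2) / (nA - 1)
  vB <- ((ssT - ssA) - nB * mB^2) / (nB - 1)
  vA <- pmax(vA, 0); vB <- pmax(vB, 0)
  num <- mA - mB
  den <- if (var_equal) {
    sqrt((((nA - 1) * vA + (nB - 1) * vB) / (n - 2)) * (1 / nA + 1 / nB))
  } else {
    sqrt(vA / nA + vB / nB)
  }
  tp <- num / den
  tp[den == 0 & num == 0] <- 0
  tp[den == 0 & num != 0] <- Inf
  p <- (sum(abs(tp) >= abs(t_obs)) + 1) / (n_permutations + 1)
  direction <- if (mean(cos_A) > mean(cos_B)) "A"
               else if (mean(cos_A) < mean(cos_B)) "B" else "none"
  list(t_statistic = t_obs, p_perm = p, direction = direction,
       n_pairs_A = nA, n_pairs_B = nB)
}

#' Participant-relabeling permutation test of within-group similarity
#'
#' Same statistic as [segment_permutation_test()] -- a two-sample t on the
#' two groups' within-group pairwise cosines -- but the null is built by
#' relabeling participants between groups and recomputing both
#' within-group cosine sets from the full participant-by-participant
#' cosine matrix. Under the null hypothesis that participants are
#' exchangeable this test is exact, and unlike pair-level exchange it
#' respects the dependence among cosines that share a participant.
#'
#' @param vectors_A,vectors_B lists of list vectors for the two groups
#'   (entries may be `NULL` for participants with no usable words;
#'   zero-norm vectors are likewise excluded).
#' @param n_permutations number of relabelings (default 50000).
#' @param seed RNG seed.
#' @param var_equal use the pooled-variance t instead of Welch.
#' @return as [segment_permutation_test()].
#' @export
segment_permutation_test_subjects <- function(vectors_A, vectors_B,
                                              n_permutations = 50000,
                                              seed = 1L, var_equal = FALSE) {
  usable <- function(vs) Filter(function(v) !is.null(v) && sum(v^2) > 0, vs)
  va <- usable(vectors_A); vb <- usable(vectors_B)
  nA <- length(va); nB <- length(vb)
  if (nA < 2 || nB < 2) stop("need at least 2 usable vectors per group")
  U <- do.call(cbind, c(va, vb))
  U <- U / rep(sqrt(colSums(U^2)), each = nrow(U))
  M <- crossprod(U)                    # participant cosine matrix
  n <- nA + nB
  kA <- nA * (nA - 1) / 2; kB <- nB * (nB - 1) / 2

  block_stats <- function(ind) {
    # ind: n x P indicator matrix of group-A membership
    q1 <- colSums(ind * (M %*% ind))       # 1'_A M 1_A (includes diagonal)
    q2 <- colSums(ind * ((M * M) %*% ind))
    cbind(sum = (q1 - colSums(ind)) / 2, ssq = (q2 - colSums(ind)) / 2)
  }
  t_from_sums <- function(sA, ssA, sB, ssB) {
    mA <- sA / kA; mB <- sB / kB
    vA <- pmax((ssA - kA * mA^2) / (kA - 1), 0)
    vB <- pmax((ssB - kB * mB^2) / (kB - 1), 0)
    num <- mA - mB
    den <- if (var_equal)
      sqrt((((kA - 1) * vA + (kB - 1) * vB) / (kA + kB - 2)) * (1 / kA + 1 / kB))
    else sqrt(vA / kA + vB / kB)
    t <- num / den
    t[den == 0 & num == 0] <- 0
    t[den == 0 & num != 0] <- Inf
    t
  }

  obs_ind <- matrix(0, n, 2)
  obs_ind[seq_len(nA), 1] <- 1
  obs_ind[nA + seq_len(nB), 2] <- 1
  oa <- block_stats(obs_ind[, 1, drop = FALSE])
  ob <- block_stats(obs_ind[, 2, drop = FALSE])
  t_obs <- t_from_sums(oa[1, "sum"], oa[1, "ssq"], ob[1, "sum"], ob[1, "ssq"])

  set.seed(seed)
  ind <- matrix(0, n, n_permutations)
  for (i in seq_len(n_permutations)) ind[sample.int(n, nA), i] <- 1
  pa <- block_stats(ind)
  pb <- block_stats(1 - ind)
  tp <- t_from_sums(pa[, "sum"], pa[, "ssq"], pb[, "sum"], pb[, "ssq"])
  p <- (sum(abs(tp) >= abs(t_obs)) + 1) / (n_permutations + 1)

  mA <- oa[1, "sum"] / kA; mB <- ob[1, "sum"] / kB
  list(t_statistic = unname(t_obs), p_perm = p,
       direction = if (mA > mB) "A" else if (mA < mB) "B" else "none",
       n_pairs_A = kA, n_pairs_B = kB)
}

#' FDR correction over narrative segments
#'
#' Benjamini-Hochberg over the testable segments' permutation p-values,
#' with a three-way direction summary (group A more similar, group B more
#' similar, not significant).
#'
#' @param results data.frame with columns `segment`, `p_perm`,
#'   `direction`, `testable` (as produced by
#'   [semantic_similarity_analysis()]).
#' @param q FDR level (default 0.05).
#' @return the input with `q_fdr` and `flagged` columns added, plus a
#'   `counts` attribute `(A_higher, B_higher, ns)`.
#' @export
fdr_over_segments <- function(results, q = 0.05) {
  if (!any(results$testable)) stop("no testable segments")
  results$q_fdr <- NA_real_
  results$flagged <- FALSE
  idx <- which(results$testable)
  adj <- fdr_correct(results$p_perm[idx], q)
  results$q_fdr[idx] <- adj$p_adjusted
  results$flagged[idx] <- adj$mask
  counts <- c(A_higher = sum(results$flagged & results$direction == "A"),
              B_higher = sum(results$flagged & results$direction == "B"),
              ns = sum(results$testable) - sum(results$flagged))
  attr(results, "counts") <- counts
  results
}

#' Word-count contrast between groups
#'
#' Percent difference of total word counts, `(larger - smaller) / larger
#' * 100`, and a two-tailed Wilcoxon signed-rank test on the paired
#' per-segment counts.
#'
#' @param counts_A,counts_B numeric vectors of per-segment word totals,
#'   aligned by segment.
#' @return list with `percent_difference`, `total_A`, `total_B`,
#'   `higher_group`, `statistic` (signed-rank V), `p_value`.
#' @export
word_count_contrast <- function(counts_A, counts_B) {
  if (length(counts_A) != length(counts_B))
    stop("counts must be aligned by segment")
  tA <- sum(counts_A); tB <- sum(counts_B)
  hi <- max(tA, tB); lo <- min(tA, tB)
  pct <- if (hi == 0) 0 else (hi - lo) / hi * 100
  d <- counts_A - counts_B
  if (all(d == 0)) {
    stat <- 0; p <- 1
  } else {
    wt <- suppressWarnings(wilcox.test(counts_A, counts_B, paired = TRUE,
                                       exact = FALSE))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  list(percent_difference = pct, total_A = tA, total_B = tB,
       higher_group = if (tA >= tB) "A" else "B",
       statistic = stat, p_value = p)
}

#' Segment-wise semantic-similarity analysis of free-association lists
#'
#' End-to-end behavioral arm: tokenizes every participant-segment word
#' list, forms list vectors by embedding sums, computes within-group
#' pairwise cosine similarities per segment, runs a permutation t-test
#' per segment, corrects over segments with BH-FDR, and contrasts word
#' counts between groups.
#'
#' @param word_lists data.frame with columns `participant_id`, `group`
#'   (`"A"`/`"B"`), `segment`, `words` (space-separated).
#' @param emb an [embedding_table()].
#' @param n_permutations permutations per segment (default 50000).
#' @param q FDR level over segments (default 0.05).
#' @param seed RNG seed (per-segment seeds are derived from it).
#' @param stopwords tokens to drop during preprocessing.
#' @param var_equal use pooled-variance t statistics.
#' @param exchange permutation unit: `"participant"` (relabel
#'   participants; calibrated under participant effects, the default) or
#'   `"pair"` (exchange cosine values, mirroring the imaging contrast).
#' @return list with `segments` (per-segment results incl. `q_fdr`,
#'   `flagged`), `counts` (three-way direction summary), `word_count`
#'   (from [word_count_contrast()]), `coverage` (vocabulary coverage of
#'   produced tokens), `n_oov`.
#' @export
semantic_similarity_analysis <- function(word_lists, emb,
                                         n_permutations = 50000, q = 0.05,
                                         seed = 1L,
                                         stopwords = character(),
                                         var_equal = FALSE,
                                         exchange = c("participant", "pair")) {
  exchange <- match.arg(exchange)
  need <- c("participant_id", "group", "segment", "words")
  if (!all(need %in% names(word_lists)))
    stop("word_lists must have columns ", paste(need, collapse = ", "))
  segs <- sort(unique(word_lists$segment))
  all_tokens <- character(0)
  vec_cache <- list()
  n_oov <- 0L
  for (i in seq_len(nrow(word_lists))) {
    tokens <- preprocess_list(word_lists$words[i], stopwords)
    all_tokens <- c(all_tokens, tokens)
    lv <- list_vector(tokens, emb)
    n_oov <- n_oov + lv$n_oov
    key <- paste(word_lists$participant_id[i], word_lists$segment[i], sep = "\r")
    vec_cache[[key]] <- list(vec = lv$vector, n_tokens = length(tokens),
                             group = word_lists$group[i])
  }

  rows <- vector("list", length(segs))
  countA <- countB <- numeric(length(segs))
  for (k in seq_along(segs)) {
    s <- segs[k]
    sub <- word_lists[word_lists$segment == s, ]
    vecs <- list(A = list(), B = list())
    for (i in seq_len(nrow(sub))) {
      key <- paste(sub$participant_id[i], s, sep = "\r")
      entry <- vec_cache[[key]]
      vecs[[entry$group]] <- c(vecs[[entry$group]], list(entry$vec))
      if (entry$group == "A") countA[k] <- countA[k] + entry$n_tokens
      else countB[k] <- countB[k] + entry$n_tokens
    }
    cos_A <- within_group_cosines(vecs$A)
    cos_B <- within_group_cosines(vecs$B)
    if (is.null(cos_A) || is.null(cos_B)) {
      rows[[k]] <- data.frame(segment = s, t_statistic = NA_real_,
                              p_perm = NA_real_, direction = "none",
                              n_pairs_A = length(cos_A %||% numeric()),
                              n_pairs_B = length(cos_B %||% numeric()),
                              testable = FALSE, stringsAsFactors = FALSE)
    } else {
      res <- if (exchange == "participant")
        segment_permutation_test_subjects(vecs$A, vecs$B, n_permutations,
                                          seed = seed + k,
                                          var_equal = var_equal)
      else
        segment_permutation_test(cos_A, cos_B, n_permutations,
                                 seed = seed + k, var_equal = var_equal)
      rows[[k]] <- data.frame(segment = s, t_statistic = res$t_statistic,
                              p_perm = res$p_perm, direction = res$direction,
                              n_pairs_A = res$n_pairs_A,
                              n_pairs_B = res$n_pairs_B,
                              testable = TRUE, stringsAsFactors = FALSE)
    }
  }
  segments <- fdr_over_segments(do.call(rbind, rows), q)
  list(segments = segments, counts = attr(segments, "counts"),
       word_count = word_count_contrast(countA, countB),
       coverage = embedding_coverage(emb, all_tokens),
       n_oov = n_oov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
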