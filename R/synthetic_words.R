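#' Configuration for the free-association word-list simulator
#'
#' Emulates the behavioral task: two groups of participants each produce a
#' short word list for every narrative segment. Each segment has a latent
#' topic vector; a participant's tokens are drawn by nearest-neighbour
#' lookup of noisy copies of their topic against a synthetic vocabulary,
#' which guarantees that list vectors correlate with topics by
#' construction. In designated "divergent" segments the affected group's
#' participants each receive an individual topic at the configured cosine
#' distance from the segment topic, in random directions, which lowers
#' that group's within-group similarity -- the effect the downstream
#' segment tests are built to detect. Defaults mirror the study design:
#' 24 participants per group, 101 segments, 500-dimensional embeddings,
#' 2% of produced tokens out of vocabulary.
#'
#' @param n_per_group participants per group.
#' @param n_segments narrative segments (default 101).
#' @param embed_dim embedding dimension (default 500).
#' @param group_topic_separation cosine distance in `[0, 2]` between an
#'   affected participant's topic and the segment topic in divergent
#'   segments (0 makes the groups exchangeable).
#' @param n_divergent_segments how many segments are divergent (default 40;
#'   irrelevant when `group_topic_separation` is 0).
#' @param divergent_group which group's participants disperse (`"B"`).
#' @param words_per_list_mean expected list length (default 6).
#' @param oov_rate probability a produced token is absent from the
#'   embedding table; must be < 1.
#' @param topic_noise_sd scale of per-token topic noise (relative to the
#'   unit-norm topic).
#' @param n_vocab synthetic vocabulary size.
#' @param seed RNG seed.
#' @return An object of class `word_sim_config`.
#' @export
word_sim_config <- function(n_per_group = 24, n_segments = 101,
                            embed_dim = 500, group_topic_separation = 0,
                            n_divergent_segments = 40,
                            divergent_group = "B",
                            words_per_list_mean = 6, oov_rate = 0.02,
                            topic_noise_sd = 0.6, n_vocab = 800,
                            seed = 1L) {
  if (n_segments < 1) stop("configuration error: n_segments must be >= 1")
  if (embed_dim < 2) stop("configuration error: embed_dim must be >= 2")
  if (group_topic_separation < 0 || group_topic_separation > 2)
    stop("configuration error: group_topic_separation must lie in [0, 2]")
  if (oov_rate < 0 || oov_rate >= 1)
    stop("configuration error: oov_rate must lie in [0, 1); 1 leaves no analyzable words")
  if (n_divergent_segments < 0 || n_divergent_segments > n_segments)
    stop("configuration error: n_divergent_segments out of range")
  if (!divergent_group %in% c("A", "B"))
    stop("configuration error: divergent_group must be 'A' or 'B'")
  if (words_per_list_mean < 1)
    stop("configuration error: words_per_list_mean must be >= 1")
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_segments = as.integer(n_segments),
         embed_dim = as.integer(embed_dim),
         group_topic_separation = group_topic_separation,
         n_divergent_segments = as.integer(n_divergent_segments),
         divergent_group = divergent_group,
         words_per_list_mean = words_per_list_mean,
         oov_rate = oov_rate, topic_noise_sd = topic_noise_sd,
         n_vocab = as.integer(n_vocab), seed = as.integer(seed)),
    class = "word_sim_config"
  )
}

unit_vec <- function(v) v / sqrt(sum(v^2))

#' Simulate free-association word lists with known segment effects
#'
#' Generates the word-list table, the covering embedding table, and the
#' ground-truth record of which segments were produced with
#' group-divergent topics (see [word_sim_config()] for the generative
#' model).
#'
#' @param config a [word_sim_config()].
#' @return list with `word_lists` (data.frame: participant_id, group,
#'   segment, words), `embeddings` (an [embedding_table()] covering all
#'   non-OOV tokens), and `ground_truth` (divergent segment indices,
#'   topics, config echo).
#' @export
generate_word_lists <- function(config) {
  stopifnot(inherits(config, "word_sim_config"))
  set.seed(config$seed)
  d <- config$embed_dim
  vocab <- matrix(rnorm(config$n_vocab * d), config$n_vocab, d)
  vocab <- vocab / sqrt(rowSums(vocab^2))
  rownames(vocab) <- sprintf("w%05d", seq_len(config$n_vocab))

  divergent <- if (config$n_divergent_segments > 0)
    sort(sample.int(config$n_segments, config$n_divergent_segments))
  else integer(0)

  ids <- c(paste0("A", seq_len(config$n_per_group)),
           paste0("B", seq_len(config$n_per_group)))
  groups <- rep(c("A", "B"), each = config$n_per_group)

  c0 <- 1 - config$group_topic_separation   # target cosine to the base topic
  s0 <- sqrt(max(0, 1 - c0^2))
  topics <- matrix(0, config$n_segments, d)

  rows <- vector("list", config$n_segments * length(ids))
  oov_id <- 0L
  ri <- 0L
  for (seg in seq_len(config$n_segments)) {
    base <- unit_vec(rnorm(d))
    topics[seg, ] <- base
    for (pi in seq_along(ids)) {
      topic <- base
      if (seg %in% divergent && groups[pi] == config$divergent_group &&
          config$group_topic_separation > 0) {
        e <- rnorm(d)
        e <- unit_vec(e - sum(e * base) * base)
        topic <- unit_vec(c0 * base + s0 * e)
      }
      L <- 1L + rpois(1, max(0, config$words_per_list_mean - 1))
      noisy <- matrix(rnorm(L * d), L, d)
      noisy <- noisy / sqrt(rowSums(noisy^2))
      noisy <- noisy * config$topic_noise_sd +
        matrix(topic, L, d, byrow = TRUE)
      sims <- noisy %*% t(vocab)
      tokens <- rownames(vocab)[max.col(sims)]
      oov <- runif(L) < config$oov_rate
      if (any(oov)) {
        tokens[oov] <- sprintf("oov%06d", oov_id + seq_len(sum(oov)))
        oov_id <- oov_id + sum(oov)
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(participant_id = ids[pi], group = groups[pi],
                               segment = seg,
                               words = paste(tokens, collapse = " "),
                               stringsAsFactors = FALSE)
    }
  }
  list(word_lists = do.call(rbind, rows),
       embeddings = embedding_table(vocab,
                                    metadata = list(source = "synthetic",
                                                    dim = d)),
       ground_truth = list(divergent_segments = divergent,
                           divergent_group = config$divergent_group,
                           topics = topics, config = config))
}

#' Read / write the word-list TSV
#'
#' Tab-separated table with columns `participant_id`, `group`, `segment`,
#' `words` (space-separated tokens).
#'
#' @param path file path.
#' @return [read_word_lists()]: the word-list data.frame.
#' @export
read_word_lists <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(participant_id = "character",
                                         group = "character",
                                         segment = "integer",
                                         words = "character"))
  df
}

#' @rdname read_word_lists
#' @param word_lists the word-list data.frame.
#' @export
write_word_lists <- function(word_lists, path) {
  utils::write.table(word_lists, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
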