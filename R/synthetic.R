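#' Configuration for the synthetic corpus generator
#'
#' Defines a planted-structure corpus: several disease groups, each post a
#' sequence of sentences, each sentence assigned to one of the three support
#' categories by the group's mixture, and each token drawn from that
#' category's vocabulary with probability `purity` (otherwise from a shared
#' background vocabulary). Word frequencies within every vocabulary are
#' Zipf-distributed (probability proportional to 1/rank^`zipf_s`), which
#' produces the heavy-tailed degree distributions typical of real text.
#'
#' Defaults emulate a moderately sized patient-forum crawl at desk scale:
#' 8 groups of 400 posts with 3–6 sentences of 4–10 content tokens each,
#' 400-word category vocabularies plus a 150-word shared background, and
#' sentence purity 0.95. The vocabularies are deliberately large relative to
#' the sentence budget so that, as in real corpora, the set of distinct
#' co-occurrence pairs keeps growing with corpus size instead of saturating
#' (saturation would flatten the edge-proportion statistic toward uniform).
#'
#' @param groups Character vector of group labels.
#' @param mixture Matrix or data frame of per-group category weights (rows =
#'   groups, columns = informational/emotional/companionship; rows sum
#'   to 1), or a single numeric vector recycled to all groups.
#' @param vocab_size Words per category vocabulary.
#' @param background_vocab_size Shared background vocabulary size.
#' @param posts_per_group Posts per group.
#' @param sentences_per_post Integer range `c(min, max)`.
#' @param tokens_per_sentence Integer range `c(min, max)`.
#' @param purity Probability a token comes from the sentence's category
#'   vocabulary rather than background.
#' @param zipf_s Zipf exponent for within-vocabulary rank frequencies.
#' @param seed Integer seed; the whole corpus is deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(groups = paste0("group", 1:8),
                             mixture = c(0.5, 0.3, 0.2),
                             vocab_size = 400L,
                             background_vocab_size = 150L,
                             posts_per_group = 400L,
                             sentences_per_post = c(3L, 6L),
                             tokens_per_sentence = c(4L, 10L),
                             purity = 0.95,
                             zipf_s = 1,
                             seed = 1L) {
  if (is.null(dim(mixture))) {
    mixture <- matrix(rep(as.numeric(mixture), length(groups)),
                      nrow = length(groups), byrow = TRUE)
  }
  mixture <- as.matrix(mixture)
  colnames(mixture) <- support_categories
  rownames(mixture) <- groups
  cfg <- list(groups = groups, mixture = mixture,
              vocab_size = as.integer(vocab_size),
              background_vocab_size = as.integer(background_vocab_size),
              posts_per_group = as.integer(posts_per_group),
              sentences_per_post = as.integer(sentences_per_post),
              tokens_per_sentence = as.integer(tokens_per_sentence),
              purity = purity, zipf_s = zipf_s, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (any(cfg$mixture < 0) ||
      any(abs(rowSums(cfg$mixture) - 1) > 1e-9)) {
    abort("mixture rows must be non-negative and sum to 1",
          class = "supportnet_config_error")
  }
  if (cfg$purity < 0 || cfg$purity > 1) {
    abort("purity must be in [0, 1]", class = "supportnet_config_error")
  }
  if (cfg$vocab_size < max(cfg$tokens_per_sentence)) {
    abort("vocab_size too small for tokens_per_sentence diversity",
          class = "supportnet_config_error")
  }
  if (cfg$purity < 1 && cfg$background_vocab_size == 0) {
    abort("purity < 1 requires a non-empty background vocabulary",
          class = "supportnet_config_error")
  }
  invisible(cfg)
}

synthetic_vocabulary <- function(cfg) {
  pad <- function(prefix, n) {
    if (n == 0) return(character(0))
    sprintf("%s%03d", prefix, seq_len(n))
  }
  list(informational = pad("info", cfg$vocab_size),
       emotional = pad("emo", cfg$vocab_size),
       companionship = pad("comp", cfg$vocab_size),
       background = pad("bg", cfg$background_vocab_size))
}

zipf_probs <- function(n, s) {
  p <- 1 / seq_len(n)^s
  p / sum(p)
}

#' Generate a synthetic post corpus with planted support structure
#'
#' See [synthetic_config()] for the generative model. Sentences are emitted
#' as space-joined tokens terminated by a period, so the corpus round-trips
#' through [tokenize_corpus()] with empty stopword/MWU lists.
#'
#' @param config A `synthetic_config`.
#' @return A list with `posts` (tibble `post_id`, `group`, `text`) and
#'   `truth` (list with `word_category` — named vector mapping every planted
#'   word, background excluded, to its category —, `mixture` — the per-group
#'   planted mixture —, and `sentence_categories` — tibble `post_id`,
#'   `ordinal`, `category`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  vocab <- synthetic_vocabulary(config)
  cat_probs <- lapply(support_categories, function(cat)
    zipf_probs(config$vocab_size, config$zipf_s))
  names(cat_probs) <- support_categories
  bg_probs <- if (config$background_vocab_size > 0)
    zipf_probs(config$background_vocab_size, config$zipf_s) else numeric(0)

  posts <- with_local_seed(config$seed, {
    rows <- list()
    sent_rows <- list()
    idx <- 1L
    for (g in config$groups) {
      mix <- config$mixture[g, ]
      for (p in seq_len(config$posts_per_group)) {
        pid <- paste0(g, "_post", p)
        n_sent <- sample(config$sentences_per_post[1]:
                           config$sentences_per_post[2], 1)
        sent_cats <- sample(support_categories, n_sent, replace = TRUE,
                            prob = mix)
        sentences <- vapply(seq_len(n_sent), function(s) {
          n_tok <- sample(config$tokens_per_sentence[1]:
                            config$tokens_per_sentence[2], 1)
          from_cat <- stats::runif(n_tok) < config$purity
          toks <- character(n_tok)
          if (any(from_cat)) {
            toks[from_cat] <- sample(vocab[[sent_cats[s]]], sum(from_cat),
                                     replace = TRUE,
                                     prob = cat_probs[[sent_cats[s]]])
          }
          if (any(!from_cat)) {
            toks[!from_cat] <- sample(vocab$background, sum(!from_cat),
                                      replace = TRUE, prob = bg_probs)
          }
          paste0(paste(toks, collapse = " "), ".")
        }, character(1))
        rows[[idx]] <- tibble(post_id = pid, group = g,
                              text = paste(sentences, collapse = " "))
        sent_rows[[idx]] <- tibble(post_id = pid,
                                   ordinal = seq_len(n_sent) - 1L,
                                   category = sent_cats)
        idx <- idx + 1L
      }
    }
    list(posts = bind_rows(rows), sentences = bind_rows(sent_rows))
  })
  word_category <- setNames(
    rep(support_categories, each = config$vocab_size),
    unlist(vocab[support_categories], use.names = FALSE))
  list(posts = posts$posts,
       truth = list(word_category = word_category,
                    mixture = config$mixture,
                    sentence_categories = posts$sentences))
}

#' Write a synthetic corpus to JSONL with a ground-truth sidecar
#'
#' @param corpus Result of [generate_corpus()].
#' @param path Output JSONL path; the ground truth is written next to it as
#'   `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus$posts)), function(i)
    jsonlite::toJSON(as.list(corpus$posts[i, ]), auto_unbox = TRUE),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  truth <- list(word_category = as.list(corpus$truth$word_category),
                mixture = corpus$truth$mixture,
                sentence_categories = corpus$truth$sentence_categories)
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Pair-counting adjusted Rand index between two label vectors.
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  n_pairs <- comb2(length(x))
  expected <- sum_i * sum_j / n_pairs
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Evaluate recovery of planted structure
#'
#' Compares a detected partition and support profile against the generator's
#' ground truth: (a) the adjusted Rand index between planted word categories
#' and detected modules, over the planted (non-background) words present in
#' the partition; (b) the majority planted category of each module; (c) the
#' maximum absolute error between the planted sentence-category mixture and
#' the recovered category proportions.
#'
#' @param truth `truth` element of [generate_corpus()]'s result.
#' @param partition A `module_partition` computed from the corpus.
#' @param profile One-row profile tibble (from [category_profile()]) for the
#'   same corpus, or `NULL` to skip the mixture comparison.
#' @param group Group whose planted mixture to compare against (defaults to
#'   the first row of the truth mixture).
#' @return A list with `ari`, `module_majority` (tibble `module`,
#'   `category`), `max_abs_error` (NA when `profile` is `NULL`), and
#'   `recovered` / `planted` mixture vectors.
#' @export
evaluate_recovery <- function(truth, partition, profile = NULL,
                              group = NULL) {
  assigned <- partition$assignment |> filter(!is.na(.data$module))
  planted <- truth$word_category[assigned$word]
  keep <- !is.na(planted)
  ari <- adjusted_rand_index(unname(planted[keep]), assigned$module[keep])
  majority <- assigned[keep, ] |>
    mutate(planted = unname(planted[keep])) |>
    group_by(.data$module) |>
    summarise(category = names(which.max(table(.data$planted))),
              .groups = "drop")
  if (is.null(profile)) {
    max_err <- NA_real_
    recovered <- NULL
    planted_mix <- NULL
  } else {
    if (is.null(group)) group <- rownames(truth$mixture)[1]
    planted_mix <- truth$mixture[group, support_categories]
    recovered <- unlist(profile[1, support_categories])
    max_err <- max(abs(recovered - planted_mix))
  }
  list(ari = ari, module_majority = majority, max_abs_error = max_err,
       recovered = recovered, planted = planted_mix)
}
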