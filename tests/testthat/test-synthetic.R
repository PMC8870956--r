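test_that("generation is deterministic and validates its configuration", {
  cfg <- small_synth_config(seed = 701L)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$posts, c2$posts)
  expect_identical(c1$truth$sentence_categories, c2$truth$sentence_categories)

  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(c1, f1)
  write_corpus_jsonl(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(paste0(f1, ".truth.json")),
                   readLines(paste0(f2, ".truth.json")))
  # the emitted JSONL round-trips through the reader
  posts <- read_posts(f1, "jsonl")
  expect_identical(posts, c1$posts)

  expect_error(synthetic_config(mixture = c(0.5, 0.2, 0.2)),
               class = "supportnet_config_error")
  expect_error(synthetic_config(purity = 1.2),
               class = "supportnet_config_error")
  expect_error(synthetic_config(vocab_size = 5,
                                tokens_per_sentence = c(4, 10)),
               class = "supportnet_config_error")
  expect_error(synthetic_config(purity = 0.9, background_vocab_size = 0),
               class = "supportnet_config_error")
})

test_that("pure sentences draw tokens from a single category vocabulary", {
  cfg <- small_synth_config(purity = 1, background_vocab_size = 0L,
                            seed = 702L)
  corp <- generate_corpus(cfg)
  sents <- tokenize_corpus(corp$posts, stopwords = character(0),
                           mwu_lexicon = character(0))
  truth_cat <- corp$truth$word_category
  cats_per_sentence <- vapply(sents$tokens, function(toks)
    length(unique(truth_cat[toks])), integer(1))
  expect_true(all(cats_per_sentence == 1))
  # and the recorded sentence labels agree with the tokens
  joined <- dplyr::left_join(sents, corp$truth$sentence_categories,
                             by = c("post_id", "ordinal"))
  first_tok_cat <- vapply(joined$tokens, function(t)
    unname(truth_cat[t[1]]), character(1))
  expect_equal(first_tok_cat, joined$category)
})

test_that("sentence-category frequencies track the planted mixture", {
  cfg <- synthetic_config(groups = "g1", mixture = c(0.6, 0.3, 0.1),
                          posts_per_group = 400L, purity = 0.95,
                          seed = 703L)
  corp <- generate_corpus(cfg)
  freq <- prop.table(table(corp$truth$sentence_categories$category))
  expect_lt(abs(freq[["informational"]] - 0.6), 0.03)
  expect_lt(abs(freq[["emotional"]] - 0.3), 0.03)
  expect_lt(abs(freq[["companionship"]] - 0.1), 0.03)
})

test_that("adjusted Rand index matches identity and the mclust reference", {
  x <- rep(1:3, each = 10)
  expect_equal(supportnet:::adjusted_rand_index(x, x), 1)
  expect_equal(supportnet:::adjusted_rand_index(x, c(x[-1], x[1])),
               mclust::adjustedRandIndex(x, c(x[-1], x[1])))
  set.seed(704)
  for (rep in 1:5) {
    a <- sample(1:4, 40, TRUE)
    b <- sample(1:3, 40, TRUE)
    expect_equal(supportnet:::adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
})

test_that("evaluate_recovery scores a perfect partition as ARI 1", {
  cfg <- small_synth_config(seed = 705L)
  corp <- generate_corpus(cfg)
  truth_cat <- corp$truth$word_category
  words <- names(truth_cat)
  net <- build_cooccurrence(lapply(seq(1, length(words), by = 4),
                                   function(i) words[i:min(i + 3,
                                                           length(words))]))
  vec <- as.integer(factor(truth_cat[net$nodes$word]))
  p <- supportnet:::new_module_partition(net, vec, 1, 0, numeric(0))
  rec <- evaluate_recovery(corp$truth, p)
  expect_equal(rec$ari, 1)
  expect_true(is.na(rec$max_abs_error))
})

test_that("high-purity corpora are recovered and yield small-world networks", {
  set.seed(706)
  aris <- vapply(0:19, function(sd) {
    cfg <- small_synth_config(purity = 1, background_vocab_size = 0L,
                              posts_per_group = 80L, seed = 800L + sd)
    corp <- generate_corpus(cfg)
    sents <- tokenize_corpus(corp$posts, stopwords = character(0),
                             mwu_lexicon = character(0))
    net <- build_cooccurrence(sents)
    part <- louvain_partition(net, seed = 1, restarts = 3)
    evaluate_recovery(corp$truth, part)$ari
  }, numeric(1))
  expect_true(all(aris >= 0.95))

  # the small-world claim concerns the generator's default vocabulary scale;
  # tiny test vocabularies make near-complete graphs where CCr is not small
  cfg <- synthetic_config(groups = "g1", posts_per_group = 150L, seed = 706L)
  corp <- generate_corpus(cfg)
  sents <- tokenize_corpus(corp$posts, stopwords = character(0),
                           mwu_lexicon = character(0))
  st <- network_statistics(build_cooccurrence(sents))
  expect_true(st$is_small_world)
  expect_lte(st$aspl, 2 * st$aspl_r)
  expect_gte(st$cc, 10 * st$cc_r)
})

test_that("recovery does not degrade as purity increases", {
  mean_ari <- vapply(c(0.7, 0.85, 1.0), function(pur) {
    aris <- vapply(1:20, function(sd) {
      cfg <- small_synth_config(
        purity = pur, posts_per_group = 50L, seed = 900L + sd)
      corp <- generate_corpus(cfg)
      sents <- tokenize_corpus(corp$posts, stopwords = character(0),
                               mwu_lexicon = character(0))
      net <- build_cooccurrence(sents)
      part <- louvain_partition(net, seed = 1, restarts = 2)
      evaluate_recovery(corp$truth, part)$ari
    }, numeric(1))
    mean(aris)
  }, numeric(1))
  # one-sided trend with a small allowance for simulation noise
  expect_gte(mean_ari[2], mean_ari[1] - 0.02)
  expect_gte(mean_ari[3], mean_ari[2] - 0.02)
})
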