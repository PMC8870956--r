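test_that("read_posts reads JSONL in file order and validates fields", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"post_id":"p1","group":"ovarian","text":"I had chemo."}',
    '{"post_id":"p2","group":"lung","text":"Scans tomorrow."}'), f)
  posts <- read_posts(f, "jsonl")
  expect_equal(posts$post_id, c("p1", "p2"))
  expect_equal(posts$group, c("ovarian", "lung"))

  writeLines(c(
    '{"post_id":"p1","group":"lung","text":"ok."}',
    '{"post_id":"p2","text":"no group here."}'), f)
  expect_error(read_posts(f, "jsonl"), "line 2.*group",
               class = "supportnet_format_error")

  expect_error(read_posts(f, "parquet"), "unknown corpus format",
               class = "supportnet_usage_error")
})

test_that("read_posts drops empty-text records with a warning", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("post_id,group,text",
               'p1,lung,"First post."',
               'p2,lung,"  "',
               'p3,colon,"Third post."'), f)
  expect_warning(posts <- read_posts(f, "csv"), "1 record")
  expect_equal(posts$post_id, c("p1", "p3"))

  writeLines(c("post_id,text", "p1,hello"), f)
  expect_error(read_posts(f, "csv"), "group",
               class = "supportnet_format_error")
})

test_that("split_sentences follows the terminal-punctuation rule set", {
  # hand-segmented fixtures for the documented rules: terminal . ! ? runs
  # end a sentence, abbreviation periods do not, unterminated text is one
  # sentence, trailing quotes/brackets stay attached
  cases <- list(
    list("I had chemo. It was hard.", c("I had chemo.", "It was hard.")),
    list("no punctuation at all", "no punctuation at all"),
    list("Dr. Smith said ok? Yes!", c("Dr. Smith said ok?", "Yes!")),
    list("Really?! Wow.", c("Really?!", "Wow.")),
    list("Mr. and Mrs. Lee came by. We chatted.",
         c("Mr. and Mrs. Lee came by.", "We chatted.")),
    list("One. Two. Three.", c("One.", "Two.", "Three.")),
    list("Ends abruptly. then lowercase", c("Ends abruptly.", "then lowercase")),
    list("What now...", "What now..."),
    list("He said \"stop.\" Then left.", c("He said \"stop.\"", "Then left.")),
    list("e.g. this stays together. New one.",
         c("e.g. this stays together.", "New one.")),
    list("St. Mary's was full! We waited.",
         c("St. Mary's was full!", "We waited.")),
    list("A question? An answer. An exclamation!",
         c("A question?", "An answer.", "An exclamation!")),
    list("  padded with spaces.  ", "padded with spaces."),
    list("one sentence, with commas, still one",
         "one sentence, with commas, still one"),
    list("First! Second? Third. fourth unterminated",
         c("First!", "Second?", "Third.", "fourth unterminated")),
    list("Chemo at 9 a.m.. Then rest.", c("Chemo at 9 a.m..", "Then rest.")),
    list("Scan (clear). Good news!", c("Scan (clear).", "Good news!")),
    list("etc. is fine mid-sentence. Right.",
         c("etc. is fine mid-sentence.", "Right.")),
    list("Multiple   spaces. Still split.",
         c("Multiple   spaces.", "Still split.")),
    list("!", "!"))
  for (case in cases) {
    expect_equal(split_sentences(case[[1]]), case[[2]], info = case[[1]])
  }
})

test_that("split_sentences output re-joins to the input modulo whitespace", {
  texts <- c(
    "I had chemo. It was hard. Dr. Smith helped!",
    "One sentence only",
    "Really?! Are you sure... Yes.",
    "  Mixed. punctuation! everywhere?  ")
  squash <- function(x) gsub("\\s+", "", paste(x, collapse = ""))
  for (tx in texts) {
    expect_equal(squash(split_sentences(tx)), squash(tx), info = tx)
  }
})

test_that("tokenize_sentence applies MWU, stopword and pruning rules", {
  expect_equal(
    tokenize_sentence("The side effects were awful!",
                      stopwords = c("the", "were"),
                      mwu_lexicon = "side effects"),
    c("side_effects", "awful"))
  expect_equal(tokenize_sentence("chemo chemo chemo",
                                 stopwords = character(0),
                                 mwu_lexicon = character(0)),
               c("chemo", "chemo", "chemo"))
  expect_equal(tokenize_sentence("...", character(0), character(0)),
               character(0))
  # numerals and single characters are pruned; case is folded
  expect_equal(tokenize_sentence("I took 3 pills at 9", character(0),
                                 character(0)),
               c("took", "pills", "at"))
  expect_equal(tokenize_sentence("CHEMO Chemo chemo", character(0),
                                 character(0)),
               rep("chemo", 3))
  # longest phrase wins
  expect_equal(
    tokenize_sentence("basal cell skin cancer is treatable",
                      stopwords = "is",
                      mwu_lexicon = c("skin cancer", "basal cell skin cancer")),
    c("basal_cell_skin_cancer", "treatable"))
})

test_that("tokenization is idempotent and never emits stopwords", {
  sw <- default_stopwords()
  mwu <- default_mwu_lexicon()
  sentences <- c(
    "The side effects of the chemo were awful, but I kept hoping!",
    "Dr. Smith scheduled a CT scan for next Tuesday morning.",
    "My husband baked bread; we watched movies all weekend.",
    "Pancreatic cancer runs in my family, so I worry a lot.")
  for (s in sentences) {
    toks <- tokenize_sentence(s, sw, mwu)
    expect_false(any(tolower(toks) %in% tolower(sw)), info = s)
    again <- tokenize_sentence(paste(toks, collapse = " "), sw, mwu)
    expect_equal(sort(again), sort(toks), info = s)
  }
})

test_that("tokenize_corpus emits per-sentence rows with 0-based ordinals", {
  posts <- tibble::tibble(
    post_id = c("p1", "p2"), group = c("lung", "colon"),
    text = c("First chemo today. Feeling hopeful!", "Short note"))
  sents <- tokenize_corpus(posts, stopwords = character(0),
                           mwu_lexicon = character(0))
  expect_equal(nrow(sents), 3)
  expect_equal(sents$ordinal, c(0L, 1L, 0L))
  expect_equal(sents$tokens[[1]], c("first", "chemo", "today"))
})
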