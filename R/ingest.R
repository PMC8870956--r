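#' Read a post corpus from JSONL or CSV
#'
#' Each record must carry `post_id`, `group` and `text`. Records whose text is
#' empty after whitespace stripping are dropped with a warning; a missing
#' required field is a format error naming the offending record.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"` (header row
#'   with the three columns).
#' @return A tibble of posts with columns `post_id`, `group`, `text`, in file
#'   order.
#' @examples
#' f <- tempfile(fileext = ".jsonl")
#' writeLines(c(
#'   '{"post_id":"p1","group":"ovarian","text":"I had chemo. It was hard."}',
#'   '{"post_id":"p2","group":"ovarian","text":"Sending hugs to all."}'
#' ), f)
#' read_posts(f, "jsonl")
#' @export
read_posts <- function(path, format = c("jsonl", "csv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(
                       paste0("unknown corpus format: ", format[1]),
                       class = "supportnet_usage_error"))
  if (!file.exists(path)) {
    abort(paste0("corpus file not found: ", path), class = "supportnet_io_error")
  }
  required <- c("post_id", "group", "text")
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(stringr::str_trim(lines))]
    records <- purrr::imap(lines, function(line, i) {
      rec <- tryCatch(jsonlite::fromJSON(line),
                      error = function(e) abort(
                        paste0("malformed JSON on line ", i, ": ",
                               conditionMessage(e)),
                        class = "supportnet_format_error"))
      missing <- setdiff(required, names(rec))
      if (length(missing) > 0) {
        abort(paste0("record on line ", i, " is missing required field(s): ",
                     paste(missing, collapse = ", ")),
              class = "supportnet_format_error")
      }
      tibble(post_id = as.character(rec$post_id),
             group = as.character(rec$group),
             text = as.character(rec$text))
    })
    posts <- bind_rows(records)
  } else {
    posts <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
    missing <- setdiff(required, names(posts))
    if (length(missing) > 0) {
      abort(paste0("CSV is missing required column(s): ",
                   paste(missing, collapse = ", ")),
            class = "supportnet_format_error")
    }
    posts <- select(posts, dplyr::all_of(required))
    posts$text[is.na(posts$text)] <- ""
  }
  empty <- !nzchar(stringr::str_trim(posts$text))
  if (any(empty)) {
    warn(paste0("dropped ", sum(empty), " record(s) with empty text (",
                paste(head(posts$post_id[empty], 5), collapse = ", "), ")"))
    posts <- posts[!empty, , drop = FALSE]
  }
  as_tibble(posts)
}

# Abbreviations whose trailing period does not end a sentence.
sentence_abbreviations <- c(
  "dr", "mr", "mrs", "ms", "prof", "st", "jr", "sr", "vs", "etc",
  "e.g", "i.e", "a.m", "p.m", "approx", "dept", "fig", "no", "al"
)

#' Split a post into sentences
#'
#' Rule-based splitting on terminal punctuation (`.`, `!`, `?`, possibly
#' repeated) with an abbreviation exception list, so "Dr. Smith said ok?"
#' stays one sentence up to the question mark. Text with no terminal
#' punctuation is returned as a single sentence. Concatenating the returned
#' sentences reproduces the input up to surrounding whitespace.
#'
#' @param text A single character string (a post's text).
#' @param abbreviations Lowercased abbreviations (without the final period)
#'   that never terminate a sentence.
#' @return Character vector of non-empty sentences.
#' @examples
#' split_sentences("I had chemo. It was hard.")
#' split_sentences("Dr. Smith said ok? Yes!")
#' @export
split_sentences <- function(text, abbreviations = sentence_abbreviations) {
  stopifnot(is.character(text), length(text) == 1)
  text <- stringr::str_trim(text)
  if (!nzchar(text)) return(character(0))
  # Protect abbreviation periods with a placeholder, split, then restore.
  protected <- text
  for (ab in abbreviations[order(-nchar(abbreviations))]) {
    pat <- paste0("(?i)\\b", stringr::str_replace_all(ab, stringr::fixed("."), "\\."),
                  "\\.")
    protected <- stringr::str_replace_all(
      protected, stringr::regex(pat),
      function(m) stringr::str_replace_all(m, stringr::fixed("."), "\uFFF0"))
  }
  # A sentence is a maximal run ending in terminal punctuation (+ closing
  # quotes/brackets) or at end of string.
  pieces <- stringr::str_extract_all(
    protected, "[^.!?]*(?:[.!?]+[\"')\\]]*|$)")[[1]]
  pieces <- stringr::str_replace_all(pieces, stringr::fixed("\uFFF0"), ".")
  pieces <- stringr::str_trim(pieces)
  pieces[nzchar(pieces)]
}

#' Tokenize one sentence
#'
#' Lowercases, concatenates longest-match multi-word units from the lexicon
#' into underscore-joined tokens (before stopword removal), strips
#' punctuation, and drops stopwords, numerals and single-character tokens.
#' Duplicate tokens are retained in order.
#'
#' @param sentence Raw sentence string.
#' @param stopwords Character vector of stopwords (compared lowercased).
#' @param mwu_lexicon Character vector of multi-word phrases.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize_sentence("The side effects were awful!",
#'                   stopwords = c("the", "were"),
#'                   mwu_lexicon = "side effects")
#' @export
tokenize_sentence <- function(sentence,
                              stopwords = default_stopwords(),
                              mwu_lexicon = default_mwu_lexicon()) {
  stopifnot(is.character(sentence), length(sentence) == 1)
  s <- tolower(sentence)
  s <- stringr::str_replace_all(s, "['\u2019]", "")  # don't -> dont
  if (length(mwu_lexicon) > 0) {
    for (phrase in tolower(mwu_lexicon)[order(-nchar(mwu_lexicon))]) {
      joined <- stringr::str_replace_all(phrase, "\\s+", "_")
      pat <- paste0("\\b", stringr::str_replace_all(phrase, "\\s+", "[\\\\s]+"), "\\b")
      s <- stringr::str_replace_all(s, pat, joined)
    }
  }
  s <- stringr::str_replace_all(s, "[^a-z0-9_]+", " ")
  tokens <- stringr::str_split_1(stringr::str_trim(s), "\\s+")
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!stringr::str_detect(tokens, "^[0-9_]+$")]       # numerals
  tokens <- tokens[nchar(stringr::str_remove_all(tokens, "_")) > 1] # 1-char
  tokens[!(tokens %in% tolower(stopwords))]
}

#' Tokenize a post corpus into sentences
#'
#' Applies [split_sentences()] and [tokenize_sentence()] to every post,
#' producing the sentence table consumed by [build_cooccurrence()].
#'
#' @param posts Tibble with `post_id`, `group`, `text` (from [read_posts()]).
#' @inheritParams tokenize_sentence
#' @return A tibble with one row per sentence: `post_id`, `group`, `ordinal`
#'   (0-based index within the post), and a `tokens` list-column. Sentences
#'   that tokenize to zero tokens are kept (with empty token vectors) and
#'   ignored downstream.
#' @export
tokenize_corpus <- function(posts,
                            stopwords = default_stopwords(),
                            mwu_lexicon = default_mwu_lexicon()) {
  stopifnot(all(c("post_id", "group", "text") %in% names(posts)))
  out <- purrr::pmap(posts[c("post_id", "group", "text")],
    function(post_id, group, text) {
      sents <- split_sentences(text)
      if (length(sents) == 0) return(NULL)
      tibble(post_id = post_id, group = group,
             ordinal = seq_along(sents) - 1L,
             tokens = lapply(sents, tokenize_sentence,
                             stopwords = stopwords, mwu_lexicon = mwu_lexicon))
    })
  bind_rows(out)
}
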