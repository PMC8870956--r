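#' Read a plain-text word list
#'
#' Reads a UTF-8 word list with one entry per line; blank lines and lines
#' starting with `#` are ignored. Entries are lowercased.
#'
#' @param path Path to the file.
#' @return A character vector of entries.
#' @export
read_wordlist <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("word list file not found: ", path), class = "supportnet_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[nzchar(lines) & !stringr::str_starts(lines, "#")]
  tolower(lines)
}

#' Default English stopword list
#'
#' The packaged Snowball-style stopword list (function words plus common
#' apostrophe-stripped contractions). Override by passing your own vector
#' or a file read with [read_wordlist()].
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  read_wordlist(system.file("extdata", "stopwords_en.txt",
                            package = "supportnet", mustWork = TRUE))
}

#' Default multi-word-unit lexicon
#'
#' Domain phrases (e.g. "side effects", "pancreatic cancer") that are joined
#' into single underscore-concatenated network nodes before stopword removal.
#' Matching is longest-first, left to right.
#'
#' @return Character vector of phrases (each two or more words).
#' @export
default_mwu_lexicon <- function() {
  read_wordlist(system.file("extdata", "mwu_lexicon.txt",
                            package = "supportnet", mustWork = TRUE))
}

#' Read a support-category lexicon
#'
#' Parses a plain-text file with `[category]` section headers followed by one
#' word per line. Categories must be pairwise disjoint.
#'
#' @param path Path to the lexicon file.
#' @return A named list of character vectors, one per category.
#' @export
read_category_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[nzchar(lines) & !stringr::str_starts(lines, "#")]
  headers <- stringr::str_match(lines, "^\\[(.+)\\]$")[, 2]
  if (is.na(headers[1])) {
    abort("lexicon file must start with a [category] header",
          class = "supportnet_format_error")
  }
  section <- cumsum(!is.na(headers))
  lex <- split(lines[is.na(headers)], section[is.na(headers)])
  names(lex) <- headers[!is.na(headers)][as.integer(names(lex))]
  lex <- lapply(lex, tolower)
  validate_category_lexicon(lex)
  lex
}

validate_category_lexicon <- function(lexicon) {
  words <- unlist(lexicon, use.names = FALSE)
  dup <- unique(words[duplicated(words)])
  if (length(dup) > 0) {
    abort(paste0("category word sets must be pairwise disjoint; duplicated: ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "supportnet_format_error")
  }
  invisible(lexicon)
}

#' Default support-category seed lexicon
#'
#' Packaged seed vocabularies for the informational / emotional /
#' companionship taxonomy, used by [assign_categories()] to score modules.
#' Real analyses are expected to refine these (or use the `overrides`
#' argument) after reading the module keywords.
#'
#' @return Named list with elements `informational`, `emotional`,
#'   `companionship`.
#' @export
default_category_lexicon <- function() {
  read_category_lexicon(system.file("extdata", "support_lexicon.txt",
                                    package = "supportnet", mustWork = TRUE))
}

support_categories <- c("informational", "emotional", "companionship")
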