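#' Build a word co-occurrence network from tokenized sentences
#'
#' Nodes are word types; an undirected edge links two distinct words that
#' appear together in at least one sentence. By default the weight of an edge
#' is the number of sentences in which the pair co-occurs (each sentence
#' counts a pair once even if a word repeats); with
#' `count_multiplicity = TRUE` every within-sentence token-pair occurrence is
#' counted instead. Words that never co-occur with another word (e.g. from
#' one-token sentences) are retained as degree-0 nodes.
#'
#' @param sentences Tibble with a `tokens` list-column (from
#'   [tokenize_corpus()]), or a bare list of character vectors.
#' @param count_multiplicity Count repeated within-sentence token pairs
#'   multiple times? Default `FALSE` (sentence-level binary incidence).
#' @return A `cooc_network` object: list with `nodes` (tibble `word`,
#'   `index`), `edges` (tibble `word1`, `word2`, `weight`, with
#'   `word1 < word2` lexicographically), `n` and `m`.
#' @examples
#' net <- build_cooccurrence(list(c("chemo", "pain", "scan"), c("pain", "scan")))
#' net$edges
#' @export
build_cooccurrence <- function(sentences, count_multiplicity = FALSE) {
  token_list <- if (is.data.frame(sentences)) sentences$tokens else sentences
  if (length(token_list) == 0) {
    abort("empty corpus: no sentences to build a network from",
          class = "supportnet_empty_input_error")
  }
  token_list <- lapply(token_list, function(x) {
    if (count_multiplicity) sort(as.character(x)) else sort(unique(as.character(x)))
  })
  words <- sort(unique(unlist(token_list, use.names = FALSE)))
  pair_tabs <- purrr::map(token_list, function(toks) {
    k <- length(toks)
    if (k < 2) return(NULL)
    idx <- utils::combn(k, 2)
    w1 <- toks[idx[1, ]]
    w2 <- toks[idx[2, ]]
    keep <- w1 != w2  # no self-loops even when counting multiplicity
    if (!any(keep)) return(NULL)
    list(w1 = w1[keep], w2 = w2[keep])
  })
  pairs <- tibble(
    word1 = unlist(lapply(pair_tabs, `[[`, "w1"), use.names = FALSE) %||%
      character(0),
    word2 = unlist(lapply(pair_tabs, `[[`, "w2"), use.names = FALSE) %||%
      character(0))
  edges <- if (nrow(pairs) == 0) {
    tibble(word1 = character(0), word2 = character(0), weight = integer(0))
  } else {
    pairs |>
      count(.data$word1, .data$word2, name = "weight") |>
      arrange(.data$word1, .data$word2)
  }
  new_cooc_network(words, edges)
}

new_cooc_network <- function(words, edges) {
  structure(
    list(nodes = tibble(word = words, index = seq_along(words)),
         edges = edges,
         n = length(words),
         m = nrow(edges)),
    class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("Word co-occurrence network: ", x$n, " words, ", x$m,
      " co-occurrence pairs\n", sep = "")
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#'
#' @param net A `cooc_network`.
#' @return An undirected `igraph` graph with a `weight` edge attribute and
#'   word names as vertex names. Degree-0 words are included.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes$word)
  if (net$m > 0) igraph::E(g)$weight <- net$edges$weight
  g
}

#' @rdname tidy.cooc_network
#' @exportS3Method generics::glance
glance.cooc_network <- function(x, ...) {
  tibble(n = x$n, m = x$m,
         density = if (x$n > 1) 2 * x$m / (x$n * (x$n - 1)) else NA_real_,
         total_weight = sum(x$edges$weight))
}

#' Tidy a co-occurrence network
#'
#' `tidy()` returns the edge table; `glance()` a one-row summary.
#'
#' @param x A `cooc_network`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.cooc_network <- function(x, ...) x$edges

#' Export a co-occurrence network
#'
#' Writes the network in a Gephi-readable format (GEXF or GraphML) or as a
#' TSV edge list (`word1<TAB>word2<TAB>weight` with a header). Node labels
#' are the words; weights are kept as a numeric edge attribute. Output is
#' deterministic: nodes and edges are written in lexicographic order.
#'
#' @param net A `cooc_network`.
#' @param path Output file path.
#' @param format One of `"gexf"`, `"graphml"`, `"tsv"`.
#' @param node_attrs Optional tibble of extra node attributes with a `word`
#'   column (e.g. module ids for Gephi colouring).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("gexf", "graphml", "tsv"),
                           node_attrs = NULL) {
  stopifnot(inherits(net, "cooc_network"))
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("cannot write to ", path, ": directory does not exist"),
          class = "supportnet_io_error")
  }
  nodes <- net$nodes
  if (!is.null(node_attrs)) {
    stopifnot("word" %in% names(node_attrs))
    nodes <- left_join(nodes, node_attrs, by = "word")
  }
  if (format == "tsv") {
    readr::write_tsv(net$edges, path)
  } else if (format == "graphml") {
    g <- as_igraph(net)
    if (!is.null(node_attrs)) {
      for (col in setdiff(names(node_attrs), "word")) {
        igraph::vertex_attr(g, col) <-
          nodes[[col]][match(igraph::V(g)$name, nodes$word)]
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_gexf(nodes, net$edges, path)
  }
  invisible(path)
}

# Minimal GEXF 1.2 writer (static undirected weighted graph). Kept by hand
# because igraph does not emit GEXF; Gephi reads this dialect directly.
write_gexf <- function(nodes, edges, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  attr_cols <- setdiff(names(nodes), c("word", "index"))
  header <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="undirected">')
  attr_decl <- if (length(attr_cols) > 0) {
    c('    <attributes class="node">',
      sprintf('      <attribute id="%d" title="%s" type="string"/>',
              seq_along(attr_cols) - 1L, esc(attr_cols)),
      '    </attributes>')
  } else character(0)
  node_xml <- if (nrow(nodes) == 0) character(0) else {
    vapply(seq_len(nrow(nodes)), function(i) {
      label <- esc(nodes$word[i])
      if (length(attr_cols) == 0) {
        sprintf('      <node id="%s" label="%s"/>', label, label)
      } else {
        vals <- vapply(attr_cols, function(col)
          sprintf('        <attvalue for="%d" value="%s"/>',
                  match(col, attr_cols) - 1L, esc(as.character(nodes[[col]][i]))),
          character(1))
        paste(c(sprintf('      <node id="%s" label="%s">', label, label),
                '        <attvalues>', vals, '        </attvalues>',
                '      </node>'), collapse = "\n")
      }
    }, character(1))
  }
  edge_xml <- if (nrow(edges) == 0) character(0) else {
    sprintf('      <edge id="%d" source="%s" target="%s" weight="%s"/>',
            seq_len(nrow(edges)) - 1L, esc(edges$word1), esc(edges$word2),
            format(edges$weight, scientific = FALSE, trim = TRUE))
  }
  xml <- c(header, attr_decl,
           "    <nodes>", node_xml, "    </nodes>",
           "    <edges>", edge_xml, "    </edges>",
           "  </graph>", "</gexf>")
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}
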