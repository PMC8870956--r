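# Independent brute-force oracles and graph builders used across tests.
# Everything here deliberately avoids the code paths it checks.

# Build a cooc_network from an explicit weighted edge list by replaying each
# edge as `weight` two-word sentences (plus one-word sentences for isolated
# nodes), exercising only the documented construction rule.
net_from_edges <- function(word1, word2, weight = 1, isolated = character(0)) {
  weight <- rep_len(weight, length(word1))
  sents <- c(
    unlist(lapply(seq_along(word1), function(e)
      rep(list(c(word1[e], word2[e])), weight[e])), recursive = FALSE),
    lapply(isolated, identity))
  build_cooccurrence(sents)
}

# Erdos-Renyi G(n, m) edge list with zero-padded labels.
random_edges <- function(n, m) {
  all_pairs <- t(utils::combn(n, 2))
  pick <- sample(nrow(all_pairs), m)
  labs <- sprintf("w%04d", seq_len(n))
  list(word1 = labs[all_pairs[pick, 1]], word2 = labs[all_pairs[pick, 2]],
       labels = labs)
}

# Dense distance matrix by Floyd-Warshall on the unweighted graph.
brute_distances <- function(net) {
  n <- net$n
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  i <- match(net$edges$word1, net$nodes$word)
  j <- match(net$edges$word2, net$nodes$word)
  for (e in seq_along(i)) d[i[e], j[e]] <- d[j[e], i[e]] <- 1
  for (k in seq_len(n)) {
    for (a in seq_len(n)) {
      dk <- d[a, k]
      if (is.finite(dk)) {
        nd <- dk + d[k, ]
        upd <- nd < d[a, ]
        d[a, upd] <- nd[upd]
      }
    }
  }
  rownames(d) <- colnames(d) <- net$nodes$word
  d
}

# ASPL over the largest connected component, from the brute distance matrix.
brute_aspl <- function(net) {
  d <- brute_distances(net)
  reach <- is.finite(d)
  comp_sizes <- rowSums(reach)
  members <- which(comp_sizes == max(comp_sizes))
  # nodes mutually reachable from the first largest-component member
  comp <- which(reach[members[1], ])
  dd <- d[comp, comp]
  mean(dd[upper.tri(dd)])
}

# Mean local clustering coefficient by direct triangle counting.
brute_cc <- function(net) {
  n <- net$n
  adj <- matrix(FALSE, n, n)
  i <- match(net$edges$word1, net$nodes$word)
  j <- match(net$edges$word2, net$nodes$word)
  for (e in seq_along(i)) adj[i[e], j[e]] <- adj[j[e], i[e]] <- TRUE
  local <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    m_i <- sum(adj[nb, nb, drop = FALSE]) / 2
    m_i / (k * (k - 1) / 2)
  }, numeric(1))
  mean(local)
}

# Direct double-sum evaluation of the resolution modularity (ordered pairs,
# diagonal included, w_ii = 0).
brute_modularity <- function(net, assignment, resolution = 1) {
  comm <- assignment[net$nodes$word]
  n <- net$n
  w <- matrix(0, n, n)
  i <- match(net$edges$word1, net$nodes$word)
  j <- match(net$edges$word2, net$nodes$word)
  for (e in seq_along(i)) w[i[e], j[e]] <- w[j[e], i[e]] <- net$edges$weight[e]
  l <- rowSums(w)
  two_m <- sum(w)
  q <- 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (comm[a] == comm[b]) {
        q <- q + w[a, b] - resolution * l[a] * l[b] / two_m
      }
    }
  }
  q / two_m
}

# All set partitions of 1..n as a list of assignment vectors (restricted
# growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, next_id) {
    k <- length(assign)
    if (k == n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (c in seq_len(next_id)) {
      recurse(c(assign, c), max(next_id, c + 1))
    }
  }
  recurse(integer(0), 1L)
  out
}

# Maximum modularity over every partition, by exhaustive search.
exhaustive_best_q <- function(net, resolution = 1) {
  words <- net$nodes$word
  best <- -Inf
  for (p in all_partitions(net$n)) {
    q <- brute_modularity(net, stats::setNames(p, words), resolution)
    if (q > best) best <- q
  }
  best
}

# Sentences forming a clique among the given words (every pair co-occurs).
clique_sentences <- function(words) {
  idx <- utils::combn(length(words), 2)
  lapply(seq_len(ncol(idx)), function(k) words[idx[, k]])
}

small_synth_config <- function(posts_per_group = 60L, vocab_size = 60L,
                               background_vocab_size = 40L, ...) {
  synthetic_config(groups = "g1", posts_per_group = posts_per_group,
                   vocab_size = vocab_size,
                   background_vocab_size = background_vocab_size, ...)
}
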