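#' Resolution-parameterised modularity of a partition
#'
#' Evaluates
#' `Q(c) = (1/2M) * sum_ij [ w_ij - lambda * l_i * l_j / (2M) ] * delta(c_i, c_j)`
#' over ordered node pairs (diagonal included, with `w_ii = 0`), where
#' `M` is half the total weight, `l_i` the node strength and `lambda` the
#' resolution. `lambda = 1` is classical Newman–Girvan modularity; larger
#' values penalise large modules and yield finer partitions.
#'
#' @param net A `cooc_network` with at least one edge.
#' @param assignment Named module membership: either a named vector (names =
#'   words) or a tibble with `word` and `module` columns, covering every node.
#' @param resolution Positive resolution parameter lambda.
#' @param weighted Use edge weights (default) or the binarised graph.
#' @return The modularity value.
#' @examples
#' net <- build_cooccurrence(list(c("a", "b")))
#' modularity_score(net, c(a = 1, b = 1))   # 0
#' modularity_score(net, c(a = 1, b = 2))   # -0.5
#' @export
modularity_score <- function(net, assignment, resolution = 1,
                             weighted = TRUE) {
  stopifnot(inherits(net, "cooc_network"), resolution > 0)
  comm <- as_assignment_vector(assignment, net$nodes$word)
  if (net$m == 0) {
    abort("modularity undefined: network has no edges",
          class = "supportnet_undefined_statistic_error")
  }
  w <- if (weighted) as.numeric(net$edges$weight) else rep(1, net$m)
  i <- match(net$edges$word1, net$nodes$word)
  j <- match(net$edges$word2, net$nodes$word)
  strength <- numeric(net$n)
  for (e in seq_along(w)) {
    strength[i[e]] <- strength[i[e]] + w[e]
    strength[j[e]] <- strength[j[e]] + w[e]
  }
  two_m <- sum(strength)
  within <- comm[i] == comm[j]
  w_in <- sum(w[within])                 # each unordered within edge once
  tot <- tapply(strength, comm, sum)     # L_c per module
  2 * w_in / two_m - resolution * sum((tot / two_m)^2)
}

as_assignment_vector <- function(assignment, words) {
  if (is.data.frame(assignment)) {
    stopifnot(all(c("word", "module") %in% names(assignment)))
    assignment <- setNames(assignment$module, assignment$word)
  }
  if (is.null(names(assignment))) {
    abort("assignment must be named by word or be a word/module tibble",
          class = "supportnet_usage_error")
  }
  missing <- setdiff(words, names(assignment))
  if (length(missing) > 0) {
    abort(paste0("assignment must cover every node; missing: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "supportnet_usage_error")
  }
  assignment[words]
}

# One Louvain level on an aggregated graph given as adjacency lists.
# adj_idx / adj_w: neighbour indices and weights (no self-loops);
# self_w: self-loop weight per node (counts twice in strength);
# returns the community vector after local moves converge.
louvain_local_moves <- function(adj_idx, adj_w, strength, two_m, resolution,
                                order) {
  n <- length(adj_idx)
  comm <- seq_len(n)
  tot <- strength
  improved_any <- FALSE
  repeat {
    moves <- 0L
    for (v in order) {
      own <- comm[v]
      s_v <- strength[v]
      tot[own] <- tot[own] - s_v
      nb <- adj_idx[[v]]
      if (length(nb) > 0) {
        nb_comm <- comm[nb]
        k_vc <- vapply(split(adj_w[[v]], nb_comm), sum, numeric(1))
        cand <- as.integer(names(k_vc))
        if (!(own %in% cand)) {
          cand <- c(cand, own)
          k_vc <- c(k_vc, 0)
        }
        gain <- k_vc - resolution * s_v * tot[cand] / two_m
        best <- which(gain == max(gain))
        # ties: prefer staying put, otherwise lowest community id
        pick <- if (own %in% cand[best]) own else min(cand[best])
      } else {
        pick <- own
      }
      if (pick != own) moves <- moves + 1L
      comm[v] <- pick
      tot[pick] <- tot[pick] + s_v
    }
    if (moves == 0L) break
    improved_any <- TRUE
  }
  list(comm = comm, improved = improved_any)
}

aggregate_graph <- function(edges_i, edges_j, edges_w, self_w, comm) {
  relab <- match(comm, sort(unique(comm)))
  n_new <- max(relab)
  ci <- relab[edges_i]
  cj <- relab[edges_j]
  lo <- pmin(ci, cj)
  hi <- pmax(ci, cj)
  self_new <- numeric(n_new)
  if (length(self_w) > 0) {
    agg_self <- tapply(self_w, relab, sum)
    self_new[as.integer(names(agg_self))] <- as.numeric(agg_self)
  }
  is_loop <- lo == hi
  if (any(is_loop)) {
    loop_add <- tapply(edges_w[is_loop], lo[is_loop], sum)
    self_new[as.integer(names(loop_add))] <-
      self_new[as.integer(names(loop_add))] + as.numeric(loop_add)
  }
  keep <- !is_loop
  if (any(keep)) {
    key <- paste(lo[keep], hi[keep])
    agg <- tapply(edges_w[keep], key, sum)
    parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
    ei <- as.integer(parts[, 1]); ej <- as.integer(parts[, 2])
    ew <- as.numeric(agg)
  } else {
    ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  }
  list(i = ei, j = ej, w = ew, self = self_new, n = n_new, relab = relab)
}

build_adjacency <- function(n, i, j, w) {
  idx <- vector("list", n)
  wts <- vector("list", n)
  ord_i <- c(i, j)
  ord_j <- c(j, i)
  ord_w <- c(w, w)
  sp <- split(seq_along(ord_i), ord_i)
  for (key in names(sp)) {
    v <- as.integer(key)
    idx[[v]] <- ord_j[sp[[key]]]
    wts[[v]] <- ord_w[sp[[key]]]
  }
  list(idx = idx, w = wts)
}

louvain_run <- function(n0, i0, j0, w0, resolution) {
  # state for the current (aggregated) level
  i <- i0; j <- j0; w <- w0
  self_w <- numeric(n0)
  n <- n0
  node_map <- seq_len(n0)   # original node -> current level node
  q_history <- numeric(0)
  repeat {
    adj <- build_adjacency(n, i, j, w)
    strength <- numeric(n)
    for (e in seq_along(w)) {
      strength[i[e]] <- strength[i[e]] + w[e]
      strength[j[e]] <- strength[j[e]] + w[e]
    }
    strength <- strength + 2 * self_w
    two_m <- sum(strength)
    order <- sample.int(n)
    res <- louvain_local_moves(adj$idx, adj$w, strength, two_m, resolution,
                               order)
    agg <- aggregate_graph(i, j, w, self_w, res$comm)
    node_map <- agg$relab[res$comm][node_map]
    # Q at this level (diagonal null included via tot^2)
    tot <- tapply(strength, res$comm, sum)
    within <- res$comm[i] == res$comm[j]
    q <- (2 * sum(w[within]) + 2 * sum(self_w)) / two_m -
      resolution * sum((tot / two_m)^2)
    q_history <- c(q_history, q)
    if (!res$improved || agg$n == n) break
    i <- agg$i; j <- agg$j; w <- agg$w; self_w <- agg$self; n <- agg$n
  }
  list(assignment = node_map, q_history = q_history)
}

#' Louvain module detection
#'
#' Detects word modules by greedy maximisation of the
#' resolution-parameterised modularity (see [modularity_score()]): repeated
#' local node moves until no gain, then aggregation of modules into
#' super-nodes, iterated until a pass yields no improvement. Node visit
#' order is randomised per seed and the best of `restarts` independent runs
#' (highest modularity) is returned, since the greedy optimiser is
#' order-dependent. Results are deterministic given
#' `(net, resolution, seed, restarts)`.
#'
#' @param net A `cooc_network` with at least one edge.
#' @param resolution Resolution parameter lambda (default 1, the standard
#'   granularity).
#' @param seed Integer seed for the randomised node orders.
#' @param restarts Number of independent runs (default 10).
#' @param weighted Use edge weights (default) or the binarised graph.
#' @return A `module_partition` object: list with `assignment` (tibble
#'   `word`, `module`, module ids contiguous integers), `resolution`,
#'   `modularity`, `n_modules`, `q_history` (modularity after each
#'   aggregation pass of the winning run; non-decreasing), and `sizes`.
#' @export
louvain_partition <- function(net, resolution = 1, seed = 1L, restarts = 10L,
                              weighted = TRUE) {
  stopifnot(inherits(net, "cooc_network"), resolution > 0, restarts >= 1)
  if (net$m == 0) {
    abort("module detection requires at least one edge",
          class = "supportnet_undefined_statistic_error")
  }
  i <- match(net$edges$word1, net$nodes$word)
  j <- match(net$edges$word2, net$nodes$word)
  w <- if (weighted) as.numeric(net$edges$weight) else rep(1, net$m)
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(restarts)) {
    run <- with_local_seed(seed + r - 1L,
                           louvain_run(net$n, i, j, w, resolution))
    q <- modularity_score(
      net, setNames(run$assignment, net$nodes$word), resolution,
      weighted = weighted)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- run
    }
  }
  assignment <- match(best$assignment, unique(best$assignment))
  new_module_partition(net, assignment, resolution, best_q, best$q_history)
}

new_module_partition <- function(net, assignment, resolution, q, q_history,
                                 filtered = FALSE) {
  tab <- tibble(word = net$nodes$word, module = as.integer(assignment))
  sizes <- tab |>
    filter(!is.na(.data$module)) |>
    count(.data$module, name = "size") |>
    arrange(.data$module)
  structure(
    list(assignment = tab, resolution = resolution, modularity = q,
         n_modules = nrow(sizes), sizes = sizes, q_history = q_history,
         filtered = filtered),
    class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition: ", x$n_modules, " modules, resolution ",
      x$resolution, ", Q = ", format(x$modularity, digits = 4),
      if (x$filtered) " (filtered)" else "", "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.module_partition
#' @exportS3Method generics::glance
glance.module_partition <- function(x, ...) {
  tibble(n_modules = x$n_modules, resolution = x$resolution,
         modularity = x$modularity, filtered = x$filtered,
         n_assigned = sum(!is.na(x$assignment$module)))
}

#' Tidy a module partition
#'
#' `tidy()` returns the word-to-module table; `glance()` a one-row summary.
#'
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.module_partition <- function(x, ...) x$assignment

#' Drop small modules
#'
#' Removes modules with fewer than `min_module_size` words (to improve
#' presentation and stabilise downstream statistics); their words become
#' unassigned (`NA`) and are excluded from edge proportions and silhouettes.
#' Remaining modules are re-indexed 1, 2, ... by descending size (ties by
#' previous id).
#'
#' @param partition A `module_partition`.
#' @param min_module_size Minimum retained module size (default 5).
#' @return A filtered `module_partition`; its `modularity` is the value of
#'   the unfiltered partition it came from.
#' @export
filter_modules <- function(partition, min_module_size = 5L) {
  stopifnot(inherits(partition, "module_partition"))
  keep <- partition$sizes |> filter(.data$size >= min_module_size)
  if (nrow(keep) == 0) {
    abort(paste0("all modules have fewer than ", min_module_size, " words"),
          class = "supportnet_empty_result_error")
  }
  keep <- keep |> arrange(desc(.data$size), .data$module) |>
    mutate(new_id = row_number())
  new_ids <- setNames(keep$new_id, keep$module)
  old <- partition$assignment$module
  remapped <- ifelse(is.na(old), NA_integer_,
                     unname(new_ids[as.character(old)]))
  out <- partition
  out$assignment$module <- as.integer(remapped)
  out$sizes <- out$assignment |>
    filter(!is.na(.data$module)) |>
    count(.data$module, name = "size") |>
    arrange(.data$module)
  out$n_modules <- nrow(out$sizes)
  out$filtered <- TRUE
  out
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
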