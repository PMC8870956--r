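#' Per-word silhouette widths on the module graph
#'
#' For each assigned word i, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with
#' `a(i)` the mean distance to the other words of its module and `b(i)` the
#' smallest mean distance to any other module. The dissimilarity is the
#' unweighted shortest-path hop length on the subgraph induced by the
#' assigned (unfiltered-out) words; unreachable pairs are assigned the
#' largest finite distance in that subgraph plus one. Words in singleton
#' modules get `s(i) = 0`.
#'
#' @param net A `cooc_network`.
#' @param partition A `module_partition` (normally filtered).
#' @param distance `"hop"` (default) or `"inverse_weight"` (shortest paths
#'   with edge length 1/weight, an alternative dissimilarity).
#' @return Tibble with columns `word`, `module`, `a`, `b`, `silhouette`.
#' @export
silhouette_widths <- function(net, partition,
                              distance = c("hop", "inverse_weight")) {
  stopifnot(inherits(net, "cooc_network"),
            inherits(partition, "module_partition"))
  distance <- match.arg(distance)
  assigned <- partition$assignment |> filter(!is.na(.data$module))
  if (length(unique(assigned$module)) < 2) {
    abort("silhouette undefined with fewer than two modules",
          class = "supportnet_undefined_statistic_error")
  }
  g <- as_igraph(net)
  sub <- igraph::induced_subgraph(g, assigned$word)
  wts <- if (distance == "hop") NA else 1 / igraph::E(sub)$weight
  d <- igraph::distances(sub, weights = wts)
  finite <- d[is.finite(d)]
  d[!is.finite(d)] <- max(finite) + 1
  ord <- match(assigned$word, rownames(d))
  d <- d[ord, ord, drop = FALSE]
  mods <- assigned$module
  uniq <- sort(unique(mods))
  # mean distance from every node to every module, excluding self for own
  sums <- rowsum(t(d), mods)                 # module x node sums
  cnt <- as.integer(table(factor(mods, levels = uniq)))
  res <- purrr::map(seq_along(assigned$word), function(ii) {
    own <- mods[ii]
    own_k <- match(own, uniq)
    a <- if (cnt[own_k] <= 1) 0 else
      (sums[own_k, ii] - 0) / (cnt[own_k] - 1)   # d[ii,ii] = 0
    other <- setdiff(seq_along(uniq), own_k)
    b <- min(sums[other, ii] / cnt[other])
    s <- if (cnt[own_k] <= 1) 0 else (b - a) / max(a, b)
    tibble(word = assigned$word[ii], module = own, a = a, b = b,
           silhouette = s)
  })
  bind_rows(res)
}

#' Mean silhouette per module
#'
#' @inheritParams silhouette_widths
#' @return Tibble with columns `module`, `silhouette` (mean over member
#'   words), `size`.
#' @seealso [silhouette_widths()] for the per-word values.
#' @export
module_silhouette <- function(net, partition,
                              distance = c("hop", "inverse_weight")) {
  silhouette_widths(net, partition, distance) |>
    group_by(.data$module) |>
    summarise(silhouette = mean(.data$silhouette), size = n(),
              .groups = "drop")
}

within_module_strength <- function(net, partition) {
  assign_map <- setNames(partition$assignment$module,
                         partition$assignment$word)
  e <- net$edges |>
    mutate(m1 = assign_map[.data$word1], m2 = assign_map[.data$word2]) |>
    filter(!is.na(.data$m1), .data$m1 == .data$m2)
  bind_rows(
    tibble(word = e$word1, module = e$m1, w = e$weight),
    tibble(word = e$word2, module = e$m2, w = e$weight)) |>
    group_by(.data$word, .data$module) |>
    summarise(strength = sum(.data$w), .groups = "drop")
}

#' Top keywords of a module
#'
#' Ranks module members by within-module weighted degree (strength summed
#' over edges to other members of the same module), ties broken
#' lexicographically, and returns the first `k` (all members when the
#' module has fewer than `k` words).
#'
#' @param net A `cooc_network`.
#' @param partition A `module_partition`.
#' @param module_id Module identifier.
#' @param k Number of keywords (default 5).
#' @return Character vector of words.
#' @export
top_keywords <- function(net, partition, module_id, k = 5L) {
  members <- partition$assignment |>
    filter(!is.na(.data$module), .data$module == module_id)
  if (nrow(members) == 0) {
    abort(paste0("no such module: ", module_id),
          class = "supportnet_usage_error")
  }
  strengths <- within_module_strength(net, partition) |>
    filter(.data$module == module_id)
  ranked <- members |>
    left_join(strengths, by = c("word", "module")) |>
    mutate(strength = dplyr::coalesce(.data$strength, 0)) |>
    arrange(desc(.data$strength), .data$word)
  head(ranked$word, k)
}
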