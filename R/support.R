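#' Within-module edge proportions (PC_k)
#'
#' For module k, `PC_k` is the number of edges with both endpoints in module
#' k divided by the total number of within-module edges over all modules.
#' Between-module edges enter neither numerator nor denominator, so the
#' proportions sum to 1. This is the statistic used to weigh how much of
#' the corpus's communication mass each module carries.
#'
#' @param net A `cooc_network`.
#' @param partition A filtered `module_partition`.
#' @return Tibble with columns `module`, `within_edges`, `pc` (sums to 1).
#' @export
edge_proportions <- function(net, partition) {
  stopifnot(inherits(net, "cooc_network"),
            inherits(partition, "module_partition"))
  assign_map <- setNames(partition$assignment$module,
                         partition$assignment$word)
  within <- net$edges |>
    mutate(m1 = assign_map[.data$word1], m2 = assign_map[.data$word2]) |>
    filter(!is.na(.data$m1), .data$m1 == .data$m2)
  if (nrow(within) == 0) {
    abort("edge proportions undefined: no within-module edges",
          class = "supportnet_undefined_statistic_error")
  }
  counts <- within |> count(module = .data$m1, name = "within_edges")
  all_mods <- sort(unique(partition$assignment$module))
  counts <- tibble(module = all_mods) |>
    left_join(counts, by = "module") |>
    mutate(within_edges = dplyr::coalesce(.data$within_edges, 0L))
  counts |> mutate(pc = .data$within_edges / sum(.data$within_edges))
}

#' Assign support categories to modules
#'
#' Scores each module against the three support-category vocabularies: the
#' score for a category is the within-module-strength-weighted fraction of
#' member words belonging to that category's word set (plain word fraction
#' when a module has no within-module edges). The highest-scoring category
#' wins; a tie or an all-zero score leaves the module `unclassified`.
#' Manual `overrides` take absolute precedence and are reported via a
#' message, supporting expert relabelling after reading the keywords.
#'
#' @param net A `cooc_network`.
#' @param partition A filtered `module_partition`.
#' @param lexicon Named list of category word vectors (default
#'   [default_category_lexicon()]).
#' @param overrides Optional named vector/list mapping module id to
#'   category.
#' @return Tibble with columns `module`, `category`, and one score column
#'   per category.
#' @export
assign_categories <- function(net, partition,
                              lexicon = default_category_lexicon(),
                              overrides = NULL) {
  validate_category_lexicon(lexicon)
  members <- partition$assignment |> filter(!is.na(.data$module))
  strengths <- within_module_strength(net, partition)
  members <- members |>
    left_join(strengths, by = c("word", "module")) |>
    mutate(strength = dplyr::coalesce(.data$strength, 0))
  cats <- names(lexicon)
  scored <- members |>
    split(members$module) |>
    purrr::imap(function(mm, mid) {
      weights <- if (sum(mm$strength) > 0) mm$strength else rep(1, nrow(mm))
      scores <- vapply(cats, function(cat)
        sum(weights[mm$word %in% lexicon[[cat]]]) / sum(weights),
        numeric(1))
      bind_rows(tibble(module = as.integer(mid), !!!as.list(scores)))
    }) |>
    bind_rows() |>
    arrange(.data$module)
  score_mat <- as.matrix(scored[cats])
  pick <- apply(score_mat, 1, function(row) {
    mx <- max(row)
    if (mx <= 0 || sum(row == mx) > 1) "unclassified" else cats[which.max(row)]
  })
  out <- scored |> mutate(category = unname(pick), .after = "module")
  if (!is.null(overrides)) {
    ov_modules <- suppressWarnings(as.integer(names(overrides)))
    bad <- setdiff(ov_modules, out$module)
    if (length(bad) > 0) {
      abort(paste0("override names nonexistent module(s): ",
                   paste(bad, collapse = ", ")),
            class = "supportnet_usage_error")
    }
    for (kk in seq_along(overrides)) {
      idx <- match(ov_modules[kk], out$module)
      message("module ", ov_modules[kk], ": category override '",
              out$category[idx], "' -> '", overrides[[kk]], "'")
      out$category[idx] <- as.character(overrides[[kk]])
    }
  }
  out
}

#' Per-module summary table
#'
#' Combines size, edge proportion, silhouette, top keywords and support
#' category into one table per filtered module, ordered by module id (i.e.
#' by descending size).
#'
#' @inheritParams assign_categories
#' @param k Number of keywords per module.
#' @param overrides Optional module-to-category overrides, passed to
#'   [assign_categories()].
#' @return Tibble with columns `module`, `size`, `within_edges`, `pc`,
#'   `silhouette`, `keywords` (single `"; "`-separated string), `category`.
#' @export
module_summaries <- function(net, partition,
                             lexicon = default_category_lexicon(),
                             k = 5L, overrides = NULL) {
  pcs <- edge_proportions(net, partition)
  sil <- module_silhouette(net, partition)
  cats <- assign_categories(net, partition, lexicon, overrides)
  kw <- vapply(pcs$module, function(mid)
    paste(top_keywords(net, partition, mid, k), collapse = "; "),
    character(1))
  pcs |>
    left_join(partition$sizes, by = "module") |>
    left_join(select(sil, "module", "silhouette"), by = "module") |>
    left_join(select(cats, "module", "category"), by = "module") |>
    mutate(keywords = kw) |>
    select("module", "size", "within_edges", "pc", "silhouette", "keywords",
           "category") |>
    arrange(.data$module)
}

#' Aggregate module proportions into a support profile
#'
#' Sums the edge proportions of the modules assigned to each support
#' category and renormalises over the three classified categories
#' (unclassified modules are excluded). Within-module edge counts per
#' category are carried along for the chi-squared comparison.
#'
#' @param summaries Module summary tibble from [module_summaries()] (needs
#'   `pc` and `category`), with within-edge counts either as a
#'   `within_edges` column or recoverable via `net`/`partition`.
#' @param group Group label to attach.
#' @return A one-row tibble: `group`, one proportion column per category
#'   (summing to 1), and one `edges_<category>` count column per category.
#' @export
category_profile <- function(summaries, group = "all") {
  stopifnot(all(c("pc", "category") %in% names(summaries)))
  if (!"within_edges" %in% names(summaries)) {
    # reconstruct counts from proportions is impossible; demand the column
    abort("summaries must carry a within_edges column",
          class = "supportnet_usage_error")
  }
  classified <- summaries |> filter(.data$category %in% support_categories)
  if (nrow(classified) == 0) {
    abort("support profile undefined: every module is unclassified",
          class = "supportnet_undefined_statistic_error")
  }
  agg <- classified |>
    group_by(.data$category) |>
    summarise(pc = sum(.data$pc), edges = sum(.data$within_edges),
              .groups = "drop")
  props <- setNames(rep(0, 3), support_categories)
  edges <- setNames(rep(0L, 3), support_categories)
  props[agg$category] <- agg$pc
  edges[agg$category] <- agg$edges
  props <- props / sum(props)
  tibble(group = group,
         informational = props[["informational"]],
         emotional = props[["emotional"]],
         companionship = props[["companionship"]],
         edges_informational = edges[["informational"]],
         edges_emotional = edges[["emotional"]],
         edges_companionship = edges[["companionship"]])
}

#' Support-profile table with column means
#'
#' Formats one profile row per group with percentages rounded to 2 decimals
#' (each row summing to 100), and appends the unweighted column means across
#' groups as a final `"(mean)"` row. The unrounded means are attached as
#' attribute `"column_means"` (in percent).
#'
#' @param profiles Tibble of profile rows (from [category_profile()], bound
#'   over groups, or any tibble with `group` and the three proportion
#'   columns on either the 0-1 or percent scale).
#' @return A tibble with columns `group`, `informational`, `emotional`,
#'   `companionship` in percent.
#' @examples
#' profile_table(cancer_support_profiles)
#' @export
profile_table <- function(profiles) {
  stopifnot(nrow(profiles) >= 1,
            all(c("group", support_categories) %in% names(profiles)))
  vals <- as.matrix(profiles[support_categories])
  if (max(rowSums(vals)) < 1.5) vals <- vals * 100   # 0-1 scale -> percent
  means <- colMeans(vals)
  out <- tibble(group = profiles$group,
                informational = unname(round(vals[, "informational"], 2)),
                emotional = unname(round(vals[, "emotional"], 2)),
                companionship = unname(round(vals[, "companionship"], 2)))
  out <- bind_rows(out, tibble(group = "(mean)",
                               informational = round(means[["informational"]], 2),
                               emotional = round(means[["emotional"]], 2),
                               companionship = round(means[["companionship"]], 2)))
  attr(out, "column_means") <- means
  out
}

#' Chi-squared comparison of support profiles across groups
#'
#' Pearson chi-squared test of homogeneity (no continuity correction) on the
#' group-by-category table of within-module edge counts, the count unit
#' underlying the edge proportions.
#'
#' @param profiles Tibble with `group` and two or more `edges_<category>`
#'   count columns (>= 2 groups); profiles from [category_profile()] carry
#'   the three standard categories.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
compare_profiles <- function(profiles) {
  count_cols <- grep("^edges_", names(profiles), value = TRUE)
  stopifnot("group" %in% names(profiles), length(count_cols) >= 2)
  if (nrow(profiles) < 2) {
    abort("need at least two groups to compare",
          class = "supportnet_usage_error")
  }
  tab <- as.matrix(profiles[count_cols])
  rownames(tab) <- profiles$group
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate contingency table: a group or category has zero edges",
          class = "supportnet_degenerate_table_error")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
}

#' Support-profile bar chart
#'
#' Stacked percentage bars of the three support categories per group.
#'
#' @param profiles Profile tibble (one row per group, proportions on the
#'   0-1 or percent scale).
#' @return A ggplot object.
#' @export
plot_support_profiles <- function(profiles) {
  vals <- profiles |>
    select("group", dplyr::all_of(support_categories)) |>
    tidyr::pivot_longer(-"group", names_to = "category",
                        values_to = "proportion")
  if (max(vals$proportion) < 1.5) vals$proportion <- vals$proportion * 100
  ggplot2::ggplot(vals, ggplot2::aes(x = .data$group, y = .data$proportion,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "share of within-module edges (%)",
                  fill = "support category") +
    ggplot2::theme_minimal()
}
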