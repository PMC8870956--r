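#' Analyse one group's sentences end to end
#'
#' Builds the co-occurrence network for one group, computes its diagnostics,
#' detects and filters modules, summarises them, and aggregates the support
#' profile.
#'
#' @param sentences Sentence tibble (from [tokenize_corpus()]) for a single
#'   group.
#' @param group Group label for the outputs.
#' @param resolution Modularity resolution (default 1).
#' @param min_module_size Minimum module size kept (default 5).
#' @param seed,restarts Passed to [louvain_partition()].
#' @param lexicon Category lexicon for [assign_categories()].
#' @param overrides Optional module-to-category overrides.
#' @return List with `net`, `stats`, `partition` (filtered), `summaries`,
#'   `profile`.
#' @export
analyze_group <- function(sentences, group,
                          resolution = 1, min_module_size = 5L,
                          seed = 1L, restarts = 10L,
                          lexicon = default_category_lexicon(),
                          overrides = NULL) {
  net <- build_cooccurrence(sentences)
  stats <- network_statistics(net)
  partition <- louvain_partition(net, resolution = resolution, seed = seed,
                                 restarts = restarts)
  filtered <- filter_modules(partition, min_module_size)
  summaries <- module_summaries(net, filtered, lexicon = lexicon,
                                overrides = overrides)
  profile <- category_profile(summaries, group = group)
  list(net = net, stats = stats, partition = filtered,
       summaries = summaries, profile = profile)
}

config_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(params, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full support analysis and write report files
#'
#' Tokenizes a post corpus, analyses every group, and writes four report
#' tables plus a run log to `out_dir`:
#' \describe{
#'   \item{network_summary.csv}{per group: sentences, words, co-occurrence
#'     pairs, ASPL/ASPLr, CC/CCr, gamma, small-world flag}
#'   \item{module_summary.csv}{per module: size, \% of edges, silhouette,
#'     keywords, category}
#'   \item{module_detection_summary.csv}{per group: modularity, clustering
#'     coefficient, mean silhouette, number of modules}
#'   \item{support_profiles.csv}{per group: percentage of each support
#'     category, with a column-mean row}
#'   \item{run_log.txt}{package/R versions, seed, config hash, and the
#'     chi-squared homogeneity test across groups}
#' }
#' Outputs are deterministic: rerunning with the same corpus and seed gives
#' byte-identical files.
#'
#' @param posts Post tibble (from [read_posts()] or [generate_corpus()]).
#' @param out_dir Output directory (created if needed).
#' @param stopwords,mwu_lexicon Passed to [tokenize_corpus()].
#' @inheritParams analyze_group
#' @return Invisibly, a list with per-group results and the four report
#'   tibbles.
#' @export
run_support_analysis <- function(posts, out_dir,
                                 stopwords = default_stopwords(),
                                 mwu_lexicon = default_mwu_lexicon(),
                                 lexicon = default_category_lexicon(),
                                 resolution = 1, min_module_size = 5L,
                                 seed = 1L, restarts = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sentences <- tokenize_corpus(posts, stopwords = stopwords,
                               mwu_lexicon = mwu_lexicon)
  groups <- unique(posts$group)
  results <- lapply(groups, function(g) {
    analyze_group(sentences |> filter(.data$group == g), g,
                  resolution = resolution,
                  min_module_size = min_module_size,
                  seed = seed, restarts = restarts, lexicon = lexicon)
  })
  names(results) <- groups

  network_summary <- bind_rows(lapply(groups, function(g) {
    st <- glance(results[[g]]$stats)
    n_sent <- sum(sentences$group == g)
    tibble(group = g, sentences = n_sent, words = st$n,
           cooccurrence_pairs = st$m,
           aspl = round(st$aspl, 3), aspl_r = round(st$aspl_r, 3),
           cc = round(st$cc, 3), cc_r = round(st$cc_r, 3),
           gamma = round(st$gamma, 3),
           small_world = st$is_small_world)
  }))
  module_summary <- bind_rows(lapply(groups, function(g) {
    results[[g]]$summaries |>
      mutate(group = g, pct_of_edges = round(100 * .data$pc, 2),
             silhouette = round(.data$silhouette, 3)) |>
      select("group", "module", "size", "pct_of_edges", "silhouette",
             "keywords", "category")
  }))
  detection_summary <- bind_rows(lapply(groups, function(g) {
    r <- results[[g]]
    tibble(group = g,
           modularity = round(r$partition$modularity, 3),
           cc = round(clustering_coefficient(r$net), 3),
           silhouette = round(mean(r$summaries$silhouette), 3),
           n_modules = r$partition$n_modules)
  }))
  profiles <- bind_rows(lapply(results, function(r) r$profile))
  profile_tab <- profile_table(profiles)

  comparison <- if (length(groups) >= 2) compare_profiles(profiles) else NULL

  readr::write_csv(network_summary, file.path(out_dir, "network_summary.csv"))
  readr::write_csv(module_summary, file.path(out_dir, "module_summary.csv"))
  readr::write_csv(detection_summary,
                   file.path(out_dir, "module_detection_summary.csv"))
  readr::write_csv(profile_tab, file.path(out_dir, "support_profiles.csv"))

  params <- list(resolution = resolution, min_module_size = min_module_size,
                 seed = seed, restarts = restarts,
                 groups = groups, n_posts = nrow(posts))
  log_lines <- c(
    paste0("supportnet version: ",
           as.character(utils::packageVersion("supportnet"))),
    paste0("R version: ", R.version.string),
    paste0("igraph version: ",
           as.character(utils::packageVersion("igraph"))),
    paste0("seed: ", seed),
    paste0("config hash: ", config_hash(params)),
    if (!is.null(comparison)) {
      paste0("chi-squared homogeneity across groups: X2 = ",
             format(comparison$statistic, digits = 6), ", df = ",
             comparison$df, ", p = ",
             format(comparison$p_value, digits = 4))
    } else "chi-squared: skipped (single group)")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"), useBytes = TRUE)

  invisible(list(results = results, network_summary = network_summary,
                 module_summary = module_summary,
                 detection_summary = detection_summary,
                 profile_table = profile_tab, comparison = comparison))
}
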