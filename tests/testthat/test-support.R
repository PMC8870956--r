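support_fixture <- function() {
  # module A = 3-clique (3 within edges), module B = one edge,
  # plus 2 between-module edges that must not enter PC_k
  net <- build_cooccurrence(c(clique_sentences(c("a1", "a2", "a3")),
                              list(c("b1", "b2"),
                                   c("a1", "b1"), c("a2", "b2"))))
  lab <- stats::setNames(c(1, 1, 1, 2, 2), c("a1", "a2", "a3", "b1", "b2"))
  vec <- as.integer(lab[net$nodes$word])
  p <- supportnet:::new_module_partition(net, vec, 1,
                                         modularity_score(net, lab),
                                         numeric(0))
  list(net = net, p = p)
}

test_that("edge proportions follow the within-module edge formula", {
  fx <- support_fixture()
  pc <- edge_proportions(fx$net, fx$p)
  expect_equal(pc$within_edges, c(3L, 1L))
  expect_equal(pc$pc, c(0.75, 0.25))
  expect_equal(sum(pc$pc), 1)

  # all edges inside one module
  net1 <- build_cooccurrence(clique_sentences(letters[1:4]))
  lab1 <- stats::setNames(rep(1, 4), letters[1:4])
  p1 <- supportnet:::new_module_partition(net1, rep(1L, 4), 1, 0, numeric(0))
  expect_equal(edge_proportions(net1, p1)$pc, 1)

  # equal-sized modules of identical topology get equal shares
  net2 <- build_cooccurrence(c(clique_sentences(c("x1", "x2", "x3")),
                               clique_sentences(c("y1", "y2", "y3"))))
  lab2 <- stats::setNames(rep(1:2, each = 3), c(paste0("x", 1:3),
                                                paste0("y", 1:3)))
  p2 <- supportnet:::new_module_partition(
    net2, as.integer(lab2[net2$nodes$word]), 1, 0, numeric(0))
  expect_equal(edge_proportions(net2, p2)$pc, c(0.5, 0.5))
})

test_that("category assignment scores modules against the lexicon", {
  fx <- support_fixture()
  lex <- list(informational = c("a1", "a2", "a3"),
              emotional = c("b1", "b2"),
              companionship = "unused_word")
  cats <- assign_categories(fx$net, fx$p, lexicon = lex)
  expect_equal(cats$category, c("informational", "emotional"))

  # reported-style keyword mix resolves to emotional support
  net <- build_cooccurrence(clique_sentences(
    c("treatment", "pain", "happy", "awful", "painful")))
  p <- supportnet:::new_module_partition(net, rep(1L, 5), 1, 0, numeric(0))
  cats <- assign_categories(net, p)   # packaged default lexicon
  expect_equal(cats$category, "emotional")

  # tie -> unclassified
  lex_tie <- list(informational = "a1", emotional = "a2",
                  companionship = "zzz")
  net3 <- build_cooccurrence(list(c("a1", "a2")))
  p3 <- supportnet:::new_module_partition(net3, rep(1L, 2), 1, 0, numeric(0))
  expect_equal(assign_categories(net3, p3, lexicon = lex_tie)$category,
               "unclassified")

  # overrides win and must name real modules
  expect_message(
    ov <- assign_categories(fx$net, fx$p, lexicon = lex,
                            overrides = c("2" = "companionship")),
    "override")
  expect_equal(ov$category, c("informational", "companionship"))
  expect_error(assign_categories(fx$net, fx$p, lexicon = lex,
                                 overrides = c("9" = "emotional")),
               class = "supportnet_usage_error")

  expect_error(supportnet:::validate_category_lexicon(
    list(informational = "pain", emotional = "pain")),
    class = "supportnet_format_error")
})

test_that("category profiles sum module proportions and renormalise", {
  summaries <- tibble::tibble(
    module = 1:3, pc = c(0.6, 0.3, 0.1), within_edges = c(60L, 30L, 10L),
    category = c("informational", "emotional", "companionship"))
  prof <- category_profile(summaries, group = "g")
  expect_equal(prof$informational, 0.6)
  expect_equal(prof$emotional, 0.3)
  expect_equal(prof$companionship, 0.1)
  expect_equal(prof$edges_emotional, 30L)

  all_info <- dplyr::mutate(summaries, category = "informational")
  prof2 <- category_profile(all_info)
  expect_equal(prof2$informational, 1)
  expect_equal(prof2$emotional, 0)

  # unclassified mass is excluded then renormalised
  part <- dplyr::mutate(summaries,
                        category = c("informational", "unclassified",
                                     "emotional"))
  prof3 <- category_profile(part)
  expect_equal(prof3$informational, 0.6 / 0.7)
  expect_equal(prof3$emotional, 0.1 / 0.7)

  expect_error(category_profile(
    dplyr::mutate(summaries, category = "unclassified")),
    class = "supportnet_undefined_statistic_error")
})

test_that("profile_table reproduces reported column means and row sums", {
  tab <- profile_table(cancer_support_profiles)
  means <- attr(tab, "column_means")
  expect_lte(abs(means[["informational"]] - 47.14), 0.0055)
  expect_lte(abs(means[["companionship"]] - 28.26), 0.0055)
  body <- tab[tab$group != "(mean)", ]
  expect_true(all(abs(rowSums(body[, -1]) - 100) <= 0.01))

  single <- profile_table(cancer_support_profiles[1, ])
  expect_equal(attr(single, "column_means")[["informational"]], 54.94)

  # 0-1 scale input is accepted too
  prof <- tibble::tibble(group = "g", informational = 0.5,
                         emotional = 0.25, companionship = 0.25)
  expect_equal(profile_table(prof)$informational[1], 50)
})

test_that("chi-squared homogeneity test behaves on hand-checkable tables", {
  identical_rows <- tibble::tibble(
    group = c("g1", "g2"),
    edges_informational = c(30L, 30L),
    edges_emotional = c(20L, 20L),
    edges_companionship = c(10L, 10L))
  res <- compare_profiles(identical_rows)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 2)

  # 2x2 diagonal table: chi2 = 40, df = 1 (expected counts all 10)
  diag_tab <- tibble::tibble(
    group = c("g1", "g2"),
    edges_informational = c(20L, 0L),
    edges_emotional = c(0L, 20L))
  res2 <- compare_profiles(diag_tab)
  expect_equal(res2$statistic, 40)
  expect_equal(res2$df, 1)

  # a zero marginal is a degenerate table
  expect_error(compare_profiles(
    dplyr::mutate(diag_tab, edges_companionship = c(0L, 0L))),
    class = "supportnet_degenerate_table_error")

  # statistic invariant under group order
  shuffled <- identical_rows[c(2, 1), ]
  shuffled$edges_informational <- c(35L, 30L)
  orig <- shuffled[c(2, 1), ]
  expect_equal(compare_profiles(shuffled)$statistic,
               compare_profiles(orig)$statistic)

  expect_error(compare_profiles(identical_rows[1, ]),
               class = "supportnet_usage_error")
})
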