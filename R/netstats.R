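#' Average shortest-path length
#'
#' Mean unweighted hop distance over all unordered node pairs of the largest
#' connected component. Distances are computed on the binarised graph;
#' weights play no role.
#'
#' @param net A `cooc_network`.
#' @return A single number, >= 1 whenever the component has >= 2 nodes.
#' @export
average_path_length <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  if (max(comp$csize) < 2) {
    abort("average shortest-path length undefined: all nodes are isolated",
          class = "supportnet_undefined_statistic_error")
  }
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  igraph::mean_distance(giant, directed = FALSE, weights = NA)
}

#' Mean clustering coefficient
#'
#' Average over all nodes of the local clustering coefficient
#' m_i / (k_i (k_i - 1) / 2), where m_i counts edges among the k_i
#' neighbours; nodes with degree < 2 contribute 0.
#'
#' @param net A `cooc_network`.
#' @return A number in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  stopifnot(net$n >= 1)
  g <- as_igraph(net)
  igraph::transitivity(g, type = "localaverage", isolates = "zero",
                       weights = NA)
}

#' Erdős–Rényi baselines for path length and clustering
#'
#' Closed-form expectations for a random graph with the same numbers of
#' nodes and edges: `aspl_r = ln(n) / (ln(2m) - ln(n))` and
#' `cc_r = 2m / (n (n - 1))`. Both returned unrounded.
#'
#' @param n Node count (>= 2).
#' @param m Edge count (>= 1, with 2m > n so the path-length baseline is
#'   defined).
#' @return Tibble with columns `aspl_r`, `cc_r`.
#' @examples
#' er_baselines(729, 6749)   # aspl_r ~ 2.258
#' @export
er_baselines <- function(n, m) {
  stopifnot(length(n) == length(m))
  if (any(n < 2) || any(m < 1)) {
    abort("er_baselines requires n >= 2 and m >= 1",
          class = "supportnet_usage_error")
  }
  if (any(2 * m <= n)) {
    abort("ER path-length baseline undefined: requires 2m > n",
          class = "supportnet_undefined_statistic_error")
  }
  tibble(aspl_r = log(n) / (log(2 * m) - log(n)),
         cc_r = 2 * m / (n * (n - 1)))
}

#' Degree distribution
#'
#' @param net A `cooc_network`.
#' @return Tibble with columns `degree`, `count` (counts sum to `n`);
#'   divide `count` by `n` for the probability p(k).
#' @export
degree_distribution_table <- function(net) {
  stopifnot(net$n >= 1)
  degs <- igraph::degree(as_igraph(net))
  tab <- table(factor(degs, levels = sort(unique(degs))))
  tibble(degree = as.integer(names(tab)), count = as.integer(tab))
}

#' Fit a discrete power law to a degree distribution
#'
#' Estimates the exponent gamma of p(k) proportional to k^-gamma by discrete
#' maximum likelihood, with the lower cutoff `k_min` selected by
#' Kolmogorov–Smirnov minimisation (Clauset-style, via igraph's `plfit`).
#' Setting `k_min` fixes the cutoff instead. A log–log least-squares mode is
#' provided for comparison only.
#'
#' @param degree_histogram Tibble with `degree` and `count` columns (from
#'   [degree_distribution_table()]), or a bare integer vector of degrees.
#' @param k_min Optional fixed lower cutoff.
#' @param method `"mle"` (default) or `"ols"` (log–log regression of p(k)
#'   on k, diagnostic only).
#' @return Tibble with columns `gamma`, `k_min`, `n_tail` (observations with
#'   degree >= k_min).
#' @export
fit_power_law <- function(degree_histogram, k_min = NULL,
                          method = c("mle", "ols")) {
  method <- match.arg(method)
  degs <- if (is.data.frame(degree_histogram)) {
    rep(degree_histogram$degree, degree_histogram$count)
  } else {
    as.integer(degree_histogram)
  }
  degs <- degs[degs >= 1]
  if (length(unique(degs)) < 2) {
    abort("power-law fit undefined: fewer than two distinct positive degrees",
          class = "supportnet_undefined_statistic_error")
  }
  if (method == "ols") {
    tab <- table(degs)
    k <- as.numeric(names(tab))
    pk <- as.numeric(tab) / length(degs)
    fit <- stats::lm(log(pk) ~ log(k))
    return(tibble(gamma = -unname(stats::coef(fit)[2]),
                  k_min = min(k), n_tail = length(degs)))
  }
  fit <- if (is.null(k_min)) {
    igraph::fit_power_law(degs, implementation = "plfit")
  } else {
    igraph::fit_power_law(degs, xmin = k_min, implementation = "plfit")
  }
  tibble(gamma = fit$alpha, k_min = fit$xmin,
         n_tail = sum(degs >= fit$xmin))
}

#' Small-world check
#'
#' A network is flagged small-world when its average shortest-path length is
#' comparable to the random-graph baseline while its clustering coefficient
#' greatly exceeds the baseline: `aspl <= r_aspl * aspl_r` and
#' `cc >= r_cc * cc_r`. The ratios make the informal "comparable" and
#' "greatly exceeds" operational and are deliberately explicit.
#'
#' @param aspl,cc Measured statistics.
#' @param aspl_r,cc_r Erdős–Rényi baselines (see [er_baselines()]).
#' @param r_aspl Maximum allowed ratio aspl / aspl_r (default 2).
#' @param r_cc Minimum required ratio cc / cc_r (default 10).
#' @return Logical.
#' @export
small_world_check <- function(aspl, cc, aspl_r, cc_r,
                              r_aspl = 2, r_cc = 10) {
  stopifnot(is.finite(aspl), is.finite(cc), is.finite(aspl_r), is.finite(cc_r))
  aspl <= r_aspl * aspl_r && cc >= r_cc * cc_r
}

#' Full network diagnostics
#'
#' Computes every summary the pipeline reports for one network: ASPL and
#' clustering coefficient with their Erdős–Rényi baselines, the power-law
#' degree exponent, the small-world flag, and the fraction of nodes in the
#' largest connected component (ASPL is computed on that component only).
#'
#' @param net A `cooc_network`.
#' @inheritParams small_world_check
#' @return A `network_stats` object (also a one-row tibble) with columns
#'   `n`, `m`, `aspl`, `cc`, `aspl_r`, `cc_r`, `gamma`, `k_min`,
#'   `is_small_world`, `component_coverage`; the degree histogram is
#'   attached as attribute `"degree_histogram"`.
#' @export
network_statistics <- function(net, r_aspl = 2, r_cc = 10) {
  stopifnot(inherits(net, "cooc_network"))
  hist <- degree_distribution_table(net)
  base <- er_baselines(net$n, net$m)
  aspl <- average_path_length(net)
  cc <- clustering_coefficient(net)
  gamma_fit <- tryCatch(fit_power_law(hist),
                        supportnet_undefined_statistic_error = function(e) {
                          tibble(gamma = NA_real_, k_min = NA_real_,
                                 n_tail = NA_integer_)
                        })
  comp <- igraph::components(as_igraph(net))
  out <- tibble(
    n = net$n, m = net$m, aspl = aspl, cc = cc,
    aspl_r = base$aspl_r, cc_r = base$cc_r,
    gamma = gamma_fit$gamma, k_min = gamma_fit$k_min,
    is_small_world = small_world_check(aspl, cc, base$aspl_r, base$cc_r,
                                       r_aspl = r_aspl, r_cc = r_cc),
    component_coverage = max(comp$csize) / net$n)
  attr(out, "degree_histogram") <- hist
  class(out) <- c("network_stats", class(out))
  out
}

#' @exportS3Method generics::glance
glance.network_stats <- function(x, ...) {
  out <- x
  attr(out, "degree_histogram") <- NULL
  class(out) <- setdiff(class(out), "network_stats")
  out
}

#' Degree distribution plot
#'
#' Log–log scatter of the empirical degree probability p(k), the standard
#' visual check for scale-free structure.
#'
#' @param net A `cooc_network`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(net) {
  hist <- degree_distribution_table(net) |>
    filter(.data$degree > 0) |>
    mutate(pk = .data$count / sum(.data$count))
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$degree, y = .data$pk)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "p(k)",
                  title = "Degree distribution (log-log)") +
    ggplot2::theme_minimal()
}
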