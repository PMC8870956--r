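#' Published network sizes of eight cancer-forum co-occurrence networks
#'
#' Node and edge counts (plus sentence counts) reported by a published word
#' co-occurrence analysis of the cancer forums of a large online health
#' community, one network per cancer type. Useful for checking the
#' closed-form Erdős–Rényi baselines ([er_baselines()]) against their
#' reported values at realistic network sizes.
#'
#' @format Tibble with columns `group`, `sentences`, `words` (n),
#'   `cooccurrence_pairs` (m), and the reported `aspl_r` (3 decimals).
#' @export
cancer_network_sizes <- tibble::tibble(
  group = c("lung", "breast", "colon", "skin", "prostate", "ovarian",
            "pancreatic", "renal"),
  sentences = c(15690L, 3222L, 2746L, 1295L, 751L, 585L, 315L, 848L),
  words = c(12830L, 4059L, 3524L, 1462L, 2005L, 936L, 729L, 1196L),
  cooccurrence_pairs = c(196620L, 48559L, 57430L, 12124L, 28475L, 10842L,
                         6749L, 9692L),
  aspl_r = c(2.764, 2.617, 2.344, 2.595, 2.272, 2.177, 2.258, 2.544)
)

#' Published support-category profiles of eight cancer groups
#'
#' Percentages of informational support, emotional support and companionship
#' reported by the same published analysis, one row per cancer type (rows
#' sum to 100). Feeding these to [profile_table()] reproduces the reported
#' column means (informational 47.14\%, companionship 28.26\%).
#'
#' @format Tibble with columns `group`, `informational`, `emotional`,
#'   `companionship` (percent).
#' @export
cancer_support_profiles <- tibble::tibble(
  group = c("lung", "breast", "colon", "skin", "prostate", "ovarian",
            "pancreatic", "renal"),
  informational = c(54.94, 40.68, 58.81, 42.02, 41.15, 37.22, 54.34, 47.92),
  emotional = c(13.32, 40.45, 8.99, 24.19, 36.73, 36.43, 13.13, 23.61),
  companionship = c(31.74, 18.87, 32.20, 33.79, 22.12, 26.35, 32.53, 28.47)
)
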