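#' Per-population allele frequencies
#'
#' Counts alleles over called genotypes: frequency = allele count /
#' (2 x typed individuals) at each group x locus; missing genotypes are
#' excluded per locus. Loci with no typed individuals anywhere in a group are
#' absent from the output (with a warning).
#'
#' @param genotypes Genotype tibble (e.g. from [simulate_individuals()] or a
#'   called consensus table).
#' @param grouping Column name used as the population grouping.
#' @return A tibble: grouping column, `locus`, `allele`, `freq`, `n_typed`.
#' @examples
#' g <- tibble::tibble(
#'   sample_id = c("a", "b"), population = "p", species = "rowi",
#'   locus = "KMS1", allele_a = c(240L, 240L), allele_b = c(240L, 244L)
#' )
#' allele_frequencies(g)  # p_240 = 0.75
#' @export
allele_frequencies <- function(genotypes, grouping = "population") {
  if (!grouping %in% names(genotypes)) {
    abort(paste0("Grouping column `", grouping, "` not found."))
  }
  typed <- dplyr::filter(genotypes, !is.na(.data$allele_a))
  if (nrow(typed) == 0L) abort("No typed genotypes to count.")
  dropped <- genotypes |>
    dplyr::distinct(.data[[grouping]], .data$locus) |>
    dplyr::anti_join(dplyr::distinct(typed, .data[[grouping]], .data$locus),
                     by = c(grouping, "locus"))
  if (nrow(dropped) > 0L) {
    warn(paste0(nrow(dropped), " group x locus combination(s) had no typed ",
                "genotypes and were dropped."))
  }
  typed |>
    tidyr::pivot_longer(c("allele_a", "allele_b"), values_to = "allele") |>
    dplyr::group_by(.data[[grouping]], .data$locus) |>
    dplyr::mutate(n_typed = dplyr::n() / 2L) |>
    dplyr::group_by(.data[[grouping]], .data$locus, .data$allele,
                    .data$n_typed) |>
    dplyr::summarise(count = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(freq = .data$count / (2 * .data$n_typed)) |>
    dplyr::select(dplyr::all_of(grouping), "locus", "allele", "freq",
                  "n_typed") |>
    dplyr::arrange(.data[[grouping]], .data$locus, .data$allele)
}

#' Per-locus diversity statistics
#'
#' For each population x locus: expected heterozygosity
#' `He = 1 - sum(p_i^2)` (optionally the small-sample unbiased variant
#' `2n/(2n-1) * He`), observed heterozygosity `Ho` = heterozygotes / typed
#' individuals, the inbreeding coefficient `FIS = (He - Ho)/He` (undefined at
#' monomorphic loci), the number of alleles, and the number of private
#' alleles (alleles whose frequency support is unique to the population, no
#' minimum-frequency filter).
#'
#' @param freqs Allele-frequency tibble from [allele_frequencies()].
#' @param genotypes The genotype tibble the frequencies were computed from.
#' @param grouping Population grouping column.
#' @param unbiased Use the `2n/(2n-1)` correction for He.
#' @return A tibble: grouping, `locus`, `n_typed`, `n_alleles`,
#'   `n_private`, `he`, `ho`, `fis`.
#' @export
diversity_by_locus <- function(freqs, genotypes, grouping = "population",
                               unbiased = FALSE) {
  priv <- freqs |>
    dplyr::filter(.data$freq > 0) |>
    dplyr::group_by(.data$locus, .data$allele) |>
    dplyr::mutate(n_pops_with = dplyr::n_distinct(.data[[grouping]])) |>
    dplyr::ungroup()

  he_tbl <- priv |>
    dplyr::group_by(.data[[grouping]], .data$locus) |>
    dplyr::summarise(
      n_typed = .data$n_typed[1],
      n_alleles = dplyr::n(),
      n_private = sum(.data$n_pops_with == 1L),
      he = 1 - sum(.data$freq^2),
      .groups = "drop"
    )
  if (unbiased) {
    he_tbl$he <- he_tbl$he * 2 * he_tbl$n_typed / (2 * he_tbl$n_typed - 1)
  }

  ho_tbl <- genotypes |>
    dplyr::filter(!is.na(.data$allele_a)) |>
    dplyr::group_by(.data[[grouping]], .data$locus) |>
    dplyr::summarise(ho = mean(.data$allele_a != .data$allele_b),
                     .groups = "drop")

  he_tbl |>
    dplyr::left_join(ho_tbl, by = c(grouping, "locus")) |>
    dplyr::mutate(fis = ifelse(.data$he > 0,
                               (.data$he - .data$ho) / .data$he, NA_real_))
}

#' Population diversity summary
#'
#' Population-level values are unweighted means of the per-locus statistics:
#' `na` is the mean number of alleles per locus, `he`/`ho` the mean
#' heterozygosities, `fis_mean` the mean of per-locus FIS over loci where it
#' is defined, and `n_private` the total count of population-specific
#' alleles. Because the mean-of-ratios and ratio-of-means FIS estimators can
#' disagree, `fis_ratio = (mean He - mean Ho) / mean He` is also emitted.
#'
#' @inheritParams diversity_by_locus
#' @return A tibble with one row per population: `n`, `na`, `n_private`,
#'   `he`, `ho`, `fis_mean`, `fis_ratio`.
#' @examples
#' pops <- tibble::tibble(population = "LSK", species = "owenii")
#' model <- simulate_populations(pops, n_alleles = 3, seed = 1)
#' truth <- simulate_individuals(model, n = 30, seed = 2)
#' auto <- dplyr::filter(truth, locus != "Z37B")
#' diversity_stats(allele_frequencies(auto), auto)
#' @export
diversity_stats <- function(freqs, genotypes, grouping = "population",
                            unbiased = FALSE) {
  by_locus <- diversity_by_locus(freqs, genotypes, grouping, unbiased)
  n_tbl <- genotypes |>
    dplyr::group_by(.data[[grouping]]) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop")
  by_locus |>
    dplyr::group_by(.data[[grouping]]) |>
    dplyr::summarise(
      na = mean(.data$n_alleles),
      n_private = sum(.data$n_private),
      he = mean(.data$he),
      ho = mean(.data$ho),
      fis_mean = mean(.data$fis, na.rm = TRUE),
      fis_ratio = (mean(.data$he) - mean(.data$ho)) / mean(.data$he),
      .groups = "drop"
    ) |>
    dplyr::left_join(n_tbl, by = grouping) |>
    dplyr::select(dplyr::all_of(grouping), "n", "na", "n_private", "he",
                  "ho", "fis_mean", "fis_ratio")
}

#' Probability of identity at one locus
#'
#' `pi_locus()` gives the probability that two unrelated individuals drawn
#' from a population in Hardy-Weinberg proportions share the single-locus
#' genotype: `PI = 2 (sum p_i^2)^2 - sum p_i^4`. `pisibs_locus()` gives the
#' conservative full-sibling analogue:
#' `PIsibs = 0.25 + 0.5 sum p_i^2 + 0.5 (sum p_i^2)^2 - 0.25 sum p_i^4`.
#' `PIsibs >= PI` always.
#'
#' @param p Numeric allele-frequency vector (non-negative, sums to 1).
#' @return A single probability.
#' @examples
#' pi_locus(c(0.5, 0.5))      # 0.375
#' pisibs_locus(c(0.5, 0.5))  # 0.59375
#' @export
pi_locus <- function(p) {
  check_freq_vector(p)
  s2 <- sum(p^2)
  2 * s2^2 - sum(p^4)
}

#' @rdname pi_locus
#' @export
pisibs_locus <- function(p) {
  check_freq_vector(p)
  s2 <- sum(p^2)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * sum(p^4)
}

check_freq_vector <- function(p) {
  if (length(p) == 0L || any(!is.finite(p)) || any(p < 0)) {
    abort("Frequency vector must be non-negative and finite.")
  }
  if (abs(sum(p) - 1) > 1e-6) {
    abort("Frequency vector must sum to 1.")
  }
  invisible(p)
}

#' Per-locus PI and PIsibs for every population
#'
#' @param freqs Allele-frequency tibble from [allele_frequencies()].
#' @param grouping Population grouping column.
#' @return A tibble: grouping, `locus`, `pi`, `pisibs`.
#' @export
pi_by_locus <- function(freqs, grouping = "population") {
  freqs |>
    dplyr::group_by(.data[[grouping]], .data$locus) |>
    dplyr::summarise(pi = pi_locus(.data$freq),
                     pisibs = pisibs_locus(.data$freq),
                     .groups = "drop")
}

#' Cumulative PI over increasing locus combinations
#'
#' Multiplies per-locus PI (and PIsibs) across loci in a given order,
#' yielding the discriminatory power of the first k loci for k = 1..L. Loci
#' are assumed independent. An exclusion set supports reduced-panel
#' comparisons (e.g. dropping the worst-performing loci).
#'
#' @param pi_tbl Per-locus PI tibble from [pi_by_locus()].
#' @param order `"panel"` keeps the supplied locus order (use `locus_order`
#'   to override); `"informative"` sorts loci by ascending PI
#'   (most informative first), per population.
#' @param exclude Locus names to drop before accumulating.
#' @param locus_order Optional explicit locus ordering.
#' @param grouping Population grouping column.
#' @return A tibble: grouping, `k`, `locus`, `pi`, `pisibs`, `pi_cum`,
#'   `pisibs_cum`; `pi_cum` is non-increasing in `k`.
#' @examples
#' pt <- tibble::tibble(population = "p", locus = c("L1", "L2"),
#'                      pi = c(0.375, 0.375), pisibs = c(0.59375, 0.59375))
#' cumulative_pi(pt)  # PI_2 = 0.140625
#' @export
cumulative_pi <- function(pi_tbl, order = c("panel", "informative"),
                          exclude = character(), locus_order = NULL,
                          grouping = "population") {
  order <- match.arg(order)
  kept <- dplyr::filter(pi_tbl, !.data$locus %in% exclude)
  if (nrow(kept) == 0L) abort("No loci left after exclusion.")
  kept |>
    dplyr::group_by(.data[[grouping]]) |>
    dplyr::group_modify(function(d, key) {
      idx <- if (!is.null(locus_order)) {
        match(intersect(locus_order, d$locus), d$locus)
      } else if (order == "informative") {
        base::order(d$pi)
      } else {
        seq_len(nrow(d))
      }
      d <- d[idx, ]
      d$k <- seq_len(nrow(d))
      d$pi_cum <- cumprod(d$pi)
      d$pisibs_cum <- cumprod(d$pisibs)
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(grouping), "k", "locus", "pi", "pisibs",
                  "pi_cum", "pisibs_cum")
}
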