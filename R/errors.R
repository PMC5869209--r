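#' Genotyping error rates across replicates
#'
#' GIMLET-style estimation: errors are discrepancies of each replicate to its
#' consensus profile (or to a reference-derived consensus). With positive =
#' non-failed replicate:
#' * **amplification failure** = failed replicates / all replicates;
#' * **allelic dropout (ADO)**, per locus = positive replicates at
#'   heterozygous-consensus sample-loci showing exactly one consensus allele
#'   and nothing else, divided by positive replicates at
#'   heterozygous-consensus sample-loci;
#' * **false alleles (FA)**, per locus = positive replicates containing at
#'   least one allele absent from the consensus, divided by positive
#'   replicates at sample-loci with a defined consensus.
#'
#' Per-sample analogues restrict the same ratios to one sample. "Across
#' loci" and "across samples" summaries are unweighted means of the defined
#' per-locus / per-sample rates; pooled rates (ratio of summed numerators to
#' summed denominators) are also reported. A unit with no
#' heterozygous-consensus loci has undefined (not zero) ADO and is excluded
#' from the mean.
#'
#' @param reps Replicate tibble.
#' @param consensus Consensus tibble from [call_consensus()] (possibly
#'   reference-derived).
#' @return An object of class `kiwi_error_rates`: a list with tibbles
#'   `by_locus`, `by_sample` and one-row `overall`. Use [tidy()] for the
#'   long per-unit rates and [glance()] for the summary row.
#' @examples
#' reps <- tibble::tibble(
#'   sample_id = "s1", population = "p", species = "mantelli",
#'   locus = "KMS1", replicate = 1:4,
#'   alleles = list(240L, c(240L, 244L), 244L, integer(0))
#' )
#' er <- error_rates(reps, call_consensus(reps))
#' glance(er)  # ADO 2/3, failure 1/4
#' @export
error_rates <- function(reps, consensus) {
  cons <- dplyr::select(consensus, "sample_id", "locus", "allele_a",
                        "allele_b", "called")
  scored <- reps |>
    dplyr::left_join(cons, by = c("sample_id", "locus")) |>
    dplyr::mutate(
      positive = lengths(.data$alleles) > 0L,
      defined = .data$called %in% TRUE,
      het = .data$defined & .data$allele_a != .data$allele_b,
      is_ado = .data$positive & .data$het &
        purrr::pmap_lgl(list(.data$alleles, .data$allele_a, .data$allele_b),
                        function(s, a, b) {
                          length(s) == 1L && s %in% c(a, b)
                        }),
      is_fa = .data$positive & .data$defined &
        purrr::pmap_lgl(list(.data$alleles, .data$allele_a, .data$allele_b),
                        function(s, a, b) {
                          length(s) > 0L && !all(s %in% c(a, b))
                        })
    )

  rate_block <- function(d) {
    dplyr::summarise(
      d,
      n_reps = dplyr::n(),
      n_failed = sum(!.data$positive),
      failure = .data$n_failed / .data$n_reps,
      n_het_pos = sum(.data$positive & .data$het),
      ado = ifelse(.data$n_het_pos > 0,
                   sum(.data$is_ado) / .data$n_het_pos, NA_real_),
      n_def_pos = sum(.data$positive & .data$defined),
      fa = ifelse(.data$n_def_pos > 0,
                  sum(.data$is_fa) / .data$n_def_pos, NA_real_),
      .groups = "drop"
    )
  }

  by_locus <- rate_block(dplyr::group_by(scored, .data$locus))
  by_sample <- rate_block(dplyr::group_by(scored, .data$sample_id))
  pooled <- rate_block(scored)

  overall <- tibble::tibble(
    amplification_failure = pooled$failure,
    ado_across_loci = mean(by_locus$ado, na.rm = TRUE),
    ado_across_samples = mean(by_sample$ado, na.rm = TRUE),
    ado_pooled = pooled$ado,
    fa_across_loci = mean(by_locus$fa, na.rm = TRUE),
    fa_across_samples = mean(by_sample$fa, na.rm = TRUE),
    fa_pooled = pooled$fa,
    n_replicates = pooled$n_reps
  )

  structure(
    list(by_locus = by_locus, by_sample = by_sample, overall = overall),
    class = "kiwi_error_rates"
  )
}

#' @export
print.kiwi_error_rates <- function(x, ...) {
  o <- x$overall
  cat("<kiwi_error_rates>\n")
  cat(sprintf("  amplification failure: %.3f\n", o$amplification_failure))
  cat(sprintf("  allelic dropout: %.3f across loci, %.3f across samples\n",
              o$ado_across_loci, o$ado_across_samples))
  cat(sprintf("  false alleles:   %.4f across loci, %.4f across samples\n",
              o$fa_across_loci, o$fa_across_samples))
  invisible(x)
}

#' @rdname error_rates
#' @param x A `kiwi_error_rates` object.
#' @param ... Unused.
#' @export
tidy.kiwi_error_rates <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$by_locus, unit = "locus"), level = "locus"),
    dplyr::mutate(dplyr::rename(x$by_sample, unit = "sample_id"),
                  level = "sample")
  ) |>
    dplyr::select("level", "unit", "failure", "ado", "fa", "n_reps",
                  "n_het_pos", "n_def_pos")
}

#' @rdname error_rates
#' @export
glance.kiwi_error_rates <- function(x, ...) {
  x$overall
}
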