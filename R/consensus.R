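#' Call consensus genotypes from replicated amplifications
#'
#' Multi-tube consensus rules at each sample x locus, counting in how many
#' positive (non-failed) replicates each allele appears:
#' * heterozygote `A/B` when exactly two alleles each appear in at least
#'   `het_min` positive replicates;
#' * homozygote `A/A` when a single allele appears in at least `hom_min`
#'   positive replicates and no other allele reaches `het_min`;
#' * three or more alleles reaching `het_min` is conflicting support — the
#'   genotype is left missing with flag `"conflict"`;
#' * otherwise missing (`"low_support"`, or `"failed"` when no replicate
#'   amplified).
#'
#' When a reference genotype table is supplied (e.g. a high-quality feather
#' sample from the same bird), the reference genotype overrides the
#' replicate-based call and replicates are subsequently scored against it.
#'
#' @param reps Replicate tibble (see [simulate_replicates()] /
#'   [read_replicate_table()]).
#' @param het_min Positive replicates required per heterozygote allele.
#' @param hom_min Positive replicates required for a homozygote call.
#' @param reference Optional genotype tibble of reference genotypes.
#' @return A consensus tibble: `sample_id`, `population`, `species`, `locus`,
#'   `allele_a`, `allele_b`, `called`, `flag`, `n_reps`, `n_positive`,
#'   `support_a`, `support_b`, `source` ("replicates" or "reference").
#' @examples
#' reps <- tibble::tibble(
#'   sample_id = "s1", population = "p", species = "mantelli",
#'   locus = "KMS1", replicate = 1:4,
#'   alleles = list(c(240L, 244L), 240L, 244L, c(240L, 244L))
#' )
#' call_consensus(reps)  # heterozygote 240/244
#' @export
call_consensus <- function(reps, het_min = 2L, hom_min = 3L,
                           reference = NULL) {
  if (het_min < 1L || hom_min < het_min) {
    abort("Need `het_min` >= 1 and `hom_min` >= `het_min`.")
  }
  ref_key <- NULL
  if (!is.null(reference)) {
    ref <- dplyr::filter(reference, !is.na(.data$allele_a))
    ref_key <- setNames(
      purrr::map2(ref$allele_a, ref$allele_b, c),
      paste(ref$sample_id, ref$locus, sep = "\r")
    )
  }

  reps |>
    dplyr::group_by(.data$sample_id, .data$population, .data$species,
                    .data$locus) |>
    dplyr::summarise(
      consensus_one(.data$alleles, het_min, hom_min,
                    ref_key[[paste(.data$sample_id[1], .data$locus[1],
                                   sep = "\r")]]),
      .groups = "drop"
    )
}

consensus_one <- function(allele_sets, het_min, hom_min, ref_genotype) {
  n_reps <- length(allele_sets)
  positive <- allele_sets[lengths(allele_sets) > 0L]
  n_pos <- length(positive)
  counts <- table(unlist(purrr::map(positive, unique)))

  support_of <- function(a) {
    s <- counts[as.character(a)]
    as.integer(dplyr::coalesce(as.integer(s), 0L))
  }

  if (!is.null(ref_genotype)) {
    a <- min(ref_genotype); b <- max(ref_genotype)
    return(tibble::tibble(
      allele_a = a, allele_b = b, called = TRUE, flag = "reference",
      n_reps = n_reps, n_positive = n_pos,
      support_a = support_of(a), support_b = support_of(b),
      source = "reference"
    ))
  }

  missing_row <- function(flag) tibble::tibble(
    allele_a = NA_integer_, allele_b = NA_integer_, called = FALSE,
    flag = flag, n_reps = n_reps, n_positive = n_pos,
    support_a = NA_integer_, support_b = NA_integer_, source = "replicates"
  )

  if (n_pos == 0L) return(missing_row("failed"))
  supported <- as.integer(names(counts)[counts >= het_min])
  if (length(supported) >= 3L) return(missing_row("conflict"))
  if (length(supported) == 2L) {
    a <- min(supported); b <- max(supported)
    return(tibble::tibble(
      allele_a = a, allele_b = b, called = TRUE, flag = "ok",
      n_reps = n_reps, n_positive = n_pos,
      support_a = support_of(a), support_b = support_of(b),
      source = "replicates"
    ))
  }
  if (length(supported) == 1L && support_of(supported) >= hom_min) {
    a <- supported
    return(tibble::tibble(
      allele_a = a, allele_b = a, called = TRUE, flag = "ok",
      n_reps = n_reps, n_positive = n_pos,
      support_a = support_of(a), support_b = support_of(a),
      source = "replicates"
    ))
  }
  missing_row("low_support")
}

#' Consensus quality index (QI)
#'
#' Scores each replicate 1 when its full single-locus genotype equals the
#' consensus (for a heterozygote the replicate must show exactly both
#' alleles; for a homozygote exactly the one allele) and 0 otherwise; failed
#' amplifications score 0. The per-locus QI is the mean replicate score, so a
#' locus where every replicate failed has QI 0.
#'
#' @param reps Replicate tibble.
#' @param consensus Consensus tibble from [call_consensus()].
#' @return A tibble with one row per sample x locus: `sample_id`,
#'   `population`, `species`, `locus`, `called`, `qi`.
#' @seealso [qi_by_sample()], [qi_summary()]
#' @export
quality_index <- function(reps, consensus) {
  cons <- dplyr::select(consensus, "sample_id", "locus", "allele_a",
                        "allele_b", "called")
  reps |>
    dplyr::left_join(cons, by = c("sample_id", "locus")) |>
    dplyr::mutate(score = replicate_score(.data$alleles, .data$allele_a,
                                          .data$allele_b)) |>
    dplyr::group_by(.data$sample_id, .data$population, .data$species,
                    .data$locus) |>
    dplyr::summarise(called = .data$called[1], qi = mean(.data$score),
                     .groups = "drop")
}

replicate_score <- function(allele_sets, allele_a, allele_b) {
  purrr::pmap_dbl(list(allele_sets, allele_a, allele_b), function(s, a, b) {
    if (is.na(a) || length(s) == 0L) return(0)
    as.numeric(setequal(s, unique(c(a, b))))
  })
}

#' Per-sample QI
#'
#' The per-sample QI is the mean per-locus QI over loci with a defined
#' consensus; a sample with no consensus at any locus has undefined QI
#' (`NA`). `QI = 1` if and only if every replicate at every consensus-defined
#' locus matches the consensus.
#'
#' @param qi Per-locus QI tibble from [quality_index()].
#' @param exclude Optional locus names to drop before averaging (e.g. the
#'   worst-performing loci when comparing a reduced panel).
#' @return A tibble: `sample_id`, `population`, `species`, `qi`,
#'   `n_loci_called`.
#' @export
qi_by_sample <- function(qi, exclude = character()) {
  qi |>
    dplyr::filter(!.data$locus %in% exclude) |>
    dplyr::group_by(.data$sample_id, .data$population, .data$species) |>
    dplyr::summarise(
      n_loci_called = sum(.data$called, na.rm = TRUE),
      qi = if (any(.data$called %in% TRUE)) {
        mean(.data$qi[.data$called %in% TRUE])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::select("sample_id", "population", "species", "qi", "n_loci_called")
}

#' Cohort QI summary
#'
#' Mean and standard deviation of per-sample QI over the cohort.
#'
#' @param qi Per-locus QI tibble from [quality_index()].
#' @param exclude Optional locus names to drop before averaging.
#' @return A one-row tibble: `n_samples`, `qi_mean`, `qi_sd`.
#' @export
qi_summary <- function(qi, exclude = character()) {
  qs <- qi_by_sample(qi, exclude = exclude)
  tibble::tibble(
    n_samples = sum(!is.na(qs$qi)),
    qi_mean = mean(qs$qi, na.rm = TRUE),
    qi_sd = sd(qs$qi, na.rm = TRUE)
  )
}

#' Flag successful genotypes by QI threshold
#'
#' A genotype is considered successful when its QI reaches the threshold
#' (boundary inclusive); 0.75 is the conventional cut-off.
#'
#' @param sample_qi Per-sample QI tibble from [qi_by_sample()].
#' @param threshold Minimum QI for success.
#' @return The input with a logical `success` column (`NA` QI gives
#'   `success = FALSE`).
#' @seealso [success_rate()]
#' @export
classify_success <- function(sample_qi, threshold = 0.75) {
  dplyr::mutate(sample_qi,
                success = !is.na(.data$qi) & .data$qi >= threshold)
}

#' @rdname classify_success
#' @return `success_rate()` returns a one-row tibble with `n_samples`,
#'   `n_success` and the cohort `success_rate`.
#' @export
success_rate <- function(sample_qi, threshold = 0.75) {
  cl <- classify_success(sample_qi, threshold)
  tibble::tibble(
    n_samples = nrow(cl),
    n_success = sum(cl$success),
    success_rate = mean(cl$success)
  )
}

#' Remove samples failing too many loci
#'
#' Drops any sample whose consensus is missing at more than `max_failed_loci`
#' loci (default 2, the conventional noninvasive-quality filter). The removed
#' sample ids are reported via a message and attached as the
#' `"removed_samples"` attribute.
#'
#' @param consensus Consensus tibble.
#' @param max_failed_loci Maximum tolerated loci without consensus.
#' @return The filtered consensus tibble.
#' @export
filter_samples <- function(consensus, max_failed_loci = 2L) {
  failed <- consensus |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_failed = sum(!.data$called), .groups = "drop")
  removed <- failed$sample_id[failed$n_failed > max_failed_loci]
  if (length(removed) > 0) {
    inform(paste0("Removed ", length(removed), " sample(s) failing > ",
                  max_failed_loci, " loci: ",
                  paste(removed, collapse = ", ")))
  }
  out <- dplyr::filter(consensus, !.data$sample_id %in% removed)
  attr(out, "removed_samples") <- removed
  out
}
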