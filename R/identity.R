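#' Sex determination from Z37B fragment sizes
#'
#' In the ZW system the female is the heterogametic sex, so dropout fails
#' asymmetrically: a female missing her W fragment looks male, but a male
#' can never gain a W. The caller is therefore asymmetric:
#' * **female** as soon as the W fragment (92 bp) appears in any positive
#'   replicate;
#' * **male** only when at least `min_pos_male` positive replicates are
#'   W-free and at least one fragment from the species' Z pool was observed;
#' * **ambiguous** when positives are too few to exclude W dropout;
#' * **failed** when every replicate failed.
#'
#' Fragments outside the species pool, and lineage-restricted Z alleles
#' observed outside their declared lineage, are annotated in `note`.
#'
#' @param reps Replicate tibble; only rows at `sex_locus` are used. Must
#'   carry a `species` column (needed to interpret Z sizes); a `lineage`
#'   column is used for the lineage annotations when present.
#' @param model Fragment-size model, default [sex_marker_model()].
#' @param min_pos_male Minimum W-free positive replicates for a male call.
#' @param sex_locus Name of the sex-linked locus.
#' @return A tibble: `sample_id`, `population`, `species`, `call` (one of
#'   "female", "male", "ambiguous", "failed"), `n_positive`, `n_with_w`,
#'   `note`.
#' @examples
#' reps <- tibble::tibble(
#'   sample_id = "s1", population = "p", species = "mantelli",
#'   locus = "Z37B", replicate = 1:4,
#'   alleles = list(c(92L, 96L), c(92L, 96L), 96L, integer(0))
#' )
#' sex_call(reps)  # female: W fragment observed
#' @export
sex_call <- function(reps, model = sex_marker_model(), min_pos_male = 2L,
                     sex_locus = "Z37B") {
  sl <- dplyr::filter(reps, .data$locus == sex_locus)
  if (nrow(sl) == 0L) abort(paste0("No replicates at sex locus ", sex_locus, "."))
  bad <- setdiff(unique(sl$species), unique(model$species))
  if (length(bad) > 0L) {
    abort(paste0("Unknown species for sex calling: ",
                 paste(bad, collapse = ", "), "."))
  }
  if (!"lineage" %in% names(sl)) sl$lineage <- NA_character_

  sl |>
    dplyr::group_by(.data$sample_id, .data$population, .data$species,
                    .data$lineage) |>
    dplyr::summarise(
      sex_call_one(.data$alleles, .data$species[1], .data$lineage[1],
                   model, min_pos_male),
      .groups = "drop"
    ) |>
    dplyr::select("sample_id", "population", "species", "call",
                  "n_positive", "n_with_w", "note")
}

sex_call_one <- function(allele_sets, species, lineage, model, min_pos_male) {
  positive <- allele_sets[lengths(allele_sets) > 0L]
  n_pos <- length(positive)
  w <- w_size_for(model, species)
  pool_all <- unique(c(w, model$z_size[model$species == species]))
  pool_here <- z_pool(model, species, lineage)
  observed <- unique(unlist(positive))
  has_w <- purrr::map_lgl(positive, ~ w %in% .x)

  notes <- character(0)
  outside <- setdiff(observed, pool_all)
  if (length(outside) > 0L) {
    notes <- c(notes, paste0("fragment(s) outside species pool: ",
                             paste(outside, collapse = ",")))
  }
  off_lineage <- setdiff(intersect(observed, pool_all), c(w, pool_here))
  if (length(off_lineage) > 0L) {
    notes <- c(notes, paste0("Z allele(s) outside declared lineage: ",
                             paste(off_lineage, collapse = ",")))
  }

  call <- if (n_pos == 0L) {
    "failed"
  } else if (any(has_w)) {
    "female"
  } else if (n_pos >= min_pos_male &&
             length(intersect(observed, setdiff(pool_all, w))) > 0L) {
    "male"
  } else {
    "ambiguous"
  }
  tibble::tibble(
    call = call, n_positive = n_pos, n_with_w = sum(has_w),
    note = if (length(notes) > 0L) paste(notes, collapse = "; ")
           else NA_character_
  )
}

#' Pairwise genotype matching for individualization
#'
#' Scores every pair of samples: loci typed in both are compared as
#' unordered allele pairs, and a pair is flagged as the same individual when
#' its mismatching-locus count is at most `max_mismatch` over at least
#' `min_shared_loci` shared loci. Samples with zero typed loci are excluded
#' with a warning. The report lists each unordered pair once
#' (`sample_1 < sample_2`); the relation itself is symmetric.
#'
#' @param genotypes Genotype tibble.
#' @param max_mismatch Maximum mismatching loci for a match.
#' @param min_shared_loci Minimum shared typed loci for a pair to be
#'   assessable.
#' @return A tibble: `sample_1`, `sample_2`, `n_shared`, `n_mismatch`,
#'   `match`.
#' @examples
#' g <- tibble::tibble(
#'   sample_id = rep(c("a", "b"), each = 2), population = "p",
#'   species = "rowi", locus = rep(c("L1", "L2"), 2),
#'   allele_a = c(240L, 100L, 240L, 100L),
#'   allele_b = c(244L, 100L, 244L, 102L)
#' )
#' match_genotypes(g)  # one mismatch at L2
#' @export
match_genotypes <- function(genotypes, max_mismatch = 0L,
                            min_shared_loci = 1L) {
  typed <- dplyr::filter(genotypes, !is.na(.data$allele_a))
  untyped <- setdiff(unique(genotypes$sample_id), unique(typed$sample_id))
  if (length(untyped) > 0L) {
    warn(paste0("Excluding ", length(untyped),
                " sample(s) with zero typed loci: ",
                paste(untyped, collapse = ", ")))
  }
  ids <- sort(unique(typed$sample_id))
  if (length(ids) < 2L) abort("Need at least two samples with typed loci.")

  wide <- typed |>
    dplyr::mutate(gt = paste(.data$allele_a, .data$allele_b, sep = "/")) |>
    tidyr::pivot_wider(id_cols = "sample_id", names_from = "locus",
                       values_from = "gt")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample_id
  m <- m[ids, , drop = FALSE]

  n <- length(ids)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    gi <- m[i, ]
    shared <- !is.na(m[rest, , drop = FALSE]) &
      matrix(!is.na(gi), nrow = length(rest), ncol = ncol(m), byrow = TRUE)
    mism <- shared & (m[rest, , drop = FALSE] !=
                        matrix(gi, nrow = length(rest), ncol = ncol(m),
                               byrow = TRUE))
    out[[i]] <- tibble::tibble(
      sample_1 = ids[i], sample_2 = ids[rest],
      n_shared = unname(rowSums(shared)), n_mismatch = unname(rowSums(mism))
    )
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(match = .data$n_mismatch <= max_mismatch &
                    .data$n_shared >= min_shared_loci)
}
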