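#' Per-replicate PCR observation model
#'
#' Error process applied independently to every replicate amplification of a
#' sample x locus: the whole reaction fails with probability `fail_prob`; a
#' heterozygous replicate that amplified loses one uniformly chosen allele
#' with probability `ado_prob` (allelic dropout, producing a false
#' homozygote); a positive replicate gains a stutter-like false allele offset
#' one repeat unit from a true allele with probability `fa_prob`. The false
#' allele never coincides with a true allele of the genotype (a stutter peak
#' identical to a real allele is unobservable as an error) and is clipped to
#' the locus size range.
#'
#' @param fail_prob,ado_prob,fa_prob Probabilities in `[0, 1]`.
#' @param replicates Number of PCR replicates per sample x locus (>= 1);
#'   quadruplicate amplification is the default design.
#' @return An object of class `kiwi_error_model`.
#' @examples
#' error_model(fail_prob = 0.06, ado_prob = 0.2, fa_prob = 0.01)
#' @export
error_model <- function(fail_prob = 0, ado_prob = 0, fa_prob = 0,
                        replicates = 4L) {
  probs <- c(fail_prob = fail_prob, ado_prob = ado_prob, fa_prob = fa_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("Error-model probabilities must lie in [0, 1].")
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    abort("`replicates` must be a positive integer.")
  }
  structure(
    list(fail_prob = fail_prob, ado_prob = ado_prob, fa_prob = fa_prob,
         replicates = replicates),
    class = "kiwi_error_model"
  )
}

#' @export
print.kiwi_error_model <- function(x, ...) {
  cat(sprintf(
    "<kiwi_error_model> fail = %.3f, dropout = %.3f, false allele = %.3f, %d replicates\n",
    x$fail_prob, x$ado_prob, x$fa_prob, x$replicates
  ))
  invisible(x)
}

#' Simulate population allele frequencies
#'
#' Builds a population model over the autosomal loci of a panel. Every locus
#' gets a common allele support (sizes drawn from the locus ladder, shared
#' across populations so populations differ in frequency, not support) and
#' per-population frequency vectors drawn from a symmetric Dirichlet. Private
#' (population-specific) alleles are then injected: per requested private
#' allele a ladder size unused by any population at that locus is added with
#' frequency `private_freq` and the vector renormalized, so private alleles
#' appear in exactly one population's support.
#'
#' @param populations A data frame with columns `population`, `species` and
#'   optionally `lineage`, one row per population.
#' @param panel Panel tibble from [kiwi_panel()].
#' @param n_alleles Number of shared alleles per autosomal locus (>= 1).
#' @param concentration Dirichlet concentration; small values give skewed
#'   frequency vectors, large values near-even ones.
#' @param n_private Number of private alleles per population (scalar or named
#'   integer vector by population).
#' @param private_freq Frequency assigned to an injected private allele
#'   before renormalization.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `kiwi_popmodel`: a list with elements `panel`,
#'   `populations` and `freqs` (tibble `population`, `locus`, `allele`,
#'   `freq`).
#' @examples
#' pops <- tibble::tibble(population = c("NI", "LSK"),
#'                        species = c("mantelli", "owenii"))
#' model <- simulate_populations(pops, n_alleles = 4, n_private = 1, seed = 1)
#' dplyr::count(model$freqs, population)
#' @export
simulate_populations <- function(populations, panel = kiwi_panel(),
                                 n_alleles = 4L, concentration = 1,
                                 n_private = 0L, private_freq = 0.1,
                                 seed = NULL) {
  populations <- tibble::as_tibble(populations)
  if (!all(c("population", "species") %in% names(populations))) {
    abort("`populations` needs columns `population` and `species`.")
  }
  if (nrow(populations) < 1L) abort("At least one population is required.")
  if (!"lineage" %in% names(populations)) {
    populations$lineage <- NA_character_
  }
  n_alleles <- as.integer(n_alleles)
  if (is.na(n_alleles) || n_alleles < 1L) {
    abort("`n_alleles` must be at least 1 for every locus.")
  }
  validate_panel(panel)
  if (!is.null(seed)) set.seed(seed)

  pops <- populations$population
  n_priv <- resolve_per_population(n_private, pops, "n_private")
  auto <- panel[!panel$sex_linked, ]

  freqs <- purrr::map_dfr(auto$locus, function(loc) {
    ladder <- allele_ladder(panel, loc)
    if (length(ladder) < n_alleles) {
      abort(paste0("Locus ", loc, " ladder has fewer than ", n_alleles,
                   " sizes; shrink `n_alleles` or widen the range."))
    }
    support <- sort(sample(ladder, n_alleles))
    purrr::map_dfr(pops, function(p) {
      w <- rgamma_dirichlet(n_alleles, concentration)
      tibble::tibble(population = p, locus = loc, allele = support, freq = w)
    })
  })

  # inject private alleles, then renormalize the affected vectors
  for (p in pops) {
    k <- n_priv[[p]]
    if (k == 0L) next
    target_loci <- sample(auto$locus, k, replace = k > nrow(auto))
    for (loc in target_loci) {
      ladder <- allele_ladder(panel, loc)
      used <- unique(freqs$allele[freqs$locus == loc])
      free <- setdiff(ladder, used)
      if (length(free) == 0L) {
        abort(paste0("No unused allele sizes left at locus ", loc,
                     " for a private allele; widen the size range."))
      }
      new_allele <- if (length(free) == 1L) free else sample(free, 1L)
      sel <- freqs$population == p & freqs$locus == loc
      freqs$freq[sel] <- freqs$freq[sel] * (1 - private_freq)
      freqs <- dplyr::bind_rows(freqs, tibble::tibble(
        population = p, locus = loc, allele = new_allele, freq = private_freq
      ))
    }
  }

  freqs <- dplyr::arrange(freqs, .data$population, .data$locus, .data$allele)
  structure(
    list(panel = panel, populations = populations, freqs = freqs),
    class = "kiwi_popmodel"
  )
}

#' @export
print.kiwi_popmodel <- function(x, ...) {
  cat(sprintf("<kiwi_popmodel> %d populations x %d autosomal loci\n",
              nrow(x$populations), sum(!x$panel$sex_linked)))
  invisible(x)
}

resolve_per_population <- function(x, pops, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(setNames(rep(as.integer(x), length(pops)), pops))
  }
  if (!all(pops %in% names(x))) {
    abort(paste0("`", what, "` must be a scalar or named for every population."))
  }
  setNames(as.integer(x[pops]), pops)
}

rgamma_dirichlet <- function(n, concentration) {
  g <- stats::rgamma(n, shape = concentration, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

#' Simulate true multilocus genotypes
#'
#' Draws individuals from a population model. Autosomal genotypes follow
#' Hardy-Weinberg proportions with inbreeding: with probability `f` the two
#' alleles are identical by descent (one draw from the frequency vector),
#' otherwise two independent draws, giving P(AA) = p^2 + f p (1 - p) and
#' P(AB) = 2 p q (1 - f). Sex is assigned by `sex_ratio` (proportion female).
#' At the sex-linked locus females carry the 92 bp W fragment plus one Z
#' fragment from the species (and lineage) pool of [sex_marker_model()];
#' males carry two independent Z draws and never the W fragment.
#'
#' @param model A `kiwi_popmodel` from [simulate_populations()].
#' @param n Individuals per population (scalar or named vector).
#' @param sex_ratio Proportion of females.
#' @param inbreeding Per-population inbreeding coefficient f in `[0, 1]`
#'   (scalar or named vector), applied per locus independently.
#' @param sex_model Fragment-size model, default [sex_marker_model()].
#' @param seed Optional integer seed.
#' @return A genotype tibble: `sample_id`, `population`, `species`,
#'   `lineage`, `sex` ("F"/"M"), `locus`, `allele_a`, `allele_b`
#'   (allele_a <= allele_b).
#' @examples
#' pops <- tibble::tibble(population = "LSK", species = "owenii")
#' model <- simulate_populations(pops, n_alleles = 2, seed = 1)
#' truth <- simulate_individuals(model, n = 5, seed = 2)
#' @export
simulate_individuals <- function(model, n, sex_ratio = 0.5, inbreeding = 0,
                                 sex_model = sex_marker_model(), seed = NULL) {
  stopifnot(inherits(model, "kiwi_popmodel"))
  if (!is.null(seed)) set.seed(seed)
  pops <- model$populations$population
  n_by <- resolve_per_population(n, pops, "n")
  f_raw <- if (length(inbreeding) == 1L && is.null(names(inbreeding))) {
    setNames(rep(inbreeding, length(pops)), pops)
  } else {
    if (!all(pops %in% names(inbreeding))) {
      abort("`inbreeding` must be a scalar or named for every population.")
    }
    inbreeding[pops]
  }
  if (any(f_raw < 0 | f_raw > 1)) abort("`inbreeding` must lie in [0, 1].")
  sex_locus <- model$panel$locus[model$panel$sex_linked]

  purrr::map_dfr(seq_along(pops), function(i) {
    p <- pops[i]
    info <- model$populations[i, ]
    np <- n_by[[p]]
    if (np < 1L) return(tibble::tibble())
    ids <- sprintf("%s_%03d", p, seq_len(np))
    sexes <- ifelse(runif(np) < sex_ratio, "F", "M")
    f <- f_raw[[p]]

    pf <- model$freqs[model$freqs$population == p, ]
    auto <- purrr::map_dfr(unique(pf$locus), function(loc) {
      v <- pf[pf$locus == loc, ]
      a1 <- sample(v$allele, np, replace = TRUE, prob = v$freq)
      a2 <- sample(v$allele, np, replace = TRUE, prob = v$freq)
      ibd <- runif(np) < f
      a2[ibd] <- a1[ibd]
      tibble::tibble(
        sample_id = ids, locus = loc,
        allele_a = pmin(a1, a2), allele_b = pmax(a1, a2)
      )
    })

    zs <- z_pool(sex_model, info$species, info$lineage)
    w <- w_size_for(sex_model, info$species)
    z1 <- sample_with_one(zs, np)
    z2 <- sample_with_one(zs, np)
    sexrows <- tibble::tibble(
      sample_id = ids, locus = sex_locus,
      allele_a = ifelse(sexes == "F", pmin(w, z1), pmin(z1, z2)),
      allele_b = ifelse(sexes == "F", pmax(w, z1), pmax(z1, z2))
    )

    meta <- tibble::tibble(sample_id = ids, population = p,
                           species = info$species, lineage = info$lineage,
                           sex = sexes)
    dplyr::bind_rows(auto, sexrows) |>
      dplyr::left_join(meta, by = "sample_id") |>
      dplyr::select("sample_id", "population", "species", "lineage", "sex",
                    "locus", "allele_a", "allele_b") |>
      dplyr::arrange(.data$sample_id, .data$locus)
  })
}

sample_with_one <- function(x, n) {
  if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE)
}

#' Simulate replicated PCR amplifications
#'
#' Applies the per-replicate observation model of [error_model()] to every
#' sample x locus of a true genotype table, emitting the multi-tube replicate
#' evidence the consensus caller consumes. Dropout acts only on heterozygous
#' truth; false alleles stay within the locus size range. Generation order is
#' deterministic under a fixed seed (rows sorted by sample, locus,
#' replicate).
#'
#' @param truth Genotype tibble from [simulate_individuals()].
#' @param em A `kiwi_error_model`.
#' @param panel Panel tibble (for repeat units and size ranges).
#' @param seed Optional integer seed.
#' @return A replicate tibble: `sample_id`, `population`, `species`, `locus`,
#'   `replicate`, and `alleles`, a list-column of sorted integer fragment
#'   sizes (`integer(0)` = failed amplification).
#' @examples
#' pops <- tibble::tibble(population = "LSK", species = "owenii")
#' model <- simulate_populations(pops, n_alleles = 2, seed = 1)
#' truth <- simulate_individuals(model, n = 2, seed = 2)
#' reps <- simulate_replicates(truth, error_model(ado_prob = 0.2), seed = 3)
#' @export
simulate_replicates <- function(truth, em = error_model(),
                                panel = kiwi_panel(), seed = NULL) {
  stopifnot(inherits(em, "kiwi_error_model"))
  if (!is.null(seed)) set.seed(seed)

  grid <- truth |>
    dplyr::arrange(.data$sample_id, .data$locus) |>
    tidyr::expand_grid(replicate = seq_len(em$replicates)) |>
    dplyr::left_join(
      dplyr::select(panel, "locus", "repeat_unit", "size_min", "size_max"),
      by = "locus"
    )

  m <- nrow(grid)
  fails <- runif(m) < em$fail_prob
  het <- grid$allele_a != grid$allele_b
  drops <- het & (runif(m) < em$ado_prob)
  keep_a <- runif(m) < 0.5
  fa_hit <- !fails & (runif(m) < em$fa_prob)
  fa_pick <- runif(m)

  grid$alleles <- purrr::pmap(
    list(grid$allele_a, grid$allele_b, grid$repeat_unit,
         grid$size_min, grid$size_max,
         fails, drops, keep_a, fa_hit, fa_pick),
    function(a, b, unit, lo, hi, fail, drop, ka, fa, fp) {
      if (fail) return(integer(0))
      obs <- unique(c(a, b))
      if (drop) obs <- if (ka) a else b
      if (fa) {
        cand <- setdiff(unique(c(a - unit, a + unit, b - unit, b + unit)),
                        c(a, b))
        cand <- cand[cand >= lo & cand <= hi]
        if (length(cand) > 0L) {
          obs <- c(obs, cand[ceiling(fp * length(cand))])
        }
      }
      sort(as.integer(obs))
    }
  )

  grid |>
    dplyr::select("sample_id", "population", "species", "locus",
                  "replicate", "alleles")
}

#' Geometric dilution series
#'
#' @param high,low End concentrations (same units); `high > low > 0`.
#' @param n Number of dilutions.
#' @return Numeric vector of `n` concentrations from `high` down to `low`.
#' @examples
#' dilution_series(5, 0.002, 10)  # the ten qPCR standards
#' @export
dilution_series <- function(high = 5, low = 0.002, n = 10L) {
  if (low <= 0 || high <= low || n < 2L) {
    abort("Need high > low > 0 and n >= 2.")
  }
  exp(seq(log(high), log(low), length.out = n))
}

#' Simulate a qPCR run
#'
#' Generates standard, unknown, spiked-sample and positive-control wells with
#' Cq values on a log-linear standard curve:
#' `Cq = intercept + slope * log10(concentration) + noise + shift`. Standards
#' default to ten serial dilutions from 5 to 0.002 ng/ul run in triplicate.
#' When `shifts` is supplied, each named sample also receives spiked wells
#' (sample plus a 2.5 ng/ul standard spike, in duplicate) whose Cq carries
#' the sample's inhibition shift, alongside spike-only positive-control wells
#' in triplicate, matching the delta-Cq inhibition design.
#'
#' @param samples Data frame with `sample_id` and `concentration` (ng/ul) for
#'   unknown wells, or `NULL` for a standards-only run.
#' @param slope,intercept Standard-curve parameters; `slope < 0`
#'   (-3.3219 corresponds to perfect doubling chemistry).
#' @param noise_sd Gaussian Cq noise standard deviation.
#' @param shifts Named numeric vector of inhibition shifts (Cq cycles) per
#'   sample id; triggers the spiked/control design.
#' @param n_replicates Replicates per unknown well group.
#' @param standards Standard concentrations; `NULL` to omit standards.
#' @param n_standard_reps Replicates per standard.
#' @param spike_conc Spike concentration (ng/ul) for inhibition wells.
#' @param n_spike_reps,n_control_reps Replicates for spiked sample wells and
#'   positive-control wells.
#' @param fail_prob Probability a well fails (Cq recorded as `NA`).
#' @param seed Optional integer seed.
#' @return A qPCR tibble: `well`, `sample_id`, `role` (one of "standard",
#'   "unknown", "spiked_sample", "positive_control"), `concentration` (known,
#'   standards and controls only), `cq`.
#' @examples
#' plate <- simulate_qpcr(
#'   samples = tibble::tibble(sample_id = "f01", concentration = 0.01),
#'   seed = 1
#' )
#' @export
simulate_qpcr <- function(samples = NULL, slope = -log(10) / log(2),
                          intercept = 22, noise_sd = 0, shifts = NULL,
                          n_replicates = 3L,
                          standards = dilution_series(5, 0.002, 10L),
                          n_standard_reps = 3L, spike_conc = 2.5,
                          n_spike_reps = 2L, n_control_reps = 3L,
                          fail_prob = 0, seed = NULL) {
  if (slope >= 0) abort("Standard-curve `slope` must be negative.")
  if (!is.null(seed)) set.seed(seed)

  rows <- list()
  if (!is.null(standards)) {
    if (any(standards <= 0)) abort("Standard concentrations must be positive.")
    rows$standard <- tidyr::expand_grid(
      concentration = standards, rep = seq_len(n_standard_reps)
    ) |>
      dplyr::mutate(sample_id = NA_character_, role = "standard",
                    true_conc = .data$concentration, shift = 0)
  }
  if (!is.null(samples)) {
    samples <- tibble::as_tibble(samples)
    if (any(samples$concentration <= 0)) {
      abort("Sample concentrations must be positive.")
    }
    rows$unknown <- tidyr::expand_grid(
      samples, rep = seq_len(n_replicates)
    ) |>
      dplyr::mutate(role = "unknown", true_conc = .data$concentration,
                    concentration = NA_real_, shift = 0)
  }
  if (!is.null(shifts)) {
    if (is.null(names(shifts))) abort("`shifts` must be named by sample id.")
    sconc <- if (!is.null(samples)) {
      setNames(samples$concentration, samples$sample_id)[names(shifts)]
    } else {
      setNames(rep(0, length(shifts)), names(shifts))
    }
    sconc[is.na(sconc)] <- 0
    rows$spiked <- tidyr::expand_grid(
      sample_id = names(shifts), rep = seq_len(n_spike_reps)
    ) |>
      dplyr::mutate(role = "spiked_sample", concentration = NA_real_,
                    true_conc = spike_conc + sconc[.data$sample_id],
                    shift = shifts[.data$sample_id])
    rows$control <- tibble::tibble(
      sample_id = NA_character_, rep = seq_len(n_control_reps),
      role = "positive_control", concentration = spike_conc,
      true_conc = spike_conc, shift = 0
    )
  }
  plate <- dplyr::bind_rows(rows)
  if (nrow(plate) == 0L) abort("Nothing to simulate: no standards or samples.")

  m <- nrow(plate)
  cq <- unname(intercept + slope * log10(plate$true_conc) + plate$shift +
                 rnorm(m, sd = noise_sd))
  cq[runif(m) < fail_prob] <- NA_real_
  plate |>
    dplyr::mutate(well = sprintf("W%03d", dplyr::row_number()), cq = cq) |>
    dplyr::select("well", "sample_id", "role", "concentration", "cq")
}
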