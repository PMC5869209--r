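test_that("fragment evidence maps to the documented sex calls", {
  # W plus a Z fragment: female
  f <- sex_call(make_reps(list(c(92, 96), c(92, 96), 96, integer(0)),
                          locus = "Z37B", species = "mantelli"))
  expect_equal(f$call, "female")

  # four W-free positives with the species Z fragment: male
  m <- sex_call(make_reps(list(94, 94, 94, 94), locus = "Z37B",
                          species = "haastii"))
  expect_equal(m$call, "male")

  # a single W-free positive cannot exclude W dropout: ambiguous
  a <- sex_call(make_reps(list(96, integer(0), integer(0), integer(0)),
                          locus = "Z37B", species = "australis"))
  expect_equal(a$call, "ambiguous")

  # all replicates failed
  x <- sex_call(make_reps(list(integer(0), integer(0)), locus = "Z37B",
                          species = "rowi"))
  expect_equal(x$call, "failed")

  expect_error(
    sex_call(make_reps(list(92), locus = "Z37B", species = "moa")),
    "Unknown species"
  )
})

test_that("one W-bearing replicate suffices for a female call", {
  f <- sex_call(make_reps(list(96, 96, c(92, 96), 96), locus = "Z37B",
                          species = "mantelli"))
  expect_equal(f$call, "female")
  expect_equal(f$n_with_w, 1L)
})

test_that("out-of-pool and off-lineage fragments are annotated", {
  out <- sex_call(make_reps(list(c(92, 80), c(92, 80)), locus = "Z37B",
                            species = "rowi"))
  expect_match(out$note, "outside species pool")

  reps <- make_reps(list(c(92, 100), c(92, 100)), locus = "Z37B",
                    species = "mantelli")
  reps$lineage <- "Northland"
  lin <- sex_call(reps)
  expect_equal(lin$call, "female")
  expect_match(lin$note, "outside declared lineage")
})

test_that("error-free simulated data is sexed perfectly for every species", {
  pops <- tibble::tibble(
    population = c("NI", "TOK", "ROWI", "LSK", "GSK"),
    species = c("mantelli", "australis", "rowi", "owenii", "haastii")
  )
  model <- simulate_populations(pops, n_alleles = 3, seed = 41)
  truth <- simulate_individuals(model, n = 12, seed = 42)
  reps <- simulate_replicates(truth, error_model(), seed = 43)
  calls <- sex_call(reps)
  truth_sex <- dplyr::distinct(truth, sample_id, sex)
  joined <- dplyr::inner_join(calls, truth_sex, by = "sample_id")
  expect_equal(nrow(joined), 60L)
  expect_true(all(joined$call == ifelse(joined$sex == "F", "female", "male")))
})

test_that("female calls survive Z dropout; thin male support turns ambiguous", {
  # female with the Z fragment dropped in every positive is still female
  f <- sex_call(make_reps(list(92, 92, integer(0), integer(0)),
                          locus = "Z37B", species = "owenii"))
  expect_equal(f$call, "female")

  # male evidence below min_pos_male flips to ambiguous
  m1 <- sex_call(make_reps(list(94, integer(0), integer(0), integer(0)),
                           locus = "Z37B", species = "owenii"))
  expect_equal(m1$call, "ambiguous")
  m2 <- sex_call(make_reps(list(94, integer(0), integer(0), integer(0)),
                           locus = "Z37B", species = "owenii"),
                 min_pos_male = 1L)
  expect_equal(m2$call, "male")
})

test_that("identical genotypes match and single-locus differences do not", {
  panel <- kiwi_panel()
  gts <- setNames(
    lapply(seq_len(23), function(i) c(100 + 2 * i, 104 + 2 * i)),
    panel$locus
  )
  g <- dplyr::bind_rows(
    make_genotypes(list(a = gts, b = gts)),
    make_genotypes(list(ch = modifyList(gts, list(KMS1 = c(240, 240)))))
  )
  rep_ <- match_genotypes(g)
  ab <- dplyr::filter(rep_, sample_1 == "a", sample_2 == "b")
  expect_equal(ab$n_mismatch, 0)
  expect_equal(ab$n_shared, 23)
  expect_true(ab$match)
  ac <- dplyr::filter(rep_, sample_1 == "a", sample_2 == "ch")
  expect_equal(ac$n_mismatch, 1)
  expect_false(ac$match)
  # raising the mismatch allowance is monotone in matches
  m0 <- sum(match_genotypes(g, max_mismatch = 0)$match)
  m1 <- sum(match_genotypes(g, max_mismatch = 1)$match)
  expect_gte(m1, m0)
})

test_that("missing loci are skipped and untyped samples excluded", {
  g <- dplyr::bind_rows(
    make_genotypes(list(
      a = list(L1 = c(100, 104), L2 = c(200, 200)),
      b = list(L1 = c(100, 104), L2 = NULL),
      z = list(L1 = NULL, L2 = NULL)
    ))
  )
  expect_warning(rep_ <- match_genotypes(g), "zero typed loci")
  expect_false("z" %in% c(rep_$sample_1, rep_$sample_2))
  ab <- dplyr::filter(rep_, sample_1 == "a", sample_2 == "b")
  expect_equal(ab$n_shared, 1)
  expect_equal(ab$n_mismatch, 0)
  # pair-level scores do not depend on sample labelling
  g_swapped <- dplyr::mutate(g, sample_id = dplyr::recode(sample_id,
                                                          a = "b", b = "a"))
  expect_warning(rep_sw <- match_genotypes(g_swapped), "zero typed loci")
  expect_equal(
    dplyr::filter(rep_sw, sample_1 == "a", sample_2 == "b")$n_shared, 1
  )
})

test_that("observed match counts agree with PI-based expectation", {
  # two loci, each ~two equifrequent alleles: per-pair match prob ~ 0.375^2
  pops <- tibble::tibble(population = "A", species = "rowi")
  tiny <- panel_definition(c("L1", "L2", "Z37B"), c(2, 2, 2),
                           c(100, 200, 90), c(138, 238, 102),
                           c(FALSE, FALSE, TRUE))
  model <- simulate_populations(pops, panel = tiny, n_alleles = 2,
                                concentration = 1e6, seed = 51)
  n <- 400
  truth <- simulate_individuals(model, n = n, seed = 52)
  g <- dplyr::filter(truth_genotypes(truth), locus != "Z37B")
  freqs <- allele_frequencies(g)
  pis <- pi_by_locus(freqs)
  expected <- choose(n, 2) * prod(pis$pi)
  observed <- sum(match_genotypes(g, max_mismatch = 0)$match)
  # pairs share individuals, so allow a generous Monte Carlo band
  expect_lt(abs(observed - expected) / expected, 0.2)
})
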