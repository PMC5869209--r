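test_that("multi-tube rules call heterozygotes and homozygotes", {
  # {A,B},{A},{B},{A,B}: both alleles in >= 2 positives -> A/B
  het <- call_consensus(make_reps(list(c(100, 104), 100, 104, c(100, 104))))
  expect_equal(het$allele_a, 100L)
  expect_equal(het$allele_b, 104L)
  expect_equal(het$flag, "ok")

  # {A},{A},{A},{fail}: one allele in 3 positives -> A/A
  hom <- call_consensus(make_reps(list(100, 100, 100, integer(0))))
  expect_equal(hom$allele_a, 100L)
  expect_equal(hom$allele_b, 100L)
  expect_equal(hom$n_positive, 3L)

  # two positives of the same allele reach het_min but not hom_min -> missing
  low <- call_consensus(make_reps(list(100, 100, integer(0), integer(0))))
  expect_false(low$called)
  expect_equal(low$flag, "low_support")

  # all failed -> missing with the failed flag
  fail <- call_consensus(make_reps(list(integer(0), integer(0))))
  expect_equal(fail$flag, "failed")
})

test_that("three well-supported alleles yield a conflict, not an error", {
  reps <- make_reps(list(c(100, 104), c(100, 108), c(104, 108), c(100, 104)))
  out <- call_consensus(reps)
  expect_false(out$called)
  expect_equal(out$flag, "conflict")
})

test_that("a reference genotype overrides sparse replicate evidence", {
  reps <- make_reps(list(100, c(100, 104)))
  ref <- make_genotypes(list(s1 = list(L1 = c(100, 104))))
  out <- call_consensus(reps, reference = ref)
  expect_equal(out$allele_a, 100L)
  expect_equal(out$allele_b, 104L)
  expect_equal(out$source, "reference")
  # without the reference the same evidence is too thin
  expect_false(call_consensus(reps)$called)
})

test_that("QI scores full-genotype concordance per replicate", {
  # 4/4 concordant at every locus -> sample QI 1
  loci <- setNames(
    rep(list(list(c(100, 104), c(100, 104), c(100, 104), c(100, 104))), 3),
    c("L1", "L2", "L3")
  )
  reps <- make_sample_reps(loci)
  cons <- call_consensus(reps)
  qi <- quality_index(reps, cons)
  expect_true(all(qi$qi == 1))
  expect_equal(qi_by_sample(qi)$qi, 1)

  # a dropout replicate scores 0 even though its allele is in the consensus
  reps2 <- make_reps(list(c(100, 104), c(100, 104), 100, integer(0)))
  cons2 <- call_consensus(reps2)
  qi2 <- quality_index(reps2, cons2)
  expect_equal(qi2$qi, 0.5)
})

test_that("per-sample QI averages per-locus QI over 23 loci as expected", {
  panel <- kiwi_panel()
  perfect <- list(c(100, 104), c(100, 104), c(100, 104), c(100, 104))
  half <- list(c(100, 104), c(100, 104), 100, 104)
  loci <- setNames(c(rep(list(perfect), 22), list(half)), panel$locus)
  reps <- make_sample_reps(loci)
  cons <- call_consensus(reps)
  qi <- quality_index(reps, cons)
  expect_equal(qi_by_sample(qi)$qi, (22 + 0.5) / 23)
})

test_that("a locus with all replicates failed has QI 0", {
  loci <- list(
    L1 = list(c(100, 104), c(100, 104), c(100, 104), c(100, 104)),
    L2 = list(integer(0), integer(0), integer(0), integer(0))
  )
  reps <- make_sample_reps(loci)
  cons <- call_consensus(reps)
  qi <- quality_index(reps, cons)
  expect_equal(qi$qi[qi$locus == "L2"], 0)
  # the uncalled locus does not enter the per-sample mean
  expect_equal(qi_by_sample(qi)$qi, 1)
})

test_that("QI is undefined for a sample with no consensus anywhere", {
  reps <- make_reps(list(integer(0), integer(0), integer(0), integer(0)))
  qi <- quality_index(reps, call_consensus(reps))
  expect_true(is.na(qi_by_sample(qi)$qi))
})

test_that("error-rate definitions match hand-scored replicates", {
  # consensus A/B; reps {A},{A,B},{B},{fail}: ADO = 2/3 positives
  reps <- make_reps(list(100, c(100, 104), 104, integer(0)))
  er <- error_rates(reps, call_consensus(make_reps(
    list(c(100, 104), c(100, 104), 100, 104)
  )))
  expect_equal(glance(er)$ado_across_loci, 2 / 3)
  expect_equal(glance(er)$amplification_failure, 1 / 4)

  # consensus A/B; reps {A,B},{A,C},{fail},{B}: FA = 1/3
  reps_fa <- make_reps(list(c(100, 104), c(100, 108), integer(0), 104))
  cons <- call_consensus(make_reps(list(c(100, 104), c(100, 104),
                                        c(100, 104), c(100, 104))))
  er_fa <- error_rates(reps_fa, cons)
  expect_equal(glance(er_fa)$fa_across_loci, 1 / 3)
})

test_that("zero-error data gives exactly zero rates and QI 1", {
  sim <- sim_two_pops(n = 8, em = error_model())
  cons <- call_consensus(sim$reps)
  er <- glance(error_rates(sim$reps, cons))
  expect_equal(er$amplification_failure, 0)
  expect_equal(er$ado_across_loci, 0)
  expect_equal(er$fa_across_loci, 0)
  qi <- quality_index(sim$reps, cons)
  expect_true(all(qi_by_sample(qi)$qi == 1))
  # and consensus reproduces truth exactly
  joined <- dplyr::inner_join(
    dplyr::select(cons, sample_id, locus, ca = allele_a, cb = allele_b),
    sim$truth, by = c("sample_id", "locus")
  )
  expect_equal(joined$ca, joined$allele_a)
  expect_equal(joined$cb, joined$allele_b)
})

test_that("ADO is undefined (not zero) without heterozygous consensus", {
  reps <- make_reps(list(100, 100, 100, 100))
  er <- error_rates(reps, call_consensus(reps))
  expect_true(is.na(glance(er)$ado_across_loci))
})

test_that("reference-scored error rates recover simulation parameters", {
  sim <- sim_two_pops(n = 40, seed = 11,
                      em = error_model(fail_prob = 0.1, ado_prob = 0.25,
                                       fa_prob = 0.02))
  ref_cons <- call_consensus(sim$reps, reference = truth_genotypes(sim$truth))
  er <- error_rates(sim$reps, ref_cons)
  o <- glance(er)
  n_het_pos <- sum(er$by_locus$n_het_pos)
  n_def_pos <- sum(er$by_locus$n_def_pos)
  expect_lt(abs(o$ado_pooled - 0.25), 3 * sqrt(0.25 * 0.75 / n_het_pos))
  expect_lt(abs(o$fa_pooled - 0.02), 3 * sqrt(0.02 * 0.98 / n_def_pos))
  expect_lt(abs(o$amplification_failure - 0.1),
            3 * sqrt(0.1 * 0.9 / o$n_replicates))
})

test_that("sample filter drops samples failing more than two loci", {
  fail4 <- list(integer(0), integer(0), integer(0), integer(0))
  good <- list(c(100, 104), c(100, 104), c(100, 104), c(100, 104))
  reps <- dplyr::bind_rows(
    make_sample_reps(setNames(c(rep(list(good), 2), rep(list(fail4), 3)),
                              paste0("L", 1:5)), sample_id = "bad"),
    make_sample_reps(setNames(c(rep(list(good), 3), rep(list(fail4), 2)),
                              paste0("L", 1:5)), sample_id = "edge"),
    make_sample_reps(setNames(rep(list(good), 5), paste0("L", 1:5)),
                     sample_id = "clean")
  )
  cons <- call_consensus(reps)
  expect_message(out <- filter_samples(cons), "bad")
  expect_setequal(unique(out$sample_id), c("edge", "clean"))
  expect_equal(attr(out, "removed_samples"), "bad")

  # an already-complete table passes through unchanged
  clean <- dplyr::filter(cons, sample_id == "clean")
  expect_equal(nrow(filter_samples(clean)), nrow(clean))
})

test_that("success classification is boundary inclusive at QI 0.75", {
  qs <- tibble::tibble(
    sample_id = c("a", "b", "c"), population = "p", species = "mantelli",
    qi = c(0.88, 0.75, 0.74), n_loci_called = 23L
  )
  cl <- classify_success(qs)
  expect_equal(cl$success, c(TRUE, TRUE, FALSE))
  expect_equal(success_rate(qs)$success_rate, 2 / 3)
})

test_that("dropping the lowest-QI loci never lowers mean sample QI", {
  sim <- sim_two_pops(n = 25, seed = 21,
                      em = error_model(fail_prob = 0.15, ado_prob = 0.2,
                                       fa_prob = 0.01))
  cons <- call_consensus(sim$reps)
  qi <- quality_index(sim$reps, cons)
  locus_qi <- qi |>
    dplyr::group_by(locus) |>
    dplyr::summarise(qi = mean(qi), .groups = "drop")
  worst <- locus_qi$locus[order(locus_qi$qi)][1:5]
  full <- qi_summary(qi)$qi_mean
  reduced <- qi_summary(qi, exclude = worst)$qi_mean
  expect_gte(reduced, full)
})
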