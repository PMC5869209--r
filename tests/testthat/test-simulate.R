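test_that("population frequencies are normalized with disjoint private alleles", {
  pops <- tibble::tibble(population = c("A", "B"),
                         species = c("mantelli", "haastii"))
  model <- simulate_populations(pops, n_alleles = 3, n_private = 1, seed = 7)
  sums <- model$freqs |>
    dplyr::group_by(population, locus) |>
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_true(all(model$freqs$freq >= 0))

  # a private allele's support is restricted to exactly one population
  support <- model$freqs |>
    dplyr::filter(freq > 0) |>
    dplyr::group_by(locus, allele) |>
    dplyr::summarise(n_pops = dplyr::n_distinct(population),
                     .groups = "drop")
  expect_true(any(support$n_pops == 1))
  private <- dplyr::anti_join(
    dplyr::filter(model$freqs, population == "A", freq > 0),
    dplyr::filter(model$freqs, population == "B", freq > 0),
    by = c("locus", "allele")
  )
  expect_gte(nrow(private), 1L)
})

test_that("five-species design with published sample sizes flows through", {
  pops <- tibble::tibble(
    population = c("mantelli", "haastii", "owenii", "rowi", "australis"),
    species = c("mantelli", "haastii", "owenii", "rowi", "australis")
  )
  model <- simulate_populations(pops, n_alleles = 4, n_private = 2, seed = 1)
  n <- c(mantelli = 233, haastii = 9, owenii = 7, rowi = 3, australis = 74)
  truth <- simulate_individuals(model, n = n, seed = 2)
  counts <- truth |>
    dplyr::distinct(sample_id, population) |>
    dplyr::count(population)
  expect_equal(setNames(counts$n, counts$population)[names(n)], n)
  # per-population allele counts are computable downstream
  auto <- dplyr::filter(truth_genotypes(truth), locus != "Z37B")
  stats <- diversity_stats(allele_frequencies(auto), auto)
  expect_equal(nrow(stats), 5L)
  expect_true(all(stats$na >= 1))
})

test_that("zero-allele and over-budget private requests error", {
  pops <- tibble::tibble(population = "A", species = "rowi")
  expect_error(simulate_populations(pops, n_alleles = 0), "at least 1")
  tiny <- panel_definition(c("L1", "Z37B"), c(2, 2), c(100, 90), c(104, 102),
                           c(FALSE, TRUE))
  # 3 ladder sizes, all consumed by the shared support: no room for privates
  expect_error(
    simulate_populations(pops, panel = tiny, n_alleles = 3, n_private = 1,
                         seed = 1),
    "private allele"
  )
})

test_that("genotype sampling follows HWE with inbreeding", {
  pops <- tibble::tibble(population = "A", species = "rowi")
  tiny <- panel_definition(c("L1", "Z37B"), c(2, 2), c(100, 140), c(138, 152),
                           c(FALSE, TRUE))
  model <- simulate_populations(pops, panel = tiny, n_alleles = 2,
                                concentration = 1e6, seed = 5)
  # near-even frequencies by construction (huge concentration): p ~= q ~= 0.5
  p <- model$freqs$freq[1]
  expect_lt(abs(p - 0.5), 0.01)

  n <- 4000
  truth <- simulate_individuals(model, n = n, seed = 6)
  auto <- dplyr::filter(truth, locus == "L1")
  het <- mean(auto$allele_a != auto$allele_b)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(het - 0.5), 3 * se)

  # complete inbreeding removes autosomal heterozygotes entirely
  truth_f1 <- simulate_individuals(model, n = 200, inbreeding = 1, seed = 7)
  auto_f1 <- dplyr::filter(truth_f1, locus == "L1")
  expect_true(all(auto_f1$allele_a == auto_f1$allele_b))
})

test_that("sex-linked genotypes follow the species fragment model", {
  pops <- tibble::tibble(population = "LSK", species = "owenii")
  model <- simulate_populations(pops, n_alleles = 2, seed = 1)
  truth <- simulate_individuals(model, n = 60, sex_ratio = 0.5, seed = 2)
  sexed <- dplyr::filter(truth, locus == "Z37B")
  females <- dplyr::filter(sexed, sex == "F")
  males <- dplyr::filter(sexed, sex == "M")
  # little spotted kiwi females: W 92 plus the 94 Z fragment
  expect_true(all(females$allele_a == 92L & females$allele_b == 94L))
  # males never carry the W fragment
  expect_true(all(males$allele_a != 92L & males$allele_b != 92L))
  expect_true(all(c(males$allele_a, males$allele_b) == 94L))
})

test_that("unknown species for the sex-linked pool errors", {
  pops <- tibble::tibble(population = "X", species = "moa")
  model <- simulate_populations(pops, n_alleles = 2, seed = 1)
  expect_error(simulate_individuals(model, n = 2, seed = 1),
               "Unknown species")
})

test_that("error-free replicates reproduce truth exactly", {
  sim <- sim_two_pops(n = 5, em = error_model())
  joined <- dplyr::left_join(
    sim$reps, sim$truth, by = c("sample_id", "population", "species", "locus")
  )
  ok <- purrr::pmap_lgl(
    list(joined$alleles, joined$allele_a, joined$allele_b),
    function(s, a, b) setequal(s, unique(c(a, b)))
  )
  expect_true(all(ok))
})

test_that("certain failure empties every replicate", {
  sim <- sim_two_pops(n = 3, em = error_model(fail_prob = 1))
  expect_true(all(lengths(sim$reps$alleles) == 0L))
})

test_that("failure fraction converges to fail_prob", {
  sim <- sim_two_pops(n = 20, em = error_model(fail_prob = 0.25))
  m <- nrow(sim$reps)
  observed <- mean(lengths(sim$reps$alleles) == 0L)
  expect_lt(abs(observed - 0.25), 3 * sqrt(0.25 * 0.75 / m))
})

test_that("false alleles stay inside the locus size range and off the truth", {
  sim <- sim_two_pops(n = 20, em = error_model(fa_prob = 0.5))
  panel <- kiwi_panel()
  joined <- dplyr::left_join(sim$reps, sim$truth,
                             by = c("sample_id", "population", "species",
                                    "locus")) |>
    dplyr::left_join(dplyr::select(panel, locus, size_min, size_max),
                     by = "locus")
  ok <- purrr::pmap_lgl(
    list(joined$alleles, joined$size_min, joined$size_max),
    function(s, lo, hi) all(s >= lo & s <= hi)
  )
  expect_true(all(ok))
})

test_that("the same seed reproduces the simulation byte for byte", {
  a <- sim_two_pops(n = 6, seed = 99, em = error_model(0.1, 0.2, 0.02))
  b <- sim_two_pops(n = 6, seed = 99, em = error_model(0.1, 0.2, 0.02))
  expect_identical(a$model$freqs, b$model$freqs)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reps, b$reps)
})

test_that("error model rejects invalid parameters", {
  expect_error(error_model(fail_prob = -0.1), "\\[0, 1\\]")
  expect_error(error_model(ado_prob = 1.2), "\\[0, 1\\]")
  expect_error(error_model(replicates = 0), "positive")
})

test_that("noiseless qPCR wells sit exactly on the standard curve", {
  plate <- simulate_qpcr(
    samples = tibble::tibble(sample_id = "s1", concentration = 0.05),
    slope = -3.4, intercept = 21, noise_sd = 0, seed = 1
  )
  std <- dplyr::filter(plate, role == "standard")
  expect_equal(std$cq, 21 - 3.4 * log10(std$concentration), tolerance = 1e-12)
  expect_equal(nrow(dplyr::distinct(std, concentration)), 10L)
  # ten serial dilutions spanning 5 down to 0.002 ng/ul
  expect_equal(range(std$concentration), c(0.002, 5))
  unk <- dplyr::filter(plate, role == "unknown")
  expect_equal(unique(unk$cq), 21 - 3.4 * log10(0.05), tolerance = 1e-12)
})

test_that("inhibition shifts appear in spiked wells only", {
  plate <- simulate_qpcr(
    samples = tibble::tibble(sample_id = c("a", "b"),
                             concentration = c(0.01, 0.01)),
    noise_sd = 0, shifts = c(a = 5, b = 0), seed = 2
  )
  sp <- dplyr::filter(plate, role == "spiked_sample")
  ctrl <- dplyr::filter(plate, role == "positive_control")
  expect_equal(nrow(ctrl), 3L)
  d <- delta_cq(plate)
  expect_equal(d$delta_cq[d$sample_id == "a"], 5, tolerance = 0.02)
  expect_equal(d$delta_cq[d$sample_id == "b"], 0, tolerance = 0.02)
})

test_that("qPCR simulation rejects bad inputs", {
  expect_error(simulate_qpcr(
    samples = tibble::tibble(sample_id = "x", concentration = -1)
  ), "positive")
  expect_error(simulate_qpcr(slope = 1), "negative")
  expect_error(dilution_series(0.002, 5), "high > low")
})
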