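# Shared fixtures and independent oracles for the test suite.

# Build a replicate tibble from a list of integer vectors (one per replicate);
# integer(0) encodes a failed amplification.
make_reps <- function(sets, sample_id = "s1", locus = "L1",
                      population = "p1", species = "mantelli") {
  tibble::tibble(
    sample_id = sample_id, population = population, species = species,
    locus = locus, replicate = seq_along(sets),
    alleles = lapply(sets, function(v) sort(as.integer(v)))
  )
}

# Stack make_reps() calls for several loci of one sample.
make_sample_reps <- function(loci_sets, sample_id = "s1",
                             population = "p1", species = "mantelli") {
  dplyr::bind_rows(lapply(names(loci_sets), function(loc) {
    make_reps(loci_sets[[loc]], sample_id = sample_id, locus = loc,
              population = population, species = species)
  }))
}

# Genotype tibble from per-sample lists of c(a, b) pairs (NULL = missing).
make_genotypes <- function(samples, population = "p1", species = "mantelli") {
  dplyr::bind_rows(lapply(names(samples), function(id) {
    loci <- samples[[id]]
    dplyr::bind_rows(lapply(names(loci), function(loc) {
      g <- loci[[loc]]
      tibble::tibble(
        sample_id = id, population = population, species = species,
        locus = loc,
        allele_a = if (is.null(g)) NA_integer_ else as.integer(min(g)),
        allele_b = if (is.null(g)) NA_integer_ else as.integer(max(g))
      )
    }))
  }))
}

# All unordered single-locus genotypes with their HWE probabilities.
hwe_genotypes <- function(p) {
  k <- length(p)
  out <- list()
  for (i in seq_len(k)) {
    for (j in i:k) {
      out[[length(out) + 1L]] <- list(
        a = i, b = j,
        prob = if (i == j) p[i]^2 else 2 * p[i] * p[j]
      )
    }
  }
  out
}

# Enumeration oracle for PI: probability two independent HWE draws share a
# genotype.
enum_pi <- function(p) {
  sum(vapply(hwe_genotypes(p), function(g) g$prob^2, numeric(1)))
}

# Enumeration oracle for PIsibs: draw two HWE parents, form the Mendelian
# offspring genotype distribution (each parent transmits one allele
# uniformly), and sum squared sib-genotype probabilities over parental
# pairs. Genotypes are encoded as min * 1000 + max for speed.
enum_pisibs <- function(p) {
  gts <- hwe_genotypes(p)
  total <- 0
  for (gm in gts) {
    for (gf in gts) {
      am <- c(gm$a, gm$b, gm$a, gm$b)
      af <- c(gf$a, gf$a, gf$b, gf$b)
      keys <- pmin(am, af) * 1000 + pmax(am, af)
      r <- rle(sort(keys))
      total <- total + gm$prob * gf$prob * sum((r$lengths / 4)^2)
    }
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random frequency vector over k alleles.
random_freqs <- function(k) {
  x <- stats::runif(k)
  x / sum(x)
}

# Small multi-population simulation used by several suites.
sim_two_pops <- function(n = 15, seed = 42, n_alleles = 4, n_private = 1,
                         em = error_model()) {
  pops <- tibble::tibble(population = c("NI", "HA"),
                         species = c("mantelli", "haastii"))
  model <- simulate_populations(pops, n_alleles = n_alleles,
                                n_private = n_private, seed = seed)
  truth <- simulate_individuals(model, n = n, seed = seed + 1)
  reps <- simulate_replicates(truth, em, seed = seed + 2)
  list(model = model, truth = truth, reps = reps)
}

# Genotype tibble view of a simulated truth table (drops sex metadata).
truth_genotypes <- function(truth) {
  dplyr::select(truth, "sample_id", "population", "species", "locus",
                "allele_a", "allele_b")
}
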