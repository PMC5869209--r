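#' Run the monitoring pipeline end to end
#'
#' Orchestrates the full analysis from a configuration list (or YAML file):
#' simulate (or read) replicate genotyping evidence, call consensus
#' genotypes, compute QI and error rates, apply the failed-loci filter,
#' estimate diversity and probability-of-identity statistics, call sexes,
#' match genotypes, run the PCoA, and summarise a qPCR plate when one is
#' configured. Stage results are returned as a bundle and, when `out_dir`
#' is given, written as CSV tables alongside a run log recording the seed
#' and parameter values.
#'
#' Configuration keys (all optional unless noted):
#' * `seed` — integer seed for the whole run;
#' * `simulate` — list with `populations` (data frame / list of rows),
#'   `n_per_population` (alias `n`; note YAML 1.1 parses a bare `n:` key as
#'   a boolean), `sex_ratio`, `inbreeding`, `n_alleles`, `concentration`,
#'   `n_private`, and `error` (list: `fail_prob`, `ado_prob`, `fa_prob`,
#'   `replicates`); either this or `inputs` is required;
#' * `inputs` — list with `replicates` (path) and optionally `reference`
#'   (genotype CSV) and `qpcr` (plate CSV);
#' * `consensus` — `het_min`, `hom_min`;
#' * `filter` — `max_failed_loci`;
#' * `success` — `threshold`;
#' * `sex` — `min_pos_male`;
#' * `match` — `max_mismatch`, `min_shared_loci`;
#' * `qpcr` — simulation parameters when simulating a plate (`samples`,
#'   `slope`, `intercept`, `noise_sd`, `shifts`);
#' * `stages` — subset of `c("consensus", "errors", "divstats", "pi",
#'   "sex", "match", "pcoa", "qpcr")` to run (default all applicable).
#'
#' @param config A named list, or path to a YAML file with the same keys.
#' @param out_dir Optional output directory for CSV results and the run log.
#' @return A list of class `kiwi_run` with elements `truth` (simulation
#'   only), `replicates`, `consensus`, `qi`, `sample_qi`, `success`,
#'   `error_rates`, `filtered`, `genotypes`, `freqs`, `diversity`, `pi`,
#'   `cumulative_pi`, `sex_calls`, `matches`, `distance`, `pcoa`, `qpcr`,
#'   plus `config`.
#' @examples
#' cfg <- list(
#'   seed = 1,
#'   simulate = list(
#'     populations = data.frame(population = "LSK", species = "owenii"),
#'     n = 8, error = list(ado_prob = 0.1)
#'   )
#' )
#' run <- run_pipeline(cfg)
#' run$sample_qi
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  known_stages <- c("consensus", "errors", "divstats", "pi", "sex", "match",
                    "pcoa", "qpcr")
  stages <- config$stages %||% known_stages
  bad <- setdiff(stages, known_stages)
  if (length(bad) > 0L) {
    abort(paste0("Unknown pipeline stage(s): ", paste(bad, collapse = ", "),
                 ". Known: ", paste(known_stages, collapse = ", "), "."))
  }
  seed <- config$seed %||% 1L
  set.seed(seed)
  res <- list(config = config)
  log_lines <- c(
    paste0("kiwisat ", as.character(utils::packageVersion("kiwisat"))),
    paste0("R ", R.version.string),
    paste0("seed: ", seed),
    paste0("stages: ", paste(stages, collapse = ", "))
  )
  panel <- kiwi_panel()

  reference <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    pops <- tibble::as_tibble(sim$populations)
    model <- with_stage("simulate", simulate_populations(
      pops, panel = panel,
      n_alleles = sim$n_alleles %||% 4L,
      concentration = sim$concentration %||% 1,
      n_private = sim$n_private %||% 0L
    ))
    # YAML 1.1 reads a bare `n:` key as a boolean, so configs may use
    # `n_per_population` instead
    n_cfg <- sim$n_per_population %||% sim$n
    if (is.logical(n_cfg)) n_cfg <- NULL
    truth <- with_stage("simulate", simulate_individuals(
      model, n = n_cfg %||% 10L, sex_ratio = sim$sex_ratio %||% 0.5,
      inbreeding = sim$inbreeding %||% 0
    ))
    em <- do.call(error_model, sim$error %||% list())
    res$truth <- truth
    res$replicates <- with_stage("simulate",
                                 simulate_replicates(truth, em, panel))
    log_lines <- c(log_lines, paste0(
      "simulated: ", dplyr::n_distinct(truth$sample_id), " samples, error ",
      "model fail=", em$fail_prob, " ado=", em$ado_prob, " fa=", em$fa_prob,
      " R=", em$replicates
    ))
  } else if (!is.null(config$inputs)) {
    res$replicates <- with_stage("read",
                                 read_replicate_table(config$inputs$replicates))
    if (!is.null(config$inputs$reference)) {
      reference <- with_stage("read",
                              read_genotype_table(config$inputs$reference))
    }
  } else {
    abort("Config needs either `simulate` or `inputs`.")
  }

  cc <- config$consensus %||% list()
  res$consensus <- with_stage("consensus", call_consensus(
    res$replicates, het_min = cc$het_min %||% 2L,
    hom_min = cc$hom_min %||% 3L, reference = reference
  ))
  res$qi <- with_stage("consensus",
                       quality_index(res$replicates, res$consensus))
  res$sample_qi <- qi_by_sample(res$qi)
  res$success <- classify_success(
    res$sample_qi, threshold = (config$success %||% list())$threshold %||% 0.75
  )

  if ("errors" %in% stages) {
    res$error_rates <- with_stage("errors",
                                  error_rates(res$replicates, res$consensus))
  }

  res$filtered <- with_stage("filter", filter_samples(
    res$consensus,
    max_failed_loci = (config$filter %||% list())$max_failed_loci %||% 2L
  ))
  res$genotypes <- res$filtered |>
    dplyr::select("sample_id", "population", "species", "locus",
                  "allele_a", "allele_b")

  auto <- dplyr::filter(res$genotypes,
                        !.data$locus %in% panel$locus[panel$sex_linked])
  if (any(c("divstats", "pi") %in% stages) &&
      any(!is.na(auto$allele_a))) {
    res$freqs <- with_stage("divstats", allele_frequencies(res$genotypes))
    if ("divstats" %in% stages) {
      res$diversity <- with_stage("divstats", diversity_stats(
        allele_frequencies(auto), auto
      ))
    }
    if ("pi" %in% stages) {
      res$pi <- with_stage("pi", pi_by_locus(res$freqs))
      res$cumulative_pi <- with_stage("pi", cumulative_pi(res$pi))
    }
  }

  if ("sex" %in% stages) {
    res$sex_calls <- with_stage("sex", sex_call(
      res$replicates,
      min_pos_male = (config$sex %||% list())$min_pos_male %||% 2L
    ))
  }
  if ("match" %in% stages &&
      dplyr::n_distinct(res$genotypes$sample_id) >= 2L) {
    mc <- config$match %||% list()
    res$matches <- with_stage("match", match_genotypes(
      res$genotypes, max_mismatch = mc$max_mismatch %||% 0L,
      min_shared_loci = mc$min_shared_loci %||% 1L
    ))
  }
  if ("pcoa" %in% stages &&
      dplyr::n_distinct(res$genotypes$sample_id) >= 3L) {
    res$distance <- with_stage("pcoa",
                               genetic_distance(res$genotypes,
                                                scaling = "mean"))
    res$pcoa <- with_stage("pcoa", pcoa(res$distance))
  }

  if ("qpcr" %in% stages &&
      (!is.null(config$qpcr) || !is.null(config$inputs$qpcr))) {
    plate <- if (!is.null(config$inputs$qpcr)) {
      with_stage("qpcr", read_qpcr_table(config$inputs$qpcr))
    } else {
      qc <- config$qpcr
      with_stage("qpcr", simulate_qpcr(
        samples = if (!is.null(qc$samples)) tibble::as_tibble(qc$samples),
        slope = qc$slope %||% (-log(10) / log(2)),
        intercept = qc$intercept %||% 22,
        noise_sd = qc$noise_sd %||% 0,
        shifts = unlist(qc$shifts)
      ))
    }
    res$qpcr_plate <- plate
    curve <- with_stage("qpcr", fit_standard_curve(plate))
    res$qpcr <- list(
      curve = curve,
      concentrations = if (any(plate$role == "unknown")) {
        with_stage("qpcr", estimate_concentration(plate, curve))
      },
      inhibition = if (any(plate$role == "spiked_sample")) {
        with_stage("qpcr", delta_cq(plate))
      }
    )
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(res, out_dir, log_lines)
  }
  structure(res, class = "kiwi_run")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage `", stage, "` failed: ",
                 conditionMessage(e)))
  })
}

write_results <- function(res, out_dir, log_lines) {
  p <- function(f) file.path(out_dir, f)
  write_replicate_table(res$replicates, p("replicates.csv"))
  readr::write_csv(dplyr::select(res$consensus, -dplyr::any_of("alleles")),
                   p("consensus.csv"), na = "")
  readr::write_csv(res$qi, p("qi_by_locus.csv"), na = "")
  readr::write_csv(res$success, p("qi_by_sample.csv"), na = "")
  if (!is.null(res$error_rates)) {
    readr::write_csv(tidy(res$error_rates), p("error_rates.csv"), na = "")
    readr::write_csv(glance(res$error_rates), p("error_rates_overall.csv"),
                     na = "")
  }
  if (!is.null(res$diversity)) {
    readr::write_csv(res$diversity, p("diversity.csv"), na = "")
  }
  if (!is.null(res$cumulative_pi)) {
    readr::write_csv(res$cumulative_pi, p("cumulative_pi.csv"), na = "")
  }
  if (!is.null(res$sex_calls)) {
    readr::write_csv(res$sex_calls, p("sex_calls.csv"), na = "")
  }
  if (!is.null(res$matches)) {
    readr::write_csv(res$matches, p("matches.csv"), na = "")
  }
  if (!is.null(res$pcoa)) {
    readr::write_csv(res$pcoa$coordinates, p("pcoa_coordinates.csv"), na = "")
  }
  if (!is.null(res$qpcr)) {
    readr::write_csv(glance(res$qpcr$curve), p("qpcr_curve.csv"), na = "")
    if (!is.null(res$qpcr$inhibition)) {
      readr::write_csv(res$qpcr$inhibition, p("qpcr_inhibition.csv"), na = "")
    }
    if (!is.null(res$qpcr$concentrations)) {
      readr::write_csv(res$qpcr$concentrations, p("qpcr_concentrations.csv"),
                       na = "")
    }
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}

#' @export
print.kiwi_run <- function(x, ...) {
  cat("<kiwi_run>\n")
  cat("  samples:", dplyr::n_distinct(x$replicates$sample_id), "\n")
  cat("  stages computed:",
      paste(intersect(c("consensus", "qi", "error_rates", "diversity", "pi",
                        "sex_calls", "matches", "pcoa", "qpcr"),
                      names(x)[!purrr::map_lgl(x, is.null)]),
            collapse = ", "), "\n")
  invisible(x)
}
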