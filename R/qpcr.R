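#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq on log10(concentration) over the standard wells.
#' Amplification efficiency is `10^(-1/slope) - 1`; a slope of -3.3219
#' (perfect doubling per cycle) corresponds to efficiency 1. A warning is
#' issued when efficiency falls outside `[0.9, 1.1]`.
#'
#' @param standards A data frame with columns `concentration` and `cq`
#'   (rows with role `"standard"` are selected automatically when a `role`
#'   column is present; failed wells, `NA` Cq, are dropped).
#' @return An object of class `kiwi_std_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n` and the underlying `model`.
#' @examples
#' std <- tibble::tibble(concentration = c(5, 0.5, 0.05),
#'                       cq = c(20, 23.3219, 26.6439))
#' glance(fit_standard_curve(std))
#' @export
fit_standard_curve <- function(standards) {
  d <- tibble::as_tibble(standards)
  if ("role" %in% names(d)) d <- dplyr::filter(d, .data$role == "standard")
  d <- dplyr::filter(d, !is.na(.data$cq))
  if (length(unique(d$concentration)) < 3L) {
    abort("Need at least 3 distinct standard concentrations.")
  }
  if (any(d$concentration <= 0)) abort("Concentrations must be positive.")
  lx <- log10(d$concentration)
  if (var(lx) == 0) abort("Standards have zero variance in log10 concentration.")
  fit <- lm(cq ~ lx, data = tibble::tibble(cq = d$cq, lx = lx))
  slope <- unname(coef(fit)[2])
  if (slope >= 0) warn("Fitted slope is non-negative; curve is not usable.")
  efficiency <- 10^(-1 / slope) - 1
  if (is.finite(efficiency) && (efficiency < 0.9 || efficiency > 1.1)) {
    warn(sprintf("Amplification efficiency %.2f outside [0.9, 1.1].",
                 efficiency))
  }
  ss_tot <- sum((d$cq - mean(d$cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]), r_squared = r2,
         efficiency = efficiency, n = nrow(d), model = fit),
    class = "kiwi_std_curve"
  )
}

#' @export
print.kiwi_std_curve <- function(x, ...) {
  cat(sprintf(
    "<kiwi_std_curve> Cq = %.4f %+.4f log10(conc); R2 = %.4f, efficiency = %.3f\n",
    x$intercept, x$slope, x$r_squared, x$efficiency
  ))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `kiwi_std_curve` object.
#' @param ... Unused.
#' @export
tidy.kiwi_std_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @export
glance.kiwi_std_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, efficiency = x$efficiency,
                 n = x$n)
}

#' Estimate sample concentrations from a standard curve
#'
#' Replicate Cq values are averaged on the Cq scale, then back-transformed:
#' `conc = 10^((Cq - intercept)/slope) * dilution_factor`. The within-sample
#' spread is the standard deviation of the per-replicate back-transformed
#' concentrations. A sample whose replicates all failed is reported as
#' failed (`NA` concentration).
#'
#' @param data A data frame with `sample_id` and `cq` (one row per
#'   replicate well; rows with role `"unknown"` are selected automatically
#'   when a `role` column is present).
#' @param curve A `kiwi_std_curve`.
#' @param dilution_factor Multiplier applied to the back-transformed
#'   concentration (scalar or named per sample), for rerun dilutions.
#' @return A tibble: `sample_id`, `n_wells`, `n_positive`, `mean_cq`,
#'   `concentration`, `concentration_sd`, `failed`.
#' @export
estimate_concentration <- function(data, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "kiwi_std_curve"))
  d <- tibble::as_tibble(data)
  if ("role" %in% names(d)) d <- dplyr::filter(d, .data$role == "unknown")
  ids <- unique(d$sample_id)
  dil <- if (length(dilution_factor) == 1L && is.null(names(dilution_factor))) {
    setNames(rep(dilution_factor, length(ids)), ids)
  } else {
    out <- setNames(rep(1, length(ids)), ids)
    out[names(dilution_factor)] <- dilution_factor
    out
  }
  back <- function(cq) 10^((cq - curve$intercept) / curve$slope)
  d |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      n_positive = sum(!is.na(.data$cq)),
      mean_cq = ifelse(.data$n_positive > 0, mean(.data$cq, na.rm = TRUE),
                       NA_real_),
      concentration_sd = sd(back(.data$cq[!is.na(.data$cq)]) *
                              dil[[.data$sample_id[1]]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      concentration = back(.data$mean_cq) * unname(dil[.data$sample_id]),
      failed = .data$n_positive == 0L
    ) |>
    dplyr::select("sample_id", "n_wells", "n_positive", "mean_cq",
                  "concentration", "concentration_sd", "failed")
}

#' Delta-Cq PCR inhibition test
#'
#' Each sample's DNA extract is spiked with a fixed amount of standard and
#' compared against spike-only positive controls:
#' `delta_cq = mean(spiked sample Cq) - mean(positive control Cq)`. Samples
#' free of inhibitors score near or below zero; copurified PCR inhibitors
#' delay amplification and push delta-Cq positive. Failed wells are imputed
#' at `failure_cq` (default 45, the total number of cycles) before
#' averaging.
#'
#' @param plate qPCR tibble with roles `"spiked_sample"` and
#'   `"positive_control"` (see [simulate_qpcr()] / [read_qpcr_table()]).
#' @param failure_cq Cq imputed for failed wells.
#' @param threshold Inhibition call threshold: inhibited iff
#'   `delta_cq > threshold`.
#' @return A tibble: `sample_id`, `n_wells`, `n_failed`, `mean_cq`,
#'   `control_cq`, `delta_cq`, `inhibited`.
#' @examples
#' plate <- tibble::tibble(
#'   well = paste0("W", 1:5),
#'   sample_id = c("f1", "f1", NA, NA, NA),
#'   role = c("spiked_sample", "spiked_sample", rep("positive_control", 3)),
#'   concentration = c(NA, NA, 2.5, 2.5, 2.5),
#'   cq = c(30.5, 29.5, 28.8, 29.2, 29.0)
#' )
#' delta_cq(plate)  # delta_cq = 1, inhibited
#' @export
delta_cq <- function(plate, failure_cq = 45, threshold = 0) {
  ctrl <- dplyr::filter(plate, .data$role == "positive_control")
  spiked <- dplyr::filter(plate, .data$role == "spiked_sample")
  if (nrow(ctrl) == 0L) abort("No positive-control wells on the plate.")
  if (nrow(spiked) == 0L) abort("No spiked sample wells on the plate.")
  control_mean <- mean(dplyr::coalesce(ctrl$cq, failure_cq))
  spiked |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      n_failed = sum(is.na(.data$cq)),
      mean_cq = mean(dplyr::coalesce(.data$cq, failure_cq)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      control_cq = control_mean,
      delta_cq = .data$mean_cq - control_mean,
      inhibited = .data$delta_cq > threshold
    )
}

#' Target-to-total DNA ratio
#'
#' Host (target) DNA measured by the specific qPCR divided by total DNA
#' measured fluorometrically, as a percentage, reconciling the pg/ul and
#' ng/ul units. Rows with missing or non-positive total DNA get `NA` with
#' `ratio_defined = FALSE`.
#'
#' @param data A data frame with `target_pg_ul` (qPCR target concentration,
#'   pg/ul) and `total_ng_ul` (fluorometric total DNA, ng/ul).
#' @return The input with `ratio_pct` and `ratio_defined` columns.
#' @examples
#' target_to_total(tibble::tibble(sample_id = "f1", target_pg_ul = 9,
#'                                total_ng_ul = 1))  # 0.9%
#' @export
target_to_total <- function(data) {
  if (!all(c("target_pg_ul", "total_ng_ul") %in% names(data))) {
    abort("Need columns `target_pg_ul` and `total_ng_ul`.")
  }
  if (any(data$target_pg_ul < 0, na.rm = TRUE)) {
    abort("Target concentrations must be non-negative.")
  }
  data |>
    dplyr::mutate(
      ratio_defined = !is.na(.data$target_pg_ul) &
        !is.na(.data$total_ng_ul) & .data$total_ng_ul > 0,
      ratio_pct = ifelse(.data$ratio_defined,
                         100 * .data$target_pg_ul /
                           (1000 * .data$total_ng_ul), NA_real_)
    )
}
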