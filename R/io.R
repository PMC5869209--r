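#' Read and write replicate tables
#'
#' Replicate tables hold the raw multi-tube genotyping evidence: one row per
#' sample x locus x replicate, with the observed allele fragment sizes
#' encoded in the `alleles` column as a `;`-separated list of integers (an
#' empty field = failed amplification). Files are plain comma-delimited text
#' with one header line; `read_replicate_table(write_replicate_table(x))`
#' round-trips exactly.
#'
#' @param path File path.
#' @param n_replicates Optional declared replicate count; rows with replicate
#'   index outside `1..n_replicates` are rejected.
#' @return `read_replicate_table()` returns the replicate tibble with a
#'   list-column `alleles`; the writers return their input invisibly.
#' @export
read_replicate_table <- function(path, n_replicates = NULL) {
  df <- read_kiwi_csv(path, c("sample_id", "population", "species", "locus",
                              "replicate", "alleles"))
  df$replicate <- as.integer(df$replicate)
  df$alleles <- parse_allele_sets(df$alleles)
  dup <- duplicated(df[c("sample_id", "locus", "replicate")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf(
      "Duplicate (sample, locus, replicate) at row %d: %s / %s / %d.",
      i, df$sample_id[i], df$locus[i], df$replicate[i]
    ))
  }
  if (any(df$replicate < 1L)) abort("Replicate indices must be >= 1.")
  if (!is.null(n_replicates) && any(df$replicate > n_replicates)) {
    i <- which(df$replicate > n_replicates)[1]
    abort(sprintf("Row %d has replicate index %d but %d replicates declared.",
                  i, df$replicate[i], n_replicates))
  }
  bad <- !purrr::map_lgl(df$alleles, ~ all(.x > 0L))
  if (any(bad)) abort("Allele sizes must be positive integers.")
  tibble::as_tibble(df)
}

#' @rdname read_replicate_table
#' @param x Table to write.
#' @export
write_replicate_table <- function(x, path) {
  out <- x
  out$alleles <- format_allele_sets(x$alleles)
  readr::write_csv(out[c("sample_id", "population", "species", "locus",
                         "replicate", "alleles")], path, na = "")
  invisible(x)
}

#' Read and write genotype tables
#'
#' Genotype tables hold one called (or true, or reference) genotype per
#' sample x locus: columns `sample_id`, `population`, `species`, `locus`,
#' `allele_a`, `allele_b`. A missing genotype has both allele fields empty;
#' allele order is normalized to `allele_a <= allele_b` on read.
#'
#' @param path File path.
#' @return `read_genotype_table()` returns a genotype tibble; the writer
#'   returns its input invisibly.
#' @export
read_genotype_table <- function(path) {
  df <- read_kiwi_csv(path, c("sample_id", "population", "species", "locus",
                              "allele_a", "allele_b"),
                      optional = c("lineage", "sex"))
  df$allele_a <- as.integer(df$allele_a)
  df$allele_b <- as.integer(df$allele_b)
  half <- xor(is.na(df$allele_a), is.na(df$allele_b))
  if (any(half)) {
    abort(sprintf("Row %d has exactly one allele; a genotype is a pair or missing.",
                  which(half)[1]))
  }
  a <- pmin(df$allele_a, df$allele_b)
  b <- pmax(df$allele_a, df$allele_b)
  df$allele_a <- a
  df$allele_b <- b
  ok <- is.na(df$allele_a) | (df$allele_a > 0L & df$allele_b > 0L)
  if (!all(ok)) abort("Allele sizes must be positive integers.")
  dup <- duplicated(df[c("sample_id", "locus")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("Duplicate (sample, locus) at row %d: %s / %s.",
                  i, df$sample_id[i], df$locus[i]))
  }
  tibble::as_tibble(df)
}

#' @rdname read_genotype_table
#' @param x Table to write.
#' @export
write_genotype_table <- function(x, path) {
  cols <- intersect(c("sample_id", "population", "species", "lineage", "sex",
                      "locus", "allele_a", "allele_b"), names(x))
  readr::write_csv(x[cols], path, na = "")
  invisible(x)
}

#' Read and write qPCR plate tables
#'
#' Wells carry `well`, `sample_id`, `role` (standard / unknown /
#' spiked_sample / positive_control), `concentration` (required for
#' standards) and `cq` (empty = failed amplification).
#'
#' @param path File path.
#' @return `read_qpcr_table()` returns the plate tibble; the writer returns
#'   its input invisibly.
#' @export
read_qpcr_table <- function(path) {
  df <- read_kiwi_csv(path, c("well", "sample_id", "role", "concentration",
                              "cq"))
  roles <- c("standard", "unknown", "spiked_sample", "positive_control")
  if (!all(df$role %in% roles)) {
    abort(paste0("Unknown well role; expected one of: ",
                 paste(roles, collapse = ", "), "."))
  }
  df$concentration <- as.numeric(df$concentration)
  df$cq <- as.numeric(df$cq)
  std_na <- df$role == "standard" & is.na(df$concentration)
  if (any(std_na)) {
    abort(sprintf("Standard well at row %d is missing its concentration.",
                  which(std_na)[1]))
  }
  if (any(!is.na(df$cq) & df$cq <= 0)) abort("Cq values must be positive.")
  tibble::as_tibble(df)
}

#' @rdname read_qpcr_table
#' @param x Table to write.
#' @export
write_qpcr_table <- function(x, path) {
  readr::write_csv(x[c("well", "sample_id", "role", "concentration", "cq")],
                   path, na = "")
  invisible(x)
}

#' Export genotypes in GenAlEx layout
#'
#' Writes the two-columns-per-locus codominant layout (with the three GenAlEx
#' header lines) used for interoperability with fragment-analysis software.
#' Missing genotypes are written as 0.
#'
#' @param x Genotype tibble.
#' @param path File path.
#' @param title Dataset title placed on the second header line.
#' @return The input, invisibly.
#' @export
write_genalex <- function(x, path, title = "kiwisat export") {
  loci <- unique(x$locus)
  wide <- x |>
    dplyr::mutate(allele_a = dplyr::coalesce(.data$allele_a, 0L),
                  allele_b = dplyr::coalesce(.data$allele_b, 0L)) |>
    tidyr::pivot_wider(id_cols = c("sample_id", "population"),
                       names_from = "locus",
                       values_from = c("allele_a", "allele_b"),
                       values_fill = 0L)
  ord <- c("sample_id", "population",
           as.vector(rbind(paste0("allele_a_", loci), paste0("allele_b_", loci))))
  wide <- wide[ord]
  pops <- unique(wide$population)
  sizes <- as.integer(table(factor(wide$population, levels = pops)))
  lines <- c(
    paste(c(length(loci), nrow(wide), length(pops), sizes), collapse = ","),
    paste(c(title, "", "", pops), collapse = ","),
    paste(c("sample_id", "pop", as.vector(rbind(loci, rep("", length(loci))))),
          collapse = ",")
  )
  body <- do.call(paste, c(lapply(wide, as.character), list(sep = ",")))
  writeLines(c(lines, body), path)
  invisible(x)
}

# -- internals ---------------------------------------------------------------

read_kiwi_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = character(), progress = FALSE,
                        show_col_types = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed delimited file (possibly truncated): ", path))
  }
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra) > 0) {
    abort(paste0("Unknown column(s): ", paste(extra, collapse = ", "), "."))
  }
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", "), "."))
  }
  df[df == ""] <- NA
  df[c(required, intersect(optional, names(df)))]
}

parse_allele_sets <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || s == "") return(integer(0))
    v <- suppressWarnings(as.integer(strsplit(s, ";", fixed = TRUE)[[1]]))
    if (anyNA(v)) abort(paste0("Unparseable allele field: '", s, "'."))
    sort(v)
  })
}

format_allele_sets <- function(x) {
  purrr::map_chr(x, function(v) paste(sort(as.integer(v)), collapse = ";"))
}
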