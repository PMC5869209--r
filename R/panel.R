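#' Microsatellite panel definition
#'
#' The monitoring panel consists of 22 autosomal microsatellite loci plus the
#' EST-derived sex-linked locus Z37B, whose W and Z fragments differ in length
#' and permit ZW (female) versus ZZ (male) calls. `kiwi_panel()` returns the
#' built-in panel; `panel_definition()` builds a custom one with the same
#' validation. Locus names carrying the KMS/Aptowe/Apt prefixes follow the
#' published marker families; loci not individually characterised in print are
#' synthetic placeholders with realistic repeat units and size ranges
#' (amplicons span roughly 74-357 bp across the panel).
#'
#' @param loci Character vector of unique locus names.
#' @param repeat_unit Integer repeat unit (bp) per locus; allele sizes at a
#'   locus are this many base pairs apart.
#' @param size_min,size_max Integer allele-size bounds (bp) per locus.
#' @param sex_linked Logical vector flagging exactly one sex-linked locus.
#'
#' @return A tibble with columns `locus`, `sex_linked`, `repeat_unit`,
#'   `size_min`, `size_max`, one row per locus.
#' @examples
#' panel <- kiwi_panel()
#' panel[panel$sex_linked, ]
#' @export
kiwi_panel <- function() {
  autosomal <- tibble::tribble(
    ~locus,      ~repeat_unit, ~size_min, ~size_max,
    "KMS1",      2L,           240L,      280L,
    "KMS2",      2L,           100L,      140L,
    "KMS4",      4L,           150L,      198L,
    "KMS7R",     2L,           290L,      330L,
    "KMS10",     2L,           120L,      160L,
    "KMS11",     4L,           180L,      228L,
    "KMS14B",    2L,           250L,      290L,
    "KMS16A",    2L,           140L,      180L,
    "KMS18",     2L,           300L,      340L,
    "KMS21",     4L,           90L,       138L,
    "KMS25",     2L,           110L,      150L,
    "KMS30",     2L,           317L,      357L,
    "Aptowe5",   2L,           74L,       114L,
    "Aptowe11",  2L,           130L,      170L,
    "Aptowe16",  4L,           160L,      208L,
    "Aptowe21",  2L,           200L,      240L,
    "Aptowe28",  2L,           210L,      250L,
    "Aptowe29",  2L,           95L,       135L,
    "Aptowe33",  4L,           170L,      218L,
    "Apt22",     2L,           220L,      260L,
    "Apt41",     2L,           105L,      145L,
    "Apt57",     4L,           140L,      188L
  )
  panel_definition(
    loci = c(autosomal$locus, "Z37B"),
    repeat_unit = c(autosomal$repeat_unit, 2L),
    size_min = c(autosomal$size_min, 90L),
    size_max = c(autosomal$size_max, 102L),
    sex_linked = c(rep(FALSE, nrow(autosomal)), TRUE)
  )
}

#' @rdname kiwi_panel
#' @export
panel_definition <- function(loci, repeat_unit, size_min, size_max, sex_linked) {
  panel <- tibble::tibble(
    locus = as.character(loci),
    sex_linked = as.logical(sex_linked),
    repeat_unit = as.integer(repeat_unit),
    size_min = as.integer(size_min),
    size_max = as.integer(size_max)
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  if (anyDuplicated(panel$locus)) {
    abort("Panel locus names must be unique.")
  }
  if (sum(panel$sex_linked) != 1L) {
    abort("Panel must flag exactly one sex-linked locus.")
  }
  if (any(panel$size_min <= 0L) || any(panel$size_max <= panel$size_min)) {
    abort("Panel size ranges must be positive with size_min < size_max.")
  }
  if (any(panel$repeat_unit < 1L)) {
    abort("Panel repeat units must be positive integers.")
  }
  invisible(panel)
}

#' Allele ladder for a panel locus
#'
#' All allele sizes a locus can take: multiples of the repeat unit within the
#' declared size range.
#'
#' @param panel A panel tibble from [kiwi_panel()].
#' @param locus Locus name.
#' @return Integer vector of fragment sizes (bp).
#' @export
allele_ladder <- function(panel, locus) {
  row <- panel[panel$locus == locus, ]
  if (nrow(row) != 1L) abort(paste0("Unknown locus: ", locus))
  seq.int(row$size_min, row$size_max, by = row$repeat_unit)
}

#' Z37B fragment-size model for sex determination
#'
#' Fragment sizes of the sex-linked Z37B marker by species. All species share
#' the 92 bp W fragment; Z fragments are species specific (ZZ = male,
#' ZW = female). Some Z alleles are restricted to particular lineages: the
#' 98 bp allele of *A. mantelli* occurs only in the Western and Eastern
#' lineages, its 100 bp allele only in the Western lineage, and the 98 bp
#' allele of *A. australis* only in Fiordland.
#'
#' @return A tibble with columns `species`, `w_size`, `z_size`, `lineages`
#'   (comma-separated lineage restriction, `NA` = all lineages), one row per
#'   species x Z allele.
#' @examples
#' sex_marker_model()
#' @export
sex_marker_model <- function() {
  tibble::tribble(
    ~species,    ~w_size, ~z_size, ~lineages,
    "mantelli",  92L,     96L,     NA_character_,
    "mantelli",  92L,     98L,     "Western,Eastern",
    "mantelli",  92L,     100L,    "Western",
    "australis", 92L,     96L,     NA_character_,
    "australis", 92L,     98L,     "Fiordland",
    "rowi",      92L,     96L,     NA_character_,
    "owenii",    92L,     94L,     NA_character_,
    "haastii",   92L,     94L,     NA_character_
  )
}

# Z sizes available to one bird given species and (optional) lineage.
z_pool <- function(model, species, lineage = NA_character_) {
  rows <- model[model$species == species, ]
  if (nrow(rows) == 0L) {
    abort(paste0("Unknown species for sex-linked model: ", species))
  }
  keep <- is.na(rows$lineages)
  if (!is.na(lineage)) {
    keep <- keep | vapply(
      strsplit(rows$lineages, ","),
      function(x) lineage %in% x, logical(1)
    )
  }
  rows$z_size[keep]
}

w_size_for <- function(model, species) {
  rows <- model[model$species == species, ]
  if (nrow(rows) == 0L) {
    abort(paste0("Unknown species for sex-linked model: ", species))
  }
  unique(rows$w_size)
}
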