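#' Codominant genotypic distance
#'
#' Squared pairwise genetic distance for codominant data, computed per locus
#' as half the squared Euclidean distance between allele-count vectors
#' (counts 0/1/2 per allele). This reproduces the standard single-locus
#' values: identical genotypes 0; `ii` vs `ij` and `ij` vs `ik` 1; `ij` vs
#' `kl` 2; `ii` vs `jk` 3; `ii` vs `jj` 4. Per-pair totals sum over loci
#' typed in both samples; with `scaling = "mean"` the sum is rescaled by
#' (panel loci / shared loci), so pairs with missing loci stay comparable
#' (no genotype interpolation is attempted).
#'
#' @param genotypes Genotype tibble.
#' @param scaling `"sum"` (plain sum over shared loci) or `"mean"`
#'   (rescaled to the full panel).
#' @return An object of class `kiwi_gendist`: list with the symmetric
#'   squared-distance `matrix`, the `n_shared` loci matrix, `n_loci`, and
#'   `scaling`. [tidy()] returns the long pair table.
#' @examples
#' g <- tibble::tibble(
#'   sample_id = rep(c("a", "b"), each = 1), population = "p",
#'   species = "rowi", locus = "L1",
#'   allele_a = c(240L, 244L), allele_b = c(240L, 244L)
#' )
#' genetic_distance(g)$matrix  # AA vs BB -> 4
#' @export
genetic_distance <- function(genotypes, scaling = c("sum", "mean")) {
  scaling <- match.arg(scaling)
  typed <- dplyr::filter(genotypes, !is.na(.data$allele_a))
  ids <- sort(unique(genotypes$sample_id))
  n <- length(ids)
  if (n < 2L) abort("Need at least two samples.")
  loci <- unique(typed$locus)

  total <- matrix(0, n, n, dimnames = list(ids, ids))
  shared <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (loc in loci) {
    d <- typed[typed$locus == loc, ]
    alleles <- sort(unique(c(d$allele_a, d$allele_b)))
    counts <- matrix(0L, nrow(d), length(alleles),
                     dimnames = list(d$sample_id, alleles))
    ia <- cbind(seq_len(nrow(d)), match(d$allele_a, alleles))
    ib <- cbind(seq_len(nrow(d)), match(d$allele_b, alleles))
    counts[ia] <- counts[ia] + 1L
    counts[ib] <- counts[ib] + 1L
    dl <- 0.5 * as.matrix(stats::dist(counts))^2
    idx <- match(d$sample_id, ids)
    total[idx, idx] <- total[idx, idx] + dl
    shared[idx, idx] <- shared[idx, idx] + 1L
  }
  diag(shared) <- length(loci)

  off <- row(shared) != col(shared)
  if (any(shared[off] == 0L)) {
    abort("Some sample pairs share no typed locus; distance undefined.")
  }
  if (scaling == "mean") {
    total[off] <- total[off] * length(loci) / shared[off]
  }
  structure(
    list(matrix = total, n_shared = shared, n_loci = length(loci),
         scaling = scaling),
    class = "kiwi_gendist"
  )
}

#' @export
print.kiwi_gendist <- function(x, ...) {
  cat(sprintf("<kiwi_gendist> %d samples, %d loci, scaling = %s\n",
              nrow(x$matrix), x$n_loci, x$scaling))
  invisible(x)
}

#' @rdname genetic_distance
#' @param x A `kiwi_gendist` object.
#' @param ... Unused.
#' @export
tidy.kiwi_gendist <- function(x, ...) {
  ids <- rownames(x$matrix)
  pairs <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble::tibble(
    sample_1 = ids[pairs[, 1]], sample_2 = ids[pairs[, 2]],
    distance_sq = x$matrix[pairs], n_shared = x$n_shared[pairs]
  )
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a squared-distance matrix: Gower
#' double-centering of `-d^2/2`, symmetric eigendecomposition, and
#' coordinates given by eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Negative eigenvalues — possible because the
#' genotypic distance need not be Euclidean — are reported but their axes
#' dropped. Percent variance is relative to the sum of positive eigenvalues.
#'
#' @param x A `kiwi_gendist` object, or a symmetric matrix of *squared*
#'   distances with sample ids as dimnames.
#' @param n_axes Maximum number of axes to keep (default: all positive).
#' @return An object of class `kiwi_pcoa`: list with `coordinates` (tibble:
#'   `sample_id`, `axis_1`, `axis_2`, ...), `eigenvalues` (descending, the
#'   retained positive ones), `pct_variance`, and `negative_eigenvalues`.
#' @examples
#' g <- tidyr::expand_grid(sample_id = c("a", "b", "c"), locus = "L1") |>
#'   dplyr::mutate(population = "p", species = "rowi",
#'                 allele_a = c(240L, 242L, 244L),
#'                 allele_b = c(240L, 242L, 244L))
#' pcoa(genetic_distance(g))
#' @export
pcoa <- function(x, n_axes = NULL) {
  d2 <- if (inherits(x, "kiwi_gendist")) x$matrix else as.matrix(x)
  if (!isSymmetric(unname(d2), tol = 1e-8)) {
    abort("Distance matrix must be symmetric.")
  }
  ids <- rownames(d2) %||% paste0("s", seq_len(nrow(d2)))
  n <- nrow(d2)
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * ctr %*% d2 %*% ctr
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)

  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  neg <- eig$values[eig$values < -tol]
  if (!is.null(n_axes)) pos <- head(pos, n_axes)
  lambda <- eig$values[pos]
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda),
                                                      length(pos))
  colnames(coords) <- paste0("axis_", seq_along(pos))

  structure(
    list(
      coordinates = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                     tibble::as_tibble(coords)),
      eigenvalues = lambda,
      pct_variance = 100 * lambda / sum(eig$values[eig$values > tol]),
      negative_eigenvalues = neg
    ),
    class = "kiwi_pcoa"
  )
}

#' @export
print.kiwi_pcoa <- function(x, ...) {
  cat(sprintf("<kiwi_pcoa> %d samples, %d axes (axis 1: %.1f%%, axis 2: %.1f%%)\n",
              nrow(x$coordinates), length(x$eigenvalues),
              x$pct_variance[1],
              ifelse(length(x$pct_variance) > 1, x$pct_variance[2], NA)))
  invisible(x)
}

#' @rdname pcoa
#' @param matrix For `tidy()`: `"coordinates"` or `"eigenvalues"`.
#' @param ... Unused.
#' @export
tidy.kiwi_pcoa <- function(x, matrix = c("coordinates", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "coordinates") {
    tidyr::pivot_longer(x$coordinates, -"sample_id", names_to = "axis",
                        names_prefix = "axis_", names_transform = as.integer,
                        values_to = "coordinate")
  } else {
    tibble::tibble(axis = seq_along(x$eigenvalues),
                   eigenvalue = x$eigenvalues,
                   pct_variance = x$pct_variance)
  }
}

#' @rdname pcoa
#' @export
glance.kiwi_pcoa <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_axes = length(x$eigenvalues),
    pct_axis_1 = x$pct_variance[1],
    pct_axis_2 = ifelse(length(x$pct_variance) > 1, x$pct_variance[2],
                        NA_real_),
    n_negative_eigenvalues = length(x$negative_eigenvalues)
  )
}
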