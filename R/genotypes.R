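#' Genotype matrices and progeny arrays
#'
#' Codominant multilocus genotypes are stored as integer matrices with two
#' adjacent columns per locus (allele codes are abstract positive integers,
#' at most 999 so they fit the 3-digit GenePop encoding). A missing genotype
#' is `NA` in *both* columns of a locus; a half-missing pair is invalid.
#'
#' @name genotypes
#' @keywords internal
NULL

locus_cols <- function(l) c(2L * l - 1L, 2L * l)

#' Build a genotype matrix
#'
#' @param alleles integer vector or matrix of allele codes, length/ncol
#'   `2 * length(loci)`; `NA` pairs mark missing loci.
#' @param loci character vector of locus names.
#' @return integer matrix with `loci` attribute and paired columns.
#' @keywords internal
genotype_matrix <- function(alleles, loci) {
  g <- if (is.matrix(alleles)) alleles else matrix(alleles, nrow = 1L)
  storage.mode(g) <- "integer"
  if (ncol(g) != 2L * length(loci)) {
    stop("genotype matrix must have 2 columns per locus", call. = FALSE)
  }
  validate_allele_pairs(g)
  attr(g, "loci") <- as.character(loci)
  colnames(g) <- paste0(rep(loci, each = 2L), c(".a1", ".a2"))
  g
}

validate_allele_pairs <- function(g) {
  for (l in seq_len(ncol(g) / 2L)) {
    cc <- locus_cols(l)
    half <- xor(is.na(g[, cc[1L]]), is.na(g[, cc[2L]]))
    if (any(half)) {
      stop(sprintf("half-missing genotype at locus column %d, row %d: %s",
                   l, which(half)[1L],
                   "either both alleles present or the whole locus missing"),
           call. = FALSE)
    }
    ok <- stats::na.omit(c(g[, cc]))
    if (length(ok) && (any(ok < 1L) || any(ok > 999L))) {
      stop(sprintf("allele codes must be in 1..999 (locus column %d)", l),
           call. = FALSE)
    }
  }
  invisible(g)
}

geno_loci <- function(g) attr(g, "loci")

#' Construct a progeny array
#'
#' A progeny array is the open-pollinated offspring set of one maternal
#' plant: the unit from which the mixed-mating model infers the family
#' selfing rate.
#'
#' @param family family (maternal plant) identifier.
#' @param population population identifier.
#' @param offspring genotype matrix (see [genotype_matrix()]), one row per
#'   genotyped offspring.
#' @param loci character vector of locus names.
#' @param mother optional maternal multilocus genotype: integer vector of
#'   length `2 * length(loci)` (`NA` pairs allowed), or `NULL` when the
#'   mother was not genotyped and must be inferred.
#' @return object of class `progeny_array`.
#' @export
progeny_array <- function(family, population, offspring, loci, mother = NULL) {
  off <- genotype_matrix(offspring, loci)
  if (nrow(off) < 1L) stop("progeny array needs >= 1 offspring", call. = FALSE)
  if (!is.null(mother)) {
    mother <- as.integer(mother)
    if (length(mother) != 2L * length(loci)) {
      stop("maternal genotype length must be 2 * n_loci", call. = FALSE)
    }
    validate_allele_pairs(matrix(mother, nrow = 1L))
  }
  structure(
    list(family = as.character(family), population = as.character(population),
         offspring = off, loci = as.character(loci), mother = mother),
    class = "progeny_array"
  )
}

#' @export
print.progeny_array <- function(x, ...) {
  cat(sprintf("<progeny_array> family %s (pop %s): %d offspring x %d loci%s\n",
              x$family, x$population, nrow(x$offspring), length(x$loci),
              if (is.null(x$mother)) ", mother unknown" else ", mother known"))
  invisible(x)
}

#' @export
format.progeny_array <- function(x, ...) {
  sprintf("progeny_array(%s/%s, n=%d, L=%d)", x$population, x$family,
          nrow(x$offspring), length(x$loci))
}

# Allele codes observed at locus l across a genotype matrix (sorted, unique).
observed_alleles <- function(g, l) {
  sort(unique(stats::na.omit(c(g[, locus_cols(l)]))))
}
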