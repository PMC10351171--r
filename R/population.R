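## Population container: pedigree data.frame plus two haplotype matrices
## (individuals x loci, 0/1) aligned row-for-row with the pedigree, and the
## genome map the haplotypes are indexed by.

new_population <- function(ped, hap1, hap2, map) {
  stopifnot(nrow(ped) == nrow(hap1), nrow(ped) == nrow(hap2),
            ncol(hap1) == nrow(map), ncol(hap2) == nrow(map))
  obj <- list(ped = ped, hap1 = hap1, hap2 = hap2, map = map)
  class(obj) <- "population"
  obj
}

#' @export
print.population <- function(x, ...) {
  gens <- range(x$ped$generation)
  cat("population:", nrow(x$ped), "individuals, generations",
      gens[1], "to", gens[2], ";", ncol(x$hap1), "loci;",
      sum(x$ped$genotyped), "genotyped\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `population`
#' @return integer count
#' @export
n_individuals <- function(pop) nrow(pop$ped)

#' Extract a genotype dosage matrix (0/1/2)
#'
#' @param pop a `population`
#' @param ids individual ids (default: all genotyped animals)
#' @param loci locus ids to extract (default: all loci in the population's
#'   map); a `marker_panel` is also accepted
#' @return integer matrix, rownames = ids, colnames = locus ids
#' @export
genotype_matrix <- function(pop, ids = NULL, loci = NULL) {
  if (is.null(ids)) ids <- pop$ped$id[pop$ped$genotyped]
  if (inherits(loci, "marker_panel")) loci <- loci$locus_ids
  rows <- match(ids, pop$ped$id)
  if (anyNA(rows)) stop("unknown individual ids requested")
  if (is.null(loci)) {
    cols <- seq_len(ncol(pop$hap1))
    locus_ids <- pop$map$locus_id
  } else {
    cols <- match(loci, pop$map$locus_id)
    if (anyNA(cols)) stop("unknown locus ids requested")
    locus_ids <- loci
  }
  g <- pop$hap1[rows, cols, drop = FALSE] + pop$hap2[rows, cols, drop = FALSE]
  dimnames(g) <- list(ids, locus_ids)
  g
}

#' Allele frequencies of the "1" allele at each locus
#' @param pop a `population`
#' @param ids individuals over which to compute frequencies (default all)
#' @return numeric vector named by locus id
#' @export
allele_freqs <- function(pop, ids = NULL) {
  if (is.null(ids)) ids <- pop$ped$id
  rows <- match(ids, pop$ped$id)
  f <- (colSums(pop$hap1[rows, , drop = FALSE]) +
          colSums(pop$hap2[rows, , drop = FALSE])) / (2 * length(rows))
  names(f) <- pop$map$locus_id
  f
}

#' Construct a founder cohort directly (no historical phase)
#'
#' Draws haplotypes as independent Bernoulli alleles at the supplied
#' frequencies. Useful for tests and for design-count checks where only the
#' pedigree book-keeping of the recent phase matters.
#'
#' @param n number of founders
#' @param map a `genome_map`
#' @param freqs per-locus allele frequency (recycled; default 0.5)
#' @param seed integer seed
#' @return a `population` at generation 0, unrelated, sexes unassigned
#' @export
founder_population <- function(n, map, freqs = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map)
  freqs <- rep_len(freqs, m)
  h1 <- matrix(rbinom(n * m, 1L, rep(freqs, each = n)), n, m)
  h2 <- matrix(rbinom(n * m, 1L, rep(freqs, each = n)), n, m)
  ped <- data.frame(id = seq_len(n), sire = 0L, dam = 0L,
                    sex = NA_character_, generation = 0L,
                    genotyped = FALSE, stringsAsFactors = FALSE)
  new_population(ped, h1, h2, map)
}
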