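## Genomic relationship matrices and the eigen-dimensionality machinery:
## the number of largest eigenvalues of G explaining x% of its variance
## (EIGx) is used as a GWA discovery / prediction training sample size.

new_grm <- function(mat, kind, freqs = NULL) {
  attr(mat, "kind") <- kind
  attr(mat, "freqs") <- freqs
  class(mat) <- c("grm", class(mat))
  mat
}

#' Genomic relationship matrix, VanRaden method 1
#'
#' `G = MM' / (2 * sum(p_i (1 - p_i)))` with `M` the genotype matrix
#' centered by twice the allele frequency.
#'
#' @param genotypes dosage matrix (individuals x loci, 0/1/2)
#' @param freqs allele frequencies used for centering; computed from
#'   `genotypes` when omitted ("current" frequencies)
#' @return a `grm` (dense matrix with `kind` and `freqs` attributes)
#' @export
build_grm_vanraden <- function(genotypes, freqs = NULL) {
  if (is.null(freqs)) freqs <- colMeans(genotypes) / 2
  stopifnot(length(freqs) == ncol(genotypes))
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0)
    stop("all loci monomorphic at the centering frequencies: zero denominator")
  M <- sweep(genotypes, 2, 2 * freqs)
  G <- tcrossprod(M) / denom
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  new_grm(G, "VANRADEN1", freqs)
}

#' Genomic relationship matrix for the association scan
#'
#' Mean-centered cross-product averaged over loci,
#' `G = (1/n_s) * sum_i (x_i - 1 xbar_i)(x_i - 1 xbar_i)'`.
#'
#' @param genotypes dosage matrix (individuals x loci)
#' @return a `grm`
#' @export
build_grm_centered_scan <- function(genotypes) {
  ns <- ncol(genotypes)
  if (ns < 1) stop("need at least one locus")
  M <- scale(genotypes, center = TRUE, scale = FALSE)
  G <- tcrossprod(M) / ns
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  new_grm(G, "CENTERED_SCAN", colMeans(genotypes) / 2)
}

#' Eigenvalue profile of a relationship matrix
#'
#' Eigenvalues sorted in descending order with cumulative fractions of the
#' trace. Negative eigenvalues within numerical tolerance of zero are
#' clipped; asymmetry beyond tolerance is an error.
#'
#' @param grm a symmetric matrix (`grm` or plain)
#' @param tol relative tolerance for PSD clipping and the symmetry check,
#'   as a fraction of the trace
#' @return an `eigen_profile`: list with `values`, `trace`, `cumfrac`
#' @export
eigen_profile <- function(grm, tol = 1e-8) {
  if (!is.matrix(grm) || nrow(grm) != ncol(grm)) stop("grm must be square")
  scale_ref <- max(sum(diag(grm)), .Machine$double.eps)
  if (max(abs(grm - t(grm))) > tol * scale_ref)
    stop("matrix is not symmetric within tolerance")
  ev <- eigen((grm + t(grm)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * scale_ref)
    stop("matrix has a negative eigenvalue beyond tolerance: ", min(ev))
  ev <- pmax(ev, 0)
  ev <- sort(ev, decreasing = TRUE)
  tr <- sum(ev)
  profile <- list(values = ev, trace = tr,
                  cumfrac = if (tr > 0) cumsum(ev) / tr else rep(0, length(ev)))
  class(profile) <- "eigen_profile"
  profile
}

#' @export
print.eigen_profile <- function(x, ...) {
  cat("eigen_profile: n =", length(x$values), ", trace =",
      signif(x$trace, 6), "\n")
  for (p in c(50, 90, 95, 98, 99))
    cat(sprintf("  EIG%d = %d\n", p, n_eigen_for_pct(x, p)))
  invisible(x)
}

#' Number of largest eigenvalues explaining x percent of variance
#'
#' @param profile an [eigen_profile()]
#' @param x percentage in (0, 100]
#' @return smallest k such that the k largest eigenvalues sum to at least
#'   x% of the trace
#' @export
n_eigen_for_pct <- function(profile, x) {
  stopifnot(x > 0, x <= 100)
  ## at x = 100 this is the numerical rank, since zero eigenvalues add nothing
  which(profile$cumfrac >= x / 100 - .Machine$double.eps^0.5)[1]
}

#' Expected dimensionality from effective population size and genome length
#'
#' The number of independent chromosome segments is `Me = 4 Ne L` and the
#' eigenvalue counts behave as EIG90 ~ NeL, EIG95 ~ 2NeL, EIG98 ~ 4NeL.
#'
#' @param ne effective population size
#' @param L genome length in Morgans
#' @return named vector (eig90, eig95, eig98, me)
#' @export
predicted_dimensionality <- function(ne, L) {
  stopifnot(ne >= 0, L >= 0)
  c(eig90 = ne * L, eig95 = 2 * ne * L, eig98 = 4 * ne * L, me = 4 * ne * L)
}

#' Build discovery / training / test selection sets sized by EIGx
#'
#' The test set is the last genotyped generation; the remaining genotyped
#' animals are split at random into discovery and training pools of equal
#' size. Within each pool the EIGx set contains as many animals as the
#' number of largest eigenvalues explaining x% of the variance (from
#' `profile`, computed on the SNP-only GRM of all genotyped animals); sets
#' are nested, smaller levels contained in larger ones. `ALL` is the whole
#' pool.
#'
#' @param genotyped data.frame with columns `id` and `generation` for the
#'   genotyped animals
#' @param profile an [eigen_profile()] of the all-animals SNP GRM
#' @param x_levels percentages, e.g. `c(50, 60, 70, 80, 90, 95, 98, 99)`
#' @param scheme `"disjoint"` (discovery and training are different
#'   animals; the default, which showed less inflation) or `"same"`
#' @param seed integer seed
#' @param include_all also emit the `ALL` level (whole pool)
#' @return a `selection_sets`: list with `test` (ids), and `levels`, a named
#'   list of `list(label, n, discovery, training)`
#' @export
make_selection_sets <- function(genotyped, profile, x_levels,
                                scheme = c("disjoint", "same"),
                                seed = NULL, include_all = TRUE) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  last_gen <- max(genotyped$generation)
  test_ids <- genotyped$id[genotyped$generation == last_gen]
  pool <- genotyped$id[genotyped$generation != last_gen]
  pool <- pool[sample.int(length(pool))]
  half <- length(pool) %/% 2L
  disc_pool <- pool[seq_len(half)]
  train_pool <- if (scheme == "same") disc_pool else pool[half + seq_len(half)]
  levels <- list()
  for (x in sort(x_levels)) {
    k <- n_eigen_for_pct(profile, x)
    if (k > length(disc_pool) || k > length(train_pool))
      stop("EIG", x, " requires ", k, " animals but the pool has only ",
           min(length(disc_pool), length(train_pool)))
    lab <- paste0("EIG", x)
    ## nested by construction: first k of a fixed permutation
    levels[[lab]] <- list(label = lab, n = k,
                          discovery = disc_pool[seq_len(k)],
                          training = train_pool[seq_len(k)])
  }
  if (include_all) {
    levels[["ALL"]] <- list(label = "ALL", n = length(disc_pool),
                            discovery = disc_pool, training = train_pool)
  }
  out <- list(test = test_ids, levels = levels, scheme = scheme)
  class(out) <- "selection_sets"
  out
}

#' @export
print.selection_sets <- function(x, ...) {
  cat("selection_sets (", x$scheme, "): test =", length(x$test), "animals\n")
  for (lv in x$levels)
    cat(sprintf("  %-6s n = %d\n", lv$label, lv$n))
  invisible(x)
}
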