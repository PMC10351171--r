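# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite runs on one CPU in minutes.

# A genome map built directly from positions (bypassing the random placer)
manual_map <- function(pos, chr = rep(1L, length(pos)),
                       len = NULL, class = rep("SNP", length(pos)),
                       locus_id = seq_along(pos)) {
  if (is.null(len)) len <- vapply(split(pos, chr), function(p) max(p) + 0.1, 1)
  map <- data.frame(chr = as.integer(chr), pos = pos,
                    locus_id = as.integer(locus_id), class = class,
                    stringsAsFactors = FALSE)
  attr(map, "chrom_lengths") <- as.numeric(len)
  class(map) <- c("genome_map", "data.frame")
  map
}

# Small but structured population: short historical phase then a few recent
# generations. Cached per-session because several files reuse it.
small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function(n_sires = 8, key = paste0("s", n_sires)) {
  if (!is.null(small_sim_cache[[key]])) return(small_sim_cache[[key]])
  cfg <- sim_config(n_chromosomes = 2, genome_length = 2,
                    n_snp = 1200, n_qtn = 50,
                    hist_schedule = data.frame(generation = c(-60, -30, 0),
                                               size = c(100, 300, 200)),
                    n_sires = n_sires, n_dams = 80, n_generations = 10,
                    genotyped_generations = 8:10, pheno_generations = 1:10,
                    h2 = 0.9)
  sim <- simulate_population(cfg, seed = 2024)
  small_sim_cache[[key]] <- sim
  sim
}

# Hand-built selection_sets object (used where the random splitter would
# get in the way of an exact oracle)
manual_sets <- function(test, training, discovery = training, label = "ALL") {
  out <- list(test = test,
              levels = setNames(list(list(label = label, n = length(training),
                                          discovery = discovery,
                                          training = training)), label),
              scheme = "manual")
  class(out) <- "selection_sets"
  out
}

# Dense-REML restricted log-likelihood, independent of the eigen-based
# implementation (direct V inverse); oracle for reml_null
rll_dense <- function(y, G, delta) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- unclass(G) + diag(delta, n)
  Vi <- solve(V)
  XtVX <- crossprod(X, Vi %*% X)
  b <- solve(XtVX, crossprod(X, Vi %*% y))
  r <- y - X %*% b
  rss <- drop(crossprod(r, Vi %*% r))
  df <- n - 1
  drop(-0.5 * (df * log(rss / df) + determinant(V)$modulus +
                 log(det(XtVX)) + df * (1 + log(2 * pi))))
}

# Exact per-variant GLS (full Sigma inverse); oracle for assoc_scan
gls_scan_oracle <- function(y, genotypes, Sigma) {
  n <- length(y)
  Si <- solve(Sigma)
  vapply(seq_len(ncol(genotypes)), function(j) {
    Xj <- cbind(1, genotypes[, j])
    XtSX <- crossprod(Xj, Si %*% Xj)
    b <- solve(XtSX, crossprod(Xj, Si %*% y))
    r <- y - Xj %*% b
    s2 <- drop(crossprod(r, Si %*% r)) / (n - 2)
    se <- sqrt(s2 * solve(XtSX)[2, 2])
    2 * pt(abs(b[2] / se), n - 2, lower.tail = FALSE)
  }, 1.0)
}
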