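## Mixed-model association: EMMAX-style. The null model
##   y = 1 mu + u + e,  u ~ N(0, G sigma_u2),  e ~ N(0, I sigma_e2)
## is fitted once by REML through a single spectral decomposition of G and
## a 1-D profile-likelihood optimization of the variance ratio; the
## per-variant scan then treats Sigma = sigma_u2 G + sigma_e2 I as known
## and performs GLS for each variant.

#' REML variance components of the null mixed model
#'
#' Profiles the restricted likelihood over the ratio
#' `delta = sigma_e2 / sigma_u2` on the eigenbasis of the GRM, so the whole
#' fit needs one eigendecomposition and a 1-D optimization.
#'
#' @param y phenotype vector
#' @param grm relationship matrix for the animals in `y` (same order)
#' @param log10_bounds search bounds for log10(delta)
#' @param tol optimizer tolerance on log10(delta)
#' @return a `varcomp`: list with `sigma_u2`, `sigma_e2`, `h2`, `loglik`
#'   (restricted), `degenerate`/`boundary` flags, and the eigen
#'   decomposition (reused by [assoc_scan()])
#' @export
reml_null <- function(y, grm, log10_bounds = c(-6, 6), tol = 1e-8) {
  n <- length(y)
  stopifnot(nrow(grm) == n, ncol(grm) == n)
  ev <- eigen((grm + t(grm)) / 2, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  U <- ev$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  p <- 1L
  ## restricted log-likelihood profiled over sigma_u2, as a function of
  ## delta = sigma_e2 / sigma_u2
  rll <- function(log10_delta) {
    delta <- 10^log10_delta
    w <- d + delta
    xw <- xt / w
    xtx <- sum(xt * xw)
    bhat <- sum(xw * yt) / xtx
    r <- yt - xt * bhat
    rss <- sum(r^2 / w)
    df <- n - p
    -0.5 * (df * log(rss / df) + sum(log(w)) + log(xtx) +
              df * (1 + log(2 * pi)))
  }
  if (var(y) < .Machine$double.eps) {
    out <- list(sigma_u2 = 0, sigma_e2 = 0, h2 = NA_real_, loglik = Inf,
                degenerate = TRUE, boundary = TRUE,
                eigen = list(values = d, vectors = U))
    class(out) <- "varcomp"
    return(out)
  }
  opt <- optimize(rll, interval = log10_bounds, maximum = TRUE, tol = tol)
  ## guard against a local optimum on a flat profile: compare to bounds
  cand <- c(opt$maximum, log10_bounds)
  vals <- c(opt$objective, rll(log10_bounds[1]), rll(log10_bounds[2]))
  best <- cand[which.max(vals)]
  delta <- 10^best
  w <- d + delta
  xw <- xt / w
  xtx <- sum(xt * xw)
  bhat <- sum(xw * yt) / xtx
  rss <- sum((yt - xt * bhat)^2 / w)
  sigma_u2 <- rss / (n - p)
  sigma_e2 <- delta * sigma_u2
  boundary <- abs(best - log10_bounds[1]) < 1e-3 ||
    abs(best - log10_bounds[2]) < 1e-3
  out <- list(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
              h2 = sigma_u2 / (sigma_u2 + sigma_e2),
              loglik = max(vals), delta = delta,
              degenerate = FALSE, boundary = boundary,
              eigen = list(values = d, vectors = U))
  class(out) <- "varcomp"
  out
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("varcomp: sigma_u2 = %.4g, sigma_e2 = %.4g, h2 = %.3f%s\n",
              x$sigma_u2, x$sigma_e2, x$h2,
              if (isTRUE(x$boundary)) " (boundary)" else ""))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#' @param alpha family-wise error rate (0.05)
#' @param n_tests number of variants tested
#' @return p-value threshold `alpha / n_tests`
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' EMMAX association scan
#'
#' Per-variant generalized least squares with the covariance
#' `Sigma = sigma_u2 G + sigma_e2 I` held fixed at the null REML estimates.
#' Each variant's substitution effect is tested by a two-sided Wald t-test
#' with `n - 2` degrees of freedom. Monomorphic variants get `beta = 0`,
#' `p = 1`.
#'
#' @param y phenotype vector
#' @param genotypes dosage matrix (same animals as `y`, variants in columns
#'   named by locus id)
#' @param vc a `varcomp` from [reml_null()] on the same animals
#' @param map optional classified `genome_map` to annotate chr/pos/is_qtn
#' @param alpha family-wise error rate for the Bonferroni threshold
#' @return an `assoc_result` data.frame: locus_id, chr, pos, beta, se, p,
#'   is_qtn, significant; the threshold is kept as an attribute
#' @export
assoc_scan <- function(y, genotypes, vc, map = NULL, alpha = 0.05) {
  n <- length(y)
  stopifnot(nrow(genotypes) == n)
  d <- vc$eigen$values
  U <- vc$eigen$vectors
  w <- vc$sigma_u2 * d + vc$sigma_e2
  if (any(w <= 0)) stop("singular covariance: non-positive weights")
  sw <- 1 / sqrt(w)
  ys <- drop(crossprod(U, y)) * sw
  x0 <- drop(crossprod(U, rep(1, n))) * sw
  Xs <- crossprod(U, genotypes) * sw
  ## Frisch-Waugh: project out the rotated intercept
  x0n2 <- sum(x0^2)
  ry <- ys - x0 * (sum(x0 * ys) / x0n2)
  cx <- drop(crossprod(Xs, x0)) / x0n2
  Rx <- Xs - outer(x0, cx)
  sxx <- colSums(Rx^2)
  sxy <- drop(crossprod(Rx, ry))
  syy <- sum(ry^2)
  mono <- sxx < max(sxx, 1) * 1e-12
  beta <- ifelse(mono, 0, sxy / sxx)
  rss <- pmax(syy - beta^2 * sxx, 0)
  df <- n - 2L
  se <- ifelse(mono, NA_real_, sqrt(rss / df / sxx))
  tstat <- ifelse(mono, 0, beta / se)
  pval <- ifelse(mono, 1, 2 * pt(abs(tstat), df = df, lower.tail = FALSE))
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)
  ids <- as.integer(colnames(genotypes) %||% seq_len(ncol(genotypes)))
  if (!is.null(map)) {
    mi <- match(ids, map$locus_id)
    chr <- map$chr[mi]; pos <- map$pos[mi]
    is_qtn <- map$class[mi] == "QTN"
  } else {
    chr <- NA_integer_; pos <- NA_real_; is_qtn <- NA
  }
  thr <- bonferroni_threshold(alpha, ncol(genotypes))
  out <- data.frame(locus_id = ids, chr = chr, pos = pos,
                    beta = beta, se = se, p = pval,
                    is_qtn = is_qtn, significant = pval < thr,
                    monomorphic = mono)
  attr(out, "threshold") <- thr
  attr(out, "alpha") <- alpha
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Count significant QTN and SNP hits
#'
#' A QTN is counted as identified only when the QTN variant itself passes
#' the threshold (significant nearby SNPs do not count).
#'
#' @param assoc an `assoc_result` (with `is_qtn` annotated)
#' @return list with `n_significant_qtn`, `n_significant_snp`, and
#'   `qtn_ids` of the identified QTN
#' @export
classify_hits <- function(assoc) {
  if (all(is.na(assoc$is_qtn))) stop("assoc result lacks is_qtn annotation")
  sig <- assoc$significant
  list(n_significant_qtn = sum(sig & assoc$is_qtn, na.rm = TRUE),
       n_significant_snp = sum(sig & !assoc$is_qtn, na.rm = TRUE),
       qtn_ids = assoc$locus_id[sig & assoc$is_qtn])
}

#' Fraction of additive variance explained by one QTN
#'
#' `%Var = 2 p q beta^2 / sigma_u2`, using the true simulated effect and
#' the current allele frequency. Vectorized.
#'
#' @param p_freq allele frequency in (0, 1)
#' @param beta true QTN substitution effect
#' @param sigma_u2 total additive genetic variance of the scenario
#' @return fraction(s) of variance
#' @export
qtn_pct_var <- function(p_freq, beta, sigma_u2) {
  stopifnot(all(p_freq > 0 & p_freq < 1), sigma_u2 > 0)
  2 * p_freq * (1 - p_freq) * beta^2 / sigma_u2
}

#' Total variance explained by the identified QTN
#'
#' Sum of [qtn_pct_var()] over the QTN declared significant in a scan.
#'
#' @param hit_qtn_ids locus ids of identified QTN (e.g.
#'   `classify_hits(...)$qtn_ids`)
#' @param arch the `trait_arch` holding true effects
#' @param freqs named allele-frequency vector covering the QTN (frequencies
#'   of the discovery cohort)
#' @return total fraction of additive variance
#' @export
total_var_explained <- function(hit_qtn_ids, arch, freqs) {
  if (length(hit_qtn_ids) == 0) return(0)
  idx <- match(hit_qtn_ids, arch$qtn_ids)
  if (anyNA(idx)) stop("hit ids not found among the QTN")
  f <- freqs[as.character(hit_qtn_ids)]
  if (anyNA(f)) stop("frequencies missing for some identified QTN")
  keep <- f > 0 & f < 1  # QTN fixed in the cohort contribute nothing
  if (!any(keep)) return(0)
  sum(qtn_pct_var(f[keep], arch$beta[idx][keep], arch$sigma_u2))
}

#' Sample size needed to reach a target variance-explained level
#'
#' Fits a local-polynomial smoother (loess) of the variance explained on
#' the sample size, evaluates it on a dense grid, and inverts by linear
#' interpolation, returning the smallest sample size whose fitted value
#' reaches the target.
#'
#' @param n sample sizes of the observed curve (>= 4 points)
#' @param pct_var variance explained at each sample size
#' @param target_pct target level (same units as `pct_var`)
#' @param span,degree loess smoothing parameters
#' @param grid_size dense-grid resolution for inversion
#' @return estimated sample size (numeric)
#' @export
sample_size_for_var <- function(n, pct_var, target_pct,
                                span = 0.75, degree = 2, grid_size = 512) {
  stopifnot(length(n) == length(pct_var), length(n) >= 4)
  o <- order(n)
  n <- n[o]; pct_var <- pct_var[o]
  ## degrade gracefully on very short curves: a local fit needs at least
  ## degree + 2 points in its neighbourhood
  k <- ceiling(span * length(n))
  degraded <- k < degree + 2
  if (degraded) degree <- 1
  if (ceiling(span * length(n)) < degree + 2)
    span <- min(1, (degree + 2) / length(n))
  maybe_quiet <- if (degraded || length(n) < 8) suppressWarnings else identity
  fit <- maybe_quiet(loess(pct_var ~ n, span = span, degree = degree,
                           control = loess.control(surface = "direct")))
  grid <- seq(min(n), max(n), length.out = grid_size)
  fitted <- maybe_quiet(predict(fit, newdata = data.frame(n = grid)))
  if (target_pct > max(fitted, na.rm = TRUE))
    stop("target ", target_pct, " is above the fitted curve maximum (",
         signif(max(fitted, na.rm = TRUE), 4), ")")
  ok <- which(fitted >= target_pct)
  k <- ok[1]
  if (k == 1) return(grid[1])
  ## linear interpolation between the bracketing grid points
  approx(x = fitted[c(k - 1, k)], y = grid[c(k - 1, k)], xout = target_pct,
         ties = "ordered")$y
}
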