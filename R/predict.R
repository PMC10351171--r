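## Breeding-value estimation: pedigree BLUP and single-step GBLUP. The
## single-step H-inverse combines the pedigree numerator relationship
## matrix A with a blended genomic matrix G over the genotyped block:
##   Hinv = Ainv + [0 0; 0 Ginv - A22inv]

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Wright's relationships by the recursive tabular method, inbreeding
#' included. Unknown parents (0 or NA) are treated as unrelated base
#' animals.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`, topologically
#'   ordered (parents before offspring)
#' @return dense relationship matrix with ids as dimnames
#' @export
build_A <- function(ped) {
  n <- nrow(ped)
  ids <- ped$id
  if (anyDuplicated(ids)) stop("duplicated ids in pedigree")
  s <- match(ped$sire, ids, nomatch = 0L)
  d <- match(ped$dam, ids, nomatch = 0L)
  known_s <- !(is.na(ped$sire) | ped$sire == 0)
  known_d <- !(is.na(ped$dam) | ped$dam == 0)
  if (any(known_s & s == 0L) || any(known_d & d == 0L))
    stop("pedigree refers to parents that are not listed")
  bad <- which(s >= seq_len(n) & s > 0L | d >= seq_len(n) & d > 0L)
  if (length(bad))
    stop("pedigree not topologically ordered: individual ", ids[bad[1]],
         " listed before (or equal to) its parent")
  if (any(s > 0L & s == d))
    stop("selfed matings are not supported")
  A <- cpp_tabular_A(s, d)
  dimnames(A) <- list(ids, ids)
  A
}

#' Blend a genomic matrix with the pedigree submatrix
#'
#' `(1 - weight) * G + weight * A22`; the default 5% blend guarantees
#' invertibility of G.
#'
#' @param G genomic relationship matrix
#' @param A22 pedigree relationships of the same (ordered) animals
#' @param weight blending weight in `[0, 1]` (default 0.05)
#' @return blended matrix
#' @export
blend_G <- function(G, A22, weight = 0.05) {
  if (!all(dim(G) == dim(A22)))
    stop("G (", nrow(G), ") and A22 (", nrow(A22), ") dimensions differ")
  stopifnot(weight >= 0, weight <= 1)
  out <- (1 - weight) * unclass(G) + weight * A22
  dimnames(out) <- dimnames(G)
  out
}

#' Assemble the single-step H-inverse
#'
#' @param Ainv inverse of the full pedigree relationship matrix
#' @param Ginv inverse of the (blended) genomic matrix
#' @param A22inv inverse of the genotyped-block pedigree submatrix
#' @param genotyped_index positions of the genotyped animals within the
#'   pedigree ordering of `Ainv`
#' @return H-inverse matrix
#' @export
build_Hinv <- function(Ainv, Ginv, A22inv, genotyped_index) {
  ng <- length(genotyped_index)
  if (nrow(Ginv) != ng || nrow(A22inv) != ng)
    stop("Ginv/A22inv dimensions do not match the genotyped index")
  if (any(genotyped_index < 1 | genotyped_index > nrow(Ainv)))
    stop("genotyped_index out of range")
  H <- Ainv
  H[genotyped_index, genotyped_index] <-
    H[genotyped_index, genotyped_index] + Ginv - A22inv
  H
}

#' Solve the single-trait mixed-model equations
#'
#' `y = 1 mu + Z u + e` with `u ~ N(0, K sigma_u2)` for a relationship
#' matrix K given through its inverse. Solves
#' `[X'X X'Z; Z'X Z'Z + Kinv * lambda]` with `lambda = sigma_e2/sigma_u2`
#' and returns solutions for every animal in `Kinv`, including those
#' without records. The variances are taken as known (the simulated
#' values), not re-estimated.
#'
#' @param y named phenotype vector (names = animal ids of the records)
#' @param Kinv relationship inverse over all evaluation animals, with ids
#'   as dimnames
#' @param sigma_u2,sigma_e2 additive and residual variances
#' @return an `evaluation_result`: list with `mu`, `u` (named solutions),
#'   and the relative residual of the solved system
#' @export
solve_mme <- function(y, Kinv, sigma_u2, sigma_e2) {
  ids <- rownames(Kinv)
  if (is.null(ids)) stop("Kinv needs animal ids as dimnames")
  if (is.null(names(y))) stop("y must be named by animal id")
  ai <- match(names(y), ids)
  if (anyNA(ai)) stop("records for animals absent from Kinv")
  lambda <- sigma_e2 / sigma_u2
  q <- nrow(Kinv)
  nrec <- length(y)
  cnt <- tabulate(ai, nbins = q)
  ZtX <- cnt
  Zty_full <- numeric(q)
  tab <- rowsum(as.numeric(y), ai)
  Zty_full[as.integer(rownames(tab))] <- tab[, 1]
  C <- matrix(0, q + 1, q + 1)
  C[1, 1] <- nrec
  C[1, -1] <- ZtX
  C[-1, 1] <- ZtX
  C[-1, -1] <- diag(cnt, q) + lambda * Kinv
  rhs <- c(sum(y), Zty_full)
  sol <- solve(C, rhs)
  rel_res <- max(abs(C %*% sol - rhs)) / max(1, max(abs(rhs)))
  if (!all(is.finite(sol))) stop("non-finite MME solution")
  if (rel_res > 1e-8) stop("MME solve failed: relative residual ", rel_res)
  out <- list(mu = sol[1], u = setNames(sol[-1], ids), rel_residual = rel_res,
              lambda = lambda)
  class(out) <- "evaluation_result"
  out
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("evaluation_result:", length(x$u), "animals, mu =", signif(x$mu, 5),
      if (!is.null(x$model)) paste0(", model = ", x$model) else "", "\n")
  invisible(x)
}

#' Run one genomic-prediction scenario
#'
#' Builds the evaluation pedigree (the phenotyped generations), the
#' requested relationship structure (ssGBLUP H-inverse on a marker panel,
#' or pedigree-only for PBLUP), and solves the mixed-model equations with
#' the training phenotypes only. The genomic matrix covers the training
#' and test genotyped animals; VanRaden centering uses the training-cohort
#' allele frequencies.
#'
#' @param pop a `population`
#' @param phen phenotype table from [assign_phenotypes()]
#' @param panel a `marker_panel` (ignored for PBLUP)
#' @param sets a `selection_sets`
#' @param level which training level to use (e.g. `"EIG90"`, `"ALL"`)
#' @param model `"ssGBLUP"` or `"PBLUP"`
#' @param sigma_u2,sigma_e2 simulated variance components of the scenario
#' @param blend_weight blending weight for G (default 0.05)
#' @param eval_generations generations forming the evaluation pedigree
#'   (default: the generations with phenotype records)
#' @return an `evaluation_result` with extra fields `gebv` (named vector
#'   for the test set), `model`, `panel`, `level`
#' @export
run_prediction_scenario <- function(pop, phen, panel, sets,
                                    level = "ALL",
                                    model = c("ssGBLUP", "PBLUP"),
                                    sigma_u2, sigma_e2,
                                    blend_weight = 0.05,
                                    eval_generations = NULL) {
  model <- match.arg(model)
  lv <- sets$levels[[level]]
  if (is.null(lv)) stop("unknown training level ", level)
  train_ids <- lv$training
  test_ids <- sets$test
  if (length(intersect(train_ids, test_ids)))
    stop("training and test sets overlap")
  if (is.null(eval_generations))
    eval_generations <- sort(unique(phen$generation[!is.na(phen$phenotype)]))
  in_eval <- pop$ped$generation %in% eval_generations
  ped_eval <- pop$ped[in_eval, c("id", "sire", "dam"), drop = FALSE]
  ## parents outside the evaluation pedigree become unknown base animals
  ped_eval$sire[!(ped_eval$sire %in% ped_eval$id)] <- 0L
  ped_eval$dam[!(ped_eval$dam %in% ped_eval$id)] <- 0L
  if (!all(train_ids %in% ped_eval$id) || !all(test_ids %in% ped_eval$id))
    stop("training/test animals missing from the evaluation pedigree")
  A <- build_A(ped_eval)
  ids <- ped_eval$id
  if (model == "ssGBLUP") {
    geno_ids <- c(train_ids, test_ids)
    gm <- genotype_matrix(pop, geno_ids, panel)
    train_freqs <- colMeans(gm[as.character(train_ids), , drop = FALSE]) / 2
    poly <- train_freqs > 0 & train_freqs < 1
    if (!any(poly)) stop("no polymorphic panel loci in the training cohort")
    G <- build_grm_vanraden(gm[, poly, drop = FALSE], freqs = train_freqs[poly])
    gi <- match(geno_ids, ids)
    A22 <- A[gi, gi, drop = FALSE]
    Gb <- blend_G(G, A22, blend_weight)
    Kinv <- build_Hinv(chol2inv(chol(A)), solve(Gb), solve(A22), gi)
    dimnames(Kinv) <- dimnames(A)
  } else {
    Kinv <- chol2inv(chol(A))
    dimnames(Kinv) <- dimnames(A)
  }
  ytr <- phen$phenotype[match(train_ids, phen$id)]
  if (anyNA(ytr)) stop("training animals lack phenotypes")
  res <- solve_mme(setNames(ytr, train_ids), Kinv, sigma_u2, sigma_e2)
  res$gebv <- res$u[as.character(test_ids)]
  res$model <- model
  res$panel <- if (model == "ssGBLUP") panel$label else "PEDIGREE"
  res$level <- level
  res
}
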