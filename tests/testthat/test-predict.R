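test_that("tabular A matches hand computations", {
  ## unrelated founders
  ped0 <- data.frame(id = 1:4, sire = 0L, dam = 0L)
  expect_equal(build_A(ped0), diag(4), ignore_attr = TRUE)
  ## full sibs from unrelated parents
  ped <- data.frame(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 2))
  A <- build_A(ped)
  expect_equal(A[3, 4], 0.5)
  expect_equal(diag(A), rep(1, 4), ignore_attr = TRUE)
  expect_equal(A[1, 3], 0.5)
  ## offspring of related parents is inbred
  ped2 <- rbind(ped, data.frame(id = 5, sire = 3, dam = 4))
  expect_equal(build_A(ped2)[5, 5], 1.25)
  ## ordering and validation
  expect_error(build_A(data.frame(id = 1:2, sire = c(2, 0), dam = c(0, 0))),
               "topologically")
  expect_error(build_A(data.frame(id = 1:3, sire = c(0, 0, 2), dam = c(0, 0, 2))),
               "selfed")
  expect_error(build_A(data.frame(id = 1:2, sire = c(9, 0), dam = c(0, 0))),
               "not listed")
})

test_that("blending shifts the spectrum away from zero", {
  set.seed(3)
  v <- rnorm(6)
  G <- outer(v, v)  # singular
  expect_equal(blend_G(G, diag(6), weight = 0), G, ignore_attr = TRUE)
  expect_equal(blend_G(G, diag(6), weight = 1), diag(6), ignore_attr = TRUE)
  Gb <- blend_G(G, diag(6), weight = 0.05)
  expect_gte(min(eigen(Gb, symmetric = TRUE, only.values = TRUE)$values),
             0.05 - 1e-12)
  expect_error(blend_G(G, diag(5)), "dimensions")
})

test_that("H-inverse assembly matches the dense joint-distribution oracle", {
  ## 5-animal pedigree, animals 3-5 genotyped
  ped <- data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3), dam = c(0, 0, 2, 2, 4))
  A <- build_A(ped)
  gi <- 3:5
  A22 <- A[gi, gi]
  set.seed(8)
  M <- matrix(rnorm(9), 3)
  G <- A22 + 0.3 * crossprod(M) / 3  # PD genomic matrix for the same animals
  Hinv <- build_Hinv(solve(A), solve(G), solve(A22), gi)
  ## literature identity for H itself, inverted densely
  A11 <- A[1:2, 1:2]; A12 <- A[1:2, gi]
  A22i <- solve(A22)
  H <- rbind(
    cbind(A11 + A12 %*% A22i %*% (G - A22) %*% A22i %*% t(A12),
          A12 %*% A22i %*% G),
    cbind(G %*% A22i %*% t(A12), G))
  expect_lt(max(abs(Hinv - solve(H))), 1e-8)
  expect_lt(max(abs(Hinv - t(Hinv))), 1e-10)
  ## trivial cases
  expect_equal(build_Hinv(solve(A), solve(A22), solve(A22), gi), solve(A),
               ignore_attr = TRUE)
  empty <- matrix(0, 0, 0)
  expect_equal(build_Hinv(solve(A), empty, empty, integer(0)), solve(A),
               ignore_attr = TRUE)
  expect_error(build_Hinv(solve(A), solve(G), solve(A22), 2:5), "dimensions|index")
})

test_that("MME solutions match the closed-form ridge when Kinv = I", {
  set.seed(12)
  n <- 30
  y <- setNames(rnorm(n, 5), 1:n)
  K <- diag(n); dimnames(K) <- list(1:n, 1:n)
  s_u <- 0.4; s_e <- 0.6
  sol <- solve_mme(y, K, s_u, s_e)
  expect_equal(sol$mu, mean(y))
  expect_equal(unname(sol$u), unname((y - mean(y)) * s_u / (s_u + s_e)))
  ## extreme shrinkage
  sol0 <- solve_mme(y, K, 1e-9, 1)
  expect_lt(max(abs(sol0$u)), 1e-6)
  ## only the variance ratio matters
  sol2 <- solve_mme(y, K, 2 * s_u, 2 * s_e)
  expect_equal(sol$u, sol2$u)
})

test_that("prediction scenarios run and reduce to GBLUP when all are genotyped", {
  sim <- small_sim()
  pop <- sim$pop; phen <- sim$phen
  cfg <- sim$config
  last <- max(pop$ped$generation)
  test_ids <- pop$ped$id[pop$ped$generation == last]
  train_ids <- pop$ped$id[pop$ped$generation %in% (last - 2):(last - 1)]
  sets <- manual_sets(test_ids, train_ids)
  chip <- build_chip_panel(sim$map, 10)
  ## restrict the evaluation pedigree to the genotyped generations only:
  ## then H-inverse collapses to the inverse of blended G (GBLUP)
  ev <- run_prediction_scenario(pop, phen, chip, sets, "ALL", "ssGBLUP",
                                sigma_u2 = cfg$sigma_u2, sigma_e2 = cfg$sigma_e2,
                                eval_generations = (last - 2):last)
  gm <- genotype_matrix(pop, c(train_ids, test_ids), chip)
  fr <- colMeans(gm[as.character(train_ids), ]) / 2
  poly <- fr > 0 & fr < 1
  G <- build_grm_vanraden(gm[, poly], freqs = fr[poly])
  ped_eval <- pop$ped[pop$ped$generation %in% (last - 2):last, c("id", "sire", "dam")]
  ped_eval$sire[!(ped_eval$sire %in% ped_eval$id)] <- 0L
  ped_eval$dam[!(ped_eval$dam %in% ped_eval$id)] <- 0L
  A <- build_A(ped_eval)
  gi <- match(c(train_ids, test_ids), ped_eval$id)
  Gb <- blend_G(G, A[gi, gi])
  Kinv <- solve(Gb)
  dimnames(Kinv) <- list(c(train_ids, test_ids), c(train_ids, test_ids))
  y <- setNames(phen$phenotype[match(train_ids, phen$id)], train_ids)
  direct <- solve_mme(y, Kinv, cfg$sigma_u2, cfg$sigma_e2)
  expect_lt(max(abs(ev$gebv - direct$u[as.character(test_ids)])), 1e-6)
  ## PBLUP path runs on the same sets
  evp <- run_prediction_scenario(pop, phen, chip, sets, "ALL", "PBLUP",
                                 sigma_u2 = cfg$sigma_u2, sigma_e2 = cfg$sigma_e2,
                                 eval_generations = (last - 2):last)
  expect_length(evp$gebv, length(test_ids))
  expect_false(identical(ev$gebv, evp$gebv))
  ## overlap between training and test is rejected
  bad <- manual_sets(test_ids, c(test_ids[1], train_ids))
  expect_error(run_prediction_scenario(pop, phen, chip, bad, "ALL", "ssGBLUP",
                                       sigma_u2 = 0.9, sigma_e2 = 0.1),
               "overlap")
})

test_that("an empty SIG augmentation changes nothing", {
  sim <- small_sim()
  pop <- sim$pop; phen <- sim$phen; cfg <- sim$config
  last <- max(pop$ped$generation)
  sets <- manual_sets(pop$ped$id[pop$ped$generation == last],
                      pop$ped$id[pop$ped$generation == last - 1])
  chip <- build_chip_panel(sim$map, 10)
  assoc <- data.frame(locus_id = sim$map$locus_id, chr = sim$map$chr,
                      pos = sim$map$pos, beta = 0, se = 1, p = 1,
                      is_qtn = sim$map$class == "QTN", significant = FALSE)
  sig <- augment_panel(chip, assoc, "SIG")
  args <- list(pop, phen, sets = sets, level = "ALL", model = "ssGBLUP",
               sigma_u2 = cfg$sigma_u2, sigma_e2 = cfg$sigma_e2,
               eval_generations = (last - 1):last)
  e1 <- do.call(run_prediction_scenario, c(list(panel = chip), args))
  e2 <- do.call(run_prediction_scenario, c(list(panel = sig), args))
  expect_equal(e1$gebv, e2$gebv)
})
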