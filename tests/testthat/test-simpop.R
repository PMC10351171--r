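test_that("sim_config validates and scales", {
  expect_error(sim_config(maf_min = 0.6), "maf_min")
  expect_error(sim_config(h2 = 0), "h2")
  expect_error(sim_config(hist_schedule = data.frame(generation = c(0, -10),
                                                     size = c(10, 10))),
               "increasing")
  cfg <- sim_config(scale_factor = 0.01)
  expect_equal(cfg$n_dams, 150L)
  expect_equal(cfg$n_snp, 5000L)
  expect_lt(max(cfg$hist_schedule$size), 501)
  ## h2 doubles as the additive variance when varP = 1
  expect_equal(cfg$sigma_u2 + cfg$sigma_e2, 1)
})

test_that("single-anchor schedule returns the founder draw unchanged", {
  cfg <- sim_config(n_chromosomes = 1, genome_length = 1, n_snp = 50, n_qtn = 2,
                    mutation_rate = 0, locus_surplus = 1,
                    hist_schedule = data.frame(generation = 0, size = 40),
                    n_sires = 2, n_dams = 5)
  pop <- simulate_historical(cfg, seed = 1)
  expect_equal(nrow(pop$ped), 40)
  set.seed(1)
  map2 <- make_genome_map(cfg)
  h1 <- matrix(rbinom(40 * nrow(map2), 1L, 0.5), 40)
  expect_equal(pop$hap1, h1)  # no drift generations were applied
})

test_that("one generation of drift preserves allele frequencies in expectation", {
  cfg <- sim_config(n_chromosomes = 1, genome_length = 1, n_snp = 300, n_qtn = 2,
                    mutation_rate = 0, locus_surplus = 1,
                    hist_schedule = data.frame(generation = c(-1, 0),
                                               size = c(120, 120)),
                    n_sires = 2, n_dams = 5)
  deltas <- vapply(1:50, function(r) {
    pop <- simulate_historical(cfg, seed = 5000 + r)
    mean(allele_freqs(pop)) - 0.5
  }, 1.0)
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 1e-12)
})

test_that("heterozygosity decays like Wright-Fisher", {
  N <- 60; t <- 30
  cfg <- sim_config(n_chromosomes = 1, genome_length = 1, n_snp = 250, n_qtn = 2,
                    mutation_rate = 0, locus_surplus = 1,
                    hist_schedule = data.frame(generation = c(-t, 0),
                                               size = c(N, N)),
                    n_sires = 2, n_dams = 5)
  hets <- vapply(1:12, function(r) {
    f <- allele_freqs(simulate_historical(cfg, seed = 300 + r))
    mean(2 * f * (1 - f))
  }, 1.0)
  ## founder draw loses one factor, each generation another
  expected <- 0.5 * (1 - 1 / (2 * N))^(t + 1)
  se <- sd(hets) / sqrt(length(hets))
  expect_lt(abs(mean(hets) - expected), 3 * se)
})

test_that("recent population has the designed pedigree structure", {
  sim <- small_sim()
  pop <- sim$pop
  cfg <- sim$config
  expect_equal(nrow(pop$ped),
               cfg$n_sires + cfg$n_dams + cfg$n_generations * cfg$n_dams)
  ## topological order: parents always listed before offspring
  off <- pop$ped$sire > 0
  expect_true(all(pop$ped$sire[off] < pop$ped$id[off]))
  expect_true(all(pop$ped$dam[off] < pop$ped$id[off]))
  par_gen <- pop$ped$generation[match(pop$ped$sire[off], pop$ped$id)]
  expect_true(all(par_gen < pop$ped$generation[off]))
  ## genotyping flags: one cohort of n_dams per genotyped generation
  expect_equal(sum(pop$ped$genotyped),
               length(cfg$genotyped_generations) * cfg$n_dams)
  ## sire replacement actually happened: more distinct sires used than slots
  expect_gt(length(unique(pop$ped$sire[off])), cfg$n_sires)
  ## every genotyped animal has complete haplotypes
  expect_false(anyNA(pop$hap1[pop$ped$genotyped, ]))
})

test_that("gamete trivial cases behave", {
  map0 <- manual_map(c(0.2, 0.4), len = 0)  # zero-length chromosome
  h <- list(c(1L, 0L), c(0L, 1L))
  g <- recombine_gamete(h, map0, seed = 3)
  expect_true(identical(g, h[[1]]) || identical(g, h[[2]]))
  ## identical parental haplotypes pass through untouched
  map1 <- manual_map(seq(0.1, 0.9, by = 0.1), len = 1)
  hh <- rep(list(rep(1L, 9)), 2)
  expect_equal(recombine_gamete(hh, map1, seed = 4), rep(1L, 9))
})

test_that("recombinant fraction follows the Haldane map function", {
  d <- 0.25
  map <- manual_map(c(0.05, 0.05 + d), len = 1)
  h <- list(c(0L, 0L), c(1L, 1L))
  set.seed(99)
  n <- 2e4
  rec <- mean(vapply(seq_len(n), function(i) {
    g <- recombine_gamete(h, map)
    g[1] != g[2]
  }, TRUE))
  chal <- 0.5 * (1 - exp(-2 * d))
  expect_lt(abs(rec - chal), 3 * sqrt(chal * (1 - chal) / n))
})

test_that("MAF filter is strict and honours targets", {
  map <- manual_map(c(0.1, 0.2, 0.3), len = 1)
  pop <- founder_population(50, map, seed = 1)
  ## force exact allele counts 4, 5, 6 out of 100
  for (j in 1:3) { pop$hap1[, j] <- 0L; pop$hap2[, j] <- 0L }
  pop$hap1[1:4, 1] <- 1L
  pop$hap1[1:5, 2] <- 1L
  pop$hap1[1:6, 3] <- 1L
  kept <- filter_segregating_maf(pop, maf_min = 0.05)
  expect_equal(kept$locus_id, 3L)  # 0.05 itself is excluded
  ## maf_min = 0 keeps all segregating loci
  expect_equal(filter_segregating_maf(pop, maf_min = 0)$locus_id, 1:3)
  ## all loci fixed -> nothing survives; targets then error
  for (j in 1:3) pop$hap1[, j] <- 0L
  expect_equal(nrow(filter_segregating_maf(pop, 0.05)), 0)
  expect_error(filter_segregating_maf(pop, 0.05, n_snp = 1, n_qtn = 1),
               "segregate")
  ## class counts match targets on a real population
  sim <- small_sim()
  expect_equal(as.vector(table(sim$map$class)[c("SNP", "QTN")]),
               c(sim$config$n_snp, sim$config$n_qtn))
  expect_false(is.unsorted(sim$map$pos[sim$map$chr == 1], strictly = TRUE))
})

test_that("QTN effects are rescaled to the target variance exactly", {
  map <- manual_map(seq(0.1, 1, 0.1), len = 1.2, class = rep("QTN", 10))
  pop <- founder_population(400, map, freqs = 0.4, seed = 8)
  fg <- genotype_matrix(pop, pop$ped$id, 1:10)
  for (s2 in c(0.3, 0.9, 0.99)) {
    arch <- sample_qtn_effects(fg, sigma_u2 = s2, seed = 11)
    expect_equal(var(drop(fg %*% arch$beta)), s2, tolerance = 1e-10)
  }
  ## single QTN with equifrequent genotype classes: |beta| -> sqrt(3 s2 / 2)
  fg1 <- matrix(rep(0:2, each = 2000), ncol = 1, dimnames = list(NULL, "1"))
  arch1 <- sample_qtn_effects(fg1, sigma_u2 = 0.3, seed = 5)
  expect_equal(abs(arch1$beta), sqrt(3 * 0.3 / 2), tolerance = 1e-3)
  ## monomorphic QTN cannot be scaled
  fg0 <- matrix(1L, 50, 2, dimnames = list(NULL, c("1", "2")))
  expect_error(sample_qtn_effects(fg0, 0.3, seed = 1), "monomorphic")
})

test_that("phenotypes follow mean + TBV + residual with the right variances", {
  sim <- small_sim()
  phen <- sim$phen
  has <- !is.na(phen$phenotype)
  expect_true(all(phen$generation[has] %in% sim$config$pheno_generations))
  expect_equal(phen$phenotype[has],
               sim$arch$mu + phen$tbv[has] + phen$residual[has])
  ## variance addition: var(y) ~ var(tbv) + sigma_e2 among phenotyped animals
  n <- sum(has)
  vy <- var(phen$phenotype[has])
  expected <- var(phen$tbv[has]) + sim$config$sigma_e2
  expect_lt(abs(vy - expected), 3 * expected * sqrt(2 / n) + 0.02)
  ## h2 = 1 limit: phenotype - mu equals TBV exactly
  arch1 <- sim$arch; arch1$sigma_u2 <- 1
  ph1 <- assign_phenotypes(arch1, sim$pop, seed = 1, var_p = 1)
  ok <- !is.na(ph1$phenotype)
  expect_equal(ph1$phenotype[ok] - arch1$mu, ph1$tbv[ok])
  ## sigma_u2 beyond varP is impossible
  arch2 <- sim$arch; arch2$sigma_u2 <- 1.2
  expect_error(assign_phenotypes(arch2, sim$pop, seed = 1), "exceeds")
})

test_that("simulate_recent rejects infeasible designs", {
  map <- manual_map(c(0.1, 0.5), len = 1)
  founders <- founder_population(10, map, seed = 1)
  cfg <- sim_config(n_chromosomes = 1, genome_length = 1, n_snp = 2, n_qtn = 2,
                    n_sires = 8, n_dams = 10, n_generations = 2,
                    genotyped_generations = 2, pheno_generations = 1:2)
  expect_error(simulate_recent(founders, cfg, seed = 1), "founder cohort")
})
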