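## Forward-in-time simulation: a historical phase to build up linkage
## disequilibrium and mutation-drift equilibrium, then a recent breeding
## phase with a small number of sires (which sets the effective population
## size), age-based culling, and genotyping of the last generations.

#' Simulate the historical population
#'
#' Random union of gametes, no selection, no migration. The population size
#' follows the anchor points of `config$hist_schedule` with linear
#' interpolation between them (the full-scale default goes 1000 -> 50,000 ->
#' 20,000 over 2000 non-overlapping generations). Founder haplotypes start
#' at allele frequency 0.5; recurrent mutation flips alleles at
#' `config$mutation_rate` per locus per meiosis.
#'
#' @param config a [sim_config()]
#' @param seed integer seed
#' @param map optional pre-built [make_genome_map()]; built from the config
#'   when omitted
#' @return a `population` holding the final historical generation
#'   (generation 0), unrelated in the pedigree sense, sexes unassigned
#' @export
simulate_historical <- function(config, seed = NULL, map = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map)) map <- make_genome_map(config)
  sched <- config$hist_schedule
  gens <- seq(sched$generation[1], sched$generation[nrow(sched)])
  sizes <- if (nrow(sched) == 1) sched$size else
    as.integer(round(approx(sched$generation, sched$size, xout = gens)$y))
  if (any(sizes < 2)) stop("historical population size < 2 at some generation")
  rng <- chr_ranges(map)
  m <- nrow(map)
  n0 <- sizes[1]
  h1 <- matrix(rbinom(n0 * m, 1L, 0.5), n0, m)
  h2 <- matrix(rbinom(n0 * m, 1L, 0.5), n0, m)
  for (t in seq_along(gens)[-1]) {
    n <- sizes[t]
    nprev <- nrow(h1)
    p1 <- sample.int(nprev, n, replace = TRUE)
    p2 <- sample.int(nprev, n, replace = TRUE)
    clash <- which(p2 == p1)
    while (length(clash)) {  # no selfing
      p2[clash] <- sample.int(nprev, length(clash), replace = TRUE)
      clash <- clash[p2[clash] == p1[clash]]
    }
    g1 <- cpp_make_gametes(h1, h2, p1, rng$start, rng$end, map$pos, rng$len,
                           config$mutation_rate)
    g2 <- cpp_make_gametes(h1, h2, p2, rng$start, rng$end, map$pos, rng$len,
                           config$mutation_rate)
    h1 <- g1; h2 <- g2
  }
  n <- nrow(h1)
  ped <- data.frame(id = seq_len(n), sire = 0L, dam = 0L,
                    sex = NA_character_, generation = 0L,
                    genotyped = FALSE, stringsAsFactors = FALSE)
  new_population(ped, h1, h2, map)
}

#' Simulate the recent breeding population
#'
#' Samples `n_sires + n_dams` founders from the supplied cohort (sexes are
#' assigned at that point), then runs `n_generations` of random mating with
#' one offspring per dam per generation. Each generation the stated fraction
#' of breeders is replaced by offspring drawn at random from the current
#' generation; culled breeders are the oldest, with random tie-breaking.
#' Animals in `genotyped_generations` are flagged genotyped.
#'
#' @param founders a `population` to draw founders from (e.g. the output of
#'   [simulate_historical()])
#' @param config a [sim_config()]
#' @param seed integer seed
#' @return a `population` containing the selected founders (generation 0)
#'   and every offspring (generations 1..n_generations), pedigree
#'   topologically ordered
#' @export
simulate_recent <- function(founders, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- config$n_sires; nd <- config$n_dams
  ngen <- config$n_generations
  nf <- ns + nd
  if (nrow(founders$ped) < nf)
    stop("founder cohort (", nrow(founders$ped), ") smaller than n_sires + n_dams (", nf, ")")
  map <- founders$map
  rng <- chr_ranges(map)
  m <- nrow(map)
  total <- nf + ngen * nd
  h1 <- matrix(0L, total, m); h2 <- matrix(0L, total, m)
  pick <- sample.int(nrow(founders$ped), nf)
  h1[1:nf, ] <- founders$hap1[pick, , drop = FALSE]
  h2[1:nf, ] <- founders$hap2[pick, , drop = FALSE]
  id <- seq_len(total)
  sire <- integer(total); dam <- integer(total)
  sex <- character(total); generation <- integer(total)
  sex[1:ns] <- "M"; sex[(ns + 1):nf] <- "F"
  generation[1:nf] <- 0L

  sire_rows <- 1:ns
  dam_rows <- (ns + 1):nf
  sire_entry <- rep(0L, ns); dam_entry <- rep(0L, nd)
  nrep_s <- as.integer(round(config$replacement_sire * ns))
  nrep_d <- as.integer(round(config$replacement_dam * nd))
  nxt <- nf + 1L
  for (g in seq_len(ngen)) {
    off <- nxt:(nxt + nd - 1L)
    s_of <- sire_rows[sample.int(ns, nd, replace = TRUE)]
    d_of <- dam_rows
    h1[off, ] <- cpp_make_gametes(h1, h2, s_of, rng$start, rng$end, map$pos,
                                  rng$len, config$mutation_rate)
    h2[off, ] <- cpp_make_gametes(h1, h2, d_of, rng$start, rng$end, map$pos,
                                  rng$len, config$mutation_rate)
    sire[off] <- s_of; dam[off] <- d_of
    sex[off] <- sample(c("M", "F"), nd, replace = TRUE)
    generation[off] <- g
    ## age-based culling: drop the oldest breeders (random tie-break),
    ## promote random offspring of the right sex
    if (nrep_s > 0) {
      cand <- off[sex[off] == "M"]
      if (length(cand) < nrep_s)
        stop("generation ", g, ": only ", length(cand),
             " male offspring for ", nrep_s, " sire replacements")
      cull <- order(sire_entry, runif(ns))[seq_len(nrep_s)]
      sire_rows[cull] <- cand[sample.int(length(cand), nrep_s)]
      sire_entry[cull] <- g
    }
    if (nrep_d > 0) {
      cand <- off[sex[off] == "F"]
      if (length(cand) < nrep_d)
        stop("generation ", g, ": only ", length(cand),
             " female offspring for ", nrep_d, " dam replacements")
      cull <- order(dam_entry, runif(nd))[seq_len(nrep_d)]
      dam_rows[cull] <- cand[sample.int(length(cand), nrep_d)]
      dam_entry[cull] <- g
    }
    nxt <- nxt + nd
  }
  ped <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                    generation = generation,
                    genotyped = generation %in% config$genotyped_generations,
                    stringsAsFactors = FALSE)
  new_population(ped, h1, h2, map)
}

#' Sample one gamete from a parent (Haldane meiosis)
#'
#' Crossover counts per chromosome are Poisson in the map length (Morgans),
#' breakpoints uniform with no interference, chromosomes assort
#' independently.
#'
#' @param parent_haplotypes list of two 0/1 vectors (or a 2-row matrix) over
#'   the loci of `genome_map`
#' @param genome_map a `genome_map`
#' @param seed integer seed
#' @param mutation_rate allele-flip probability per locus (default 0)
#' @return an integer 0/1 haplotype vector
#' @export
recombine_gamete <- function(parent_haplotypes, genome_map, seed = NULL,
                             mutation_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(parent_haplotypes))
    parent_haplotypes <- list(parent_haplotypes[1, ], parent_haplotypes[2, ])
  stopifnot(length(parent_haplotypes) == 2,
            length(parent_haplotypes[[1]]) == nrow(genome_map),
            length(parent_haplotypes[[2]]) == nrow(genome_map))
  rng <- chr_ranges(genome_map)
  h1 <- matrix(as.integer(parent_haplotypes[[1]]), 1)
  h2 <- matrix(as.integer(parent_haplotypes[[2]]), 1)
  drop(cpp_make_gametes(h1, h2, 1L, rng$start, rng$end, genome_map$pos,
                        rng$len, mutation_rate))
}

#' MAF-filter candidate loci and assign SNP / QTN classes
#'
#' Allele frequencies are computed in the recent-population founder cohort
#' (generation 0 of `pop` by default). Loci with minor allele frequency
#' strictly greater than `maf_min` survive; QTN and then SNPs are sampled
#' from the survivors without replacement.
#'
#' @param pop a `population`
#' @param maf_min strict MAF threshold (default 0.05)
#' @param n_snp,n_qtn target counts; when both are `NULL` every surviving
#'   locus is kept and labelled SNP
#' @param cohort_ids individuals over which frequencies are computed
#'   (default: generation 0)
#' @param seed integer seed for the class assignment
#' @return a `genome_map` restricted to the selected loci with `class` set
#'   to `"SNP"` or `"QTN"`
#' @export
filter_segregating_maf <- function(pop, maf_min = 0.05,
                                   n_snp = NULL, n_qtn = NULL,
                                   cohort_ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cohort_ids)) cohort_ids <- pop$ped$id[pop$ped$generation == 0L]
  f <- allele_freqs(pop, cohort_ids)
  maf <- pmin(f, 1 - f)
  surv <- which(maf > maf_min)
  if (is.null(n_snp) && is.null(n_qtn)) {
    out <- subset_map(pop$map, surv)
    out$class <- rep("SNP", nrow(out))
    return(out)
  }
  n_snp <- n_snp %||% 0L
  n_qtn <- n_qtn %||% 0L
  if (length(surv) < n_snp + n_qtn)
    stop("only ", length(surv), " loci segregate with MAF > ", maf_min,
         " but ", n_snp + n_qtn, " are required")
  chosen_qtn <- surv[sample.int(length(surv), n_qtn)]
  rest <- setdiff(surv, chosen_qtn)
  chosen_snp <- rest[sample.int(length(rest), n_snp)]
  keep <- sort(c(chosen_qtn, chosen_snp))
  out <- subset_map(pop$map, keep)
  out$class <- ifelse(out$locus_id %in% pop$map$locus_id[chosen_qtn], "QTN", "SNP")
  out
}

#' Sample QTN effects and rescale to a target additive variance
#'
#' Effect magnitudes are gamma(shape) distributed with random sign; all
#' effects are then rescaled by a single constant so that the realized
#' variance of true breeding values in the founder cohort equals
#' `sigma_u2` exactly.
#'
#' @param founder_genotypes dosage matrix (founders x QTN, 0/1/2); column
#'   names are taken as the QTN locus ids
#' @param sigma_u2 target additive genetic variance
#' @param shape gamma shape parameter (0.4)
#' @param mu overall trait mean (1.0)
#' @param seed integer seed
#' @return a `trait_arch`: list with `qtn_ids`, `beta`, `sigma_u2`, `mu`
#' @export
sample_qtn_effects <- function(founder_genotypes, sigma_u2, shape = 0.4,
                               mu = 1.0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_qtn <- ncol(founder_genotypes)
  if (n_qtn < 1) stop("need at least one QTN")
  beta <- rgamma(n_qtn, shape = shape, scale = 1) *
    sample(c(-1, 1), n_qtn, replace = TRUE)
  tbv_raw <- drop(founder_genotypes %*% beta)
  v <- var(tbv_raw)
  if (!is.finite(v) || v <= 0)
    stop("raw TBV variance is zero: all QTN monomorphic in the founders?")
  beta <- beta * sqrt(sigma_u2 / v)
  arch <- list(qtn_ids = as.integer(colnames(founder_genotypes) %||%
                                      seq_len(n_qtn)),
               beta = beta, sigma_u2 = sigma_u2, mu = mu)
  class(arch) <- "trait_arch"
  arch
}

#' True breeding values under a trait architecture
#' @param pop a `population`
#' @param arch a `trait_arch`
#' @param ids individuals (default all)
#' @return numeric vector named by id
#' @export
true_breeding_values <- function(pop, arch, ids = NULL) {
  if (is.null(ids)) ids <- pop$ped$id
  q <- genotype_matrix(pop, ids, arch$qtn_ids)
  drop(q %*% arch$beta)
}

#' Assign phenotypes
#'
#' phenotype = mu + TBV + residual, residual ~ N(0, var_p - sigma_u2).
#' Phenotypes are defined only for `generations` (by default the last ten
#' generations, matching records restricted to generations 11-20 in the
#' full design); other animals get NA.
#'
#' @param arch a `trait_arch`
#' @param pop a `population`
#' @param seed integer seed
#' @param generations generations that receive phenotypes
#' @param var_p total phenotypic variance (1.0)
#' @return data.frame (id, generation, tbv, residual, phenotype)
#' @export
assign_phenotypes <- function(arch, pop, seed = NULL, generations = NULL,
                              var_p = 1.0) {
  if (!is.null(seed)) set.seed(seed)
  if (arch$sigma_u2 > var_p)
    stop("additive variance (", arch$sigma_u2,
         ") exceeds phenotypic variance (", var_p, ")")
  if (is.null(generations)) {
    gmax <- max(pop$ped$generation)
    generations <- seq(max(1L, gmax - 9L), gmax)
  }
  tbv <- true_breeding_values(pop, arch)
  has_phe <- pop$ped$generation %in% generations
  sigma_e <- sqrt(var_p - arch$sigma_u2)
  residual <- rep(NA_real_, nrow(pop$ped))
  residual[has_phe] <- rnorm(sum(has_phe), 0, sigma_e)
  data.frame(id = pop$ped$id,
             generation = pop$ped$generation,
             tbv = tbv,
             residual = residual,
             phenotype = ifelse(has_phe, arch$mu + tbv + residual, NA_real_))
}

#' Run the whole synthetic-data stage
#'
#' Historical phase, recent phase, MAF filtering / SNP-QTN labelling, trait
#' architecture, and phenotypes, with child seeds derived per stage.
#'
#' @param config a [sim_config()]
#' @param seed master seed
#' @return list with `pop` (recent population), `map` (classified
#'   genome map), `arch`, `phen`, and `config`
#' @export
simulate_population <- function(config, seed = 1) {
  hist <- simulate_historical(config, seed = derive_seed(seed, 1))
  pop <- simulate_recent(hist, config, seed = derive_seed(seed, 2))
  map <- filter_segregating_maf(pop, config$maf_min,
                                n_snp = config$n_snp, n_qtn = config$n_qtn,
                                seed = derive_seed(seed, 3))
  founder_ids <- pop$ped$id[pop$ped$generation == 0L]
  qtn_ids <- map$locus_id[map$class == "QTN"]
  fg <- genotype_matrix(pop, founder_ids, qtn_ids)
  arch <- sample_qtn_effects(fg, sigma_u2 = config$sigma_u2,
                             shape = config$gamma_shape, mu = config$mean,
                             seed = derive_seed(seed, 4))
  phen <- assign_phenotypes(arch, pop, seed = derive_seed(seed, 5),
                            generations = config$pheno_generations,
                            var_p = config$phenotypic_variance)
  list(pop = pop, map = map, arch = arch, phen = phen, config = config)
}
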