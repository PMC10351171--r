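#' Simulation configuration
#'
#' Holds every knob of the forward-in-time simulation: genome layout,
#' marker/QTN targets, the historical population-size schedule, the recent
#' breeding design (sires, dams, replacement rates), and the trait
#' architecture. Defaults reproduce the full-scale design: a bovine-like
#' genome of 29 chromosomes totalling 23.19 Morgans carrying 500k SNPs and
#' 200 QTN (MAF > 0.05), a historical population going 1000 -> 50,000 ->
#' 20,000 over 2000 generations, and a recent population of 50 sires x
#' 15,000 dams mated for 20 generations with 80%/30% sire/dam replacement.
#' The full design is far too large for a desktop; use `scale_factor` (or
#' set the fields directly) for desk-scale runs.
#'
#' @param n_chromosomes number of chromosomes
#' @param genome_length total genetic length in Morgans (split evenly across
#'   chromosomes unless `chrom_lengths` is given)
#' @param chrom_lengths optional vector of per-chromosome lengths in Morgans
#' @param n_snp target number of SNPs after MAF filtering
#' @param n_qtn target number of QTN after MAF filtering (200 or 2000 in the
#'   full design)
#' @param maf_min minor-allele-frequency filter; loci are kept when
#'   MAF is strictly greater than this (default 0.05)
#' @param mutation_rate recurrent (allele-flipping) mutation probability per
#'   locus per meiosis (default 2.5e-5)
#' @param locus_surplus how many candidate loci to simulate per target locus,
#'   to leave room for fixation and MAF filtering
#' @param hist_schedule data.frame (generation, size) of population-size
#'   anchor points for the historical phase; sizes between anchors are
#'   linearly interpolated
#' @param n_sires breeding males per generation (5 gives Ne ~ 20, 50 gives
#'   Ne ~ 200 in the full design)
#' @param n_dams breeding females per generation (15,000 at full scale)
#' @param n_generations recent generations of random mating (20)
#' @param replacement_sire,replacement_dam fraction of breeders replaced by
#'   random offspring each generation (oldest culled first)
#' @param genotyped_generations recent generations whose animals are
#'   genotyped (16:20 at full scale)
#' @param pheno_generations recent generations with phenotype and pedigree
#'   records (11:20 at full scale)
#' @param h2 trait heritability (0.3, 0.9 or 0.99 in the full design); equals
#'   the additive variance because the phenotypic variance is 1
#' @param mean overall trait mean (1.0)
#' @param phenotypic_variance total phenotypic variance (1.0)
#' @param gamma_shape shape of the gamma distribution of QTN effect sizes
#'   (0.4)
#' @param scale_factor optional global shrink in (0, 1]: scales marker/QTN
#'   targets, historical sizes and duration, and the number of dams
#'   proportionally so the whole pipeline runs at desk scale. Genome length
#'   and the numbers of sires are left alone (they set Ne and Me) unless
#'   changed explicitly.
#' @return an object of class `sim_config`
#' @export
#' @examples
#' cfg <- sim_config(scale_factor = 0.01, n_chromosomes = 2,
#'                   genome_length = 2, n_sires = 5)
#' cfg$n_dams
sim_config <- function(n_chromosomes = 29,
                       genome_length = 23.19,
                       chrom_lengths = NULL,
                       n_snp = 500000,
                       n_qtn = 200,
                       maf_min = 0.05,
                       mutation_rate = 2.5e-5,
                       locus_surplus = 1.5,
                       hist_schedule = data.frame(
                         generation = c(-2000, -1000, 0),
                         size = c(1000, 50000, 20000)),
                       n_sires = 50,
                       n_dams = 15000,
                       n_generations = 20,
                       replacement_sire = 0.80,
                       replacement_dam = 0.30,
                       genotyped_generations = 16:20,
                       pheno_generations = 11:20,
                       h2 = 0.3,
                       mean = 1.0,
                       phenotypic_variance = 1.0,
                       gamma_shape = 0.4,
                       scale_factor = 1) {
  stopifnot(scale_factor > 0, scale_factor <= 1)
  if (scale_factor < 1) {
    n_snp <- max(20L, as.integer(round(n_snp * scale_factor)))
    n_qtn <- max(2L, as.integer(round(n_qtn * scale_factor)))
    n_dams <- max(10L, as.integer(round(n_dams * scale_factor)))
    hist_schedule$size <- pmax(10L, as.integer(round(hist_schedule$size * scale_factor)))
    g0 <- hist_schedule$generation
    hist_schedule$generation <- as.integer(round(g0 * scale_factor))
    ## anchors must stay distinct and end at 0
    if (anyDuplicated(hist_schedule$generation))
      hist_schedule <- hist_schedule[!duplicated(hist_schedule$generation), , drop = FALSE]
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- rep(genome_length / n_chromosomes, n_chromosomes)
  }
  stopifnot(length(chrom_lengths) == n_chromosomes, all(chrom_lengths >= 0))
  if (!(maf_min >= 0 && maf_min < 0.5)) stop("maf_min must be in [0, 0.5)")
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  stopifnot(is.data.frame(hist_schedule),
            all(c("generation", "size") %in% names(hist_schedule)))
  if (is.unsorted(hist_schedule$generation, strictly = TRUE))
    stop("hist_schedule generations must be strictly increasing")
  if (any(hist_schedule$size < 2)) stop("historical population sizes must be >= 2")
  if (n_sires < 1 || n_dams < 1) stop("need at least one sire and one dam")
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths = as.numeric(chrom_lengths),
    genome_length = sum(chrom_lengths),
    n_snp = as.integer(n_snp),
    n_qtn = as.integer(n_qtn),
    maf_min = maf_min,
    mutation_rate = mutation_rate,
    locus_surplus = locus_surplus,
    hist_schedule = hist_schedule,
    n_sires = as.integer(n_sires),
    n_dams = as.integer(n_dams),
    n_generations = as.integer(n_generations),
    replacement_sire = replacement_sire,
    replacement_dam = replacement_dam,
    genotyped_generations = as.integer(genotyped_generations),
    pheno_generations = as.integer(pheno_generations),
    h2 = h2,
    sigma_u2 = h2 * phenotypic_variance,
    sigma_e2 = (1 - h2) * phenotypic_variance,
    mean = mean,
    phenotypic_variance = phenotypic_variance,
    gamma_shape = gamma_shape,
    scale_factor = scale_factor)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_chromosomes, "chromosomes /", round(x$genome_length, 3), "Morgans;",
      x$n_snp, "SNPs +", x$n_qtn, "QTN (MAF >", x$maf_min, ")\n")
  cat("  historical:",
      paste(x$hist_schedule$size, collapse = " -> "),
      "over generations",
      paste(range(x$hist_schedule$generation), collapse = ".."), "\n")
  cat("  recent:", x$n_sires, "sires x", x$n_dams, "dams,",
      x$n_generations, "generations; genotyped:",
      paste(range(x$genotyped_generations), collapse = "-"), "\n")
  cat("  trait: h2 =", x$h2, ", mean =", x$mean,
      ", varP =", x$phenotypic_variance, "\n")
  invisible(x)
}

## Read a key=value config file into sim_config arguments (CLI support).
## Vector-valued keys use comma separation, e.g. genotyped_generations=16,17.
parse_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  out <- lapply(vals, function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  names(out) <- keys
  out
}
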