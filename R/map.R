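#' Construct a genome map of candidate loci
#'
#' Places biallelic candidate loci uniformly at random along each chromosome.
#' The number of loci per chromosome is proportional to its genetic length.
#' Loci start out unclassified (`class = "CAND"`); [filter_segregating_maf()]
#' later keeps the segregating ones and labels them SNP or QTN.
#'
#' @param config a [sim_config()]
#' @param seed integer seed
#' @param n_loci number of candidate loci (default: surplus times the SNP +
#'   QTN targets)
#' @return a `genome_map`: data.frame with columns `chr`, `pos` (Morgans,
#'   chromosome-local, strictly increasing within chromosome), `locus_id`,
#'   `class`; chromosome lengths kept as the `chrom_lengths` attribute
#' @export
make_genome_map <- function(config, seed = NULL,
                            n_loci = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_loci))
    n_loci <- ceiling((config$n_snp + config$n_qtn) * config$locus_surplus)
  len <- config$chrom_lengths
  prob <- if (sum(len) > 0) len / sum(len) else rep(1 / length(len), length(len))
  per_chr <- as.vector(stats::rmultinom(1, n_loci, prob))
  chr <- rep.int(seq_along(len), per_chr)
  pos <- unlist(lapply(seq_along(len), function(c) {
    p <- sort(runif(per_chr[c], 0, len[c]))
    ## enforce strict increase (ties are measure-zero but guard anyway)
    while (anyDuplicated(p)) p <- sort(jitter(p, amount = 1e-9))
    p
  }), use.names = FALSE)
  map <- data.frame(chr = chr, pos = pos,
                    locus_id = seq_len(n_loci),
                    class = rep("CAND", n_loci),
                    stringsAsFactors = FALSE)
  attr(map, "chrom_lengths") <- len
  class(map) <- c("genome_map", "data.frame")
  map
}

## 1-based index range of each chromosome in a position-sorted map
chr_ranges <- function(map) {
  lens <- attr(map, "chrom_lengths")
  nchr <- length(lens)
  start <- integer(nchr); end <- integer(nchr)
  for (c in seq_len(nchr)) {
    idx <- which(map$chr == c)
    if (length(idx)) {
      start[c] <- min(idx); end[c] <- max(idx)
    } else {
      start[c] <- 1L; end[c] <- 0L  # empty chromosome
    }
  }
  list(start = start, end = end, len = lens)
}

## Subset a genome map keeping attributes/class
subset_map <- function(map, keep) {
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- attr(map, "chrom_lengths")
  class(out) <- c("genome_map", "data.frame")
  out
}
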