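## Plain-text interchange: pedigree, phenotypes, trait architecture, panel
## files, PLINK-text genotypes (.ped/.map), and a dense GRM container.

#' Write a pedigree file
#'
#' Whitespace-delimited columns: id, sire, dam, generation, sex.
#'
#' @param pop a `population` (or a pedigree data.frame)
#' @param file output path
#' @export
write_pedigree <- function(pop, file) {
  ped <- if (inherits(pop, "population")) pop$ped else pop
  data.table::fwrite(ped[c("id", "sire", "dam", "generation", "sex")],
                     file, sep = " ", col.names = TRUE)
  invisible(file)
}

#' Write a phenotype table (TSV: id, phenotype, tbv)
#' @param phen output of [assign_phenotypes()]
#' @param file output path
#' @param drop_missing drop animals without phenotype (default TRUE)
#' @export
write_phenotypes <- function(phen, file, drop_missing = TRUE) {
  out <- phen[c("id", "phenotype", "tbv")]
  if (drop_missing) out <- out[!is.na(out$phenotype), , drop = FALSE]
  data.table::fwrite(out, file, sep = "\t")
  invisible(file)
}

#' Write the trait architecture (TSV: locus_id, beta)
#' @param arch a `trait_arch`
#' @param file output path
#' @export
write_trait <- function(arch, file) {
  data.table::fwrite(data.frame(locus_id = arch$qtn_ids, beta = arch$beta),
                     file, sep = "\t")
  invisible(file)
}

#' Write / read a marker panel (one locus id per line)
#' @param panel a `marker_panel`
#' @param file path
#' @export
write_panel <- function(panel, file) {
  writeLines(as.character(panel$locus_ids), file)
  invisible(file)
}

#' @rdname write_panel
#' @param label panel label to attach on read
#' @export
read_panel <- function(file, label = "PANEL") {
  new_panel(as.integer(readLines(file)), label)
}

#' Write genotypes as PLINK-text (.ped/.map)
#'
#' The .map carries chromosome, locus id, genetic position (Morgans) and an
#' integer base-pair surrogate (position x 1e6). Dosages are encoded as
#' allele pairs `1 1` / `1 2` / `2 2`.
#'
#' @param genotypes dosage matrix (individuals x loci), rownames = ids,
#'   colnames = locus ids
#' @param map `genome_map` covering (at least) the written loci
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`
#' @export
write_plink <- function(genotypes, map, prefix) {
  ids <- rownames(genotypes) %||% seq_len(nrow(genotypes))
  loci <- as.integer(colnames(genotypes) %||% seq_len(ncol(genotypes)))
  mi <- match(loci, map$locus_id)
  if (anyNA(mi)) stop("written loci missing from the map")
  mp <- data.frame(chr = map$chr[mi],
                   id = paste0("loc", loci),
                   cm = map$pos[mi],
                   bp = as.integer(round(map$pos[mi] * 1e6)))
  data.table::fwrite(mp, paste0(prefix, ".map"), sep = "\t", col.names = FALSE)
  a1 <- matrix("1", nrow(genotypes), ncol(genotypes))
  a2 <- a1
  a1[genotypes == 2] <- "2"
  a2[genotypes >= 1] <- "2"
  alle <- matrix("", nrow(genotypes), 2 * ncol(genotypes))
  alle[, seq(1, 2 * ncol(genotypes), 2)] <- a1
  alle[, seq(2, 2 * ncol(genotypes), 2)] <- a2
  ped <- cbind(FID = "0", IID = as.character(ids), PAT = "0", MAT = "0",
               SEX = "0", PHE = "-9", alle)
  data.table::fwrite(data.table::as.data.table(ped), paste0(prefix, ".ped"),
                     sep = " ", col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK-text genotypes written by [write_plink()]
#' @param prefix path prefix of the `.ped`/`.map` pair
#' @return list with `genotypes` (dosage matrix), `map` (data.frame chr,
#'   locus_id, pos), `ids`
#' @export
read_plink <- function(prefix) {
  mp <- data.table::fread(paste0(prefix, ".map"), header = FALSE,
                          col.names = c("chr", "id", "cm", "bp"))
  pd <- data.table::fread(paste0(prefix, ".ped"), header = FALSE,
                          colClasses = "character")
  ids <- pd[[2]]
  al <- as.matrix(pd[, -(1:6)])
  m <- ncol(al) / 2
  g <- (al[, seq(1, 2 * m, 2), drop = FALSE] == "2") +
    (al[, seq(2, 2 * m, 2), drop = FALSE] == "2")
  storage.mode(g) <- "integer"
  locus_ids <- as.integer(sub("^loc", "", mp$id))
  dimnames(g) <- list(ids, locus_ids)
  list(genotypes = g,
       map = data.frame(chr = mp$chr, locus_id = locus_ids, pos = mp$cm),
       ids = ids)
}

#' Persist a GRM in a dense binary container with an id index
#'
#' Layout: a one-line header (`eigdim_grm <n>`), the ids (one per line),
#' then the lower triangle including the diagonal as doubles.
#'
#' @param grm matrix with ids as dimnames
#' @param file path
#' @export
write_grm <- function(grm, file) {
  n <- nrow(grm)
  ids <- rownames(grm) %||% as.character(seq_len(n))
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(c(paste("eigdim_grm", n), ids), con)
  lt <- unclass(grm)[lower.tri(grm, diag = TRUE)]
  writeBin(as.double(lt), con, size = 8)
  invisible(file)
}

#' @rdname write_grm
#' @export
read_grm <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr <- readLines(con, n = 1)
  parts <- strsplit(hdr, " ")[[1]]
  if (parts[1] != "eigdim_grm") stop("not an eigdim GRM container")
  n <- as.integer(parts[2])
  ids <- readLines(con, n = n)
  lt <- readBin(con, "double", n * (n + 1) / 2, size = 8)
  G <- matrix(0, n, n)
  G[lower.tri(G, diag = TRUE)] <- lt
  G <- G + t(G) - diag(diag(G))
  dimnames(G) <- list(ids, ids)
  G
}
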