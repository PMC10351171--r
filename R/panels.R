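## Marker panels: full sequence (SNPs + QTN merged by position), the regular
## chip (every tenth SNP), and chip panels augmented with GWA-preselected
## variants (TOPv by p-value order, or SIG by Bonferroni significance).

new_panel <- function(locus_ids, label, map = NULL) {
  obj <- list(locus_ids = as.integer(locus_ids), label = label)
  class(obj) <- "marker_panel"
  obj
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel", x$label, ":", length(x$locus_ids), "loci\n")
  invisible(x)
}

#' Sequence panel: all SNPs and QTN interleaved in genome order
#'
#' Mimics sequence data in which the causal variants are contained in the
#' genotypes: SNP and QTN loci are merged by map position.
#'
#' @param map a classified `genome_map`
#' @return a `marker_panel` labelled `SEQ`
#' @export
build_sequence_panel <- function(map) {
  keep <- map$class %in% c("SNP", "QTN")
  sub <- map[keep, , drop = FALSE]
  ## deterministic tie-break for duplicated positions: class then locus id
  o <- order(sub$chr, sub$pos, sub$class, sub$locus_id)
  dup <- duplicated(sub[c("chr", "pos")])
  if (any(dup))
    warning(sum(dup), " duplicated map position(s); ties broken by (class, locus_id)")
  new_panel(sub$locus_id[o], "SEQ")
}

#' Regular chip panel: every step-th SNP in genome order
#'
#' QTN are excluded. With the full-scale 500k SNPs and the default step of
#' 10 this yields the regular 50k chip.
#'
#' @param map a classified `genome_map`
#' @param step keep one SNP in every `step` (default 10)
#' @return a `marker_panel` labelled `CHIP50K`
#' @export
build_chip_panel <- function(map, step = 10) {
  stopifnot(step >= 1)
  snp <- map[map$class == "SNP", , drop = FALSE]
  o <- order(snp$chr, snp$pos)
  ids <- snp$locus_id[o]
  new_panel(ids[seq(1, length(ids), by = step)], "CHIP50K")
}

#' Augment a chip panel with GWA-preselected variants
#'
#' `TOPv` adds the `v` variants with the smallest p-values regardless of
#' significance; `SIG` adds every variant passing the stored significance
#' threshold. The result is the union with the chip, deduplicated and in
#' genome order. p-value ties are broken by genome position.
#'
#' @param chip a `marker_panel` (the chip)
#' @param assoc an `assoc_result` from [assoc_scan()]
#' @param mode `"TOPv"` or `"SIG"`
#' @param v for `TOPv`, how many variants to add
#' @return a `marker_panel` labelled `CHIP50K_TOPv` or `CHIP50K_SIG`
#' @export
augment_panel <- function(chip, assoc, mode = c("TOPv", "SIG"), v = NULL) {
  mode <- match.arg(mode)
  if (mode == "TOPv") {
    if (is.null(v)) stop("TOPv mode needs v")
    if (v > nrow(assoc))
      stop("v = ", v, " exceeds the ", nrow(assoc), " tested variants")
    o <- order(assoc$p, assoc$chr, assoc$pos)
    add <- assoc$locus_id[o][seq_len(v)]
    label <- paste0("CHIP50K_TOP", v)
  } else {
    add <- assoc$locus_id[assoc$significant]
    label <- "CHIP50K_SIG"
  }
  ids <- sort(unique(c(chip$locus_ids, add)))
  new_panel(ids, label)
}
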