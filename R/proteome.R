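#' Filter a motif table down to long motifs
#'
#' Keeps motifs with at least `min_units` RG+RGG units, preserving order.
#' The default of 10 targets "extra-long" GAR motifs of the kind that are
#' rare at proteome scale; the comparison is inclusive (`>=`), and the
#' threshold is exposed because the boundary between reports of "at least 10"
#' and "more than 10" repeats is ambiguous in the literature.
#'
#' @param results A `gar_scan` object or motif table.
#' @param min_units Minimum RG+RGG unit count (default 10; must be >= 2).
#' @return The filtered motif table.
#' @export
filter_long_motifs <- function(results, min_units = 10L) {
  if (min_units < 2L) stop("min_units must be >= 2", call. = FALSE)
  m <- motif_table(results)
  out <- m[(m$rg + m$rgg) >= min_units, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' RG/RGG richness of a motif
#'
#' `RGG_RICH` when RGG units outnumber RG units, `RG_RICH` for the reverse,
#' `BALANCED` on a tie.
#'
#' @param rg,rgg Integer vectors of unit counts (recycled).
#' @return Character vector of richness labels.
#' @export
classify_richness <- function(rg, rgg) {
  ifelse(rgg > rg, "RGG_RICH", ifelse(rg > rgg, "RG_RICH", "BALANCED"))
}

.thandapani_patterns <- c(
  TRI_RGG = "RGG([A-Z]{0,4}RGG){2}",
  DI_RGG  = "RGG[A-Z]{0,4}RGG",
  TRI_RG  = "RG(?!G)([A-Z]{0,4}RG(?!G)){2}",
  DI_RG   = "RG(?!G)[A-Z]{0,4}RG(?!G)"
)

#' Tri/di-RGG sequence class
#'
#' Classifies a sequence by the classical RGG-box scheme: `TRI_RGG`
#' (`RGG(X0-4)RGG(X0-4)RGG`), `DI_RGG`, `TRI_RG`, `DI_RG`, tested in that
#' priority order (a tri instance always contains a di instance, so order
#' matters), or `NONE`. An RGG element is an arginine followed by at least
#' two glycines, an RG element an arginine followed by exactly one;
#' `X(0,4)` is 0-4 arbitrary residues. Elements are non-overlapping, scanned
#' left to right.
#'
#' @param sequence Character vector of uppercase residue strings.
#' @return Character vector of class labels.
#' @examples
#' thandapani_class("RGGAARGGAARGG")  # "TRI_RGG"
#' thandapani_class("AAAA")           # "NONE"
#' @export
thandapani_class <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    for (lab in names(.thandapani_patterns)) {
      if (grepl(.thandapani_patterns[[lab]], s, perl = TRUE)) return(lab)
    }
    "NONE"
  }, character(1), USE.NAMES = FALSE)
}

#' Census of long GAR motifs in a batch of sequences
#'
#' Scans the records, keeps motifs with at least `min_units` RG+RGG units,
#' and annotates each with its `units` count, `richness`
#' ([classify_richness()]), `thandapani` class (of the motif string) and the
#' number of motifs in the batch sharing an identical motif string
#' (`identical_group`, a proxy for isoform-duplicated motifs). Rows are
#' sorted by units descending, then accession.
#'
#' @param x A `gar_records` data frame or FASTA path.
#' @param min_units Minimum RG+RGG unit count (default 10).
#' @return A census motif table (works with [write_gar_csv()]).
#' @export
gar_census <- function(x, min_units = 10L) {
  scan <- if (inherits(x, "gar_scan")) x else gar_scan(x)
  m <- filter_long_motifs(scan$motifs, min_units)
  m$units <- m$rg + m$rgg
  m$richness <- classify_richness(m$rg, m$rgg)
  m$thandapani <- thandapani_class(m$pattern)
  m$identical_group <- as.integer(ave(seq_len(nrow(m)), m$pattern,
                                      FUN = length))
  m <- m[order(-m$units, m$accession), , drop = FALSE]
  rownames(m) <- NULL
  m
}
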