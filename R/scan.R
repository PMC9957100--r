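#' Scan protein records for GAR motifs
#'
#' Runs the full pipeline on a batch of records: motif assembly
#' ([find_gar_motifs()]) followed by per-motif statistics
#' ([compute_stats()]). The result carries one report row per motif and the
#' input records, and feeds the reporting functions ([write_gar_csv()],
#' [write_gar_txt()], [summarize_batch()], [chart_data()]) and the census
#' ([gar_census()]).
#'
#' @param x A `gar_records` data frame (see [read_fasta()]) or a path to a
#'   FASTA file.
#' @param min_units Keep only motifs with at least this many RG+RGG units
#'   (default 2, the grammar minimum).
#' @return An object of class `gar_scan`: a list with `records` and `motifs`,
#'   where `motifs` is a data frame with columns `accession`, `start`, `end`,
#'   `pattern`, `rg`, `rgg`, `n_units`, `total_pct`, `g_to_r`, `g_pct`,
#'   `r_pct`, `non_gr_pct` and the list-column `else_counts`.
#' @examples
#' gar_scan(gar_records("AARGRGAA", "demo"))
#' @export
gar_scan <- function(x, min_units = 2L) {
  if (is.character(x) && length(x) == 1L && !inherits(x, "gar_records"))
    x <- read_fasta(x)
  stopifnot(is.data.frame(x), all(c("identifier", "sequence") %in% names(x)))
  if (min_units < 2L) stop("min_units must be >= 2", call. = FALSE)

  rows <- lapply(seq_len(nrow(x)), function(i) {
    m <- find_gar_motifs(x$sequence[i])
    if (nrow(m) == 0L) return(NULL)
    full_length <- nchar(x$sequence[i])
    stats <- lapply(seq_len(nrow(m)), function(k) compute_stats(m[k, ], full_length))
    data.frame(
      accession = x$identifier[i],
      record = i,
      start = m$start, end = m$end, pattern = m$pattern,
      rg = m$rg, rgg = m$rgg, n_units = m$n_units,
      total_pct = vapply(stats, `[[`, numeric(1), "total_pct"),
      g_to_r = vapply(stats, `[[`, numeric(1), "g_to_r"),
      g_pct = vapply(stats, `[[`, numeric(1), "g_pct"),
      r_pct = vapply(stats, `[[`, numeric(1), "r_pct"),
      non_gr_pct = vapply(stats, `[[`, numeric(1), "non_gr_pct"),
      else_counts = I(lapply(stats, `[[`, "else_counts")),
      stringsAsFactors = FALSE)
  })
  motifs <- do.call(rbind, rows)
  if (is.null(motifs)) {
    motifs <- data.frame(accession = character(), record = integer(),
                         start = integer(), end = integer(),
                         pattern = character(), rg = integer(),
                         rgg = integer(), n_units = integer(),
                         total_pct = numeric(), g_to_r = numeric(),
                         g_pct = numeric(), r_pct = numeric(),
                         non_gr_pct = numeric(), stringsAsFactors = FALSE)
    motifs$else_counts <- list()
  }
  motifs <- motifs[motifs$n_units >= min_units, , drop = FALSE]
  rownames(motifs) <- NULL
  structure(list(records = x, motifs = motifs), class = "gar_scan")
}

#' @export
print.gar_scan <- function(x, ...) {
  cat(sprintf("GAR motif scan: %d record(s), %d motif(s)\n",
              nrow(x$records), nrow(x$motifs)))
  if (nrow(x$motifs)) {
    shown <- x$motifs[, c("accession", "start", "end", "rg", "rgg",
                          "total_pct", "g_to_r", "g_pct", "r_pct",
                          "non_gr_pct")]
    print(utils::head(shown, 20), row.names = FALSE)
    if (nrow(shown) > 20) cat("...", nrow(shown) - 20, "more row(s)\n")
  }
  invisible(x)
}
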