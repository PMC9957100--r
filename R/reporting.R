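# extract the motif table whether given a gar_scan or a plain data frame
motif_table <- function(results) {
  if (inherits(results, "gar_scan")) results$motifs else results
}

#' Write the per-motif report as CSV
#'
#' One row per motif, in input order, with the fixed header
#' `Accession,Pattern,Position,RG,RGG,Else,Total%,G/R,G%,R%,Non-GR%`.
#' Position is formatted `start..end`, the Else cell as `'X': n` pairs joined
#' by `", "` in first-occurrence order (quoted, since it contains commas),
#' and all 1-decimal statistics are printed with exactly one decimal.
#' Census tables (see [gar_census()]) gain the extra columns
#' `Richness,Thandapani,Units`.
#'
#' @param results A `gar_scan` object or its motif table (optionally with
#'   census columns).
#' @param file Path or connection.
#' @return Invisibly, `file`.
#' @export
write_gar_csv <- function(results, file) {
  m <- motif_table(results)
  census <- all(c("richness", "thandapani") %in% names(m))
  header <- c("Accession", "Pattern", "Position", "RG", "RGG", "Else",
              "Total%", "G/R", "G%", "R%", "Non-GR%")
  if (census) header <- c(header, "Richness", "Thandapani", "Units")
  if (nrow(m) == 0L) {
    writeLines(paste(header, collapse = ","), file)
    return(invisible(file))
  }
  d1 <- function(x) sprintf("%.1f", x)
  out <- data.frame(
    Accession = m$accession,
    Pattern = m$pattern,
    Position = paste0(m$start, "..", m$end),
    RG = m$rg, RGG = m$rgg,
    Else = vapply(m$else_counts, format_else, character(1)),
    Total = d1(m$total_pct), GR = d1(m$g_to_r), G = d1(m$g_pct),
    R = d1(m$r_pct), NonGR = d1(m$non_gr_pct),
    stringsAsFactors = FALSE)
  if (census) {
    out$Richness <- m$richness
    out$Thandapani <- m$thandapani
    out$Units <- m$rg + m$rgg
  }
  con <-if (inherits(file, "connection")) file else base::file(file, "w")
  if (!inherits(file, "connection")) on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  utils::write.table(out, con, sep = ",", quote = which(names(out) == "Else"),
                     row.names = FALSE, col.names = FALSE, qmethod = "double")
  invisible(file)
}

#' Read back a report CSV
#'
#' Companion to [write_gar_csv()]; numeric cells round-trip exactly.
#'
#' @param file Path or connection.
#' @return A data frame with the report columns (`Else` as character).
#' @export
read_gar_csv <- function(file) {
  utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
}

#' Batch summary over all scanned records
#'
#' Tallies the batch: number of input sequences, how many carry at least one
#' motif (with a 1-decimal percentage), the total RG and RGG unit counts over
#' all motifs, and the pooled non-GR residue distribution.
#'
#' @param results A `gar_scan` object.
#' @return An object of class `gar_summary`: a list with `n_sequences`,
#'   `n_with_motifs`, `pct_with_motifs`, `total_rg`, `total_rgg`,
#'   `total_non_gr` (named integer vector, descending by count, ties
#'   alphabetical).
#' @export
summarize_batch <- function(results) {
  stopifnot(inherits(results, "gar_scan"))
  m <- results$motifs
  pooled <- pool_else(m$else_counts)
  n_seq <- nrow(results$records)
  n_hit <- length(unique(m$record))
  structure(list(
    n_sequences = n_seq,
    n_with_motifs = n_hit,
    pct_with_motifs = if (n_seq > 0) round1(100 * n_hit / n_seq) else NA_real_,
    total_rg = sum(m$rg),
    total_rgg = sum(m$rgg),
    total_non_gr = pooled
  ), class = "gar_summary")
}

# pool a list of else_counts vectors; descending by count, ties alphabetical
pool_else <- function(else_list) {
  all_counts <- unlist(else_list)
  if (is.null(all_counts) || length(all_counts) == 0L)
    return(stats::setNames(integer(0), character(0)))
  pooled <- tapply(all_counts, names(all_counts), sum)
  pooled <- stats::setNames(as.integer(pooled), names(pooled))
  pooled[order(-pooled, names(pooled))]
}

#' @export
print.gar_summary <- function(x, ...) {
  cat(sprintf("input sequences: %d\nsequences with GAR motifs: %d (%.1f%%)\n",
              x$n_sequences, x$n_with_motifs, x$pct_with_motifs))
  cat(sprintf("total RG: %d\ntotal RGG: %d\n", x$total_rg, x$total_rgg))
  cat("non-GR residues:", if (length(x$total_non_gr))
    format_else(x$total_non_gr) else "none", "\n")
  invisible(x)
}

#' Chart data: RG/RGG pie and non-GR bar
#'
#' The pie gives the percentage split of RG vs RGG units over all motifs
#' (summing to 100 when any unit exists); the bar gives the pooled non-GR
#' residue counts, descending by count with alphabetical tie-break.
#'
#' @param results A `gar_scan` object.
#' @return A list of class `gar_chart` with `pie` (named numeric,
#'   `RG`/`RGG`) and `bar` (named integer vector); both empty when the scan
#'   found no units.
#' @export
chart_data <- function(results) {
  s <- summarize_batch(results)
  total <- s$total_rg + s$total_rgg
  pie <- if (total > 0) {
    c(RG = round1(100 * s$total_rg / total),
      RGG = round1(100 * s$total_rgg / total))
  } else stats::setNames(numeric(0), character(0))
  structure(list(pie = pie, bar = s$total_non_gr), class = "gar_chart")
}

#' Write chart data as JSON
#'
#' Emits `{"pie": {"RG": ..., "RGG": ...}, "bar": [["F", 27], ...]}` for
#' headless plotting.
#'
#' @param chart A `gar_chart` object from [chart_data()].
#' @param file Path or connection.
#' @return Invisibly, `file`.
#' @export
write_chart_json <- function(chart, file) {
  bar <- lapply(seq_along(chart$bar), function(i)
    list(names(chart$bar)[i], unname(chart$bar[i])))
  jsonlite::write_json(list(pie = as.list(chart$pie), bar = bar), file,
                       auto_unbox = TRUE)
  invisible(file)
}

#' Write the plain-text report
#'
#' Per record: an identifier line, one block per motif (position, pattern,
#' unit counts, else composition, percentages), then the full sequence with
#' motifs bracketed (see [bracket_sequence()]); records without motifs are
#' echoed with a "no GAR motif found" note. Batch totals are appended when
#' more than one record was scanned.
#'
#' @param results A `gar_scan` object.
#' @param file Path or connection.
#' @return Invisibly, `file`.
#' @export
write_gar_txt <- function(results, file) {
  stopifnot(inherits(results, "gar_scan"))
  recs <- results$records
  m <- results$motifs
  lines <- character(0)
  for (i in seq_len(nrow(recs))) {
    header <- paste0(">", recs$identifier[i],
                     if (nzchar(recs$description[i]))
                       paste0(" ", recs$description[i]) else "")
    lines <- c(lines, header)
    mi <- m[m$record == i, , drop = FALSE]
    if (nrow(mi) == 0L) {
      lines <- c(lines, "no GAR motif found", "sequence:",
                 recs$sequence[i], "")
      next
    }
    for (k in seq_len(nrow(mi))) {
      r <- mi[k, ]
      lines <- c(lines,
        sprintf("GAR motif %d: position %d..%d", k, r$start, r$end),
        paste0("  pattern: ", r$pattern),
        sprintf("  RG: %d  RGG: %d", r$rg, r$rgg),
        paste0("  else: ", {
          e <- format_else(r$else_counts[[1]])
          if (nzchar(e)) e else "none"
        }),
        sprintf("  total%%: %.1f  G/R: %.1f  G%%: %.1f  R%%: %.1f  non-GR%%: %.1f",
                r$total_pct, r$g_to_r, r$g_pct, r$r_pct, r$non_gr_pct))
    }
    lines <- c(lines, "sequence:",
               bracket_sequence(recs$sequence[i], mi), "")
  }
  if (nrow(recs) > 1L) {
    s <- summarize_batch(results)
    lines <- c(lines, "=== batch totals ===",
      sprintf("input sequences: %d", s$n_sequences),
      sprintf("sequences with GAR motifs: %d (%.1f%%)",
              s$n_with_motifs, s$pct_with_motifs),
      sprintf("total RG: %d", s$total_rg),
      sprintf("total RGG: %d", s$total_rgg),
      paste0("non-GR residues: ", if (length(s$total_non_gr))
        format_else(s$total_non_gr) else "none"))
  }
  writeLines(lines, file)
  invisible(file)
}
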