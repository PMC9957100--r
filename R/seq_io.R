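#' Read protein sequences from a FASTA file
#'
#' Parses single- or multi-record protein FASTA and normalizes the sequences
#' for motif scanning: sequence lines are concatenated, whitespace stripped,
#' lowercase letters uppercased, and stop ("*") and gap ("-", ".") characters
#' removed (with a warning). Record order is preserved.
#'
#' The identifier is the first whitespace-delimited token of the header line
#' (without the leading ">"); the remainder, if any, is kept as the
#' description. Duplicate identifiers within one file are disambiguated by
#' appending "#2", "#3", ... so downstream reports stay unambiguous.
#'
#' Non-standard residue letters (B, J, O, U, X, Z) are retained: the motif
#' grammar's wildcard slots match any residue, and rejecting them would block
#' proteome-scale scans.
#'
#' @param file Path to a FASTA file, or a connection.
#' @return A data frame of class `gar_records` with columns `identifier`,
#'   `description` and `sequence` (uppercase residue strings).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "rg", "rg"), fa)
#' read_fasta(fa)
#' @seealso [write_fasta()], [gar_scan()]
#' @export
read_fasta <- function(file) {
  lines <- readLines(file, warn = FALSE)
  parse_fasta(lines)
}

#' @rdname read_fasta
#' @param lines Character vector of FASTA lines (as from `readLines()`).
#' @export
parse_fasta <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop("FASTA input is empty", call. = FALSE)
  is_header <- startsWith(lines, ">")
  if (!is_header[1L])
    stop("FASTA input does not start with '>': found text before the first record",
         call. = FALSE)
  rec_id <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  identifier <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        trimws(sub("^\\S+\\s*", "", headers)), "")
  seqs <- vapply(seq_along(headers), function(i) {
    paste(lines[rec_id == i & !is_header], collapse = "")
  }, character(1))

  seqs <- gsub("[[:space:]]", "", seqs)
  seqs <- toupper(seqs)
  stripped <- gsub("[*.-]", "", seqs)
  if (any(stripped != seqs))
    warning("stripped stop ('*') and/or gap ('-', '.') characters from ",
            sum(stripped != seqs), " record(s)", call. = FALSE)
  seqs <- stripped

  empty <- !nzchar(seqs)
  if (any(empty))
    stop("FASTA record with empty sequence: ",
         paste(identifier[empty], collapse = ", "), call. = FALSE)
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad))
    stop("FASTA record with non-residue characters after normalization: ",
         paste(identifier[bad], collapse = ", "), call. = FALSE)

  # disambiguate duplicated identifiers with a numeric suffix
  if (anyDuplicated(identifier)) {
    counts <- ave(seq_along(identifier), identifier, FUN = seq_along)
    dup <- counts > 1L
    identifier[dup] <- paste0(identifier[dup], "#", counts[dup])
  }

  out <- data.frame(identifier = identifier, description = description,
                    sequence = seqs, stringsAsFactors = FALSE)
  class(out) <- c("gar_records", class(out))
  out
}

#' Write protein records to FASTA
#'
#' Sequences are wrapped at 60 columns. Writing and re-reading a `gar_records`
#' object round-trips identifier/sequence pairs exactly.
#'
#' @param records A `gar_records` data frame (or any data frame with
#'   `identifier`, `description`, `sequence` columns).
#' @param file Path or connection to write to.
#' @param width Line width for sequence wrapping (default 60).
#' @return Invisibly, `file`.
#' @export
write_fasta <- function(records, file, width = 60L) {
  stopifnot(all(c("identifier", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  out <- unlist(lapply(seq_len(nrow(records)), function(i) {
    header <- paste0(">", records$identifier[i],
                     if (nzchar(desc[i])) paste0(" ", desc[i]) else "")
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    c(header, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(out, file)
  invisible(file)
}

#' Build a gar_records data frame from residue strings
#'
#' Convenience constructor used by tests and examples; applies the same
#' normalization and validation as [read_fasta()].
#'
#' @param sequences Character vector of residue strings.
#' @param identifiers Optional identifiers (defaults to `seq1`, `seq2`, ...).
#' @param descriptions Optional descriptions.
#' @return A `gar_records` data frame.
#' @export
gar_records <- function(sequences,
                        identifiers = paste0("seq", seq_along(sequences)),
                        descriptions = "") {
  lines <- unlist(Map(function(id, d, s) {
    c(paste0(">", id, if (nzchar(d)) paste0(" ", d) else ""), s)
  }, identifiers, rep_len(descriptions, length(sequences)), sequences,
  USE.NAMES = FALSE))
  parse_fasta(lines)
}
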