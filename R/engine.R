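#' Find all maximal GAR motifs in one sequence
#'
#' Left-to-right greedy maximal assembly: seed at the leftmost unconsumed
#' anchor, extend anchor-by-anchor while every inter-anchor segment satisfies
#' the gap grammar ([is_valid_gap()]), keep the chain only if it has at least
#' two anchors, then prepend the longest qualifying leading context
#' (`G(0,3)-X(0,1)`, never overlapping a previously emitted motif) and append
#' `min(2, g_run)` trailing glycines. Scanning resumes after the emitted
#' motif, so motifs of one sequence are pairwise disjoint and sorted.
#'
#' @param sequence A single uppercase residue string.
#' @return A data frame with one row per motif: `start`, `end` (1-based,
#'   inclusive), `pattern` (the motif substring), `rg`, `rgg` (unit counts),
#'   `n_units`, and a list-column `anchors` holding the per-motif anchor
#'   table from [find_anchors()] (absolute coordinates).
#' @examples
#' find_gar_motifs("AARGRGAA")
#' find_gar_motifs("HRGRGRGRGRGRGRGRGRGRGG")  # leading H via the wildcard slot
#' @export
find_gar_motifs <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  anc <- find_anchors(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- nrow(anc)
  res <- list()
  prev_end <- 0L
  i <- 1L
  while (i <= n) {
    if (anc$r_pos[i] <= prev_end) { i <- i + 1L; next }
    j <- i
    while (j < n &&
           is_valid_gap(substr(sequence, anc$r_pos[j] + 1L,
                               anc$r_pos[j + 1L] - 1L)))
      j <- j + 1L
    if (j > i) {
      # leading context: the residue adjacent to R may be anything, up to
      # three further residues are taken while they are G; never beyond the
      # previous motif's end
      lo <- prev_end + 1L
      start <- anc$r_pos[i]
      p <- start - 1L
      if (p >= lo) {
        start <- p
        k <- p - 1L
        while (k >= lo && k >= anc$r_pos[i] - 4L && chars[k] == "G") {
          start <- k
          k <- k - 1L
        }
      }
      end <- anc$r_pos[j] + min(2L, anc$g_run[j])
      res[[length(res) + 1L]] <- list(start = start, end = end, idx = i:j)
      prev_end <- end
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(res) == 0L) {
    out <- data.frame(start = integer(), end = integer(),
                      pattern = character(), rg = integer(), rgg = integer(),
                      n_units = integer(), stringsAsFactors = FALSE)
    out$anchors <- list()
    return(out)
  }
  start <- vapply(res, `[[`, integer(1), "start")
  end <- vapply(res, `[[`, integer(1), "end")
  anchors <- lapply(res, function(m) anc[m$idx, , drop = FALSE])
  out <- data.frame(
    start = start, end = end,
    pattern = substring(sequence, start, end),
    rg = vapply(anchors, function(a) sum(a$class == "RG"), integer(1)),
    rgg = vapply(anchors, function(a) sum(a$class == "RGG"), integer(1)),
    n_units = vapply(anchors, nrow, integer(1)),
    stringsAsFactors = FALSE)
  out$anchors <- anchors
  out
}

#' Bracket motif spans inside the full sequence
#'
#' Inserts `[` before each motif start and `]` after each motif end, as in
#' the text report's sequence echo. Removing the brackets restores the input
#' sequence exactly.
#'
#' @param sequence The full residue string.
#' @param motifs A motif table for this sequence, as from
#'   [find_gar_motifs()] (only `start`/`end` are used).
#' @return The bracketed sequence string.
#' @examples
#' bracket_sequence("AARGRGAA", data.frame(start = 3L, end = 6L))
#' @export
bracket_sequence <- function(sequence, motifs) {
  if (nrow(motifs) == 0L) return(sequence)
  n <- nchar(sequence)
  if (any(motifs$start < 1L) || any(motifs$end > n) ||
      any(motifs$start > motifs$end))
    stop("motif coordinates outside the sequence", call. = FALSE)
  pieces <- character(0)
  pos <- 1L
  for (k in seq_len(nrow(motifs))) {
    pieces <- c(pieces,
                substr(sequence, pos, motifs$start[k] - 1L), "[",
                substr(sequence, motifs$start[k], motifs$end[k]), "]")
    pos <- motifs$end[k] + 1L
  }
  paste0(paste(pieces, collapse = ""), substr(sequence, pos, n))
}
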