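#' The GAR motif grammar
#'
#' A GAR motif is a maximal chain of at least two anchor units, where an
#' anchor unit is an arginine immediately followed by one or two glycines
#' (`R-G(1,2)`; one following G inside the motif makes an RG unit, two or more
#' an RGG unit). The residues strictly between two chained anchor arginines
#' must fit the gap grammar
#' `G(1,2) G(0,3) X(0,5) G(0,3) X(0,1)` (X = any residue), and the motif may
#' start with a leading context of up to three glycines plus one wildcard
#' residue (`G(0,3)-X(0,1)`) immediately before the first anchor.
#'
#' Consequences of the grammar (exposed here as read-only constants): at most
#' 14 residues may separate two chained anchor arginines, at most 6 of them
#' non-glycine, so poly-G tracts of up to 13 straight glycines are bridged;
#' the shortest possible motif is `RGRG` (4 residues).
#'
#' @return A list of grammar constants: `unit_g`, `lead_g`, `lead_x`, the five
#'   inter-anchor slots `gap`, `min_units`, `max_gap`, `max_gap_non_g` and
#'   `min_motif_length`.
#' @examples
#' gar_pattern()$max_gap
#' @export
gar_pattern <- function() {
  list(
    unit_g = c(1L, 2L),
    lead_g = c(0L, 3L),
    lead_x = c(0L, 1L),
    gap = list(g1 = c(1L, 2L), g2 = c(0L, 3L), x1 = c(0L, 5L),
               g3 = c(0L, 3L), x2 = c(0L, 1L)),
    min_units = 2L,
    max_gap = 14L,
    max_gap_non_g = 6L,
    min_motif_length = 4L
  )
}

# full-match of the inter-anchor gap grammar; PCRE backtracking performs a
# complete search over slot assignments, so a match exists iff some assignment
# of G{1,2} G{0,3} X{0,5} G{0,3} X{0,1} covers the segment
.gap_regex <- "^G{1,2}G{0,3}[A-Z]{0,5}G{0,3}[A-Z]{0,1}$"

#' Locate anchor units in a sequence
#'
#' Every arginine immediately followed by at least one glycine is an anchor;
#' an arginine followed by anything else is an ordinary residue (it can sit in
#' a wildcard slot of the gap grammar but never forms a unit). The G run is
#' the number of consecutive glycines directly after the R in the full
#' sequence.
#'
#' @param sequence A single uppercase residue string.
#' @return A data frame with one row per anchor, in sequence order:
#'   `r_pos` (1-based position of the R), `g_run` (length of the following
#'   G run), `class` (`"RG"` if `g_run == 1`, `"RGG"` if `g_run >= 2`).
#' @examples
#' find_anchors("RGRG")
#' find_anchors("RRGG")  # the first R is not an anchor
#' @export
find_anchors <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  m <- gregexpr("RG+", sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(r_pos = integer(), g_run = integer(),
                      class = character(), stringsAsFactors = FALSE))
  }
  r_pos <- as.integer(m)
  g_run <- attr(m, "match.length") - 1L
  data.frame(r_pos = r_pos, g_run = g_run,
             class = ifelse(g_run >= 2L, "RGG", "RG"),
             stringsAsFactors = FALSE)
}

#' Test a segment against the inter-anchor gap grammar
#'
#' `segment` is the residue string strictly between two anchor arginines.
#' Returns `TRUE` iff it full-matches `G(1,2) G(0,3) X(0,5) G(0,3) X(0,1)`
#' for some slot assignment (X matches any residue, including G).
#'
#' @param segment Character vector of candidate gap segments.
#' @return Logical vector.
#' @examples
#' is_valid_gap("G")                    # minimal gap: RGRG
#' is_valid_gap(strrep("G", 13))        # longest straight poly-G tract
#' is_valid_gap("GAAAAAAG")             # FALSE: 6 non-G cannot be placed
#' @export
is_valid_gap <- function(segment) {
  grepl(.gap_regex, segment, perl = TRUE)
}
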