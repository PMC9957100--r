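#' Round to one decimal, ties away from zero
#'
#' The report's 1-decimal values use half-away-from-zero rounding (so 0.05
#' becomes 0.1), applied once to the exact value.
#'
#' @param x Numeric vector.
#' @return `x` rounded to the nearest multiple of 0.1.
#' @export
round1 <- function(x) {
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Count RG and RGG units of a motif
#'
#' Each anchor is tallied once: RG when followed by exactly one motif-internal
#' glycine, RGG when followed by two or more. Classification uses the G run
#' inside the motif span, so the 2-glycine trailing cap never demotes a
#' terminal RGG unit.
#'
#' @param motif One row of a [find_gar_motifs()] table (a data frame or list
#'   with an `anchors` element).
#' @return Named integer vector `c(rg = , rgg = )`.
#' @export
classify_units <- function(motif) {
  a <- motif$anchors
  if (is.list(a) && !is.data.frame(a)) a <- a[[1L]]
  c(rg = sum(a$class == "RG"), rgg = sum(a$class == "RGG"))
}

#' Residue composition of a motif
#'
#' Counts glycines, arginines (anchored or bare) and all other ("else")
#' residues over the motif span. Else counts are keyed by residue letter in
#' order of first occurrence, matching the report layout. Bare arginines
#' count toward R, never toward else.
#'
#' @param pattern The motif residue string.
#' @return A list with `g`, `r` (integer counts) and `else_counts` (named
#'   integer vector, possibly empty).
#' @export
residue_composition <- function(pattern) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  other <- ch[!(ch %in% c("G", "R"))]
  else_counts <- if (length(other)) {
    tab <- table(factor(other, levels = unique(other)))
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  list(g = sum(ch == "G"), r = sum(ch == "R"), else_counts = else_counts)
}

#' Per-motif report statistics
#'
#' Computes the full per-motif report row: unit counts, else composition,
#' coverage of the motif in the polypeptide (`Total%`), the G/R ratio and the
#' percentages of G, R and other residues within the motif, each rounded to
#' one decimal with [round1()].
#'
#' @param motif One row of a [find_gar_motifs()] table.
#' @param full_length Length of the full polypeptide the motif came from;
#'   must be at least the motif length.
#' @return A list with `rg`, `rgg`, `else_counts`, `total_pct`, `g_to_r`,
#'   `g_pct`, `r_pct`, `non_gr_pct`.
#' @examples
#' m <- find_gar_motifs("RGRG")
#' compute_stats(m[1, ], full_length = 4L)
#' @export
compute_stats <- function(motif, full_length) {
  pattern <- motif$pattern
  len <- nchar(pattern)
  if (full_length < len)
    stop("full_length (", full_length, ") is shorter than the motif (",
         len, ")", call. = FALSE)
  units <- classify_units(motif)
  comp <- residue_composition(pattern)
  stopifnot(comp$r > 0L)  # motifs carry >= 2 anchors, so R is never absent
  list(
    rg = unname(units["rg"]),
    rgg = unname(units["rgg"]),
    else_counts = comp$else_counts,
    total_pct = round1(100 * len / full_length),
    g_to_r = round1(comp$g / comp$r),
    g_pct = round1(100 * comp$g / len),
    r_pct = round1(100 * comp$r / len),
    non_gr_pct = round1(100 * (len - comp$g - comp$r) / len)
  )
}

#' Format an else-composition vector as in the report tables
#'
#' `c(P = 1L, F = 5L)` becomes `"'P': 1, 'F': 5"`; an empty vector becomes
#' `""`.
#'
#' @param else_counts Named integer vector from [residue_composition()].
#' @return A single string.
#' @export
format_else <- function(else_counts) {
  if (length(else_counts) == 0L) return("")
  paste0("'", names(else_counts), "': ", else_counts, collapse = ", ")
}

# inverse of format_else; also accepts the compact "P:1;F:5" fixture encoding
parse_else <- function(x) {
  x <- trimws(x)
  if (is.na(x) || !nzchar(x)) return(stats::setNames(integer(0), character(0)))
  parts <- strsplit(x, if (grepl(";", x)) ";" else ",")[[1L]]
  parts <- trimws(parts)
  key <- gsub("[': ]", "", sub(":[^:]*$", "", parts))
  val <- as.integer(sub("^.*:", "", gsub("[' ]", "", parts)))
  stats::setNames(val, key)
}
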