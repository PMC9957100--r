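# Independent brute-force oracle for the motif grammar.
#
# Gap validity is decided by exhaustive enumeration of every slot assignment
# (a,b,c,d,e) of G{1,2} G{0,3} X{0,5} G{0,3} X{0,1}; motif assembly marks
# every anchor by a character scan, tests each adjacent anchor pair, takes
# maximal runs of chained anchors and applies the leading/trailing rules by
# enumeration. Shares no code with the package engine.

# per-length list of mandatory-G position sets, from the full slot enumeration
oracle_gap_masks <- local({
  seen <- vector("list", 14L)
  for (a in 1:2) for (b in 0:3) for (cc in 0:5) for (d in 0:3) for (e in 0:1) {
    L <- a + b + cc + d + e
    gpos <- c(seq_len(a + b), if (d > 0) a + b + cc + seq_len(d))
    key <- paste(gpos, collapse = ",")
    if (is.null(seen[[L]])) seen[[L]] <- list()
    if (!key %in% names(seen[[L]])) seen[[L]][[key]] <- gpos
  }
  lapply(seen, unname)
})

oracle_gap_ok <- function(segment) {
  L <- nchar(segment)
  if (L < 1L || L > 14L) return(FALSE)
  ch <- strsplit(segment, "", fixed = TRUE)[[1L]]
  for (gpos in oracle_gap_masks[[L]]) {
    if (all(ch[gpos] == "G")) return(TRUE)
  }
  FALSE
}

oracle_anchors <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  r_pos <- integer(0); g_run <- integer(0)
  for (i in seq_len(max(n - 1L, 0L))) {
    if (ch[i] == "R" && ch[i + 1L] == "G") {
      run <- 0L; k <- i + 1L
      while (k <= n && ch[k] == "G") { run <- run + 1L; k <- k + 1L }
      r_pos <- c(r_pos, i); g_run <- c(g_run, run)
    }
  }
  data.frame(r_pos = r_pos, g_run = g_run)
}

# longest leading-context length (<= 4) before position rpos, not reaching
# below lo: enumerate b in 0:3, e in 0:1 suffix shapes G^b X^e
oracle_lead_start <- function(ch, rpos, lo) {
  best <- rpos
  for (b in 0:3) for (e in 0:1) {
    L <- b + e
    s <- rpos - L
    if (L == 0L || s < lo) next
    gpart <- if (b > 0) ch[s:(s + b - 1L)] else character(0)
    if (all(gpart == "G") && s < best) best <- s
  }
  best
}

oracle_motifs <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  anc <- oracle_anchors(sequence)
  n <- nrow(anc)
  out <- data.frame(start = integer(), end = integer(),
                    rg = integer(), rgg = integer())
  prev_end <- 0L
  i <- 1L
  while (i <= n) {
    if (anc$r_pos[i] <= prev_end) { i <- i + 1L; next }
    j <- i
    while (j < n && oracle_gap_ok(substr(sequence, anc$r_pos[j] + 1L,
                                         anc$r_pos[j + 1L] - 1L)))
      j <- j + 1L
    if (j > i) {
      start <- oracle_lead_start(ch, anc$r_pos[i], prev_end + 1L)
      end <- anc$r_pos[j] + min(2L, anc$g_run[j])
      cls <- anc$g_run[i:j] >= 2L
      out <- rbind(out, data.frame(start = start, end = end,
                                   rg = sum(!cls), rgg = sum(cls)))
      prev_end <- end
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# random test sequence over a motif-prone alphabet
random_seq <- function(n) {
  paste(sample(c("G", "R", "A", "F", "S", "P", "D"), n, replace = TRUE,
               prob = c(0.35, 0.25, 0.08, 0.08, 0.08, 0.08, 0.08)),
        collapse = "")
}

expect_engine_equals_oracle <- function(sequence) {
  got <- find_gar_motifs(sequence)[, c("start", "end", "rg", "rgg")]
  want <- oracle_motifs(sequence)
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want, label = paste("engine on", sequence))
}
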