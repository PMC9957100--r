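test_that("an extracted motif string is re-found as one motif covering it", {
  ncl <- "GGRGGGRGGFGGRGGGRGGRGGFGGRGRGGFGGRGGFRGGRGG"
  m <- find_gar_motifs(ncl)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1L)
  expect_equal(m$end, nchar(ncl))
  expect_equal(m$rg, 1L)
  expect_equal(m$rgg, 9L)
})

test_that("an over-long inter-anchor segment splits the domain in two", {
  zf <- golden_rows("T2")
  syn <- make_synthetic_record(list(
    c("pad", "MKTEAS"),
    c("motif", zf$pattern[1]),
    c("spacer", "FGGGFKSPGGE"),
    c("motif", zf$pattern[2])), "zebrafish_fbl")
  m <- find_gar_motifs(syn$record$sequence)
  expect_equal(m$start, c(7L, 50L))
  expect_equal(m$end, c(38L, 79L))
  expect_equal(m[, c("start", "end")], syn$expected,
               ignore_attr = TRUE)
})

test_that("single anchors and anchor-free sequences give no motif", {
  expect_equal(nrow(find_gar_motifs("MARGGAAAA")), 0L)
  expect_equal(nrow(find_gar_motifs("ACDEFH")), 0L)
  expect_equal(nrow(find_gar_motifs("")), 0L)
})

test_that("leading context takes one wildcard plus up to three glycines", {
  m <- find_gar_motifs("HRGRGRGRGRGRGRGRGRGRGG")
  expect_equal(m$start, 1L)  # leading H via the X(0,1) slot
  expect_equal(m$end, 22L)

  # wildcard adjacent to R plus G run; stops at a non-G further out
  m <- find_gar_motifs("AAGGFRGRG")
  expect_equal(m$start, 3L)
  expect_equal(m$pattern, "GGFRGRG")

  # trailing glycines are capped at two even when the run continues
  m <- find_gar_motifs("ARGGGGARGGGG")
  expect_equal(m$pattern, "ARGGGGARGG")
  expect_equal(m$rgg, 2L)  # classification uses the run, not the cap
})

test_that("motif spans are bracketed and brackets strip cleanly", {
  s <- "AARGRGAA"
  expect_equal(bracket_sequence(s, data.frame(start = 3L, end = 6L)),
               "AA[RGRG]AA")
  # the engine itself also claims the adjacent residue via the wildcard slot
  m <- find_gar_motifs(s)
  expect_equal(bracket_sequence(s, m), "A[ARGRG]AA")
  expect_equal(bracket_sequence("AAAA", find_gar_motifs("AAAA")), "AAAA")

  s2 <- paste0("RGRG", strrep("A", 15), "RGGRGG")
  m2 <- find_gar_motifs(s2)
  expect_equal(nrow(m2), 2L)
  b <- bracket_sequence(s2, m2)
  expect_equal(gsub("[][]", "", b), s2)

  bad <- data.frame(start = 3L, end = 99L)
  expect_error(bracket_sequence(s, bad), "coordinates")
})

test_that("every golden motif string is idempotent under the engine", {
  g <- golden_rows("all")
  for (i in seq_len(nrow(g))) {
    m <- find_gar_motifs(g$pattern[i])
    expect_equal(nrow(m), 1L, label = paste("motif count for", g$label[i]))
    expect_equal(unname(unlist(m[, c("start", "end")])),
                 c(1L, nchar(g$pattern[i])),
                 label = paste("span for", g$label[i]))
  }
})

test_that("engine agrees with the brute-force oracle on random sequences", {
  set.seed(101)
  for (k in 1:300) {
    expect_engine_equals_oracle(random_seq(sample(10:200, 1)))
  }
})

test_that("inserting 15 non-G residues inside a motif splits it", {
  set.seed(7)
  for (k in 1:25) {
    m <- random_gar_motif(5, p_rgg = 0.5)
    anc <- find_anchors(m)
    cut <- anc$r_pos[4]  # inside the inter-anchor region between units 3 and 4
    s <- paste0(substr(m, 1, cut - 1), strrep("A", 15),
                substr(m, cut, nchar(m)))
    res <- find_gar_motifs(s)
    expect_equal(nrow(res), 2L)
    expect_true(res$end[1] < cut && res$start[2] > cut)
    expect_engine_equals_oracle(s)
  }
})

test_that("motifs per sequence are disjoint and ordered", {
  set.seed(202)
  for (k in 1:100) {
    m <- find_gar_motifs(random_seq(sample(30:150, 1)))
    if (nrow(m) < 2) next
    expect_true(all(diff(m$start) > 0))
    expect_true(all(m$start[-1] > m$end[-nrow(m)]))
  }
})
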