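test_that("CSV report has the fixed schema and formatted cells", {
  scan <- gar_scan(golden_records("T2"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_gar_csv(scan, f)
  lines <- readLines(f)
  expect_equal(lines[1],
    "Accession,Pattern,Position,RG,RGG,Else,Total%,G/R,G%,R%,Non-GR%")

  tab <- read_gar_csv(f)
  expect_equal(nrow(tab), 22L)
  expect_equal(tab$Position[1], "1..32")  # isolated strings scan from 1
  expect_equal(tab$Else[1], "'P': 1, 'F': 2, 'D': 1")
  expect_equal(tab$RG, as.character(scan$motifs$rg))
  # 1-decimal cells round-trip exactly as printed
  expect_equal(tab[["G/R"]], sprintf("%.1f", scan$motifs$g_to_r))
  expect_equal(tab[["Non-GR%"]], sprintf("%.1f", scan$motifs$non_gr_pct))
})

test_that("scan of motif-free records writes a header-only CSV", {
  scan <- gar_scan(gar_records("MKTEASLLPLA", "none"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_gar_csv(scan, f)
  expect_equal(length(readLines(f)), 1L)
})

test_that("text report brackets motifs and strips back to the input", {
  recs <- gar_records(c("AARGRGAA", "MKTEASLLPLA"), c("hit", "miss"))
  scan <- gar_scan(recs)
  f <- withr::local_tempfile(fileext = ".txt")
  write_gar_txt(scan, f)
  txt <- readLines(f)
  expect_true("A[ARGRG]AA" %in% txt)
  seq_lines <- txt[which(txt == "sequence:") + 1L]
  expect_equal(gsub("[][]", "", seq_lines), recs$sequence)
  expect_true(any(grepl("no GAR motif found", txt)))
  # batch totals: 1 of 2 records carries motifs
  expect_true(any(grepl("sequences with GAR motifs: 1 \\(50.0%\\)", txt)))
})

test_that("batch summary reproduces the published vertebrate tallies", {
  s2 <- summarize_batch(gar_scan(golden_records("T2")))
  expect_equal(s2$total_rg, 38L)
  expect_equal(s2$total_rgg, 210L)
  expect_equal(s2$n_sequences, 22L)
  expect_equal(s2$n_with_motifs, 22L)
  expect_equal(s2$pct_with_motifs, 100.0)

  s3 <- summarize_batch(gar_scan(golden_records("T3")))
  expect_equal(s3$total_rg, 112L)
  expect_equal(s3$total_rgg, 115L)

  # NCL orthologue motifs pool to 22 F
  t2 <- golden_rows("T2")
  ncl <- gar_records(t2$pattern[7:12], paste0("ncl", 1:6))
  expect_equal(summarize_batch(gar_scan(ncl))$total_non_gr[["F"]], 22L)
})

test_that("batch totals are invariant to record order", {
  t2 <- golden_rows("T2")
  set.seed(3)
  perm <- sample(nrow(t2))
  a <- summarize_batch(gar_scan(gar_records(t2$pattern, paste0("r", 1:22))))
  b <- summarize_batch(gar_scan(gar_records(t2$pattern[perm],
                                            paste0("r", 1:22))))
  expect_equal(a$total_rg, b$total_rg)
  expect_equal(a$total_rgg, b$total_rgg)
  expect_equal(a$total_non_gr, b$total_non_gr)
})

test_that("chart data gives the RG/RGG pie and pooled non-GR bar", {
  t2 <- golden_rows("T2")
  gar1 <- chart_data(gar_scan(gar_records(t2$pattern[13:22],
                                          paste0("g", 1:10))))
  expect_equal(gar1$bar[["F"]], 49L)
  fbl <- chart_data(gar_scan(gar_records(t2$pattern[1:6], paste0("f", 1:6))))
  expect_equal(fbl$bar[["F"]], 27L)
  expect_equal(sum(fbl$pie), 100)
  # descending counts, alphabetical ties
  expect_true(all(diff(fbl$bar) <= 0))

  single <- chart_data(gar_scan(gar_records("RGRG", "x")))
  expect_equal(single$pie, c(RG = 100.0, RGG = 0.0))
  expect_equal(length(single$bar), 0L)
})

test_that("chart JSON has pie percentages and bar pairs", {
  scan <- gar_scan(gar_records(c("RGRGG", "RGFRGG"), c("a", "b")))
  f <- withr::local_tempfile(fileext = ".json")
  write_chart_json(chart_data(scan), f)
  j <- jsonlite::read_json(f)
  expect_named(j, c("pie", "bar"))
  expect_equal(j$pie$RG + j$pie$RGG, 100)
  expect_equal(j$bar[[1]][[1]], "F")
  expect_equal(j$bar[[1]][[2]], 1L)
})
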