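---
title: "Finding and characterizing GAR motifs"
author: "garmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and characterizing GAR motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(garmotif)
```

## Background

Glycine- and arginine-rich (GAR) motifs — stretches of interleaved RG and RGG
repeats, often called RGG boxes — occur in many RNA-binding proteins. The
nucleolar proteins fibrillarin (FBL), nucleolin (NCL) and GAR1 carry
extra-long GAR domains (often >50 residues with more than 10 repeats); the
FET proteins (FUS, EWS, TAF15) and many hnRNPs carry shorter, scattered
motifs. The arginines in these regions are the main substrates of protein
arginine methyltransferases, and the motifs contribute multivalency for
protein/RNA interaction and liquid–liquid phase separation. Comparing such
motifs requires a consistent operational definition and a fixed set of
composition statistics; this package provides both.

## The motif grammar

The unit of the grammar is the **anchor**: an arginine immediately followed
by at least one glycine. An anchor whose motif-internal glycine run has
length one is an *RG unit*; length two or more makes an *RGG unit*. An
arginine not followed by glycine ("bare R") is never a unit — it can only
occupy a wildcard slot, counts toward the motif's R percentage, and never
appears in the else composition. This asymmetric treatment is forced by the
published report rows the package reproduces (e.g. the FUS motif
`RRGG...`, whose leading R is reported in R% but neither as a unit nor as an
"else" residue).

A **GAR motif** is a maximal chain of two or more anchors in which every
segment strictly between consecutive anchor arginines full-matches

```
G(1,2) · G(0,3) · X(0,5) · G(0,3) · X(0,1)
```

with X any residue (including G). Two consequences shape the motif's reach:
at most 14 residues, of which at most 6 non-glycine, may separate chained
anchors, and straight poly-G tracts of up to 13 glycines are bridged (the
literal grammar even admits 14 when the final wildcard is glycine; the
package implements the literal grammar and documents the off-by-one rather
than resolving it). Two slightly different formulations of this grammar
circulate, capping the middle glycine block at 2 or at 3; `garmotif`
implements the G(0,3) form, the only one that bridges the 13-glycine tract
observed in the human fibrillarin domain. A motif may begin with a leading
context `G(0,3)-X(0,1)` immediately before its first anchor — so one
arbitrary residue adjacent to the R, plus up to three glycines — and ends
with the last anchor's R followed by `min(2, run)` glycines. Unit
classification uses the run, not the cap, so a truncated terminal `RGGGG` is
still an RGG unit. The shortest motif is `RGRG`.

## Assembly algorithm

`find_gar_motifs()` works left to right: locate all anchors; seed a chain at
the leftmost unconsumed anchor; extend anchor-by-anchor while the
inter-anchor segment satisfies the gap grammar; keep chains of ≥2 anchors;
attach the longest qualifying leading context that does not overlap a
previously emitted motif; cap the trailing glycines; resume after the motif.
This makes motifs per sequence pairwise disjoint, ordered, and deterministic.
Gap validity is decided by a backtracking regular-expression full-match,
which is a complete search over slot assignments; the test suite checks it
against an independent oracle that enumerates all 384 slot tuples, and checks
the whole engine against a brute-force assembler on randomized sequences.

Greedy leftmost-maximal assembly is a genuine design choice: a globally
optimizing assembler could prefer different chain boundaries in contrived
inputs. The greedy rule reproduces every published motif span in the golden
fixtures and keeps output order stable, which is why it was chosen.

## Statistics and rounding

Per motif: RG/RGG unit counts; the else composition (non-G, non-R residues,
keyed in first-occurrence order); `Total%` = motif length / polypeptide
length × 100; `G/R` = glycine count / arginine count; and G%, R%, non-GR% of
the motif length. All 1-decimal values use `round1()`: half away from zero,
applied once to the exact value. The rounding mode of the original analyses
is not documented; half-away-from-zero is this package's documented choice.

The packaged golden fixtures (`golden_rows()`) transcribe 86 published
per-motif report rows: 22 vertebrate FBL/NCL/GAR1 motifs, 43 motifs of 16
human RG/RGG-repeat proteins, and 21 human-proteome long motifs. The golden
test suite reproduces every printed cell exactly — except nine cells, frozen
in `golden_discrepancies()`, where the published tables contradict their own
arithmetic: three motif strings are printed in two tables with two different
percentage values (only one of which can follow from the string), one row's
percentages sum to 100.3, and the remainder are double-rounding artifacts
(x.x45 printed as x.y). For those cells the suite requires agreement with
the exact arithmetic of the printed string instead. All batch tallies (38
RG/210 RGG over the vertebrate set; 112/115 over the human RG/RGG set;
pooled F counts of 27/22/49) reproduce exactly.

`Total%` and motif positions within real full-length proteins are only
reproducible with the full protein sequences, which are not shipped; the
fixtures are the isolated motif strings, so position checks use synthetic
constructs (below) and `Total%` is validated structurally (bounds, 100% on
full-cover strings).

## Long-motif census and classes

`filter_long_motifs()` keeps motifs with at least `min_units` RG+RGG units
(default 10, inclusive comparison — reports of "at least 10" and "more than
10" repeats both circulate, so the threshold is a flag). `gar_census()` adds
`units`, `richness` (`RGG_RICH` / `RG_RICH` / `BALANCED` by comparing the
two unit counts) and the classical tri/di-RGG class of the motif string:
`TRI_RGG` (`RGG(X0-4)RGG(X0-4)RGG`), `DI_RGG`, `TRI_RG`, `DI_RG`, tested in
that priority order because every tri instance contains a di instance.
Whether the historical classification allowed overlapping elements is not
recorded; elements here are non-overlapping, scanned left to right, with an
RGG element requiring ≥2 following glycines and an RG element exactly one.
Isoform collapsing in published proteome censuses was manual; the census
instead reports `identical_group`, the number of batch rows sharing an
identical motif string.

## Synthetic data

`random_gar_motif(n_units, p_rgg, gap_model, seed)` draws anchor classes
i.i.d. (RGG with probability `p_rgg`, default 0.5 — the two unit kinds are
roughly balanced across the golden sets taken together) and joins them with
segments sampled only from the gap grammar, filling wildcard slots from a
non-G/non-R alphabet so the drawn unit count and classes cannot be
perturbed. By construction each draw is a single motif covering its whole
string; the suite verifies this on 10,000 draws, and uses the generator for
splitting experiments (inserting 15 consecutive non-G residues into an
inter-anchor region must split a motif, never merge across it).

What the generator emulates is the *grammar*, not real proteins: real GAR
domains have strongly non-uniform else compositions (F-rich in nucleolar
proteins, P/D/S-rich elsewhere), positional preferences, and flanking
sequence. Passing the generator-based tests therefore demonstrates
engine/grammar correctness, not biological realism; the golden fixtures
carry the realism.

## Degenerate inputs and numerical choices

Empty FASTA, text before the first header, or empty sequences are
input-format errors naming the record; stop (`*`) and gap (`-`, `.`)
characters are stripped with a warning; non-standard residue letters (B, J,
O, U, X, Z) are retained and treated as ordinary non-G/non-R residues, since
the wildcard slots match any residue and rejection would block proteome
scans. Duplicate identifiers get `#2`, `#3`, ... suffixes. Scanning is on
the uppercased sequence. Sequences with no anchors, or a single anchor,
yield an empty motif table and a successful exit. A motif always contains
≥2 arginines, so the G/R ratio is always defined (asserted, not handled).

## Problem sizes

The default test run checks the engine against the brute-force oracle on
1,000 random sequences of length ≤200 over a motif-prone alphabet, plus
10,000 generator idempotence draws and the full 86-row golden suite; the
whole suite runs in well under a minute on one CPU. These sizes give each
property thousands of distinct gap segments and chain configurations while
keeping the suite quick to iterate.

## Known limitations

* Motif positions/coverage inside real proteins require the full sequences;
  only isolated motif strings are packaged.
* The FG/FGG repeat family is not modeled; only R-anchored units.
* The grammar is fixed (constants are exposed read-only via
  `gar_pattern()`); there is no fuzzy matching.
* Published proteome-wide gene/isoform counts are not reproduced — they
  depend on a specific proteome release that is not shipped.
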