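# garmotif

Detection and characterization of glycine- and arginine-rich (GAR) motifs in
protein sequences.

Many RNA-binding and nucleolar proteins — fibrillarin (FBL), nucleolin (NCL),
GAR1, the FET family (FUS, EWS, TAF15), numerous hnRNPs — carry low-complexity
regions built from arginine–glycine (RG) and arginine–glycine–glycine (RGG)
repeats. These "GAR" motifs (also called RGG boxes) are hotspots of arginine
methylation and drivers of protein/RNA interaction and liquid–liquid phase
separation. `garmotif` finds such motifs, reports the composition statistics
used to compare them, and supports proteome-scale censuses of the rare
extra-long motifs.

## The model

An **anchor unit** is an arginine immediately followed by at least one
glycine: exactly one following G makes an *RG unit*, two or more an *RGG
unit*. An arginine not followed by glycine is a "bare R" — an ordinary
residue. A **GAR motif** is a maximal chain of at least two anchors in which
the residue segment strictly between consecutive anchor arginines full-matches
the bounded gap grammar

```
G(1,2) · G(0,3) · X(0,5) · G(0,3) · X(0,1)        (X = any residue)
```

so at most 14 residues, at most 6 of them non-glycine, may separate chained
anchors; straight poly-G tracts of 13 glycines are bridged. The motif may
begin with a leading context `G(0,3)-X(0,1)` before the first anchor and ends
with the last anchor's R plus at most two glycines. The shortest motif is
`RGRG`.

Per motif the package reports: RG and RGG unit counts, the non-GR ("else")
residue spectrum, coverage of the polypeptide (`Total%`), the G/R ratio, and
the percentages of G, R and other residues (all 1-decimal). Batches get
pooled totals, an RG/RGG pie split and a non-GR bar distribution; the census
adds RG/RGG richness and classical tri/di-RGG class labels.

## Worked example

Scan the human fibrillarin GAR-domain string (one of the packaged golden
fixtures) as a single record:

```r
library(garmotif)
fbl <- golden_rows("T2")$pattern[6]   # 73-residue human FBL GAR domain
gar_scan(gar_records(fbl, "NP_001427.2"))
#> GAR motif scan: 1 record(s), 1 motif(s)
#>    accession start end rg rgg total_pct g_to_r g_pct r_pct non_gr_pct
#>  NP_001427.2     1  73  6   9       100    3.1  64.4  20.5       15.1
```

One motif covering the whole string: 6 RG + 9 RGG units, a G/R ratio of 3.1
(most arginines are flanked by several glycines), 64.4% glycine, 20.5%
arginine and 15.1% other residues (mostly phenylalanine, the typical
interrupting residue in nucleolar GAR domains).

Batch statistics over all 22 vertebrate FBL/NCL/GAR1 motif fixtures:

```r
summarize_batch(gar_scan(golden_records("T2")))
#> input sequences: 22
#> sequences with GAR motifs: 22 (100.0%)
#> total RG: 38
#> total RGG: 210
#> non-GR residues: 'F': 98, 'N': 20, 'P': 16, 'S': 12, 'D': 9, 'Q': 4, ...
```

A command-line wrapper lives at `inst/cli/garmotif.R`:

```sh
Rscript inst/cli/garmotif.R scan input.fasta --csv out.csv --txt out.txt
Rscript inst/cli/garmotif.R census proteome.fasta --threshold 10 --csv long.csv
```

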