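# mirweed

Small RNA sequencing analysis for miRNA discovery in herbicide-resistant
weeds, at desk scale and fully reproducible from code.

Non-target-site resistance (NTSR) to herbicides — everything beyond
mutations of the herbicide's target enzyme — is increasingly attributed to
gene-regulatory changes, and miRNAs are prime candidates. The motivating
study design compares one herbicide-**s**ensitive pool with three
**r**esistant pools of American sloughgrass (*Beckmannia syzigachne*),
sequences a small RNA library per pool, and asks which miRNAs differ
between the resistant and sensitive pools. `mirweed` implements that
analysis end to end for users who want to run, test, or simulate it:

1. **Read cleaning** (`trim_adapter()`, `clean_library()`) — 3' adapter
   removal (leftmost ≥8-nt adapter-prefix match, ≤1 mismatch), then a
   fixed-precedence filter cascade: mean base quality < 20 → contains N →
   shorter than 18 nt → longer than 30 nt → clean, with exact per-library
   accounting (`clean = total − low_quality − N − short − long`).
2. **Annotation** (`classify_tags()`, `identify_conserved()`) — unique
   tags are assigned to rRNA/tRNA/snRNA/snoRNA/miRNA/unannotated by
   exhaustive mismatch-limited (Hamming) matching against category
   reference sets; conserved miRNAs are mature-reference hits with ≤2
   mismatches, grouped into `bsy-miR…` families.
3. **Novel miRNA prediction** (`predict_novel()`) — unannotated tags are
   mapped to the transcriptome, candidate precursor windows are folded by
   a Zuker-style dynamic program under a simplified nearest-neighbor
   energy model, and candidates are kept when the hairpin satisfies
   MFE ≤ −20 kcal/mol, ≥16 miRNA/miRNA\* pairs, ≤4 bulges, and ≤4 nt
   duplex asymmetry (inclusive bounds).
4. **Target prediction** (`predict_targets()`) — gap-free miRNA:mRNA
   duplexes scored per position (match / G:U wobble = 0.5 / mismatch = 1)
   under five rules: ≤4 mismatches; no run of 3+ adjacent mismatches; ≤1
   mismatch at positions 1–9; none at 10–11; weighted penalty ≤2.5 over
   positions 1–12.
5. **Differential expression** (`tpm_normalize()`, `call_differential()`)
   — TPM = count / clean reads × 10⁶; zeros revised to 0.01 at comparison
   time; pairs with both values < 1 TPM excluded; fold change =
   log₂(R/S); Welch's t-test when replicates exist, with calls requiring
   p < 0.05 and ≥2-fold change.
6. **qPCR quantification** (`delta_delta_ct()`, `compare_groups()`) —
   2^−ΔΔCT relative expression against the mean of three reference genes
   (CAP, GAPDH, UBQ) and a calibrator group, with Welch significance
   calls.
7. **Synthetic data** (`make_transcriptome()`, `plant_hairpins()`,
   `simulate_libraries()`, `simulate_qpcr()`) — a generator that plants
   compliant hairpins, ~60% rRNA contamination, controlled filter
   failures, ≥2-fold differential miRNAs and qPCR plates, with ground
   truth for recovery tests.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; `mirna_de` and `rel_expr` results support
`tidy()`, `glance()`, and `autoplot()`.

## Worked example

```r
library(mirweed)
library(dplyr)

tr    <- make_transcriptome(40, c(400, 1500), gc = 0.56, seed = 11)
ph    <- plant_hairpins(tr, 10, seed = 12)       # 10 hairpins, 3 at 4-fold
refs  <- make_reference_sets(seed = 13)
fq    <- simulate_libraries(ph$truth, ph$transcripts, refs,
                            default_library_specs(n_reads = 1e5, seed = 14))

cl    <- lapply(seq_len(nrow(fq)), \(i) clean_library(fq$path[i], library = fq$library[i]))
stats <- bind_rows(lapply(cl, `[[`, "stats"))
stats
#>   library total_reads low_quality n_reads too_short too_long clean_reads
#> 1       S      100000         968      93      4998     1792       92149
#> 2      R1      100000        1030     112      4981     1841       92036
#> 3      R2      100000         990      81      4997     1803       92129
#> 4      R3      100000         991     115      4986     1785       92123

tags  <- collapse_unique(bind_rows(lapply(cl, \(x)
           tibble(library = x$stats$library, sequence = x$tags$sequence))))
ann   <- classify_tags(tags, refs)               # ~60% rRNA, Table-style output

un    <- ann$assignments |> filter(category == "unannotated")
novel <- predict_novel(un, ph$transcripts)       # recovers all 10 planted hairpins
novel |> select(name, mature_seq, mfe, paired, bulges, asymmetry) |> head(3)
#>   name            mature_seq              mfe     paired bulges asymmetry
#> 1 novel-bsy-miR-1 GGAAUCAGACCUCCAGCUCCGUG -112.80     23      0         0
#> 2 novel-bsy-miR-2 ACCCCUCCGAGGCGGGUCCA    -112.50     20      0         0
#> 3 novel-bsy-miR-3 CGUGUCCUGUUAUAAAAUUUAUAC -97.25     24      0         0
```

The cleaning table shows every read assigned to exactly one fate (the
row sums reproduce each library total exactly); the `novel` table lists
hairpin calls with their precursor MFE (kcal/mol) and duplex statistics,
all passing the four calling criteria. Differential calls then follow
from `tpm_normalize()` + `call_differential()` (the three planted 4-fold
miRNAs come back `up`/`down` with log₂ fold changes near ±2), and
`qpcr_table()` reproduces a validation-style table whose calibrator
column is identically 1.

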