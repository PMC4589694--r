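# amplimine

In silico PCR mining of GMO detection-method amplicons.

GMO control laboratories work with validated PCR assays — primer pairs,
usually with an internal TaqMan probe — classed by target specificity:
**event**-specific (a unique transgene/genome integration junction),
**construct**-specific (an artificial junction between construct elements),
**element**-specific (a single promoter/terminator/marker element) and
**taxon**-specific (an endogenous species gene). `amplimine` screens
nucleotide sequence collections with such a panel by in silico PCR and turns
the results into an annotated amplicon collection:

1. **Binding-site search** — every target window alignable end-to-end to a
   primer with ≤ *n* mismatches and ≤ *g* indels (IUPAC-aware; defaults
   n = 2, g = 2), found by an exact feasibility dynamic program.
2. **Pairing and extraction** — convergent site pairs on opposite strands
   with an outer span inside the product window (default 50–500 bp); products
   whose primer edits sum to more than the combined cap (default 2) are
   discarded, and product sequences are extracted reading
   forward-primer → reverse-primer.
3. **Probe verification** — both-strand local alignment (match +1,
   mismatch −2, gap open −2, extend −1), annotating each amplicon as
   `perfect` / `mismatched` / `not_found` / `no_probe`.
4. **Species and provenance annotation** from an offline record→species
   mapping, plus the dataset label of origin.
5. **Tab-delimited output** — a fixed 18-column table (`amplicon_columns()`).

Downstream, `dedup_identical()` groups 100%-identical amplicons,
`greedy_cluster()` builds a cd-hit-style non-redundant set (identity ≥ 0.9,
coverage ≥ 0.9 of both sequences), `build_matrix()` /
`summarize_detection()` compute per-dataset screening consistency (with a
strict perfect-match mode: 0 gaps and 0 mismatches in primers and probe),
and `candidate_events()` shortlists records consistent with observed
screening calls. A synthetic fixture generator (`generate_dataset()`) plants
primer/probe sites with controlled edit budgets so the whole pipeline is
testable offline; see the methods vignette
(`vignettes/amplicon-mining.Rmd`) for the model and design details.

## Worked example

```r
library(amplimine)

bundle <- generate_dataset(fixture_spec(seed = 1, n_transgenic = 3, n_plant = 3,
                                        n_patent = 2, redundancy = 3),
                           methods = synthetic_methods_panel())
amp <- scan_amplicons(bundle$records, bundle$methods,
                      species_map = bundle$species_map)
amp[1:4, c("record_id", "method_id", "strand", "start", "end",
           "product_length", "total_edits", "probe_status", "species")]
#>  record_id     method_id strand start end product_length total_edits probe_status      species
#>     TGN001 QT-EVE-SY-001      +    81 182            102           0      perfect     Zea mays
#>     TGN002 QL-EVE-SY-002      +    81 192            112           0     no_probe  Glycine max
#>     TGN002 QL-ELE-SY-002      +   743 861            119           0     no_probe  Glycine max
#>     TGN003 QT-EVE-SY-003      +    81 189            109           0      perfect Oryza sativa
```

Each row is one predicted product: its coordinates on the input record
(1-based, forward strand), per-primer edit counts summarised in
`total_edits`, and the probe verdict. Deduplication collapses the six
patent-like records (2 constructs × 3 near-identical copies) onto their
distinct sequences:

```r
dedup_identical(amp)
#> cluster_set (exact): 14 amplicons in 10 clusters
#>   sizes: min 1 / median 1 / max 3
```

The strict screening summary shows the dataset-class signature — GM-specific
assays silent on plant-genomic records, taxon assays silent on transgenic
records, and the event-specific 1:1 amplicon-to-record ratio:

```r
summ <- summarize_detection(build_matrix(amp, strict = TRUE),
                            bundle$records, bundle$methods)
summ[summ$amplicon_count > 0, ]
#>    dataset_label specificity methods_detecting_fraction records_detected_fraction amplicon_count record_count amplicons_per_record
#>  transgenic_like       event                       0.50                      1.00              3            3                    1
#>  transgenic_like   construct                       0.33                      0.33              1            1                    1
#>  transgenic_like     element                       0.25                      0.33              1            1                    1
#>       plant_like       taxon                       0.75                      1.00              3            3                    1
#>      patent_like       event                       0.33                      1.00              6            6                    1
```

## Command line

The same pipeline is scriptable via the installed `exec/amplimine` launcher:

```sh
amplimine synth  -o fixtures --seed 7
amplimine scan   -m methods.tsv -o amplicons.tab -d 50-500 -n 2 -g 2 \
                 tgn=fixtures/transgenic_like.fasta pln=fixtures/plant_like.fasta
amplimine cluster -t amplicons.tab -o nonredundant.fasta --report clusters.tsv
amplimine matrix  -t amplicons.tab -m methods.tsv -o summary.tsv \
                 tgn=fixtures/transgenic_like.fasta pln=fixtures/plant_like.fasta
```

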