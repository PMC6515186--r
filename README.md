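# aptastruct

Secondary-structure element analysis of single-stranded DNA aptamer pools.

Aptamer screens that skip iterative enrichment produce dozens of candidate
sequences whose *function* is easier to rationalize through their predicted
self-hybridized secondary structures than through their primary sequences.
`aptastruct` implements that structural comparison end to end:

1. **Library model** — seedable generation of the standard 69-mer design
   (fixed 14-nt 5' flank, 40-nt variable insert, fixed 15-nt 3' flank) with
   equibase or A-rich insert composition.
2. **Folding** — an exact maximum-pairing baseline folder (C++), an adapter
   for external thermodynamic DNA folding binaries (152 mM Na+, 4 mM Mg++,
   23 °C, 5% suboptimality window), and a connectivity-table directory
   engine for injecting any other folder's output.
3. **Seven-letter decomposition** — every base of a structure is labelled as
   single-stranded segment (`S`), hairpin stem (`H`), hairpin loop (`L`),
   internal loop (`I`), bulge (`G`), duplex (`D`) or multi-branched loop
   (`M`); structures sharing identical element counts form families.
4. **Positional scoring** — per-position element frequencies,
   dominant-vs-suboptimal difference maps, and a pseudocount-smoothed
   position-specific score matrix against a random background.
5. **Multiple structural string alignment** — progressive alignment of the
   structure strings (identity substitution, affine gaps, neighbor-joining
   guide tree), fully deterministic.
6. **Consensus domains** — alignment columns are classified
   gap / consensus / non-gap; maximal consensus runs are domains with
   per-sequence membership, conservation, fixed-flank content, and
   projections back onto ungapped base coordinates.

## Worked example

```r
library(aptastruct)

lib <- generate_library(equibase_design(), 4, seed = 11)
lib[[1]]$sequence
#> "GGGACAGGGCTAGCGCTCCACGACCGAATTGGCGCTGGCGGCCGTGGCATGCGCGAGGCAAAGCTTCCG"

folds <- fold_population(lib, folding_conditions(), baseline_engine())
ann   <- annotate_population(folds, dominant_only = TRUE)
to_ss_string(ann[[1]])
#> "DDDGDGDDDDDDDGDDDDDDDDGHHHLLLHHHDDGDDDGDDDDGDDDDGDGDDDDDDGHLLLHDDDDDS"
ann[[1]]$count_vector
#>  S  H  L  I  G  D  M
#>  1  2  2  0 10 11  1

aln <- progressive_align(vapply(ann, to_ss_string, ""))
aln
#> multiple_alignment: 4 rows x 86 columns
domain_stats(aln, segment_regions(classify_columns(aln)))
#> 8 consensus domains; 7.75 domains per sequence; 81.5% of SS$ in domains
```

For a single call that runs every stage and writes all tables (structure
table, frequency/difference/score matrices, alignments, region tables, 1D
track) reproducibly to disk, see `run_pipeline()`:

```r
rep <- run_pipeline(pipeline_config(seed = 1, engine = baseline_engine()))
```

`vignette("aptastruct-methods")` documents the model, every default
parameter, and the rationale for each under-determined design choice.

## Testing

```r
testthat::test_dir("tests/testthat", package = "aptastruct",
                   load_package = "installed")
```

The suite is property-based where possible: the baseline folder is checked
against exhaustive search, the annotator against an independent
loop-decomposition oracle, the aligner against brute-force path enumeration,
and the domain machinery against structures *planted* with known element
counts (`planted_spec()` / `plant_structure()`).

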