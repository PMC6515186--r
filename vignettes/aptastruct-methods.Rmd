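---
title: "Methods: structural decomposition and consensus-domain analysis of ssDNA pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural decomposition and consensus-domain analysis of ssDNA pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptastruct)
```

This vignette documents the model, the algorithmic choices, and the default
parameters behind every stage of the package, in the order the pipeline runs
them. Where a published convention under-determines an implementation detail,
the choice made here is stated explicitly.

## 1. The screening library model

A candidate molecule is a 69-nt single-stranded DNA: a fixed 14-nt 5' flank
(`GGGACAGGGCTAGC`), a 40-nt variable insert, and a fixed 15-nt 3' flank
(`GAGGCAAAGCTTCCG`). Two insert compositions are built in:

```{r}
equibase_design()$composition
arich_design()$composition
```

`generate_library()` samples the insert bases i.i.d. from the design
composition, seeded; fixed flanks are emitted verbatim. The generator is a
*stand-in* for a real combinatorial selection: real selected pools carry
sequence correlations that i.i.d. sampling cannot reproduce, so statistics
computed on generated "candidate" panels are approximations of what a real
selected panel would give, while generated *background* pools are exactly the
null model they are meant to be.

## 2. Folding

`folding_conditions()` records the buffer used throughout: 152 mM Na+, 4 mM
Mg++, 23 °C, and a 5% suboptimality window. Two engines implement
`engine_fold()`:

* `baseline_engine()` — an exact maximum-pairing folder (Nussinov dynamic
  program, C++) over Watson–Crick plus G·T wobble pairs with a minimum
  hairpin loop of 3 nt. Its "energy" is the negated pair count. It exists to
  make the pipeline self-contained and property-testable; it is not a
  thermodynamic model.
* `vienna_engine()` — an adapter for external thermodynamic folding binaries
  with DNA parameters. Divalent magnesium is folded into an effective
  monovalent concentration, `(Na_mM + 120 * sqrt(Mg_mM)) / 1000` M, a
  standard empirical equivalence for helix stability. Suboptimal structures
  are enumerated within the energy window and re-filtered exactly by
  `select_suboptimal()`: a structure is kept when
  `|dG - dG1| <= window * |dG1|`, where `dG1` is the dominant (lowest)
  energy. Structures are ranked by energy, then pair count, then
  lexicographic dot-bracket, and relabelled `S1..Sn` so that ranking is
  deterministic under ties.

`ct_dir_engine()` serves pre-computed connectivity-table files, so output
from any external folder can be injected without code changes.

## 3. The seven-letter structural alphabet

`annotate_structure()` decomposes a pseudoknot-free base-pair set into seven
secondary structure elements and writes one letter per base:

| letter | element |
|---|---|
| `S` | single-stranded (exterior) segment |
| `H` | hairpin stem (helix closing a hairpin loop) |
| `L` | hairpin loop |
| `I` | internal loop |
| `G` | bulge |
| `D` | duplex (helix *not* closing a hairpin loop) |
| `M` | multi-branched loop |

A maximal stack of pairs is one helix; the loop at its inner end determines
the helix letter. A helix whose loop contains no further helix is a hairpin
stem (`H`); any other helix is a duplex (`D`), and its loop is classified by
its branch count and unpaired-run geometry (`I`, `G`, or `M`). This "helix
letter follows its loop" rule is the open design decision of the
decomposition; it makes `H == L` and `D == I + G + M` identities that the
planted-structure generator and the tests rely on. A multi-branched loop may
contain zero unpaired bases, in which case it is recorded as an element with
an empty span.

```{r}
ann <- annotate_structure(parse_dotbracket(".((((...(....).((...))..))))."))
ann$ss_string
ann$count_vector
```

Structures sharing an identical 7-element count vector form a *family*
(`assign_families()`; a family needs at least two members).

## 4. Positional scoring

`compute_frequencies()` turns a set of equal-length structure strings into a
7 × L frequency matrix; `delta_sse()` reports dominant-only minus
dominant-plus-suboptimal frequencies in percentage points. `compute_pssm()`
scores candidate structure letters against a background:

* background probabilities `mu = (c_bg + alpha) / (N_bg + 7 alpha)`,
* smoothed foreground probabilities
  `theta = (7 alpha mu + c) / (7 alpha + N)`,
* weight `W = f log2(theta / mu)` with raw frequency `f = c / N`,
* per-position information `H_j = max(0, log2 7 - sum_k f log2(1 / mu))`,
* score `S = H_j * W`, plus a display variant `Dsp = H_j * log2(theta / mu)`
  that is negative for letters absent from the foreground.

`alpha = 1` is the default pseudocount. The formulas are a reconstruction of
the common information-content × log-odds design for small foregrounds; the
S ≡ 0 identity when foreground frequencies equal the background (as
`alpha` → 0) is enforced by tests.

## 5. Multiple structural string alignment

`progressive_align()` aligns structure strings over the seven-letter
alphabet with an identity substitution scheme — match 10, mismatch 0, gap
open 10, gap extend 0.2 (a gap of length L costs `10 + 0.2 L`) — chosen as
ClustalW-like magnitudes with an identity matrix, since no substitution
theory exists for structural letters. Pairwise distances
`d = 1 - identity` from global affine-gap (Gotoh) alignments feed a
neighbor-joining guide tree; profiles are merged leaf-to-root
(profile–profile affine alignment, "once a gap, always a gap"). All ties are
broken deterministically: diagonal over gap moves in tracebacks, and
lexicographically smallest label pair in the guide tree, so a fixed input
yields a byte-identical alignment.

## 6. Consensus domains

`classify_columns()` labels each alignment column, in priority order: *gap*
(gap fraction ≥ 50%), else *consensus* (one letter reaches ≥ 50% of **all**
rows, gaps included in the denominator), else *non-gap*. Maximal runs of a
class form regions (`segment_regions()`); consensus runs are the consensus
domains. A row *contains* a domain when it matches the column consensus
letter in ≥ 50% of the domain's columns. This membership rule is a
deliberate, documented choice: published per-sequence domain averages
constrain but do not uniquely determine the rule, and the 50%-of-columns
criterion is the simplest one consistent with them. `domain_stats()` reports
per-domain lengths, conservation, frequency, and the fraction of domain
bases that fall in the fixed flanks (positions 1–14 and 55–69 by default);
`project_domains()` maps domains back to ungapped base coordinates,
yielding per-base inclusion ratios, inter-domain distances, and per-domain
base loss (gaps inside domain columns).

## 7. End-to-end runs and problem sizes

`run_pipeline()` chains every stage for a foreground (given as FASTA or
generated) and a generated background, writing all tables under
`out_dir`. Reruns with the same configuration are byte-identical; the seed
and a configuration hash are stamped into every artifact header. The default
background of 1000 sequences is subsampled (seeded) to `max_align = 250`
rows before alignment; all-against-all distances are quadratic in row count,
and 250 rows keep a run within minutes on one CPU while leaving domain
statistics stable. These sizes are package defaults, not scientific
constants, and can be raised freely.

```{r}
cfg <- pipeline_config(n_foreground = 6, n_background = 12, seed = 42,
                       engine = baseline_engine())
rep <- suppressMessages(run_pipeline(cfg))
rep
```

## 8. Planted structures as ground truth

`planted_spec()` + `plant_structure()` generate a base-pair set (and a
Watson–Crick-compatible sequence) whose decomposition has *exactly* a
requested element-count vector, after validating realizability
(`H == L`, `D == I + G + M`, branch and length constraints). The test suite
uses planted structures as ground truth for the annotator, the aligner and
the domain machinery — including recovering a hairpin planted at bases
55–67 of every member of a synthetic population as a consensus domain.
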