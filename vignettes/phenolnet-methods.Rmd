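---
title: "Methods: multilayer regulatory networks for berry phenylpropanoid pathways"
author: "phenolnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilayer regulatory networks for berry phenylpropanoid pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolnet)
```

# The problem and the approach

Secondary metabolism in developing fruit — the phenylpropanoid, flavonoid
and stilbene branches in grape berry being the motivating case — is
regulated by an interplay of transcription factors, miRNAs and long
non-coding RNAs acting on large, partly tandem-duplicated enzyme gene
families. No single data layer resolves this: co-expression alone cannot
separate direct regulators from co-regulated bystanders, and sequence
features alone (promoter elements, miRNA complementarity, genomic
adjacency) carry no condition information. `phenolnet` operationalises
the standard integrative strategy as one tested pipeline:

1. **Signed co-expression network (GCN).** Genes-by-samples abundances
   from a multi-cultivar developmental series are correlated (Pearson)
   and thresholded at a hard cutoff on `|r|`, keeping the sign. The
   guilt-by-association premise is that genes co-varying across berry
   development share regulation; negative edges mark the antagonism
   between ripening-specific and early-development gene sets.
2. **lncRNA co-location layer.** Candidate lncRNA-gene regulatory pairs
   require both genomic proximity (interval intersection within a
   flanking window of the lncRNA, default 100 kb) and strong
   co-expression (`|r|` above the same cutoff). lncRNAs are classified
   antisense (opposite-strand overlap with a gene), intergenic (no
   overlap), or sense-overlapping.
3. **miRNA target layer.** Plant miRNAs silence targets through
   near-perfect complementarity. Each miRNA is slid over every
   transcript window and scored with a cumulative expectation penalty:
   0 per Watson-Crick pair, 0.5 per G:U wobble, 1 per mismatch, doubled
   inside the core region (miRNA positions 2-13), reported at
   expectation ≤ 3.
4. **Promoter CRE layer.** Promoters (default 2 kb upstream) are
   scanned for IUPAC-degenerate TF-binding motifs on both strands; motif
   presence is tested per co-expression module with a one-sided
   hypergeometric test and Benjamini-Hochberg correction.
5. **Integration.** All layers merge into one typed graph
   (enzyme genes, TFs, lncRNAs, miRNAs; five edge types), from which
   pathway-focused subnetworks, modules and degree-centrality reports
   are derived. High-degree regulators attached to a pathway are the
   analysis's hub/"switch" candidates.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `pcc_threshold` | 0.8 | — | Hard cutoff on `|r|`, strict inequality; edges need `|r| > 0.8`, so `r = 0.8` exactly is excluded. |
| `tf_pcc_threshold` | = `pcc_threshold` | — | TF-gene edges may in principle deserve their own stringency; exposed separately, defaulting to the global value. |
| `transform` | `log2(x+1)` | log2 abundance | Correlating raw RNA-Seq-like abundances lets a few high-expression stages dominate; log transform is the field's default. Configurable to `raw`. |
| `window_bp` | 100,000 | bp | The co-location window flanking the lncRNA interval. Reports of antisense pairs sometimes use tighter windows (e.g. 50 kb); the window is a single exposed parameter rather than a per-class constant. |
| `mismatch_penalty`, `wobble_penalty` | 1, 0.5 | score | Classical plant miRNA target scoring; G:U wobbles are tolerated at half weight. |
| `core_start`, `core_end`, `core_multiplier` | 2, 13, 2 | miRNA positions | Seed-proximal pairing matters most for plant miRNA cleavage; penalties there are doubled. |
| `max_expectation` | 3 | score | Reporting cutoff; per-(miRNA, gene) minima are flagged. |
| `promoter_length` | 2,000 | bp | Upstream window per gene; truncated with a warning at chromosome edges. |
| `min_module_size` | 3 | genes | Modules smaller than this are not enrichment-tested (a 1-2 gene "module" cannot carry a meaningful hypergeometric signal). |
| `module_method` | `components` | — | Positive-edge connected components; `greedy` modularity on `|r|` as an alternative. |

The miRNA scheme is *psRNATarget-like*: the classical penalty constants
in ungapped mode, with every constant exposed. It is not a byte-level
reproduction of any external server's scores — bulge/gapped alignment
and target-site accessibility energies are deliberately out of scope, in
exchange for exactly reproducible integer/half-integer scores that an
independent rescoring oracle can verify.

# What the synthetic generator emulates — and what it does not

The generator reproduces the *structure* the analysis assumes, not the
biology of any real genome:

* **Expression**: a 5-cultivar × 4-stage design. Planted modules follow
  stage templates on a 0-1 scale — `ripening_up` (a logistic rise at the
  mid-development pivot, the veraison-like switch), its mirror
  `early_up`, and an orthogonal `mid_peak` — scaled to an amplitude of 4
  log2 units around a baseline of 5, plus i.i.d. Gaussian log-scale
  noise. Abundances are emitted as `2^z − 1`, so the default
  `log2(x+1)` correlation recovers the planted structure exactly at
  zero noise. `within_module_r < 1` adds gene-specific variance
  calibrated so the expected pairwise correlation equals the target.
  The study-condition default noise is 20% of the amplitude
  (`noise_sd = 0.8`).
* **Genome**: a tandem cluster of nine same-strand 2-kb paralogs with
  5-kb gaps and an intergenic lncRNA 20 kb upstream (the chromosome-10
  stilbene-synthase-array motif), plus an antisense lncRNA overlapping a
  gene on the opposite strand; remaining genes spaced on a filler
  chromosome. Sequences are uniform-random A/C/G/T.
* **Promoters**: uniform-random backgrounds with the motif
  rejection-scrubbed from non-planted promoters (both strands), so the
  planted fraction is exact. Fractional counts round half up
  (`n = 7, fraction = 0.5` plants 4).
* **miRNA pairs**: reverse complements of real transcript windows with
  exactly the requested number of mismatches and wobbles at recorded
  positions; the truth expectation is computed arithmetically from the
  recorded positions, independent of the scoring code it validates.

Not emulated: realistic base composition and repeat structure, read-level
noise, isoforms, mappability artifacts, batch effects between cultivars,
or lncRNA discovery itself (lncRNA coordinates are an *input* layer, as
they come from an external prediction catalog in practice). Passing on
synthetic data therefore demonstrates algorithmic correctness and
recoverability of planted structure under controlled noise — not
performance on real RNA-Seq compendia.

The end-to-end fixture (`simulate_study()`) uses noise at 10% of the
amplitude, emulating the strong co-regulation the co-location layer is
designed to detect (a tandem array whose members and adjacent lncRNA are
tightly co-expressed); the module-recovery benchmark keeps the harsher
20% default.

# Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally; GFF3
  (1-based inclusive) and BED (0-based half-open) are converted on
  parsing and round-trip exactly. A consequence worth stating: with a
  100,000-bp window, a gene whose gap from the lncRNA is *exactly*
  100,000 bp is excluded (half-open intersection), 99,999 bp is
  included.
* **Distance** is the gap between closest interval ends, 0 on overlap;
  proximity ignores strand (strand matters only for classification).
* **Missing values**: correlations are pairwise-complete with a minimum
  of 3 shared finite samples, otherwise `NA` (never an edge);
  zero-variance genes are flagged and excluded from edges. No
  multiple-testing control is applied to correlations — the method uses
  a hard threshold, not p-values.
* **Dynamic-gene pre-filter**: the default style of use is an explicit
  curated gene list (as when an analysis restricts to a pathway set);
  stage-mean fold-change and CV rules are provided as alternatives. The
  package makes no claim to reproduce any particular published
  differential-expression selection, whose criteria are not public.
* **Module detection**: published figures of this kind typically
  delineate clusters by eye; the package substitutes a reproducible
  rule — connected components of the positive-edge backbone — and does
  not claim its labels match any manually drawn cluster. Negative edges
  never join modules; they are reported as between-module links.
  Labels are deterministic: modules are numbered by lexicographically
  smallest member; ties in greedy modularity are fixed by the recorded
  seed.
* **TF edge direction**: co-expression is symmetric, but edges with
  exactly one TF endpoint are re-typed `tf_coexpression` and directed
  TF → target for regulator-semantics readability; the `directed` flag
  keeps the undirected view recoverable. TF-TF pairs stay undirected.
* **Ties in duplex scoring**: all equally scoring windows are reported;
  the per-pair minimum flag goes to the smallest window start.
* **Enrichment** uses motif *presence* (≥ 1 hit), not hit counts,
  matching presence-style promoter annotation; the test is one-sided
  hypergeometric with BH correction across all (module, motif) pairs.
* **Determinism**: every simulation takes a seed and restores the
  caller's RNG; the pipeline fans one global seed out to stages by
  fixed offsets, and two runs from the same seed are byte-identical,
  manifest included (no timestamps; relative paths only).

# Problem sizes used in the shipped checks

The test-suite and the acceptance script work at desk scale, chosen so
the full suite runs in well under a minute: random matrices up to
50 genes × 24 samples against a brute-force Pearson oracle; 20
simulation seeds for module recovery (3 × 10-gene modules, 30
background genes) and for planted-edge recovery; up to 200 features for
exhaustive interval checking; all 4,096 hexamers for motif-matching
enumeration; 1,000 random perturbations for score monotonicity; and two
full pipeline runs on a ~60-gene study for the byte-identity check.

# Known limitations

* Correlation thresholding yields no edge-wise error control; the
  threshold is a stated convention, not an inferred quantity.
* The miRNA scorer is ungapped: targets requiring bulges are invisible
  to it, and scores are not comparable to energy-based methods.
* Hypergeometric enrichment treats promoters as exchangeable; promoter
  length truncation and compositional bias are not modelled.
* Co-location is a candidate filter, not mechanism inference: decoy,
  guide or scaffold roles of a lncRNA cannot be distinguished from
  these data.
* With `components` as the module rule, a single spurious strong
  positive edge can merge two modules; the greedy-modularity option is
  more robust on dense noisy graphs but less interpretable.
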