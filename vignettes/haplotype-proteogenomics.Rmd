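---
title: "Haplotype-aware proteogenomics with haplopept: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-aware proteogenomics with haplopept}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopept)
```

## The model

Alleles of common variants co-occur nonrandomly (linkage disequilibrium),
so a protein-coding gene carries a small set of *haplotypes*, each encoding
one protein sequence. `haplopept` represents a haplotype as a set of
length-preserving amino acid substitutions (`posREF>ALT`, 1-based on the
parent protein) plus a population frequency. Indels and stop-gain/loss
variants are deliberately out of scope: the haplotype sequence always has
the parent's length, which is what makes residue-level bookkeeping simple —
every haplotype peptide span projects positionally onto reference
coordinates.

The pipeline asks three questions of such a search space:

1. **What can be seen?** Fully tryptic digestion with missed cleavages
   defines the peptide universe; classification assigns each unique peptide
   a variant class and a specificity class; residue coverage partitions the
   proteome.
2. **Which substitutions are reachable?** A substitution is discoverable
   only through peptides that were not *downgraded* below the occurrence's
   own substitution burden (see below), yielding the
   single-only/multi-only/either/not-discoverable stratification.
3. **Can a claimed match be trusted?** PSM-level quality control: spectrum
   angular similarity against a prediction, calibrated retention-time
   deviation, and target-decoy q-values.

### The downgrade rule

A peptide string may occur on many database sequences with different
substitution content. Its variant class is the **minimum** burden over all
occurrences: a peptide that is multivariant on one haplotype but matches a
reference elsewhere exactly is canonical; multivariant on one haplotype and
single-variant on another gives single-variant. Substitutions sitting in an
occurrence whose burden exceeds the peptide's class are *not* discoverable
through that peptide — identifying the peptide would not prove the
substitution. This rule is implemented once (`classify_peptides`) and
re-used by discoverability, coverage and the identified-substitution
summaries, so the same semantics apply everywhere.

### Specificity

Specificity is defined over *genes*, not accessions: `nonspecific` peptides
map to products of more than one gene, `protein_specific` peptides to
several records of one gene (e.g. reference plus a haplotype), and
`proteoform_specific` peptides to exactly one record. Contaminants carry no
gene annotation; each contaminant accession acts as its own gene unit, so a
peptide shared with a contaminant is nonspecific. Contaminant occurrences
never carry substitutions, and peptides matching contaminants are removed
from the confident PSM subset before coverage summaries.

### Coverage partition

On each reference protein, a residue is `variant_mapped` if at least one
non-downgraded, in-range peptide whose occurrence contains a substitution
covers it (haplotype spans projected onto the reference); `canonical_only`
if it is covered but only by substitution-free peptides; `not_discoverable`
otherwise. The three classes sum to 100% per protein by construction, and
aggregates are residue-weighted. A residue covered by a canonical peptide
*and* by a downgraded variant occurrence counts as `canonical_only`: it is
observable, just not informative about variation. Nonspecific peptides
contribute coverage to every gene they map to; this double-counting is the
standard shared-peptide caveat and is reported, not resolved.

### Quality control

Observed peaks are matched to predicted peaks when their m/z differ by at
most 10 ppm **relative to the predicted m/z** (the prediction is the
hypothesis under test; the alternative denominator changes nothing at these
tolerances). Assignment is greedy one-to-one by ascending ppm difference,
ties broken by lower predicted then lower observed m/z; exact ppm ties are
a measure-zero event in floating point, so the tie-break only pins down
determinism. Matched pairs whose predicted intensity is missing form the
"missing prediction" category and are excluded from the intensity vectors.
The similarity of the matched vectors `M`, `P` is

\[ C(M,P) = \frac{\sum_i m_i p_i}{\sqrt{\sum_i m_i^2}\sqrt{\sum_i p_i^2}},
\qquad A(M,P) = 1 - \frac{\arccos C}{\pi} . \]

For nonnegative intensities `A` lies in `[0.5, 1]`; it is symmetric and
invariant to positive rescaling, which is also why the median-intensity
scaling of the observed spectrum (applied for mirror plots and before
similarity computation) cannot change `A`. With no matched peak the
similarity is undefined and reported as `NA`, never as 0. The sums run over
matched peaks only; zero-padding unmatched predicted peaks would change the
statistic and is not done.

Retention-time deviation centers and scales the observed and predicted
series by the mean and standard deviation of a calibration set — the PSMs
passing the FDR threshold — and reports `|z_obs − z_pred|`. Target-decoy
FDR at score `s` is `#decoys ≥ s / #targets ≥ s`; the q-value is the
minimum FDR over thresholds at or below the PSM's score, capped at 1, and
the confident subset is targets with q-value strictly below the threshold.
The simple estimator (no `+1` correction) is the default because the
reference workflow delegates error estimation to an external rescorer; the
conservative `(#decoys+1)/#targets` variant is available via
`estimator = "plus_one"`.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `max_missed` | 2 | cleavages | standard tryptic search setting |
| `length_range` | 8–40 | residues | observable tryptic peptide window |
| cleavage rule | `[KR]` not before P | — | common search-engine default; `strict_kr` switch disables the proline exception |
| `tolerance_ppm` | 10 | ppm | high-resolution fragment matching |
| `fdr_threshold` | 0.01 | — | 1% PSM-level FDR |
| `min_allele_frequency` | 0.01 | proportion | common variation only |

Digestion treats I and L as distinct residues (sequences are compared
literally), never clips the initiator methionine, and excludes semi-tryptic
peptides. Translated stop symbols (`*`) are removed from input sequences
and the removal positions recorded as junctions; any peptide spanning a
junction is excluded, as are peptides containing non-standard residues
(X, B, Z, U) — the record itself is kept.

## What the synthetic generator emulates

`generate_proteome()` is a stated world, not a tuning knob:

* Sequences are uniform over the 20 residues with K and R boosted to 10%
  each, so tryptic fragments have realistic lengths and the 8–40 window is
  well populated.
* Haplotypes are generated directly in phased form (the pipeline consumes
  phased haplotypes; genotype phasing is upstream of its scope), with
  frequencies drawn from a Beta distribution, floored at
  `min_allele_frequency`, and jointly capped so the reference haplotype
  keeps positive frequency; per protein, haplotype plus reference
  frequencies sum to 1.
* Planted pairs rewrite a short region into a clean tryptic fragment
  (preceded by K, terminated by R, no internal K/R, 14–26 residues) and
  place two substitutions inside it on one dedicated haplotype. By
  construction any tryptic peptide containing either substitution contains
  both, so each pair contributes exactly one multivariant peptide and two
  `multi_only` substitutions to the manifest — the planted count of
  substitutions is therefore twice the planted peptide count.
* A configurable fraction of background substitutions replaces a K/R,
  destroying a cleavage site; alternative alleles are never K, R or P, so
  substitutions destroy but never create sites. This keeps the planted
  guarantees exact while still exercising the cleavage-site-loss path.
* Simulated true PSMs are the predicted spectra of their own peptides with
  log-normal intensity noise, m/z jitter inside the matching tolerance, and
  spurious peaks. Planted false matches are labeled decoys and pair a
  spectrum with the reversed-but-terminal permutation of a different
  peptide; because a search engine reports the *best* random match — which
  shares peaks by selection — a minority of the assigned peptide's
  predicted ions is planted into the spectrum with unrelated intensities.
  Without this selection effect a false match would typically share 0–1
  peaks, and a single matched peak makes the cosine trivially 1, inverting
  the intended similarity ordering.

What it does **not** emulate: real fragmentation physics, isotope
envelopes, chimeric spectra, homologous gene families (nonspecific peptides
arise only by chance string collisions), realistic variant density (the
default world is far denser in variants per protein than a human proteome),
or substitutions with masses coinciding with modifications. A green test
therefore establishes the correctness of the bookkeeping — digestion,
classification, coverage arithmetic, FDR machinery — not field performance
on real spectra.

The bundled predictor (`toy_predictor()`) is a deterministic stand-in for
learned fragmentation/retention-time models: monoisotopic b/y ladders with
a bell-shaped intensity profile and missing predictions for the terminal
ions, plus a hydropathy-based retention time. Any object with the same
two-function interface can replace it.

## Numerical choices

* Frequency comparison "haplotype more frequent than the reference" is
  strict, with a `1e-9` guard so floating-point noise cannot flip an exact
  tie (reference frequency is computed as 1 minus a float sum).
* Coverage percentages are conserved to `1e-6` per protein; the aggregate
  is residue-weighted.
* Decoy generation reverses each cleavage-delimited segment keeping the
  terminal K/R; colliding decoy peptides trigger seeded re-shuffles of the
  segment interiors (default 10 attempts). Peptides built from segments
  with at most one interior residue are fixed points of any such shuffle,
  so a small number of collisions can be irreducible; they are kept and
  reported in a warning and as an attribute, never silently dropped.
* Internal coordinates are 0-based half-open spans; substitution notation
  stays 1-based, matching the conventional `527D>E` form.
* Redundant haplotypes (empty substitution set, or duplicating another
  record's sequence) are kept in the FASTA but flagged, since
  classification handles redundancy anyway.

## Open design points, resolved

* A single `min_allele_frequency` is exposed and populations are not
  modeled; the frequency is interpreted as the worldwide one.
* Substitutions are keyed per protein (isoform), not deduplicated per
  genomic variant, matching per-isoform reporting upstream; deduplication
  would be a reporting-layer change only.
* The stage functions plus `run_pipeline()` are the interface; no shell
  entry point is shipped, since every consumer of this package is an R
  analysis.
* One decoy is generated per target record, exactly.

## Limitations

Absolute search-space sizes and coverage percentages from real human
proteomes are not reproducible here by design — they require the full
reference proteome, the haplotype tables and the raw spectra. The q-value
machinery models simple target-decoy competition, not a rescorer's
posterior error probabilities (PEPs are accepted as pass-through input
only). Mirror-plot annotation follows the fixed category scheme; peaks
matching an ion with a predicted intensity of exactly zero are left
unannotated.
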