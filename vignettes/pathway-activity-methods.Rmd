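---
title: "Methods: pathway presence and transcriptional activity in MAG-resolved communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway presence and transcriptional activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magflux)
```

## Scope and assumptions

`magflux` starts where assembly, binning, annotation, and read mapping end.
Its inputs are (a) a merged ORF catalog in which every gene carries a MAG
label, a nucleotide length, a Prodigal-style two-character completeness flag,
and zero or more KO assignments; (b) a gene-by-sample matrix of expected
transcript counts; (c) a sample sheet mapping samples to conditions and
replicates; and (d) a pathway catalog. The package assumes KO annotation is
the functional unit — no sequence-level evidence is reconsidered — and that
counts are comparable across genes after length normalization.

Partial ORFs (flags `01`, `10`, `11`) are retained everywhere except in the
full-length QC metric: transcripts were mapped against the complete catalog
upstream, so removing truncated genes would discard real signal. Whether this
matches any particular upstream workflow is a user responsibility; the QC
fraction (`full_length_fraction()`) is reported so assemblies can be compared.

## The pathway catalog and its grammar

Steps are written in a deliberately flat grammar: `","` separates alternative
enzymes or complexes (OR), `"+"` joins the required subunits of one complex
(AND), and a `-` prefix marks an optional subunit. No parentheses or nesting
are allowed. The flat OR-of-ANDs form covers every structure the packaged 90
pathways need, keeps presence evaluation decidable by direct enumeration, and
makes the catalog diffable by curators. Optional subunits are recorded but
excluded from both presence evaluation and expression aggregation: their
treatment in pathway-completeness conventions is ambiguous, and excluding
them is the deterministic, conservative choice (a complex is neither rescued
nor penalized by an accessory subunit).

Every step is a key step unless the catalog says `key: false`; the packaged
catalog marks only passive transport steps (e.g. the LCFA `fadL` uptake step,
lactate permease) as non-key. All 90 pathways use completeness threshold 1.0
except the methylmalonyl-CoA pathway (`MMC`, 11 steps, threshold 0.9):
requiring 10 of 11 steps tolerates the incompleteness typical of MAGs in this
unusually long syntrophic route. `validate_catalog()` reports threshold
exceptions and KOs reused across steps of one pathway so such choices stay
visible.

KO membership of the packaged catalog was curated from KEGG pathway and
module maps for the named pathway set. The catalog *format* is the stable
contract; users with their own curation load it with `load_catalog()` and get
identical machinery.

## Presence calling

A step is detected in a MAG when at least one variant has all required
subunits among the MAG's KOs. Completeness is the detected fraction of key
steps, and presence is decided as

`n_detected × den ≥ num × n_key_steps`

with the threshold held as an exact decimal fraction `num/den` (up to six
fractional digits). The integer cross-product avoids the classic artifact
where `10/11 ≥ 0.9` fails in floating point; the 10-of-11 boundary is the
rule users care about most, so it must be exact. Zero-key-step pathways are
rejected at load time.

Presence uses genomic KO content only. "Expressed pathway" is a separate,
composable notion — presence AND positive pathway expression — because
encoding and performing are precisely the distinction the comparative
analysis is meant to draw.

## TPM and aggregation rules

TPM is computed over the entire merged catalog per sample (counts divided by
gene length in kb, then scaled so each column sums to 10^6). Samples with no
signal are an error naming the sample, as are genes without lengths. Columns
are not re-normalized after any aggregation step, so all aggregated values
remain on the TPM scale.

Aggregation is bottom-up:

* **KO within a MAG**: summed TPM over the MAG's gene copies carrying the KO.
  A gene with several KOs contributes its full TPM to each; splitting rules
  would be arbitrary, and single-KO assignment is the common case upstream.
* **Step**: per variant, the arithmetic mean over required subunits, with an
  unexpressed or unannotated subunit entering as 0 — the mean penalizes
  incompletely expressed complexes while staying defined; variants are then
  summed, so alternative enzymes and gene copies accumulate. The per-variant
  mean *before* the cross-variant sum is a genuine design choice (a joint
  mean across variants was also defensible); the chosen form keeps a
  single-enzyme alternative from being diluted by an unrelated complex's
  subunit count.
* **Pathway**: the mean over all steps (key and non-key), silent steps
  entering as 0. For pathways that pass the presence filter every step has
  annotated genes, so the zero-fill matters mainly for the
  expressed-but-absent diagnostics.
* **Guild share**: 100 × a MAG's pathway expression over the summed
  expression across *eligible* MAGs (those with a positive presence call).
  Restricting to eligible MAGs keeps stray single-gene hits in non-encoding
  genomes from contaminating the comparison. An all-zero guild is reported
  with zero shares and an explicit flag rather than NaN.

A KO reused by two steps of one pathway is counted in both (and flagged by
`validate_catalog()`). A KO shared by two *pathways* lets expression leak
between their activities — e.g. the enoyl-CoA hydratase and hydroxyacyl-CoA
dehydrogenase KOs shared by long- and short-chain beta-oxidation. This is a
property of KO-level annotation, not a bug; within-guild rankings for such
pathway pairs should be read with that caveat, and the recovery experiments
below use KO-disjoint pathways so they measure estimator noise rather than
catalog cross-talk.

Replicate aggregation reports the arithmetic mean and the n−1 sample
standard deviation; a single replicate yields an NA sd rather than 0.
Rankings sort by descending mean share with ascending MAG id as the
tie-break, making every output deterministic. The active-population filter
keeps MAGs whose relative expression strictly exceeds the threshold
(default 1% of a sample's transcriptome) in at least one sample; strictness
follows the "over 1%" reading, and the threshold is a parameter.

## The synthetic community generator

`simulate_community()` emulates exactly what the pipeline consumes: for each
MAG and each truly encoded pathway, every step receives at least one gene per
required subunit of one uniformly chosen variant (so variant-level OR logic
is exercised across MAGs), plus unannotated and off-catalog decoy genes.
Counts are negative binomial with `mu = baseline_mean × length/1000 ×
multiplier` and `size = 1/dispersion` — the standard overdispersed RNA-seq
count model; length-proportional means are what make TPM recover the
configured activity structure. Defaults mirror the targeted study design:
five conditions along an organic-loading gradient (`H15`…`H1`, hydraulic
retention times in days), three replicates, 86% full-length genes. Community
size (20 MAGs), baseline mean (50 counts per kb-gene), and dispersion (0.2)
are desk-scale choices: large enough for stable shares, small enough that the
full test suite runs in minutes. A per-pathway, per-condition effect matrix
can modulate means along the gradient (used by the `analysis/` drivers to
shift methanogenesis route dominance).

What the generator does *not* emulate: annotation errors other than dropout
(no wrong KOs on pathway genes), mapping ambiguity between paralogs,
compositional coupling beyond TPM's closure, genome incompleteness other
than `degrade_mag()`'s step-level deletions, and any sequence-level effects.
Passing recovery tests therefore demonstrates the estimator is correct under
its own model, not that real annotations are reliable.

Randomness is hierarchical: one user seed derives fixed sub-seeds for the
community structure, the gene-level attributes, and each sample's counts, so
identical configs are byte-reproducible and adding samples does not reshuffle
the community.

## Validation problem sizes

The test suite validates each aggregation rule against hand-computed values
and brute-force enumerators that walk (variant, subunit, gene copy) triples:
1000 random step instances for the aggregation oracle, 1000 random
(KO set, pathway) instances for presence monotonicity and threshold
equivalence, 1000 random matrices for TPM conservation (tolerance 1e-6
relative), and 200 for the same check inside the acceptance script. Presence
recovery runs a 12-MAG community at zero annotation dropout and compares
calls with the encoded truth derived from the generator's emitted KO content
(KO sharing between pathways means a MAG can genuinely encode more than its
sampled profile). Ranking recovery simulates 100 seeds of a 5-MAG community
over two KO-disjoint pathways with 4-fold-separated multipliers and three
replicates, requiring the true top-3 ordering per pathway in at least 95 of
100 seeds. Empirical count means are checked against the configured NB means
within three standard errors over 250 simulated samples.

## Known limitations

* The packaged catalog's KO content is a curation, not an authority; swap in
  your own catalog file for serious use and rely on `validate_catalog()`.
* Pathway completeness is not corrected for genome completeness; apart from
  the MMC threshold, an incomplete MAG simply fails the 100% rule.
* KO-level quantification cannot separate isofunctional paralogs or
  moonlighting enzymes shared between pathways.
* Guild shares are compositional (they sum to 100% within a sample);
  comparing a MAG's share across conditions confounds its own activity with
  the guild total, which is why the flux table reports unnormalized summed
  TPM alongside.
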