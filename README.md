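# magflux

Genome-resolved metatranscriptomic pathway activity for anaerobic microbial
communities.

Anaerobic digesters (and many natural methanogenic habitats) mineralize
organic carbon through a chain of guilds — hydrolytic fermenters, amino-acid
degraders, syntrophic fatty-acid and propionate oxidizers, and methanogens.
Metagenome-assembled genomes (MAGs) tell you who *encodes* each pathway;
metatranscriptomes tell you who actually *performs* it. `magflux` is for
microbiologists and bioreactor engineers who have per-MAG gene catalogs with
KEGG Orthology (KO) annotations plus per-sample transcript counts and want to:

1. call pathway presence per MAG under explicit completeness thresholds,
2. quantify pathway-level transcriptional activity per MAG and sample,
3. rank the active populations within each functional guild, and
4. summarize community-level carbon flux across reactor conditions.

## The model

**Pathway catalog.** Each pathway is an ordered list of reaction steps; each
step is a flat OR-of-ANDs over KOs (`","` = alternative enzymes/complexes,
`"+"` = subunits of one complex, `-K#####` = optional subunit). The packaged
catalog defines 90 anaerobic pathways from polymer hydrolysis to
methanogenesis and energy conservation.

**Presence.** A pathway is present in a MAG iff the fraction of detected key
steps reaches its completeness threshold:

```
detect(step)   = ∃ variant: all required subunits ∈ MAG KOs
completeness   = n_detected / n_key_steps
present        ⇔ completeness ≥ θ        (θ = 1.0 by default)
```

The 11-step methylmalonyl-CoA (MMC) pathway of syntrophic propionate
oxidation alone uses θ = 0.9 (≥ 10 of 11 steps), tolerating MAG
incompleteness in this long route. The threshold comparison is done in exact
integer arithmetic, so the 10/11 boundary is never a floating-point accident.

**Activity.** Gene counts are normalized to transcripts per million
(TPM_i = (c_i/ℓ_i) / Σ_j (c_j/ℓ_j) × 10⁶), then aggregated:

- KO level: sum of TPM over a MAG's gene copies carrying the KO;
- step level: per variant, the arithmetic mean over required subunits
  (absent subunits enter as 0), then the sum across variants — multiple
  enzymes or gene copies catalyzing a reaction accumulate;
- pathway level: the mean over *all* steps;
- guild share: a MAG's percentage of the summed pathway expression across the
  MAGs in which the pathway is present (mean ± sd over replicates).

A synthetic-community generator (negative-binomial counts with
length-proportional means and per-MAG × pathway activity multipliers)
provides known ground truth for every stage.

## Worked example

```r
library(magflux)

catalog <- default_catalog()
length(catalog$pathways)          # 90
catalog$pathways$MMC$threshold    # 0.9

# a MAG encoding the xylose isomerase pathway (both steps)
genes <- attach_ko_annotations(read_gene_table("genes.tsv"), "ko.tsv")
calls <- call_presence(genes, catalog)
subset(calls, pathway_id == "xylose_isomerase_pathway")

tpm   <- compute_tpm(read_count_matrix("counts.tsv"), genes)
act   <- pathway_activity(tpm, genes, catalog)
agg   <- replicate_aggregate(guild_shares_all(act, calls),
                             read_sample_sheet("samples.tsv"))
rank_active(agg, "lcfa_beta_oxidation", "H1")
```

The `analysis/` directory holds the numbered workflow the package was built
around: `01_simulate_community.R` generates a 12-MAG consortium (627 genes,
five loading conditions × 3 replicates, 86.1% full-length genes),
`02_run_pipeline.R` runs the full reconstruction (78 of 1080 MAG × pathway
pairs called present; TPM columns sum to 10⁶ to 2 × 10⁻¹⁶ relative),
`03_guild_ranking.R` ranks guild members — e.g. the dominant LCFA
beta-oxidizer MAG007 climbs from 52.2 ± 4.8% to 74.9 ± 1.2% of guild
expression as loading increases — and `04_carbon_flux.R` tabulates carbon
flux, showing methanogenesis route dominance shifting from hydrogenotrophic
(79.3% at the lowest loading) to aceticlastic (57.7% at the highest).

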