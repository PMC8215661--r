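# alpzone

Post-sequencing analysis of soil eDNA metabarcoding surveys of green algae
(Chlorophyta) along alpine elevational gradients — for ecologists who have a
MOTU × PCR read-count table with replicate, blank and positive-control PCRs,
an environmental table, and want defensible answers to: *which MOTUs and
PCRs are trustworthy, how does diversity change along the gradients, what
drives community turnover, and which taxa are niche specialists?*

The package implements:

* **MOTU-table quality control** — amplicon length bounds (65–200 bp, or
  65–130 bp for the 23S marker), the >10-reads-in-some-PCR rarity rule,
  target-clade restriction, removal of MOTUs more abundant in negative
  controls than in any sample, rejection of PCRs under the per-marker read
  minimum (200 / 1,000), and replicate-outlier flagging by Euclidean
  distance on Hellinger-transformed profiles to the replicate barycenter.
* **Diversity** — Hill numbers ^qD = (Σ pᵢ^q)^{1/(1−q)} (exponential
  Shannon entropy at q = 1), multiplicative β = γ/ᾱ, seven-slice gradient
  ANOVA R² with Kruskal–Wallis tests and Benjamini–Hochberg adjustment,
  Mann–Whitney group contrasts, endemism profiles, class abundance trends.
* **Ordination** — iterative VIF screening (VIF = 1/(1−R²), threshold 5),
  Hellinger transform, PCoA, partial RDA with reduced-model permutation
  tests (999 permutations), forward–backward selection, per-variable
  partial adjusted R², and Tukey-bisquare IRLS regression for
  marker-vs-marker log–log comparison.
* **Niche inference** — the Outlying Mean Index decomposition (marginality,
  marginal tolerance, residual tolerance), a dual permutation criterion for
  specialization (marginality larger *or* marginal tolerance smaller than
  expected, each one-sided at α = 0.05), abundance-weighted optimal ranges,
  and a PCA of specialized-taxon niche centers.
* **A synthetic study generator** — 5 staggered sites over 1,250–2,940 m,
  two soil horizons, PCR triplicates, blanks, a 13-species halving mock
  community, niche-structured taxa of two dominant classes, spiked
  contaminants and forced PCR failures, all with exposed ground truth.

## Worked example

```r
library(alpzone)

study <- simulate_study(generator_config(seed = 1))
study$table
#> MOTU table: 89 MOTUs x 191 PCRs; 1,751,065 reads

qc <- qc_pipeline(study$table, study$pcrs)
for (r in qc$reports) print(r)
#> [length] removed 4 MOTUs, 0 PCRs, 8,592 reads
#> [rare] removed 8 MOTUs, 0 PCRs, 89 reads
#> [clade] removed 4 MOTUs, 0 PCRs, 8,653 reads
#> [contaminants] removed 3 MOTUs, 0 PCRs, 3,710 reads
#> [failed_pcrs] removed 0 MOTUs, 17 PCRs, 481 reads
```

The three removed contaminants are exactly the three the generator spiked
into the blanks, and the 17 rejected PCRs are the 9 forced low-depth
failures plus the 8 (near-empty) blanks. Downstream:

```r
env <- study$env[match(rownames(qc$community), study$env$sample_id), ]
vif_select(env, c("Elevation", "pH", "Nitrogen", "Carbon", "C_N_ratio",
                  "OrganicMatter", "FDD", "CWD", "DTR"))$kept
#> "C_N_ratio" "CWD" "DTR" "FDD" "Nitrogen" "pH"
# Carbon/OrganicMatter (derived from Nitrogen x C/N) and Elevation
# (collinear with FDD) are removed.

set.seed(1)
partial_rda(hellinger(qc$community), env,
            c("C_N_ratio", "CWD", "DTR", "FDD", "Nitrogen", "pH"),
            condition = "Site")
#> partial RDA: 6 predictor df | condition: Site; R2 = 0.2021,
#>   adjusted R2 = 0.1118, permutation p = 0.001 (n = 999)

set.seed(1)
sp <- specialization_test(qc$community, env, c("Elevation", "pH"))
sum(sp$specialized)
#> 35        # of 59 taxa with reads in the aggregated communities

optimal_range(qc$community, env, "Elevation",
              sp$taxon[which.max(sp$marginality)])
#> motu_019 / Elevation: peak 1254, range [1189, 1327], median 1250,
#>   MW p = 0.0185
```

That most-marginal taxon is a planted low-elevation specialist (true
optimum 1,319 m): its recovered density peak is 65 m off the truth, inside
its reported optimal range. The adjusted R² (~0.11) says environmental
predictors explain little of the community variance even when clearly
significant — typical of sparse eDNA community data.

## Command line

```sh
alpzone simulate --config cfg.yaml --seed 1 --out sim/
alpzone qc --table sim/motu_table.tsv --pcrs sim/pcrs.csv --out qc/
alpzone diversity --table qc/filtered_table.tsv --pcrs qc/filtered_pcrs.csv --env sim/env.csv --out div/
alpzone ordinate --community qc/community.csv --env sim/env.csv --condition Site --n-perm 999 --seed 1 --out ord/
alpzone niche --community qc/community.csv --env sim/env.csv --n-perm 999 --seed 1 --out niche/
```

All randomness is governed by `--seed`; outputs are byte-identical across
runs with the same seed and inputs.
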