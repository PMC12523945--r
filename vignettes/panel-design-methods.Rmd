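---
title: "Methods: SNP panel design and its validation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP panel design and its validation battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how each stage of `snpanel` is defined, which
choices were genuinely open, and what the simulation-based tests do and
do not establish.

## Genotype model and coordinates

All statistics operate on a samples × loci dosage matrix counting copies
of the first ALT allele (0/1/2, `NA` for `./.`). Genotypes are treated as
unphased throughout; a phase separator in the VCF is accepted and
ignored, since none of the implemented statistics uses phase.
Multi-allelic records are kept on import but flagged, and the screening
cascade's biallelic-SNP rule removes them before any statistic is
computed. Coordinates mirror VCF (1-based, inclusive); the only 0-based
half-open output is the panel BED, converted explicitly at write time.

## The screening cascade

The cascade applies, in order: site QUAL >= `min_qual` (20); biallelic
SNP; depth; MAF >= `min_maf` (0.05); missing rate < `max_missing`
(0.25, strict, matching a "retain < 0.25" rule); heterozygosity rate;
and minimum spacing (`min_spacing_bp` = 5). Conventions that needed
fixing:

* **Depth.** "The average depth" is scoped as the grand mean of
  per-locus mean depths over the *pre-filter* input, computed once. A
  locus passes if its mean depth lies in `depth_window` = `[1/3, 5]`
  times that grand mean and is at least `min_site_depth` = 5×. Scoping
  the mean to the input (rather than re-computing it as rules fire)
  keeps each rule's pass set independent of cascade order and makes the
  per-rule attrition report meaningful.
* **Denominators.** Missing rate counts all samples; MAF and
  heterozygosity rate count non-missing calls only.
* **Heterozygosity direction.** The natural reading for chip design —
  and the one consistent with ranking loci by *low* heterozygosity — is
  to remove loci with het rate *above* `max_het_rate` = 0.5 (excess
  heterozygosity signals paralog collapse). The opposite direction is
  available as `filter_params(het_rule = "remove_low")` for toolchains
  that drop low-het loci instead.
* **Spacing.** Enforced last, greedily in rank order (below), so a
  conflict always evicts the lower-ranked locus. Conflicts can only
  occur inside maximal runs of same-sequence loci with consecutive gaps
  under the minimum, so each run is resolved independently; this makes
  the greedy solution order-independent and cheap at 10^5 loci.

Ranking is lexicographic: MAF descending, missing rate ascending, het
rate ascending, then `(seq_id, pos)` as a deterministic tie-break.
Selection stops at `target_size` (default 5000) or exhaustion. Weakening
any single threshold can only grow the surviving set (tested as a
monotonicity property).

## Probe design

Each selected SNP receives two `probe_length` = 110 bp probes. Probe B
starts `round(110 × (1 − overlap_target))` bases after probe A
(`overlap_target` = 0.65 → shift 38, shared window 72 bp ≈ 0.655),
with the shared window centred on the SNP; near sequence ends the pair
slides while keeping the shift, and fails with reason `edge` when no
placement keeps the SNP at least `min_snp_edge_bp` = 10 bp from every
probe end. A pass additionally requires per-probe GC in
`gc_range` = [0.30, 0.70] (N bases excluded from the GC computation) and
at most `max_homology` = 5 homologous regions.

"Homologous region" is operationalized without an aligner: the probe's
k-mers (`k` = 15) are matched against both strands of the reference, hit
positions are merged when within one probe length, and a merged window
with at least `min_seed_hits` = 5 shared k-mers counts as one region
(the probe's own source window therefore counts, so a unique probe
scores 1). k = 15 makes random collisions negligible at the 10^5–10^9 bp
scale (expected ≈ L/4^15 hits per k-mer) while 5 seed hits corresponds
to roughly a 19 bp identical stretch — sensitive to any biologically
meaningful cross-hybridization target, insensitive to scattered chance
matches. The k-mer count is an upper bound on the exact-duplicate count
(every exact copy is found; near-duplicates may add windows), which is
the conservative side for capture specificity. A locus-evaluation window
of `eval_window_bp` = 120 centred on the SNP and the 2-probes-per-locus
dimensioning are exposed as named parameters.

Failed loci are replaced by next-ranked candidates (respecting spacing)
until the target size is reached or candidates run out; rejections are
data (`fail_reason`), never exceptions.

## Diversity statistics

With `p` the alt-allele frequency among non-missing calls and
`q = 1 − p`: `maf = min(p, q)`, `he = 1 − p² − q²` (plug-in; the
`2n/(2n−1)` unbiased variant is a flag, off by default to match common
chip toolchains), `pic = he − 2p²q²` (Botstein's two-allele form),
`ao ∈ {1, 2}`, `ae = 1/(p² + q²)` (so `ae = 1/(1 − he)` exactly, an
identity asserted to 1e-12), and `ho` the heterozygote fraction. Group
tables recompute frequencies within each group, add a pooled `All` row,
and average per-locus values unweighted over loci with at least one call
in the group — each locus counts once regardless of call rate, matching
the flat per-breed presentation such tables conventionally use.

## LD

`r²` is the squared Pearson correlation of dosage vectors over samples
called at both loci (composite/unphased LD). EM haplotype-frequency
`r²` is deliberately out of scope: genotypes are unphased and
dosage-correlation is what genotype-file LD tools compute. Pairs need
at least 4 complete observations and two polymorphic members; skips are
counted, not raised. Decay curves are distance-binned means; the
half-decay distance is the midpoint of the first bin where the 3-bin
moving-average-smoothed curve falls to half its maximum — a formula-free
summary chosen because decay "rates" are usually compared only
ordinally. The simulator draws loci independently, so it produces no LD
by itself; `inject_block_ld()` copies a block-head locus into its
neighbours with a distance-growing flip probability to give the decay
estimator something to measure. That device is a testing instrument,
not a population-genetic model — real LD reflects recombination history
the simulator does not attempt.

## Population structure

The GRM is VanRaden-style: entries are means over pairwise-called loci
of `(g_i − 2p)(g_j − 2p)/(2p(1−p))` with pooled frequencies,
monomorphic loci excluded. PCA is the eigendecomposition of the GRM;
scores are eigenvectors scaled by the square root of their eigenvalues,
variance explained is relative to the sum of positive eigenvalues, and
signs are fixed by making the largest-magnitude loading positive.
Because frequencies are centred on the sample itself, off-diagonals are
biased by about `−1/(n−1)` — visible in the "unrelated samples" tests,
which therefore use n = 100.

The admixture model is the standard binomial mixture
`g_ij ~ Bin(2, Σ_k q_ik f_kj)`, fitted by plain EM: guaranteed monotone,
closed-form M-step, adequate at desk scale; the quasi-Newton
acceleration used by large-cohort tools buys speed, not different
optima, and monotonicity is a property the tests assert on every run.
`F` is clamped to `[1e-6, 1 − 1e-6]` to keep the likelihood finite.
One numerical caveat discovered in testing: when many `f_kj` saturate at
the clamp bounds, responsibilities of order `1/f` amplify float rounding
in the `Q` rows exponentially across iterations, so `Q` is renormalized
every M-step (a no-op in exact arithmetic). Local optima are handled by
seeded restarts (`n_starts` = 5 by default; 1 inside cross-validation,
where speed matters and the masked-prediction error is averaged over
folds anyway). Label switching is resolved by greedy correlation
matching (`align_ancestries()`).

K is chosen by masked-entry cross-validation: non-missing genotype
entries are partitioned into folds (default 5), each fold is masked and
predicted as `2 Σ_k q_ik f_kj`, and the error is the masked-entry RMSE
averaged over folds; binomial deviance is available as a flag. RMSE was
preferred as the default because it stays bounded when predicted
frequencies approach the clamp bounds. Best K is the strict argmin with
a smallest-K tie-break — no plateau heuristic, since any such rule would
be arbitrary.

## Trees

The p-distance between two individuals is the mean over co-called loci
of `|g_i − g_j|/2` — the allele-sharing analogue of sequence p-distance,
fixed here because sequence p-distance is not defined on genotype
matrices. Neighbor joining uses the Saitou–Nei criterion via `ape::nj`;
negative branch estimates are clamped to zero with the deficit moved to
the sibling edge, preserving the joined pair's distance. Bootstrap
support resamples loci with replacement, rebuilds the tree, and scores
each internal edge of the base tree by the frequency of its bipartition
among replicates; bipartitions are keyed canonically by the side not
containing the alphabetically first sample, so supports are invariant
to sample order (up to genuine ties in the NJ criterion, which the
rational grid of dosage distances can produce at small locus counts).
Newick output keeps 6 significant digits, writes supports as
internal-node labels, and single-quotes labels containing metacharacters.
Trees are built at individual level with groups read off as clusters;
`group_distance()` provides the pooled-frequency breed-level
alternative, since either convention is defensible.

## The simulator as a study design

Defaults describe a moderately structured multi-breed cohort: ancestral
MAF ~ Uniform(0.05, 0.95) (so the MAF filter has real attrition),
Balding–Nichols differentiation with configurable per-population F,
mean depth 20× (Poisson per call), 2% missingness, 5% of sites with
QUAL below 20, and six reference sequences — genome-scale assemblies
collapsed into a handful of sequence sets, as targeted-genotyping
pipelines commonly do. Loci are placed at least 10 bp apart and 200 bp
from sequence ends so probe context always exists; reference bases are
uniform ACGT. All randomness flows from one integer seed (the reference
uses `seed`, the population `seed + 1`), making every artifact
byte-reproducible.

What passing tests show: the estimators recover parameters the
generating model defines (F via Hudson FST, Q via EM, population splits
via NJ/bootstrap/PCA) and the pipeline's guarantees (spacing, filter
compliance, probe constraints, determinism) hold at scale. What they do
not show: behaviour under real-data features the simulator omits —
recombination-driven LD, mapping and batch artifacts, related
individuals, uneven group sizes, non-uniform base composition and
repeat structure of real genomes.

## Problem sizes

The shipped tests and the acceptance script use desk-scale sizes chosen
to exercise each property with margin: 10 000 screened candidates
(14 000 simulated loci × 50 samples) for panel guarantees, 5000-locus
probe evaluation on a 600 kb reference, 60-sample × 1000–2000-locus
cohorts for structure recovery (10 seeded CV replicates at K = 1..5),
200 random additive 5–8-taxon trees, 200 bootstrap replicates, and a
twice-run 30-sample pipeline hashed file-by-file for byte identity.

## Known limitations

No coalescent/recombination model (LD only via the block-copy device);
no supervised admixture, projection of new samples, or Q standard
errors; no haplotype phasing or D′; no thermodynamic probe modelling
(Tm, hairpins, cross-hybridization energies); no BCF/tabix — inputs at
the intended scale (≤ ~10^5 loci) stream as plain VCF.
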