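---
title: "Differential N-glycosylation site occupancy: models, filters and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential N-glycosylation site occupancy: models, filters and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

N-linked glycans are attached co-translationally to asparagines inside the
sequon N-X-S/T (X ≠ Pro). When the supply of the lipid-linked oligosaccharide
(LLO) donor is limited — the situation in type-I congenital disorders of
glycosylation — transfer becomes incomplete and some sequons are left
unoccupied. Two features of a protein govern how hard it is hit: the
*efficiency* of each of its sequons (NxT sequons are transferred more
efficiently than NxS; non-canonical acceptor sites are worse still, and an
aromatic residue two positions upstream of the Asn helps), and its
*multiplicity* — the number of glycosylation sites it carries, since every
additional under-occupied site is an additional destabilising lesion.

`glycosens` implements the computational side of testing this hypothesis with
label-free mass spectrometry: a total-proteome experiment quantifies protein
abundance, a lectin-enriched, deglycosylated-peptide experiment quantifies
per-site glyco signal, and the two are filtered, tested and cross-referenced
without any imputation. Because deposited MS data are not needed to exercise
the code, the package ships a generative model of the whole design.

## Data model and conventions

* Proteins are tibbles with `protein_id` and an upper-case `sequence`.
* Quantification tables (`quant_matrix`) are features × samples on the raw
  intensity scale; `NA` means *not detected* and is distinct from zero.
  Intensities stay raw in I/O; log2 happens inside the statistics, so reading
  and writing is lossless.
* Missing values are never imputed anywhere. Every decision that would
  normally be distorted by imputation is instead made from detection
  *patterns* (counts of non-missing cells per genotype).
* Site coordinates are 1-based and name the Asn residue itself, matching
  UniProt site annotation; glycosite features are keyed
  `"<protein_id>:<position>"`.
* The sample design (`sample_id`, `genotype`, `pair_id`) declares the
  littermate pairing used by the paired total-proteome test.

## Sequon annotation and the reference glycoproteome

`scan_sequons()` reports every window N-[^P]-[S/T], overlapping sequons
included, and `classify_site()` assigns each Asn key its class (`NxT`, `NxS`,
`non_canonical`), its −2 residue and the aromaticity of that residue
(aromatic = F, Y, H, W). Sites at positions 1–2 have no −2 context; they are
excluded from −2-dependent contrasts only, never from anything else, so
unrelated statistics are not silently shrunk.

The *reference glycoproteome* is evidence-based: a site belongs to it when
its deglycosylated-peptide feature is detected in at least two control
samples (`build_reference_glycoproteome()`). Mutant detections do not count —
the reference must not absorb genotype effects. Sites absent from
user-supplied known-site lists are flagged `novel`
(`call_novel_sites()`); non-canonical detected sites are kept both in the
reference and in multiplicity counts.

Per-protein multiplicity is the number of distinct reference positions.
A scanner-based count is reported alongside
(`multiplicity_profiles()$scanned_multiplicity`), but every enrichment uses
the evidence-based count: annotation-based counts mix true sites with never
occupied sequons.

## Differential analysis

**Total proteome.** Only proteins detected in all samples of both genotypes
are tested (`filter_complete_cases()`), which is what makes the no-imputation
rule tenable. Within-pair log2 differences (mutant − control) go into a
two-sided paired t-test, and false discovery is controlled with
Benjamini–Hochberg; a protein is `decreased`/`increased` at q < 0.05 with the
matching sign. BH was chosen because the procedure is deterministic and fully
specified; the threshold stays at q < 0.05.

**Glycosites.** Filtering is control-anchored (`filter_glyco_sites()`):
a site is testable when detected in ≥ 3 of 4 control samples. Sites detected
*solely* in one genotype (zero in the other, ≥ 3 in their own) bypass the
test: `exclusive_control` sites are candidate complete-occupancy losses,
`exclusive_mutant` the mirror. Exclusivity takes precedence, so the four
outcome sets partition the input. Testable sites get a two-sided unpaired
t-test on detected log2 values only — Welch by default (`var_equal = FALSE`
is the safer reading of an "unpaired t-test"; the pooled-variance version is
a flag). At least two detected values per genotype are required; below that
the site is reported `unchanged` with a `low_coverage` flag rather than
tested on a pseudo-replicate. No q-value is computed in this branch; calls
are at p < 0.05, as in the original design.

Degenerate rows (zero variance) get p = 1 when the shift is zero, the
smallest positive double when a nonzero shift is perfectly consistent, and a
`degenerate` flag either way.

**Occupancy cross-reference.** A decreased or control-exclusive glycosite
whose *unmodified* counterpart peptide appears in ≥ 3 mutant samples and no
control sample is called `unoccupied_in_mutant`: the peptide backbone is
present yet unglycosylated. If that pattern fails but the parent protein
itself is decreased, the site is `protein_level_change` — an added
disambiguation category, since abundance loss alone can explain a glyco
decrease. Everything else is `occupancy_reduced_unconfirmed`. Matching is by
site key only; reconciling tryptic boundaries or missed cleavages between
experiments is out of scope.

## Enrichment statistics

All 2×2 questions go through `fisher_enrichment()`: rows are in-set/out-set,
columns hit/non-hit, p is the two-sided Fisher exact probability, and the
headline effect size is *fold enrichment* (hit fraction in the set over hit
fraction in the whole background), with the odds ratio reported alongside.
The background convention for "glycoproteins among decreased proteins" is all
tested proteins; restricting to detected glycoproteins is a one-line change
on the caller's side.

`multiplicity_enrichment()` runs the same test at thresholds ≥1 … ≥4; at ≥1
every glycoprotein is a hit, so the fold is exactly 1 — a built-in
no-enrichment anchor.

Group multiplicity comparisons (`multiplicity_group_test()`) use a
Mann–Whitney test. Multiplicities are small integers, so ties are everywhere,
and the base exact distribution does not handle ties; the package therefore
computes the exact permutation distribution itself with a shift algorithm
over doubled midranks whenever the smaller group has ≤ 8 observations (and
the pooled size is ≤ 40), and otherwise uses the tie-corrected normal
approximation. The two-sided p is `min(1, 2·min(P(W ≤ w), P(W ≥ w)))`.

`sequon_position_enrichment()` contrasts decreased versus unchanged sites —
"unchanged" is the inclusive set: every reference site not called decreased
(or control-exclusive) and not called increased (or mutant-exclusive). It
emits a per-position, per-residue Fisher table plus the two headline
features: non-aromatic −2 and Ser at +2 (the NxS motif); a long-format logo
matrix accompanies the tests.

`nxs_multiplicity_correlation()` bins sites by parent-protein multiplicity
(singleton bins below the cap, ≥ 8 pooled, the pooled bin positioned at the
cap), computes the NxS percentage per bin and series, drops bins with fewer
than 3 sites, requires at least 3 usable bins, and reports a Pearson r per
series. A series with constant percentages is reported r = 0, p = 1 rather
than `NA`. Binned points are the default; the per-protein variant is left to
the caller, as the point construction is not uniquely determined by the
figure it mirrors.

## The synthetic glycoproteome

`sim_config()` fixes the generative model. Per site with transfer efficiency
*e* (NxT 0.98, NxS 0.92, non-canonical 0.70, +0.02 for an aromatic −2,
capped at 0.995):

* occupancy in control: `o_ctrl = e`
* occupancy in mutant: `o_mut = e · max(0, 1 − κ·s·(1 − e))`

with global stress `s ∈ [0, 1]` (default 0.5) and sensitivity `κ` (default
3) — the simplest form in which less efficient sequons lose more occupancy,
with κ amplifying the spread. Per protein, `Δu = Σ (o_ctrl − o_mut)` is the
expected increase in unoccupied sites and the mutant abundance multiplier is
`r = exp(−λ·Δu)` (λ default 1), so degradation grows with multiplicity
through Δu only.

The quantification model: protein log2 abundance ~ N(20, 2); per-sample
intensity adds a litter effect (sd 0.3) and replicate noise (sd 0.25), and
mutant samples shift by log2 r. A glycosite adds `log2(occupancy)` and a
fixed per-peptide ionization offset (sd 1) to its protein's intensity; the
unmodified counterpart uses `log2(1 − occupancy)`. Zero occupancy means the
species does not exist, hence missing — never intensity 0. Finally, every
cell is observed with probability `plogis((log2 I − 18)/1)`: the
missing-not-at-random dropout regime of label-free MS.

Two cohorts are simulated, mirroring the study design: the total-proteome
cohort is littermate-paired (the pair effect is shared by the two samples of
a pair, which is what justifies the paired test) and also hosts the
unmodified-peptide features; the glycoproteomics cohort consists of distinct
animals, so its biological effects are independent per sample and the
unpaired Welch test is correctly calibrated (its null call rate at p < 0.05
sits near 5%, which the test suite checks over ten seeds).

Sequences are random backbones over the 19 non-Asn residues with each
simulated sequon written in at its recorded position (sites spaced 8
residues apart, each owning its −2…+2 block). Excluding Asn from the
backbone means scanning a simulated protein recovers exactly the ground
truth — convenient for testing, at the price of unrealistically Asn-free
inter-site stretches. One global seed drives every draw; the
glycoproteomics cohort uses a stream derived deterministically from it, so
whole studies are bit-reproducible.

What the generator does *not* emulate: digestion and missed cleavages,
charge states, lectin-specific capture bias, multi-site glycopeptides (one
feature per site is assumed throughout), correlated protein complexes, or
any transcriptional stress response. Passing recovery tests therefore show
that the pipeline detects the encoded mechanism under MNAR dropout at the
study's sample size — not that it would behave identically on real spectra.

## Behaviour at the default study size, and validation scenarios

Four paired replicates leave the paired t-test with three degrees of
freedom. After BH correction, the q < 0.05 set of differentially abundant
proteins is tiny on most simulated studies at default stress: a protein
needs |log2 r| beyond roughly 2 to clear it, and proteins degraded that
strongly tend to drop out of the complete-case set beforehand, because
their mutant intensities fall below the detection midpoint. The biological
signal is nevertheless plainly there: the acceptance script reports the
same two contrasts on the nominally decreased set (p < 0.05, negative
fold), where glycoprotein enrichment and the ≥ 4-multiplicity excess are
strong and stable across seeds. Contrasts anchored on the glyco branch
(mean multiplicity of proteins with decreased glycopeptides versus the
rest, the +2 Ser excess, direction dominance of decreases) do not depend on
the q-gate and recover reliably.

Two further properties are checked in scenarios chosen for identifiability
rather than realism:

* *Null calibration* uses `stress = 0, lambda = 0`: the glyco branch's
  nominal call rate must sit in a band around 5%, and the multiplicity
  contrast must show no systematic signal.
* *Occupancy-collapse recovery* uses `stress = 1, κ = 13, lambda = 0`. At
  the default mild stress no site's occupancy reaches exactly zero
  (`κ·s·(1 − e) ≥ 1` would need e ≤ 1/3, below any sequon class), so the
  premise of the `unoccupied_in_mutant` call would be vacuous. Under the
  collapse scenario NxS and non-canonical sites are truly unoccupied while
  λ = 0 keeps the protein — and its unmodified counterpart — detectable in
  the mutant, which is precisely the detection pattern the call is designed
  to read.

Problem sizes used by the test suite: unit tests run hundreds of proteins;
the calibration and recovery checks run the full 2,000-protein design over
10–20 seeds; the exact-test oracles sweep every 2×2 table with total ≤ 40
and enumerate Mann–Whitney labelings up to 6 vs 6.

## Numerical and design choices

* Fisher p via the hypergeometric sum of probabilities ≤ the observed
  table's (the standard two-sided convention); verified exhaustively against
  enumeration.
* Exact Mann–Whitney with ties via doubled midranks; verified against full
  labeling enumeration.
* BH q-values verified against the step-up definition on random p-vectors.
* The paired and Welch tests are vectorized closed forms over rows; unit
  tests pin them to `stats::t.test` to machine precision.
* p-values serialize at full precision; result tables round-trip through the
  bundled readers with missingness conserved.
* Multiplicity for enrichment is evidence-based by default; scanner-based
  counts are exposed but not used in tests of the degradation hypothesis.
* Each glycosite feature is assumed to represent one site; collapsing
  multi-site peptides is upstream of this package.

## Limitations

The generator's effect sizes and noise levels are stylized; absolute counts
(reference size, decreased fractions) depend on them and are not calibrated
to any particular instrument. The cross-reference matches sites by
coordinate only. Occupancy stoichiometry (the occupied fraction itself) is
not estimated — that would require matched modified/unmodified
quantification within one run.
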