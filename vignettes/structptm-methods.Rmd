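---
title: "Structural context of PTMs from predicted structures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural context of PTMs from predicted structures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Predicted protein structures come with two per-model uncertainty estimates:
a per-residue confidence (pLDDT, stored in the B-factor column of
AlphaFold-style files) and a pairwise positional uncertainty, the predicted
aligned error (PAE, in Å). `structptm` treats a predicted structure not as a
static object but as an estimate with position-dependent uncertainty, and
derives from it a small set of per-residue quantities that put
posttranslational modification (PTM) sites in structural context.

```{r, eval = FALSE}
library(structptm)
chim <- make_chimera(list(segment_spec("globule", 100),
                          segment_spec("coil", 15),
                          segment_spec("globule", 100)), seed = 1)
ann <- annotate_structure(chim$structure, chim$pae)
```

## The exposure metric (pPSE)

The prediction-aware part-sphere exposure of residue *i* counts the alpha
carbons of other residues *j* that satisfy both of

* a distance rule: ‖CA~j~ − CA~i~‖ + PAE\*(i,j) ≤ *r*, where
  PAE\*(i,j) = max(PAE[i,j], PAE[j,i]) when `use_pae = TRUE`;
* an angle rule: the angle between the side-chain direction
  u~i~ = (CB~i~ − CA~i~)/‖·‖ and CA~j~ − CA~i~ is at most the cone
  half-angle *a*.

Large counts mean buried residues; small counts mean exposed ones. Both
boundaries are inclusive, matching the inclusive conventions used for the
downstream thresholds (exposure class at pPSE ≤ 5, disorder at smoothed
pPSE ≤ 34.27). Two configurations matter in practice:

| purpose | radius | angle | PAE |
|---|---|---|---|
| side-chain exposure | 12 Å | 70° | yes |
| disorder score | 24 Å | 180° (full sphere) | yes |

The 12 Å/70° choice reflects the ~3.5 Å scale of an amino acid and the
flexibility of side chains around the CB direction; at 180° the metric no
longer depends on the side-chain direction at all, which is the right
property for a disorder score. For glycine, which has no CB, the side-chain
direction is built from the backbone by the standard ideal-tetrahedral
virtual-CB construction from N, CA and C — the same convention used by
half-sphere-exposure implementations. The PAE is symmetrized by the maximum
of the two directional entries: the matrix is not exactly symmetric, and
taking the maximum is the conservative reading (an uncertain neighbour is
never counted). The raw matrix is kept as parsed; symmetrization happens
only at the point of use.

## Disordered regions and short IDRs

Intrinsically disordered regions (IDRs) are called from the full-sphere
24 Å profile: it is smoothed along the sequence by a running mean over
`position ± half_window` (window truncated at the termini; default
half-window 10 residues) and residues with a smoothed value ≤ 34.27 are
flagged disordered. A disordered residue in this sense has few confidently
placed neighbours even in a large sphere, which captures both extended
geometry and high PAE. The 34.27 default is the published operating point
of this score family (85% true-positive rate at 5% false positives); since
the matching smoothing window is not published alongside it, the window is
an explicit parameter with 10 as the documented default, and the threshold
should be recalibrated if the window is changed.

A **short IDR** is a maximal disordered run of at most 20 residues
sandwiched between structured runs of at least 80 residues on *both* sides
— flexible linkers and loops embedded in large folded domains, the pattern
followed by kinase activation loops. Runs touching a terminus never
qualify. Because smoothing erodes the edges of a disordered stretch, each
short IDR is also reported extended by 5 residues on either side (clipped
to the sequence); modifications directly adjacent to a flexible region can
still affect its conformation.

## Enrichment statistics

All enrichment designs reduce to a 2×2 table over a residue universe:
acceptor residues of the PTM type (S/T/Y for phosphorylation, K for
ubiquitination/sumoylation/acetylation, K/R for methylation, S/T for the
O-glycosylations), cross-classified as in/out of a structural category and
modified/unmodified. The two-sided Fisher exact test is implemented
directly as a hypergeometric enumeration — the p-value sums the
probabilities of all tables with the observed margins that are no more
probable than the observed one, with the customary `1 + 1e-7` relative
tolerance on that comparison — and the odds ratio is the sample odds ratio
(a·d)/(b·c), reported as `Inf`/`NaN` rather than Haldane-corrected when a
margin cell is empty. Benjamini–Hochberg correction is applied within one
analysis family: all PTM types of one design, or all proteins of one
per-protein scan. The per-protein scan tests each protein's own acceptors
only, so a protein with all its modifications in structured regions gets an
odds ratio below 1.

## 3D proximity and cluster tests

The PAE-aware distance between residues is
‖CA~i~ − CA~j~‖ + max(PAE[i,j], PAE[j,i]). Two analyses build on it, and
both use only *eligible* residues — structured residues and short IDRs;
disordered runs longer than 20 residues are removed, because their
coordinates (and hence distances) are not meaningful and PTMs cluster
there in linear sequence anyway.

**Global profiles.** For every modified source residue, every eligible
target acceptor in the same protein is assigned to the bin of its distance;
per bin, the fraction of modified targets is compared with randomized
backgrounds in which each protein's target modification count is
redistributed uniformly over its eligible acceptors. Self-proximity bins
start at 1 Å (right-closed bins of 5 Å up to 35 Å; the residue itself is
excluded, and sub-1 Å pairs are ignored rather than binned); colocalization
profiles start at 0 Å so that competition of two PTM types for the identical
residue shows up in the leading bin. Randomization is per protein, which
preserves each protein's modification count and length as confounders. A
bin is marked significant when |z| ≥ 1.96 against the randomization mean
and standard deviation — the criterion is explicit and configurable, and
the raw z is always reported. With the display default of 5 randomizations
the z statistic is t-distributed with 4 degrees of freedom, so |z| values
up to ~3 arise by chance in roughly 5% of null bins; for calibration work
the package's own checks use 100 randomizations, where the null exceedance
rate of |z| ≥ 3 drops to ~0.35%.

**Per-protein cluster test.** For each protein with at least 3 modified
eligible acceptors, the observed mean pairwise PAE-aware distance among the
modified residues is compared with the means of random draws of the same
number of residues from the protein's eligible acceptors of the same
acceptor class, without replacement (default 10,000 draws). The empirical
p-value uses the add-one estimator (1 + #{null ≤ observed})/(1 + N), which
is never zero, and is BH-adjusted across all tested proteins. When every
eligible acceptor is modified the null is degenerate and p = 1 by
construction.

## Motif analysis

Motifs are restricted regular expressions with exactly one capture group
marking the central acceptor (e.g. `R.R..([ST])F`); all occurrences are
reported, including overlapping ones, via zero-width lookahead matching.
Sequence windows of ±6 residues around sites are padded with `_` at the
termini so all windows have fixed width; windows whose central residue is
not a valid acceptor are excluded. The log-odds position-specific scoring
matrix is score(a, pos) = log₂(((count + pc·bg~a~)/(N~pos~ + pc))/bg~a~)
with a background-proportional pseudocount (default total mass 1) and
padding excluded from the column counts, so an all-padding column scores
exactly zero. The published analyses delegate this scoring to an external
web tool whose exact pseudocount scheme is not printed; this formula is the
package's documented stand-in, and it converges to the zero matrix on
background-sampled windows as the window count grows. For exposure-split
motif comparisons, the high-exposure set is additionally down-sampled (with
a seed) to the size of the low-exposure set, so differences in logo sharpness
cannot be explained by set size.

## The synthetic-structure generator

`make_chimera()` concatenates segments of three kinds: ideal α-helices
(2.3 Å radius, 1.5 Å rise, 100°/residue twist, consecutive CA–CA ≈ 3.8 Å),
extended coils (exact 3.8 Å steps along a jittered forward direction), and
compact globules (a serpentine space-filling walk on a 3.8 Å grid inside a
cube sized to the residue count, with small Gaussian jitter — guaranteeing
realistic high neighbour counts without any simulation). Backbone N and C
atoms are placed from the local chain tangent plus a perpendicular offset
so the virtual-CB construction is always well defined; CB atoms are placed
with that same construction, and glycines get none. The PAE matrix is a
block structure: each segment's `intra_pae` inside the segment and the
larger of the two segments' `inter_pae` across segments, with a zero
diagonal. Defaults emulate typical AlphaFold output — pLDDT ≈ 92 and
PAE ≈ 2 Å in structured segments, pLDDT ≈ 35 and PAE ≈ 15 Å in coils, 25 Å
between domains. All randomness flows through one private, explicitly
seeded RNG stream per call; the caller's RNG state is untouched and equal
seeds give bit-identical output.

`simulate_ptm_sites()` modifies each acceptor independently, with separate
probabilities for exposed (raw pPSE ≤ cutoff) and buried residues, and can
plant a 3D hotspot: acceptors within a CA-distance radius of a chosen
center are modified at the exposed-probability rate regardless of their own
exposure. Setting `exposure_cutoff = -1` makes the baseline probability
apply everywhere outside the hotspot, which is how the package's own
recovery checks plant clean clusters.

What the generator does *not* emulate: real side-chain packing and rotamers,
sequence-dependent disorder propensity, beta-sheet topology, domain-domain
interfaces, and the correlated PAE structure of real predictions (real PAE
varies smoothly, not blockwise). Tests passing on these fixtures therefore
demonstrate that the *statistics and geometry* are implemented correctly,
not that the biological signal in any real proteome will look the same.

## Numerical choices and degenerate inputs

* Distance and angle boundaries are inclusive; the angle rule is evaluated
  on cosines with a 1e-12 slack so exactly-on-cone constructions (e.g. 90°)
  are not lost to floating-point rounding of `cos()`.
* The PAE diagonal is clamped to zero at load; negative, non-finite or
  non-square matrices are rejected, as is any size mismatch with the
  structure.
* Single-residue structures have pPSE 0; empty site tables give empty
  profiles with a warning rather than an error.
* Fisher tables with an empty row or column give p = 1 and an undefined
  (`NaN`) odds ratio; negative cells are an error.
* BH is stable under ties and invariant to input permutation.
* Fragmented AlphaFold entries (`-F2` and beyond in the filename) are
  rejected: fragment files overlap and cannot be re-indexed 1..n safely.
* Residue numbering is always re-based to 1..n in author order (PTM tables
  are 1-based UniProt positions); the author numbering is kept as metadata.

## Problem sizes used by the package's own checks

The test-suite and the acceptance script work at desk scale, chosen so the
statistical properties they probe are in the regime where their nominal
behaviour is expected: 50 random mixed-architecture fixtures (≤ 200
residues) for the exposure oracle; all 2×2 tables with total ≤ 60 for the
Fisher enumeration; a 10-protein chimera proteome (~400 phosphoacceptors)
for enrichment calibration, where the exact test is near-nominal — on
smaller universes its discreteness makes it visibly conservative; 500
protein instances at 1,000 permutations for the cluster-test uniformity
check; and 200 replicate profiles at 100 randomizations for the global-null
z calibration. The larger permutation default (10,000) is the published
operating value and remains the function default.

## Known limitations

* Single chains only; complexes, NMR ensembles and experimental structures
  with gaps are out of scope (rejected, not repaired).
* The IDR threshold is tied to an unpublished smoothing window; treat the
  (window, threshold) pair as one unit when recalibrating.
* The PSSM normalization is a documented stand-in for an external tool's
  unpublished scheme; absolute scores should not be compared across tools.
* Proximity analysis is within-protein; cross-protein (complex-level)
  modification crosstalk is not modelled.
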