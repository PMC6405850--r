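---
title: "Methods: loop conformational landscapes, contacts and sequence statistics"
author: "loopscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop conformational landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscape)
```

# Scope

`loopscape` characterises the conformational behaviour of flexible protein
loops — the serpin reactive-centre loop (RCL) being the motivating case —
from three directions: structural ensembles (clustering, RMSF, dihedrals,
salt bridges, frustration), sequences (conservation and covariation), and
wet-lab curves (thermal melts, stoichiometry of inhibition). Because
production molecular-dynamics trajectories are rarely distributable, the
package carries a first-class synthetic-data module that generates every
input type with known ground truth; all statistical claims made by the test
suite are claims about those generators, and this vignette is explicit
about what that does and does not show.

# The synthetic generators as study conditions

**Multi-basin loop ensembles.** `sampleEnsemble()` emulates a loop
exchanging between metastable conformations. Each basin is an
ideal-geometry backbone built from a per-residue (φ, ψ, ω) template by NeRF
internal-coordinate construction (bond lengths N–CA 1.458 Å, CA–C 1.525 Å,
C–N 1.329 Å, C=O 1.231 Å; standard backbone angles; the IUPAC torsion sign
convention, cross-checked against two independent torsion implementations).
The default is an 18-residue loop — the P17–P1′ span, residues 342–359 in
α1-antitrypsin numbering, giving the canonical 72 backbone atoms and
216-dimensional coordinate space — with three well-separated basins
(extended β, α-helical, polyproline-II-like templates; equal weights),
per-coordinate Gaussian jitter of 0.15–0.3 Å, and a Markov chain with
self-transition probability 0.9–0.95. These defaults stand in for the kind
of landscape a loop explores across a few hundred nanoseconds of sampling;
they do not reproduce any particular trajectory (none are published for the
motivating study), so recovery results quantify the pipeline, not the
biology.

*Markov parameterisation.* A chain with "stay probability on the diagonal
and off-diagonal mass proportional to the weights" cannot in general have
the weights as its stationary distribution (the row-normalised jump chain
has stationary ∝ w(1 − w)). We therefore use
`P = s·I + (1 − s)·1wᵀ`: off-diagonals are exactly proportional to the
weights and the stationary distribution is exactly `w`; the price is that
the realised self-transition probability is `s + (1 − s)w_i ≥ s`. The
initial state is drawn from `w`, so occupancy estimators are unbiased from
frame one.

*Pose noise.* Global rotation/translation noise per frame is off by
default, so superposition machinery can be exercised explicitly;
conformational jitter is drawn before pose noise, so switching pose noise
on leaves the underlying conformations at a given seed unchanged — this is
what makes the rigid-motion invariance tests sharp.

**Salt-bridge series.** A formed/broken two-state chain with the same
`s·I + (1 − s)·1pᵀ` construction (exact stationary formed-probability),
observed through Gaussian distance noise around 3.0 Å (formed) and 6.0 Å
(broken). At the default persistence 0.95 the autocorrelation inflates the
occupancy estimator's standard deviation to ≈ 0.006 at n = 10⁵ frames, so
the ±0.02 recovery band used in tests is a ≈ 3σ statement.

**Melt curves and inhibition assays.** The melt generator is the Boltzmann
sigmoid `s(T) = b_F + (b_U − b_F)/(1 + exp((T_m − T)/a))` on a 35–95 °C
grid. The inhibition generator is the residual-activity line
`a(r) = max(0, 1 − r/SI)` on ratios 0–2, **in triplicate by default** —
SI determinations are conventionally triplicate assays, and the replicate
structure matters quantitatively (below).

**Alignments.** Columns are i.i.d. from a BLOSUM-style background
frequency table (shipped as `aa_background_freqs.tsv`); conserved columns
are fixed; a covarying pair is a mixture, with probability `coupling`, of
"both columns receive the same background-drawn residue" versus
independence. The mixture weight controls mutual information monotonically
and makes `coupling = 1` a deterministic association, which is what the
permutation-significance tests exploit.

# The clustering pipeline

`loopMatrix()` extracts the loop backbone (residues ascending; N, CA, C, O
within each residue; columns atom-major x/y/z), optionally superposing all
frames onto scaffold Cα of a reference frame first — the loop itself is
excluded from the fit so that the PCA captures loop motion rather than body
tumbling. For loop-only synthetic ensembles no superposition is applied.

`fitPCA()` eigendecomposes the covariance of the mean-centred rows with
base `eigen()` rather than a truncated SVD so that all 3A components are
reported, rank-deficient directions carrying zero eigenvalue. This keeps
the component matrix a complete orthonormal basis: projection is an
isometry, which is why clustering in full PC space is *identical* to
clustering the centred raw coordinates (tested as exact label equality up
to renaming).

`minClusterSize()` is round-half-up of `fraction × nFrames` with a floor of
2; at the conventional 1 % fraction an 8993-frame concatenation gives 90.
The round-half-up rule is chosen precisely so that 89.93 → 90.

`clusterConformations()` runs HDBSCAN. No R implementation is available in
the package's dependency environment, so the algorithm is implemented here
from its published description: core distances at `minSamples` (default =
minimum cluster size, matching the reference implementation's default
behaviour), mutual-reachability distances, a single-linkage tree
(`stats::hclust`), condensation at the minimum cluster size, and
excess-of-mass cluster selection on condensed-tree stabilities. Numerical
details: λ = 1/distance with zero heights floored at 10⁻³ of the smallest
positive height; the hierarchy root is never selected unless
`allowSingleCluster = TRUE`. That switch resolves a genuine ambiguity in
degenerate cases: with the default (`FALSE`, as in the reference
implementation) structureless input comes back all-noise, while a single
tight blob needs `allowSingleCluster = TRUE` to be reported as one cluster.
Both behaviours are contract-tested. Clusters are relabelled 0-based by
decreasing size; medoids (member minimising summed Euclidean distance to
co-members, ties to the lowest frame index) are computed in the clustering
coordinate space.

Whether to cluster in 2 PC dimensions (as landscapes are usually plotted)
or the full space is left to the caller (`projectPCA(..., k)`); the package
default is the full, distance-preserving space.

# Ensemble metrics

RMSF uses an iteratively refined mean reference: superpose all frames onto
a reference, re-average, and repeat until the mean moves < 10⁻⁶ Å (≤ 20
iterations). The fit selection defaults to all atoms; for loop work the
recommended choice is scaffold Cα, so loop fluctuation is measured relative
to the body. `fitSelection = NA` disables superposition entirely, which is
the configuration in which the isotropic-jitter calibration is exact: for
i.i.d. per-coordinate jitter σ the RMSF is σ√3 (the superposed estimate
shrinks by roughly `sqrt(1 − 6/(3A))`, about 2 % for 48 atoms; the tests
document a 5 % band). Block averaging (`block` in frames; a trajectory's
physical time per frame travels as `frameInterval` metadata) retains and
flags the trailing partial block. A 500-ps convention can equally be read
as subsampling; block averaging is the package's default reading, and
subsampling is available by slicing frames before the call.

The Kabsch superposition uses the SVD construction with a determinant
correction, so the returned rotation is always proper even for reflected
inputs; its RMSD is checked against an independent rigid-fit implementation
(bio3d) in the tests.

# Salt bridges and frustration

A salt bridge is "formed" when the minimum distance over charged-atom pairs
(Asp OD1/OD2, Glu OE1/OE2 × Lys NZ, Arg NH1/NH2/NE, His ND1/NE2) is at or
below the cutoff; 4.0 Å is the common literature criterion and the default,
exposed as a parameter because the convention varies. Histidine is excluded
by default (protonation-dependent) and flagged when included. Candidate
pairs are pre-screened at cutoff + 2 Å. Occupancy is monotone in the
cutoff and exactly additive over concatenated ensembles (frame-weighted
mean); the report applies the conventional > 20 % floor.

Frustration follows the mutational scheme: residue identities of a contact
are mutated at fixed geometry, decoy pairs drawn i.i.d. from the
structure's composition (or enumerated exhaustively with composition
weights), and the index is the z-score
`F = (⟨E_decoy⟩ − E_native)/σ_decoy`, classified minimal at F ≥ 0.78 and
high at F ≤ −1 (the conventional thresholds). The energy model is a
deliberate reduction: a 20×20 contact potential plus a Debye-screened
Coulomb term `q_i q_j exp(−r/λ_D)/(k·r)` with k = 4.15 and λ_D = 10 Å.
The shipped potential table is *synthetic* — a hydrophobicity-derived
(Kyte–Doolittle product/sum) surrogate, named
`contact_potential_synthetic.tsv` to say so — because the index is
invariant under affine rescaling of the energy model (a property the tests
verify), the qualitative behaviour, not the table's absolute values,
carries the analysis. Any symmetric 20×20 table can be swapped in.
Contacts are Cβ–Cβ (Cα for glycine) within 8 Å at sequence separation ≥ 2;
results on real proteins with this reduced Hamiltonian are qualitative.

# Sequence statistics

Percent identity is `100 × identity columns / aligned length`, the length
including gap columns. A column where both sequences are gapped counts
toward the length but not the identity (configurable via
`gapGapIdentity`); the choice is conservative and does not affect
ungapped-position arithmetic such as the 379-column / 148-difference → 61 %
case.

Conservation is `1 − H/ln 20` with gaps excluded from the frequencies,
graded 1–9 by 9-quantile binning (9 = most conserved; an all-gap column is
masked). OMES is the χ² independence statistic over sequences jointly
observed at both columns, skipping zero-expectation cells — it is tested
for exact equality against a brute-force contingency implementation. ELSC
scores the enrichment of a column's composition in the perturbation subset
(sequences carrying the most frequent residue at the other column) via
log-binomial-coefficient ratios with largest-remainder rounding of the
expected subset counts; the orientation is chosen so that larger = more
covarying (the sign under which the planted pair is the matrix argmax).
SCA is the perturbation (ΔΔG-statistic) formulation with coupling constant
k = 1; in the raw log-ratio the background frequencies cancel, so the
shipped background table enters through the pseudocount regularisation of
the column frequencies instead. Both perturbation methods are directional;
matrices store `max(score_ij, score_ji)` and record the convention.
Columns with > 50 % unobserved letters are masked, as are perturbation
subsets below 10 sequences.

Significance is by independent column permutation (preserving compositions,
destroying inter-column dependence), `p = (1 + #{null ≥ obs})/(1 + B)`,
with Benjamini–Hochberg adjustment across pairs. The framework reports
p-values; it deliberately does not assert a significance criterion for
"coevolving", since that threshold is a scientific judgement.

# Assay fits

The melt fit is Levenberg–Marquardt least squares of the Boltzmann sigmoid,
initialised from the terminal 10 % of points (baselines) and the
half-amplitude crossing (T_m). A fit whose amplitude is below 3 residual
standard deviations — or where the optimiser cannot even start, as on a
transition-free trace — is returned flagged `unidentifiable` rather than
as an error, because flat melts are a real experimental outcome. Heating
and cooling traces are fitted with the same model and their T_m difference
reported as hysteresis. Both fits are scale-equivariant in the signal.

The SI fit is ordinary least squares of residual activity on ratio over the
linear regime, with SI = −intercept/slope and a delta-method standard
error. The linear regime is defined as ratios whose replicate-mean activity
exceeds 0.1; applying the floor to the replicate mean rather than to single
noisy points avoids stochastic inclusion of zero-floor points. The floor
value 0.1 excludes post-intercept saturation and is configurable.

*Why triplicates matter.* With single measurements at ratios 0–2 (step
0.25), additive noise σ = 0.05 and the 0.1 floor, the x-intercept
estimator's standard error is ≈ 0.063 for SI ≈ 1.6, so the expected mean
absolute error is ≈ 0.05 — recovery to better than 0.05 is not achievable
in expectation from a single-replicate assay of this design. With the
conventional triplicate protocol the error drops to ≈ 0.04, which is the
regime the tests verify. This is the reason the assay generator defaults to
`replicates = 3`.

# Problem sizes and reproducibility

The test suite and acceptance script run entirely on generated data at
sizes chosen to make the statistics sharp but the runs quick: 300-frame
ensembles for cluster recovery (10 seeds), 10⁴ frames for the RMSF
calibration, 10⁵ steps for occupancy estimation, 61-point melts (20 noise
seeds), triplicate 9-ratio assays (50 seeds), and ≤ 8-column alignments
with 99–199 permutations. Every stochastic function takes an explicit seed
and restores the caller's RNG state; `runLoopscape()` writes a manifest
(parameters, package version, input checksums, seed) alongside every
artifact, and reruns with the same manifest are byte-identical.

# Known limitations

- The synthetic basins are rigid templates plus isotropic jitter: no
  solvent, no force field, no kinetics beyond first-order switching.
  Passing recovery tests shows the pipeline recovers structure it can
  represent; it says nothing about basin definitions in real ensembles.
- The frustration Hamiltonian is a reduction; per-contact classes on real
  structures should be read qualitatively.
- Covariation methods are uncorrected for phylogeny; with few effective
  sequences their power is limited — a negative finding on a small
  alignment is expected behaviour, not evidence of absence.
- The PDB parser reads ATOM records only (no HETATM, no mmCIF, no binary
  trajectory formats) and treats author residue numbering as authoritative;
  chimeric numbering schemes are handled by external alias tables such as
  `rclPositionTable()`.
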