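---
title: "Ensemble analysis for peptide-mimetic design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble analysis for peptide-mimetic design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensemblemimic)
```

This vignette is the package's own account of the science it implements:
what is being modelled, which quantities are computed and how, which
parameters matter, what the synthetic generators do and do not emulate, and
where genuinely open design choices were resolved.

## The analysis chain

The package answers one question: *which contiguous stretch of a protein
fragment moves like the corresponding stretch of the full-length protein?*
The premise is that a fragment region that reproduces the parent protein's
local dynamics is the best candidate for a minimal mimetic peptide. The
chain runs: ensembles → alignment → per-residue fluctuations → fluctuation
difference → window selection → peptide constructs, with two side analyses
(conformer clustering, and lysine exposure for cross-linker reactivity)
that characterise the protein ensemble itself.

All analyses operate on an `Ensemble`: an ordered set of conformers sharing
one heavy-atom topology. Hydrogens are excluded everywhere, at parse time.
Crystal structures resolve hydrogens poorly and ensemble generators differ
in whether they place them, so an "all atoms" deviation is read throughout
as *all heavy atoms*; this keeps every RMSd comparable across input
sources. Water (HOH) records and alternate locations other than `' '`/`'A'`
are likewise dropped, and multi-chain files reduce to their first chain
with a warning.

## Superposition and RMSd

Optimal rigid-body superposition uses the Kabsch algorithm: SVD of the
covariance of the centred point sets, with the reflection case corrected by
flipping the smallest singular vector so the rotation is always proper. Two
selections parameterise every RMSd: the *fit* selection, on which the
superposition is computed, and the *measure* selection, over which the
deviation is evaluated. They are kept separate because the two conventions
in use differ: conformer clustering uses fit = measure = backbone, while
the fragment-versus-protein cross matrix fits on the mapped backbone and
measures over all mapped heavy atoms. Superposing on the backbone and then
measuring all atoms is the standard construction of an "all atoms" RMSd
between structures of different flexibility, and it is the documented
choice here; fitting on all atoms instead changes values by a few percent
but not the shape of the matrix. No mass or occupancy weighting is applied:
all atoms weigh equally.

Ensemble alignment iterates superposition onto a running mean structure
(initialised at frame 1) until the mean moves by less than 1e-6 Å or ten
iterations — in practice two to three iterations suffice for unimodal
ensembles.

## Residue fluctuation analysis

After backbone alignment, the per-residue fluctuation is

RMSF_r = sqrt( mean over frames of the mean squared displacement of residue
r's basis atoms about their mean positions ).

The default basis is the Cα atom, the standard per-residue fluctuation
measure; a `residue_heavy` basis is available and coincides with the Cα
value whenever residues move rigidly. One caveat is inherent to any RMSF:
superposition absorbs six rigid degrees of freedom, so aligned RMSF values
sit a few percent below the unaligned fluctuation about a fixed reference,
and more so for short chains. Tests that validate the samplers' analytic
amplitudes therefore measure the unaligned fluctuation
(`residue_fluctuation(..., align = FALSE)`); analyses of real ensembles,
which do drift, should keep the default.

## Solvent accessibility and the lysine descriptor

Solvent-accessible surface area uses the Shrake–Rupley construction: for
each atom, test points on a sphere of radius vdW + probe are classified
against every neighbouring expanded sphere, and the accessible fraction
scales the sphere area. Defaults: water-mimicking probe 1.4 Å, Bondi radii
(C 1.70, N 1.55, O 1.52, S 1.80 Å; unknown elements fall back to 1.70 Å
with a warning), and 960 sphere points, where the quadrature error on an
isolated sphere is below 1%. The points come from a deterministic golden
spiral rather than random sampling, so SASA values are seed-free and
exactly reproducible. Because a fixed lab-frame grid would make the values
weakly orientation-dependent (a 2–5% wobble under rotation), coordinates
are first brought to a canonical pose — centroid at the origin, principal
axes as the frame, axis signs fixed by the third moment of the projections
— which makes the computed areas invariant under rigid transformation of
the input to numerical precision.

The lysine exposure descriptor, ASASA, is the mean over *all* frames of a
lysine's sidechain SASA (sidechain = heavy atoms outside N/CA/C/O: CB–NZ
on real structures, the CB pseudo-atom on synthetic chains). Averaging over
all sampled frames, rather than over cluster representatives, is the
literal reading of a trajectory-averaged exposure and uses strictly more
information. The reactivity ranking min–max normalises ASASA over the
lysine set, optionally min–max normalises the *negated* amine partial
charge (a more negative charge is read as greater electron availability on
the amine, i.e. higher nucleophilicity toward an NHS ester), and combines
the available descriptors by a weighted mean, default equal weights. No
combination rule is canonical for these two descriptors; the equal-weight
mean is the neutral choice and the weight is exposed. Charges are consumed
from a TSV — quantum-chemistry computation is out of scope by design.

## Clustering

Conformers are clustered by agglomerative average linkage on the backbone
RMSd matrix: repeatedly merge the pair of clusters with the smallest mean
inter-cluster distance, stopping when that minimum exceeds the cutoff
(default 2.0 Å). A "cutoff among the members of a cluster" admits more
than one reading; the average-linkage merge threshold used here is
equivalent to cutting the average-linkage dendrogram at the cutoff height
(and is verified against `hclust`/`cutree` in the tests). Complete linkage
— every intra-cluster pair within the cutoff — is the stricter alternative
reading and produces more, smaller clusters. Ties in the merge order are
broken toward the smallest member indices, and each cluster is represented
by its medoid (smallest mean distance to the other members, ties to the
lowest frame index), so the whole procedure is deterministic.

## The synthetic generators

Desk-scale testing cannot rerun nanosecond explicit-solvent MD, so the
package generates ensembles whose *statistics* are controlled.

**Reference geometry.** `build_reference_chain` places Cα atoms on a
regular helix with exact 3.8 Å Cα–Cα spacing; the helix is parameterised by
rise per residue and residues per turn, with the radius following from the
chord constraint. The default (rise 3.5 Å, 20 residues/turn) is a gently
curled, nearly extended chain. N, C, O and a single CB pseudo-sidechain
(1.5 Å perpendicular to the local chain direction; absent for Gly) ride in
the local tangent/normal/binormal frame. This is deliberately idealised:
the generators control dynamics, not secondary structure.

**Gaussian sampler.** Each frame displaces every residue rigidly by an
independent isotropic Gaussian with per-axis standard deviation `a_r`
(default 0.3 Å, a typical well-ordered-core amplitude), so the expected
unaligned Cα RMSF is exactly `a_r·√3 ≈ 0.52` Å — an analytic ground truth
the fluctuation code is tested against (measured/expected within 5% at
1000 frames). A loop range (default 108–127 for the full-length chain,
mirroring a known highly flexible loop) multiplies the amplitude by 3.
Rigid-residue displacement keeps intra-residue geometry fixed, so sidechain
exposure varies only through packing.

**Elastic-network Langevin sampler.** Cα beads are connected by harmonic
springs (unit spring constant, rest length = reference distance) between
all pairs within a 10 Å cutoff and propagated by overdamped Euler–Maruyama
dynamics, `x ← x − (dt/γ)∇U + sqrt(2·kT·dt/γ)·ξ`, with kT = 0.5, dt = 0.05,
γ = 1, 2000 equilibration steps and a recording stride of 20; backbone and
CB atoms ride rigidly with their Cα, and any coordinate exceeding 10³ Å
aborts with a stability error. For this sampler the default reference is a
*compact* helix (rise 1.5 Å, 3.6 residues/turn, about 12 contacts per bead):
an elastic network emulates a folded protein, whose core owes its rigidity
to a dense contact network. A `loop_range` strips all non-adjacent springs
from loop residues, emulating a solvent-exposed loop without tertiary
packing; the resulting loop-over-core mean-RMSF ratio is 1.6–2.0 across
seeds, reproducing qualitatively the elevated flexibility of a real
disordered loop. At kT = 0 the dynamics relaxes to the spring minimum (the
reference itself), giving zero RMSF — a built-in energy sanity check.

**Planted mimicry pairs.** `sample_fragment_pair` generates the protein
ensemble plus a fragment ensemble (default residues 1–38) whose amplitudes
equal the protein's inside a planted window (default 8–12) and are
multiplied by `outside_scale` (default 3) elsewhere, with an independent
seed. Downstream, the window selector should recover the planted window;
it does so in ≥ 95 of 100 seeds at 150 frames, which is the package's
end-to-end correctness experiment. What these generators do *not* emulate:
force-field energetics, solvent, anharmonic transitions between
conformational basins, correlated sidechain motion, or realistic
absolute RMSd scales. Passing tests demonstrate that the *analysis chain*
is correct and sensitive to planted signal; they say nothing about the
conformational behaviour of any real protein. In particular, under the
default synthetic amplitudes the fragment-versus-protein cross-RMSd values
fall almost entirely below 2 Å, so the fraction of values in the 2–4 Å
band — a headline statistic for real MD ensembles, where it is large — is
near zero here and is reported descriptively, not asserted.

**Seeding.** Seeds are mandatory in every spec; samplers use a private RNG
stream and restore the global state, so no analysis consumes unseeded
randomness and identical spec + seed is bitwise reproducible.

## Window selection and peptide construction

The mimicry comparison takes the per-residue difference
|RMSF_frag(i) − RMSF_prot(map(i))| over a strictly increasing 1:1 residue
mapping (positional identity for N-terminal fragments; no sequence
alignment is attempted). The core window is the contiguous stretch of
`window_len` residues (default 5) minimising the mean difference — an
exhaustive scan over all windows, with ties to the smallest start. The
selected window is then extended by up to `max_extension` (default 1)
residues per side while the flanking residue is hydrophilic on the
Kyte–Doolittle scale (hydropathy < 0); this reproduces the classic pattern
of padding a hydrophobic core (e.g. HLIKP) with hydrophilic neighbours
(Gln, Ser) for solubility. The extended peptide is fused downstream of the
HIV-1 Tat 47–58 carrier with a Gly linker, and a scrambled control is
drawn by a seeded Fisher–Yates permutation, redrawn until it differs from
the input (impossible, and an error, only when all residues are
identical).

Degenerate inputs are handled explicitly: windows longer than the mapped
region, non-contiguous residue numbering (the scan skips stretches with
gaps), cores at the chain end (no extension on that side), and profiles
missing mapped residues (an error naming the mapping).

## Numerical choices and problem sizes

Tolerances: Kabsch rotations are proper orthogonal to 1e-9; alignment
converges at 1e-6 Å mean shift; clustering symmetry is checked at 1e-9;
SASA quadrature error is below 1% at 960 points (and halves when the point
count doubles). Tie-breaks are lowest-index everywhere. The test suite
exercises the full study sizes — 147-residue protein, 38-residue fragment,
150 frames, 150 × 150 = 22 500 cross-RMSd values — because they run in
seconds; the repeated-seed experiments (100 seeds for loop flexibility and
window recovery) use 40–150 frames per seed, sizes at which the planted
effects are already far above sampling noise.

## Known limitations

Single-chain ensembles only; no mmCIF; missing residues are detected and
reported, never rebuilt (no loop modelling); no binding-affinity or
solubility prediction beyond the hydropathy rule; the lysine descriptors
rank *relative* adduct propensity and have no absolute calibration; and
the packaged human Fhit sequence is the only bundled data — every other
input is either user-supplied or generated.
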