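---
title: "Rotational symmetry of ring particles and oligomer interfaces: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotational symmetry of ring particles and oligomer interfaces: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringsym)
```

# The problem

Membrane-protein complexes that form rings — here the motivating case is
the flagellar export-gate protein FliP, which assembles into a ring of
about 10 nm diameter, and its partner FliO, a 5 nm ring carrying three
clamp-like appendages — show up in negative-stain electron microscopy as
small, noisy 2-D projections.  The question a microscopist asks of such
images is stoichiometry: how many subunits does the ring have?  A k-fold
ring, once resampled around its center, is a signal periodic in angle with
period $2\pi/k$, so the subunit count is a frequency-detection problem.

`ringsym` implements that detection chain as reusable, tested components,
together with a synthetic particle generator that provides ground truth
(real micrograph-scale data for this problem are typically not deposited),
and a companion module that characterizes the oligomer seen in a crystal
of the ring subunit's periplasmic domain: chain superposition, assembly
grouping, pseudo-D2 detection and interface chemistry.

# The symmetry chain

For a boxed particle image $I(x,y)$ with pixel size $a$ (Å/px) the chain
is:

1. **Normalize**: $I \mapsto (I - \bar I)/\mathrm{sd}(I)$.  Constant
   images are rejected as degenerate.
2. **Center**: the image is smoothed with a Gaussian of
   $\sigma = 2$ px, values below a noise floor (3 × the median absolute
   deviation of the smoothed image; zero for a clean image) are clipped,
   and the center is a weighted algebraic circle fit (Kåsa fit) through
   the remaining density.  For density lying on a circle the fit is
   exact; unlike a plain centroid it is insensitive to uneven intensity
   among the subunit blobs, whose lever arm (the ring radius) would
   otherwise amplify per-blob noise into pixel-scale center errors.  A
   degenerate fit falls back to the clipped centroid.
3. **Ring radius**: the rotational average (pixels binned by rounded
   radius, computed on the smoothed image), argmax over radius, refined by
   quadratic interpolation around the discrete peak.  The search is
   confined to ±30% of the Kåsa circle radius when available, because at
   small radii a bin averages only a handful of pixels and smoothed noise
   there can otherwise capture the argmax.  The diameter is also reported
   in nm, $d = 2 r a / 10$.
4. **Annulus and polar resampling**: the annulus
   $[0.6\,r_\mathrm{peak},\ 1.4\,r_\mathrm{peak}]$ is resampled by
   bilinear interpolation onto a polar grid of 32 radii × 360 angles
   (`toPolar()`).  360 angles is Nyquist-safe for $k_\max = 8$ with wide
   margin.
5. **Matched filter and collapse**: the image entering the polar stage is
   smoothed with a Gaussian of $\sigma = 2$ px, and the polar rows are
   collapsed to one angular profile $f(\theta_j)$ using the particle's
   own radial profile as ring weights.  Both steps are matched filters —
   in radius and at the blob scale — and both are switchable
   (`profileWeighting = "uniform"`, `matchedFilterSigmaPx = 0`).  They
   matter most for low orders: a 3-fold ring's fundamental exceeds its
   6-fold harmonic by only ~1.5× in power, and at SNR 2 the unweighted,
   unfiltered collapse misassigns ~20% of 3-fold rings to the harmonic,
   versus ~1% with the defaults.  An alternative collapse
   (`acfMode = "per_radius"`) computes one autocorrelation per polar ring
   and averages the curves; both modes agree on noiseless rings.
6. **Circular autocorrelation**:
   $c(m) = \sum_j f_j f_{(j+m) \bmod N} / \sum_j f_j^2$, so $c(0) = 1$.
7. **Symmetry spectrum**: $p_k = |\mathrm{DFT}(c)_k|$.  By the
   Wiener–Khinchin relation $p_k$ equals the squared magnitude of the
   profile's k-th Fourier coefficient divided by the profile power; the
   test suite asserts this against a naive $O(N^2)$ DFT oracle to 1e-8.
8. **Assignment**: $k_\mathrm{best} = \arg\max_{k \in [3, 8]} p_k$, ties
   broken toward smaller k (deterministic; exercised only in degenerate
   cases).  DC and $k < 3$ are excluded from the score normalization
   because background ramps and residual center error load $k = 1$.

Harmonic ambiguity is resolved by fundamental argmax only; pooling
harmonics would conflate a k-fold ring with its 2k-fold harmonic.

## Confidence flags

A call is flagged `lowConfidence` when any of these holds:

* best-to-runner-up power ratio < 1.5, or score
  $p_{k_\mathrm{best}} / \sum_{k=3}^{8} p_k$ < 0.4 — the call is not
  decisive within the band;
* power at $k = 2$ exceeds the in-band peak — the signature of elongated
  non-ring particles such as ring side views (two parallel bars), whose
  fundamental lies below the candidate band;
* the angular profile's variance is less than $10^{-6}$ of the polar
  sample variance — the angular signal is numerically empty.  Score and
  ratio are scale-free, so without an absolute floor a rotationally
  featureless object (a uniform annulus) would be scored on pure
  grid-interpolation residue, which is deterministic and concentrates at
  the lattice orders.  The floor is set far below any plausible real
  signal (faint signal is handled by the score/ratio thresholds, not by
  this guard).

The flags mirror how such data behave in practice: particles that are not
clean top views — side views, incomplete rings — produce spread spectra
and are reported with their argmax plus the flag rather than silently
binned.  Degenerate particles (constant images, centering failures) are
recorded per row and counted, never dropped silently, and never abort a
stack.

# The synthetic generator

`generateRingParticle()` renders one particle deterministically from a
`RingModel` and a seed; `generateDataset()` renders a stack with one
ground-truth row per slice, with per-particle seeds
`(masterSeed + i − 1) mod (2^31 − 1)` so any slice is reproducible in
isolation and reruns are bit-identical.

The default geometry matches the only sizes the motivating data state: a
96 px box at 2.0 Å/px, ring radius 25 px (10 nm diameter, `flipRingModel()`)
with 3 px Gaussian blobs; the FliO-like preset (`flioRingModel()`) uses
radius 12.5 px (5 nm) with three clamp blobs at $2\pi/3$ spacing.  The
FliO body is rendered as a dense 9-blob ring so the three clamps dominate
the angular signal, approximating a quasi-continuous annulus with 3-fold
appendages.  Signal-to-noise ratio is defined as blob amplitude over noise
standard deviation (the motivating work never quantifies its noise; SNR 2
is used as the default stress level in tests).  Protein contrast is
positive; stain-dark data are handled by the `invert` option.

Confounder classes parameterize views the analysis should *not* call
confidently: `side_view` (two parallel bars separated by the ring
diameter, bar length equal to the diameter), `partial_ring` (a contiguous
arc of 25–50% of the blobs deleted, fraction drawn uniformly), and
`clamp_ring`.  The confounder geometry is a stand-in — the source data
only establish that such views exist, not their distribution — so tests
assert directions (confounders are flagged low-confidence more often than
rings at equal SNR), not rates.

What the generator does **not** emulate: contrast transfer function and
defocus, stain granularity and correlated noise, 3-D projection of real
density, micrograph-level context (picking), and subunit shape beyond an
isotropic Gaussian.  Passing tests therefore demonstrate that the chain
recovers rotational order from noisy, jittered, ramped ring images of the
stated geometry — not that it would survive CTF artifacts or stain
variability on real micrographs.

# Numerical choices

* Coordinates are 0-based with pixel centers at integers; pixel matrices
  are indexed x-first, matching the MRC fast axis.
* MRC output is mode 2 (float32), little-endian, with the pixel size in
  the cell header; reading rejects non-square slices, NaN pixels, and
  non-float modes explicitly.  TIFF/PNG single images are mapped to
  [0, 1] and require an explicit pixel size.
* Bilinear interpolation everywhere in the polar stage (exact for linear
  images; ~1–2% peak attenuation at blob curvature, which cancels in the
  normalized spectrum).
* The uniform radial grid includes both annulus endpoints; averaging
  those samples estimates the uniform-in-r annulus mean with an
  $(n-1)/n$ endpoint bias that is irrelevant to the (mean-subtracted)
  angular analysis.
* `set.seed`-scoped randomness (`withr::with_seed`) keeps the generator
  from touching the caller's RNG state.

# Structure module

`readStructure()` parses mmCIF/PDB via bio3d (or a plain coordinate CSV),
keeps author chain ids and author residue numbering, drops hydrogens,
waters and ligands, and collapses altlocs to the highest-occupancy
conformer (ties toward "A").

* **Superposition** (`superposeCa()`): Kabsch least-squares fit (proper
  rotations only, via SVD with determinant correction) over Cα atoms
  matched by author residue number; RMSD is computed after the fit.  The
  rotation matrix itself feeds point-group detection, which is why the
  fit is implemented in-package; tests check it against a brute-force
  rotation-grid oracle (1e-4 Å on 10-atom toys) and against construction
  (known transforms recovered to 1e-6).
* **Assemblies** (`groupIntoAssemblies()`): connected components of the
  chain contact graph, edge iff any inter-chain heavy-atom pair < 4.5 Å.
* **Point group** (`detectPointSymmetry()`): a tetramer is D2 when the
  three rotations from the first chain to the others are all within 15°
  of 180° about mutually orthogonal axes (within 15°); the tolerance
  admits *pseudo* symmetry and is configurable.  Dimers at ~180° are C2;
  single chains C1; everything else "other".
* **Interfaces** (`findInterfaceResidues()`): residue pairs with any
  heavy-atom distance < 4.5 Å; salt bridges are Arg/Lys side-chain N to
  Asp/Glu carboxylate O pairs < 4.0 Å.  Both cutoffs are conventional
  values (the motivating work names residues but no cutoffs) and are
  exposed in the API and CLI.  Hydrophobicity classification uses the
  apolar set {ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO}: hydrophobic at
  apolar fraction ≥ 0.7, hydrophilic ≤ 0.3, mixed between — declared
  constants standing in for qualitative labels.
* **Molecule-pair roles** (`molPairRoles()`): within a tetramer the three
  symmetry-distinct pair relations are labeled from the interfaces
  themselves — contact-free pairs are "A–D"-like, the contacting pair(s)
  with the largest apolar fraction "A–B", the rest "A–C" — because the
  deposition's chain lettering need not match the molecule labels used in
  descriptions of the structure.

## The synthetic tetramer stand-in

`syntheticTetramer()` builds, entirely in code, a labelled-synthetic
coordinate model realizing the reported features of the FliP
periplasmic-domain crystal tetramer: chains spanning residues 122–188,
two tetramers (8 chains) with pairwise Cα RMSD below 0.46 Å, pseudo-D2
relations, a hydrophobic A–B interface carrying Tyr-124, Phe-128,
Met-154, Leu-155, Pro-176 and Leu-180, a mixed A–C interface carrying
Met-127, Arg-130, Val-131, Arg-134, Phe-138, Glu-142, Glu-182, Val-185,
Ala-186 and Phe-187 with Arg-134↔Glu-142/Glu-182 salt bridges, and no
A–D contact.  Chain A occupies one octant and B, C, D are its images
under 180° rotations about the z, x and y axes; interface residues carry
side-chain atoms placed near the corresponding 2-fold axis so that each
meets its image at ~2.8 Å.  Per-chain Gaussian coordinate noise
(σ = 0.12 Å, giving chain-pair RMSDs of ≈ σ√6 ≈ 0.3 Å) makes the
symmetry pseudo; σ = 0 gives exact D2 for construction oracles.

The stand-in exists because the real deposition is an external download,
while the analysis code must be testable self-contained.  It validates
the *code paths* — superposition, grouping, D2 detection, interface and
salt-bridge chemistry, classification thresholds — against engineered
truth.  It does not validate the real crystal's numbers; running
`readStructure()` on the deposited mmCIF and `structureReport()` on the
result performs the same computation on the real model.

```{r structure-demo}
mod <- syntheticTetramer()
max(rmsdMatrix(mod))
detectPointSymmetry(mod, groupIntoAssemblies(mod)[[1]])$group
findInterfaceResidues(mod, "A", "B")
```

# Problem sizes and determinism

The test suite and the acceptance script use: 600 particles (100 per
order 3..8) at SNR 2 for recovery rates; 60 noiseless particles for the
exactness check; 3 × 300 particles across noise σ ∈ {0.25, 0.5, 1.0} for
monotone degradation; 100 particles for radius recovery; 100 random
profiles (N = 360) for the Wiener–Khinchin oracle; and the 8-chain
synthetic tetramer for all structure checks.  Every random quantity is
seeded; generation and analysis are bit-reproducible for a fixed seed and
configuration, and the reports rewrite byte-identically.

# Known limitations

* The symmetry call is per-particle on raw (or externally class-averaged)
  boxed images; the package performs no alignment or 2-D classification,
  and no 3-D point-group inference from projections.
* Accuracy claims hold under the generator's noise model (additive white
  Gaussian noise, linear ramps); real negative-stain noise is correlated
  and signal-dependent.
* Ring radius estimation assumes a single dominant radial peak; nested
  double rings would need an explicit annulus.
* The hydrophobicity classification is residue-set based, not
  buried-surface-area based; no SASA, electrostatics, or refinement
  quality metrics are computed.
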