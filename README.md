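# ringsym

Rotational-symmetry (stoichiometry) analysis of ring-shaped macromolecular
complexes from boxed negative-stain EM particle images, plus
crystal-structure oligomer analysis for the ring subunit.

## The problem

Ring-forming membrane proteins — the motivating case is the flagellar
export-gate protein FliP, a ~10 nm ring, and its partner FliO, a ~5 nm
ring with three clamp-like appendages — appear in negative-stain EM as
noisy 2-D projections.  The stoichiometry question ("how many subunits?")
becomes a frequency-detection problem once the particle is resampled
around its center: a k-fold ring is periodic in angle with period 2π/k.

`ringsym` implements the detection chain for microscopists and method
developers:

1. polar resampling of an annulus about the estimated particle center,
2. the angular profile's circular autocorrelation
   c(m) = Σⱼ fⱼ f₍ⱼ₊ₘ₎ / Σⱼ fⱼ², and
3. Fourier analysis of c: power pₖ = |DFT(c)ₖ| (by Wiener–Khinchin, the
   normalized squared magnitude of the profile's k-th Fourier
   coefficient), with the symmetry order assigned as
   k* = argmax₍ₖ₌₃…₈₎ pₖ, plus confidence diagnostics.

A synthetic ring-particle generator with per-particle ground truth stands
in for non-deposited micrograph data, so every stage is testable.  A
companion structure module analyzes the crystal oligomer of the ring
subunit's periplasmic domain: Cα superposition (Kabsch), assembly grouping
by contact graph, pseudo-D2 point-group detection, and interface
residue / salt-bridge / hydrophobicity characterization, validated against
a code-built synthetic pseudo-D2 tetramer and applicable to any deposited
mmCIF/PDB model via `readStructure()`.

## Worked example

```r
library(ringsym)

# a 6-fold FliP-like ring: radius 25 px at 2.0 A/px (10 nm diameter),
# amplitude 1, additive Gaussian noise sd 0.5 (SNR 2)
img <- generateRingParticle(flipRingModel(noiseSigma = 0.5), seed = 42L,
                            particleIdent = "demo")
res <- analyzeParticle(img)
res$assignment
#> SymmetryAssignment 'demo': k = 6 (score 0.977, ratio 84.25)
round(spectrumPower(res$spectrum, 3:8), 3)
#>       3       4       5       6       7       8
#>   1.820   0.120   0.389 153.311   1.162   0.059
c(res$radiusPx, res$diameterNm)
#> 25.23 10.09
```

The call is 6-fold with 97.7% of the candidate-band power at k = 6, and
the measured ring diameter is 10.09 nm.  Stack-level analysis
(`analyzeStack()`) tallies these calls into a histogram over orders 3–8
and `evaluateAgainstTruth()` scores them against generator truth.

The same chain runs from the shell:

```sh
ringsym=$(Rscript -e 'cat(system.file("scripts/ringsym", package = "ringsym"))')
Rscript $ringsym simulate --spec sim.yaml --out demo.mrcs --truth demo_truth.csv
Rscript $ringsym analyze  --stack demo.mrcs --out demo
#> analyzed 30 particles: 3-fold: 0, 4-fold: 0, 5-fold: 10, 6-fold: 20, ...
Rscript $ringsym evaluate --assignments demo_assignments.csv --truth demo_truth.csv
#>   class  n accuracy low_confidence_rate
#> 1     5 10        1                   0
#> 2     6 20        1                   0
```

Structure side, on the bundled synthetic stand-in (or any mmCIF/PDB file):

```r
mod <- syntheticTetramer()
max(rmsdMatrix(mod))                                   # 0.322 A over 28 pairs
detectPointSymmetry(mod, groupIntoAssemblies(mod)[[1]])$group   # "D2"
findInterfaceResidues(mod, "A", "B")
#> Interface A-B (cutoff 4.5 A): 6 residue contacts, 0 salt bridges;
#> hydrophobic (apolar fraction 0.83)
```

## Package layout

* `R/ringgen.R` — synthetic particle/dataset generator (`RingModel`,
  `generateRingParticle()`, `generateDataset()`, presets).
* `R/imagetools.R` — MRC/MRCS (mode 2) and TIFF/PNG I/O, normalization,
  center estimation.
* `R/symmetry.R` — polar transform, angular profile, circular
  autocorrelation, symmetry spectrum, assignment, radius estimation.
* `R/pipeline.R` — stack analysis, histogram, reports, truth evaluation,
  YAML configuration.
* `R/structure.R`, `R/synthetic-tetramer.R` — structure parsing,
  superposition, assemblies, point groups, interfaces, and the synthetic
  tetramer stand-in.
* `inst/scripts/ringsym` — command-line front end
  (simulate / analyze / evaluate / structure).
* `vignettes/ring-symmetry-analysis.Rmd` — the methods vignette: model,
  assumptions, parameter rationale, numerical choices, limitations.
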