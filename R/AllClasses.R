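.PARTICLE_CLASSES <- c("ring", "side_view", "partial_ring", "clamp_ring")

#' Parametric model of a synthetic ring particle
#'
#' A \code{RingModel} holds every parameter needed to render one synthetic
#' negative-stain-like particle: the blob symmetry order, ring geometry in
#' pixels, signal amplitude, additive noise level, a linear background ramp,
#' in-plane rotation, center jitter, box size and pixel size.  Protein
#' contrast is positive (bright); analysis of stain-dark data uses the
#' \code{invert} option of [AnalysisConfig()].
#'
#' @slot nFold integer symmetry order (number of blobs), >= 1.
#' @slot ringRadiusPx ring radius in pixels, > 0.
#' @slot blobSigmaPx isotropic Gaussian blob s.d. in pixels, > 0.
#' @slot amplitude peak blob intensity (arbitrary units).
#' @slot noiseSigma s.d. of additive i.i.d. Gaussian noise, >= 0.
#' @slot backgroundSlope numeric length 2, linear ramp per pixel in x and y.
#' @slot rotationRad in-plane rotation in radians, in [0, 2*pi).
#' @slot centerOffsetPx numeric length 2, center offset from the box center.
#' @slot boxPx even box edge length in pixels, >= 32.
#' @slot pixelSizeA pixel size in Angstrom per pixel, > 0.
#' @slot particleClass one of \code{"ring"}, \code{"side_view"},
#'   \code{"partial_ring"}, \code{"clamp_ring"}.
#' @seealso [RingModel()], [generateRingParticle()]
#' @exportClass RingModel
setClass("RingModel",
  representation(
    nFold           = "integer",
    ringRadiusPx    = "numeric",
    blobSigmaPx     = "numeric",
    amplitude       = "numeric",
    noiseSigma      = "numeric",
    backgroundSlope = "numeric",
    rotationRad     = "numeric",
    centerOffsetPx  = "numeric",
    boxPx           = "integer",
    pixelSizeA      = "numeric",
    particleClass   = "character"
  )
)

setValidity("RingModel", function(object) {
  msg <- character()
  if (length(object@nFold) != 1L || object@nFold < 1L)
    msg <- c(msg, "nFold must be a single integer >= 1")
  if (object@ringRadiusPx <= 0) msg <- c(msg, "ringRadiusPx must be > 0")
  if (object@blobSigmaPx <= 0) msg <- c(msg, "blobSigmaPx must be > 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(object@backgroundSlope) != 2L)
    msg <- c(msg, "backgroundSlope must have length 2")
  if (object@rotationRad < 0 || object@rotationRad >= 2 * pi)
    msg <- c(msg, "rotationRad must lie in [0, 2*pi)")
  if (length(object@centerOffsetPx) != 2L)
    msg <- c(msg, "centerOffsetPx must have length 2")
  if (object@boxPx < 32L || object@boxPx %% 2L != 0L)
    msg <- c(msg, "boxPx must be an even integer >= 32")
  if (object@pixelSizeA <= 0) msg <- c(msg, "pixelSizeA must be > 0")
  if (!object@particleClass %in% .PARTICLE_CLASSES)
    msg <- c(msg, sprintf("particleClass must be one of: %s",
                          paste(.PARTICLE_CLASSES, collapse = ", ")))
  # geometric invariants: the rendered density must fit in the box, and the
  # requested order must be resolvable at the blob size
  if (length(msg) == 0L) {
    reach <- object@ringRadiusPx + 3 * object@blobSigmaPx +
      sqrt(sum(object@centerOffsetPx^2))
    if (object@particleClass == "clamp_ring")
      reach <- reach + 2.5 * object@blobSigmaPx
    if (reach >= object@boxPx / 2)
      msg <- c(msg, sprintf(
        "ring does not fit in box: radius + 3*sigma + |offset| = %.1f >= boxPx/2 = %.1f",
        reach, object@boxPx / 2))
    if (object@nFold >= pi * object@ringRadiusPx / object@blobSigmaPx)
      msg <- c(msg, sprintf(
        "nFold = %d not resolvable: must be < pi*radius/sigma = %.1f",
        object@nFold, pi * object@ringRadiusPx / object@blobSigmaPx))
  }
  if (length(msg)) msg else TRUE
})

#' One boxed particle image
#'
#' Square 2-D float image with pixel-size metadata; the unit the symmetry
#' engine consumes.  Pixels are stored with the x axis as the first array
#' index: \code{pixels(img)[i, j]} is the value at x = i-1, y = j-1, with
#' 0-based coordinates and pixel centers at integers (origin at the first
#' pixel).
#'
#' @slot pixels numeric matrix, square, all values finite, edge >= 32 px.
#' @slot pixelSizeA pixel size in Angstrom per pixel.
#' @slot particleId particle identifier string.
#' @exportClass ParticleImage
setClass("ParticleImage",
  representation(pixels = "matrix", pixelSizeA = "numeric",
                 particleId = "character")
)

setValidity("ParticleImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (d[1] != d[2]) msg <- c(msg, "image must be square")
  if (d[1] < 32L) msg <- c(msg, "box must be >= 32 px")
  if (!all(is.finite(object@pixels))) msg <- c(msg, "pixels must be finite")
  if (length(object@pixelSizeA) != 1L || object@pixelSizeA <= 0)
    msg <- c(msg, "pixelSizeA must be a single value > 0")
  if (length(msg)) msg else TRUE
})

#' Polar resampling of an annulus
#'
#' Result of resampling an image onto (radius, angle) coordinates about a
#' center: \code{values[i, j]} is the bilinear interpolation at radius
#' \code{r_i} (uniform over \code{[rMinPx, rMaxPx]}) and angle
#' \code{theta_j = 2*pi*(j-1)/nAngles}.
#'
#' @slot values numeric matrix, nRings x nAngles.
#' @slot rMinPx,rMaxPx annulus bounds in pixels.
#' @exportClass PolarImage
setClass("PolarImage",
  representation(values = "matrix", rMinPx = "numeric", rMaxPx = "numeric")
)

setValidity("PolarImage", function(object) {
  msg <- character()
  if (object@rMinPx < 1) msg <- c(msg, "rMinPx must be >= 1")
  if (object@rMaxPx <= object@rMinPx) msg <- c(msg, "rMaxPx must exceed rMinPx")
  if (ncol(object@values) < 4L) msg <- c(msg, "need at least 4 angular samples")
  if (length(msg)) msg else TRUE
})

#' Rotational-order power spectrum
#'
#' Power at rotational order k = 0..kMax, computed as the magnitude of the
#' discrete Fourier coefficients of the circular autocorrelation of the
#' angular profile.  By the Wiener-Khinchin relation this equals the squared
#' magnitude of the profile's k-th Fourier coefficient, normalized by the
#' profile's total power.
#'
#' @slot power named numeric vector, names "0".."kMax", all values >= 0.
#' @slot nAngles number of angular samples the spectrum was computed from.
#' @exportClass SymmetrySpectrum
setClass("SymmetrySpectrum",
  representation(power = "numeric", nAngles = "integer")
)

setValidity("SymmetrySpectrum", function(object) {
  msg <- character()
  if (any(object@power < 0)) msg <- c(msg, "power must be nonnegative")
  if (is.null(names(object@power)) ||
      !identical(names(object@power), as.character(seq_along(object@power) - 1L)))
    msg <- c(msg, "power must be named \"0\", \"1\", ...")
  if (length(msg)) msg else TRUE
})

#' Per-particle symmetry call
#'
#' @slot particleId particle identifier.
#' @slot kBest assigned rotational order (argmax of power over the candidate
#'   range; ties broken toward smaller k).
#' @slot score power at kBest divided by total candidate-range power, in
#'   [0, 1].
#' @slot confidenceRatio power at kBest over power at the runner-up order,
#'   >= 1.
#' @slot bandFraction fraction of the profile's total angular power that
#'   falls in the candidate band (both frequency signs counted); a
#'   featureless profile leaves almost nothing there.
#' @slot lowConfidence flag set when the call is weakly supported.
#' @exportClass SymmetryAssignment
setClass("SymmetryAssignment",
  representation(particleId = "character", kBest = "integer",
                 score = "numeric", confidenceRatio = "numeric",
                 bandFraction = "numeric", lowConfidence = "logical")
)

setValidity("SymmetryAssignment", function(object) {
  msg <- character()
  if (object@score < 0 || object@score > 1 + 1e-12)
    msg <- c(msg, "score must lie in [0, 1]")
  if (object@confidenceRatio < 1 - 1e-12)
    msg <- c(msg, "confidenceRatio must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Stack-level symmetry tally
#'
#' Counts of particles assigned to each candidate order, plus the number of
#' particles rejected as degenerate (e.g. constant images).  Counts and
#' degenerates always sum to the number of particles analyzed.
#'
#' @slot counts named integer vector over k = kMin..kMax.
#' @slot nTotal number of particles analyzed.
#' @slot nDegenerate number of particles rejected upstream.
#' @exportClass SymmetryHistogram
setClass("SymmetryHistogram",
  representation(counts = "integer", nTotal = "integer",
                 nDegenerate = "integer")
)

setValidity("SymmetryHistogram", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (sum(object@counts) + object@nDegenerate != object@nTotal)
    msg <- c(msg, "counts + degenerates must equal nTotal")
  if (length(msg)) msg else TRUE
})

#' Analysis configuration
#'
#' All tunables of the per-particle symmetry chain and the stack pipeline.
#' \code{annulusMode = "auto"} places the annulus at
#' \code{[annulusInner, annulusOuter] * r_peak} where \code{r_peak} comes
#' from [estimateRingRadius()]; \code{"explicit"} uses \code{rMinPx} and
#' \code{rMaxPx} as given.
#'
#' @slot kMin,kMax candidate order range (defaults 3..8).
#' @slot nAngles,nRings polar sampling grid (defaults 360 x 32).
#' @slot annulusMode "auto" or "explicit".
#' @slot rMinPx,rMaxPx explicit annulus bounds (used when annulusMode is
#'   "explicit").
#' @slot annulusInner,annulusOuter annulus bounds relative to the radial
#'   peak (auto mode; defaults 0.6 and 1.4).
#' @slot confidenceRatioMin,scoreMin low-confidence thresholds (defaults
#'   1.5 and 0.4).
#' @slot angularVarianceMin floor on the ratio of angular-profile variance
#'   to polar-sample variance below which the angular signal is considered
#'   numerically empty and the call flagged (default 1e-6).
#' @slot invert flip image contrast before analysis (for stain-dark data).
#' @slot acfMode "collapse" (one profile, the weighted radial mean over the
#'   annulus) or "per_radius" (one ACF per polar ring, averaged afterwards).
#' @slot smoothSigmaPx Gaussian smoothing s.d. used for center and radius
#'   estimation.
#' @slot matchedFilterSigmaPx Gaussian smoothing s.d. applied to the image
#'   before polar sampling (0 disables); suppresses noise and harmonic
#'   power at the blob scale.
#' @slot profileWeighting "matched" (rings weighted by the particle's
#'   radial profile when collapsing) or "uniform".
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(
    kMin = "integer", kMax = "integer",
    nAngles = "integer", nRings = "integer",
    annulusMode = "character", rMinPx = "numeric", rMaxPx = "numeric",
    annulusInner = "numeric", annulusOuter = "numeric",
    confidenceRatioMin = "numeric", scoreMin = "numeric",
    angularVarianceMin = "numeric",
    invert = "logical", acfMode = "character", smoothSigmaPx = "numeric",
    matchedFilterSigmaPx = "numeric", profileWeighting = "character"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@kMin < 1L) msg <- c(msg, "kMin must be >= 1")
  if (object@kMax < object@kMin) msg <- c(msg, "kMax must be >= kMin")
  if (object@nAngles < 4L * object@kMax)
    msg <- c(msg, "nAngles must be >= 4*kMax")
  if (!object@annulusMode %in% c("auto", "explicit"))
    msg <- c(msg, "annulusMode must be \"auto\" or \"explicit\"")
  if (!object@acfMode %in% c("collapse", "per_radius"))
    msg <- c(msg, "acfMode must be \"collapse\" or \"per_radius\"")
  if (!object@profileWeighting %in% c("matched", "uniform"))
    msg <- c(msg, "profileWeighting must be \"matched\" or \"uniform\"")
  if (object@matchedFilterSigmaPx < 0)
    msg <- c(msg, "matchedFilterSigmaPx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Parsed macromolecular structure
#'
#' Heavy (non-hydrogen) protein atoms of a crystallographic model, one row
#' per atom, with author chain identifiers and author residue numbering.
#' Waters, ligands and hydrogens are removed at parse time and alternate
#' locations are collapsed to the highest-occupancy conformer.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{atom} (PDB atom name), \code{element},
#'   \code{x}, \code{y}, \code{z} (Angstrom).
#' @slot source origin of the model (file path or description).
#' @exportClass StructureModel
setClass("StructureModel",
  representation(atoms = "data.frame", source = "character")
)

setValidity("StructureModel", function(object) {
  msg <- character()
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else {
    if (!all(is.finite(object@atoms$x) & is.finite(object@atoms$y) &
             is.finite(object@atoms$z)))
      msg <- c(msg, "coordinates must be finite")
    if (any(object@atoms$element %in% c("H", "D")))
      msg <- c(msg, "hydrogens must be excluded")
  }
  if (length(msg)) msg else TRUE
})

#' Rigid-body superposition result
#'
#' Optimal proper-rotation least-squares fit of one chain's C-alpha trace
#' onto another's:  \code{rotation \%*\% x + translation} maps the mobile
#' coordinates onto the reference.
#'
#' @slot rotation 3x3 orthonormal matrix with det +1.
#' @slot translation length-3 vector (Angstrom).
#' @slot rmsdA root-mean-square deviation after the fit (Angstrom).
#' @slot nAtoms number of atom pairs fitted.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsdA = "numeric", nAtoms = "integer")
)

setValidity("SuperpositionResult", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-6) msg <- c(msg, "rotation must be proper (det +1)")
  }
  if (object@rmsdA < 0) msg <- c(msg, "rmsdA must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Chain-pair interface summary
#'
#' Residue-level description of the contact interface between two chains:
#' residue pairs with any inter-chain heavy-atom distance below the cutoff,
#' the per-chain interface residue sets, detected salt bridges, and a
#' hydrophobicity classification of the interface residue set.
#'
#' @slot chainA,chainB chain identifiers.
#' @slot cutoffA heavy-atom contact cutoff (Angstrom).
#' @slot contacts data.frame: \code{resnoA}, \code{resnameA}, \code{resnoB},
#'   \code{resnameB}, \code{minDistA} (minimum heavy-atom distance).
#' @slot residuesA,residuesB data.frames of interface residues
#'   (\code{resno}, \code{resname}), ordered by residue number.
#' @slot saltBridges data.frame: basic/acidic residue pair and N-O distance.
#' @slot hydrophobicFraction fraction of interface residues in the apolar
#'   set (ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO).
#' @slot classification "hydrophobic" (fraction >= 0.7), "hydrophilic"
#'   (<= 0.3), "mixed" (between), or "empty".
#' @exportClass InterfaceSummary
setClass("InterfaceSummary",
  representation(chainA = "character", chainB = "character",
                 cutoffA = "numeric", contacts = "data.frame",
                 residuesA = "data.frame", residuesB = "data.frame",
                 saltBridges = "data.frame",
                 hydrophobicFraction = "numeric",
                 classification = "character")
)

setValidity("InterfaceSummary", function(object) {
  msg <- character()
  if (!object@classification %in% c("hydrophobic", "mixed", "hydrophilic", "empty"))
    msg <- c(msg, "classification must be hydrophobic/mixed/hydrophilic/empty")
  if (nrow(object@contacts) && any(object@contacts$minDistA > object@cutoffA))
    msg <- c(msg, "all contact distances must be <= cutoff")
  if (length(msg)) msg else TRUE
})
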