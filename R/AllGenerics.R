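#' Pixel matrix of a particle image
#' @param x a [ParticleImage-class]
#' @return numeric matrix (x-first indexing; see [ParticleImage-class])
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "ParticleImage", function(x) x@pixels)

#' Pixel size in Angstrom per pixel
#' @param x a [ParticleImage-class]
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ParticleImage", function(x) x@pixelSizeA)

#' Particle identifier
#' @param x a [ParticleImage-class] or [SymmetryAssignment-class]
#' @export
setGeneric("particleId", function(x) standardGeneric("particleId"))

#' @rdname particleId
#' @export
setMethod("particleId", "ParticleImage", function(x) x@particleId)

#' @rdname particleId
#' @export
setMethod("particleId", "SymmetryAssignment", function(x) x@particleId)

#' Polar sample values
#' @param x a [PolarImage-class]
#' @return numeric matrix, rings in rows, angles in columns
#' @export
setGeneric("polarValues", function(x) standardGeneric("polarValues"))

#' @rdname polarValues
#' @export
setMethod("polarValues", "PolarImage", function(x) x@values)

#' Per-order power of a symmetry spectrum
#' @param x a [SymmetrySpectrum-class]
#' @param k optional integer vector of orders; default all stored orders
#' @return named numeric vector of power values
#' @export
setGeneric("spectrumPower", function(x, k = NULL) standardGeneric("spectrumPower"))

#' @rdname spectrumPower
#' @export
setMethod("spectrumPower", "SymmetrySpectrum", function(x, k = NULL) {
  if (is.null(k)) return(x@power)
  x@power[as.character(k)]
})

#' Assigned symmetry order
#' @param x a [SymmetryAssignment-class]
#' @export
setGeneric("kBest", function(x) standardGeneric("kBest"))

#' @rdname kBest
#' @export
setMethod("kBest", "SymmetryAssignment", function(x) x@kBest)

#' Assignment score (fraction of candidate-range power at kBest)
#' @param x a [SymmetryAssignment-class]
#' @export
setGeneric("assignmentScore", function(x) standardGeneric("assignmentScore"))

#' @rdname assignmentScore
#' @export
setMethod("assignmentScore", "SymmetryAssignment", function(x) x@score)

#' Ratio of best to runner-up power
#' @param x a [SymmetryAssignment-class]
#' @export
setGeneric("confidenceRatio", function(x) standardGeneric("confidenceRatio"))

#' @rdname confidenceRatio
#' @export
setMethod("confidenceRatio", "SymmetryAssignment", function(x) x@confidenceRatio)

#' Low-confidence flag of an assignment
#' @param x a [SymmetryAssignment-class]
#' @export
setGeneric("isLowConfidence", function(x) standardGeneric("isLowConfidence"))

#' @rdname isLowConfidence
#' @export
setMethod("isLowConfidence", "SymmetryAssignment", function(x) x@lowConfidence)

#' Histogram counts by symmetry order
#' @param x a [SymmetryHistogram-class]
#' @return named integer vector
#' @export
setGeneric("histogramCounts", function(x) standardGeneric("histogramCounts"))

#' @rdname histogramCounts
#' @export
setMethod("histogramCounts", "SymmetryHistogram", function(x) x@counts)

#' Atom table of a structure
#' @param x a [StructureModel-class]
#' @return data.frame, one row per heavy atom
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' Chain identifiers of a structure
#' @param x a [StructureModel-class]
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname chainIds
#' @export
setMethod("chainIds", "StructureModel", function(x) unique(x@atoms$chain))

#' Post-fit RMSD in Angstrom
#' @param x a [SuperpositionResult-class]
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))

#' @rdname rmsd
#' @export
setMethod("rmsd", "SuperpositionResult", function(x) x@rmsdA)

#' Fitted rotation matrix
#' @param x a [SuperpositionResult-class]
#' @export
setGeneric("rotationMatrix", function(x) standardGeneric("rotationMatrix"))

#' @rdname rotationMatrix
#' @export
setMethod("rotationMatrix", "SuperpositionResult", function(x) x@rotation)

#' Interface residues of one side of a chain-pair interface
#' @param x an [InterfaceSummary-class]
#' @param side "A" or "B"
#' @return data.frame with columns resno, resname
#' @export
setGeneric("interfaceResidues", function(x, side = "A")
  standardGeneric("interfaceResidues"))

#' @rdname interfaceResidues
#' @export
setMethod("interfaceResidues", "InterfaceSummary", function(x, side = "A") {
  side <- match.arg(side, c("A", "B"))
  if (side == "A") x@residuesA else x@residuesB
})

#' Salt bridges of an interface
#' @param x an [InterfaceSummary-class]
#' @return data.frame, one row per basic/acidic residue pair
#' @export
setGeneric("saltBridges", function(x) standardGeneric("saltBridges"))

#' @rdname saltBridges
#' @export
setMethod("saltBridges", "InterfaceSummary", function(x) x@saltBridges)

setMethod("show", "RingModel", function(object) {
  cat(sprintf(
    "RingModel: %s, %d-fold, r = %.1f px (%.1f nm diameter), sigma = %.1f px\n",
    object@particleClass, object@nFold, object@ringRadiusPx,
    2 * object@ringRadiusPx * object@pixelSizeA / 10, object@blobSigmaPx))
  cat(sprintf("  box %d px @ %.2f A/px; amplitude %.3g, noise %.3g (SNR %s)\n",
    object@boxPx, object@pixelSizeA, object@amplitude, object@noiseSigma,
    if (object@noiseSigma > 0)
      sprintf("%.2f", object@amplitude / object@noiseSigma) else "Inf"))
})

setMethod("show", "ParticleImage", function(object) {
  cat(sprintf("ParticleImage '%s': %d x %d px @ %.2f A/px, range [%.3g, %.3g]\n",
    object@particleId, nrow(object@pixels), ncol(object@pixels),
    object@pixelSizeA, min(object@pixels), max(object@pixels)))
})

setMethod("show", "PolarImage", function(object) {
  cat(sprintf("PolarImage: %d rings x %d angles, annulus [%.1f, %.1f] px\n",
    nrow(object@values), ncol(object@values), object@rMinPx, object@rMaxPx))
})

setMethod("show", "SymmetrySpectrum", function(object) {
  cat(sprintf("SymmetrySpectrum (k = 0..%d, from %d angles)\n",
              length(object@power) - 1L, object@nAngles))
  k <- seq_along(object@power) - 1L
  show <- k >= 1L & k <= min(12L, max(k))
  print(round(object@power[show], 4))
})

setMethod("show", "SymmetryAssignment", function(object) {
  cat(sprintf("SymmetryAssignment '%s': k = %d (score %.3f, ratio %.2f%s)\n",
    object@particleId, object@kBest, object@score, object@confidenceRatio,
    if (object@lowConfidence) ", LOW CONFIDENCE" else ""))
})

setMethod("show", "SymmetryHistogram", function(object) {
  cat(sprintf("SymmetryHistogram: %d particles (%d degenerate)\n",
              object@nTotal, object@nDegenerate))
  print(object@counts)
})

setMethod("show", "StructureModel", function(object) {
  ch <- unique(object@atoms$chain)
  cat(sprintf("StructureModel [%s]: %d chains (%s), %d residues, %d heavy atoms\n",
    object@source, length(ch), paste(ch, collapse = ","),
    nrow(unique(object@atoms[, c("chain", "resno")])), nrow(object@atoms)))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd = %.4f A over %d atoms\n",
              object@rmsdA, object@nAtoms))
})

setMethod("show", "InterfaceSummary", function(object) {
  cat(sprintf(
    "Interface %s-%s (cutoff %.1f A): %d residue contacts, %d salt bridges; %s (apolar fraction %.2f)\n",
    object@chainA, object@chainB, object@cutoffA, nrow(object@contacts),
    nrow(object@saltBridges), object@classification,
    object@hydrophobicFraction))
})
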