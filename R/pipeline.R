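#' Construct an analysis configuration
#'
#' @param kMin,kMax candidate order range (default 3..8)
#' @param nAngles,nRings polar sampling grid (default 360 x 32,
#'   Nyquist-safe for kMax = 8 with wide margin)
#' @param annulusMode "auto" (annulus from the radial peak) or "explicit"
#' @param rMinPx,rMaxPx explicit annulus bounds
#' @param annulusInner,annulusOuter annulus relative to the radial peak
#' @param confidenceRatioMin,scoreMin low-confidence thresholds
#' @param angularVarianceMin numerically-empty-signal floor (see
#'   [assignSymmetry()])
#' @param invert flip contrast before analysis
#' @param acfMode "collapse" or "per_radius"
#' @param smoothSigmaPx smoothing s.d. for center and radius estimation
#' @param matchedFilterSigmaPx smoothing s.d. applied before polar sampling
#'   (0 disables the matched filter)
#' @param profileWeighting "matched" or "uniform" ring weighting in the
#'   collapse step
#' @return an [AnalysisConfig-class]
#' @export
analysisConfig <- function(kMin = 3L, kMax = 8L, nAngles = 360L,
                           nRings = 32L, annulusMode = "auto",
                           rMinPx = NA_real_, rMaxPx = NA_real_,
                           annulusInner = 0.6, annulusOuter = 1.4,
                           confidenceRatioMin = 1.5, scoreMin = 0.4,
                           angularVarianceMin = 1e-6,
                           invert = FALSE, acfMode = "collapse",
                           smoothSigmaPx = 2, matchedFilterSigmaPx = 2,
                           profileWeighting = "matched") {
  new("AnalysisConfig", kMin = as.integer(kMin), kMax = as.integer(kMax),
      nAngles = as.integer(nAngles), nRings = as.integer(nRings),
      annulusMode = annulusMode, rMinPx = rMinPx, rMaxPx = rMaxPx,
      annulusInner = annulusInner, annulusOuter = annulusOuter,
      confidenceRatioMin = confidenceRatioMin, scoreMin = scoreMin,
      angularVarianceMin = angularVarianceMin, invert = invert, acfMode = acfMode, smoothSigmaPx = smoothSigmaPx,
      matchedFilterSigmaPx = matchedFilterSigmaPx,
      profileWeighting = profileWeighting)
}

#' Read an analysis configuration from YAML
#'
#' Recognized keys (snake_case) mirror the arguments of [analysisConfig()]:
#' \code{k_min}, \code{k_max}, \code{n_angles}, \code{n_rings},
#' \code{annulus_mode}, \code{r_min_px}, \code{r_max_px},
#' \code{annulus_inner}, \code{annulus_outer}, \code{confidence_ratio_min},
#' \code{score_min}, \code{invert}, \code{acf_mode}, \code{smooth_sigma_px}.
#'
#' @param path YAML file
#' @return an [AnalysisConfig-class]
#' @export
readAnalysisConfig <- function(path) {
  y <- yaml::read_yaml(path)
  key <- c(k_min = "kMin", k_max = "kMax", n_angles = "nAngles",
           n_rings = "nRings", annulus_mode = "annulusMode",
           r_min_px = "rMinPx", r_max_px = "rMaxPx",
           annulus_inner = "annulusInner", annulus_outer = "annulusOuter",
           confidence_ratio_min = "confidenceRatioMin",
           score_min = "scoreMin", angular_variance_min = "angularVarianceMin",
           invert = "invert", acf_mode = "acfMode",
           smooth_sigma_px = "smoothSigmaPx",
           matched_filter_sigma_px = "matchedFilterSigmaPx",
           profile_weighting = "profileWeighting")
  args <- y[names(y) %in% names(key)]
  names(args) <- key[names(args)]
  do.call(analysisConfig, args)
}

#' Run the symmetry chain on one particle
#'
#' normalize -> center -> radial peak -> annulus -> matched filter ->
#' polar -> angular profile -> circular autocorrelation -> Fourier
#' spectrum -> assignment.
#'
#' @param image a [ParticleImage-class]
#' @param config an [AnalysisConfig-class]
#' @return list with \code{assignment} ([SymmetryAssignment-class]),
#'   \code{spectrum}, \code{radiusPx}, \code{diameterNm}
#' @export
analyzeParticle <- function(image, config = analysisConfig()) {
  validObject(config)
  if (config@invert) image <- invertImage(image)
  img <- normalizeImage(image)
  ctr <- estimateCenter(img, smoothSigmaPx = config@smoothSigmaPx)
  rad <- estimateRingRadius(img, ctr, smoothSigmaPx = config@smoothSigmaPx)
  box <- nrow(img@pixels)
  if (config@annulusMode == "auto") {
    rMin <- max(1, config@annulusInner * rad$radiusPx)
    rMax <- min(box / 2 - 1, config@annulusOuter * rad$radiusPx)
    # keep the annulus inside the box around the estimated center
    margin <- min(ctr[["cx"]], ctr[["cy"]],
                  box - 1 - ctr[["cx"]], box - 1 - ctr[["cy"]])
    rMax <- min(rMax, margin)
  } else {
    rMin <- config@rMinPx; rMax <- config@rMaxPx
  }
  if (rMax <= rMin)
    stop("degenerate annulus: radial peak too close to the box edge")
  polarInput <- if (config@matchedFilterSigmaPx > 0)
    new("ParticleImage",
        pixels = EBImage::gblur(img@pixels,
                                sigma = config@matchedFilterSigmaPx),
        pixelSizeA = img@pixelSizeA, particleId = img@particleId)
  else img
  polar <- toPolar(polarInput, ctr, rMin, rMax, nRings = config@nRings,
                   nAngles = config@nAngles)
  weights <- NULL
  if (config@profileWeighting == "matched" && config@acfMode == "collapse") {
    radii <- seq(rMin, rMax, length.out = config@nRings)
    weights <- pmax(stats::approx(seq_along(rad$profile), rad$profile,
                                  xout = radii, rule = 2)$y, 0)
    if (sum(weights) == 0) weights <- NULL
  }
  spec <- .polarSpectrum(polar, kMax = max(16L, config@kMax),
                         acfMode = config@acfMode, weights = weights)
  polarVar <- stats::var(as.vector(polar@values))
  profVar <- stats::var(angularProfile(polar, weights = weights))
  avr <- if (polarVar > 0) profVar / polarVar else 0
  asg <- assignSymmetry(spec, kMin = config@kMin, kMax = config@kMax,
                        confidenceRatioMin = config@confidenceRatioMin,
                        scoreMin = config@scoreMin,
                        angularVarianceRatio = avr,
                        angularVarianceMin = config@angularVarianceMin,
                        particleIdent = image@particleId)
  list(assignment = asg, spectrum = spec, radiusPx = rad$radiusPx,
       diameterNm = rad$diameterNm)
}

#' Analyze a whole particle stack
#'
#' Runs [analyzeParticle()] on every image.  Per-particle failures
#' (constant images, centering failures, ...) are recorded in the
#' assignment table and counted as degenerate -- they never abort the
#' stack.  Deterministic for a fixed stack and configuration.
#'
#' @param stack list of [ParticleImage-class] (e.g. from [readStack()])
#' @param config an [AnalysisConfig-class]
#' @param verbose print one summary line at the end
#' @return list with \code{assignments} (data.frame: particle_id, k_best,
#'   score, confidence_ratio, low_confidence, radius_px, diameter_nm,
#'   error) and \code{histogram} ([SymmetryHistogram-class])
#' @export
analyzeStack <- function(stack, config = analysisConfig(), verbose = FALSE) {
  validObject(config)
  n <- length(stack)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    img <- stack[[i]]
    res <- tryCatch(analyzeParticle(img, config), error = function(e) e)
    rows[[i]] <- if (inherits(res, "error")) {
      data.frame(particle_id = img@particleId, k_best = NA_integer_,
                 score = NA_real_, confidence_ratio = NA_real_,
                 band_fraction = NA_real_,
                 low_confidence = NA, radius_px = NA_real_,
                 diameter_nm = NA_real_, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      a <- res$assignment
      data.frame(particle_id = a@particleId, k_best = a@kBest,
                 score = a@score, confidence_ratio = a@confidenceRatio,
                 band_fraction = a@bandFraction,
                 low_confidence = a@lowConfidence,
                 radius_px = res$radiusPx, diameter_nm = res$diameterNm,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  assignments <- if (n > 0) do.call(rbind, rows) else
    data.frame(particle_id = character(), k_best = integer(),
               score = numeric(), confidence_ratio = numeric(),
               band_fraction = numeric(), low_confidence = logical(), radius_px = numeric(),
               diameter_nm = numeric(), error = character(),
               stringsAsFactors = FALSE)
  ks <- config@kMin:config@kMax
  counts <- vapply(ks, function(k) sum(assignments$k_best == k, na.rm = TRUE),
                   integer(1))
  names(counts) <- as.character(ks)
  hist <- new("SymmetryHistogram", counts = counts, nTotal = as.integer(n),
              nDegenerate = as.integer(sum(is.na(assignments$k_best))))
  if (verbose)
    message(sprintf("analyzed %d particles: %s; %d degenerate", n,
                    paste(sprintf("%s-fold: %d", names(counts), counts),
                          collapse = ", "), hist@nDegenerate))
  list(assignments = assignments, histogram = hist)
}

#' Write analysis reports
#'
#' Writes \code{<prefix>_assignments.csv} (the per-particle table),
#' \code{<prefix>_histogram.json} (counts, fractions, totals) and
#' \code{<prefix>_histogram.png} (bar plot of counts by order).
#'
#' @param histogram a [SymmetryHistogram-class]
#' @param assignments assignment table from [analyzeStack()]
#' @param outPrefix output path prefix
#' @return named character vector of the files written, invisibly
#' @export
reportResults <- function(histogram, assignments, outPrefix) {
  validObject(histogram)
  csv <- paste0(outPrefix, "_assignments.csv")
  js <- paste0(outPrefix, "_histogram.json")
  png <- paste0(outPrefix, "_histogram.png")
  utils::write.csv(assignments, csv, row.names = FALSE, quote = FALSE)
  counts <- histogram@counts
  fractions <- if (histogram@nTotal > 0)
    as.numeric(counts) / histogram@nTotal else rep(0, length(counts))
  names(fractions) <- paste0("fraction_", names(counts))
  jsonlite::write_json(
    c(list(n_total = histogram@nTotal, n_degenerate = histogram@nDegenerate,
           counts = as.list(counts)), as.list(fractions)),
    js, auto_unbox = TRUE, digits = NA)
  grDevices::png(png, width = 640, height = 480)
  graphics::barplot(counts, xlab = "rotational symmetry order",
                    ylab = "particles", col = "grey60",
                    main = sprintf("n = %d (%d degenerate)",
                                   histogram@nTotal, histogram@nDegenerate))
  grDevices::dev.off()
  invisible(c(assignments = csv, histogram = js, plot = png))
}

#' Score assignments against generator ground truth
#'
#' Joins the assignment table with a ground-truth table by particle id and
#' tabulates per-true-class accuracy and the confusion matrix.  For ring
#' classes the true label is the generated symmetry order; confounder
#' classes (side views, partial rings, clamp rings) keep their class name.
#'
#' @param assignments assignment table from [analyzeStack()]
#' @param truth ground-truth data.frame (or CSV path) from
#'   [generateDataset()]
#' @return list with \code{perClass} (data.frame: class, n, accuracy,
#'   low_confidence_rate) and \code{confusion} (table true class x assigned
#'   k)
#' @export
evaluateAgainstTruth <- function(assignments, truth) {
  if (is.character(truth)) truth <- utils::read.csv(truth)
  missing <- setdiff(assignments$particle_id, truth$particle_id)
  if (length(missing))
    stop("join error: particle ids missing from truth: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  m <- merge(assignments, truth, by = "particle_id", sort = TRUE)
  trueClass <- ifelse(m$particle_class == "ring",
                      as.character(m$n_fold), m$particle_class)
  assigned <- ifelse(is.na(m$k_best), "degenerate", as.character(m$k_best))
  confusion <- table(true = trueClass, assigned = assigned)
  perClass <- do.call(rbind, lapply(sort(unique(trueClass)), function(cl) {
    sel <- trueClass == cl
    correct <- if (cl %in% as.character(1:99))
      mean(m$k_best[sel] == as.integer(cl), na.rm = FALSE) else NA_real_
    data.frame(class = cl, n = sum(sel), accuracy = correct,
               low_confidence_rate = mean(m$low_confidence[sel] %in% TRUE),
               stringsAsFactors = FALSE)
  }))
  list(perClass = perClass, confusion = confusion)
}
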