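#' Construct a ring-particle model
#'
#' Defaults reproduce the FliP-like geometry used throughout: a 6-fold ring
#' of radius 25 px at 2.0 Angstrom/px, i.e. a 10 nm ring diameter, in a
#' 96 px box with 3 px blobs.
#'
#' @param nFold blob symmetry order (>= 1).
#' @param ringRadiusPx ring radius in pixels.
#' @param blobSigmaPx blob s.d. in pixels.
#' @param amplitude peak blob intensity.
#' @param noiseSigma additive Gaussian noise s.d.
#' @param backgroundSlope length-2 linear ramp per pixel (x, y).
#' @param rotationRad in-plane rotation, radians in [0, 2*pi).
#' @param centerOffsetPx length-2 offset of the ring center from the box
#'   center, pixels.
#' @param boxPx even box edge, >= 32.
#' @param pixelSizeA pixel size, Angstrom per pixel.
#' @param particleClass "ring", "side_view", "partial_ring" or "clamp_ring".
#' @return a validated [RingModel-class]
#' @examples
#' RingModel()                    # FliP-like hexamer, 10 nm
#' RingModel(nFold = 5L)
#' @export
RingModel <- function(nFold = 6L, ringRadiusPx = 25, blobSigmaPx = 3,
                      amplitude = 1, noiseSigma = 0,
                      backgroundSlope = c(0, 0), rotationRad = 0,
                      centerOffsetPx = c(0, 0), boxPx = 96L,
                      pixelSizeA = 2.0, particleClass = "ring") {
  new("RingModel", nFold = as.integer(nFold), ringRadiusPx = ringRadiusPx,
      blobSigmaPx = blobSigmaPx, amplitude = amplitude,
      noiseSigma = noiseSigma, backgroundSlope = as.numeric(backgroundSlope),
      rotationRad = rotationRad, centerOffsetPx = as.numeric(centerOffsetPx),
      boxPx = as.integer(boxPx), pixelSizeA = pixelSizeA,
      particleClass = particleClass)
}

#' FliP-like and FliO-like particle presets
#'
#' \code{flipRingModel()} is a hexameric ring of 10 nm diameter (radius
#' 25 px at 2.0 A/px).  \code{flioRingModel()} is a 5 nm ring carrying 3
#' radially protruding clamp blobs; its body is rendered as a dense ring of
#' small blobs so that the 3 clamps dominate the angular signal.
#'
#' @param ... overrides passed to [RingModel()].
#' @return a [RingModel-class]
#' @export
flipRingModel <- function(...) {
  args <- list(...)
  defaults <- list(nFold = 6L, ringRadiusPx = 25, blobSigmaPx = 3,
                   pixelSizeA = 2.0, boxPx = 96L, particleClass = "ring")
  do.call(RingModel, utils::modifyList(defaults, args))
}

#' @rdname flipRingModel
#' @export
flioRingModel <- function(...) {
  args <- list(...)
  defaults <- list(nFold = 9L, ringRadiusPx = 12.5, blobSigmaPx = 2,
                   pixelSizeA = 2.0, boxPx = 96L,
                   particleClass = "clamp_ring")
  do.call(RingModel, utils::modifyList(defaults, args))
}

# 0-based pixel-center coordinate grids, x-first indexing
.coordGrids <- function(box) {
  idx <- seq_len(box) - 1
  list(x = matrix(idx, box, box), y = matrix(idx, box, box, byrow = TRUE))
}

.addBlob <- function(img, g, cx, cy, sigma, amplitude) {
  img + amplitude * exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * sigma^2))
}

# distance from every pixel to a segment of half-length L through (cx, cy)
# with direction u
.segmentDistance <- function(g, cx, cy, ux, uy, L) {
  dx <- g$x - cx
  dy <- g$y - cy
  t <- pmin(pmax(dx * ux + dy * uy, -L), L)
  sqrt((dx - t * ux)^2 + (dy - t * uy)^2)
}

#' Render one synthetic particle
#'
#' Deterministic given \code{(model, seed)}.  The signal depends on the
#' particle class:
#' \describe{
#'   \item{ring}{sum of \code{nFold} isotropic Gaussian blobs at angles
#'     \code{rotationRad + 2*pi*i/nFold} on a circle of \code{ringRadiusPx}
#'     about the (possibly offset) center.}
#'   \item{side_view}{two parallel Gaussian bars of length equal to the
#'     ring diameter, separated by twice the ring radius.}
#'   \item{partial_ring}{a ring with a contiguous arc of blobs deleted;
#'     the arc fraction is drawn uniformly in [0.25, 0.5].}
#'   \item{clamp_ring}{a ring plus 3 radially protruding blobs at 2*pi/3
#'     spacing.}
#' }
#' A linear background ramp and i.i.d. Gaussian noise of s.d.
#' \code{noiseSigma} are then added.  Protein contrast is positive.
#'
#' @param model a [RingModel-class]
#' @param seed integer seed controlling noise and the partial-ring arc
#' @param particleIdent identifier stored on the image
#' @return a [ParticleImage-class]
#' @examples
#' img <- generateRingParticle(flipRingModel(), seed = 1L)
#' @export
generateRingParticle <- function(model, seed = 1L, particleIdent = "particle") {
  validObject(model)
  box <- model@boxPx
  g <- .coordGrids(box)
  c0 <- (box - 1) / 2
  cx <- c0 + model@centerOffsetPx[1]
  cy <- c0 + model@centerOffsetPx[2]

  withr::with_seed(as.integer(seed), {
    img <- matrix(0, box, box)
    r <- model@ringRadiusPx
    s <- model@blobSigmaPx
    n <- model@nFold
    ang <- model@rotationRad + 2 * pi * (seq_len(n) - 1) / n

    if (model@particleClass == "ring" || model@particleClass == "clamp_ring") {
      keep <- seq_len(n)
    } else if (model@particleClass == "partial_ring") {
      frac <- stats::runif(1, 0.25, 0.5)
      nDel <- max(1L, round(frac * n))
      start <- sample.int(n, 1L)
      del <- ((start - 1L) + seq_len(nDel) - 1L) %% n + 1L
      keep <- setdiff(seq_len(n), del)
    } else keep <- integer()

    for (i in keep)
      img <- .addBlob(img, g, cx + r * cos(ang[i]), cy + r * sin(ang[i]),
                      s, model@amplitude)

    if (model@particleClass == "clamp_ring") {
      rc <- r + 2.5 * s
      for (j in 0:2) {
        a <- model@rotationRad + 2 * pi * j / 3
        img <- .addBlob(img, g, cx + rc * cos(a), cy + rc * sin(a),
                        s, model@amplitude)
      }
    }

    if (model@particleClass == "side_view") {
      # two parallel bars (the projected ring walls), bar length = diameter
      ux <- cos(model@rotationRad); uy <- sin(model@rotationRad)
      nx <- -uy; ny <- ux
      for (sgn in c(-1, 1)) {
        d <- .segmentDistance(g, cx + sgn * r * nx, cy + sgn * r * ny,
                              ux, uy, r)
        img <- img + model@amplitude * exp(-d^2 / (2 * s^2))
      }
    }

    img <- img + model@backgroundSlope[1] * (g$x - c0) +
      model@backgroundSlope[2] * (g$y - c0)
    if (model@noiseSigma > 0)
      img <- img + matrix(stats::rnorm(box * box, sd = model@noiseSigma),
                          box, box)
    new("ParticleImage", pixels = img, pixelSizeA = model@pixelSizeA,
        particleId = as.character(particleIdent))
  })
}

#' Specify a synthetic dataset
#'
#' A dataset is a concatenation of template blocks: \code{counts[i]}
#' particles rendered from \code{templates[[i]]}.  Per-particle seeds are
#' derived from \code{masterSeed} by a counter scheme
#' (\code{seed_i = (masterSeed + i - 1) mod (2^31 - 1)}, with \code{i} the
#' 1-based slice index), so any slice can be regenerated in isolation and
#' the whole dataset is bit-reproducible.
#'
#' @param templates list of [RingModel-class] objects
#' @param counts integer vector, same length, counts >= 0
#' @param masterSeed integer master seed
#' @return object of class \code{DatasetSpec} (a validated list)
#' @export
datasetSpec <- function(templates, counts, masterSeed = 1L) {
  if (is(templates, "RingModel")) templates <- list(templates)
  stopifnot(length(templates) == length(counts), all(counts >= 0))
  for (t in templates) validObject(t)
  structure(list(templates = templates, counts = as.integer(counts),
                 masterSeed = as.integer(masterSeed)),
            class = "DatasetSpec")
}

#' Default mixture preset spanning orders 3..8
#'
#' Equal counts of FliP-like rings for every symmetry order from 3 to 8,
#' mirroring the candidate range of the assignment step.
#'
#' @param countPerOrder particles per symmetry order
#' @param masterSeed master seed
#' @param noiseSigma noise s.d. shared by all templates (amplitude is 1, so
#'   the signal-to-noise ratio is \code{1/noiseSigma})
#' @param randomRotation if TRUE each template gets a distinct fixed
#'   rotation offset so blob phases differ across orders
#' @return a \code{DatasetSpec}
#' @export
mixtureSpec <- function(countPerOrder = 100L, masterSeed = 1L,
                        noiseSigma = 0.5, randomRotation = TRUE) {
  orders <- 3:8
  templates <- lapply(seq_along(orders), function(i) {
    k <- orders[i]
    rot <- if (randomRotation) (0.37 * i) %% (2 * pi / k) else 0
    flipRingModel(nFold = as.integer(k), noiseSigma = noiseSigma,
                  rotationRad = rot)
  })
  datasetSpec(templates, rep(as.integer(countPerOrder), length(orders)),
              masterSeed = masterSeed)
}

.particleSeed <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) + i - 1) %% 2147483647)
}

.modelToRow <- function(model) {
  data.frame(
    n_fold = model@nFold, ring_radius_px = model@ringRadiusPx,
    blob_sigma_px = model@blobSigmaPx, amplitude = model@amplitude,
    noise_sigma = model@noiseSigma,
    background_slope_x = model@backgroundSlope[1],
    background_slope_y = model@backgroundSlope[2],
    rotation_rad = model@rotationRad,
    center_offset_x = model@centerOffsetPx[1],
    center_offset_y = model@centerOffsetPx[2],
    box_px = model@boxPx, pixel_size_A = model@pixelSizeA,
    particle_class = model@particleClass, stringsAsFactors = FALSE)
}

#' Generate a synthetic particle stack with ground truth
#'
#' Renders every particle of a [datasetSpec()] in order and returns the
#' stack together with a ground-truth table (one row per slice, all model
#' parameters plus the per-particle seed).  Optionally writes the stack as
#' mode-2 MRC and the truth as CSV; rerunning with the same spec is
#' bit-identical.
#'
#' @param spec a \code{DatasetSpec}
#' @param stackPath optional output path for an MRC/MRCS stack
#' @param truthPath optional output path for the ground-truth CSV
#' @return list with \code{images} (list of [ParticleImage-class]) and
#'   \code{truth} (data.frame)
#' @examples
#' ds <- generateDataset(datasetSpec(flipRingModel(), 3L, masterSeed = 7L))
#' nrow(ds$truth)
#' @export
generateDataset <- function(spec, stackPath = NULL, truthPath = NULL) {
  stopifnot(inherits(spec, "DatasetSpec"))
  total <- sum(spec$counts)
  images <- vector("list", total)
  rows <- vector("list", total)
  i <- 0L
  for (b in seq_along(spec$templates)) {
    model <- spec$templates[[b]]
    for (j in seq_len(spec$counts[b])) {
      i <- i + 1L
      pid <- sprintf("p%05d", i)
      sd <- .particleSeed(spec$masterSeed, i)
      images[[i]] <- generateRingParticle(model, seed = sd,
                                          particleIdent = pid)
      rows[[i]] <- cbind(data.frame(particle_id = pid,
                                    stringsAsFactors = FALSE),
                         .modelToRow(model), data.frame(seed = sd))
    }
  }
  truth <- if (total > 0) do.call(rbind, rows) else
    cbind(data.frame(particle_id = character()),
          .modelToRow(RingModel())[0, ], data.frame(seed = integer()))
  if (!is.null(stackPath)) {
    px <- if (total > 0) images[[1]]@pixelSizeA else 1
    writeStack(images, stackPath, pixelSizeA = px)
  }
  if (!is.null(truthPath))
    utils::write.csv(truth, truthPath, row.names = FALSE, quote = FALSE)
  list(images = images, truth = truth)
}

#' Read or write a dataset specification as YAML
#'
#' The YAML layout is a \code{master_seed} plus a \code{blocks} list, each
#' block holding a \code{count} and any [RingModel()] arguments (snake_case
#' keys, e.g. \code{n_fold}, \code{ring_radius_px}).
#'
#' @param path YAML file path
#' @return \code{readDatasetSpec}: a \code{DatasetSpec}
#' @export
readDatasetSpec <- function(path) {
  y <- yaml::read_yaml(path)
  key <- c(n_fold = "nFold", ring_radius_px = "ringRadiusPx",
           blob_sigma_px = "blobSigmaPx", amplitude = "amplitude",
           noise_sigma = "noiseSigma", background_slope = "backgroundSlope",
           rotation_rad = "rotationRad", center_offset_px = "centerOffsetPx",
           box_px = "boxPx", pixel_size_A = "pixelSizeA",
           particle_class = "particleClass")
  templates <- list(); counts <- integer()
  for (b in y$blocks) {
    args <- b[setdiff(names(b), "count")]
    names(args) <- key[names(args)]
    if (any(is.na(names(args)))) stop("unknown key in dataset spec block")
    templates <- c(templates, list(do.call(RingModel, args)))
    counts <- c(counts, as.integer(b$count))
  }
  datasetSpec(templates, counts, masterSeed = as.integer(y$master_seed %||% 1L))
}

#' @rdname readDatasetSpec
#' @param spec a \code{DatasetSpec} to serialize
#' @export
writeDatasetSpec <- function(spec, path) {
  blocks <- lapply(seq_along(spec$templates), function(i) {
    m <- spec$templates[[i]]
    list(count = spec$counts[i], n_fold = m@nFold,
         ring_radius_px = m@ringRadiusPx, blob_sigma_px = m@blobSigmaPx,
         amplitude = m@amplitude, noise_sigma = m@noiseSigma,
         background_slope = as.list(m@backgroundSlope),
         rotation_rad = m@rotationRad,
         center_offset_px = as.list(m@centerOffsetPx),
         box_px = m@boxPx, pixel_size_A = m@pixelSizeA,
         particle_class = m@particleClass)
  })
  yaml::write_yaml(list(master_seed = spec$masterSeed, blocks = blocks), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
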