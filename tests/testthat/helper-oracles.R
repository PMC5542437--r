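# Independent oracles used across the test files.  These deliberately avoid
# the package's own code paths.

# brute-force O(N^2) DFT magnitudes of a real vector, orders 0..kMax
naiveDftPower <- function(f, kMax) {
  N <- length(f)
  vapply(0:kMax, function(k) {
    Mod(sum(f * exp(-2i * pi * k * (seq_len(N) - 1) / N)))
  }, numeric(1))
}

# naive normalized squared-magnitude angular DFT of a profile
naiveProfilePower <- function(f, kMax) {
  naiveDftPower(f, kMax)^2 / sum(f^2)
}

# bilinear image rotation about the box center (own implementation, kept
# independent of toPolar)
rotateBilinear <- function(m, angleRad) {
  box <- nrow(m)
  c0 <- (box - 1) / 2
  idx <- seq_len(box) - 1
  X <- matrix(idx, box, box); Y <- matrix(idx, box, box, byrow = TRUE)
  xs <- c0 + cos(angleRad) * (X - c0) - sin(angleRad) * (Y - c0)
  ys <- c0 + sin(angleRad) * (X - c0) + cos(angleRad) * (Y - c0)
  xs <- pmin(pmax(xs, 0), box - 1); ys <- pmin(pmax(ys, 0), box - 1)
  x0 <- pmin(floor(xs), box - 2); y0 <- pmin(floor(ys), box - 2)
  fx <- xs - x0; fy <- ys - y0
  i00 <- x0 + 1 + y0 * box
  out <- m[i00] * (1 - fx) * (1 - fy) + m[i00 + 1] * fx * (1 - fy) +
    m[i00 + box] * (1 - fx) * fy + m[i00 + 1 + box] * fx * fy
  matrix(out, box, box)
}

# dense-grid + refinement rigid-fit RMSD between small point sets (the
# independent superposition oracle: no SVD)
bruteForceRmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  rotmat <- function(a) {
    Rz <- matrix(c(cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1]), 0,
                   0, 0, 1), 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                   sin(a[2]), 0, cos(a[2])), 3)
    Rz2 <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0,
                    0, 0, 1), 3)
    Rz %*% Ry %*% Rz2
  }
  obj <- function(a) sqrt(mean(rowSums((Xc %*% t(rotmat(a)) - Yc)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  gridB <- seq(0, pi, length.out = 7)
  best <- c(0, 0, 0); bestV <- obj(best)
  for (a1 in grid) for (a2 in gridB) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < bestV) { bestV <- v; best <- c(a1, a2, a3) }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# minimal fixed-column PDB writer for parser fixtures
writePdbFixture <- function(df, path) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    alt <- if (is.null(df$alt)) " " else substr(paste0(r$alt, " "), 1, 1)
    occ <- if (is.null(df$occ)) 1 else r$occ
    name <- if (nchar(r$atom) < 4) sprintf(" %-3s", r$atom) else r$atom
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name, alt, r$resname, r$chain, r$resno, r$x, r$y, r$z,
            occ, 0, r$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
}

# rotationally featureless test object: a smooth Gaussian-profile annulus
uniformAnnulusImage <- function(box = 96L, r0 = 25, s = 3, pixelSizeA = 2) {
  idx <- seq_len(box) - 1
  X <- matrix(idx, box, box); Y <- matrix(idx, box, box, byrow = TRUE)
  r <- sqrt((X - (box - 1) / 2)^2 + (Y - (box - 1) / 2)^2)
  new("ParticleImage", pixels = exp(-(r - r0)^2 / (2 * s^2)),
      pixelSizeA = pixelSizeA, particleId = "uniform_annulus")
}

# direct analytic evaluation of the n-blob ring signal (generator oracle)
analyticRingImage <- function(n, radius, sigma, amplitude, rot, offset, box) {
  idx <- seq_len(box) - 1
  X <- matrix(idx, box, box); Y <- matrix(idx, box, box, byrow = TRUE)
  cx <- (box - 1) / 2 + offset[1]; cy <- (box - 1) / 2 + offset[2]
  img <- matrix(0, box, box)
  for (i in 0:(n - 1)) {
    a <- rot + 2 * pi * i / n
    img <- img + amplitude *
      exp(-((X - cx - radius * cos(a))^2 + (Y - cy - radius * sin(a))^2) /
            (2 * sigma^2))
  }
  img
}
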