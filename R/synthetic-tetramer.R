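#' Synthetic pseudo-D2 tetramer (FliP periplasmic-domain-like stand-in)
#'
#' Builds, entirely in code, a SYNTHETIC coordinate model that realizes the
#' published structural features of the FliP periplasmic-domain crystal
#' tetramer: chains of residues 122..188, four chains related by (pseudo)
#' D2 symmetry, two tetramers per model, a hydrophobic A-B interface
#' carrying Tyr-124, Phe-128, Met-154, Leu-155, Pro-176 and Leu-180, a
#' mixed A-C interface carrying Met-127, Arg-130, Val-131, Arg-134,
#' Phe-138, Glu-142, Glu-182, Val-185, Ala-186 and Phe-187 with
#' Arg-134/Glu-142 and Arg-134/Glu-182 salt bridges, and no A-D contact.
#' It is a geometric stand-in for validating the analysis code, not a
#' model of the real protein fold: backbone geometry and side-chain
#' placement are schematic.
#'
#' Chain A occupies the (+,+,+) region; chains B, C, D are its images under
#' 180-degree rotations about the z, x and y axes.  With
#' \code{perturbSigma > 0} every chain receives independent Gaussian
#' coordinate noise, making the symmetry pseudo and the pairwise C-alpha
#' RMSD approximately \code{perturbSigma * sqrt(6)} (about 0.3 Angstrom at
#' the default), below the 0.46 Angstrom spread reported for the real
#' deposition.  With \code{perturbSigma = 0} the D2 symmetry is exact.
#'
#' @param perturbSigma per-coordinate Gaussian noise s.d. (Angstrom)
#' @param seed integer seed (perturbation is deterministic given the seed)
#' @param nTetramers 1 or 2 (the second tetramer is translated 300 Angstrom
#'   away, emulating two copies in an asymmetric unit)
#' @return a [StructureModel-class] with chains A..D (and E..H)
#' @examples
#' mod <- syntheticTetramer()
#' groupIntoAssemblies(mod)
#' @export
syntheticTetramer <- function(perturbSigma = 0.12, seed = 1L,
                              nTetramers = 2L) {
  stopifnot(nTetramers %in% 1:2, perturbSigma >= 0)
  resnos <- 122:188
  named <- c("122" = "THR", "124" = "TYR", "127" = "MET", "128" = "PHE",
             "130" = "ARG", "131" = "VAL", "134" = "ARG", "138" = "PHE",
             "142" = "GLU", "154" = "MET", "155" = "LEU", "176" = "PRO",
             "180" = "LEU", "182" = "GLU", "185" = "VAL", "186" = "ALA",
             "187" = "PHE", "188" = "LYS")
  fillers <- c("SER", "GLY", "ASN", "THR")
  resnames <- vapply(resnos, function(r) {
    nm <- named[as.character(r)]
    if (is.na(nm)) fillers[(r %% length(fillers)) + 1L] else nm
  }, character(1))

  # backbone: a coarse helical C-alpha trace kept > 5 Angstrom away from
  # all three 2-fold axes so the backbone itself makes no inter-chain
  # contact
  i <- seq_along(resnos) - 1L
  ca <- cbind(x = 6 + 1.5 * cos(0.7 * i),
              y = 6 + 1.5 * sin(0.7 * i),
              z = 4 + 3.6 * i)
  rows <- data.frame(resno = resnos, resname = resnames, atom = "CA",
                     element = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                     stringsAsFactors = FALSE)

  addAtom <- function(resno, atom, element, x, y, z) {
    rows <<- rbind(rows, data.frame(
      resno = resno, resname = named[as.character(resno)], atom = atom,
      element = element, x = x, y = y, z = z, stringsAsFactors = FALSE))
  }
  # A-B interface: side-chain atoms poked toward the z axis; each meets its
  # own image in chain B at ~2.8 Angstrom
  abRes <- c(124L, 128L, 154L, 155L, 176L, 180L)
  abAtom <- c("OH", "CZ", "SD", "CD1", "CG", "CD1")
  abElem <- c("O", "C", "S", "C", "C", "C")
  for (k in seq_along(abRes))
    addAtom(abRes[k], abAtom[k], abElem[k], 1.0, 1.0, 8 + 4 * k)
  # A-C interface: side-chain atoms poked toward the x axis
  acRes <- c(127L, 130L, 131L, 138L, 185L, 186L, 187L)
  acAtom <- c("SD", "CD", "CG1", "CZ", "CG1", "CB", "CZ")
  acElem <- c("S", "C", "C", "C", "C", "C", "C")
  for (k in seq_along(acRes))
    addAtom(acRes[k], acAtom[k], acElem[k], 6 + 4 * k, 1.0, 1.0)
  # Arg-134 guanidinium against the carboxylates of Glu-142 and Glu-182 of
  # the x-axis-related chain (salt bridges across the A-C interface)
  addAtom(134L, "NE", "N", 40.0, 0.9, 1.2)
  addAtom(134L, "NH1", "N", 40.6, 1.0, 1.0)
  addAtom(134L, "NH2", "N", 39.6, 1.1, 0.9)
  addAtom(142L, "OE1", "O", 40.4, 1.2, -0.9)
  addAtom(142L, "OE2", "O", 41.0, 1.3, -1.1)
  addAtom(182L, "OE1", "O", 39.4, 1.3, -1.0)
  addAtom(182L, "OE2", "O", 38.9, 1.4, -1.2)

  rows <- rows[order(rows$resno, rows$atom != "CA"), , drop = FALSE]
  A <- as.matrix(rows[, c("x", "y", "z")])
  flip <- list(
    A = diag(3),
    B = diag(c(-1, -1, 1)),   # 180 deg about z
    C = diag(c(1, -1, -1)),   # 180 deg about x
    D = diag(c(-1, 1, -1)))   # 180 deg about y

  withr::with_seed(as.integer(seed), {
    build <- function(chainId, Rmat, shift) {
      xyz <- A %*% t(Rmat)
      xyz <- sweep(xyz, 2, shift, `+`)
      if (perturbSigma > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = perturbSigma),
                            nrow(xyz), 3)
      data.frame(chain = chainId, resno = rows$resno,
                 resname = rows$resname, atom = rows$atom,
                 element = rows$element, x = xyz[, 1], y = xyz[, 2],
                 z = xyz[, 3], stringsAsFactors = FALSE)
    }
    chains <- list()
    ids <- c("A", "B", "C", "D")
    for (t in seq_len(nTetramers)) {
      shift <- if (t == 1L) c(0, 0, 0) else c(300, 300, 300)
      for (k in 1:4) {
        id <- LETTERS[(t - 1L) * 4L + k]
        chains[[id]] <- build(id, flip[[ids[k]]], shift)
      }
    }
    structureFromAtoms(do.call(rbind, chains),
                       source = sprintf("synthetic pseudo-D2 tetramer (sigma=%g, seed=%d)",
                                        perturbSigma, seed))
  })
}
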