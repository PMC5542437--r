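# a tiny two-chain fixture with known composition for the parser tests
.twoChainFixture <- function(path) {
  df <- rbind(
    data.frame(chain = "A", resno = 1:3, resname = c("GLY", "ALA", "SER"),
               atom = "CA", element = "C",
               x = c(0, 3.8, 7.6), y = 0, z = 0),
    data.frame(chain = "A", resno = 2, resname = "ALA", atom = "CB",
               element = "C", x = 3.8, y = 1.5, z = 0),
    data.frame(chain = "B", resno = 1:3, resname = c("GLY", "ALA", "SER"),
               atom = "CA", element = "C",
               x = c(0, 3.8, 7.6), y = 10, z = 0))
  writePdbFixture(df, path)
  df
}

test_that("PDB fixtures parse with the constructed composition", {
  f <- tempfile(fileext = ".pdb")
  df <- .twoChainFixture(f)
  mod <- readStructure(f)
  expect_identical(sort(chainIds(mod)), c("A", "B"))
  expect_identical(nrow(atomTable(mod)), nrow(df))
  expect_identical(modeledRange(mod, "A"), c(1L, 3L))
  a <- atomTable(mod)
  expect_equal(a$x[a$chain == "A" & a$atom == "CB"], 3.8)
})

test_that("hydrogens and waters are excluded at parse time", {
  f <- tempfile(fileext = ".pdb")
  df <- rbind(
    data.frame(chain = "A", resno = 1:3, resname = "GLY", atom = "CA",
               element = "C", x = c(0, 3.8, 7.6), y = 0, z = 0),
    data.frame(chain = "A", resno = 2, resname = "GLY", atom = "HA",
               element = "H", x = 3.8, y = 0.5, z = 0),
    data.frame(chain = "A", resno = 50, resname = "HOH", atom = "O",
               element = "O", x = 20, y = 20, z = 20))
  writePdbFixture(df, f)
  mod <- readStructure(f)
  expect_identical(nrow(atomTable(mod)), 3L)
  expect_false(any(atomTable(mod)$element == "H"))
  expect_false(any(atomTable(mod)$resname == "HOH"))
})

test_that("altlocs collapse to the highest occupancy, ties toward A", {
  f <- tempfile(fileext = ".pdb")
  df <- rbind(
    data.frame(chain = "A", resno = 1:3, resname = "GLY", atom = "CA",
               element = "C", x = c(0, 3.8, 7.6), y = 0, z = 0,
               alt = "", occ = 1),
    # resno 2 gets two conformers for CB: B wins on occupancy
    data.frame(chain = "A", resno = 2, resname = "GLY", atom = "CB",
               element = "C", x = 1, y = 1, z = 0, alt = "A", occ = 0.4),
    data.frame(chain = "A", resno = 2, resname = "GLY", atom = "CB",
               element = "C", x = 2, y = 2, z = 0, alt = "B", occ = 0.6),
    # resno 3 gets a tie: altloc A wins
    data.frame(chain = "A", resno = 3, resname = "GLY", atom = "CB",
               element = "C", x = 5, y = 5, z = 0, alt = "A", occ = 0.5),
    data.frame(chain = "A", resno = 3, resname = "GLY", atom = "CB",
               element = "C", x = 6, y = 6, z = 0, alt = "B", occ = 0.5))
  writePdbFixture(df, f)
  a <- atomTable(readStructure(f))
  expect_identical(nrow(a), 5L)
  expect_equal(a$x[a$resno == 2 & a$atom == "CB"], 2)
  expect_equal(a$x[a$resno == 3 & a$atom == "CB"], 5)
})

test_that("degenerate structure files fail loudly", {
  f <- tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(readStructure(f), "unparseable|no protein atoms")
  # a chain without C-alpha atoms is named in the error
  f2 <- tempfile(fileext = ".pdb")
  writePdbFixture(data.frame(chain = "Q", resno = 1, resname = "GLY",
                             atom = "CB", element = "C", x = 0, y = 0,
                             z = 0), f2)
  expect_error(readStructure(f2), "chain Q")
  expect_error(readStructure(tempfile(fileext = ".pdb")), "not found")
})

test_that("coordinate tables (.csv) load as structures", {
  mod <- syntheticTetramer(perturbSigma = 0, nTetramers = 1L)
  f <- tempfile(fileext = ".csv")
  write.csv(atomTable(mod), f, row.names = FALSE)
  back <- readStructure(f)
  expect_identical(chainIds(back), c("A", "B", "C", "D"))
  expect_equal(atomTable(back)$x, atomTable(mod)$x)
})

test_that("modeled range ignores internal gaps", {
  f <- tempfile(fileext = ".pdb")
  writePdbFixture(data.frame(chain = "A", resno = c(1L, 2L, 9L),
                             resname = "GLY", atom = "CA", element = "C",
                             x = c(0, 3.8, 7.6), y = 0, z = 0), f)
  expect_identical(modeledRange(readStructure(f), "A"), c(1L, 9L))
})

test_that("self-superposition gives zero RMSD and the identity rotation", {
  mod <- syntheticTetramer()
  s <- superposeCa(mod, "A", "A")
  expect_lt(rmsd(s), 1e-9)
  expect_lt(max(abs(rotationMatrix(s) - diag(3))), 1e-9)
})

test_that("a known rigid transform is recovered to 1e-6", {
  base <- atomTable(syntheticTetramer(perturbSigma = 0, nTetramers = 1L))
  a <- base[base$chain == "A", ]
  ang <- c(0.3, -1.1, 2.0)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]),
                 0, 0, 0, 1), 3)
  R <- Rz %*% Ry %*% Rx
  tvec <- c(5, -3, 11)
  b <- a; b$chain <- "B"
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  b$x <- xyz[, 1] + tvec[1]; b$y <- xyz[, 2] + tvec[2]
  b$z <- xyz[, 3] + tvec[3]
  mod <- structureFromAtoms(rbind(a, b), source = "transform fixture")
  s <- superposeCa(mod, "A", "B")
  expect_lt(rmsd(s), 1e-6)
  expect_lt(max(abs(rotationMatrix(s) - R)), 1e-6)
  expect_lt(max(abs(s@translation - tvec)), 1e-6)
})

test_that("superposition is symmetric and invariant to rigid pre-transforms", {
  mod <- syntheticTetramer()
  expect_equal(rmsd(superposeCa(mod, "A", "B")),
               rmsd(superposeCa(mod, "B", "A")), tolerance = 1e-9)
  # rigidly move chain A: fitted RMSD to chain B must not change
  at <- atomTable(mod)
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  sel <- at$chain == "A"
  xyz <- as.matrix(at[sel, c("x", "y", "z")]) %*% t(R)
  at$x[sel] <- xyz[, 1] + 40; at$y[sel] <- xyz[, 2]; at$z[sel] <- xyz[, 3]
  mod2 <- structureFromAtoms(at, source = "moved")
  expect_equal(rmsd(superposeCa(mod2, "A", "B")),
               rmsd(superposeCa(mod, "A", "B")), tolerance = 1e-9)
})

test_that("fitted RMSD matches a brute-force rotational search on small sets", {
  set.seed(7)
  for (rep in 1:3) {
    X <- matrix(rnorm(8 * 3, sd = 4), 8, 3)
    Y <- X + matrix(rnorm(8 * 3, sd = 0.5), 8, 3)
    a <- data.frame(chain = "A", resno = 1:8, resname = "GLY", atom = "CA",
                    element = "C", x = X[, 1], y = X[, 2], z = X[, 3])
    b <- data.frame(chain = "B", resno = 1:8, resname = "GLY", atom = "CA",
                    element = "C", x = Y[, 1], y = Y[, 2], z = Y[, 3])
    mod <- structureFromAtoms(rbind(a, b), source = "toy")
    expect_equal(rmsd(superposeCa(mod, "A", "B")), bruteForceRmsd(X, Y),
                 tolerance = 1e-4)
  }
})

test_that("superposition requires at least 3 shared residues", {
  a <- data.frame(chain = "A", resno = 1:2, resname = "GLY", atom = "CA",
                  element = "C", x = c(0, 1), y = 0, z = 0)
  b <- data.frame(chain = "B", resno = 1:2, resname = "GLY", atom = "CA",
                  element = "C", x = c(0, 1), y = 5, z = 0)
  mod <- structureFromAtoms(rbind(a, b), source = "tiny")
  expect_error(superposeCa(mod, "A", "B"), "fewer than 3")
})

test_that("the synthetic tetramer reproduces the deposited-model statistics", {
  mod <- syntheticTetramer()       # default: pseudo-D2, 2 tetramers
  expect_identical(chainIds(mod), LETTERS[1:8])
  M <- rmsdMatrix(mod)
  expect_true(all(M[upper.tri(M)] <= 0.46))
  expect_gt(max(M), 0)             # pseudo, not exact
  for (ch in chainIds(mod))
    expect_identical(modeledRange(mod, ch), c(122L, 188L))
})

test_that("contact-graph grouping separates the two tetramers", {
  mod <- syntheticTetramer()
  groups <- groupIntoAssemblies(mod)
  expect_length(groups, 2)
  expect_identical(sort(vapply(groups, length, integer(1))), c(4L, 4L))
  single <- structureFromAtoms(
    atomTable(mod)[atomTable(mod)$chain == "A", ], source = "one chain")
  expect_identical(groupIntoAssemblies(single), list("A"))
  # two copies of the A-B dimer translated far apart form two assemblies
  at <- atomTable(syntheticTetramer(perturbSigma = 0, nTetramers = 1L))
  dimer <- at[at$chain %in% c("A", "B"), ]
  far <- dimer
  far$chain <- c(A = "E", B = "F")[far$chain]
  far$x <- far$x + 100
  mod2 <- structureFromAtoms(rbind(dimer, far), source = "two dimers")
  expect_length(groupIntoAssemblies(mod2), 2)
})

test_that("point-group detection: exact D2, pseudo D2, C2, C1, other", {
  exact <- syntheticTetramer(perturbSigma = 0, nTetramers = 1L)
  sym <- detectPointSymmetry(exact, c("A", "B", "C", "D"))
  expect_identical(sym$group, "D2")
  expect_lt(max(abs(sym$rotations$angle_deg - 180)), 1e-6)
  expect_lt(max(abs(sym$axisAnglesDeg - 90)), 1e-6)

  pseudo <- syntheticTetramer()
  g <- groupIntoAssemblies(pseudo)[[1]]
  expect_identical(detectPointSymmetry(pseudo, g)$group, "D2")

  at <- atomTable(exact)
  expect_identical(
    detectPointSymmetry(structureFromAtoms(at[at$chain == "A", ], "c1"))$group,
    "C1")
  dimer <- structureFromAtoms(at[at$chain %in% c("A", "B"), ], "dimer")
  expect_identical(detectPointSymmetry(dimer, c("A", "B"))$group, "C2")

  # a dimer related by a 90-degree rotation is not a C2
  a <- at[at$chain == "A", ]
  b <- a; b$chain <- "B"
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*%
    t(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3))
  b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
  rot90 <- structureFromAtoms(rbind(a, b), source = "rot90")
  expect_identical(detectPointSymmetry(rot90, c("A", "B"))$group, "other")
})

test_that("interfaces carry the engineered residue sets", {
  mod <- syntheticTetramer()
  ab <- findInterfaceResidues(mod, "A", "B")
  expect_true(all(c(124L, 128L, 154L, 155L, 176L, 180L) %in%
                    interfaceResidues(ab, "A")$resno))
  expect_identical(ab@classification, "hydrophobic")
  expect_gte(ab@hydrophobicFraction, 0.7)

  ac <- findInterfaceResidues(mod, "A", "C")
  expect_true(all(c(127L, 130L, 131L, 134L, 138L, 142L, 182L, 185L, 186L,
                    187L) %in% interfaceResidues(ac, "A")$resno))
  expect_identical(ac@classification, "mixed")

  ad <- findInterfaceResidues(mod, "A", "D")
  expect_identical(nrow(ad@contacts), 0L)
  expect_identical(ad@classification, "empty")

  # all reported distances respect the cutoff
  expect_true(all(ab@contacts$minDistA <= 4.5))
  # contact symmetry: interface(B, A) holds the same residue pairs
  ba <- findInterfaceResidues(mod, "B", "A")
  expect_identical(ab@contacts[, c("resnoA", "resnoB")],
                   setNames(ba@contacts[, c("resnoB", "resnoA")],
                            c("resnoA", "resnoB")))
  # chains far apart have no interface
  at <- atomTable(mod)
  far <- at[at$chain %in% c("A", "E"), ]
  expect_identical(
    nrow(findInterfaceResidues(structureFromAtoms(far, "far"),
                               "A", "E")@contacts), 0L)
})

test_that("salt bridges match the engineered Arg-134/Glu pairs", {
  mod <- syntheticTetramer()
  ac <- findInterfaceResidues(mod, "A", "C")
  sb <- saltBridges(ac)
  key <- paste(sb$basic_resno, sb$acidic_resno)
  expect_true(all(c("134 142", "134 182") %in% key))
  expect_true(all(sb$distance_A < 4.0))
  expect_true(all(sb$basic_resname == "ARG"))
  expect_true(all(sb$acidic_resname == "GLU"))
  # bridges are a subset of the interface contacts at their cutoff
  contactKey <- c(paste(ac@contacts$resnoA, ac@contacts$resnoB),
                  paste(ac@contacts$resnoB, ac@contacts$resnoA))
  expect_true(all(key %in% contactKey))
  # no bridges across the contact-free A-D pair
  expect_identical(nrow(detectSaltBridges(mod, "A", "D")), 0L)
})

test_that("salt-bridge detection obeys the distance cutoff", {
  mk <- function(d) {
    structureFromAtoms(rbind(
      data.frame(chain = "A", resno = 1:3, resname = "ARG", atom = "CA",
                 element = "C", x = c(0, 3.8, 7.6), y = 0, z = 0),
      data.frame(chain = "A", resno = 2, resname = "ARG", atom = "NH1",
                 element = "N", x = 3.8, y = 2, z = 0),
      data.frame(chain = "B", resno = 1:3, resname = "GLU", atom = "CA",
                 element = "C", x = c(0, 3.8, 7.6), y = 2 + d + 2, z = 0),
      data.frame(chain = "B", resno = 2, resname = "GLU", atom = "OE1",
                 element = "O", x = 3.8, y = 2 + d, z = 0)),
      source = "bridge fixture")
  }
  expect_identical(nrow(detectSaltBridges(mk(3.0), "A", "B")), 1L)
  expect_identical(nrow(detectSaltBridges(mk(6.0), "A", "B")), 0L)
  # no charged residues -> empty
  mod <- syntheticTetramer()
  expect_identical(nrow(detectSaltBridges(mod, "A", "B")), 0L)
})

test_that("an all-charged interface classifies as hydrophilic", {
  mod <- structureFromAtoms(rbind(
    data.frame(chain = "A", resno = 1:3, resname = c("ARG", "GLU", "ARG"),
               atom = "CA", element = "C", x = c(0, 3.8, 7.6), y = 0,
               z = 0),
    data.frame(chain = "B", resno = 1:3, resname = c("GLU", "ARG", "GLU"),
               atom = "CA", element = "C", x = c(0, 3.8, 7.6), y = 3,
               z = 0)), source = "charged")
  ifc <- findInterfaceResidues(mod, "A", "B")
  expect_identical(ifc@classification, "hydrophilic")
  expect_lte(ifc@hydrophobicFraction, 0.3)
  expect_identical(classifyInterfaceHydrophobicity(ifc), "hydrophilic")
})

test_that("molecule-pair roles follow the interface character", {
  mod <- syntheticTetramer()
  g <- groupIntoAssemblies(mod)[[1]]
  roles <- molPairRoles(mod, g)
  expect_identical(sort(table(roles$role), method = "radix"),
                   sort(table(c("A-B", "A-B", "A-C", "A-C", "A-D", "A-D")),
                        method = "radix"))
  expect_true(all(roles$classification[roles$role == "A-B"] == "hydrophobic"))
  expect_true(all(roles$classification[roles$role == "A-C"] == "mixed"))
  expect_true(all(roles$n_contacts[roles$role == "A-D"] == 0))
})

test_that("the structure report aggregates every analysis", {
  mod <- syntheticTetramer()
  f <- tempfile(fileext = ".json")
  rep <- structureReport(mod, reportPath = f)
  expect_lte(rep$maxRmsdA, 0.46)
  expect_length(rep$assemblies, 2)
  expect_identical(rep$assemblies[[1]]$pointGroup, "D2")
  js <- jsonlite::read_json(f)
  expect_identical(js$assemblies[[2]]$point_group, "D2")
  expect_identical(js$modeled_ranges$A, list(122L, 188L))
})
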