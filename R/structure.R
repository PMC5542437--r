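.WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")
.APOLAR_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")
.BASIC_N_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
.ACIDIC_O_ATOMS <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

#' Build a StructureModel from an atom table
#'
#' @param atoms data.frame with columns chain, resno, resname, atom,
#'   element, x, y, z
#' @param source label recorded on the model
#' @return a [StructureModel-class]
#' @export
structureFromAtoms <- function(atoms, source = "in-memory") {
  atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  atoms <- atoms[!atoms$resname %in% .WATER_RESIDUES, , drop = FALSE]
  rownames(atoms) <- NULL
  model <- new("StructureModel", atoms = atoms, source = source)
  for (ch in unique(atoms$chain))
    if (!any(atoms$atom[atoms$chain == ch] == "CA"))
      stop("chain ", ch, " has no C-alpha atoms")
  model
}

#' Read a macromolecular structure
#'
#' Parses mmCIF (.cif) or PDB (.pdb/.ent) via bio3d, or a plain coordinate
#' table (.csv with columns chain, resno, resname, atom, element, x, y, z).
#' Waters and ligands are excluded, hydrogens dropped, and alternate
#' locations collapsed to the highest-occupancy conformer (ties broken
#' toward altloc "A").  Author chain ids and author residue numbering are
#' kept.
#'
#' @param path structure file
#' @return a [StructureModel-class]
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    at <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(structureFromAtoms(at, source = basename(path)))
  }
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE),
    error = function(e) stop("unparseable structure file: ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("parse error: no protein atoms in ", path)
  el <- toupper(trimws(at$elesy))
  noEl <- is.na(el) | el == ""
  el[noEl] <- substr(gsub("[^A-Za-z].*", "", at$elety[noEl]), 1L, 1L)
  at$element <- el
  # collapse altlocs: highest occupancy wins, ties go to altloc "A"
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE][!duplicated(sort(key)), , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resname = at$resid, atom = at$elety,
                      element = at$element, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structureFromAtoms(atoms, source = basename(path))
}

#' Modeled residue range of a chain
#'
#' Smallest and largest author residue numbers carrying coordinates
#' (internal gaps are ignored).
#'
#' @param model a [StructureModel-class]
#' @param chain chain identifier
#' @return integer vector \code{c(min, max)}
#' @export
modeledRange <- function(model, chain) {
  at <- model@atoms[model@atoms$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty chain: ", chain)
  range(at$resno)
}

.caCoords <- function(model, chain) {
  at <- model@atoms
  ca <- at[at$chain == chain & at$atom == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  structure(as.matrix(ca[, c("x", "y", "z")]), resno = ca$resno)
}

# Kabsch: optimal proper rotation R and translation t with R x + t ~ y
.kabsch <- function(X, Y) {
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  C <- crossprod(Xc, Yc)
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fit <- Xc %*% t(R)
  list(R = R, t = as.numeric(my - R %*% mx),
       rmsd = sqrt(mean(rowSums((fit - Yc)^2))))
}

#' Superpose the C-alpha traces of two chains
#'
#' Least-squares rigid fit (proper rotation only) over C-alpha atoms
#' matched by author residue number; the RMSD is computed after the fit.
#' \code{rotation \%*\% x + translation} maps chain A onto chain B.
#'
#' @param model a [StructureModel-class]
#' @param chainA,chainB chain identifiers
#' @return a [SuperpositionResult-class]
#' @export
superposeCa <- function(model, chainA, chainB) {
  A <- .caCoords(model, chainA); B <- .caCoords(model, chainB)
  common <- intersect(attr(A, "resno"), attr(B, "resno"))
  if (length(common) < 3L)
    stop("superposition error: fewer than 3 common C-alpha residues between ",
         chainA, " and ", chainB)
  X <- A[match(common, attr(A, "resno")), , drop = FALSE]
  Y <- B[match(common, attr(B, "resno")), , drop = FALSE]
  k <- .kabsch(X, Y)
  new("SuperpositionResult", rotation = k$R, translation = k$t,
      rmsdA = k$rmsd, nAtoms = length(common))
}

#' Pairwise C-alpha RMSD matrix over all chains
#'
#' @param model a [StructureModel-class]
#' @return symmetric numeric matrix of post-fit RMSDs (Angstrom)
#' @export
rmsdMatrix <- function(model) {
  ch <- chainIds(model)
  M <- matrix(0, length(ch), length(ch), dimnames = list(ch, ch))
  for (i in seq_along(ch)) for (j in seq_len(i - 1L)) {
    M[i, j] <- M[j, i] <- rmsd(superposeCa(model, ch[i], ch[j]))
  }
  M
}

.chainXyz <- function(model, chain) {
  at <- model@atoms
  as.matrix(at[at$chain == chain, c("x", "y", "z"), drop = FALSE])
}

.pairDistances <- function(A, B) {
  # full heavy-atom distance matrix, nrow(A) x nrow(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Group chains into assemblies by contact graph
#'
#' Two chains are connected when any inter-chain heavy-atom pair lies
#' closer than the cutoff; assemblies are the connected components.
#'
#' @param model a [StructureModel-class]
#' @param contactCutoffA heavy-atom contact cutoff (Angstrom)
#' @return list of character vectors of chain ids
#' @export
groupIntoAssemblies <- function(model, contactCutoffA = 4.5) {
  ch <- chainIds(model)
  if (length(ch) == 1L) return(list(ch))
  xyz <- lapply(ch, .chainXyz, model = model)
  edges <- matrix(character(0), ncol = 2)
  for (i in seq_along(ch)) for (j in seq_len(i - 1L)) {
    if (min(.pairDistances(xyz[[i]], xyz[[j]])) < contactCutoffA)
      edges <- rbind(edges, c(ch[i], ch[j]))
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = ch))
  comp <- igraph::components(g)
  unname(split(ch, comp$membership[ch]))
}

.rotationAngleDeg <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

.rotationAxis <- function(R) {
  e <- eigen(R)
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sqrt(sum(v^2))
}

#' Detect the point-group symmetry of a chain group
#'
#' Superposes the first chain onto every other chain and classifies the
#' resulting rotations.  A tetramer is classified D2 when its three
#' inter-chain rotations are all within \code{angTolDeg} of 180 degrees
#' about mutually orthogonal axes (also within \code{angTolDeg}); a dimer
#' related by a ~180 degree rotation is C2; a single chain is C1; anything
#' else is "other".  The default 15 degree tolerance admits pseudo
#' (approximate) symmetry.
#'
#' @param model a [StructureModel-class]
#' @param chainGroup character vector of chain ids (default: all chains)
#' @param angTolDeg angular tolerance in degrees
#' @return list with \code{group} ("C1", "C2", "D2" or "other"),
#'   \code{rotations} (data.frame: chain, angle_deg, axis components) and
#'   \code{axisAnglesDeg} (pairwise angles between rotation axes)
#' @export
detectPointSymmetry <- function(model, chainGroup = NULL, angTolDeg = 15) {
  if (is.null(chainGroup)) chainGroup <- chainIds(model)
  n <- length(chainGroup)
  if (n == 1L)
    return(list(group = "C1", rotations = NULL, axisAnglesDeg = numeric(0)))
  ref <- chainGroup[1]
  rot <- lapply(chainGroup[-1], function(ch)
    rotationMatrix(superposeCa(model, ref, ch)))
  ang <- vapply(rot, .rotationAngleDeg, numeric(1))
  axes <- lapply(rot, .rotationAxis)
  rotations <- data.frame(chain = chainGroup[-1], angle_deg = ang,
                          ax = vapply(axes, `[`, numeric(1), 1L),
                          ay = vapply(axes, `[`, numeric(1), 2L),
                          az = vapply(axes, `[`, numeric(1), 3L))
  axisAngles <- numeric(0)
  if (n == 2L) {
    group <- if (abs(ang[1] - 180) <= angTolDeg) "C2" else "other"
  } else if (n == 4L) {
    all180 <- all(abs(ang - 180) <= angTolDeg)
    pairs <- utils::combn(3L, 2L)
    axisAngles <- apply(pairs, 2L, function(p) {
      acos(pmin(abs(sum(axes[[p[1]]] * axes[[p[2]]])), 1)) * 180 / pi
    })
    orthogonal <- all(abs(axisAngles - 90) <= angTolDeg)
    group <- if (all180 && orthogonal) "D2" else "other"
  } else group <- "other"
  list(group = group, rotations = rotations, axisAnglesDeg = axisAngles)
}

.residueLabel <- function(resname, resno) sprintf("%s-%d", resname, resno)

#' Find the contact interface between two chains
#'
#' Lists every residue pair with any inter-chain heavy-atom distance below
#' the cutoff, derives the per-chain interface residue sets (ordered by
#' residue number), detects salt bridges, and classifies the interface
#' hydrophobicity from the apolar fraction of the combined interface
#' residue set.
#'
#' @param model a [StructureModel-class]
#' @param chainA,chainB chain identifiers
#' @param cutoffA heavy-atom contact cutoff (default 4.5 Angstrom)
#' @param saltBridgeCutoffA basic-N to acidic-O cutoff (default 4.0)
#' @return an [InterfaceSummary-class]
#' @export
findInterfaceResidues <- function(model, chainA, chainB, cutoffA = 4.5,
                                  saltBridgeCutoffA = 4.0) {
  atA <- model@atoms[model@atoms$chain == chainA, , drop = FALSE]
  atB <- model@atoms[model@atoms$chain == chainB, , drop = FALSE]
  D <- .pairDistances(as.matrix(atA[, c("x", "y", "z")]),
                      as.matrix(atB[, c("x", "y", "z")]))
  hit <- which(D < cutoffA, arr.ind = TRUE)
  if (nrow(hit)) {
    df <- data.frame(resnoA = atA$resno[hit[, 1]],
                     resnameA = atA$resname[hit[, 1]],
                     resnoB = atB$resno[hit[, 2]],
                     resnameB = atB$resname[hit[, 2]],
                     d = D[hit], stringsAsFactors = FALSE)
    agg <- stats::aggregate(d ~ resnoA + resnameA + resnoB + resnameB,
                            data = df, FUN = min)
    names(agg)[names(agg) == "d"] <- "minDistA"
    contacts <- agg[order(agg$resnoA, agg$resnoB), , drop = FALSE]
    rownames(contacts) <- NULL
    resA <- unique(contacts[, c("resnoA", "resnameA")])
    resA <- data.frame(resno = resA$resnoA, resname = resA$resnameA)
    resA <- resA[order(resA$resno), , drop = FALSE]
    resB <- unique(contacts[, c("resnoB", "resnameB")])
    resB <- data.frame(resno = resB$resnoB, resname = resB$resnameB)
    resB <- resB[order(resB$resno), , drop = FALSE]
    rownames(resA) <- rownames(resB) <- NULL
  } else {
    contacts <- data.frame(resnoA = integer(), resnameA = character(),
                           resnoB = integer(), resnameB = character(),
                           minDistA = numeric(), stringsAsFactors = FALSE)
    resA <- resB <- data.frame(resno = integer(), resname = character())
  }
  sb <- detectSaltBridges(model, chainA, chainB,
                          cutoffA = saltBridgeCutoffA)
  allRes <- c(resA$resname, resB$resname)
  frac <- if (length(allRes)) mean(allRes %in% .APOLAR_RESIDUES) else NA_real_
  cls <- classifyInterfaceHydrophobicity(frac)
  new("InterfaceSummary", chainA = chainA, chainB = chainB,
      cutoffA = cutoffA, contacts = contacts, residuesA = resA,
      residuesB = resB, saltBridges = sb,
      hydrophobicFraction = if (is.na(frac)) 0 else frac,
      classification = cls)
}

#' Detect salt bridges between two chains
#'
#' Reports every (Arg/Lys side-chain nitrogen, Asp/Glu side-chain
#' carboxylate oxygen) pair across the chain interface closer than the
#' cutoff, aggregated per residue pair (minimum N-O distance).
#'
#' @param model a [StructureModel-class]
#' @param chainA,chainB chain identifiers
#' @param cutoffA N-O distance cutoff (default 4.0 Angstrom)
#' @return data.frame: basic_chain, basic_resno, basic_resname,
#'   acidic_chain, acidic_resno, acidic_resname, distance_A
#' @export
detectSaltBridges <- function(model, chainA, chainB, cutoffA = 4.0) {
  at <- model@atoms
  pick <- function(chain, table) {
    sel <- at$chain == chain &
      mapply(function(rn, an) rn %in% names(table) &&
               an %in% table[[rn]], at$resname, at$atom)
    at[sel, , drop = FALSE]
  }
  out <- list()
  for (dir in list(c(chainA, chainB), c(chainB, chainA))) {
    bas <- pick(dir[1], .BASIC_N_ATOMS)
    aci <- pick(dir[2], .ACIDIC_O_ATOMS)
    if (nrow(bas) == 0L || nrow(aci) == 0L) next
    D <- .pairDistances(as.matrix(bas[, c("x", "y", "z")]),
                        as.matrix(aci[, c("x", "y", "z")]))
    hit <- which(D < cutoffA, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    df <- data.frame(basic_chain = dir[1],
                     basic_resno = bas$resno[hit[, 1]],
                     basic_resname = bas$resname[hit[, 1]],
                     acidic_chain = dir[2],
                     acidic_resno = aci$resno[hit[, 2]],
                     acidic_resname = aci$resname[hit[, 2]],
                     distance_A = D[hit], stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- stats::aggregate(
      distance_A ~ basic_chain + basic_resno + basic_resname +
        acidic_chain + acidic_resno + acidic_resname,
      data = df, FUN = min)
  }
  if (length(out) == 0L)
    return(data.frame(basic_chain = character(), basic_resno = integer(),
                      basic_resname = character(), acidic_chain = character(),
                      acidic_resno = integer(), acidic_resname = character(),
                      distance_A = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$basic_chain, res$basic_resno, res$acidic_resno), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify interface hydrophobicity
#'
#' The apolar residue set is ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO.  An
#' interface is "hydrophobic" when the apolar fraction of its residues is
#' >= 0.7, "hydrophilic" when <= 0.3, "mixed" in between, and "empty" when
#' there are no interface residues.
#'
#' @param x an [InterfaceSummary-class], or a bare apolar fraction
#' @return classification string
#' @export
classifyInterfaceHydrophobicity <- function(x) {
  frac <- if (is(x, "InterfaceSummary")) {
    allRes <- c(x@residuesA$resname, x@residuesB$resname)
    if (length(allRes) == 0L) NA_real_ else mean(allRes %in% .APOLAR_RESIDUES)
  } else x
  if (is.na(frac)) return("empty")
  if (frac >= 0.7) "hydrophobic" else if (frac <= 0.3) "hydrophilic" else "mixed"
}

#' Label molecule pairs of a tetramer by interface character
#'
#' Within a tetramer there are three symmetry-distinct pair relations.  The
#' labels are derived from the interfaces themselves: contact-free pairs
#' play the A-D role, the contacting pair with the largest apolar fraction
#' plays the A-B role, and the remaining contacting pairs play the A-C
#' role.
#'
#' @param model a [StructureModel-class]
#' @param chainGroup chain ids of one tetramer
#' @param cutoffA contact cutoff
#' @return data.frame: chainA, chainB, n_contacts, hydrophobic_fraction,
#'   classification, role; plus attribute "interfaces" (list of
#'   [InterfaceSummary-class])
#' @export
molPairRoles <- function(model, chainGroup, cutoffA = 4.5) {
  pairs <- utils::combn(chainGroup, 2L)
  ifc <- apply(pairs, 2L, function(p)
    findInterfaceResidues(model, p[1], p[2], cutoffA = cutoffA))
  df <- data.frame(chainA = pairs[1, ], chainB = pairs[2, ],
                   n_contacts = vapply(ifc, function(x) nrow(x@contacts),
                                       integer(1)),
                   hydrophobic_fraction = vapply(ifc, function(x)
                     x@hydrophobicFraction, numeric(1)),
                   classification = vapply(ifc, function(x)
                     x@classification, character(1)),
                   stringsAsFactors = FALSE)
  role <- rep("A-C", nrow(df))
  role[df$n_contacts == 0L] <- "A-D"
  contacting <- which(df$n_contacts > 0L)
  if (length(contacting)) {
    best <- contacting[which.max(df$hydrophobic_fraction[contacting])]
    role[contacting[df$hydrophobic_fraction[contacting] ==
                      df$hydrophobic_fraction[best]]] <- "A-B"
  }
  df$role <- role
  attr(df, "interfaces") <- ifc
  df
}

#' Full structure report
#'
#' Computes the pairwise C-alpha RMSD matrix, assembly grouping, point
#' symmetry per assembly, and per-pair interface summaries within each
#' assembly; optionally writes the report as JSON.
#'
#' @param model a [StructureModel-class]
#' @param reportPath optional JSON output path
#' @param contactCutoffA,saltBridgeCutoffA,angTolDeg analysis parameters
#' @return report list, invisibly when writing
#' @export
structureReport <- function(model, reportPath = NULL, contactCutoffA = 4.5,
                            saltBridgeCutoffA = 4.0, angTolDeg = 15) {
  M <- rmsdMatrix(model)
  groups <- groupIntoAssemblies(model, contactCutoffA)
  perAssembly <- lapply(groups, function(g) {
    sym <- detectPointSymmetry(model, g, angTolDeg = angTolDeg)
    roles <- if (length(g) == 4L) molPairRoles(model, g, contactCutoffA)
             else NULL
    list(chains = g, pointGroup = sym$group, rotations = sym$rotations,
         pairRoles = roles)
  })
  rep <- list(chains = chainIds(model),
              modeledRanges = lapply(stats::setNames(nm = chainIds(model)),
                                     function(ch) modeledRange(model, ch)),
              rmsdMatrix = M, maxRmsdA = max(M),
              assemblies = perAssembly)
  if (!is.null(reportPath)) {
    jsonlite::write_json(
      list(chains = rep$chains,
           modeled_ranges = rep$modeledRanges,
           rmsd_matrix = M, max_rmsd_A = max(M),
           assemblies = lapply(perAssembly, function(a)
             list(chains = a$chains, point_group = a$pointGroup,
                  pair_roles = a$pairRoles))),
      reportPath, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
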