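## Geometric annotation of ligand binding sites and conformational
## change from atomic coordinates. File parsing is delegated to bio3d;
## the geometric criteria (contact distance, heavy-atom hydrogen-bond
## distance/angle, centroid distance and interplanar angle for
## aromatic stacking) are deliberately simple, exposed defaults --
## structural papers usually report these interactions qualitatively.

#' Read an atomic structure from PDB or mmCIF
#'
#' Thin wrapper around `bio3d::read.pdb()` / `bio3d::read.cif()`
#' returning the package's [Structure-class] container.
#'
#' @param path file path.
#' @param format `"auto"` (by extension; default), `"pdb"` or `"cif"`.
#' @return a [Structure-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("cannot parse '", path, "': file is empty")
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif"
              else "pdb"
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e)
      stop("cannot parse '", path, "' as ", toupper(format), ": ",
           conditionMessage(e)),
    warning = function(w)
      stop("cannot parse '", path, "' as ", toupper(format), ": ",
           conditionMessage(w)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0)
    stop("cannot parse '", path, "': no atom records")
  ele <- a$elesy
  if (is.null(ele) || all(is.na(ele)) || all(ele == ""))
    ele <- .elementFromName(a$elety)
  ele[is.na(ele) | ele == ""] <- .elementFromName(a$elety[is.na(ele) |
                                                           ele == ""])
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  df <- data.frame(chain = chain, resno = as.integer(a$resno),
                   resid = a$resid, elety = a$elety,
                   elesy = toupper(trimws(ele)),
                   x = a$x, y = a$y, z = a$z)
  new("Structure", atoms = df, source = path)
}

## infer element symbol from an atom name (first alphabetic character,
## two-letter check for common cases)
.elementFromName <- function(elety) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9 ]+", "", elety)))
  two <- c("CL", "BR", "FE", "ZN", "MG", "NA", "CA", "MN", "SE")
  ifelse(nm %in% two, nm, substr(nm, 1, 1))
}

#' Write a structure as a minimal PDB file
#'
#' @param s a [Structure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(s, path) {
  stopifnot(is(s, "Structure"))
  validObject(s)
  a <- s@atoms
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, elesy = a$elesy)
  invisible(path)
}

.coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

## squared cross-distances between two coordinate matrices
.crossDist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

.splitLigand <- function(s, ligand) {
  a <- s@atoms
  heavy <- a[a$elesy != "H", , drop = FALSE]
  lig <- heavy[heavy$resid == ligand, , drop = FALSE]
  if (nrow(lig) == 0)
    stop("ligand residue '", ligand, "' not found in structure")
  env <- heavy[heavy$resid != ligand, , drop = FALSE]
  list(lig = lig, env = env)
}

#' Residues in contact with a ligand
#'
#' Residues with any heavy atom within `cutoff` Angstrom of any ligand
#' heavy atom, sorted by minimum distance.
#'
#' @param s a [Structure-class].
#' @param ligand ligand residue name (e.g. `"CBD"`).
#' @param cutoff contact distance cutoff (Angstrom, default 4.5).
#' @return data.frame with `chain`, `resno`, `resid`, `minDist`.
#' @export
ligandContacts <- function(s, ligand, cutoff = 4.5) {
  stopifnot(is(s, "Structure"), cutoff >= 0)
  sp <- .splitLigand(s, ligand)
  if (nrow(sp$env) == 0 || cutoff == 0)
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), minDist = numeric()))
  D <- .crossDist(.coords(sp$env), .coords(sp$lig))
  minD <- apply(D, 1, min)
  key <- paste(sp$env$chain, sp$env$resno)
  agg <- tapply(minD, key, min)
  hit <- names(agg)[agg <= cutoff]
  if (!length(hit))
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), minDist = numeric()))
  first <- match(hit, key)
  out <- data.frame(chain = sp$env$chain[first],
                    resno = sp$env$resno[first],
                    resid = sp$env$resid[first],
                    minDist = as.numeric(agg[hit]))
  out <- out[order(out$minDist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect ligand hydrogen bonds (heavy-atom criterion)
#'
#' Donor/acceptor candidates are N and O atoms. A pair (one ligand
#' atom, one environment atom) is reported when the heavy-atom
#' distance is at most `dMax` and, for at least one orientation, the
#' angle at the donor between its bonded heavy-atom antecedent and the
#' acceptor is at least `angleMin` (no explicit hydrogens required).
#' Donors without an identifiable antecedent fall back to
#' distance-only detection with `noAngle = TRUE`.
#'
#' @param s a [Structure-class].
#' @param ligand ligand residue name.
#' @param dMax donor-acceptor heavy-atom distance cutoff (Angstrom,
#'   default 3.5).
#' @param angleMin minimum donor angle (degrees, default 120).
#' @return data.frame with donor/acceptor identification, `dist`,
#'   `angle` (degrees; `NA` when undeterminable) and `noAngle`.
#' @export
detectHbonds <- function(s, ligand, dMax = 3.5, angleMin = 120) {
  stopifnot(is(s, "Structure"), dMax > 0)
  sp <- .splitLigand(s, ligand)
  allHeavy <- rbind(sp$lig, sp$env)
  ligNO <- sp$lig[sp$lig$elesy %in% c("N", "O"), , drop = FALSE]
  envNO <- sp$env[sp$env$elesy %in% c("N", "O"), , drop = FALSE]
  empty <- data.frame(donorChain = character(), donorResno = integer(),
                      donorResid = character(), donorAtom = character(),
                      acceptorChain = character(),
                      acceptorResno = integer(),
                      acceptorResid = character(),
                      acceptorAtom = character(), dist = numeric(),
                      angle = numeric(), noAngle = logical())
  if (nrow(ligNO) == 0 || nrow(envNO) == 0) return(empty)

  D <- .crossDist(.coords(ligNO), .coords(envNO))
  hits <- which(D <= dMax & D >= 2.2, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)

  AH <- .coords(allHeavy)
  ## donor angle: max over bonded heavy neighbours (covalent, < 1.8 A)
  donorAngle <- function(dRow, aXYZ) {
    dXYZ <- as.numeric(dRow[c("x", "y", "z")])
    dn <- .crossDist(matrix(dXYZ, 1), AH)[1, ]
    nb <- which(dn > 1e-6 & dn < 1.8)
    nb <- nb[.crossDist(matrix(aXYZ, 1), AH[nb, , drop = FALSE])[1, ] >
             1e-6]
    if (!length(nb)) return(NA_real_)
    angs <- vapply(nb, function(j) {
      u <- AH[j, ] - dXYZ
      w <- aXYZ - dXYZ
      cosv <- sum(u * w) / (sqrt(sum(u^2)) * sqrt(sum(w^2)))
      acos(pmin(1, pmax(-1, cosv))) * 180 / pi
    }, numeric(1))
    max(angs)
  }

  rows <- lapply(seq_len(nrow(hits)), function(h) {
    li <- hits[h, 1]; ei <- hits[h, 2]
    lr <- ligNO[li, ]; er <- envNO[ei, ]
    dd <- D[li, ei]
    aLig <- donorAngle(lr, as.numeric(er[c("x", "y", "z")]))
    aEnv <- donorAngle(er, as.numeric(lr[c("x", "y", "z")]))
    ## choose the orientation with the better (larger) donor angle;
    ## undeterminable angles fall back to distance-only detection
    cand <- list(list(donor = er, acceptor = lr, angle = aEnv),
                 list(donor = lr, acceptor = er, angle = aLig))
    angles <- c(aEnv, aLig)
    if (all(is.na(angles))) {
      pick <- cand[[1]]; ok <- TRUE; noAng <- TRUE
    } else {
      best <- which.max(angles)
      pick <- cand[[best]]
      ok <- angles[best] >= angleMin
      noAng <- FALSE
    }
    if (!ok) return(NULL)
    data.frame(donorChain = pick$donor$chain,
               donorResno = pick$donor$resno,
               donorResid = pick$donor$resid,
               donorAtom = pick$donor$elety,
               acceptorChain = pick$acceptor$chain,
               acceptorResno = pick$acceptor$resno,
               acceptorResid = pick$acceptor$resid,
               acceptorAtom = pick$acceptor$elety,
               dist = dd, angle = pick$angle, noAngle = noAng)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## aromatic ring templates (protein side chains)
.RING_TEMPLATES <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

.ringGeometry <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Detect aromatic (pi-pi) stacking with a ligand ring
#'
#' Protein aromatic rings (Phe/Tyr/Trp/His templates) are paired with
#' the ligand ring defined by `ligandRing`; a pair is reported when the
#' ring-centroid distance is at most `centroidMax` and the interplanar
#' angle (between ring normals, folded to \[0, 90\] degrees) is at most
#' `angleMax` (near-parallel stacking).
#'
#' @param s a [Structure-class].
#' @param ligand ligand residue name.
#' @param ligandRing character vector of ligand atom names forming the
#'   aromatic ring (>= 5 atoms).
#' @param centroidMax centroid distance cutoff (Angstrom, default 5.5).
#' @param angleMax maximum interplanar angle (degrees, default 30).
#' @return data.frame with ring identification, `centroidDist` and
#'   `planeAngle`; rings with fewer than 5 resolved atoms are skipped
#'   with a warning.
#' @export
detectPiStacks <- function(s, ligand, ligandRing, centroidMax = 5.5,
                           angleMax = 30) {
  stopifnot(is(s, "Structure"), length(ligandRing) >= 5)
  sp <- .splitLigand(s, ligand)
  ligAtoms <- sp$lig[sp$lig$elety %in% ligandRing, , drop = FALSE]
  if (nrow(ligAtoms) < 5) {
    warning("ligand ring has fewer than 5 resolved atoms; skipped")
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), centroidDist = numeric(),
                      planeAngle = numeric()))
  }
  ligGeom <- .ringGeometry(.coords(ligAtoms))

  env <- sp$env
  key <- unique(env[env$resid %in% names(.RING_TEMPLATES),
                    c("chain", "resno", "resid")])
  rows <- list()
  for (r in seq_len(nrow(key))) {
    res <- env[env$chain == key$chain[r] & env$resno == key$resno[r], ,
               drop = FALSE]
    for (tmpl in .RING_TEMPLATES[[key$resid[r]]]) {
      ra <- res[res$elety %in% tmpl, , drop = FALSE]
      if (nrow(ra) < 5) {
        warning(sprintf("ring %s%s %s has fewer than 5 resolved atoms; skipped",
                        key$chain[r], key$resno[r], key$resid[r]))
        next
      }
      g <- .ringGeometry(.coords(ra))
      cd <- sqrt(sum((g$centroid - ligGeom$centroid)^2))
      cosv <- abs(sum(g$normal * ligGeom$normal))
      ang <- acos(pmin(1, cosv)) * 180 / pi
      if (cd <= centroidMax && ang <= angleMax)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = key$chain[r], resno = key$resno[r],
          resid = key$resid[r], centroidDist = cd, planeAngle = ang)
    }
  }
  if (!length(rows))
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), centroidDist = numeric(),
                      planeAngle = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(out$centroidDist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full ligand interaction report
#'
#' Convenience wrapper combining [ligandContacts()], [detectHbonds()]
#' and (when `ligandRing` is given) [detectPiStacks()].
#'
#' @inheritParams detectPiStacks
#' @param contactCutoff,dMax,angleMin,centroidMax,angleMax geometric
#'   criteria; see the individual detectors.
#' @return an [InteractionReport-class].
#' @export
interactionReport <- function(s, ligand, ligandRing = NULL,
                              contactCutoff = 4.5, dMax = 3.5,
                              angleMin = 120, centroidMax = 5.5,
                              angleMax = 30) {
  stacks <- if (is.null(ligandRing))
    data.frame(chain = character(), resno = integer(),
               resid = character(), centroidDist = numeric(),
               planeAngle = numeric())
  else detectPiStacks(s, ligand, ligandRing, centroidMax, angleMax)
  new("InteractionReport",
      contacts = ligandContacts(s, ligand, contactCutoff),
      hbonds = detectHbonds(s, ligand, dMax, angleMin),
      pistacks = stacks, ligand = ligand,
      cutoffs = list(contactCutoff = contactCutoff, dMax = dMax,
                     angleMin = angleMin, centroidMax = centroidMax,
                     angleMax = angleMax))
}

#' Apply a rigid transform to a structure
#'
#' @param s a [Structure-class].
#' @param rotation 3x3 rotation matrix (applied as `xyz %*% rotation`).
#' @param translation length-3 translation (Angstrom).
#' @return the transformed [Structure-class].
#' @export
applyTransform <- function(s, rotation = diag(3),
                           translation = c(0, 0, 0)) {
  stopifnot(is(s, "Structure"))
  xyz <- .coords(s@atoms) %*% rotation
  xyz <- sweep(xyz, 2, translation, "+")
  a <- s@atoms
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("Structure", atoms = a, source = s@source)
}

.selectAtoms <- function(atoms, selection) {
  heavy <- atoms$elesy != "H"
  if (is.function(selection)) return(atoms[selection(atoms) & heavy, ])
  switch(selection,
    calpha = atoms[atoms$elety == "CA" & heavy, ],
    backbone = atoms[atoms$elety %in% c("N", "CA", "C", "O") & heavy, ],
    heavy = atoms[heavy, ],
    all = atoms,
    stop("unknown selection '", selection, "'"))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Pairs atoms between the two structures by (chain, residue number,
#' atom name) within the selection, solves the proper-rotation
#' least-squares problem via singular value decomposition, and reports
#' the aligned RMSD plus per-residue displacements between paired
#' representative atoms (C-alpha when present, otherwise the first
#' paired atom of the residue).
#'
#' @param fixed,mobile [Structure-class] objects.
#' @param selection `"calpha"` (default), `"backbone"`, `"heavy"`,
#'   `"all"`, or a predicate `function(atoms) -> logical`.
#' @param onUnmatched `"error"` (default: selected atoms without a
#'   partner in the other structure abort with a list of unpaired
#'   residues) or `"drop"` (silently restrict to the paired set).
#' @return a [SuperpositionResult-class]. The transform maps mobile
#'   coordinates onto the fixed frame as
#'   `xyz %*% rotation + translation`.
#' @export
superpose <- function(fixed, mobile, selection = "calpha",
                      onUnmatched = c("error", "drop")) {
  stopifnot(is(fixed, "Structure"), is(mobile, "Structure"))
  onUnmatched <- match.arg(onUnmatched)
  fa <- .selectAtoms(fixed@atoms, selection)
  ma <- .selectAtoms(mobile@atoms, selection)
  fk <- paste(fa$chain, fa$resno, fa$elety)
  mk <- paste(ma$chain, ma$resno, ma$elety)
  common <- intersect(fk, mk)
  unpaired <- c(setdiff(fk, mk), setdiff(mk, fk))
  if (length(unpaired) && onUnmatched == "error")
    stop("unpaired atoms in selection (",
         length(unpaired), "): ",
         paste(head(unique(unpaired), 10L), collapse = ", "),
         if (length(unique(unpaired)) > 10L) ", ...")
  if (length(common) < 3L)
    stop("need at least 3 paired atoms for superposition")
  F <- .coords(fa[match(common, fk), ])
  M <- .coords(ma[match(common, mk), ])
  cf <- colMeans(F); cm <- colMeans(M)
  Fc <- sweep(F, 2, cf); Mc <- sweep(M, 2, cm)
  if (svd(Fc)$d[2] < 1e-8 || svd(Mc)$d[2] < 1e-8)
    stop("paired atoms are collinear; superposition is degenerate")
  H <- crossprod(Mc, Fc)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$u %*% S %*% t(sv$v)      # mobile %*% R aligns onto fixed
  tr <- as.numeric(cf - cm %*% R)
  Ma <- sweep(M %*% R, 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((Ma - F)^2)))

  ## per-residue displacement between representative paired atoms
  resKey <- paste(fa$chain[match(common, fk)],
                  fa$resno[match(common, fk)])
  elety <- fa$elety[match(common, fk)]
  perRes <- do.call(rbind, lapply(unique(resKey), function(kk) {
    idx <- which(resKey == kk)
    rep_ <- if ("CA" %in% elety[idx]) idx[elety[idx] == "CA"][1]
            else idx[1]
    data.frame(chain = fa$chain[match(common, fk)][rep_],
               resno = fa$resno[match(common, fk)][rep_],
               resid = fa$resid[match(common, fk)][rep_],
               displacement = sqrt(sum((Ma[rep_, ] - F[rep_, ])^2)))
  }))
  rownames(perRes) <- NULL
  new("SuperpositionResult", rotation = R, translation = tr,
      rmsd = rmsd, perResidue = perRes)
}

#' RMSD between paired atoms without alignment
#'
#' Plain root-mean-square deviation over atoms paired by (chain,
#' residue number, atom name) within the selection -- no superposition
#' is performed.
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
structureRmsd <- function(fixed, mobile, selection = "calpha") {
  fa <- .selectAtoms(fixed@atoms, selection)
  ma <- .selectAtoms(mobile@atoms, selection)
  fk <- paste(fa$chain, fa$resno, fa$elety)
  mk <- paste(ma$chain, ma$resno, ma$elety)
  common <- intersect(fk, mk)
  if (!length(common)) stop("no paired atoms")
  F <- .coords(fa[match(common, fk), ])
  M <- .coords(ma[match(common, mk), ])
  sqrt(mean(rowSums((F - M)^2)))
}
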