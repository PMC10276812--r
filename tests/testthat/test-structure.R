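test_that("PDB write/read round-trips coordinates at file precision", {
  fx <- genStructureFixtures()
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(fx$chain, tf)
  s <- readStructure(tf)
  expect_equal(nrow(atoms(s)), 12)
  expect_lt(max(abs(as.matrix(atoms(s)[, c("x", "y", "z")]) -
                    as.matrix(atoms(fx$chain)[, c("x", "y", "z")]))),
            1e-3)
  expect_identical(atoms(s)$resno, atoms(fx$chain)$resno)
})

test_that("unreadable structure files produce informative errors", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  file.create(tf)
  expect_error(readStructure(tf), "empty")
  expect_error(readStructure("/no/such/file.pdb"), "not found")
  writeLines(c("not", "a", "structure"), tf)
  expect_error(readStructure(tf), "parse")
})

test_that("ligand contacts respect the cutoff and sort by distance", {
  ## one residue at 3.0 A, one at 6.0 A from a single-atom ligand
  mk <- function(rows) {
    df <- do.call(rbind, lapply(rows, function(r)
      data.frame(chain = r[[1]], resno = r[[2]], resid = r[[3]],
                 elety = r[[4]], elesy = r[[5]], x = r[[6]], y = r[[7]],
                 z = r[[8]])))
    new("Structure", atoms = df, source = "inline")
  }
  s <- mk(list(list("A", 1L, "ALA", "CB", "C", 3, 0, 0),
               list("A", 2L, "GLY", "CA", "C", 6, 0, 0),
               list("L", 9L, "LIG", "C1", "C", 0, 0, 0)))
  hits <- ligandContacts(s, "LIG", cutoff = 4.5)
  expect_equal(hits$resno, 1L)
  expect_equal(hits$minDist, 3)
  expect_equal(nrow(ligandContacts(s, "LIG", cutoff = 0)), 0)
  both <- ligandContacts(s, "LIG", cutoff = 7)
  expect_equal(both$resno, c(1L, 2L))   # sorted by min distance
  expect_error(ligandContacts(s, "XYZ"), "not found")
})

test_that("contact detection agrees with an all-pairs double loop", {
  fx <- genStructureFixtures()
  s <- fx$ringsParallel
  cutoff <- 4.5
  a <- atoms(s)
  lig <- a[a$resid == "LIG", ]
  env <- a[a$resid != "LIG", ]
  ## brute-force oracle: literal nested loops over atom pairs
  minD <- Inf
  for (i in seq_len(nrow(env))) for (j in seq_len(nrow(lig))) {
    dd <- sqrt((env$x[i] - lig$x[j])^2 + (env$y[i] - lig$y[j])^2 +
               (env$z[i] - lig$z[j])^2)
    minD <- min(minD, dd)
  }
  hits <- ligandContacts(s, "LIG", cutoff)
  expect_equal(nrow(hits), as.integer(minD <= cutoff))
  if (nrow(hits)) expect_equal(hits$minDist[1], minD, tolerance = 1e-12)
})

test_that("hydrogen-bond detection applies distance and donor-angle criteria", {
  fx <- genStructureFixtures()
  expect_equal(nrow(detectHbonds(fx$hbondTriad, "LIG")), 1)
  expect_equal(nrow(detectHbonds(fx$hbondDecoy, "LIG")), 0)
  ## tightening the angle beyond the planted 170 degrees removes it
  expect_equal(nrow(detectHbonds(fx$hbondTriad, "LIG",
                                 angleMin = 175)), 0)
  ## tightening the distance below 2.8 A removes it
  expect_equal(nrow(detectHbonds(fx$hbondTriad, "LIG", dMax = 2.5)), 0)
})

test_that("pi-stack detection applies centroid and interplanar criteria", {
  fx <- genStructureFixtures()
  ring <- paste0("C", 1:6)
  expect_equal(nrow(detectPiStacks(fx$ringsParallel, "LIG", ring)), 1)
  expect_equal(nrow(detectPiStacks(fx$ringsPerpendicular, "LIG", ring)),
               0)
  ## same rings too far apart
  far <- applyTransform(fx$ringsParallel)
  a <- atoms(far)
  a[a$resid == "LIG", c("z")] <- a[a$resid == "LIG", "z"] + 4
  far <- new("Structure", atoms = a, source = "inline")
  expect_equal(nrow(detectPiStacks(far, "LIG", ring)), 0)
  ## incomplete rings are skipped with a warning
  a2 <- atoms(fx$ringsParallel)
  a2 <- a2[!(a2$resid == "PHE" & a2$elety %in% c("CG", "CD1")), ]
  part <- new("Structure", atoms = a2, source = "inline")
  expect_warning(res <- detectPiStacks(part, "LIG", ring),
                 "fewer than 5")
  expect_equal(nrow(res), 0)
})

test_that("interaction detection is invariant to rigid motion", {
  fx <- genStructureFixtures()
  for (i in 1:5) {
    R <- randomRotation(500 + i)
    tr <- rnorm(3, 0, 20)
    hb0 <- detectHbonds(fx$hbondTriad, "LIG")
    hb1 <- detectHbonds(applyTransform(fx$hbondTriad, R, tr), "LIG")
    expect_equal(hb1$dist, hb0$dist, tolerance = 1e-9)
    expect_equal(hb1$angle, hb0$angle, tolerance = 1e-6)
    st0 <- detectPiStacks(fx$ringsParallel, "LIG", paste0("C", 1:6))
    st1 <- detectPiStacks(applyTransform(fx$ringsParallel, R, tr),
                          "LIG", paste0("C", 1:6))
    expect_equal(st1$centroidDist, st0$centroidDist, tolerance = 1e-9)
    ## atom order must not matter either
    perm <- atoms(fx$hbondTriad)
    set.seed(600 + i)
    perm <- perm[sample(nrow(perm)), ]
    rownames(perm) <- NULL
    hb2 <- detectHbonds(new("Structure", atoms = perm,
                            source = "inline"), "LIG")
    expect_equal(hb2$dist, hb0$dist, tolerance = 1e-12)
  }
})

test_that("superposition recovers rigid transforms and reports displacements", {
  fx <- genStructureFixtures()
  ## identical structures: zero RMSD, identity rotation
  s0 <- superpose(fx$chain, fx$chain)
  expect_lt(s0@rmsd, 1e-10)
  expect_equal(s0@rotation, diag(3), tolerance = 1e-8)
  ## translated copy aligns exactly
  s1 <- superpose(fx$chain, applyTransform(fx$chain,
                                           translation = c(5, -3, 12)))
  expect_lt(s1@rmsd, 1e-10)
  ## planted rotation: pre-alignment displacement known, post ~ 0
  s2 <- superpose(fx$chain, fx$chainRotated)
  expect_lt(s2@rmsd, 1e-6)
  expect_equal(structureRmsd(fx$chain, fx$chainRotated),
               fx$planted$preRmsd, tolerance = 1e-9)
  ## per-residue displacements after alignment of a rotated+translated
  ## copy vanish
  s3 <- superpose(fx$chain,
                  applyTransform(fx$chainRotated, randomRotation(7),
                                 c(10, 0, -4)))
  expect_lt(max(s3@perResidue$displacement), 1e-6)
  ## RMSD is invariant to rigid motion of either input
  R <- randomRotation(8)
  s4 <- superpose(applyTransform(fx$chain, R, c(1, 2, 3)),
                  fx$chainRotated)
  expect_equal(s4@rmsd, s2@rmsd, tolerance = 1e-9)
})

test_that("superposition agrees with an independent Kabsch implementation", {
  fx <- genStructureFixtures()
  mobile <- applyTransform(fx$chainRotated, randomRotation(17),
                           c(-6, 2, 9))
  ours <- superpose(fx$chain, mobile)
  fixedXyz <- as.numeric(t(as.matrix(atoms(fx$chain)[, c("x", "y", "z")])))
  mobXyz <- as.numeric(t(as.matrix(atoms(mobile)[, c("x", "y", "z")])))
  ref <- bio3d::rmsd(fixedXyz, mobXyz, fit = TRUE)
  expect_equal(ours@rmsd, ref, tolerance = 1e-4)
})

test_that("unpaired or degenerate selections are rejected", {
  fx <- genStructureFixtures()
  a <- atoms(fx$chain)
  trimmed <- new("Structure", atoms = a[1:8, ], source = "inline")
  expect_error(superpose(fx$chain, trimmed), "unpaired")
  expect_silent(superpose(fx$chain, trimmed, onUnmatched = "drop"))
  ## collinear points have no unique superposition
  lin <- a; lin$y <- 0; lin$z <- 0
  linS <- new("Structure", atoms = lin, source = "inline")
  expect_error(superpose(linS, linS), "collinear")
})
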