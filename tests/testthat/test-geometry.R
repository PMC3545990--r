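test_that("Kabsch superposition recovers constructed rigid transforms", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  s_self <- superpose(P, P)
  expect_equal(s_self$rmsd, 0, tolerance = 1e-12)
  expect_equal(s_self$rotation, diag(3), tolerance = 1e-10)
  expect_equal(s_self$n_atoms, 10)

  Rz <- rotation_about(c(0, 0, 1), 30)
  Q <- rigid_move(P, Rz, c(1, -2, 3))
  s <- superpose(P, Q)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(rotation_angle(s), 30, tolerance = 1e-9)
  # applying the transform then recomputing gives the identity
  s2 <- superpose(apply_superposition(s, P), Q)
  expect_equal(s2$rmsd, 0, tolerance = 1e-9)
  expect_equal(rotation_angle(s2), 0, tolerance = 1e-6)

  # rotation is proper orthonormal
  expect_equal(crossprod(s$rotation), diag(3), tolerance = 1e-10)
  expect_equal(det(s$rotation), 1, tolerance = 1e-10)

  # least-squares optimality: no rigid transform beats the returned rmsd,
  # and the minimum agrees with an independent superposition routine
  Qn <- Q + matrix(rnorm(30, sd = 0.3), 10, 3)
  sn <- superpose(P, Qn)
  expect_equal(sn$rmsd,
               as.numeric(bio3d::rmsd(as.numeric(t(Qn)), as.numeric(t(P)),
                                      fit = TRUE)),
               tolerance = 1e-3)  # bio3d::rmsd rounds to 3 decimals
  for (i in 1:10) {
    Rp <- rotation_about(rnorm(3), runif(1, 0.5, 10)) %*% sn$rotation
    moved <- rigid_move(P, Rp, colMeans(Qn) - as.numeric(Rp %*% colMeans(P)))
    expect_gte(sqrt(mean(rowSums((moved - Qn)^2))), sn$rmsd - 1e-12)
  }

  collinear <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(collinear, collinear), "degenerate")
  expect_error(superpose(P[1:2, ], Q[1:2, ]), "at least 3")
  expect_error(superpose(P, Q[1:5, ]), "paired")
})

test_that("rotation angles follow the axis-angle closed form", {
  expect_equal(rotation_angle(diag(3)), 0)
  expect_equal(rotation_angle(diag(c(1, -1, -1))), 180)  # flip about x
  R10 <- rotation_about(c(1, 1, 0), 10)
  expect_equal(rotation_angle(R10 %*% R10), 20, tolerance = 1e-9)
  expect_error(rotation_angle(diag(c(1, 1, -1))), "proper rotation")
})

test_that("docking angle recovers a constructed inhibitor rotation and is symmetric", {
  pair <- toy_complex_pair(deg = 8)
  expect_equal(docking_angle(pair$c1, pair$c1, "E", "I"), 0,
               tolerance = 1e-6)
  a12 <- docking_angle(pair$c1, pair$c2, "E", "I")
  a21 <- docking_angle(pair$c2, pair$c1, "E", "I")
  expect_equal(a12, 8, tolerance = 1e-6)
  expect_lt(abs(a12 - a21), 1e-6)

  pair25 <- toy_complex_pair(deg = 25, seed = 7)
  expect_equal(docking_angle(pair25$c1, pair25$c2, "E", "I"), 25,
               tolerance = 1e-6)
  expect_error(docking_angle(pair$c1, pair$c2, "E", "Z"), "empty selection")
})

test_that("chi1 dihedrals follow the IUPAC sign convention", {
  expect_equal(chi1(serine_with_chi1(180), "A", 10)$value, 180,
               tolerance = 1e-6)
  expect_equal(chi1(serine_with_chi1(-60), "A", 10)$value, -60,
               tolerance = 1e-6)
  expect_equal(chi1(serine_with_chi1(65), "A", 10)$value, 65,
               tolerance = 1e-6)
  # reflection negates the signed dihedral
  m <- serine_with_chi1(-60)
  m$z <- -m$z
  expect_equal(chi1(m, "A", 10)$value, 60, tolerance = 1e-6)

  # independent oracle: bio3d torsion on the same atom quadruple
  ser <- serine_with_chi1(-60)
  expect_equal(bio3d::torsion.xyz(as.numeric(t(coords(ser)))), -60,
               tolerance = 1e-6, ignore_attr = TRUE)

  gly <- structure_model("A", 1, "GLY", c("N", "CA", "C"), c("N", "C", "C"),
                         x = c(0, 1.4, 2), y = c(0, 0, 1), z = 0)
  expect_error(chi1(gly, "A", 1), "no chi1")
})

test_that("contacts are classified by ionic > hbond > close-approach > vdw precedence", {
  # Arg guanidino to Asp carboxylate at 3.03 A: ionic (the salt-bridge
  # distance of a crystal-packing contact), even though donor/acceptor
  m <- structure_model(chain = c("A", "B"), resno = c(19, 28),
                       resid = c("ARG", "ASP"), atom = c("NH1", "OD1"),
                       element = c("N", "O"), x = c(0, 3.03), y = 0, z = 0)
  expect_equal(contacts(m, list(chain = "A"), list(chain = "B"))$class,
               "ionic")

  # backbone N...O donor/acceptor at the 3.2 A threshold boundary
  nearhb <- structure_model(chain = c("A", "B"), resno = 1:2, resid = "GLY",
                            atom = c("N", "O"), element = c("N", "O"),
                            x = c(0, 3.19), y = 0, z = 0)
  expect_equal(contacts(nearhb, list(chain = "A"), list(chain = "B"))$class,
               "hbond")
  farhb <- nearhb
  farhb$x[2] <- 3.21
  expect_equal(contacts(farhb, list(chain = "A"), list(chain = "B"))$class,
               "vdw")

  # apolar carbon pair at 3.5 A: van der Waals contact
  cc <- structure_model(chain = c("A", "B"), resno = 1:2, resid = "GLY",
                        atom = c("CA", "CA"), element = c("C", "C"),
                        x = c(0, 3.5), y = 0, z = 0)
  expect_equal(contacts(cc, list(chain = "A"), list(chain = "B"))$class,
               "vdw")

  # sub-van-der-Waals serine OG to carbonyl carbon (trapped tetrahedral
  # intermediate): close approach
  sub <- structure_model(chain = c("A", "B"), resno = c(741, 17),
                         resid = c("SER", "ARG"), atom = c("OG", "C"),
                         element = c("O", "C"), x = c(0, 1.6), y = 0, z = 0)
  ct <- contacts(sub, list(chain = "A"), list(chain = "B"))
  expect_equal(ct$class, "close_approach")
  expect_equal(ct$distance, 1.6)

  # beyond every threshold: empty result is allowed
  far <- structure_model(chain = c("A", "B"), resno = 1:2, resid = "GLY",
                         atom = c("CA", "CA"), element = c("C", "C"),
                         x = c(0, 8), y = 0, z = 0)
  expect_equal(nrow(contacts(far, list(chain = "A"), list(chain = "B"))), 0)
})

test_that("atom distances and central angles are exact on constructed fixtures", {
  m <- structure_model(chain = "A", resno = c(1, 2), resid = "GLY",
                       atom = c("CA", "CA"), element = "C",
                       x = c(0, 1), y = 0, z = 0)
  expect_equal(atom_distance(m, "A:1:CA", "A:2:CA"), 1.0)
  both <- structure_model(chain = "A", resno = c(1, 1), resid = "GLY",
                          atom = c("CA", "C"), element = "C",
                          x = c(0, 1), y = 0, z = 0)
  expect_error(atom_distance(both, list(chain = "A", resno = 1), "A:1:C"),
               "exactly 1")

  # ideal tetrahedral center
  tet <- structure_model("A", 1, "XXX", c("C1", "S1", "S2", "S3", "S4"),
                         c("C", "N", "N", "N", "N"),
                         x = c(0, 1, -1, 1, -1), y = c(0, 1, -1, -1, 1),
                         z = c(0, 1, 1, -1, -1))
  ang <- angles_at_center(tet, list(resno = 1, atom = "C1"),
                          lapply(paste0("S", 1:4),
                                 function(a) list(resno = 1, atom = a)))
  expect_equal(ang$angles, rep(2 * atan(sqrt(2)) * 180 / pi, 6),
               tolerance = 1e-9)
  expect_equal(ang$mean, 109.4712, tolerance = 1e-5)

  right <- structure_model("A", 1, "XXX", c("C1", "S1", "S2"),
                           c("C", "N", "N"),
                           x = c(0, 1, 0), y = c(0, 0, 1), z = 0)
  expect_equal(angles_at_center(right, list(resno = 1, atom = "C1"),
                                list(list(resno = 1, atom = "S1"),
                                     list(resno = 1, atom = "S2")))$angles,
               90)
  coinc <- structure_model("A", 1, "XXX", c("C1", "S1"), c("C", "N"),
                           x = 0, y = 0, z = 0)
  expect_error(angles_at_center(coinc, list(resno = 1, atom = "C1"),
                                list(list(resno = 1, atom = "S1"),
                                     list(resno = 1, atom = "S1"))),
               "coincide")
})

test_that("all measurements are invariant under global rigid motion", {
  pair <- toy_complex_pair(deg = 8)
  ser <- serine_with_chi1(-60)
  sub <- structure_model(chain = c("A", "B"), resno = c(741, 17),
                         resid = c("SER", "ARG"), atom = c("OG", "C"),
                         element = c("O", "C"), x = c(0, 1.6), y = 0, z = 0)
  set.seed(5)
  for (i in 1:5) {
    R <- rotation_about(rnorm(3), runif(1, 10, 170))
    shift <- rnorm(3, sd = 20)
    expect_equal(chi1(move_model(ser, R, shift), "A", 10)$value, -60,
                 tolerance = 1e-6)
    expect_equal(atom_distance(move_model(sub, R, shift), "A:741:OG",
                               "B:17:C"), 1.6, tolerance = 1e-9)
    expect_equal(docking_angle(move_model(pair$c1, R, shift), pair$c2,
                               "E", "I"), 8, tolerance = 1e-6)
    two <- structure_model("A", 1:2, "GLY", "O", "O",
                           x = c(0, 2), y = 0, z = 0)
    # slice discretisation is mildly anisotropic: totals agree to ~0.5%
    expect_equal(sasa(move_model(two, R, shift))$total, sasa(two)$total,
                 tolerance = 5e-3)
  }
})
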