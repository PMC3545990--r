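# constructed coordinate fixtures for the geometry suite

rotation_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

rigid_move <- function(xyz, R, shift) {
  t(R %*% t(xyz)) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
}

# internal-coordinate placement (NeRF): position d with given bond length
# to c, angle b-c-d and dihedral a-b-c-d
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# serine-like residue with a chosen chi1, plus flanking glycine
serine_with_chi1 <- function(chi1_deg, chain = "A", resno = 10) {
  N <- c(0, 0, 0)
  CA <- c(1.46, 0, 0)
  CB <- CA + 1.53 * c(cos((180 - 110) * pi / 180),
                      sin((180 - 110) * pi / 180), 0)
  OG <- place_atom(N, CA, CB, 1.42, 110, chi1_deg)
  structure_model(chain = chain, resno = resno, resid = "SER",
                  atom = c("N", "CA", "CB", "OG"),
                  element = c("N", "C", "C", "O"),
                  x = c(N[1], CA[1], CB[1], OG[1]),
                  y = c(N[2], CA[2], CB[2], OG[2]),
                  z = c(N[3], CA[3], CB[3], OG[3]))
}

ca_model <- function(xyz, chain = "A", resid = "GLY") {
  structure_model(chain = chain, resno = seq_len(nrow(xyz)), resid = resid,
                  atom = "CA", element = "C",
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# two copies of a protease+inhibitor CA complex where the inhibitor of
# copy 2 is additionally rotated by `deg` about an axis through its
# centroid, then the whole copy is rigidly moved
toy_complex_pair <- function(deg = 8, seed = 42) {
  set.seed(seed)
  prot1 <- matrix(rnorm(60, sd = 5), 20, 3)
  inh1 <- matrix(rnorm(24, sd = 3), 8, 3) + 15
  mk <- function(prot, inh)
    structure_model(chain = c(rep("E", nrow(prot)), rep("I", nrow(inh))),
                    resno = c(seq_len(nrow(prot)), seq_len(nrow(inh))),
                    resid = "GLY", atom = "CA", element = "C",
                    x = c(prot[, 1], inh[, 1]), y = c(prot[, 2], inh[, 2]),
                    z = c(prot[, 3], inh[, 3]))
  G <- rotation_about(c(1, 2, 3), 25)
  shift <- c(4, -2, 7)
  ctr <- colMeans(inh1)
  inh_rot <- rigid_move(sweep(inh1, 2, ctr), rotation_about(c(0.3, -1, 0.5), deg),
                        ctr)
  list(c1 = mk(prot1, inh1),
       c2 = mk(rigid_move(prot1, G, shift), rigid_move(inh_rot, G, shift)))
}

move_model <- function(model, R, shift) {
  xyz <- rigid_move(coords(model), R, shift)
  model$x <- xyz[, 1]
  model$y <- xyz[, 2]
  model$z <- xyz[, 3]
  model
}

# minimal hand-written PDB text (fixed-width records)
pdb_fixture_lines <- function() {
  c("HEADER    TOY FIXTURE",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      12.005   5.100  -6.900  1.00 11.00           C",
    "ATOM      3  C   ARG A  17       1.250  -2.500   3.750  1.00 12.00           C",
    "ATOM      4  CA  ARG A  17       2.000  -1.300   4.100  1.00 12.50           C",
    "END")
}

pdb_altloc_lines <- function() {
  c("ATOM      1  CA ASER A   1       0.000   0.000   0.000  0.60 10.00           C",
    "ATOM      2  CA BSER A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      3  N   SER A   1       0.000   1.400   0.000  1.00 10.00           N",
    "END")
}

write_pdb_fixture <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}
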