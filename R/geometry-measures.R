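## Point measurements on structures: distances, bond angles, dihedrals
## (chi1), and interface contact classification.

#' Signed dihedral angle over four points
#'
#' IUPAC convention: the angle of the a-b-c-d torsion, signed by the
#' right-hand rule about the b->c axis, in degrees in `(-180, 180]`.
#'
#' @param a,b,c,d length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## gamma atom defining chi1 by residue type
chi1_gamma_atom <- function(resid) {
  switch(resid,
         SER = "OG", THR = "OG1", CYS = "SG", VAL = "CG1", ILE = "CG1",
         GLY = NA_character_, ALA = NA_character_, "CG")
}

#' Chi1 side-chain dihedral of a residue
#'
#' Signed IUPAC N-CA-CB-gamma torsion, with the gamma atom chosen by
#' residue type (OG for Ser, OG1 for Thr, SG for Cys, CG1 for Val/Ile,
#' CG otherwise).  Gly and Ala have no chi1.
#'
#' @param model a `structure_model`.
#' @param chain,resno residue selector.
#' @return Object of class `dihedral_measure`: `value` (degrees in
#'   `(-180, 180]`), `angle = "chi1"`, `chain`, `resno`, `resid`.
#' @export
chi1 <- function(model, chain, resno) {
  res <- select_atoms(model, chain = chain, resno = resno)
  resid <- res$resid[1]
  gamma <- chi1_gamma_atom(resid)
  if (is.na(gamma))
    stop("residue ", resid, " ", chain, ":", resno, " has no chi1")
  pick <- function(nm) {
    i <- which(res$atom == nm)
    if (length(i) != 1)
      stop("chi1: residue ", chain, ":", resno, " (", resid,
           ") is missing atom ", nm)
    as.numeric(res[i, c("x", "y", "z")])
  }
  val <- dihedral_angle(pick("N"), pick("CA"), pick("CB"), pick(gamma))
  structure(list(value = val, angle = "chi1", chain = chain,
                 resno = resno, resid = resid),
            class = "dihedral_measure")
}

resolve_one <- function(model, sel) {
  at <- do.call(select_atoms, c(list(model), sel))
  if (nrow(at) != 1)
    stop("selector resolves to ", nrow(at), " atoms (need exactly 1): ",
         paste(unlist(sel), collapse = ":"))
  as.numeric(at[1, c("x", "y", "z")])
}

#' Distance between two uniquely selected atoms
#'
#' @param model a `structure_model`.
#' @param selA,selB selector lists (`list(chain=, resno=, atom=)`) or
#'   `chain:resnum:atom` strings, each resolving to exactly one atom.
#' @return Euclidean distance in Angstrom.
#' @export
atom_distance <- function(model, selA, selB) {
  if (is.character(selA)) selA <- parse_selector(selA)
  if (is.character(selB)) selB <- parse_selector(selB)
  a <- resolve_one(model, selA)
  b <- resolve_one(model, selB)
  sqrt(sum((a - b)^2))
}

#' Bond angles subtended at a central atom
#'
#' All unique pairwise angles substituent-center-substituent, plus their
#' arithmetic mean; used e.g. to test the near-tetrahedral geometry at a
#' scissile carbonyl carbon trapped as a tetrahedral intermediate.
#'
#' @param model a `structure_model`.
#' @param center selector (list or string) resolving to one atom.
#' @param substituents list of selectors, each resolving to one atom
#'   (>= 2 required).
#' @return List with `angles` (degrees, one per unique pair), `mean`,
#'   and `pairs` (indices).
#' @export
angles_at_center <- function(model, center, substituents) {
  if (is.character(center)) center <- parse_selector(center)
  stopifnot(length(substituents) >= 2)
  ctr <- resolve_one(model, center)
  pts <- lapply(substituents, function(s) {
    if (is.character(s)) s <- parse_selector(s)
    resolve_one(model, s)
  })
  vecs <- lapply(pts, function(p) {
    v <- p - ctr
    n <- sqrt(sum(v^2))
    if (n < 1e-8) stop("angles_at_center: substituent coincides with center")
    v / n
  })
  pairs <- utils::combn(length(vecs), 2)
  angles <- apply(pairs, 2, function(ij) {
    acos(max(-1, min(1, sum(vecs[[ij[1]]] * vecs[[ij[2]]])))) * 180 / pi
  })
  list(angles = angles, mean = mean(angles), pairs = t(pairs))
}

## -- contact classification ------------------------------------------------

## fixed per-residue donor/acceptor typing (heavy atoms; no hydrogens at
## typical resolutions, so detection is distance-only)
hbond_donors <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH",
  TRP = "NE1", CYS = "SG", HOH = "O")
hbond_acceptors <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
  MET = "SD", HOH = "O")
charged_pos <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                    HIS = c("ND1", "NE2"))
charged_neg <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

atom_in_table <- function(resid, atom, table) {
  atom %in% table$backbone | mapply(function(r, a) {
    t <- table[[r]]
    !is.null(t) && a %in% t
  }, resid, atom)
}

#' Interatomic contacts between two atom groups, classified
#'
#' Reports every heavy-atom pair between the two groups within the
#' maximum threshold, classified by precedence: `ionic` (atoms of
#' oppositely charged groups, Arg/Lys/His vs Asp/Glu/C-terminal OXT,
#' within `ionic_max`), `hbond` (donor/acceptor pair within
#' `hbond_max`), `close_approach` (below `close_max`, e.g. the
#' sub-van-der-Waals Ser-OG to carbonyl-carbon approach of a trapped
#' tetrahedral intermediate), else `vdw` (within `vdw_max`).
#'
#' @param model a `structure_model`.
#' @param selA,selB selector lists defining the two groups.
#' @param hbond_max,ionic_max,vdw_max,close_max class thresholds in
#'   Angstrom (defaults 3.2, 4.0, 4.0, 3.0).
#' @return Data frame of contacts: atoms, residues, `distance`, `class`.
#' @export
contacts <- function(model, selA, selB, hbond_max = 3.2, ionic_max = 4.0,
                     vdw_max = 4.0, close_max = 3.0) {
  A <- do.call(select_atoms, c(list(model), selA))
  B <- do.call(select_atoms, c(list(model), selB))
  A <- A[A$element != "H", , drop = FALSE]
  B <- B[B$element != "H", , drop = FALSE]
  if (nrow(A) == 0 || nrow(B) == 0) stop("contacts: empty heavy-atom group")
  maxd <- max(hbond_max, ionic_max, vdw_max, close_max)
  d2 <- outer(rowSums(coords(A)^2), rowSums(coords(B)^2), "+") -
    2 * coords(A) %*% t(coords(B))
  hit <- which(d2 <= maxd^2, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), atom_a = character(),
                      chain_b = character(), resno_b = integer(),
                      resid_b = character(), atom_b = character(),
                      distance = numeric(), class = character()))
  ia <- hit[, 1]; ib <- hit[, 2]
  dist <- sqrt(pmax(d2[hit], 0))
  pos_a <- atom_in_table(A$resid[ia], A$atom[ia],
                         c(charged_pos, backbone = list(character())))
  neg_a <- atom_in_table(A$resid[ia], A$atom[ia],
                         c(charged_neg, backbone = list("OXT")))
  pos_b <- atom_in_table(B$resid[ib], B$atom[ib],
                         c(charged_pos, backbone = list(character())))
  neg_b <- atom_in_table(B$resid[ib], B$atom[ib],
                         c(charged_neg, backbone = list("OXT")))
  don_a <- atom_in_table(A$resid[ia], A$atom[ia], hbond_donors)
  acc_a <- atom_in_table(A$resid[ia], A$atom[ia], hbond_acceptors)
  don_b <- atom_in_table(B$resid[ib], B$atom[ib], hbond_donors)
  acc_b <- atom_in_table(B$resid[ib], B$atom[ib], hbond_acceptors)
  ionic <- ((pos_a & neg_b) | (neg_a & pos_b)) & dist <= ionic_max
  hbond <- !ionic & ((don_a & acc_b) | (acc_a & don_b)) & dist <= hbond_max
  close <- !ionic & !hbond & dist < close_max
  vdw <- !ionic & !hbond & !close & dist <= vdw_max
  cls <- rep(NA_character_, length(dist))
  cls[vdw] <- "vdw"
  cls[close] <- "close_approach"
  cls[hbond] <- "hbond"
  cls[ionic] <- "ionic"
  out <- data.frame(
    chain_a = A$chain[ia], resno_a = A$resno[ia], resid_a = A$resid[ia],
    atom_a = A$atom[ia],
    chain_b = B$chain[ib], resno_b = B$resno[ib], resid_b = B$resid[ib],
    atom_b = B$atom[ib],
    distance = dist, class = cls, stringsAsFactors = FALSE)
  out <- out[!is.na(out$class), , drop = FALSE]
  out[order(out$distance), , drop = FALSE]
}
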