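## Least-squares rigid-body superposition (Kabsch algorithm) and the
## docking angle relating two copies of an inhibitor after superimposing
## their protease partners.

as_coords <- function(x) {
  if (inherits(x, "structure_model") || is.data.frame(x)) x <- coords(x)
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3, is.numeric(x))
  x
}

#' Optimal rigid superposition of paired atom sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' of `R %*% moving + t` onto `fixed` over all rigid transforms, via SVD
#' of the cross-covariance with the determinant-corrected (no
#' reflection) Kabsch construction.
#'
#' @param moving,fixed paired atom sets: n x 3 matrices or
#'   `structure_model`s (row i of `moving` pairs with row i of `fixed`);
#'   n >= 3, non-collinear.
#' @return Object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom) and `n_atoms`.
#' @export
superpose <- function(moving, fixed) {
  P <- as_coords(moving)
  Q <- as_coords(fixed)
  if (nrow(P) != nrow(Q))
    stop("superpose: atom sets must be paired (equal length)")
  if (nrow(P) < 3) stop("superpose: need at least 3 atom pairs")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  if (min(svd(P0)$d) < 1e-8 * max(svd(P0)$d, 1))
    stop("superpose: degenerate (collinear or coincident) geometry")
  H <- crossprod(P0, Q0)                  # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cq - R %*% cp)
  moved <- t(R %*% t(P)) + matrix(tr, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_atoms = nrow(P)),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#'
#' @param sup a [superpose()] result.
#' @param x n x 3 matrix or `structure_model`.
#' @return Transformed n x 3 coordinate matrix.
#' @export
apply_superposition <- function(sup, x) {
  stopifnot(inherits(sup, "superposition"))
  X <- as_coords(x)
  t(sup$rotation %*% t(X)) + matrix(sup$translation, nrow(X), 3,
                                    byrow = TRUE)
}

#' Rotation angle (axis-angle magnitude) of a superposition
#'
#' `acos((trace(R) - 1)/2)` in degrees, in `[0, 180]`.
#'
#' @param x a [superpose()] result or a 3 x 3 rotation matrix.
#' @return Angle in degrees.
#' @export
rotation_angle <- function(x) {
  R <- if (inherits(x, "superposition")) x$rotation else as.matrix(x)
  stopifnot(all(dim(R) == c(3, 3)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("rotation_angle: not a proper rotation matrix")
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

## paired CA coordinate sets for two models over shared residue numbers
pair_ca <- function(model1, model2, chain1, chain2) {
  ca1 <- select_atoms(model1, chain = chain1, atom = "CA")
  ca2 <- select_atoms(model2, chain = chain2, atom = "CA")
  k1 <- paste(ca1$resno, ca1$icode)
  k2 <- paste(ca2$resno, ca2$icode)
  shared <- intersect(k1, k2)
  if (length(shared) == 0)
    stop("no shared residues between chain ", chain1, " and chain ",
         chain2, "; missing: ",
         paste(head(setdiff(k1, k2), 5), collapse = ", "))
  n_drop <- length(union(k1, k2)) - length(shared)
  if (n_drop > 0)
    message("pairing dropped ", n_drop, " unshared residue(s)")
  list(a = coords(ca1)[match(shared, k1), , drop = FALSE],
       b = coords(ca2)[match(shared, k2), , drop = FALSE])
}

#' Docking angle between two copies of a protease-inhibitor complex
#'
#' Superposes the protease of complex 1 onto the protease of complex 2
#' over shared C-alpha atoms, applies that transform to the inhibitor of
#' complex 1, and returns the axis-angle magnitude of the residual
#' best-fit rotation of the transformed inhibitor 1 onto inhibitor 2
#' (again over shared C-alpha).  This is the rigid rotation the
#' inhibitor makes relative to its protease between the two complexes.
#'
#' @param complex1,complex2 `structure_model`s each containing a protease
#'   and an inhibitor chain.
#' @param protease_chain,inhibitor_chain chain id(s); a length-2 vector
#'   gives the chain in complex 1 and complex 2 respectively.
#' @return Docking angle difference in degrees, in `[0, 180]`.
#' @export
docking_angle <- function(complex1, complex2, protease_chain,
                          inhibitor_chain) {
  pc <- rep_len(protease_chain, 2)
  ic <- rep_len(inhibitor_chain, 2)
  prot <- pair_ca(complex1, complex2, pc[1], pc[2])
  sup_prot <- superpose(prot$a, prot$b)
  inh <- pair_ca(complex1, complex2, ic[1], ic[2])
  inh1_moved <- apply_superposition(sup_prot, inh$a)
  rotation_angle(superpose(inh1_moved, inh$b))
}

#' Pairwise C-alpha RMSD after optimal superposition
#'
#' @param model1,model2 `structure_model`s.
#' @param chain1,chain2 chains to compare (paired by residue number).
#' @return The [superpose()] result over shared C-alpha atoms.
#' @export
ca_superpose <- function(model1, model2, chain1, chain2) {
  p <- pair_ca(model1, model2, chain1, chain2)
  superpose(p$a, p$b)
}
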