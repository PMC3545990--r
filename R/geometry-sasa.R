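## Lee-Richards solvent-accessible surface area by z-slice arc
## integration, and buried interface area of a complex.

#' United-atom radii for SASA (Chothia-style)
#'
#' Heavy-atom radii in Angstrom: C 1.87, N 1.65, O 1.40, S 1.85.
#' Hydrogens are implicit (united-atom model) and are dropped before
#' the calculation.
#'
#' @return Named numeric vector of radii.
#' @export
sasa_radii <- function() c(C = 1.87, N = 1.65, O = 1.40, S = 1.85)

#' Solvent-accessible surface area (Lee-Richards)
#'
#' Slices each solvent-expanded atom sphere (radius `r + probe`)
#' perpendicular to z and integrates, per slice, the arc of its circle
#' not occluded by neighbouring expanded spheres; each slice of
#' thickness `h` contributes `accessible_angle * R * h` (a spherical
#' zone has area `2*pi*R*h`, so the accessible fraction of the zone is
#' the accessible arc fraction).  Slices are centred per atom with
#' thickness adapted down from `slice` so that an isolated sphere is
#' exact.  Deterministic for fixed slice spacing.
#'
#' @param model a `structure_model` or data frame with `element`, `x`,
#'   `y`, `z` columns.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param slice maximum slice spacing in Angstrom (default 0.1).
#' @param radii named radii vector (default [sasa_radii()]).
#' @param water include waters (default `FALSE`).
#' @return Object of class `sasa_result`: `area` (per atom, Angstrom^2),
#'   `total`, `probe`, `slice`, and the atom table used.
#' @export
sasa <- function(model, probe = 1.4, slice = 0.1, radii = sasa_radii(),
                 water = FALSE) {
  atoms <- as.data.frame(model)
  if (!water && !is.null(atoms$is_water))
    atoms <- atoms[!atoms$is_water, , drop = FALSE]
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", ,
                 drop = FALSE]
  if (nrow(atoms) == 0) stop("sasa: no heavy atoms to measure")
  unknown <- setdiff(unique(atoms$element), names(radii))
  if (length(unknown))
    stop("sasa: no radius for element(s) ", paste(unknown, collapse = ", "),
         " (atoms: ",
         paste(head(atoms$atom[atoms$element %in% unknown], 5),
               collapse = ", "), ")")
  r <- radii[atoms$element] + probe
  x <- atoms$x; y <- atoms$y; z <- atoms$z
  n <- length(r)
  area <- numeric(n)

  # neighbour lists from the full distance matrix (structures here are
  # a few thousand atoms at most)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2 + outer(z, z, "-")^2
  rsum2 <- outer(r, r, "+")^2
  nb <- lapply(seq_len(n), function(i) {
    j <- which(d2[i, ] < rsum2[i, ])
    j[j != i]
  })

  for (i in seq_len(n)) {
    Ri <- r[i]
    ns <- max(1L, ceiling(2 * Ri / slice))
    h <- 2 * Ri / ns
    zs <- z[i] - Ri + (seq_len(ns) - 0.5) * h
    js <- nb[[i]]
    if (length(js) == 0) {
      area[i] <- 4 * pi * Ri^2
      next
    }
    dxs <- x[js] - x[i]
    dys <- y[js] - y[i]
    dxy <- sqrt(dxs^2 + dys^2)
    th <- atan2(dys, dxs)
    acc_total <- 0
    for (k in seq_len(ns)) {
      ri_z <- sqrt(max(Ri^2 - (zs[k] - z[i])^2, 0))
      if (ri_z <= 0) next
      dzj <- zs[k] - z[js]
      live <- abs(dzj) < r[js]
      if (!any(live)) {
        acc_total <- acc_total + 2 * pi * h
        next
      }
      rj_z <- sqrt(r[js][live]^2 - dzj[live]^2)
      d <- dxy[live]
      # full occlusion of circle i by a neighbour circle
      if (any(d + ri_z <= rj_z)) next
      cut <- d < ri_z + rj_z & d + rj_z > ri_z & d > 0
      if (!any(cut)) {
        acc_total <- acc_total + 2 * pi * h
        next
      }
      alpha <- acos(pmin(1, pmax(-1,
        (d[cut]^2 + ri_z^2 - rj_z[cut]^2) / (2 * d[cut] * ri_z))))
      acc <- accessible_angle(th[live][cut], alpha)
      acc_total <- acc_total + acc * h
    }
    area[i] <- acc_total * Ri
  }
  structure(list(area = area, total = sum(area), probe = probe,
                 slice = slice, atoms = atoms),
            class = "sasa_result")
}

## measure of [0, 2pi) not covered by arcs centred at theta with
## half-widths alpha
accessible_angle <- function(theta, alpha) {
  lo <- theta - alpha
  hi <- theta + alpha
  lo <- lo %% (2 * pi)
  hi <- hi %% (2 * pi)
  wrap <- hi < lo
  starts <- c(lo, rep(0, sum(wrap)))
  ends <- c(ifelse(wrap, 2 * pi, hi), hi[wrap])
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  covered <- 0
  cur_end <- -1
  for (m in seq_along(starts)) {
    if (starts[m] > cur_end) {
      covered <- covered + ends[m] - starts[m]
      cur_end <- ends[m]
    } else if (ends[m] > cur_end) {
      covered <- covered + ends[m] - cur_end
      cur_end <- ends[m]
    }
  }
  max(2 * pi - covered, 0)
}

#' Surface area buried on complex formation
#'
#' `sasa(A alone) + sasa(B alone) - sasa(A+B complex)`; symmetric in the
#' two parts, and zero when the parts are too far apart for any
#' expanded spheres to touch.
#'
#' @param model a `structure_model` containing both parts.
#' @param selA,selB selector lists partitioning the complex atoms (they
#'   must not overlap).
#' @param ... passed to [sasa()] (`probe`, `slice`, `radii`).
#' @return Buried area in Angstrom^2.
#' @export
buried_area <- function(model, selA, selB, ...) {
  A <- do.call(select_atoms, c(list(model), selA))
  B <- do.call(select_atoms, c(list(model), selB))
  ra <- rownames(A)
  rb <- rownames(B)
  if (length(intersect(ra, rb)))
    stop("buried_area: part selections overlap (",
         length(intersect(ra, rb)), " shared atoms)")
  complex <- model[rownames(model) %in% c(ra, rb), , drop = FALSE]
  class(complex) <- class(model)
  sasa(A, ...)$total + sasa(B, ...)$total - sasa(complex, ...)$total
}

#' Brute-force spherical-quadrature SASA (reference oracle)
#'
#' Independent check of [sasa()]: samples each expanded sphere with a
#' Fibonacci point set and counts points outside every other expanded
#' sphere.  Slow; intended for small test systems only.
#'
#' @inheritParams sasa
#' @param n_points quadrature points per sphere.
#' @return List with per-atom `area` and `total`.
#' @export
sasa_quadrature <- function(model, probe = 1.4, radii = sasa_radii(),
                            n_points = 5000, water = FALSE) {
  atoms <- as.data.frame(model)
  if (!water && !is.null(atoms$is_water))
    atoms <- atoms[!atoms$is_water, , drop = FALSE]
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  r <- radii[atoms$element] + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  # Fibonacci sphere
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  unit <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  area <- vapply(seq_len(n), function(i) {
    pts <- sweep(unit * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      free <- free & dj2 > r[j]^2
      if (!any(free)) break
    }
    4 * pi * r[i]^2 * mean(free)
  }, 1)
  list(area = area, total = sum(area))
}
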