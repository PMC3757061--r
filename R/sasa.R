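#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each heavy atom is covered with a quasi-uniform
#' sphere of test points at radius (van der Waals + probe); the
#' accessible fraction is the share of points not buried inside any
#' neighbouring atom's expanded sphere.  Van der Waals radii are the
#' Bondi set, probe radius defaults to 1.4 Angstrom (water).
#'
#' @param ens a [structure_ensemble()].
#' @param frame frame index (default 1); use [sasa_series()] for a time
#'   series.
#' @param nodes optional character vector of node labels restricting
#'   the per-residue report.
#' @param probe probe radius (Angstrom, default 1.4).
#' @param n_points test points per atom sphere (default 960).
#' @return named numeric vector: SASA (Angstrom^2) per node.
#' @export
sasa <- function(ens, frame = 1, nodes = NULL, probe = 1.4, n_points = 960) {
  a <- ens$atoms
  co <- frame_coords(ens, frame)
  heavy <- a$element != "H"
  co <- co[heavy, , drop = FALSE]
  ah <- a[heavy, , drop = FALSE]
  radii <- bondi_radius(ah$element)
  per_atom <- sasa_atoms(co, radii, probe, n_points)
  out <- tapply(per_atom, ah$node, sum)
  out <- stats::setNames(as.numeric(out), names(out))
  roster <- node_table(ens)$node
  out <- out[roster[roster %in% names(out)]]
  if (!is.null(nodes)) out <- out[nodes]
  out
}

#' Per-frame SASA time series for selected nodes
#'
#' @param ens a [structure_ensemble()].
#' @param nodes node label(s).
#' @inheritParams sasa
#' @return matrix, frames x nodes (Angstrom^2).
#' @export
sasa_series <- function(ens, nodes, probe = 1.4, n_points = 960) {
  out <- t(vapply(seq_len(n_frames(ens)), function(f)
    sasa(ens, f, nodes = nodes, probe = probe, n_points = n_points),
    numeric(length(nodes))))
  if (length(nodes) == 1) out <- matrix(out, ncol = 1)
  colnames(out) <- nodes
  out
}

bondi_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, MG = 1.73,
           `NA` = 2.27, K = 2.75, CA = 2.31, ZN = 1.39, FE = 2.00)
  el <- toupper(element)
  miss <- setdiff(unique(el), names(tab))
  if (length(miss))
    stop("no van der Waals radius for element(s): ",
         paste(miss, collapse = ", "))
  unname(tab[el])
}

# quasi-uniform points on the unit sphere (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

sasa_atoms <- function(co, radii, probe, n_points) {
  n <- nrow(co)
  pts <- sphere_points(n_points)
  er <- radii + probe
  out <- numeric(n)
  # neighbour lists by distance cutoff
  dmax <- max(er)
  for (i in seq_len(n)) {
    ri <- er[i]
    d <- sqrt(rowSums(sweep(co, 2, co[i, ])^2))
    nb <- which(d < ri + er & seq_len(n) != i)
    test <- sweep(pts * ri, 2, co[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- rowSums(sweep(test[acc, , drop = FALSE], 2, co[j, ])^2)
      acc[acc] <- dj2 > er[j]^2
    }
    out[i] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  out
}
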