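#' Structure ensembles
#'
#' A `structure_ensemble` holds a conformational ensemble: a constant
#' atom roster (chain, residue number, residue type, atom name, element)
#' and a frames x 3N coordinate matrix in Angstrom (the bio3d `xyz`
#' convention: x1,y1,z1,x2,...).  One network node is defined per
#' residue, plus one node per ligand entry (nucleotide, divalent ion,
#' structural water).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`,
#'   `elety` (atom name) and optionally `element` (guessed from the atom
#'   name when absent).
#' @param xyz numeric matrix, frames x (3 * natoms).
#' @return an object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "resid", "elety")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns; expected ", 3 * nrow(atoms))
  if (!("element" %in% names(atoms)))
    atoms$element <- toupper(substr(gsub("[0-9]", "", atoms$elety), 1, 1))
  atoms$node <- paste0(atoms$chain, ":", atoms$resno)
  if (anyDuplicated(unique(atoms[, c("node", "resid")])$node))
    stop("residue indices must be unique per chain")
  structure(list(atoms = atoms, xyz = xyz), class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("Structure ensemble:", nrow(x$xyz), "frames,",
      nrow(x$atoms), "atoms,", length(unique(x$atoms$node)), "nodes\n")
  invisible(x)
}

#' @export
dim.structure_ensemble <- function(x) c(nrow(x$xyz), nrow(x$atoms))

n_frames <- function(ens) nrow(ens$xyz)

# node roster: one row per residue/ligand node, in atom order
node_table <- function(ens) {
  a <- ens$atoms
  idx <- !duplicated(a$node)
  data.frame(node = a$node[idx], chain = a$chain[idx],
             resno = a$resno[idx], resid = a$resid[idx],
             stringsAsFactors = FALSE)
}

# frame coordinates as natoms x 3
frame_coords <- function(ens, frame) {
  matrix(ens$xyz[frame, ], ncol = 3, byrow = TRUE)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Logical mask of side-chain atoms used for contact counting.  All heavy
# atoms except backbone N/CA/C/O; glycine keeps CA as its sole
# "side-chain" atom (otherwise it could never form links); ligand nodes
# (non-amino-acid residues) use all their atoms.
sidechain_mask <- function(ens) {
  a <- ens$atoms
  aa <- a$resid %in% AMINO3
  sc <- !(a$elety %in% BACKBONE_ATOMS) & a$element != "H"
  # glycine: no side chain -> use CA
  gly <- a$resid == "GLY"
  sc[gly] <- a$elety[gly] == "CA"
  sc[!aa] <- a$element[!aa] != "H"
  sc
}

# Calpha (or node representative) atom index per node: CA for amino
# acids, first atom for ligands.
node_rep_atoms <- function(ens) {
  a <- ens$atoms
  nodes <- unique(a$node)
  vapply(nodes, function(nd) {
    rows <- which(a$node == nd)
    ca <- rows[a$elety[rows] == "CA"]
    if (length(ca)) ca[1] else rows[1]
  }, integer(1))
}

#' Read a multi-model PDB file as a structure ensemble
#'
#' @param path path to a (multi-model) PDB file.
#' @return a [structure_ensemble()].
#' @export
read_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  atoms <- data.frame(chain = pdb$atom$chain, resno = pdb$atom$resno,
                      resid = pdb$atom$resid, elety = pdb$atom$elety,
                      stringsAsFactors = FALSE)
  el <- pdb$atom$elesy
  if (!is.null(el) && !all(is.na(el))) atoms$element <- toupper(trimws(el))
  structure_ensemble(atoms, unclass(xyz))
}

#' Write a structure ensemble as a multi-model PDB file
#'
#' @param ens a [structure_ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  a <- ens$atoms
  aa <- a$resid %in% AMINO3
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(ens)
  for (f in seq_len(nf)) {
    co <- frame_coords(ens, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    rec <- ifelse(aa, "ATOM  ", "HETATM")
    nm <- a$elety
    nm4 <- ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), sprintf("%-4s", nm))
    lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, seq_len(nrow(a)), nm4, a$resid, a$chain, a$resno,
                     co[, 1], co[, 2], co[, 3], 1, 0, a$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Specification of a synthetic structure ensemble
#'
#' Describes a toy ensemble with controllable statistical structure:
#' Gaussian positional fluctuations around a reference geometry with a
#' low-rank-plus-isotropic covariance (so PCA/LMI ground truth is
#' known), side-chain contacts persistent in a controllable fraction of
#' frames (so occurrence filtering is testable), and optional
#' ligand-like nodes carrying the nucleotide/ion/water normalization
#' values.  Synthetic residues are typed `SYN` with normalization factor
#' 100 so that interaction-strength arithmetic is transparent
#' (I_ij = n_ij when both factors are 100).
#'
#' @param n_res number of residues.
#' @param n_frames number of frames.
#' @param sigma isotropic fluctuation SD per coordinate (Angstrom).
#' @param sidechain_atoms side-chain pseudo-atoms per residue (1..4),
#'   recycled.
#' @param correlations data.frame with columns `i`, `j`, `rho`: pairs of
#'   residues whose 3-D displacements share a latent factor with
#'   correlation `rho` per coordinate (pairs must be disjoint).
#' @param contacts data.frame with columns `i`, `j`, `persistence`:
#'   residue pairs whose side chains touch in that fraction of frames
#'   (realized atom-pair count = sidechain_atoms i x j).  The contact
#'   graph must be a union of simple chains: each residue in at most two
#'   contacts, no cycles.
#' @param modes list of planted collective modes, each
#'   `list(sd = <Angstrom>)`; a random unit direction in 3N space is
#'   drawn per mode and displaced by N(0, sd^2) amplitudes.
#' @param ligands character vector from `c("GTP", "MG", "HOH")`.
#' @param spacing Calpha spacing along the chain axis (Angstrom).
#' @param seed random seed making generation deterministic.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_res, n_frames, sigma = 0.3,
                          sidechain_atoms = 2, correlations = NULL,
                          contacts = NULL, modes = NULL,
                          ligands = character(), spacing = 10,
                          seed = 1) {
  if (!is.null(contacts)) {
    if (any(contacts$persistence < 0 | contacts$persistence > 1))
      stop("persistence fractions must be in [0,1]")
    key <- cbind(pmin(contacts$i, contacts$j), pmax(contacts$i, contacts$j))
    if (anyDuplicated(key))
      stop("infeasible contact plan: overlapping target pairs")
    cg <- igraph::graph_from_data_frame(
      data.frame(from = as.character(contacts$i),
                 to = as.character(contacts$j)), directed = FALSE)
    if (max(igraph::degree(cg)) > 2 ||
        igraph::gsize(cg) != igraph::gorder(cg) -
          igraph::count_components(cg))
      stop("infeasible contact plan: the contact graph must be a union ",
           "of simple chains (each residue in at most 2 contacts, ",
           "no cycles)")
  }
  if (!is.null(correlations)) {
    if (any(abs(correlations$rho) > 1)) stop("rho must be in [-1,1]")
    if (anyDuplicated(c(correlations$i, correlations$j)))
      stop("correlation pairs must be disjoint")
  }
  structure(list(n_res = n_res, n_frames = n_frames, sigma = sigma,
                 sidechain_atoms = rep_len(sidechain_atoms, n_res),
                 correlations = correlations, contacts = contacts,
                 modes = modes, ligands = ligands, spacing = spacing,
                 seed = seed),
            class = "ensemble_spec")
}

#' Generate a synthetic structure ensemble
#'
#' Deterministic given `spec$seed`.  Residue fluctuations move each
#' residue rigidly (Calpha and its side-chain pseudo-atoms together), so
#' the Calpha displacement covariance is exactly the planted one.  In
#' contact frames the partner residues' side-chain clusters are stacked
#' at 2.8--3.6 Angstrom spacing, realizing exactly
#' `sidechain_atoms[i] * sidechain_atoms[j]` atom pairs within the
#' 4.5 Angstrom cutoff for each planted contact and none for any other
#' pair.  Contact plans may chain residues (a union of simple paths in
#' the contact graph), so connected protein structure graphs can be
#' planted.  The ground-truth record (planted covariance
#' structure, contact plan, per-pair realized occurrence) is attached as
#' attribute `truth`.
#'
#' @param spec an [ensemble_spec()].
#' @return a [structure_ensemble()] with attribute `truth`.
#' @export
gen_ensemble <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_res
  nf <- spec$n_frames
  nsc <- spec$sidechain_atoms

  # reference geometry: residues advance along x on a coarse helix
  # (a collinear reference would make rigid-body superposition
  # rotationally degenerate); side chains radial.  The x advance alone
  # keeps non-contact residue pairs >= `spacing` apart.
  sc_off <- list(c(0, 1.2, 0), c(0, -1.2, 0), c(0, 0, 1.2), c(0, 0, -1.2))
  atoms <- list(); ref <- list(); res_of_atom <- integer()
  for (k in seq_len(n)) {
    ca <- c(spec$spacing * (k - 1), 6 * cos(k), 6 * sin(k))
    atoms[[length(atoms) + 1]] <- data.frame(
      chain = "A", resno = k, resid = "SYN", elety = "CA", element = "C")
    ref[[length(ref) + 1]] <- ca
    res_of_atom <- c(res_of_atom, k)
    for (s in seq_len(nsc[k])) {
      atoms[[length(atoms) + 1]] <- data.frame(
        chain = "A", resno = k, resid = "SYN", elety = paste0("S", s),
        element = "C")
      ref[[length(ref) + 1]] <- ca + sc_off[[s]]
      res_of_atom <- c(res_of_atom, k)
    }
  }
  # ligand nodes, placed far off the chain axis
  lig_atoms <- list(GTP = c("PG", "O1", "C5"), MG = "MG", HOH = "O")
  lig_elem <- list(GTP = c("P", "O", "C"), MG = "MG", HOH = "O")
  li <- 0
  lig_res_index <- integer()
  for (lg in spec$ligands) {
    li <- li + 1
    base <- c(spec$spacing * (li - 1), 30, 0)
    resno <- n + li
    nm <- lig_atoms[[lg]]
    for (s in seq_along(nm)) {
      atoms[[length(atoms) + 1]] <- data.frame(
        chain = "L", resno = resno, resid = lg, elety = nm[s],
        element = lig_elem[[lg]][s])
      ref[[length(ref) + 1]] <- base + c(0, 0, 0.8 * (s - 1))
      res_of_atom <- c(res_of_atom, resno)
    }
    lig_res_index <- c(lig_res_index, resno)
  }
  atoms <- do.call(rbind, atoms)
  ref <- do.call(rbind, ref)
  natoms <- nrow(atoms)
  n_nodes <- n + li

  # per-node 3-D displacements: shared factors for planted correlations,
  # independent isotropic remainder, plus planted collective modes
  disp <- array(stats::rnorm(nf * n_nodes * 3), dim = c(nf, n_nodes, 3))
  if (!is.null(spec$correlations)) {
    for (r in seq_len(nrow(spec$correlations))) {
      i <- spec$correlations$i[r]; j <- spec$correlations$j[r]
      rho <- spec$correlations$rho[r]
      g <- matrix(stats::rnorm(nf * 3), nf, 3)
      a <- sqrt(abs(rho))
      disp[, i, ] <- a * g + sqrt(1 - abs(rho)) *
        matrix(stats::rnorm(nf * 3), nf, 3)
      disp[, j, ] <- sign(rho) * a * g + sqrt(1 - abs(rho)) *
        matrix(stats::rnorm(nf * 3), nf, 3)
    }
  }
  disp <- disp * spec$sigma

  mode_truth <- list()
  if (!is.null(spec$modes)) {
    for (m in spec$modes) {
      v <- stats::rnorm(n_nodes * 3)
      v <- v / sqrt(sum(v^2))
      z <- stats::rnorm(nf, sd = m$sd)
      disp <- disp + array(outer(z, v), dim = c(nf, n_nodes, 3))
      # array() fills [frame, node, coord] column-major, so v is laid out
      # coordinate-block-wise; record it in the interleaved (x1,y1,z1,...)
      # order used by the ensemble coordinates
      v_int <- as.numeric(t(matrix(v, n_nodes, 3)))
      mode_truth[[length(mode_truth) + 1]] <- list(direction = v_int,
                                                   sd = m$sd)
    }
  }

  # contact frames (deterministic Bernoulli draws per contact row)
  contact_on <- NULL
  oriented <- NULL
  if (!is.null(spec$contacts)) {
    contact_on <- matrix(FALSE, nf, nrow(spec$contacts))
    for (r in seq_len(nrow(spec$contacts)))
      contact_on[, r] <- stats::runif(nf) < spec$contacts$persistence[r]
    # Orient each chain component from an endpoint so that every contact
    # has a parent placed before its child.  Children are stacked along
    # +y from the parent's side-chain centroid: 2.8 A from a home
    # cluster (radius <= 1.2 A), 3.6 A from a placed one (radius
    # <= 0.3 A), so adjacent clusters realize every atom pair within
    # the 4.5 A cutoff while non-adjacent clusters stay > 4.5 A apart.
    cg <- igraph::graph_from_data_frame(
      data.frame(from = as.character(spec$contacts$i),
                 to = as.character(spec$contacts$j)), directed = FALSE)
    ckey <- paste(pmin(spec$contacts$i, spec$contacts$j),
                  pmax(spec$contacts$i, spec$contacts$j))
    comp <- igraph::components(cg)
    plist <- list()
    for (cid in seq_len(comp$no)) {
      vs <- which(comp$membership == cid)
      root <- vs[igraph::degree(cg, vs) == 1][1]
      b <- igraph::bfs(cg, root = root, father = TRUE, unreachable = FALSE)
      ord <- as.integer(b$order)
      ord <- ord[!is.na(ord)]
      for (v in ord[-1]) {
        pi <- as.integer(igraph::V(cg)$name[as.integer(b$father[v])])
        ci <- as.integer(igraph::V(cg)$name[v])
        plist[[length(plist) + 1]] <-
          c(parent = pi, child = ci,
            row = match(paste(min(pi, ci), max(pi, ci)), ckey))
      }
    }
    oriented <- do.call(rbind, plist)
  }

  sc_atoms_of <- lapply(seq_len(n_nodes), function(k) {
    a <- which(res_of_atom == k & atoms$elety != "CA")
    if (length(a)) a else which(res_of_atom == k)
  })

  xyz <- matrix(0, nf, 3 * natoms)
  node_of_atom <- res_of_atom  # node index == residue index (ligands appended)
  for (f in seq_len(nf)) {
    co <- ref + disp[f, node_of_atom, , drop = TRUE]
    if (!is.null(oriented)) {
      placed <- logical(n_nodes)
      for (r in seq_len(nrow(oriented))) {
        if (!contact_on[f, oriented[r, "row"]]) next
        p <- oriented[r, "parent"]; ch <- oriented[r, "child"]
        ai <- sc_atoms_of[[p]]; aj <- sc_atoms_of[[ch]]
        centre <- colMeans(co[ai, , drop = FALSE])
        base <- centre + c(0, if (placed[p]) 3.6 else 2.8, 0)
        for (s in seq_along(aj))
          co[aj[s], ] <- base + c(0.2 * s - 0.1 * (length(aj) + 1), 0, 0)
        placed[ch] <- TRUE
      }
    }
    xyz[f, ] <- as.numeric(t(co))
  }
  ens <- structure_ensemble(atoms, xyz)
  attr(ens, "truth") <- list(
    spec = spec,
    contact_occurrence = if (!is.null(contact_on)) colMeans(contact_on),
    modes = mode_truth)
  ens
}
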