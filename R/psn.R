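#' Residue-type normalization factors for interaction strengths
#'
#' The percentage interaction strength between two residues is
#' I_ij = 100 * n_ij / sqrt(N_i * N_j), where n_ij counts side-chain
#' atom pairs within the distance cutoff and N_i, N_j are residue-type
#' normalization factors accounting for side-chain size and contact
#' propensity.  The 20 amino-acid values are the published
#' Kannan-Vishveshwara constants; the ligand values are those used for
#' heterotrimeric G-protein systems: GTP 361.3, Mg2+ 23.8, water 27.0.
#' Synthetic residues (`SYN`) use 100 so that I_ij = n_ij in tests.
#'
#' @param extra optional named numeric vector of additional residue
#'   types (all values must be > 0).
#' @return named numeric vector, residue type -> N.
#' @export
norm_table <- function(extra = NULL) {
  tab <- c(
    ALA = 55.7551, ARG = 93.7891, ASN = 73.4097, ASP = 75.1507,
    CYS = 54.9528, GLN = 78.1301, GLU = 78.8288, GLY = 47.3129,
    HIS = 83.7357, ILE = 67.9452, LEU = 72.2517, LYS = 69.6096,
    MET = 69.2569, PHE = 93.3082, PRO = 51.3310, SER = 61.3946,
    THR = 63.7075, TRP = 106.7030, TYR = 100.7190, VAL = 62.3673,
    GTP = 361.3, MG = 23.8, HOH = 27.0, SYN = 100)
  if (!is.null(extra)) {
    if (any(extra <= 0)) stop("normalization factors must be > 0")
    tab[names(extra)] <- extra
  }
  tab
}

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
            "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
            "THR", "TRP", "TYR", "VAL", "SYN")

node_norms <- function(nodes, norm) {
  miss <- setdiff(unique(nodes$resid), names(norm))
  if (length(miss))
    stop("no normalization factor for residue type(s): ",
         paste(miss, collapse = ", "))
  norm[nodes$resid]
}

# Count side-chain atom pairs within `cutoff` for every node pair in one
# frame.  Returns a data.frame (i, j, n) over pairs with n > 0, with
# i < j as node indices.
frame_contacts <- function(co, sc_idx, node_of_sc, cutoff) {
  if (length(sc_idx) < 2) return(data.frame(i = integer(), j = integer(), n = integer()))
  d <- as.matrix(stats::dist(co[sc_idx, , drop = FALSE]))
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  if (!nrow(hit)) return(data.frame(i = integer(), j = integer(), n = integer()))
  ni <- node_of_sc[hit[, 1]]; nj <- node_of_sc[hit[, 2]]
  keep <- ni != nj
  ni <- ni[keep]; nj <- nj[keep]
  if (!length(ni)) return(data.frame(i = integer(), j = integer(), n = integer()))
  a <- pmin(ni, nj); b <- pmax(ni, nj)
  tab <- table(paste(a, b))
  key <- do.call(rbind, strsplit(names(tab), " "))
  data.frame(i = as.integer(key[, 1]), j = as.integer(key[, 2]),
             n = as.integer(tab))
}

#' Interaction strength between two nodes in one frame
#'
#' @param ens a [structure_ensemble()].
#' @param frame frame index.
#' @param i,j node labels (`"chain:resno"`) or node indices.
#' @param cutoff atom-pair distance cutoff in Angstrom (default 4.5).
#' @param norm normalization table from [norm_table()].
#' @return I_ij as a percentage (symmetric, >= 0); counts all side-chain
#'   atom pairs within the cutoff, not unique atoms.
#' @export
interaction_strength <- function(ens, frame, i, j, cutoff = 4.5,
                                 norm = norm_table()) {
  nodes <- node_table(ens)
  to_idx <- function(x) {
    if (is.character(x)) {
      k <- match(x, nodes$node)
      if (is.na(k)) stop("unknown node: ", x)
      k
    } else as.integer(x)
  }
  i <- to_idx(i); j <- to_idx(j)
  N <- node_norms(nodes, norm)
  sc <- sidechain_mask(ens)
  node_idx <- match(ens$atoms$node, nodes$node)
  co <- frame_coords(ens, frame)
  ai <- which(sc & node_idx == i)
  aj <- which(sc & node_idx == j)
  if (!length(ai) || !length(aj)) return(0)
  dmat <- sqrt(outer(rowSums(co[ai, , drop = FALSE]^2), rowSums(co[aj, , drop = FALSE]^2), "+") -
               2 * co[ai, , drop = FALSE] %*% t(co[aj, , drop = FALSE]))
  n_ij <- sum(dmat <= cutoff)
  100 * n_ij / sqrt(N[[i]] * N[[j]])
}

# Per-pair, per-frame interaction strengths for all candidate pairs
# (neighbor exclusion applied).  Returns list(nodes, pairs, I) where I is
# an n_pairs x n_frames matrix.
ensemble_strengths <- function(ens, cutoff = 4.5, neighbor_cutoff = 3,
                               norm = norm_table()) {
  nodes <- node_table(ens)
  N <- node_norms(nodes, norm)
  sc <- sidechain_mask(ens)
  node_idx <- match(ens$atoms$node, nodes$node)
  sc_idx <- which(sc)
  node_of_sc <- node_idx[sc_idx]
  nf <- n_frames(ens)
  nn <- nrow(nodes)
  amino <- nodes$resid %in% AMINO3

  pair_key <- function(i, j) (i - 1) * nn + j  # i < j
  counts <- new.env(hash = TRUE)
  for (f in seq_len(nf)) {
    fc <- frame_contacts(frame_coords(ens, f), sc_idx, node_of_sc, cutoff)
    if (!nrow(fc)) next
    for (r in seq_len(nrow(fc))) {
      k <- as.character(pair_key(fc$i[r], fc$j[r]))
      v <- counts[[k]]
      if (is.null(v)) v <- integer(nf)
      v[f] <- fc$n[r]
      counts[[k]] <- v
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    return(list(nodes = nodes,
                pairs = data.frame(i = integer(), j = integer()),
                I = matrix(0, 0, nf)))
  }
  kk <- as.numeric(keys)
  ii <- (kk - 1) %/% nn + 1
  jj <- kk - (ii - 1) * nn
  # neighbor exclusion: same chain, both amino-acid nodes, |resno| <= cutoff
  excl <- nodes$chain[ii] == nodes$chain[jj] & amino[ii] & amino[jj] &
    abs(nodes$resno[ii] - nodes$resno[jj]) <= neighbor_cutoff
  keep <- which(!excl)
  I <- matrix(0, length(keep), nf)
  for (r in seq_along(keep)) {
    k <- keys[keep[r]]
    I[r, ] <- 100 * counts[[k]] / sqrt(N[[ii[keep[r]]]] * N[[jj[keep[r]]]])
  }
  list(nodes = nodes, pairs = data.frame(i = ii[keep], j = jj[keep]), I = I)
}

#' Build a Protein Structure Graph from an ensemble
#'
#' An edge connects nodes i and j when their per-frame interaction
#' strength I_ij is at least `imin` (and at least one atom pair is in
#' contact) in at least `occurrence` of the frames; nodes within the
#' sequence neighbor cutoff never link.  The stored edge strength is the
#' mean I_ij over the frames where the edge is present.
#'
#' @param ens a [structure_ensemble()], or the result of the internal
#'   strength computation (reused by [optimal_imin()]).
#' @param imin interaction-strength cutoff (percent); `"auto"` selects
#'   it with [optimal_imin()].
#' @param occurrence minimum fraction of frames (default 0.30).
#' @param neighbor_cutoff sequence neighbor exclusion (default 3).
#' @param cutoff atom-pair distance cutoff (default 4.5 Angstrom).
#' @param norm normalization table.
#' @return an object of class `psg`: list with `nodes`, `edges`
#'   (data.frame: node_i, node_j, i, j, I_mean, occurrence), `imin`,
#'   `present` (edge x frame logical matrix, for per-frame path graphs).
#' @export
build_psg <- function(ens, imin = 0, occurrence = 0.30,
                      neighbor_cutoff = 3, cutoff = 4.5,
                      norm = norm_table()) {
  es <- if (inherits(ens, "structure_ensemble")) {
    if (n_frames(ens) < 1) stop("empty ensemble")
    ensemble_strengths(ens, cutoff, neighbor_cutoff, norm)
  } else ens
  if (identical(imin, "auto"))
    imin <- optimal_imin(es, occurrence = occurrence)
  nf <- ncol(es$I)
  present <- es$I >= imin & es$I > 0
  occ <- rowMeans(present)
  keep <- occ >= occurrence
  I_mean <- vapply(seq_len(nrow(es$I)), function(r)
    if (any(present[r, ])) mean(es$I[r, present[r, ]]) else 0, numeric(1))
  edges <- data.frame(
    node_i = es$nodes$node[es$pairs$i[keep]],
    node_j = es$nodes$node[es$pairs$j[keep]],
    i = es$pairs$i[keep], j = es$pairs$j[keep],
    I_mean = I_mean[keep], occurrence = occ[keep],
    stringsAsFactors = FALSE)
  structure(list(nodes = es$nodes, edges = edges, imin = imin,
                 occurrence_threshold = occurrence,
                 present = present[keep, , drop = FALSE], n_frames = nf),
            class = "psg")
}

#' @export
print.psg <- function(x, ...) {
  cat("Protein structure graph: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " links (Imin ", x$imin, "%, occurrence >= ",
      x$occurrence_threshold * 100, "%)\n", sep = "")
  h <- hubs(x)
  cat("  hubs (degree >= 4):", length(h), "\n")
  invisible(x)
}

psg_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("node_i", "node_j", "I_mean")], directed = FALSE,
    vertices = g$nodes$node)
  ig
}

#' Hub nodes of a structure graph
#'
#' @param g a `psg`.
#' @param min_links minimum number of links making a node a hub
#'   (default 4).
#' @return character vector of hub node labels.
#' @export
hubs <- function(g, min_links = 4) {
  deg <- table(c(g$edges$node_i, g$edges$node_j))
  names(deg)[deg >= min_links]
}

#' Connected node clusters of a structure graph
#'
#' @param g a `psg`.
#' @return list with `members` (list of character vectors of node
#'   labels, sorted by decreasing size; isolated nodes form singleton
#'   clusters) and `sizes` (matching integer vector).
#' @export
node_clusters <- function(g) {
  ig <- psg_igraph(g)
  cm <- igraph::components(ig)
  cl <- split(names(cm$membership), cm$membership)
  cl <- cl[order(-vapply(cl, length, integer(1)))]
  list(members = unname(cl),
       sizes = unname(vapply(cl, length, integer(1))))
}

# largest-component size over the node set for edges with value >= x
largest_cluster_size <- function(n_nodes, ei, ej, val, x) {
  # tolerance guards against 0.01-grid floating-point accumulation:
  # a link with strength exactly at the cut is kept
  keep <- val >= x - 1e-9 & val > 0
  if (!any(keep)) return(1L)
  ig <- igraph::graph_from_edgelist(cbind(ei[keep], ej[keep]), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, n_nodes - igraph::gorder(ig)))
  max(igraph::components(ig)$csize)
}

#' Optimal interaction-strength cutoff by largest-cluster halving
#'
#' Sweeps I_min on a 0.01% grid and returns the smallest value at which
#' the size of the largest node cluster is at most half of its size at
#' I_min = 0 (values rounded to the second decimal place).
#'
#' @param x a [structure_ensemble()], a precomputed strength set, or a
#'   data.frame of static links with columns `i`, `j` (node indices or
#'   labels) and `strength`.
#' @param occurrence edge-occurrence threshold (ensembles only).
#' @param n_nodes total node count (edge-list input only; defaults to
#'   the largest index mentioned).
#' @param ... passed to the strength computation for ensembles.
#' @return I_min in percent.  If the graph is already below half size at
#'   I_min = 0, returns 0 with a warning.
#' @export
optimal_imin <- function(x, occurrence = 0.30, n_nodes = NULL, ...) {
  if (inherits(x, "structure_ensemble")) x <- ensemble_strengths(x, ...)
  if (is.data.frame(x)) {
    ids <- unique(c(x$i, x$j))
    if (is.character(ids)) {
      ei <- match(x$i, ids); ej <- match(x$j, ids)
      if (is.null(n_nodes)) n_nodes <- length(ids)
    } else {
      ei <- x$i; ej <- x$j
      if (is.null(n_nodes)) n_nodes <- max(ei, ej)
    }
    crit <- x$strength
  } else {
    # per-pair critical I_min: largest value v such that the edge is
    # present (I >= v in >= occurrence of frames)
    nf <- ncol(x$I)
    k <- ceiling(occurrence * nf)
    crit <- apply(x$I, 1, function(v) sort(v, decreasing = TRUE)[k])
    ei <- x$pairs$i; ej <- x$pairs$j
    if (is.null(n_nodes)) n_nodes <- nrow(x$nodes)
  }
  base <- largest_cluster_size(n_nodes, ei, ej, crit, 0)
  half <- base / 2
  if (base <= 1 || largest_cluster_size(n_nodes, ei, ej, crit, 1e-9) <= half) {
    warning("graph already fragmented below half size at Imin 0")
    return(0)
  }
  grid <- seq(0.01, max(crit) + 0.01, by = 0.01)
  for (v in grid) {
    if (largest_cluster_size(n_nodes, ei, ej, crit, v) <= half)
      return(round(v, 2))
  }
  round(max(crit) + 0.01, 2)
}
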