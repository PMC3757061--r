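#' Generalized correlation of atomic motions (linear mutual information)
#'
#' Computes the pairwise linear mutual information of the 3-D node
#' displacement vectors (node representative atoms: Calpha for amino
#' acids, first atom for ligands) with the Gaussian estimator
#' I = 1/2 (ln det C_i + ln det C_j - ln det C_ij), and maps it to the
#' generalized correlation coefficient r = sqrt(1 - exp(-2 I / 3)),
#' which is 1 for identical motions and 0 for independent ones.
#'
#' @param ens a [structure_ensemble()].
#' @param fit superpose frames to the ensemble mean before computing
#'   displacements (default `FALSE`; synthetic ensembles have no global
#'   motion, MD frames should be pre-fitted or use `fit = TRUE`).
#' @param regularize ridge added to singular covariance blocks; applied
#'   automatically (and flagged via attribute `regularized`) when a
#'   block determinant underflows.
#' @return symmetric node x node matrix in \[0,1\] with unit diagonal
#'   and node labels as dimnames.
#' @export
lmi_correlation <- function(ens, fit = FALSE, regularize = 1e-10) {
  nodes <- node_table(ens)
  rep_atoms <- node_rep_atoms(ens)
  nf <- n_frames(ens)
  nn <- nrow(nodes)
  if (nf < 10 * 3)
    warning("fewer than 30 frames; LMI estimates will be noisy")
  cols <- as.numeric(t(outer(rep_atoms - 1, 1:3, function(a, k) 3 * a + k)))
  X <- ens$xyz[, cols, drop = FALSE]
  if (fit) X <- superpose_xyz(X)
  X <- scale(X, center = TRUE, scale = FALSE)
  C <- crossprod(X) / (nf - 1)
  reg_flag <- FALSE
  r <- matrix(0, nn, nn, dimnames = list(nodes$node, nodes$node))
  logdet <- function(M) {
    d <- determinant(M, logarithm = TRUE)
    as.numeric(d$modulus)
  }
  ld1 <- numeric(nn)
  for (i in seq_len(nn)) {
    bi <- (3 * i - 2):(3 * i)
    Ci <- C[bi, bi]
    if (rcond(Ci) < 1e-12) { Ci <- Ci + regularize * diag(3); reg_flag <- TRUE }
    ld1[i] <- logdet(Ci)
  }
  for (i in seq_len(nn - 1)) {
    bi <- (3 * i - 2):(3 * i)
    for (j in (i + 1):nn) {
      bj <- (3 * j - 2):(3 * j)
      Cij <- C[c(bi, bj), c(bi, bj)]
      if (rcond(Cij) < 1e-12) { Cij <- Cij + regularize * diag(6); reg_flag <- TRUE }
      I <- 0.5 * (ld1[i] + ld1[j] - logdet(Cij))
      I <- max(I, 0)
      r[i, j] <- r[j, i] <- sqrt(1 - exp(-2 * I / 3))
    }
  }
  diag(r) <- 1
  attr(r, "regularized") <- reg_flag
  r
}

# deterministic unit-weight shortest path with tie-breaking:
# shortest length first, then largest total link strength (SumWgt), then
# lexicographically smallest node-label sequence.  adj is a list of
# integer neighbor vectors (sorted by label); w is a lookup of link
# strengths.
shortest_path_det <- function(adj, wmat, labels, from, to) {
  n <- length(adj)
  INF <- .Machine$integer.max
  dist <- rep(INF, n)
  dist[from] <- 0L
  # BFS layers
  frontier <- from
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (dist[v] == INF) { dist[v] <- dist[u] + 1L; nxt <- c(nxt, v) }
      }
    }
    frontier <- unique(nxt)
  }
  if (dist[to] == INF) return(NULL)
  # backtrack from `to`, choosing at each step the predecessor giving the
  # best (max strength, lexicographic) path; dynamic programming over
  # BFS layers from `from`
  best_w <- rep(-Inf, n); best_path <- vector("list", n)
  best_w[from] <- 0; best_path[[from]] <- from
  order_nodes <- order(dist)
  for (u in order_nodes) {
    if (dist[u] == INF || u == from) next
    preds <- adj[[u]][dist[adj[[u]]] == dist[u] - 1L]
    if (!length(preds)) next
    cand_w <- best_w[preds] + wmat[cbind(preds, u)]
    top <- which(cand_w == max(cand_w))
    if (length(top) > 1) {
      seqs <- vapply(preds[top], function(p)
        paste(labels[c(best_path[[p]], u)], collapse = "\r"), character(1))
      top <- top[order(seqs)][1]
    }
    p <- preds[top[1]]
    best_w[u] <- cand_w[top[1]]
    best_path[[u]] <- c(best_path[[p]], u)
  }
  list(path = best_path[[to]], sum_w = best_w[to], length = dist[to] - 1L)
}

eligible_pairs <- function(nodes, seq_exclude = 5) {
  nn <- nrow(nodes)
  amino <- nodes$resid %in% AMINO3
  out <- which(upper.tri(matrix(TRUE, nn, nn)), arr.ind = TRUE)
  i <- out[, 1]; j <- out[, 2]
  same <- nodes$chain[i] == nodes$chain[j] & amino[i] & amino[j]
  keep <- !(same & abs(nodes$resno[i] - nodes$resno[j]) <= seq_exclude)
  cbind(i[keep], j[keep])
}

#' Shortest communication pathways over an ensemble
#'
#' For every eligible extremity pair (all node pairs except amino-acid
#' pairs at sequence distance within `seq_exclude`), the per-frame
#' shortest path is searched on that frame's graph restricted to the
#' stable PSG connectivities (edges passing the occurrence filter).
#' Paths must contain at least one internal residue whose generalized
#' correlation with either extremity is at least `corr` (direct links,
#' with no internal node, are kept and flagged).  A path's frequency is
#' the number of frames in which that identical node sequence was
#' selected divided by the total number of frames; paths below `freq`
#' are discarded.  Ties between equally short paths are broken by the
#' larger total link strength, then lexicographically, making the
#' search deterministic.
#'
#' @param g a `psg` from [build_psg()] (with its per-frame presence
#'   records).
#' @param lmi node x node generalized-correlation matrix from
#'   [lmi_correlation()] on the same ensemble.
#' @param corr correlation threshold (default 0.3).
#' @param freq path-frequency retention threshold (default 0.3).
#' @param seq_exclude sequence-distance exclusion for extremities
#'   (default 5).
#' @param pairs optional 2-column matrix of node indices restricting
#'   the extremity pairs searched.
#' @return an object of class `path_set`: data.frame with columns
#'   `ext_i`, `ext_j`, `path` (node labels joined by "->"), `length`
#'   (internal node count), `frequency`, `corr_score`, `sum_wgt`,
#'   `avg_wgt`, `direct`; attribute `diagnostics` counts skipped pairs.
#' @export
shortest_paths_psn <- function(g, lmi, corr = 0.3, freq = 0.3,
                               seq_exclude = 5, pairs = NULL) {
  nodes <- g$nodes
  nn <- nrow(nodes)
  labels <- nodes$node
  if (is.null(pairs)) pairs <- eligible_pairs(nodes, seq_exclude)
  if (!nrow(g$edges))
    return(empty_path_set())
  wmat <- matrix(0, nn, nn)
  wmat[cbind(g$edges$i, g$edges$j)] <- g$edges$I_mean
  wmat[cbind(g$edges$j, g$edges$i)] <- g$edges$I_mean
  nf <- g$n_frames
  tallies <- new.env(hash = TRUE)
  skipped <- 0L
  for (f in seq_len(nf)) {
    on <- g$present[, f]
    if (!any(on)) { skipped <- skipped + nrow(pairs); next }
    ei <- g$edges$i[on]; ej <- g$edges$j[on]
    adj <- vector("list", nn)
    for (k in seq_along(ei)) {
      adj[[ei[k]]] <- c(adj[[ei[k]]], ej[k])
      adj[[ej[k]]] <- c(adj[[ej[k]]], ei[k])
    }
    adj <- lapply(adj, function(v) if (is.null(v)) integer() else sort(v))
    for (p in seq_len(nrow(pairs))) {
      sp <- shortest_path_det(adj, wmat, labels, pairs[p, 1], pairs[p, 2])
      if (is.null(sp)) { skipped <- skipped + 1L; next }
      key <- paste(sp$path, collapse = ",")
      cur <- tallies[[key]]
      if (is.null(cur)) cur <- list(count = 0L, sum_w = sp$sum_w,
                                    length = sp$length, pair = pairs[p, ])
      cur$count <- cur$count + 1L
      tallies[[key]] <- cur
    }
  }
  keys <- ls(tallies)
  if (!length(keys)) return(empty_path_set(skipped))
  rows <- lapply(keys, function(k) {
    tl <- tallies[[k]]
    idx <- as.integer(strsplit(k, ",")[[1]])
    internal <- idx[-c(1, length(idx))]
    direct <- length(internal) == 0
    if (direct) {
      cs <- 1.0
    } else {
      corr_ok <- lmi[idx[1], internal] >= corr | lmi[idx[length(idx)], internal] >= corr
      if (!any(corr_ok)) return(NULL)  # lacks a correlated internal residue
      cs <- sum(corr_ok) / length(internal)
    }
    data.frame(ext_i = labels[idx[1]], ext_j = labels[idx[length(idx)]],
               path = paste(labels[idx], collapse = "->"),
               length = length(internal),
               frequency = tl$count / nf,
               corr_score = cs,
               sum_wgt = tl$sum_w,
               avg_wgt = tl$sum_w / (length(idx) - 1),
               direct = direct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty_path_set(skipped))
  out <- out[out$frequency >= freq, , drop = FALSE]
  out <- out[order(-out$frequency, out$path), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("path_set", "data.frame")
  attr(out, "diagnostics") <- list(skipped = skipped, n_frames = nf)
  out
}

empty_path_set <- function(skipped = 0L) {
  out <- data.frame(ext_i = character(), ext_j = character(),
                    path = character(), length = integer(),
                    frequency = numeric(), corr_score = numeric(),
                    sum_wgt = numeric(), avg_wgt = numeric(),
                    direct = logical(), stringsAsFactors = FALSE)
  class(out) <- c("path_set", "data.frame")
  attr(out, "diagnostics") <- list(skipped = skipped)
  out
}

#' Correlation score of a path
#'
#' Ratio between the number of internal residues correlated with either
#' extremity and the path length (which excludes the two extremities).
#' Direct links (no internal nodes) are reported as 1.0 with attribute
#' `direct = TRUE`.
#'
#' @param path character vector of node labels (extremities included).
#' @param lmi generalized-correlation matrix with node dimnames.
#' @param corr correlation threshold (default 0.3).
#' @return score in \[0,1\].
#' @export
correlation_score <- function(path, lmi, corr = 0.3) {
  if (length(path) < 2) stop("a path needs at least two nodes")
  internal <- path[-c(1, length(path))]
  if (!length(internal)) {
    out <- 1.0
    attr(out, "direct") <- TRUE
    return(out)
  }
  ok <- lmi[path[1], internal] >= corr | lmi[path[length(path)], internal] >= corr
  sum(ok) / length(internal)
}

path_nodes <- function(p) strsplit(p, "->", fixed = TRUE)

path_links <- function(nodes_vec) {
  if (length(nodes_vec) < 2) return(character())
  a <- nodes_vec[-length(nodes_vec)]; b <- nodes_vec[-1]
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Meta-path: most recurrent links across a path pool
#'
#' For each link l, the recurrence score is
#' r(l) = 100 * sum_ij p_ij(l) / sum_ij p_ij, where p_ij is the number
#' of pool paths between extremity pair (i,j) and p_ij(l) those that
#' traverse l.  Only links with r at least `retain` x the highest score
#' are kept in the meta-path.
#'
#' @param pathset a `path_set` (already frequency-filtered: the pool of
#'   paths with frequency >= 30%).
#' @param retain retained-link fraction of the maximum score
#'   (default 0.3).
#' @return an object of class `meta_path`: data.frame with `node_i`,
#'   `node_j`, `r` (percent) and `retained`.
#' @export
metapath <- function(pathset, retain = 0.3) {
  if (!nrow(pathset)) stop("empty path pool")
  total <- nrow(pathset)
  links <- lapply(path_nodes(pathset$path), path_links)
  tab <- table(unlist(links))
  r <- 100 * as.numeric(tab) / total
  key <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
  out <- data.frame(node_i = key[, 1], node_j = key[, 2], r = r,
                    stringsAsFactors = FALSE)
  out$retained <- out$r >= retain * max(out$r)
  out <- out[order(-out$r), ]
  rownames(out) <- NULL
  class(out) <- c("meta_path", "data.frame")
  out
}

#' Recurrent linked-node fragments in a path pool
#'
#' Fragment recurrence is the number of paths containing the fragment
#' divided by the total number of paths; fragments are read
#' direction-agnostically (A-B-C and C-B-A are the same fragment).
#'
#' @param pathset a `path_set`.
#' @param length fragment length in nodes (default 3).
#' @return data.frame with `fragment` and `recurrence`, sorted by
#'   decreasing recurrence.
#' @export
fragments <- function(pathset, length = 3) {
  if (!nrow(pathset)) stop("empty path pool")
  total <- nrow(pathset)
  frag_of <- function(nodes_vec) {
    n <- base::length(nodes_vec)
    if (n < length) return(character())
    unique(vapply(seq_len(n - length + 1), function(s) {
      f <- nodes_vec[s:(s + length - 1)]
      rf <- rev(f)
      if (paste(rf, collapse = "-") < paste(f, collapse = "-")) f <- rf
      paste(f, collapse = "-")
    }, character(1)))
  }
  tab <- table(unlist(lapply(path_nodes(pathset$path), frag_of)))
  if (!base::length(tab))
    return(data.frame(fragment = character(), recurrence = numeric()))
  out <- data.frame(fragment = names(tab),
                    recurrence = as.numeric(tab) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$recurrence, out$fragment), ]
  rownames(out) <- NULL
  out
}

#' @export
summary.path_set <- function(object, ...) {
  if (!nrow(object)) return(list(n_paths = 0L))
  list(n_paths = nrow(object),
       max_length = max(object$length),
       avg_length = mean(object$length),
       max_freq = max(object$frequency) * 100,
       length_max_freq = object$length[which.max(object$frequency)],
       max_score = max(object$corr_score),
       min_score = min(object$corr_score),
       avg_score = mean(object$corr_score),
       max_sumwgt = max(object$sum_wgt),
       min_sumwgt = min(object$sum_wgt),
       avg_sumwgt = mean(object$sum_wgt),
       max_avgwgt = max(object$avg_wgt),
       min_avgwgt = min(object$avg_wgt),
       avg_avgwgt = mean(object$avg_wgt))
}

#' Network-parameter summary of a structure graph and its path pool
#'
#' Gathers the headline network descriptors: I_min, total hubs, size of
#' the most populated node cluster (with its hub and link counts), and
#' the path-pool statistics (counts, lengths, frequencies, correlation
#' scores, SumWgt/AvgWgt strengths).
#'
#' @param g a `psg`.
#' @param pathset a `path_set` from [shortest_paths_psn()].
#' @return named list of scalars.
#' @export
network_parameters <- function(g, pathset) {
  cl <- node_clusters(g)
  first <- if (length(cl$members)) cl$members[[1]] else character()
  in_first <- g$edges$node_i %in% first & g$edges$node_j %in% first
  c(list(imin = g$imin,
         hubs_total = length(hubs(g)),
         nodes_first_cluster = length(first),
         hubs_first_cluster = sum(hubs(g) %in% first),
         links_first_cluster = sum(in_first)),
    summary(pathset))
}
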