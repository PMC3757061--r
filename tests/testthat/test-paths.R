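make_adj <- function(n, edges) {
  adj <- lapply(seq_len(n), function(i) integer())
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

test_that("deterministic shortest paths match exhaustive enumeration", {
  set.seed(7)
  for (inst in 1:100) {
    n <- sample(4:12, 1)
    all_pairs <- t(combn(n, 2))
    m <- sample(seq(n - 1, min(2 * n, nrow(all_pairs))), 1)
    edges <- all_pairs[sample(nrow(all_pairs), m), , drop = FALSE]
    w <- matrix(0, n, n)
    wts <- round(runif(m, 0.1, 9), 2)
    w[edges] <- wts
    w[edges[, 2:1, drop = FALSE]] <- wts
    labels <- sprintf("N%02d", seq_len(n))
    adj <- make_adj(n, edges)
    ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, n - igraph::gorder(ig))
    for (q in 1:3) {
      ft <- sample(n, 2)
      got <- rodnet:::shortest_path_det(adj, w, labels, ft[1], ft[2])
      d <- igraph::distances(ig, ft[1], ft[2])[1, 1]
      if (is.infinite(d)) {
        expect_null(got)
        next
      }
      expect_equal(got$length, as.integer(d) - 1L)  # internal node count
      asp <- igraph::all_shortest_paths(ig, ft[1], ft[2])$vpaths
      cand_w <- vapply(asp, function(p) {
        p <- as.integer(p)
        sum(w[cbind(p[-length(p)], p[-1])])
      }, numeric(1))
      expect_equal(got$sum_w, max(cand_w), tolerance = 1e-9)
      best <- asp[abs(cand_w - max(cand_w)) < 1e-9]
      seqs <- vapply(best, function(p)
        paste(labels[as.integer(p)], collapse = "\r"), character(1))
      expect_equal(paste(labels[got$path], collapse = "\r"), sort(seqs)[1])
    }
  }
})

test_that("extremity pairs exclude close sequence neighbours", {
  nodes <- data.frame(
    node = c("A:1", "A:5", "A:7", "L:2"),
    chain = c("A", "A", "A", "L"),
    resno = c(1, 5, 7, 2),
    resid = c("SYN", "SYN", "SYN", "GTP"),
    stringsAsFactors = FALSE)
  ep <- rodnet:::eligible_pairs(nodes, seq_exclude = 5)
  got <- paste(ep[, 1], ep[, 2])
  # excluded: 1-5 (d=4), 5-7 (d=2); kept: 1-7 (d=6) and all ligand pairs
  expect_setequal(got, c("1 3", "1 4", "2 4", "3 4"))
})

test_that("correlation scores count correlated internal residues", {
  lmi <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  lmi["a", "b"] <- lmi["b", "a"] <- 0.8
  expect_equal(correlation_score(c("a", "b", "c", "d"), lmi), 0.5)
  lmi["d", "c"] <- lmi["c", "d"] <- 0.5
  expect_equal(correlation_score(c("a", "b", "c", "d"), lmi), 1)
  direct <- correlation_score(c("a", "d"), lmi)
  expect_equal(as.numeric(direct), 1)
  expect_true(attr(direct, "direct"))
  expect_error(correlation_score("a", lmi), "two nodes")
})

test_that("paths through a persistent chain are found at full frequency", {
  spec <- ensemble_spec(20, 60, sigma = 0.15, sidechain_atoms = 2,
                        contacts = data.frame(i = c(1, 5, 9),
                                              j = c(5, 9, 13),
                                              persistence = 1),
                        correlations = data.frame(i = 5, j = 13, rho = 0.7),
                        seed = 3)
  ens <- gen_ensemble(spec)
  g <- build_psg(ens)
  ps <- shortest_paths_psn(g, lmi_correlation(ens))
  chain_path <- ps[ps$ext_i == "A:1" & ps$ext_j == "A:13", ]
  expect_equal(nrow(chain_path), 1)
  expect_equal(chain_path$path, "A:1->A:5->A:9->A:13")
  expect_equal(chain_path$frequency, 1)
  expect_equal(chain_path$length, 2)
  # the A:5 -> A:13 direct-extremity path has correlated internals too
  expect_true(all(ps$frequency >= 0.3))
  expect_true(all(ps$corr_score >= 0 & ps$corr_score <= 1))
})

test_that("paths lacking a correlated internal residue are dropped", {
  # enough frames that background correlations stay well below 0.3
  spec <- ensemble_spec(20, 500, sigma = 0.15, sidechain_atoms = 2,
                        contacts = data.frame(i = c(1, 5),
                                              j = c(5, 9),
                                              persistence = 1),
                        seed = 4)
  ens <- gen_ensemble(spec)
  g <- build_psg(ens)
  ps <- shortest_paths_psn(g, lmi_correlation(ens))
  # no planted correlations: the only survivors are direct links
  expect_true(all(ps$direct))
})

test_that("meta-path recurrence scores are exact on a hand pool", {
  ps <- data.frame(
    ext_i = c("a", "a", "e"), ext_j = c("c", "d", "b"),
    path = c("a->b->c", "a->b->d", "e->b"),
    length = c(1L, 1L, 0L), frequency = 1, corr_score = 1,
    sum_wgt = 1, avg_wgt = 1, direct = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  class(ps) <- c("path_set", "data.frame")
  mp <- metapath(ps)
  expect_equal(mp$r[mp$node_i == "a" & mp$node_j == "b"], 100 * 2 / 3)
  expect_equal(mp$r[mp$node_i == "b" & mp$node_j == "c"], 100 * 1 / 3)
  expect_true(all(mp$retained))
  mp2 <- metapath(ps, retain = 0.6)
  expect_equal(sum(mp2$retained), 1)
  expect_error(metapath(ps[0, ]), "empty")
})

test_that("fragments are read direction-agnostically", {
  ps <- data.frame(
    ext_i = c("a", "d"), ext_j = c("d", "a"),
    path = c("a->b->c->d", "d->c->b->a"),
    length = 2L, frequency = 1, corr_score = 1, sum_wgt = 1,
    avg_wgt = 1, direct = FALSE, stringsAsFactors = FALSE)
  class(ps) <- c("path_set", "data.frame")
  fr <- fragments(ps)
  expect_setequal(fr$fragment, c("a-b-c", "b-c-d"))
  expect_equal(fr$recurrence, c(1, 1))
})

test_that("network parameters summarize graph and path pool", {
  ens <- gen_ensemble(ensemble_spec(
    20, 30, sigma = 0.15, sidechain_atoms = 2,
    contacts = data.frame(i = c(1, 5, 9), j = c(5, 9, 13), persistence = 1),
    correlations = data.frame(i = 5, j = 13, rho = 0.7), seed = 3))
  g <- build_psg(ens)
  ps <- shortest_paths_psn(g, lmi_correlation(ens))
  np <- network_parameters(g, ps)
  expect_equal(np$imin, 0)
  expect_equal(np$nodes_first_cluster, 4)
  expect_equal(np$links_first_cluster, 3)
  expect_equal(np$n_paths, nrow(ps))
  expect_true(np$max_freq <= 100)
})
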