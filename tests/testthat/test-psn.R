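# two-node ensemble with per-frame control of the second node's side
# chain: node B sits at x = xb[f] in frame f (contact iff |xb| <= 4.5)
two_node_frames <- function(xb, resno_b = 10) {
  atoms <- data.frame(
    chain = "A", resno = c(1, 1, resno_b, resno_b), resid = "SYN",
    elety = c("CA", "S1", "CA", "S1"), element = "C")
  xyz <- t(vapply(xb, function(x)
    c(0, 0, 100, 0, 0, 0, x, 0, 100, x, 0, 0), numeric(12)))
  structure_ensemble(atoms, xyz)
}

test_that("normalization table carries the published ligand factors", {
  nt <- norm_table()
  expect_equal(nt[["GTP"]], 361.3)
  expect_equal(nt[["MG"]], 23.8)
  expect_equal(nt[["HOH"]], 27.0)
  expect_equal(nt[["SYN"]], 100)
  over <- norm_table(extra = c(XYZ = 50))
  expect_equal(over[["XYZ"]], 50)
})

test_that("interaction strength matches hand arithmetic", {
  # residue A:1, two side-chain atoms; residue A:10, one side-chain atom
  # 3 A away from both -> n = 2 pairs, I = 100 * 2 / sqrt(100 * 100)
  atoms <- data.frame(
    chain = "A", resno = c(1, 1, 1, 10, 10), resid = "SYN",
    elety = c("CA", "S1", "S2", "CA", "S1"), element = "C")
  xyz <- matrix(c(0, 0, 100,  0, 0, 0,  1, 0, 0,
                  0, 3, 100,  0, 3, 0), nrow = 1)
  ens <- structure_ensemble(atoms, xyz)
  expect_equal(interaction_strength(ens, 1, "A:1", "A:10"), 2)
})

test_that("ligand nodes use their own normalization factors", {
  atoms <- data.frame(
    chain = c("A", "A", "L", "L", "L", "L", "L"),
    resno = c(1, 1, 2, 2, 2, 3, 4),
    resid = c("SYN", "SYN", "GTP", "GTP", "GTP", "MG", "HOH"),
    elety = c("CA", "S1", "PG", "O1", "C5", "MG", "O"),
    element = c("C", "C", "P", "O", "C", "MG", "O"))
  xyz <- matrix(c(0, 0, 100,  0, 0, 0,
                  0, 3, 0,  1, 3, 0,  0.5, 3.5, 0,
                  3, 0, 0,
                  0, -3, 0), nrow = 1)
  ens <- structure_ensemble(atoms, xyz)
  # SYN side chain (1 atom) vs all 3 GTP atoms within 4.5 A
  expect_equal(interaction_strength(ens, 1, "A:1", "L:2"),
               100 * 3 / sqrt(100 * 361.3), tolerance = 1e-12)
  expect_equal(interaction_strength(ens, 1, "A:1", "L:3"),
               100 * 1 / sqrt(100 * 23.8), tolerance = 1e-12)
  expect_equal(interaction_strength(ens, 1, "A:1", "L:4"),
               100 * 1 / sqrt(100 * 27.0), tolerance = 1e-12)
})

test_that("sequence neighbors within three positions are excluded", {
  close_pair <- two_node_frames(rep(3, 4), resno_b = 4)   # |dresno| = 3
  st <- rodnet:::ensemble_strengths(close_pair)
  expect_equal(nrow(st$pairs), 0)
  far_pair <- two_node_frames(rep(3, 4), resno_b = 5)     # |dresno| = 4
  st2 <- rodnet:::ensemble_strengths(far_pair)
  expect_equal(nrow(st2$pairs), 1)
})

test_that("links require presence in at least 30% of frames", {
  on3 <- two_node_frames(c(3, 3, 3, 50, 50, 50, 50, 50, 50, 50))
  expect_equal(nrow(build_psg(on3)$edges), 1)  # exactly 30%: retained
  on2 <- two_node_frames(c(3, 3, 50, 50, 50, 50, 50, 50, 50, 50))
  expect_equal(nrow(build_psg(on2)$edges), 0)
})

test_that("the Imin cut drops weak links monotonically", {
  # contacts with different atom-pair counts give different strengths
  spec <- ensemble_spec(12, 30, sidechain_atoms = c(1, 2, 3, 1, 2, 3),
                        contacts = data.frame(i = c(1, 2, 3),
                                              j = c(7, 8, 9),
                                              persistence = 1),
                        seed = 8)
  ens <- gen_ensemble(spec)
  g0 <- build_psg(ens, imin = 0)
  expect_equal(nrow(g0$edges), 3)
  strengths <- sort(g0$edges$I_mean)
  g_mid <- build_psg(ens, imin = strengths[2])
  g_hi <- build_psg(ens, imin = strengths[3] + 0.01)
  key <- function(g) paste(g$edges$node_i, g$edges$node_j)
  expect_true(all(key(g_mid) %in% key(g0)))
  expect_true(all(key(g_hi) %in% key(g_mid)))
  expect_equal(nrow(g_mid$edges), 2)
  expect_equal(nrow(g_hi$edges), 0)
})

test_that("hubs are nodes with at least four links", {
  g4 <- build_psg(star_ensemble(4))
  expect_equal(hubs(g4), "A:1")
  deg <- table(c(g4$edges$node_i, g4$edges$node_j))
  expect_equal(unname(deg[["A:1"]]), 4)
  g3 <- build_psg(star_ensemble(3))
  expect_length(hubs(g3), 0)
  # a stricter cutoff is honoured
  expect_length(hubs(g4, min_links = 5), 0)
})

test_that("clusters are reported in decreasing size order", {
  g <- build_psg(star_ensemble(4))
  cl <- node_clusters(g)
  expect_equal(cl$sizes[1], 5)
  expect_true(all(diff(cl$sizes) <= 0))
  expect_equal(sum(cl$sizes), nrow(g$nodes))
})

test_that("optimal Imin finds the halving cut on a designed chain", {
  # chain 1-2-3-4-5-6 with the critical link in the middle
  df <- data.frame(i = 1:5, j = 2:6, strength = c(10, 8, 4, 6, 2))
  expect_equal(optimal_imin(df, n_nodes = 6), 4.01)
  # permutation invariance
  perm <- df[sample(nrow(df)), ]
  expect_equal(optimal_imin(perm, n_nodes = 6), 4.01)
})

test_that("optimal Imin equals a brute-force sweep on random graphs", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(6:14, 1)
    npairs <- sample(n:(2 * n), 1)
    pairs <- t(combn(n, 2))
    pick <- pairs[sample(nrow(pairs), min(npairs, nrow(pairs))), ,
                  drop = FALSE]
    df <- data.frame(i = pick[, 1], j = pick[, 2],
                     strength = round(runif(nrow(pick), 0, 12), 2))
    expect_equal(optimal_imin(df, n_nodes = n),
                 brute_force_imin(df, n), info = paste("instance", rep))
  }
})

test_that("an edgeless graph yields Imin 0 with a warning", {
  df <- data.frame(i = 1, j = 2, strength = 0)
  expect_warning(out <- optimal_imin(df, n_nodes = 10), "fragment")
  expect_equal(out, 0)
})

test_that("halving tracks the global largest-cluster size", {
  # two disjoint pairs: the largest cluster size stays 2 until both
  # links are gone (the second pair takes over when the first breaks)
  df <- data.frame(i = c(1, 3), j = c(2, 4), strength = c(5, 7))
  expect_equal(optimal_imin(df, n_nodes = 10), 7.01)
})
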