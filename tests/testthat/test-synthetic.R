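test_that("generation is deterministic under a fixed seed", {
  spec <- ensemble_spec(8, 20, contacts = data.frame(i = 1, j = 5,
                                                     persistence = 0.5),
                        ligands = "GTP", seed = 33)
  a <- gen_ensemble(spec)
  b <- gen_ensemble(spec)
  expect_identical(a$xyz, b$xyz)
  expect_identical(a$atoms, b$atoms)
})

test_that("infeasible specs are rejected", {
  expect_error(ensemble_spec(10, 5, contacts = data.frame(
    i = c(1, 5), j = c(5, 1), persistence = c(0.5, 0.5))), "overlap")
  expect_error(ensemble_spec(10, 5, contacts = data.frame(
    i = c(1, 5, 9), j = c(5, 9, 1), persistence = 0.5)), "chain")
  expect_error(ensemble_spec(12, 5, contacts = data.frame(
    i = c(1, 1, 1), j = c(5, 9, 12), persistence = 0.5)), "chain")
  expect_error(ensemble_spec(10, 5, contacts = data.frame(
    i = 1, j = 5, persistence = 1.2)), "persistence")
  expect_error(ensemble_spec(10, 5, correlations = data.frame(
    i = 1, j = 5, rho = 1.5)), "rho")
})

test_that("planted contact persistence is realized within tolerance", {
  spec <- ensemble_spec(10, 2000, sidechain_atoms = 2,
                        contacts = data.frame(i = 2, j = 8,
                                              persistence = 0.40),
                        seed = 5)
  ens <- gen_ensemble(spec)
  # measure directly: frames with any side-chain atom pair < 4.5 A
  sc2 <- which(ens$atoms$resno == 2 & ens$atoms$elety != "CA")
  sc8 <- which(ens$atoms$resno == 8 & ens$atoms$elety != "CA")
  hit <- vapply(seq_len(nrow(ens$xyz)), function(f) {
    co <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
    d <- as.matrix(stats::dist(co[c(sc2, sc8), ]))
    any(d[seq_along(sc2), -seq_along(sc2)] < 4.5)
  }, logical(1))
  expect_equal(mean(hit), 0.40, tolerance = 0.05)
  expect_equal(mean(hit), attr(ens, "truth")$contact_occurrence[1])
})

test_that("contact frames realize exactly nsc_i x nsc_j atom pairs", {
  spec <- ensemble_spec(10, 50, sidechain_atoms = c(3, 2),
                        contacts = data.frame(i = 1, j = 6,
                                              persistence = 0.5),
                        seed = 9)
  ens <- gen_ensemble(spec)
  st <- rodnet:::ensemble_strengths(ens)
  row <- which(st$pairs$i == 1 & st$pairs$j == 6)
  I <- st$I[row, ]
  # nsc(1) = 3, nsc(6) = 2 under the recycled pattern c(3, 2)
  expect_true(all(I %in% c(0, 100 * 6 / sqrt(100 * 100))))
  on <- I > 0
  expect_equal(mean(on), attr(ens, "truth")$contact_occurrence[1])
  # no other residue pair ever touches
  expect_true(all(st$I[-row, ] == 0))
})

test_that("chained contacts realize only the planted links", {
  spec <- ensemble_spec(20, 60, sidechain_atoms = 2,
                        contacts = data.frame(i = c(1, 5, 9),
                                              j = c(5, 9, 13),
                                              persistence = 1),
                        seed = 2)
  ens <- gen_ensemble(spec)
  st <- rodnet:::ensemble_strengths(ens)
  touched <- st$pairs[rowSums(st$I > 0) > 0, c("i", "j")]
  got <- sort(paste(pmin(touched$i, touched$j),
                    pmax(touched$i, touched$j)))
  expect_equal(got, sort(c("1 5", "5 9", "9 13")))
  expect_true(all(st$I[rowSums(st$I > 0) > 0, ] == 4))
})

test_that("planted correlations are recovered by linear mutual information", {
  spec <- ensemble_spec(20, 10000, sigma = 0.3,
                        correlations = data.frame(i = 3, j = 17, rho = 0.8),
                        seed = 21)
  ens <- gen_ensemble(spec)
  L <- lmi_correlation(ens)
  expect_equal(L[3, 17], 0.8, tolerance = 0.05)
  off <- L[upper.tri(L)]
  off <- off[off < 0.5]
  expect_lt(max(off), 0.15)
})

test_that("multi-model PDB round trip preserves the ensemble", {
  spec <- ensemble_spec(6, 4, sidechain_atoms = 2, ligands = c("GTP", "MG"),
                        seed = 13)
  ens <- gen_ensemble(spec)
  path <- tempfile(fileext = ".pdb")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(dim(back), dim(ens))
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3)  # PDB has 3 decimals
  expect_identical(back$atoms$resid, ens$atoms$resid)
  expect_identical(back$atoms$elety, ens$atoms$elety)
  expect_identical(back$atoms$chain, ens$atoms$chain)
})

test_that("ligand nodes appear on their own chain with printed norms", {
  spec <- ensemble_spec(4, 2, ligands = c("GTP", "MG", "HOH"), seed = 1)
  ens <- gen_ensemble(spec)
  nt <- rodnet:::node_table(ens)
  expect_equal(sum(nt$chain == "L"), 3)
  expect_setequal(nt$resid[nt$chain == "L"], c("GTP", "MG", "HOH"))
})
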