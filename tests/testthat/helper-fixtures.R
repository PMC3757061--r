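# Shared fixtures and a lazy cache for expensive simulations, built at
# most once per suite run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

toy_cascade <- function() cached("toy_cascade", gen_toy_cascade("cascade"))

toy_precoupled <- function()
  cached("toy_precoupled", add_precoupling(gen_toy_cascade("cascade")))

# dim/bright single-flash responses of the wild-type toy cascade
wt_dim_response <- function()
  cached("wt_dim", simulate_flash(toy_precoupled(), flash_stimulus(5),
                                  t_end = 40))

wt_bright_response <- function()
  cached("wt_bright", simulate_flash(toy_precoupled(), flash_stimulus(5000),
                                     t_end = 40))

# flash family bracketing the toy model's half-maximal amplitude
wt_family <- function() cached("wt_family", {
  stims <- gen_flash_family(2, 5000, 7)
  lapply(stims, function(s) simulate_flash(toy_precoupled(), s, t_end = 40))
})

# hand-built one-frame ensemble: atoms at given coordinates, one row per
# atom: chain, resno, resid, elety, element, x, y, z (repeated frames
# allowed via `frames`)
make_ensemble <- function(df, frames = 1) {
  atoms <- df[c("chain", "resno", "resid", "elety", "element")]
  xyz1 <- as.numeric(t(as.matrix(df[c("x", "y", "z")])))
  xyz <- matrix(rep(xyz1, each = frames), nrow = frames)
  structure_ensemble(atoms, xyz)
}

# star ensemble: one central residue side chain at the origin and `k`
# satellite side chains 4 A away along distinct axes (mutually > 4.5 A
# apart); residue numbers spaced by 10 so no pair is sequence-excluded
star_ensemble <- function(k = 4) {
  dirs <- rbind(c(4, 0, 0), c(-4, 0, 0), c(0, 4, 0), c(0, -4, 0),
                c(0, 0, 4), c(0, 0, -4))
  stopifnot(k <= nrow(dirs))
  rows <- list()
  add_res <- function(resno, sc_pos) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = "A", resno = resno, resid = "SYN", elety = "CA",
      element = "C", x = sc_pos[1], y = sc_pos[2], z = sc_pos[3] + 100)
    rows[[length(rows) + 1]] <<- data.frame(
      chain = "A", resno = resno, resid = "SYN", elety = "S1",
      element = "C", x = sc_pos[1], y = sc_pos[2], z = sc_pos[3])
  }
  add_res(1, c(0, 0, 0))
  for (s in seq_len(k)) add_res(1 + 10 * s, dirs[s, ])
  make_ensemble(do.call(rbind, rows))
}

# synthetic photoresponse object for feature-extraction unit tests
fake_response <- function(time, dJ, intensity = 1) {
  structure(list(time = time, dJ = dJ, J_dark = 14,
                 stimulus = flash_stimulus(intensity), normalized = FALSE),
            class = "photoresponse")
}

# brute-force reference for optimal_imin: scan the 0.01 grid directly
# on a pair-strength table, recomputing clusters per cut
brute_force_imin <- function(df, n_nodes) {
  full <- largest_cluster_ref(df, n_nodes, 0)
  grid <- seq(0, max(df$strength) + 0.01, by = 0.01)
  for (x in grid) {
    if (largest_cluster_ref(df, n_nodes, x) <= full / 2) return(x)
  }
  Inf
}

largest_cluster_ref <- function(df, n_nodes, cut) {
  keep <- df$strength >= cut - 1e-9
  g <- igraph::graph_from_data_frame(
    data.frame(from = df$i[keep], to = df$j[keep]), directed = FALSE,
    vertices = data.frame(name = seq_len(n_nodes)))
  max(igraph::components(g)$csize)
}
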