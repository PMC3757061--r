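#' Miniature phototransduction cascades
#'
#' Generates small reaction networks that mimic the activation /
#' deactivation motif of the rod cascade: photoisomerized receptor
#' catalytically activates the G protein, active G-alpha binds and
#' activates the effector (PDE), shutoff proceeds through intrinsic
#' GTPase activity and GAP-accelerated hydrolysis after RGS binding, and
#' the effector hydrolyses a cyclic-nucleotide pool that gates the
#' circulating current (Hill coefficient 3).
#'
#' Two variants are provided:
#' \describe{
#'   \item{`linear`}{a 3-reaction activation/decay chain whose Delta J
#'     has a closed-form double-exponential solution, for solver
#'     verification.}
#'   \item{`cascade`}{a 14-reaction motif with named parameters
#'     (`kP1`, `kP2`, `kP3`, `kP4`, `kRGS1`, `kRGS2`, `kGt1`, `kGt2`)
#'     matching the wild-type kinetic constants of the full rod model
#'     (0.05, 0.033, 5.5e-2, 940.7, 1.498e-9, 21.09, 1.57e-7, 256.07),
#'     for scaling and mutant-building experiments.  `ga_species` is
#'     declared so [build_mutant()] works out of the box.}
#' }
#'
#' In the `cascade` variant the 2:1 G-alpha:PDE branch (`kP3`, `kP4`) is
#' present but dynamically negligible (kP3 ~ 1.5e-9), and the
#' RGS-bound complex remains hydrolytically active until the GAP step
#' (`kRGS2`) disrupts it, so deep `kRGS2` reductions prolong the
#' saturating phase of bright-flash responses.
#'
#' @param variant "cascade" (default) or "linear".
#' @return a [reaction_network()] with an output current observable.
#' @export
gen_toy_cascade <- function(variant = c("cascade", "linear")) {
  variant <- match.arg(variant)
  if (variant == "linear") {
    # R* -> A -> (degraded); J = -A.  With a delta-like flash making A0
    # activated receptors, A(t) is a double exponential.
    species <- c(R = 1e4, Rst = 0, A = 0)
    pars <- c(k1 = 2, k2 = 0.5, c_area = 0.5, R_dark0 = 1e4)
    reactions <- list(
      reaction("stim", c(R = 1), c(Rst = 1),
               rate_expr = quote(light * c_area * R / R_dark0)),
      reaction("act", c(Rst = 1), c(A = 1), rate_param = "k1"),
      reaction("decay", c(A = 1), numeric(), rate_param = "k2"))
    return(reaction_network(species, reactions, pars,
                            output = quote(-A), id = "toy_linear"))
  }
  species <- c(
    R = 1e4, Rst = 0,
    Gt = 8000, Ga = 0, GaGDP = 0,
    PDE = 2000, GaPDE = 0, GaPDEa = 0, GaPDEaGa = 0, GaPDEa2 = 0,
    RGS = 4e6, RGSGaPDEa = 0,
    cG = 1000)
  pars <- c(
    c_area = 0.5, R_dark0 = 1e4,
    kRrec = 2,              # R* shutoff
    kG = 2.5e-3,            # catalytic Gt activation per R*
    kGt1 = 0.05,            # intrinsic GTPase, free G-alpha-GTP
    kGt2 = 0.033,           # intrinsic GTPase in PDE complexes
    kP1 = 5.5e-2,           # G-alpha-GTP binding to inactive PDE
    kP2 = 940.7,            # activation of one PDE catalytic subunit
    kP3 = 1.498e-9,         # binding of a second G-alpha-GTP
    kP4 = 21.09,            # activation of the second subunit
    kRGS1 = 1.57e-7,        # RGS binding to the active complex
    kRGS2 = 256.07,         # GAP action and complex disruption
    kre = 2,                # heterotrimer re-association
    bdark = 1,              # dark cGMP turnover rate
    bsub = 2e-3,            # hydrolysis per active PDE subunit
    alpha = 1000,           # cGMP synthesis (balances dark turnover)
    J_dark = 14, cG_dark = 1000)
  reactions <- list(
    reaction("stim", c(R = 1), c(Rst = 1),
             rate_expr = quote(light * c_area * R / R_dark0)),
    reaction("r_shutoff", c(Rst = 1), c(R = 1), rate_param = "kRrec"),
    reaction("g_act", c(Rst = 1, Gt = 1), c(Rst = 1, Ga = 1),
             rate_param = "kG"),
    reaction("gtpase_free", c(Ga = 1), c(GaGDP = 1), rate_param = "kGt1"),
    reaction("pde_bind", c(Ga = 1, PDE = 1), c(GaPDE = 1), rate_param = "kP1"),
    reaction("pde_act", c(GaPDE = 1), c(GaPDEa = 1), rate_param = "kP2"),
    reaction("gtpase_cplx", c(GaPDEa = 1), c(GaGDP = 1, PDE = 1),
             rate_param = "kGt2"),
    reaction("pde_bind2", c(Ga = 1, GaPDEa = 1), c(GaPDEaGa = 1),
             rate_param = "kP3"),
    reaction("pde_act2", c(GaPDEaGa = 1), c(GaPDEa2 = 1), rate_param = "kP4"),
    reaction("rgs_bind", c(GaPDEa = 1, RGS = 1), c(RGSGaPDEa = 1),
             rate_param = "kRGS1"),
    reaction("gap", c(RGSGaPDEa = 1), c(GaGDP = 1, PDE = 1, RGS = 1),
             rate_param = "kRGS2"),
    reaction("reassoc", c(GaGDP = 1), c(Gt = 1), rate_param = "kre"),
    reaction("cg_turnover", c(cG = 1), numeric(),
             rate_expr = quote((bdark + bsub *
               (GaPDEa + GaPDEaGa + 2 * GaPDEa2 + RGSGaPDEa)) * cG)),
    reaction("cg_synth", numeric(), c(cG = 1),
             rate_expr = quote(alpha)))
  ga <- c(Gt = 1L, Ga = 1L, GaGDP = 1L, GaPDE = 1L, GaPDEa = 1L,
          GaPDEaGa = 2L, GaPDEa2 = 2L, RGSGaPDEa = 1L)
  reaction_network(species, reactions, pars,
                   output = quote(J_dark * (cG / cG_dark)^3),
                   ga_species = ga, id = "toy_cascade")
}

#' Generate a family of flash stimuli
#'
#' @param min,max smallest and largest flash strength (photons um^-2).
#' @param n number of flashes.
#' @param spacing "log" (default) or "linear".
#' @param onset,duration passed to [flash_stimulus()].
#' @return list of [flash_stimulus()] objects with strictly increasing
#'   intensity.
#' @export
gen_flash_family <- function(min, max, n, spacing = c("log", "linear"),
                             onset = 0, duration = 0.01) {
  spacing <- match.arg(spacing)
  if (n < 1) stop("n must be >= 1")
  if (n == 1) {
    intens <- min
  } else if (spacing == "log") {
    if (min <= 0) stop("log spacing requires min > 0")
    intens <- 10^seq(log10(min), log10(max), length.out = n)
  } else {
    intens <- seq(min, max, length.out = n)
  }
  lapply(intens, flash_stimulus, onset = onset, duration = duration)
}
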