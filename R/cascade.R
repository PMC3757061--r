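#' Add dark rhodopsin-transducin precoupling reactions
#'
#' Appends the reversible formation of dark R-Gt complexes:
#' R + Gt -> RGt (rate `kRGt1`) and RGt -> R + Gt (rate `kRGt2`).  The
#' default constants are calibrated so that at the dark steady state
#' about 20% of the transducin pool is precoupled to rhodopsin: with
#' rhodopsin in large excess the bound fraction is
#' [R] / ([R] + kRGt2/kRGt1), so the default dissociation constant is
#' set to 4 x the dark rhodopsin amount.
#'
#' @param net a [reaction_network()].
#' @param kon association rate constant (per amount per s); `NULL` uses
#'   1e-4.
#' @param koff dissociation rate constant (per s); `NULL` derives it
#'   from mass-action equilibrium with reactant depletion so that the
#'   dark precoupled fraction equals `target_fraction`.
#' @param target_fraction dark precoupled fraction the default constants
#'   are calibrated to (default 0.20).
#' @param r_species,gt_species names of the dark rhodopsin and holo-Gt
#'   species in `net`.
#' @param complex_species name for the new R-Gt complex species.
#' @return the extended network; the precoupled fraction at steady state
#'   is available through [dark_steady_state()].
#' @export
add_precoupling <- function(net, kon = NULL, koff = NULL,
                            target_fraction = 0.20,
                            r_species = "R", gt_species = "Gt",
                            complex_species = "RGt") {
  missing_sp <- setdiff(c(r_species, gt_species), names(net$species))
  if (length(missing_sp))
    stop("precoupling requires species not present in the network: ",
         paste(missing_sp, collapse = ", "))
  if (is.null(kon)) kon <- 1e-4
  if (is.null(koff)) {
    # at equilibrium koff/kon = [R]_free [Gt]_free / [RGt]; with fraction
    # f of the Gt pool bound, [RGt] = f Gt0, [Gt]_free = (1-f) Gt0 and
    # [R]_free = R0 - f Gt0
    f <- target_fraction
    r0 <- net$species[[r_species]]
    g0 <- net$species[[gt_species]]
    if (r0 - f * g0 <= 0)
      stop("not enough dark rhodopsin to precouple ", f, " of the Gt pool")
    koff <- kon * (r0 - f * g0) * (1 - f) / f
  }
  if (!(complex_species %in% names(net$species)))
    net$species[complex_species] <- 0
  net$parameters["kRGt1"] <- kon
  net$parameters["kRGt2"] <- koff
  fwd <- reaction("precoupling_on",
                  reactants = stats::setNames(c(1, 1), c(r_species, gt_species)),
                  products = stats::setNames(1, complex_species),
                  rate_param = "kRGt1")
  rev <- reaction("precoupling_off",
                  reactants = stats::setNames(1, complex_species),
                  products = stats::setNames(c(1, 1), c(r_species, gt_species)),
                  rate_param = "kRGt2")
  net$reactions <- c(net$reactions, list(fwd), list(rev))
  if (!is.null(net$ga_species) && !(complex_species %in% names(net$ga_species)))
    net$ga_species[complex_species] <- 1L
  attr(net, "precoupling") <- list(gt = gt_species, complex = complex_species)
  validate_network(net)
  net
}

#' Specification of an explicit mutant G-alpha extension
#'
#' Captures the zygosity-dependent expression levels of a mutant G-alpha
#' and the fold reductions applied to the kinetic parameters of its
#' reaction copies.  Heterozygous rods express the normal total level of
#' G-alpha, 25% of which is mutant; homozygous rods express only 35% of
#' the native level, all of it mutant.
#'
#' @param zygosity "heterozygous" or "homozygous"; selects the default
#'   `fraction` and `level`.
#' @param fraction mutant fraction of total G-alpha (in \[0,1\]).
#' @param level total G-alpha level relative to native (in \[0,1\]).
#' @param scalings named fold reductions applied to the mutant parameter
#'   copies (suffix `_m`), e.g. `c(kP1 = 35000, kP2 = 35000, kRGS1 = 2)`.
#'   A fold of 0 sets the mutant parameter to 0.
#' @param label mutant species suffix.
#' @return an object of class `mutant_spec`.
#' @export
mutant_spec <- function(zygosity = c("heterozygous", "homozygous"),
                        fraction = NULL, level = NULL,
                        scalings = c(kP1 = 35000, kP2 = 35000, kRGS1 = 2),
                        label = "m") {
  zygosity <- match.arg(zygosity)
  if (is.null(fraction)) fraction <- if (zygosity == "heterozygous") 0.25 else 1
  if (is.null(level))    level    <- if (zygosity == "heterozygous") 1 else 0.35
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0,1]")
  if (level < 0 || level > 1) stop("level must be in [0,1]")
  if (length(scalings) && any(unlist(scalings) < 0))
    stop("fold reductions must be >= 0")
  structure(list(zygosity = zygosity, fraction = fraction, level = level,
                 scalings = scalings, label = label),
            class = "mutant_spec")
}

mut_name <- function(sp, n_mut, n_units, label) {
  if (n_mut == 0) return(sp)
  if (n_units == 1) return(paste0(sp, "_", label))
  paste0(sp, "_", label, n_mut)
}

#' Graft an explicit mutant G-alpha species into a cascade model
#'
#' Every reaction involving a G-alpha carrying species (as declared in
#' `net$ga_species`) is duplicated with mutant species substituted.  For
#' reactions carrying a single G-alpha unit this adds one all-mutant
#' copy; reactions that combine two G-alpha carriers (the 2:1 G-alpha:PDE
#' branch) additionally get the mixed WT/mutant combinations, whose
#' complexes are tracked by their mutant-unit count (the two binding
#' orders are kinetically identical and share one state).  Duplicated
#' reactions use independently scalable parameter copies named
#' `<param>_<label>`.  Initial amounts follow the zygosity rule: for each
#' dark G-alpha carrier, mutant = fraction x level x native and
#' WT = (1-fraction) x level x native, so total G-alpha equals the
#' zygosity-specified level.
#'
#' @param net a [reaction_network()] with `ga_species` declared.
#' @param spec a [mutant_spec()].
#' @return the extended network, with `spec$scalings` already applied to
#'   the mutant parameter copies.
#' @export
build_mutant <- function(net, spec) {
  if (is.null(net$ga_species))
    stop("net$ga_species must declare the G-alpha carrying species")
  ga <- net$ga_species
  lbl <- spec$label

  # register mutant species variants (per mutant-unit count)
  for (sp in names(ga)) {
    for (k in seq_len(ga[[sp]])) {
      nm <- mut_name(sp, k, ga[[sp]], lbl)
      if (!(nm %in% names(net$species))) net$species[nm] <- 0
    }
  }

  new_reactions <- list()
  new_params <- character()
  for (r in net$reactions) {
    ga_reac <- intersect(names(r$reactants), names(ga))
    ga_prod <- intersect(names(r$products), names(ga))
    if (!length(ga_reac) && !length(ga_prod)) next
    if (is.null(r$rate_param))
      stop("cannot duplicate reaction '", r$id,
           "' with a general rate law for the mutant species")
    # enumerate mutant-unit counts (0..u) per G-alpha carrying reactant;
    # a reactant with stoichiometry s and k mutant units contributes s*k.
    slots <- ga_reac
    if (!length(slots)) {
      # pure production of a G-alpha species (e.g. zero-order): single
      # all-mutant copy
      combos <- list(stats::setNames(integer(0), character(0)))
    } else {
      combos <- expand.grid(lapply(slots, function(sp) 0:ga[[sp]]))
      combos <- lapply(seq_len(nrow(combos)), function(i)
        stats::setNames(as.integer(combos[i, ]), slots))
      combos <- combos[vapply(combos, function(k) any(k > 0), logical(1))]
    }
    for (cmb in combos) {
      # mutant units entering the reaction
      units_in <- sum(vapply(names(cmb), function(sp)
        r$reactants[[sp]] * cmb[[sp]], numeric(1)))
      if (!length(slots)) units_in <- sum(r$products[ga_prod] * ga[ga_prod])
      reac_new <- r$reactants
      names(reac_new) <- vapply(names(reac_new), function(sp) {
        if (sp %in% names(cmb) && cmb[[sp]] > 0)
          mut_name(sp, cmb[[sp]], ga[[sp]], lbl) else sp
      }, character(1))
      # distribute mutant units over G-alpha carrying products
      prod_new <- r$products
      remaining <- units_in
      pn <- names(prod_new)
      for (i in seq_along(pn)) {
        sp <- pn[i]
        if (sp %in% names(ga)) {
          take <- min(remaining, ga[[sp]] * r$products[[sp]])
          if (take > 0) {
            if (r$products[[sp]] > 1 && take %% r$products[[sp]] != 0)
              stop("ambiguous mutant assignment in reaction '", r$id, "'")
            per <- take / r$products[[sp]]
            pn[i] <- mut_name(sp, per, ga[[sp]], lbl)
            remaining <- remaining - take
          }
        }
      }
      names(prod_new) <- pn
      if (remaining > 0)
        stop("mutant unit conservation violated in reaction '", r$id,
             "': ", remaining, " unit(s) unassigned")
      pm <- paste0(r$rate_param, "_", lbl)
      if (!(pm %in% names(net$parameters))) {
        net$parameters[pm] <- net$parameters[[r$rate_param]]
        new_params <- c(new_params, pm)
      }
      new_reactions <- c(new_reactions, list(
        reaction(paste0(r$id, "_", lbl,
                        if (length(combos) > 1)
                          paste0("_", paste0(as.integer(cmb), collapse = "")) else ""),
                 reactants = reac_new, products = prod_new,
                 rate_param = pm, reversible = r$reversible)))
    }
  }
  net$reactions <- c(net$reactions, new_reactions)

  # general rate laws and the output observable must see the total pool
  # of each G-alpha carrier: substitute X -> (X + X_m [+ X_m2])
  subs <- list()
  for (sp in names(ga)) {
    vars <- c(sp, vapply(seq_len(ga[[sp]]), function(k)
      mut_name(sp, k, ga[[sp]], lbl), character(1)))
    e <- as.name(vars[1])
    for (v in vars[-1]) e <- call("+", e, as.name(v))
    subs[[sp]] <- e
  }
  net$reactions <- lapply(net$reactions, function(r) {
    if (!is.null(r$rate_expr))
      r$rate_expr <- eval(call("substitute", r$rate_expr, subs))
    r
  })
  if (!is.null(net$output))
    net$output <- eval(call("substitute", net$output, subs))

  # zygosity rule on dark initial amounts
  native_total <- sum(net$species[names(ga)] * ga)
  for (sp in names(ga)) {
    init0 <- net$species[[sp]]
    if (init0 > 0) {
      net$species[[mut_name(sp, ga[[sp]], ga[[sp]], lbl)]] <-
        spec$fraction * spec$level * init0
      net$species[[sp]] <- (1 - spec$fraction) * spec$level * init0
    }
  }
  total <- sum(net$species[names(ga)] * ga) +
    sum(vapply(names(ga), function(sp) {
      sum(vapply(seq_len(ga[[sp]]), function(k)
        net$species[[mut_name(sp, k, ga[[sp]], lbl)]] * ga[[sp]], numeric(1)))
    }, numeric(1)))
  if (abs(total - spec$level * native_total) > 1e-6 * max(native_total, 1))
    stop("zygosity rule violates G-alpha conservation")
  attr(net, "mutant") <- spec
  # record mutant species for mass-conservation accounting
  mut_sp <- unlist(lapply(names(ga), function(sp)
    vapply(seq_len(ga[[sp]]), function(k)
      mut_name(sp, k, ga[[sp]], lbl), character(1))))
  mut_units <- unlist(lapply(names(ga), function(sp) seq_len(ga[[sp]])))
  attr(net, "mutant_species") <- stats::setNames(as.integer(mut_units), mut_sp)

  if (length(spec$scalings)) {
    sc <- stats::setNames(unlist(spec$scalings),
                          paste0(names(spec$scalings), "_", lbl))
    sc <- sc[names(sc) %in% names(net$parameters)]
    if (length(sc)) net <- scale_parameters(net, sc)
  }
  validate_network(net)
  net
}

#' Total G-alpha content of a state vector
#'
#' Sums G-alpha units over all wild-type and mutant carrying species;
#' used to assert mass conservation along simulations.
#'
#' @param net network with `ga_species` (and optionally mutant copies).
#' @param state named species amounts (defaults to initial amounts).
#' @return total number of G-alpha units.
#' @export
total_galpha <- function(net, state = net$species) {
  ga <- net$ga_species
  if (is.null(ga)) stop("net$ga_species is not declared")
  tot <- sum(state[names(ga)] * ga, na.rm = TRUE)
  ms <- attr(net, "mutant_species")
  if (!is.null(ms)) {
    # a mutant variant of a u-unit carrier with k mutant units still
    # carries u total G-alpha units
    lbl <- attr(net, "mutant")$label
    for (sp in names(ga)) {
      u <- ga[[sp]]
      for (k in seq_len(u)) {
        nm <- mut_name(sp, k, u, lbl)
        if (nm %in% names(state)) tot <- tot + state[[nm]] * u
      }
    }
  }
  tot
}
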