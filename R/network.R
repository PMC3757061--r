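#' Reaction networks for G-protein signalling cascades
#'
#' A `reaction_network` is a self-contained description of a mass-action
#' (or general rate-law) reaction system: species with initial amounts,
#' reactions with stoichiometries and rate laws, kinetic parameters, a
#' compartment volume, and an optional output observable (the circulating
#' current J for phototransduction models).
#'
#' @param species named numeric vector of initial amounts (>= 0), or a
#'   data.frame with columns `name` and `init`.
#' @param reactions list of objects created by [reaction()].
#' @param parameters named numeric vector of kinetic parameters.
#' @param compartment compartment volume (scalar, default 1).
#' @param output optional R expression (quoted) in species/parameter names
#'   giving the output observable J; `NULL` means no current readout.
#' @param ga_species optional named integer vector: species that contain
#'   the G-alpha subunit, mapped to the number of G-alpha units each
#'   carries.  Required by [build_mutant()].
#' @param id model identifier string.
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, parameters,
                             compartment = 1, output = NULL,
                             ga_species = NULL, id = "model") {
  if (is.data.frame(species)) {
    sp <- stats::setNames(as.numeric(species$init), as.character(species$name))
  } else {
    sp <- species
  }
  if (is.null(names(sp)) || any(!nzchar(names(sp))))
    stop("species must be named")
  if (anyDuplicated(names(sp)))
    stop("duplicated species names: ",
         paste(unique(names(sp)[duplicated(names(sp))]), collapse = ", "))
  if (any(sp < 0)) stop("initial amounts must be >= 0")
  if (length(parameters) && (is.null(names(parameters)) || any(!nzchar(names(parameters)))))
    stop("parameters must be named")

  net <- structure(list(species = sp, reactions = reactions,
                        parameters = parameters, compartment = compartment,
                        output = output, ga_species = ga_species, id = id),
                   class = "reaction_network")
  validate_network(net)
  net
}

#' Define a single reaction
#'
#' Rate laws are either mass-action (give `rate_param`, the name of the
#' rate constant; the rate is k * prod(reactant^stoich)) or a general
#' quoted R expression in species, parameters and `t` (give `rate_expr`).
#'
#' @param id reaction identifier.
#' @param reactants named numeric vector of reactant stoichiometries
#'   (empty vector for zero-order production).
#' @param products named numeric vector of product stoichiometries.
#' @param rate_param name of the mass-action rate constant.
#' @param rate_expr quoted R expression for a general rate law.
#' @param reversible logical flag (informational; reversible SBML
#'   reactions keep their full rate law in `rate_expr`).
#' @return an object of class `reaction`.
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(),
                     rate_param = NULL, rate_expr = NULL, reversible = FALSE) {
  if (is.null(rate_param) && is.null(rate_expr))
    stop("reaction '", id, "': either rate_param or rate_expr is required")
  structure(list(id = id, reactants = reactants, products = products,
                 rate_param = rate_param, rate_expr = rate_expr,
                 reversible = isTRUE(reversible)),
            class = "reaction")
}

validate_network <- function(net) {
  spn <- names(net$species)
  prn <- names(net$parameters)
  for (r in net$reactions) {
    ref <- c(names(r$reactants), names(r$products))
    bad <- setdiff(ref, spn)
    if (length(bad))
      stop("reaction '", r$id, "' references undeclared species: ",
           paste(bad, collapse = ", "))
    if (!is.null(r$rate_param) && !(r$rate_param %in% prn))
      stop("reaction '", r$id, "' references undeclared parameter '",
           r$rate_param, "'")
  }
  invisible(net)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network '", x$id, "'\n", sep = "")
  cat("  ", length(x$species), " species, ", length(x$reactions),
      " reactions, ", length(x$parameters), " parameters\n", sep = "")
  if (!is.null(x$ga_species))
    cat("  G-alpha carrying species: ",
        paste(names(x$ga_species), collapse = ", "), "\n", sep = "")
  if (!is.null(x$output))
    cat("  output: J =", deparse(x$output), "\n")
  invisible(x)
}

#' @export
summary.reaction_network <- function(object, ...) {
  eq <- vapply(object$reactions, function(r) {
    side <- function(s) {
      if (!length(s)) return("0")
      paste(ifelse(s == 1, names(s), paste0(s, " ", names(s))), collapse = " + ")
    }
    paste0(side(r$reactants), " -> ", side(r$products))
  }, character(1))
  data.frame(id = vapply(object$reactions, `[[`, character(1), "id"),
             equation = eq,
             rate = vapply(object$reactions, function(r)
               if (!is.null(r$rate_param)) r$rate_param else deparse(r$rate_expr),
               character(1)),
             stringsAsFactors = FALSE)
}

# stoichiometry matrix, species x reactions
stoich_matrix <- function(net) {
  spn <- names(net$species)
  S <- matrix(0, length(spn), length(net$reactions),
              dimnames = list(spn, vapply(net$reactions, `[[`, character(1), "id")))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    if (length(r$reactants)) S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
    if (length(r$products))  S[names(r$products), j]  <- S[names(r$products), j]  + r$products
  }
  S
}

# Build the deSolve derivative function.  `extra` supplies time-varying
# inputs (e.g. the photon flux `light`) as a named list of functions of t.
ode_function <- function(net, extra = NULL) {
  S <- stoich_matrix(net)
  reactions <- net$reactions
  pars <- as.list(net$parameters)
  nr <- length(reactions)
  # precompile rate evaluators
  mass <- vapply(reactions, function(r) !is.null(r$rate_param), logical(1))
  rate_exprs <- lapply(reactions, `[[`, "rate_expr")
  rate_k <- vapply(reactions, function(r)
    if (!is.null(r$rate_param)) r$rate_param else NA_character_, character(1))
  function(t, y, parms) {
    env <- list2env(c(as.list(y), pars), parent = baseenv())
    assign("t", t, envir = env)
    if (!is.null(extra))
      for (nm in names(extra)) assign(nm, extra[[nm]](t), envir = env)
    v <- numeric(nr)
    for (j in seq_len(nr)) {
      if (mass[j]) {
        r <- reactions[[j]]
        vj <- get(rate_k[j], envir = env)
        if (length(r$reactants)) {
          conc <- y[names(r$reactants)]
          vj <- vj * prod(pmax(conc, 0)^r$reactants)
        }
        v[j] <- vj
      } else {
        v[j] <- eval(rate_exprs[[j]], env)
      }
    }
    list(as.numeric(S %*% v))
  }
}

eval_output <- function(net, state_matrix) {
  if (is.null(net$output)) stop("network has no output observable")
  env <- c(as.data.frame(state_matrix), as.list(net$parameters))
  eval(net$output, env)
}

#' Relax a reaction network to its dark steady state
#'
#' Integrates the system without light input until the derivative norm
#' falls below `tol` (or `t_max` is reached).  Also reports the fraction
#' of the transducin pool precoupled to dark rhodopsin when R-Gt
#' precoupling species are present (see [add_precoupling()]).
#'
#' @param net a [reaction_network()].
#' @param t_max maximum relaxation time (s), default 2000.
#' @param tol convergence tolerance on the max absolute derivative
#'   relative to the largest species amount, default 1e-10.
#' @param rtol,atol solver tolerances.
#' @return list with `state` (named amounts), `precoupled_fraction`,
#'   `converged`, `t_used`.
#' @export
dark_steady_state <- function(net, t_max = 2000, tol = 1e-10,
                              rtol = 1e-8, atol = 1e-12) {
  f <- ode_function(net, extra = list(light = function(t) 0))
  y <- net$species
  scale <- max(abs(y), 1)
  t_used <- 0
  step <- max(t_max / 8, 1)
  converged <- FALSE
  repeat {
    out <- deSolve::lsoda(y, c(0, step), f, parms = NULL,
                          rtol = rtol, atol = atol)
    y <- stats::setNames(as.numeric(out[nrow(out), -1]), names(y))
    t_used <- t_used + step
    d <- max(abs(unlist(f(t_used, y, NULL))))
    if (d < tol * scale) { converged <- TRUE; break }
    if (t_used >= t_max) break
  }
  if (!converged && max(abs(unlist(f(t_used, y, NULL)))) > 1e-4 * scale)
    stop("no dark steady state within t_max = ", t_max,
         " s (max |dx/dt| = ", signif(max(abs(unlist(f(t_used, y, NULL)))), 3), ")")
  y[y < 0 & y > -1e-9 * scale] <- 0
  list(state = y, precoupled_fraction = precoupled_fraction(net, y),
       converged = converged, t_used = t_used)
}

# Fraction of the Gt pool bound in dark R-Gt complexes.  Species named in
# attr "precoupling" (set by add_precoupling) define the complex; without
# precoupling reactions the fraction is 0.
precoupled_fraction <- function(net, state) {
  pc <- attr(net, "precoupling")
  if (is.null(pc)) return(0)
  nm <- names(state)
  bound <- sum(state[grep(paste0("^", pc$complex, "($|_)"), nm)])
  free <- sum(state[grep(paste0("^", pc$gt, "($|_)"), nm)])
  if (bound + free <= 0) return(0)
  bound / (bound + free)
}

#' Scale kinetic parameters by fold reductions
#'
#' New value = original / fold; fold 0 sets the parameter to exactly 0
#' (complete loss of the reaction).
#'
#' @param net a [reaction_network()].
#' @param scalings named numeric vector or list, parameter name -> fold
#'   reduction (>= 0).
#' @return the modified network.
#' @export
scale_parameters <- function(net, scalings) {
  scalings <- unlist(scalings)
  bad <- setdiff(names(scalings), names(net$parameters))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(names(net$parameters), collapse = ", "))
  if (any(scalings < 0)) stop("fold reductions must be >= 0")
  for (nm in names(scalings)) {
    f <- scalings[[nm]]
    net$parameters[[nm]] <- if (f == 0) 0 else net$parameters[[nm]] / f
  }
  net
}
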