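#' SBML input/output for reaction networks
#'
#' Reads SBML Level 2/3 models into [reaction_network()] objects and
#' writes networks back out as SBML Level 3 Version 1.  The kinetic-law
#' MathML subset supported covers the arithmetic operators (times,
#' divide, plus, minus, power), exp/ln/log, numbers (including
#' e-notation) and identifiers; models using unsupported constructs
#' (events, rules, function definitions, piecewise laws) raise an
#' explicit unsupported-feature error naming the construct.
#'
#' @name sbml-io
NULL

mathml_to_r <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) stop("SBML parse error: <math> must have one child")
    return(mathml_to_r(kids[[1]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- xml2::xml_contents(node)
      txt <- trimws(xml2::xml_text(parts[xml2::xml_name(parts) != "sep"]))
      txt <- txt[nzchar(txt)]
      return(as.numeric(txt[1]) * 10^as.numeric(txt[2]))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (nm == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (!is.na(url) && grepl("time", url)) return(as.name("t"))
    stop("unsupported SBML feature: csymbol '", xml2::xml_text(node), "'")
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_r)
    fold <- function(fun, args) Reduce(function(a, b) call(fun, a, b), args)
    switch(op,
      times  = fold("*", args),
      plus   = if (length(args)) fold("+", args) else 0,
      minus  = if (length(args) == 1) call("-", args[[1]]) else fold("-", args),
      divide = fold("/", args),
      power  = fold("^", args),
      exp    = call("exp", args[[1]]),
      ln     = call("log", args[[1]]),
      log    = if (length(args) == 1) call("log10", args[[1]])
               else call("log", args[[2]], args[[1]]),
      root   = call("sqrt", args[[length(args)]]),
      stop("unsupported SBML feature: MathML operator <", op, ">"))
  } else {
    stop("unsupported SBML feature: MathML element <", nm, ">")
  }
}

r_to_mathml <- function(e) {
  if (is.numeric(e)) return(paste0("<cn> ", format(e, digits = 17), " </cn>"))
  if (is.name(e)) {
    if (identical(as.character(e), "t"))
      return(paste0("<csymbol encoding=\"text\" definitionURL=",
                    "\"http://www.sbml.org/sbml/symbols/time\"> t </csymbol>"))
    return(paste0("<ci> ", as.character(e), " </ci>"))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    args <- as.list(e)[-1]
    tag <- switch(op, "*" = "times", "+" = "plus", "-" = "minus",
                  "/" = "divide", "^" = "power", "exp" = "exp",
                  "log" = "ln", "sqrt" = "root", "(" = NULL,
                  stop("cannot serialize operator '", op, "' to MathML"))
    if (is.null(tag)) return(r_to_mathml(args[[1]]))
    paste0("<apply><", tag, "/>",
           paste(vapply(args, r_to_mathml, character(1)), collapse = ""),
           "</apply>")
  } else stop("cannot serialize '", deparse(e), "' to MathML")
}

sp_refs <- function(rnode, tag) {
  lst <- xml2::xml_find_first(rnode, paste0("./", tag))
  if (inherits(lst, "xml_missing")) return(numeric())
  refs <- xml2::xml_find_all(lst, "./speciesReference")
  if (!length(refs)) return(numeric())
  st <- xml2::xml_attr(refs, "stoichiometry")
  st[is.na(st)] <- "1"
  stats::setNames(as.numeric(st), xml2::xml_attr(refs, "species"))
}

#' Load an SBML model
#'
#' @param path path to an SBML Level 2 or Level 3 file.
#' @param id model identifier (defaults to the file's model id).
#' @return a [reaction_network()].  Reactions keep their full kinetic
#'   laws as rate expressions; species initial amounts are taken from
#'   `initialAmount` (or `initialConcentration` x compartment size).
#' @export
load_model <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML: ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, "//model")
  if (inherits(model, "xml_missing"))
    stop("malformed SBML: no <model> element")
  for (bad in c("listOfEvents", "listOfRules", "listOfFunctionDefinitions",
                "listOfConstraints")) {
    node <- xml2::xml_find_first(model, paste0("./", bad))
    if (!inherits(node, "xml_missing") && length(xml2::xml_children(node)))
      stop("unsupported SBML feature: ", bad)
  }
  comp_nodes <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  comp_size <- if (length(comp_nodes)) {
    sz <- xml2::xml_attr(comp_nodes[1], "size")
    if (is.na(sz)) sz <- xml2::xml_attr(comp_nodes[1], "volume")
    if (is.na(sz)) 1 else as.numeric(sz)
  } else 1

  spn <- xml2::xml_find_all(model, "./listOfSpecies/species")
  if (!length(spn)) stop("malformed SBML: no species declared")
  ids <- xml2::xml_attr(spn, "id")
  amt <- as.numeric(xml2::xml_attr(spn, "initialAmount"))
  conc <- as.numeric(xml2::xml_attr(spn, "initialConcentration"))
  init <- ifelse(!is.na(amt), amt,
                 ifelse(!is.na(conc), conc * comp_size, 0))
  species <- stats::setNames(init, ids)

  pn <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  parameters <- stats::setNames(as.numeric(xml2::xml_attr(pn, "value")),
                                xml2::xml_attr(pn, "id"))
  parameters <- parameters[!is.na(names(parameters))]

  rn <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  reactions <- vector("list", length(rn))
  for (i in seq_along(rn)) {
    node <- rn[[i]]
    rid <- xml2::xml_attr(node, "id")
    reac <- sp_refs(node, "listOfReactants")
    prod <- sp_refs(node, "listOfProducts")
    bad <- setdiff(c(names(reac), names(prod)), ids)
    if (length(bad))
      stop("malformed SBML: reaction '", rid,
           "' references undeclared species: ", paste(bad, collapse = ", "))
    kl <- xml2::xml_find_first(node, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("unsupported SBML feature: reaction '", rid, "' has no kineticLaw")
    # local parameters are hoisted with a reaction-scoped prefix
    loc <- xml2::xml_find_all(
      kl, "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")
    sub_env <- list()
    for (lp in loc) {
      lid <- xml2::xml_attr(lp, "id")
      gname <- paste0(rid, "__", lid)
      parameters[gname] <- as.numeric(xml2::xml_attr(lp, "value"))
      sub_env[[lid]] <- as.name(gname)
    }
    math <- xml2::xml_find_first(kl, "./math")
    if (inherits(math, "xml_missing"))
      stop("unsupported SBML feature: reaction '", rid, "' kineticLaw has no <math>")
    expr <- mathml_to_r(math)
    if (length(sub_env))
      expr <- eval(call("substitute", expr, sub_env))
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    # recognise plain mass-action laws k * reactants^stoich
    mk <- massaction_param(expr, reac, names(parameters))
    reactions[[i]] <- if (!is.null(mk))
      reaction(rid, reac, prod, rate_param = mk, reversible = rev)
    else
      reaction(rid, reac, prod, rate_expr = expr, reversible = rev)
  }
  if (is.null(id)) {
    id <- xml2::xml_attr(model, "id")
    if (is.na(id)) id <- basename(path)
  }
  # package-specific annotation: output observable and G-alpha census
  output <- NULL
  ga_species <- NULL
  out_node <- xml2::xml_find_first(model, "./annotation//output")
  if (!inherits(out_node, "xml_missing"))
    output <- str2lang(xml2::xml_text(out_node))
  ga_node <- xml2::xml_find_first(model, "./annotation//gaSpecies")
  if (!inherits(ga_node, "xml_missing")) {
    kv <- strsplit(strsplit(xml2::xml_text(ga_node), ";", fixed = TRUE)[[1]],
                   "=", fixed = TRUE)
    ga_species <- stats::setNames(
      vapply(kv, function(p) as.integer(p[2]), integer(1)),
      vapply(kv, `[[`, character(1), 1))
  }
  reaction_network(species, reactions, parameters,
                   compartment = comp_size, output = output,
                   ga_species = ga_species, id = id)
}

# If expr is exactly k * prod(reactant^stoich) (in any association order),
# return the parameter name k, else NULL.
massaction_param <- function(expr, reactants, par_names) {
  factors <- list()
  flatten <- function(e) {
    if (is.call(e) && identical(as.character(e[[1]]), "*")) {
      flatten(e[[2]]); flatten(e[[3]])
    } else factors[[length(factors) + 1]] <<- e
  }
  flatten(expr)
  k <- NULL
  need <- reactants
  for (f in factors) {
    if (is.name(f)) {
      ch <- as.character(f)
      if (ch %in% names(need) && need[[ch]] == 1) { need <- need[names(need) != ch]; next }
      if (ch %in% par_names && is.null(k)) { k <- ch; next }
      return(NULL)
    } else if (is.call(f) && identical(as.character(f[[1]]), "^") &&
               is.name(f[[2]]) && is.numeric(f[[3]])) {
      ch <- as.character(f[[2]])
      if (ch %in% names(need) && need[[ch]] == f[[3]]) {
        need <- need[names(need) != ch]; next
      }
      return(NULL)
    } else return(NULL)
  }
  if (!is.null(k) && !length(need)) k else NULL
}

#' Write a reaction network as SBML Level 3
#'
#' @param net a [reaction_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'level="3" version="1">'),
    paste0('  <model id="', esc(net$id), '">'))
  # package-specific annotation: output observable and G-alpha census
  if (!is.null(net$output) || !is.null(net$ga_species)) {
    esc_txt <- function(x)
      gsub(">", "&gt;", gsub("<", "&lt;", gsub("&", "&amp;", x)))
    ann <- c('    <annotation>',
             '      <modelMeta xmlns="https://rodnet.invalid/sbml-meta">')
    if (!is.null(net$output))
      ann <- c(ann, paste0('        <output>',
                           esc_txt(paste(deparse(net$output), collapse = " ")),
                           '</output>'))
    if (!is.null(net$ga_species))
      ann <- c(ann, paste0('        <gaSpecies>',
                           paste(names(net$ga_species), net$ga_species,
                                 sep = "=", collapse = ";"),
                           '</gaSpecies>'))
    ann <- c(ann, '      </modelMeta>', '    </annotation>')
    lines <- c(lines, ann)
  }
  lines <- c(lines,
    '    <listOfCompartments>',
    paste0('      <compartment id="cell" size="', net$compartment,
           '" constant="true"/>'),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (nm in names(net$species))
    lines <- c(lines, paste0(
      '      <species id="', nm, '" compartment="cell" initialAmount="',
      format(net$species[[nm]], digits = 17),
      '" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>'))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (nm in names(net$parameters))
    lines <- c(lines, paste0(
      '      <parameter id="', nm, '" value="',
      format(net$parameters[[nm]], digits = 17), '" constant="true"/>'))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (r in net$reactions) {
    lines <- c(lines, paste0('      <reaction id="', r$id, '" reversible="',
                             tolower(as.character(r$reversible)),
                             '" fast="false">'))
    refs <- function(tag, v) {
      if (!length(v)) return(character())
      c(paste0('        <', tag, '>'),
        vapply(names(v), function(s) paste0(
          '          <speciesReference species="', s, '" stoichiometry="',
          v[[s]], '" constant="true"/>'), character(1)),
        paste0('        </', tag, '>'))
    }
    lines <- c(lines, refs("listOfReactants", r$reactants),
               refs("listOfProducts", r$products))
    expr <- if (!is.null(r$rate_param)) {
      e <- as.name(r$rate_param)
      for (s in names(r$reactants)) {
        term <- if (r$reactants[[s]] == 1) as.name(s)
                else call("^", as.name(s), r$reactants[[s]])
        e <- call("*", e, term)
      }
      e
    } else r$rate_expr
    lines <- c(lines,
               '        <kineticLaw>',
               paste0('          <math xmlns="http://www.w3.org/1998/Math/MathML">',
                      r_to_mathml(expr), '</math>'),
               '        </kineticLaw>',
               '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
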