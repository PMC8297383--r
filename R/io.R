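#' Read a metabolic model from SBML or JSON
#'
#' Two on-disk dialects are supported: SBML Level 3 with the `fbc` package
#' (flux bounds as parameters, gene-product associations, an active
#' objective) and a flat JSON dialect (schema below). Bounds, GPR rules,
#' the objective and chemical formulae are taken from the file; carbon
#' counts come from explicit metadata (JSON) or from formula parsing.
#'
#' JSON schema (version 1): a single object with fields `id`, `version`,
#' `objective`, `metabolites` (array of `{id, name, compartment, formula,
#' carbons}`), `reactions` (array of `{id, stoichiometry: {met: coef},
#' lower_bound, upper_bound, gpr, kind}`) and `genes` (array of ids).
#'
#' @param path file path.
#' @param format `"sbml"` or `"json"`; guessed from the extension when
#'   missing (`.xml`/`.sbml` vs `.json`).
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  format <- match.arg(format, c("sbml", "json"))
  out <- tryCatch(
    if (format == "sbml") read_model_sbml(path) else read_model_json(path),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("no objective", msg)) stop(msg, call. = FALSE)
      stop("format error in ", sQuote(path), ": ", msg, call. = FALSE)
    })
  out
}

#' Write a metabolic model to SBML or JSON
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"sbml"` or `"json"`; guessed from the extension when
#'   missing. Explicit carbon metadata without a formula is exported to SBML
#'   as a carbon-only formula (`"C6"`), preserving [carbon_content()] across
#'   a round trip.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  validate_model(model)
  if (is.null(format))
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  format <- match.arg(format, c("sbml", "json"))
  if (format == "sbml") write_model_sbml(model, path) else write_model_json(model, path)
  invisible(path)
}

# ---- JSON dialect ----------------------------------------------------------

read_model_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$objective)) stop("no objective declared in ", sQuote(path))
  mets <- do.call(rbind, lapply(j$metabolites, function(m) data.frame(
    id = m$id, name = m$name %||% m$id, compartment = m$compartment %||% "c",
    formula = m$formula %||% NA_character_,
    carbons = as.numeric(m$carbons %||% NA_real_), stringsAsFactors = FALSE)))
  rxns <- lapply(j$reactions, function(r) list(
    id = r$id, stoich = unlist(r$stoichiometry),
    lb = as.numeric(r$lower_bound), ub = as.numeric(r$upper_bound),
    gpr = r$gpr %||% "", kind = r$kind))
  m <- metabolic_model(rxns, mets, objective = j$objective,
                       genes = unlist(j$genes), id = j$id %||% "model")
  if (!is.null(j$annotation)) m$annotation <- j$annotation
  m
}

write_model_json <- function(model, path) {
  j <- list(
    id = model$id, version = 1L, objective = model$objective,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      r <- model$metabolites[i, ]
      l <- list(id = r$id, name = r$name, compartment = r$compartment,
                formula = if (is.na(r$formula)) NULL else r$formula,
                carbons = if (is.na(r$carbons)) NULL else r$carbons)
      l[!vapply(l, is.null, logical(1))]
    }),
    reactions = lapply(model$reactions, function(r) list(
      id = r$id, stoichiometry = as.list(r$stoich),
      lower_bound = r$lb, upper_bound = r$ub, gpr = r$gpr, kind = r$kind)),
    genes = as.list(model$genes))
  if (!is.null(model$annotation)) j$annotation <- model$annotation
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# ---- SBML Level 3 + fbc ----------------------------------------------------
# Hand-written serialisation on top of xml2: emits fbc version-2 flux bounds
# (as shared parameters), gene-product associations and an active objective.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

gpr_to_fbc <- function(rule, indent) {
  pad <- strrep(" ", indent)
  if (is.character(rule))
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                   pad, xml_escape(rule)))
  tag <- if (rule$op == "and") "fbc:and" else "fbc:or"
  inner <- vapply(rule$args, gpr_to_fbc, character(1), indent = indent + 2)
  paste0(pad, "<", tag, ' sboTerm="SBO:0000173">\n',
         paste(inner, collapse = "\n"), "\n", pad, "</", tag, ">")
}

write_model_sbml <- function(model, path) {
  bnds <- reaction_bounds(model)
  vals <- sort(unique(as.numeric(bnds)))
  pid <- stats::setNames(sprintf("bnd_%d", seq_along(vals)), sprintf("%.17g", vals))
  pref <- function(v) pid[[sprintf("%.17g", v)]]

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', xml_escape(model$id)),
    '    <listOfCompartments>')
  for (cmp in unique(model$metabolites$compartment))
    lines <- c(lines, sprintf('      <compartment id="%s" constant="true"/>',
                              xml_escape(cmp)))
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    formula <- mt$formula
    if (is.na(formula) && !is.na(mt$carbons)) formula <- sprintf("C%d", as.integer(mt$carbons))
    lines <- c(lines, sprintf(
      '      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
      xml_escape(mt$id), xml_escape(mt$name), xml_escape(mt$compartment),
      if (is.na(formula)) "" else sprintf(' fbc:chemicalFormula="%s"', xml_escape(formula))))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (k in seq_along(vals))
    lines <- c(lines, sprintf(
      '      <parameter id="bnd_%d" value="%s" constant="true"/>',
      k, format(vals[k], digits = 17)))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (r in model$reactions) {
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      xml_escape(r$id), if (r$lb < 0) "true" else "false", pref(r$lb), pref(r$ub)))
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    if (length(subs) > 0) {
      lines <- c(lines, '        <listOfReactants>')
      for (mi in names(subs))
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          xml_escape(mi), format(-subs[[mi]], digits = 17)))
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prods) > 0) {
      lines <- c(lines, '        <listOfProducts>')
      for (mi in names(prods))
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          xml_escape(mi), format(prods[[mi]], digits = 17)))
      lines <- c(lines, '        </listOfProducts>')
    }
    if (!is.null(r$rule)) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 gpr_to_fbc(r$rule, 10), '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             '        <fbc:listOfFluxObjectives>',
             sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                     xml_escape(model$objective)),
             '        </fbc:listOfFluxObjectives>',
             '      </fbc:objective>',
             '    </fbc:listOfObjectives>')
  if (length(model$genes) > 0) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>',
               vapply(model$genes, function(g) sprintf(
                 '      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                 xml_escape(g), xml_escape(g)), character(1)),
               '    </fbc:listOfGeneProducts>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
}

# namespace-agnostic attribute lookup (attributes may or may not carry the
# fbc prefix depending on the producing tool)
attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- names(at) == name | endsWith(names(at), paste0(":", name))
  if (any(hit)) at[[which(hit)[1]]] else NA_character_
}

find_local <- function(node, name)
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))

fbc_to_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") return(attr_any(node, "geneProduct"))
  kids <- xml2::xml_children(node)
  kids <- kids[xml2::xml_name(kids) %in% c("and", "or", "geneProductRef")]
  if (nm %in% c("and", "or"))
    return(list(op = nm, args = lapply(kids, fbc_to_gpr)))
  if (length(kids) == 1L) return(fbc_to_gpr(kids[[1]]))
  stop("cannot interpret gene association element <", nm, ">")
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)

  species <- find_local(doc, "species")
  boundary <- vapply(species, function(s)
    identical(attr_any(s, "boundaryCondition"), "true"), logical(1))
  mets <- do.call(rbind, lapply(species[!boundary], function(s) data.frame(
    id = attr_any(s, "id"),
    name = {n <- attr_any(s, "name"); if (is.na(n)) attr_any(s, "id") else n},
    compartment = {cp <- attr_any(s, "compartment"); if (is.na(cp)) "c" else cp},
    formula = attr_any(s, "chemicalFormula"),
    carbons = NA_real_, stringsAsFactors = FALSE)))
  boundary_ids <- vapply(species[boundary], attr_any, character(1), name = "id")

  pars <- find_local(doc, "parameter")
  pval <- stats::setNames(as.numeric(vapply(pars, attr_any, character(1), name = "value")),
                          vapply(pars, attr_any, character(1), name = "id"))
  bound_of <- function(node, which, default) {
    ref <- attr_any(node, which)
    if (!is.na(ref) && ref %in% names(pval)) return(pval[[ref]])
    if (!is.na(ref) && !is.na(suppressWarnings(as.numeric(ref))))
      return(as.numeric(ref))
    default
  }

  rnodes <- find_local(doc, "reaction")
  rxns <- lapply(rnodes, function(rn) {
    rid <- attr_any(rn, "id")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in find_local(rn, "speciesReference")) {
        # speciesReference nodes are shared between the two lists in this
        # flat scan; filter by parent list name
        if (xml2::xml_name(xml2::xml_parent(sr)) != side) next
        sp <- attr_any(sr, "species")
        if (sp %in% boundary_ids) next
        coef <- as.numeric(attr_any(sr, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0) + sgn * coef
      }
    }
    rev <- identical(attr_any(rn, "reversible"), "true")
    lb <- bound_of(rn, "lowerFluxBound", if (rev) -FLUX_BIG else 0)
    ub <- bound_of(rn, "upperFluxBound", FLUX_BIG)
    gpa <- find_local(rn, "geneProductAssociation")
    gpr <- if (length(gpa) > 0) deparse_gpr(fbc_to_gpr(gpa[[1]])) else ""
    list(id = rid, stoich = st, lb = lb, ub = ub, gpr = gpr)
  })

  fobj <- find_local(doc, "fluxObjective")
  if (length(fobj) == 0L)
    stop("no objective declared in ", sQuote(path))
  objective <- attr_any(fobj[[1]], "reaction")

  gp <- find_local(doc, "geneProduct")
  genes <- vapply(gp, function(g) {
    lb <- attr_any(g, "label")
    if (is.na(lb)) attr_any(g, "id") else lb
  }, character(1))

  mnode <- find_local(doc, "model")
  id <- if (length(mnode) > 0) attr_any(mnode[[1]], "id") else "model"
  metabolic_model(rxns, mets, objective = objective,
                  genes = if (length(genes)) genes else NULL,
                  id = if (is.na(id)) "model" else id)
}

# ---- flux tables -----------------------------------------------------------

#' Write a flux distribution as a two-column TSV
#' @param fluxes a `flux_distribution` or a named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(fluxes, path) {
  if (inherits(fluxes, "flux_distribution")) fluxes <- fluxes$fluxes
  utils::write.table(
    data.frame(reaction_id = names(fluxes), flux = as.numeric(fluxes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flux distribution from a two-column TSV
#' @param path file with header `reaction_id`, `flux`.
#' @return named numeric vector of fluxes.
#' @export
read_flux_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d$flux), d$reaction_id)
}
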