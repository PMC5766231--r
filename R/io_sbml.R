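# Minimal SBML Level 3 (FBC v2) support on top of xml2. Covers the subset a
# constraint-based workflow needs: species, reactions with stoichiometry,
# flux-bound parameters, fbc gene product associations (rendered back to
# and/or GPR strings) and groups as subsystem labels. Kinetic laws, units,
# rules and events are out of scope.

SBML_NS <- c(
  s = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  g = "http://www.sbml.org/sbml/level3/version1/groups/version1"
)

gpa_to_text <- function(node, gene_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    return(gene_label(ref))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, gpa_to_text, "", gene_label = gene_label)
  if (nm == "and") {
    paste(vapply(parts, function(p)
      if (grepl(" or ", p, fixed = TRUE)) paste0("(", p, ")") else p, ""),
      collapse = " and ")
  } else if (nm == "or") {
    paste(parts, collapse = " or ")
  } else if (length(parts) == 1) parts else
    stop("unsupported geneProductAssociation node: ", nm)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unreadable SBML file: ", path,
                                           " (", conditionMessage(e), ")"))
  mdl <- xml2::xml_find_first(doc, "//s:model", SBML_NS)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)

  params <- xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter", SBML_NS)
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))

  gps <- xml2::xml_find_all(doc, "//fbc:listOfGeneProducts/fbc:geneProduct", SBML_NS)
  gp_ids <- xml2::xml_attr(gps, "id")
  gp_labels <- xml2::xml_attr(gps, "label")
  gp_labels[is.na(gp_labels)] <- gp_ids[is.na(gp_labels)]
  gene_label <- function(ref) {
    i <- match(ref, gp_ids)
    if (is.na(i)) ref else gp_labels[i]
  }

  sp <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", SBML_NS)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  mets$compartment[is.na(mets$compartment)] <- "c"

  # groups -> subsystem per member reaction
  groups <- xml2::xml_find_all(doc, "//g:listOfGroups/g:group", SBML_NS)
  subsys <- character(0)
  for (grp in groups) {
    gname <- xml2::xml_attr(grp, "name")
    if (is.na(gname)) gname <- xml2::xml_attr(grp, "id")
    members <- xml2::xml_find_all(grp, ".//g:member", SBML_NS)
    refs <- xml2::xml_attr(members, "idRef")
    subsys[refs] <- gname
  }

  rnodes <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", SBML_NS)
  rxns <- do.call(rbind, lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    reac <- xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", SBML_NS)
    prod <- xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", SBML_NS)
    coef <- function(nodes, sign) {
      if (!length(nodes)) return(numeric(0))
      v <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      v[is.na(v)] <- 1
      setNames(sign * v, xml2::xml_attr(nodes, "species"))
    }
    st <- c(coef(reac, -1), coef(prod, +1))
    st <- tapply(st, names(st), sum) # merge duplicated species refs
    st <- setNames(as.numeric(st), names(st))
    lbp <- xml2::xml_attr(rn, "lowerFluxBound", ns = SBML_NS)
    ubp <- xml2::xml_attr(rn, "upperFluxBound", ns = SBML_NS)
    lb <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else
      if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation/*", SBML_NS)
    gpr <- if (inherits(gpa, "xml_missing")) "" else gpa_to_text(gpa, gene_label)
    data.frame(id = rid, lower_bound = lb, upper_bound = ub, reversible = rev,
               gpr = gpr,
               subsystem = if (rid %in% names(subsys)) subsys[[rid]] else "",
               stoich = I(list(st)), stringsAsFactors = FALSE)
  }))
  mid <- xml2::xml_attr(mdl, "id")
  metabolic_model(mets, rxns, id = if (is.na(mid)) "model" else mid)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

gpr_to_gpa_xml <- function(rule) {
  if (!is.null(rule$gene))
    return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>',
                   xml_escape(gene_to_sid(rule$gene))))
  inner <- paste(vapply(rule$children, gpr_to_gpa_xml, ""), collapse = "")
  sprintf("<fbc:%s>%s</fbc:%s>", rule$op, inner, rule$op)
}

gene_to_sid <- function(g) paste0("G_", gsub("[^A-Za-z0-9_]", "_", g))

write_model_sbml <- function(model, path) {
  rx <- model$reactions
  # bound parameters, deduplicated by value
  vals <- sort(unique(c(rx$lower_bound, rx$upper_bound)))
  fmt1 <- function(v) vapply(v, function(x) format(x, digits = 17), "")
  pid <- setNames(sprintf("fb_%d", seq_along(vals)), fmt1(vals))
  pref <- function(v) pid[[fmt1(v)]]
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" xmlns:groups="%s" level="3"',
                   ' version="1" fbc:required="false" groups:required="false">'),
            SBML_NS[["s"]], SBML_NS[["fbc"]], SBML_NS[["g"]]),
    sprintf('<model id="%s" fbc:strict="true">', xml_escape(model$id)),
    '<listOfCompartments>',
    sprintf('<compartment id="%s" constant="true"/>',
            unique(model$metabolites$compartment)),
    '</listOfCompartments>',
    '<listOfSpecies>',
    sprintf(paste0('<species id="%s" name="%s" compartment="%s"',
                   ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
                   ' constant="false"/>'),
            xml_escape(model$metabolites$id), xml_escape(model$metabolites$name),
            xml_escape(model$metabolites$compartment)),
    '</listOfSpecies>',
    '<listOfParameters>',
    sprintf('<parameter id="%s" value="%s" constant="true"/>',
            pid, fmt1(vals)),
    '</listOfParameters>')

  genes <- unique(unlist(lapply(rx$gpr[nzchar(rx$gpr)],
                                function(g) gpr_genes(parse_gpr(g)))))
  if (length(genes)) {
    lines <- c(lines, '<fbc:listOfGeneProducts>',
               sprintf('<fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                       vapply(genes, gene_to_sid, ""), xml_escape(genes)),
               '</fbc:listOfGeneProducts>')
  }

  lines <- c(lines, '<listOfReactions>')
  for (k in seq_len(nrow(rx))) {
    st <- rx$stoich[[k]]
    subs <- st[st < 0]
    prods <- st[st > 0]
    lines <- c(lines, sprintf(
      paste0('<reaction id="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      xml_escape(rx$id[k]), if (rx$reversible[k]) "true" else "false",
      pref(rx$lower_bound[k]), pref(rx$upper_bound[k])))
    if (nzchar(rx$gpr[k]))
      lines <- c(lines, '<fbc:geneProductAssociation>',
                 gpr_to_gpa_xml(parse_gpr(rx$gpr[k])),
                 '</fbc:geneProductAssociation>')
    if (length(subs))
      lines <- c(lines, '<listOfReactants>',
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         xml_escape(names(subs)), fmt1(-unname(subs))),
                 '</listOfReactants>')
    if (length(prods))
      lines <- c(lines, '<listOfProducts>',
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         xml_escape(names(prods)), fmt1(unname(prods))),
                 '</listOfProducts>')
    lines <- c(lines, '</reaction>')
  }
  lines <- c(lines, '</listOfReactions>')

  subsys <- unique(rx$subsystem[nzchar(rx$subsystem)])
  if (length(subsys)) {
    lines <- c(lines, '<groups:listOfGroups>')
    for (i in seq_along(subsys)) {
      members <- rx$id[rx$subsystem == subsys[i]]
      lines <- c(lines,
                 sprintf('<groups:group groups:id="sg_%d" groups:name="%s" groups:kind="partonomy">',
                         i, xml_escape(subsys[i])),
                 '<groups:listOfMembers>',
                 sprintf('<groups:member groups:idRef="%s"/>', xml_escape(members)),
                 '</groups:listOfMembers>', '</groups:group>')
    }
    lines <- c(lines, '</groups:listOfGroups>')
  }
  lines <- c(lines, '</model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
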