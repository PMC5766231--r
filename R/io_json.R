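# The json_toy dialect: a light JSON serialization for small models, used for
# fixtures and study bundles. Layout:
# {
#   "id": "...", "description": "...",
#   "metabolites": [{"id": "A", "name": "A", "compartment": "c"}, ...],
#   "reactions": [{"id": "R1", "stoich": {"A": -1, "B": 1},
#                  "lower_bound": 0, "upper_bound": 1000,
#                  "reversible": false, "gpr": "g1 and g2",
#                  "subsystem": "chain1", "exchange": false}, ...]
# }

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("not a json_toy model file (missing metabolites/reactions): ", path)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "c" else m$compartment,
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    st <- unlist(r$stoich)
    data.frame(id = r$id,
               lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               reversible = isTRUE(r$reversible),
               gpr = if (is.null(r$gpr)) "" else r$gpr,
               subsystem = if (is.null(r$subsystem)) "" else r$subsystem,
               is_exchange = if (is.null(r$exchange)) length(st) == 1L
                             else isTRUE(r$exchange),
               stoich = I(list(st)),
               stringsAsFactors = FALSE)
  }))
  metabolic_model(mets, rxns,
                  id = if (is.null(doc$id)) "model" else doc$id)
}

write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      as.list(model$metabolites[i, c("id", "name", "compartment")])
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      list(id = r$id, stoich = as.list(r$stoich[[1]]),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           reversible = r$reversible, gpr = r$gpr, subsystem = r$subsystem,
           exchange = r$is_exchange)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a constraint-based model
#'
#' Supported dialects: SBML Level 3 with the FBC extension (flux bounds, gene
#' product associations, groups as subsystems) and the package's `json_toy`
#' JSON dialect for small fixture models. GPR strings and subsystem labels are
#' preserved verbatim; a reaction without a gene association gets an empty GPR
#' string.
#'
#' @param path file path.
#' @param format `"sbml"`, `"json_toy"`, or `"auto"` (by file extension).
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "json_toy")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "json_toy"
  switch(format, sbml = read_model_sbml(path), json_toy = read_model_json(path))
}

#' Write a constraint-based model
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"sbml"`, `"json_toy"`, or `"auto"` (by file extension).
#' @return the path, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json_toy")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "json_toy"
  switch(format, sbml = write_model_sbml(model, path),
         json_toy = write_model_json(model, path))
}
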