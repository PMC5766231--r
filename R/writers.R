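# Plain-text result writers (TSV/JSON), matching the package's external
# interfaces: reaction tables, FVA results, classifications, activity calls,
# differential sets and validation summaries.

#' Write a reaction table
#'
#' @param model a `metabolic_model`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_reaction_table <- function(model, path) {
  rx <- model$reactions
  write.table(data.frame(id = rx$id, lower_bound = rx$lower_bound,
                         upper_bound = rx$upper_bound,
                         subsystem = rx$subsystem, gpr = rx$gpr),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an FVA result with blocked flags
#'
#' @param fva data.frame from [flux_variability()].
#' @param path output TSV path.
#' @param tol blockedness tolerance, see [find_blocked()].
#' @return the path, invisibly.
#' @export
write_fva <- function(fva, path, tol = 1e-9) {
  fva$blocked <- fva$id %in% find_blocked(fva, tol)
  write.table(fva, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reaction classification
#'
#' @param classification a `reaction_classification`.
#' @param table the reaction-expression table it was computed from.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_classification <- function(classification, table, path) {
  cls <- setNames(rep("moderate", length(table)), names(table))
  cls[classification$R_H] <- "high"
  cls[classification$R_L] <- "low"
  write.table(data.frame(id = names(table), expression = unname(table),
                         class = unname(cls)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write activity calls
#'
#' @param calls an `activity_calls` data.frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_activity_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a differential-activity result
#'
#' Writes the condition-specific reactions (TSV: reaction, condition) and, if
#' present, per-pathway counts alongside (suffix `_pathways.tsv`).
#'
#' @param diff a `differential_activity` object.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_differential <- function(diff, path) {
  tab <- rbind(
    if (length(diff$specific_to_A))
      data.frame(reaction = diff$specific_to_A, condition = "A"),
    if (length(diff$specific_to_B))
      data.frame(reaction = diff$specific_to_B, condition = "B"))
  if (is.null(tab)) tab <- data.frame(reaction = character(0),
                                      condition = character(0))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(diff$pathway_counts))
    write.table(diff$pathway_counts,
                sub("\\.tsv$", "_pathways.tsv", path),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an exchange-validation result as JSON
#'
#' @param validation an `exchange_validation` object.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_validation <- function(validation, path) {
  jsonlite::write_json(
    list(contingency = unclass(validation$contingency),
         true_positive_rate = validation$true_positive_rate,
         fisher_p = validation$fisher_p,
         n_undetermined = validation$n_undetermined),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read measured-exchange labels from TSV
#'
#' Expected columns: `metabolite`, `direction` (uptake/secretion), `status`
#' (active/inactive).
#'
#' @param path TSV file path.
#' @return data.frame usable with [validate_exchanges()].
#' @export
read_measured_exchanges <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite", "direction", "status") %in% names(tab)))
  tab
}
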