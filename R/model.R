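# Constraint-based model container and structural transformations.

#' Construct a constraint-based metabolic model
#'
#' The central container of the package: metabolites, reactions with
#' stoichiometry, flux bounds, reversibility, gene-protein-reaction (GPR)
#' rules, subsystem (pathway) labels and exchange flags. Steady-state analysis
#' operates on the implied stoichiometric matrix `S` (metabolites x
#' reactions), under `S v = 0` with `lower_bound <= v <= upper_bound`.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `reversible`, `gpr`, `subsystem` and a list column
#'   `stoich` of named numeric vectors (negative coefficient = substrate).
#'   An optional logical column `is_exchange` marks boundary reactions; when
#'   absent, reactions touching exactly one metabolite are flagged as
#'   exchanges.
#' @param id optional model identifier.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("id", "name", "compartment"))
    if (is.null(metabolites[[col]])) stop("metabolites lack column '", col, "'")
  for (col in c("id", "lower_bound", "upper_bound", "stoich"))
    if (is.null(reactions[[col]])) stop("reactions lack column '", col, "'")
  if (is.null(reactions$reversible)) reactions$reversible <- reactions$lower_bound < 0
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  if (is.null(reactions$is_exchange))
    reactions$is_exchange <- vapply(reactions$stoich, length, 1L) == 1L
  model <- structure(list(id = id, metabolites = metabolites,
                          reactions = reactions),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, stoichiometry references, bound ordering, non-empty
#' compartments and the single-metabolite property of exchange reactions.
#' Errors name the offending entity.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly, if valid.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite id: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id))
    stop("duplicate reaction id: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  if (any(!nzchar(mets$compartment)))
    stop("empty compartment for metabolite: ",
         paste(mets$id[!nzchar(mets$compartment)], collapse = ", "))
  bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(bad))
    stop("lower_bound > upper_bound for reaction: ", paste(bad, collapse = ", "))
  for (k in seq_len(nrow(rxns))) {
    st <- rxns$stoich[[k]]
    if (!length(st)) stop("reaction ", rxns$id[k], " has empty stoichiometry")
    dangling <- setdiff(names(st), mets$id)
    if (length(dangling))
      stop("reaction ", rxns$id[k], " references unknown metabolite: ",
           paste(dangling, collapse = ", "))
    if (rxns$is_exchange[k] && length(st) != 1L)
      stop("exchange reaction ", rxns$id[k], " must touch exactly one metabolite")
  }
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites in rows, reactions in columns.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (k in seq_along(rxns)) {
    st <- model$reactions$stoich[[k]]
    S[names(st), k] <- st
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "'\n", sep = "")
  cat("  metabolites:", nrow(x$metabolites), "\n")
  cat("  reactions:  ", nrow(x$reactions),
      sprintf("(%d exchange, %d reversible)\n",
              sum(x$reactions$is_exchange), sum(x$reactions$reversible)))
  subs <- unique(x$reactions$subsystem)
  subs <- subs[nzchar(subs)]
  if (length(subs))
    cat("  subsystems: ", paste(head(subs, 5), collapse = ", "),
        if (length(subs) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Convert a model to irreversible form
#'
#' Every reaction with a negative lower bound is rewritten in non-negative
#' direction(s): a genuinely two-sided reaction with bounds `[a < 0, b > 0]`
#' is split into a forward copy (`_fwd`, bounds `[0, b]`) and a backward copy
#' (`_bwd`, bounds `[0, -a]`, negated stoichiometry); a backward-only reaction
#' (`b <= 0`) becomes a single `_bwd` reaction with bounds `[max(0,-b), -a]`.
#' GPR and subsystem annotations are copied to both directions. The activity
#' MILP requires this form, as does flux variability analysis as used here.
#'
#' @param model a `metabolic_model`.
#' @return list with the converted `model` and `mapping`, a named list from
#'   each original reaction id to the one or two reaction ids it produced.
#' @export
to_irreversible <- function(model) {
  validate_model(model)
  rx <- model$reactions
  out <- vector("list", nrow(rx))
  mapping <- vector("list", nrow(rx))
  names(mapping) <- rx$id
  for (k in seq_len(nrow(rx))) {
    r <- rx[k, ]
    a <- r$lower_bound
    b <- r$upper_bound
    if (a >= 0) {
      r$reversible <- FALSE
      out[[k]] <- r
      mapping[[k]] <- r$id
    } else if (b <= 0) {
      # runs backward only: flip orientation
      r2 <- r
      r2$id <- paste0(r$id, "_bwd")
      r2$stoich <- list(-r$stoich[[1]])
      r2$lower_bound <- max(0, -b)
      r2$upper_bound <- -a
      r2$reversible <- FALSE
      out[[k]] <- r2
      mapping[[k]] <- r2$id
    } else {
      fw <- r
      fw$id <- paste0(r$id, "_fwd")
      fw$lower_bound <- 0
      fw$upper_bound <- b
      fw$reversible <- FALSE
      bw <- r
      bw$id <- paste0(r$id, "_bwd")
      bw$stoich <- list(-r$stoich[[1]])
      bw$lower_bound <- 0
      bw$upper_bound <- -a
      bw$reversible <- FALSE
      out[[k]] <- rbind(fw, bw)
      mapping[[k]] <- c(fw$id, bw$id)
    }
  }
  reactions <- do.call(rbind, out)
  rownames(reactions) <- NULL
  m2 <- metabolic_model(model$metabolites, reactions, id = model$id)
  list(model = m2, mapping = mapping)
}

# Exchange reactions touching a metabolite, with direction under the package
# convention: secretion consumes the metabolite (coefficient < 0), uptake
# produces it (coefficient > 0).
exchange_reactions_for <- function(model, metabolite,
                                   direction = c("any", "secretion", "uptake")) {
  direction <- match.arg(direction)
  rx <- model$reactions
  hit <- character(0)
  for (k in which(rx$is_exchange)) {
    st <- rx$stoich[[k]]
    if (!identical(names(st), metabolite)) next
    if (direction == "secretion" && st >= 0) next
    if (direction == "uptake" && st <= 0) next
    hit <- c(hit, rx$id[k])
  }
  hit
}

#' Force measured exchange reactions to stay active during reduction
#'
#' Before blocked-reaction detection, every exchange reaction touching an
#' experimentally measured metabolite gets its bounds fixed to
#' `[min_magnitude, max_magnitude]` (both directions of a split exchange), so
#' it must carry flux of at least `min_magnitude` and can never be classified
#' as blocked. Original bounds are recorded and restored with
#' [restore_exchange_bounds()] before activity inference.
#'
#' @param model an irreversible `metabolic_model`.
#' @param measured_metabolites character vector of metabolite ids.
#' @param min_magnitude,max_magnitude forced bounds, flux units; defaults
#'   0.001 and 1000.
#' @return the model with modified bounds and an attribute recording the
#'   original ones.
#' @export
force_measured_exchanges <- function(model, measured_metabolites,
                                     min_magnitude = 0.001,
                                     max_magnitude = 1000) {
  if (any(model$reactions$lower_bound < 0))
    stop("force_measured_exchanges expects an irreversible model")
  if (!length(measured_metabolites)) return(model)
  rx_ids <- character(0)
  missing <- character(0)
  for (m in measured_metabolites) {
    hit <- exchange_reactions_for(model, m)
    if (!length(hit)) missing <- c(missing, m) else rx_ids <- c(rx_ids, hit)
  }
  if (length(missing))
    stop("measured metabolite(s) with no exchange reaction: ",
         paste(missing, collapse = ", "))
  idx <- match(unique(rx_ids), model$reactions$id)
  orig <- data.frame(id = model$reactions$id[idx],
                     lower_bound = model$reactions$lower_bound[idx],
                     upper_bound = model$reactions$upper_bound[idx],
                     stringsAsFactors = FALSE)
  model$reactions$lower_bound[idx] <- min_magnitude
  model$reactions$upper_bound[idx] <- max_magnitude
  attr(model, "forced_bounds") <- orig
  model
}

#' Restore exchange bounds modified by [force_measured_exchanges()]
#'
#' @param model a model carrying the `forced_bounds` attribute.
#' @return the model with original bounds, bit-identical to the input of the
#'   forcing step.
#' @export
restore_exchange_bounds <- function(model) {
  orig <- attr(model, "forced_bounds")
  if (is.null(orig)) return(model)
  idx <- match(orig$id, model$reactions$id)
  keep <- !is.na(idx) # forced reactions may have been reduced away
  model$reactions$lower_bound[idx[keep]] <- orig$lower_bound[keep]
  model$reactions$upper_bound[idx[keep]] <- orig$upper_bound[keep]
  attr(model, "forced_bounds") <- NULL
  model
}
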