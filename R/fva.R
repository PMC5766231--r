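# Flux variability analysis and blocked-reaction model reduction.

fba_constraints <- function(model) {
  S <- stoich_matrix(model)
  list(A = S, rel = rep("=", nrow(S)), rhs = rep(0, nrow(S)),
       lb = model$reactions$lower_bound, ub = model$reactions$upper_bound)
}

#' Flux variability analysis
#'
#' For every reaction, minimizes and maximizes its steady-state flux over
#' `{v : S v = 0, lb <= v <= ub}` by two linear programs. The model must be
#' irreversible (all lower bounds >= 0) as produced by [to_irreversible()].
#'
#' @param model an irreversible `metabolic_model`.
#' @return data.frame with columns `id`, `min_flux`, `max_flux`, `feasible`.
#' @export
flux_variability <- function(model) {
  if (any(model$reactions$lower_bound < 0))
    stop("flux_variability expects an irreversible model")
  con <- fba_constraints(model)
  m <- ncol(con$A)
  if (!lp_feasible(con$A, con$rel, con$rhs, con$lb, con$ub))
    stop("model admits no steady-state flux distribution at all")
  res <- data.frame(id = model$reactions$id,
                    min_flux = NA_real_, max_flux = NA_real_,
                    feasible = TRUE, stringsAsFactors = FALSE)
  obj <- rep(0, m)
  for (k in seq_len(m)) {
    obj[k] <- 1
    lo <- lp_solve(obj, con$A, con$rel, con$rhs, con$lb, con$ub, maximize = FALSE)
    hi <- lp_solve(obj, con$A, con$rel, con$rhs, con$lb, con$ub, maximize = TRUE)
    obj[k] <- 0
    if (lo$status != "optimal" || hi$status != "optimal") {
      res$feasible[k] <- FALSE
    } else {
      res$min_flux[k] <- lo$objective
      res$max_flux[k] <- hi$objective
    }
  }
  res
}

#' Identify blocked reactions from an FVA result
#'
#' A reaction is blocked when it cannot carry flux in any steady state:
#' both its minimal and maximal flux are within `tol` of zero (or its LPs
#' were infeasible).
#'
#' @param fva data.frame from [flux_variability()].
#' @param tol numeric tolerance on LP optima (default `1e-9`, the solver
#'   noise floor).
#' @return character vector of blocked reaction ids.
#' @export
find_blocked <- function(fva, tol = 1e-9) {
  blocked <- !fva$feasible |
    (abs(fva$min_flux) <= tol & abs(fva$max_flux) <= tol)
  blocked[is.na(blocked)] <- TRUE
  fva$id[blocked]
}

#' Remove blocked reactions and orphaned metabolites
#'
#' Drops the given reactions, then every metabolite that is neither substrate
#' nor product of any remaining reaction.
#'
#' @param model a `metabolic_model`.
#' @param blocked character vector of reaction ids to remove (typically from
#'   [find_blocked()]).
#' @return the reduced `metabolic_model`.
#' @export
reduce_model <- function(model, blocked) {
  unknown <- setdiff(blocked, model$reactions$id)
  if (length(unknown))
    stop("blocked set contains unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  if (!length(blocked)) return(model)
  rx <- model$reactions[!(model$reactions$id %in% blocked), , drop = FALSE]
  used <- unique(unlist(lapply(rx$stoich, names)))
  mets <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  rownames(rx) <- NULL
  rownames(mets) <- NULL
  out <- metabolic_model(mets, rx, id = model$id)
  attr(out, "forced_bounds") <- attr(model, "forced_bounds")
  out
}

#' Reduce a model for activity inference
#'
#' The full reduction recipe: force the exchange reactions of measured
#' metabolites to be active ([force_measured_exchanges()]) so they can never
#' be classified blocked, run FVA, find blocked reactions, restore the
#' original exchange bounds, and remove blocked reactions plus orphaned
#' metabolites.
#'
#' @param model an irreversible `metabolic_model`.
#' @param measured_metabolites metabolite ids with experimental
#'   consumption/production measurements (may be empty).
#' @param tol blockedness tolerance, see [find_blocked()].
#' @return list with `model` (reduced), `blocked` (removed reaction ids) and
#'   `fva` (the FVA table).
#' @export
reduce_pipeline <- function(model, measured_metabolites = character(0),
                            tol = 1e-9) {
  forced <- force_measured_exchanges(model, measured_metabolites)
  fva <- flux_variability(forced)
  blocked <- find_blocked(fva, tol = tol)
  restored <- restore_exchange_bounds(forced)
  list(model = reduce_model(restored, blocked), blocked = blocked, fva = fva)
}
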