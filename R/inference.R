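# Per-reaction activity calls by sensitivity analysis, robustness consensus
# across threshold sets, two-condition differential activity, and qualitative
# validation of predicted exchange fluxes.

#' Sensitivity-based activity call for one reaction
#'
#' Solves two MILPs: one with the reaction forced active (flux >= epsilon)
#' and one forced inactive (zero flux). The reaction is ACTIVE when agreement
#' with expression is strictly higher under forced activation, INACTIVE when
#' strictly higher under forced inactivation, and UNDETERMINED on a tie
#' (alternative optima exist either way). An infeasible forcing is recorded
#' as objective `-Inf`, so a reaction that cannot carry epsilon flux is
#' always INACTIVE.
#'
#' @param problem an `imat_problem`.
#' @param reaction a reaction id of the problem's model.
#' @return list with `reaction`, `state`, `obj_forced_active`,
#'   `obj_forced_inactive`.
#' @export
sensitivity_call <- function(problem, reaction) {
  if (!(reaction %in% problem$model$reactions$id))
    stop("unknown reaction: ", reaction)
  force_and_solve <- function(kind) {
    ex <- problem$extra_constraints
    ex[reaction] <- kind
    solve_imat(imat_problem(problem$model, problem$classification,
                            epsilon = problem$epsilon,
                            extra_constraints = ex))$objective
  }
  oa <- force_and_solve("fixed-active")
  oi <- force_and_solve("fixed-inactive")
  if (is.infinite(oa) && is.infinite(oi))
    stop("model inconsistency: reaction ", reaction,
         " is infeasible both forced active and forced inactive")
  state <- if (oa > oi) "ACTIVE" else if (oa < oi) "INACTIVE" else "UNDETERMINED"
  list(reaction = reaction, state = state,
       obj_forced_active = oa, obj_forced_inactive = oi)
}

#' Activity calls for many reactions
#'
#' Applies [sensitivity_call()] per reaction. With `shortcut = TRUE`
#' (default) the unconstrained optimum is solved once and its flux vector
#' used as a witness: a reaction carrying flux >= epsilon there already
#' attains the optimum under forced activation, so only the opposite forcing
#' needs a solve (and symmetrically for zero flux). This halves the MILP
#' count and is mathematically exact; `shortcut = FALSE` always solves both
#' forcings. Results do not depend on iteration order.
#'
#' @param problem an `imat_problem`.
#' @param reactions reaction ids to classify (default: all model reactions).
#' @param shortcut reuse the unconstrained optimum as a one-sided witness.
#' @return data.frame with columns `id`, `state`, `obj_active`,
#'   `obj_inactive`, of class `activity_calls`.
#' @export
classify_all <- function(problem, reactions = NULL, shortcut = TRUE) {
  if (is.null(reactions)) reactions <- problem$model$reactions$id
  base <- if (shortcut) solve_imat(problem) else NULL
  eps <- problem$epsilon
  rows <- lapply(reactions, function(r) {
    if (shortcut && base$status == "optimal") {
      vr <- base$v[[r]]
      solve_forced <- function(kind) {
        ex <- problem$extra_constraints
        ex[r] <- kind
        solve_imat(imat_problem(problem$model, problem$classification,
                                epsilon = eps, extra_constraints = ex))$objective
      }
      if (vr >= eps - 1e-6) {
        oa <- base$objective
        oi <- solve_forced("fixed-inactive")
      } else if (abs(vr) <= 1e-6) {
        oi <- base$objective
        oa <- solve_forced("fixed-active")
      } else {
        oa <- solve_forced("fixed-active")
        oi <- solve_forced("fixed-inactive")
      }
      state <- if (oa > oi) "ACTIVE" else if (oa < oi) "INACTIVE" else "UNDETERMINED"
      data.frame(id = r, state = state, obj_active = oa, obj_inactive = oi,
                 stringsAsFactors = FALSE)
    } else {
      s <- sensitivity_call(problem, r)
      data.frame(id = r, state = s$state, obj_active = s$obj_forced_active,
                 obj_inactive = s$obj_forced_inactive, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("activity_calls", class(out))
  out
}

# Named state vector from an activity_calls data.frame (or pass-through).
states_of <- function(calls) {
  if (is.data.frame(calls)) setNames(calls$state, calls$id)
  else calls
}

#' Threshold-robustness consensus of activity calls
#'
#' Classifies the expression table at each threshold pair, runs the
#' sensitivity analysis for each, and keeps a reaction's state only when it
#' is identical across every pair: ACTIVE (or INACTIVE) independently of the
#' thresholds, otherwise UNDETERMINED.
#'
#' @param model an irreversible, reduced `metabolic_model`.
#' @param table reaction-expression table for one condition
#'   ([reaction_expression()]).
#' @param threshold_pairs list of `c(lower, upper)` percentile pairs;
#'   default `list(c(25, 75), c(33, 66), c(40, 60))`.
#' @param epsilon activity flux threshold, default 1.
#' @param reactions reactions to call (default all).
#' @return list with `consensus` (named state vector) and `per_pair` (list of
#'   `activity_calls` keyed by "lower/upper").
#' @export
robustness_consensus <- function(model, table,
                                 threshold_pairs = list(c(25, 75), c(33, 66),
                                                        c(40, 60)),
                                 epsilon = 1, reactions = NULL) {
  if (!length(threshold_pairs)) stop("need at least one threshold pair")
  per_pair <- lapply(threshold_pairs, function(tp) {
    cls <- classify_reactions(table, tp)
    classify_all(imat_problem(model, cls, epsilon = epsilon), reactions)
  })
  names(per_pair) <- vapply(threshold_pairs,
                            function(tp) paste(tp, collapse = "/"), "")
  mats <- vapply(per_pair, states_of,
                 character(nrow(per_pair[[1]])))
  if (is.null(dim(mats))) mats <- matrix(mats, nrow = 1)
  consensus <- apply(mats, 1, function(s)
    if (all(s == s[1]) && s[1] != "UNDETERMINED") s[1] else "UNDETERMINED")
  names(consensus) <- per_pair[[1]]$id
  list(consensus = consensus, per_pair = per_pair)
}

#' Differential reaction activity between two conditions
#'
#' A reaction is specific to one condition when its activity state is
#' unambiguously different: ACTIVE there and INACTIVE in the other condition.
#' Reactions UNDETERMINED in either condition are excluded. Counts are
#' aggregated per subsystem (pathway).
#'
#' @param calls_A,calls_B `activity_calls` data.frames or named state vectors
#'   over the same reaction universe.
#' @param subsystems named character vector mapping reaction ids to subsystem
#'   labels (e.g. `setNames(model$reactions$subsystem, model$reactions$id)`).
#' @return object of class `differential_activity`: `specific_to_A`,
#'   `specific_to_B`, and `pathway_counts` (data.frame subsystem / count_A /
#'   count_B).
#' @export
differential_activity <- function(calls_A, calls_B, subsystems = NULL) {
  a <- states_of(calls_A)
  b <- states_of(calls_B)
  if (!setequal(names(a), names(b)))
    stop("the two conditions cover different reaction universes")
  b <- b[names(a)]
  sp_a <- names(a)[a == "ACTIVE" & b == "INACTIVE"]
  sp_b <- names(a)[a == "INACTIVE" & b == "ACTIVE"]
  counts <- NULL
  if (!is.null(subsystems)) {
    subs <- sort(unique(subsystems[c(sp_a, sp_b)]))
    counts <- data.frame(
      subsystem = subs,
      count_A = vapply(subs, function(s) sum(subsystems[sp_a] == s), 0L),
      count_B = vapply(subs, function(s) sum(subsystems[sp_b] == s), 0L),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(specific_to_A = sp_a, specific_to_B = sp_b,
                 pathway_counts = counts),
            class = "differential_activity")
}

#' @export
print.differential_activity <- function(x, ...) {
  cat("Differential activity:",
      length(x$specific_to_A), "reactions specific to A,",
      length(x$specific_to_B), "to B\n")
  if (!is.null(x$pathway_counts) && nrow(x$pathway_counts)) {
    cat("Per-pathway counts:\n")
    print(x$pathway_counts, row.names = FALSE)
  }
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on the margins, sums the hypergeometric probabilities of all
#' tables at most as probable as the observed one (the classical two-sided
#' rule, as in [stats::fisher.test()], which performs the computation).
#' Degenerate tables with a zero margin admit only one configuration and get
#' p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  fisher.test(table)$p.value
}

#' Validate predicted exchange activity against measurements
#'
#' Compares the predicted activity states of exchange-direction reactions
#' with qualitatively measured consumption/production of metabolites. Under
#' the package's direction convention an exchange reaction consuming its
#' metabolite is a secretion and one producing it is an uptake. Builds the
#' 2x2 contingency table predicted x measured over the measured entries
#' (UNDETERMINED predictions are excluded and counted), the true positive
#' rate TP / (TP + FN) with "measured active" as positive class, and the
#' two-sided Fisher exact p-value.
#'
#' @param calls `activity_calls` or named state vector covering the exchange
#'   reactions.
#' @param measured data.frame with columns `metabolite`, `direction`
#'   (`"uptake"` or `"secretion"`) and `status` (`"active"` or `"inactive"`).
#' @param model the `metabolic_model` the calls refer to (used to map
#'   metabolite/direction pairs to exchange reactions).
#' @return object of class `exchange_validation`: `contingency`,
#'   `true_positive_rate`, `fisher_p`, `n_undetermined`, `mapping`.
#' @export
validate_exchanges <- function(calls, measured, model) {
  states <- states_of(calls)
  stopifnot(all(c("metabolite", "direction", "status") %in% names(measured)))
  if (!all(measured$direction %in% c("uptake", "secretion")))
    stop("direction must be 'uptake' or 'secretion'")
  if (!all(measured$status %in% c("active", "inactive")))
    stop("status must be 'active' or 'inactive'")
  rxn <- character(nrow(measured))
  unmapped <- character(0)
  for (k in seq_len(nrow(measured))) {
    hit <- exchange_reactions_for(model, measured$metabolite[k],
                                  measured$direction[k])
    hit <- intersect(hit, names(states))
    if (!length(hit)) {
      unmapped <- c(unmapped,
                    paste0(measured$metabolite[k], "/", measured$direction[k]))
      next
    }
    rxn[k] <- hit[1]
  }
  if (length(unmapped))
    stop("measured entries with no mapped exchange reaction: ",
         paste(unmapped, collapse = ", "))
  predicted <- states[rxn]
  keep <- predicted != "UNDETERMINED"
  tab <- matrix(0L, 2, 2,
                dimnames = list(predicted = c("active", "inactive"),
                                measured = c("active", "inactive")))
  for (k in which(keep)) {
    i <- if (predicted[k] == "ACTIVE") 1L else 2L
    j <- if (measured$status[k] == "active") 1L else 2L
    tab[i, j] <- tab[i, j] + 1L
  }
  tp <- tab[1, 1]
  fn <- tab[2, 1]
  structure(list(contingency = tab,
                 true_positive_rate = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 fisher_p = fisher_exact(tab),
                 n_undetermined = sum(!keep),
                 mapping = data.frame(metabolite = measured$metabolite,
                                      direction = measured$direction,
                                      reaction = rxn,
                                      predicted = unname(predicted),
                                      measured = measured$status,
                                      stringsAsFactors = FALSE)),
            class = "exchange_validation")
}

#' @export
print.exchange_validation <- function(x, ...) {
  cat("Exchange-flux validation (", sum(x$contingency), " comparable entries, ",
      x$n_undetermined, " undetermined excluded)\n", sep = "")
  print(x$contingency)
  cat(sprintf("true positive rate: %.3f   Fisher exact p: %.4g\n",
              x$true_positive_rate, x$fisher_p))
  invisible(x)
}

#' Hypergeometric enrichment of condition-specific reactions per pathway
#'
#' For each subsystem, tests whether the condition-specific reactions are
#' over-represented among its members (one-sided hypergeometric test,
#' Benjamini-Hochberg adjusted). This is an optional convenience summary of
#' [differential_activity()] results; it is this package's own choice of
#' enrichment procedure.
#'
#' @param specific character vector of condition-specific reaction ids.
#' @param subsystems named character vector reaction id -> subsystem over the
#'   full reaction universe.
#' @return data.frame subsystem / n_subsystem / n_specific / p / p_adj.
#' @export
pathway_enrichment <- function(specific, subsystems) {
  subs <- sort(unique(subsystems))
  n <- length(subsystems)
  k <- length(specific)
  rows <- lapply(subs, function(s) {
    in_s <- names(subsystems)[subsystems == s]
    q <- length(intersect(specific, in_s))
    p <- phyper(q - 1, length(in_s), n - length(in_s), k, lower.tail = FALSE)
    data.frame(subsystem = s, n_subsystem = length(in_s), n_specific = q,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
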