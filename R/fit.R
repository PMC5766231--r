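# The modelling front-end: imat() runs the whole inference for one condition
# and returns a fitted object with the usual methods.

#' Fit context-specific reaction activity to expression data
#'
#' The full single-condition pipeline: convert the model to irreversible
#' form, reduce it by removing blocked reactions (with measured exchanges
#' protected from blocking), map gene expression onto reactions through the
#' GPR rules, partition reactions into highly / lowly expressed sets at the
#' percentile thresholds, solve the activity MILP, and (by default) call
#' per-reaction activity states by sensitivity analysis. Optionally a
#' threshold-robustness consensus over several threshold pairs is computed.
#'
#' @param model a `metabolic_model` (any reversibility; converted
#'   internally).
#' @param expression an `expression_profile`, or a named numeric vector of
#'   gene levels (one value per gene).
#' @param thresholds percentile pair `c(lower, upper)`, default `c(33, 66)`.
#' @param epsilon minimum flux for a reaction to count as active, default 1.
#' @param measured_metabolites metabolite ids whose exchanges must survive
#'   reduction (and can be validated later with [validate_exchanges()]).
#' @param reduce run blocked-reaction removal first (default TRUE).
#' @param sensitivity compute per-reaction activity calls (default TRUE).
#' @param consensus_sets optional list of threshold pairs for a robustness
#'   consensus, e.g. `list(c(25, 75), c(33, 66), c(40, 60))`.
#' @return an object of class `imat_fit`.
#' @export
#' @examples
#' fx <- make_fig5_fixture()
#' fit <- imat(fx$model, fx$expression)
#' fit
#' activity_states(fit)[c("EX_Met_G", "EX_Met_H", "EX_Met_I")]
imat <- function(model, expression, thresholds = c(33, 66), epsilon = 1,
                 measured_metabolites = character(0), reduce = TRUE,
                 sensitivity = TRUE, consensus_sets = NULL) {
  cl <- match.call()
  irr <- to_irreversible(model)
  work <- irr$model
  blocked <- character(0)
  fva <- NULL
  if (reduce) {
    red <- reduce_pipeline(work, measured_metabolites)
    work <- red$model
    blocked <- red$blocked
    fva <- red$fva
  }
  table <- reaction_expression(work, expression)
  classification <- classify_reactions(table, thresholds)
  problem <- imat_problem(work, classification, epsilon = epsilon)
  solution <- solve_imat(problem)
  calls <- if (sensitivity) classify_all(problem) else NULL
  consensus <- if (!is.null(consensus_sets))
    robustness_consensus(work, table, consensus_sets, epsilon = epsilon)
  else NULL
  structure(list(call = cl,
                 model = work, original_model = model,
                 irreversible_mapping = irr$mapping,
                 blocked = blocked, fva = fva,
                 expression_table = table,
                 classification = classification,
                 epsilon = epsilon,
                 problem = problem,
                 solution = solution,
                 activity = calls,
                 consensus = consensus,
                 condition = if (inherits(expression, "expression_profile"))
                   expression$condition else NA_character_),
            class = "imat_fit")
}

#' Activity states of a fitted model
#'
#' @param fit an `imat_fit`.
#' @param consensus return the threshold-robustness consensus states instead
#'   of the single-threshold calls (requires `consensus_sets` at fit time).
#' @return named character vector of ACTIVE / INACTIVE / UNDETERMINED.
#' @export
activity_states <- function(fit, consensus = FALSE) {
  stopifnot(inherits(fit, "imat_fit"))
  if (consensus) {
    if (is.null(fit$consensus)) stop("fit was run without consensus_sets")
    return(fit$consensus$consensus)
  }
  if (is.null(fit$activity)) stop("fit was run with sensitivity = FALSE")
  states_of(fit$activity)
}

#' @export
print.imat_fit <- function(x, ...) {
  cat("Context-specific activity fit")
  if (!is.na(x$condition)) cat(" (condition '", x$condition, "')", sep = "")
  cat("\n  model: ", nrow(x$model$reactions), " reactions after removing ",
      length(x$blocked), " blocked\n", sep = "")
  cat(sprintf("  classification at (%g, %g): %d high, %d low\n",
              x$classification$thresholds[1], x$classification$thresholds[2],
              length(x$classification$R_H), length(x$classification$R_L)))
  cat("  MILP objective:", x$solution$objective, "of",
      length(x$classification$R_H) + length(x$classification$R_L),
      "attainable\n")
  if (!is.null(x$activity)) {
    s <- states_of(x$activity)
    cat(sprintf("  activity calls: %d ACTIVE, %d INACTIVE, %d UNDETERMINED\n",
                sum(s == "ACTIVE"), sum(s == "INACTIVE"),
                sum(s == "UNDETERMINED")))
  }
  invisible(x)
}

#' @export
summary.imat_fit <- function(object, ...) {
  s <- if (!is.null(object$activity)) states_of(object$activity) else NULL
  subs <- setNames(object$model$reactions$subsystem, object$model$reactions$id)
  per_sub <- NULL
  if (!is.null(s)) {
    us <- sort(unique(subs))
    per_sub <- data.frame(
      subsystem = us,
      n = vapply(us, function(x) sum(subs == x), 0L),
      active = vapply(us, function(x) sum(s[subs == x] == "ACTIVE"), 0L),
      inactive = vapply(us, function(x) sum(s[subs == x] == "INACTIVE"), 0L),
      undetermined = vapply(us, function(x)
        sum(s[subs == x] == "UNDETERMINED"), 0L),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- list(fit = object, per_subsystem = per_sub)
  class(out) <- "summary.imat_fit"
  out
}

#' @export
print.summary.imat_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$per_subsystem)) {
    cat("\nPer-subsystem activity:\n")
    print(x$per_subsystem, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.imat_fit <- function(object, ...) object$solution$v

#' @export
fitted.imat_fit <- function(object, ...) object$solution$v

#' Predicted exchange activity of a fitted model
#'
#' Turns the activity calls of exchange-direction reactions into qualitative
#' consumption/production predictions per metabolite.
#'
#' @param object an `imat_fit`.
#' @param ... unused.
#' @return data.frame metabolite / direction / reaction / state.
#' @export
predict.imat_fit <- function(object, ...) {
  s <- activity_states(object)
  rx <- object$model$reactions
  rows <- lapply(which(rx$is_exchange), function(k) {
    st <- rx$stoich[[k]]
    data.frame(metabolite = names(st),
               direction = if (st[[1]] < 0) "secretion" else "uptake",
               reaction = rx$id[k],
               state = s[[rx$id[k]]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
plot.imat_fit <- function(x, ...) {
  sm <- summary(x)$per_subsystem
  if (is.null(sm)) stop("nothing to plot: fit was run with sensitivity = FALSE")
  m <- t(as.matrix(sm[, c("active", "inactive", "undetermined")]))
  colnames(m) <- sm$subsystem
  barplot(m, beside = TRUE, legend.text = rownames(m),
          col = c("forestgreen", "firebrick", grey(0.7)),
          ylab = "reactions", las = 2, ...)
  invisible(x)
}

#' Differential activity between two fitted conditions
#'
#' Convenience wrapper around [differential_activity()] for two `imat_fit`
#' objects fitted on the same model.
#'
#' @param fit_A,fit_B `imat_fit` objects.
#' @param consensus compare consensus states instead of single-threshold
#'   calls.
#' @return a `differential_activity` object.
#' @export
compare_conditions <- function(fit_A, fit_B, consensus = FALSE) {
  a <- activity_states(fit_A, consensus = consensus)
  b <- activity_states(fit_B, consensus = consensus)
  subs <- setNames(fit_A$model$reactions$subsystem, fit_A$model$reactions$id)
  differential_activity(a, b, subs)
}
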