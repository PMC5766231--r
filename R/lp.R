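# Linear and mixed-integer programming layer.
#
# The package carries its own exact solver: a dense bounded-variable two-phase
# primal simplex (src/simplex.cpp, Bland's rule, hence finite termination) and
# a deterministic depth-first branch-and-bound for the binary variables of the
# activity MILP. Problem sizes here are toy-to-small (tens of reactions), so a
# dense tableau is the right tool; no external solver is required.

#' Solve a linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A x (rel) rhs` and
#' `lb <= x <= ub`. Rows may mix relations `"="`, `"<="`, `">="`; slack and
#' surplus variables are added internally. Lower bounds must be finite
#' (metabolic flux variables always are); upper bounds may be `Inf`.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix (dense), one row per constraint.
#' @param rel character vector of row relations, each `"="`, `"<="` or `">="`.
#' @param rhs numeric right-hand sides.
#' @param lb,ub numeric variable bounds.
#' @param maximize logical; maximize (default) or minimize.
#' @param maxit simplex iteration cap.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (solution, only when optimal) and `objective`.
#' @keywords internal
lp_solve <- function(obj, A, rel, rhs, lb, ub, maximize = TRUE, maxit = 50000L) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  stopifnot(length(rel) == nrow(A), length(rhs) == nrow(A),
            length(obj) == ncol(A), length(lb) == ncol(A), length(ub) == ncol(A))
  if (!all(rel %in% c("=", "<=", ">=")))
    stop("unknown constraint relation: ", paste(setdiff(rel, c("=", "<=", ">=")), collapse = ", "))
  n <- ncol(A)
  slack_rows <- which(rel != "=")
  if (length(slack_rows)) {
    Sl <- matrix(0, nrow(A), length(slack_rows))
    for (k in seq_along(slack_rows)) {
      i <- slack_rows[k]
      Sl[i, k] <- if (rel[i] == "<=") 1 else -1
    }
    A <- cbind(A, Sl)
    obj <- c(obj, rep(0, length(slack_rows)))
    lb <- c(lb, rep(0, length(slack_rows)))
    ub <- c(ub, rep(Inf, length(slack_rows)))
  }
  res <- .simplex_bounded(A, as.numeric(rhs),
                          if (maximize) as.numeric(obj) else -as.numeric(obj),
                          as.numeric(lb), as.numeric(ub), as.integer(maxit))
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible", "2" = "unbounded",
                   "3" = "iteration_limit")
  if (status == "iteration_limit")
    stop("simplex iteration limit reached; increase maxit")
  if (status != "optimal")
    return(list(status = status, x = NULL, objective = NA_real_))
  list(status = "optimal",
       x = res$x[seq_len(n)],
       objective = if (maximize) res$objective else -res$objective)
}

# Feasibility-only LP (phase 1).
lp_feasible <- function(A, rel, rhs, lb, ub) {
  res <- lp_solve(rep(0, ncol(A)), A, rel, rhs, lb, ub)
  res$status == "optimal"
}

#' Solve a mixed-integer linear program by branch and bound
#'
#' Depth-first branch and bound over the integer-constrained variables, with
#' LP-relaxation bounding through the built-in simplex. Branching is
#' deterministic (first fractional variable, "up" branch explored first), so
#' repeated solves return identical solutions. When the objective is integral
#' on every integer solution (the activity MILP's objective is a count), the
#' floor of the relaxation bound is used for pruning.
#'
#' @inheritParams lp_solve
#' @param int_idx indices of variables constrained to be integer.
#' @return list with `status`, `x`, `objective`.
#' @keywords internal
milp_solve <- function(obj, A, rel, rhs, lb, ub, int_idx, maximize = TRUE) {
  if (!length(int_idx)) {
    res <- lp_solve(obj, A, rel, rhs, lb, ub, maximize = maximize)
    return(res)
  }
  int_idx <- sort(unique(as.integer(int_idx)))
  integral_obj <- all(obj[-int_idx] == 0) &&
    all(obj[int_idx] == round(obj[int_idx]))
  # work in maximize space throughout
  sgn <- if (maximize) 1 else -1

  best_val <- -Inf
  best_x <- NULL
  # node = list(lb, ub); DFS via stack, last pushed explored first
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    res <- lp_solve(obj, A, rel, rhs, node$lb, node$ub, maximize = maximize)
    if (res$status != "optimal") next
    relax <- sgn * res$objective
    bound <- if (integral_obj) floor(relax + 1e-6) else relax
    if (bound <= best_val + 1e-9 && !is.null(best_x)) next
    frac <- abs(res$x[int_idx] - round(res$x[int_idx]))
    if (all(frac < 1e-6)) {
      val <- if (integral_obj) round(relax) else relax
      if (val > best_val + 1e-9 || is.null(best_x)) {
        best_val <- val
        best_x <- res$x
        best_x[int_idx] <- round(best_x[int_idx])
      }
      next
    }
    j <- int_idx[which(frac >= 1e-6)[1]]
    xj <- res$x[j]
    dn <- node
    dn$ub[j] <- floor(xj)
    up <- node
    up$lb[j] <- ceiling(xj)
    stack[[length(stack) + 1L]] <- dn
    stack[[length(stack) + 1L]] <- up
  }
  if (is.null(best_x))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  list(status = "optimal", x = best_x, objective = sgn * best_val)
}
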