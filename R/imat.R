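# The activity MILP. Given an irreversible model and a reaction
# classification, find a steady-state flux distribution maximizing
#
#   sum_{i in R_H} (y+_i + y-_i)  +  sum_{i in R_L} y+_i
#
# subject to S v = 0 and the flux bounds, where for i in R_H the binary y+_i
# indicates a significant positive flux (y+_i = 1 => v_i >= epsilon) and y-_i
# a significant negative flux (y-_i = 1 => v_i <= -epsilon, impossible on an
# irreversible model, so the negative branch is carried in the encoding but
# can never fire), and for i in R_L y+_i indicates shut-off
# (y+_i = 1 => v_i = 0). All indicator constraints are linearized with each
# reaction's own bounds as big-M constants.

#' Construct an activity-inference MILP problem
#'
#' @param model an irreversible, typically reduced, `metabolic_model`.
#' @param classification a `reaction_classification`; entries for reactions
#'   absent from the model (e.g. removed as blocked) are dropped with a
#'   warning.
#' @param epsilon minimum flux (flux units) for a reaction to count as
#'   active; default 1.
#' @param extra_constraints named character vector mapping reaction ids to
#'   `"fixed-active"` (flux at least epsilon) or `"fixed-inactive"` (zero
#'   flux), used by the sensitivity analysis.
#' @return an object of class `imat_problem`.
#' @export
imat_problem <- function(model, classification, epsilon = 1,
                         extra_constraints = character(0)) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(classification, "reaction_classification"),
            epsilon > 0)
  if (any(model$reactions$lower_bound < 0))
    stop("the activity MILP requires an irreversible model")
  ids <- model$reactions$id
  lost <- setdiff(c(classification$R_H, classification$R_L), ids)
  if (length(lost)) {
    warning("dropping classified reaction(s) not in the model: ",
            paste(lost, collapse = ", "))
    classification$R_H <- setdiff(classification$R_H, lost)
    classification$R_L <- setdiff(classification$R_L, lost)
  }
  if (length(extra_constraints)) {
    if (is.null(names(extra_constraints)) ||
        !all(names(extra_constraints) %in% ids))
      stop("extra_constraints must be named by model reaction ids")
    if (!all(extra_constraints %in% c("fixed-active", "fixed-inactive")))
      stop("extra_constraints values must be 'fixed-active' or 'fixed-inactive'")
  }
  structure(list(model = model, classification = classification,
                 epsilon = epsilon, extra_constraints = extra_constraints),
            class = "imat_problem")
}

# Bounds with the sensitivity forcings applied.
apply_forcings <- function(problem) {
  lb <- problem$model$reactions$lower_bound
  ub <- problem$model$reactions$upper_bound
  ids <- problem$model$reactions$id
  ex <- problem$extra_constraints
  for (r in names(ex)) {
    k <- match(r, ids)
    if (ex[[r]] == "fixed-active") lb[k] <- max(lb[k], problem$epsilon)
    else ub[k] <- 0 # fixed-inactive: v = 0 (infeasible if lb > 0, as intended)
  }
  list(lb = lb, ub = ub)
}

build_imat_milp <- function(problem) {
  model <- problem$model
  eps <- problem$epsilon
  S <- stoich_matrix(model)
  ids <- model$reactions$id
  m <- length(ids)
  H <- match(problem$classification$R_H, ids)
  L <- match(problem$classification$R_L, ids)
  nH <- length(H)
  nL <- length(L)
  nvar <- m + nH + nL + nH # v, y+_H, y+_L, y-_H
  vn <- c(ids,
          if (nH) paste0("yplus.", ids[H]),
          if (nL) paste0("yplus.", ids[L]),
          if (nH) paste0("yminus.", ids[H]))
  bounds <- apply_forcings(problem)
  lb <- c(bounds$lb, rep(0, nvar - m))
  ub <- c(bounds$ub, rep(1, nvar - m))

  rows <- list()
  add_row <- function(cols, coefs, rel, rhs) {
    r <- numeric(nvar)
    r[cols] <- coefs
    rows[[length(rows) + 1L]] <<- list(r = r, rel = rel, rhs = rhs)
  }
  for (i in seq_len(nrow(S)))
    rows[[length(rows) + 1L]] <- list(r = c(S[i, ], rep(0, nvar - m)),
                                      rel = "=", rhs = 0)
  ub_model <- model$reactions$upper_bound
  for (j in seq_along(H)) {
    i <- H[j]
    yp <- m + j
    ym <- m + nH + nL + j
    add_row(c(i, yp), c(1, -eps), ">=", 0)                    # y+=1 => v >= eps
    add_row(c(i, ym), c(1, ub_model[i] + eps), "<=", ub_model[i]) # y-=1 => v <= -eps
    add_row(c(yp, ym), c(1, 1), "<=", 1)
  }
  for (j in seq_along(L)) {
    i <- L[j]
    yp <- m + nH + j
    add_row(c(i, yp), c(1, ub_model[i]), "<=", ub_model[i])   # y+=1 => v <= 0
    lo <- model$reactions$lower_bound[i]
    add_row(c(i, yp), c(1, lo), ">=", lo)                     # y+=1 => v >= 0
  }
  A <- do.call(rbind, lapply(rows, `[[`, "r"))
  list(obj = c(rep(0, m), rep(1, nH + nL + nH)),
       A = A,
       rel = vapply(rows, `[[`, "", "rel"),
       rhs = vapply(rows, `[[`, 0, "rhs"),
       lb = lb, ub = ub,
       int_idx = seq.int(m + 1L, length.out = nH + nL + nH),
       var_names = vn, m = m, H = H, L = L, nH = nH, nL = nL)
}

#' Solve the activity MILP
#'
#' Returns one provably optimal solution. Because alternative optima with the
#' same objective usually exist, activity claims about individual reactions
#' should be made through [sensitivity_call()] / [classify_all()], which
#' compare objective values rather than inspect a single flux vector.
#'
#' @param problem an `imat_problem`.
#' @return an object of class `imat_solution`: `status` (`"optimal"` or
#'   `"infeasible"`), integer `objective`, flux vector `v`, binary vectors
#'   `y_plus` (over R_H then R_L) and `y_minus` (over R_H).
#' @export
solve_imat <- function(problem) {
  stopifnot(inherits(problem, "imat_problem"))
  p <- build_imat_milp(problem)
  res <- milp_solve(p$obj, p$A, p$rel, p$rhs, p$lb, p$ub, p$int_idx)
  if (res$status != "optimal")
    return(structure(list(status = "infeasible", objective = -Inf,
                          v = NULL, y_plus = NULL, y_minus = NULL,
                          epsilon = problem$epsilon),
                     class = "imat_solution"))
  ids <- problem$model$reactions$id
  v <- setNames(res$x[seq_len(p$m)], ids)
  yp <- setNames(round(res$x[p$m + seq_len(p$nH + p$nL)]),
                 ids[c(p$H, p$L)])
  ym <- setNames(round(res$x[p$m + p$nH + p$nL + seq_len(p$nH)]), ids[p$H])
  sol <- structure(list(status = "optimal",
                        objective = as.integer(round(res$objective)),
                        v = v, y_plus = yp, y_minus = ym,
                        epsilon = problem$epsilon),
                   class = "imat_solution")
  check_imat_solution(problem, sol)
  sol
}

# Defensive verification of the solution invariants (tolerance 1e-6).
check_imat_solution <- function(problem, sol, tol = 1e-6) {
  S <- stoich_matrix(problem$model)
  if (any(abs(S %*% sol$v) > tol))
    stop("internal error: returned flux violates mass balance")
  bounds <- apply_forcings(problem)
  if (any(sol$v < bounds$lb - tol) || any(sol$v > bounds$ub + tol))
    stop("internal error: returned flux violates bounds")
  for (i in problem$classification$R_H)
    if (sol$y_plus[[i]] == 1 && sol$v[[i]] < problem$epsilon - tol)
      stop("internal error: active indicator without sufficient flux on ", i)
  for (i in problem$classification$R_L)
    if (sol$y_plus[[i]] == 1 && abs(sol$v[[i]]) > tol)
      stop("internal error: shut-off indicator with non-zero flux on ", i)
  expected <- sum(sol$y_plus) + sum(sol$y_minus)
  if (sol$objective != expected)
    stop("internal error: objective does not match indicator sum")
  invisible(TRUE)
}

#' @export
print.imat_solution <- function(x, ...) {
  if (x$status != "optimal") {
    cat("Activity MILP: infeasible\n")
    return(invisible(x))
  }
  cat("Activity MILP solution: objective", x$objective,
      "(epsilon =", x$epsilon, ")\n")
  cat("  reactions carrying flux >= epsilon:",
      sum(x$v >= x$epsilon - 1e-6), "of", length(x$v), "\n")
  invisible(x)
}

#' Brute-force optimum of the activity MILP (testing oracle)
#'
#' Enumerates all `2^(|R_H|+|R_L|)` activity assignments over the classified
#' reactions, checks each by LP feasibility (active: flux >= epsilon;
#' inactive: zero flux) and returns the best achievable agreement score. Kept
#' deliberately independent of [solve_imat()]'s branch-and-bound path; only
#' usable for small labelled sets.
#'
#' @param problem an `imat_problem` with at most 16 classified reactions.
#' @return integer: the maximal objective, or `-Inf` if no assignment is
#'   feasible (cannot happen on a feasible model since the all-inactive
#'   assignment only fixes fluxes to zero... unless forcings contradict it).
#' @export
brute_force_objective <- function(problem) {
  stopifnot(inherits(problem, "imat_problem"))
  labelled <- c(problem$classification$R_H, problem$classification$R_L)
  nlab <- length(labelled)
  if (nlab > 16) stop("brute force limited to 16 classified reactions, got ", nlab)
  model <- problem$model
  con <- fba_constraints(model)
  bounds <- apply_forcings(problem)
  idx <- match(labelled, model$reactions$id)
  in_h <- labelled %in% problem$classification$R_H
  eps <- problem$epsilon
  best <- -Inf
  for (mask in 0:(2^nlab - 1)) {
    active <- as.logical(bitwAnd(mask, 2^(seq_len(nlab) - 1)))
    score <- sum(active & in_h) + sum(!active & !in_h)
    if (score <= best) next
    lb <- bounds$lb
    ub <- bounds$ub
    lb[idx[active]] <- pmax(lb[idx[active]], eps)
    ub[idx[!active]] <- 0
    if (any(lb > ub)) next
    if (lp_feasible(con$A, con$rel, con$rhs, lb, ub)) best <- score
  }
  best
}
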