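test_that("FVA reproduces hand-solved ranges", {
  # single chain with conserved flux: every reaction spans (0, 10)
  fva <- flux_variability(chain_model(ub = 10))
  expect_true(all(fva$min_flux == 0))
  expect_true(all(abs(fva$max_flux - 10) < 1e-9))
  expect_true(all(fva$feasible))

  # dead-end product forces zero flux
  m <- toy_model(list(
    list(id = "EX_in", stoich = c(A = 1), ub = 10),
    list(id = "R_AB", stoich = c(A = -1, B = 1), ub = 10),
    list(id = "R_AD", stoich = c(A = -1, D = 1), ub = 10), # D has no consumer
    list(id = "EX_out", stoich = c(B = -1), ub = 10)))
  fva2 <- flux_variability(m)
  expect_equal(fva2$max_flux[fva2$id == "R_AD"], 0)

  # diamond: shared input capacity 10, each branch spans (0, 10)
  dia <- toy_model(list(
    list(id = "EX_in", stoich = c(A = 1), ub = 10),
    list(id = "R_AB", stoich = c(A = -1, B = 1)),
    list(id = "R_AC", stoich = c(A = -1, C = 1)),
    list(id = "R_BD", stoich = c(B = -1, D = 1)),
    list(id = "R_CD", stoich = c(C = -1, D = 1)),
    list(id = "EX_out", stoich = c(D = -1))))
  fva3 <- flux_variability(dia)
  for (r in c("R_AB", "R_AC", "R_BD", "R_CD")) {
    expect_equal(fva3$min_flux[fva3$id == r], 0)
    expect_equal(fva3$max_flux[fva3$id == r], 10, tolerance = 1e-9)
  }

  expect_error(flux_variability(toy_model(list(
    list(id = "R", stoich = c(A = -1, B = 1), lb = -3, ub = 3)))),
    "irreversible")
})

test_that("blockedness uses the tolerance on both LP optima", {
  fva <- data.frame(id = c("a", "b", "c", "d"),
                    min_flux = c(0, 0, 0, NA),
                    max_flux = c(5e-10, 2e-9, 10, NA),
                    feasible = c(TRUE, TRUE, TRUE, FALSE))
  expect_setequal(find_blocked(fva, tol = 1e-9), c("a", "d"))
  expect_setequal(find_blocked(fva, tol = 1e-8), c("a", "b", "d"))
})

test_that("reduction removes blocked reactions and orphaned metabolites", {
  m <- chain_model()
  expect_identical(reduce_model(m, character(0)), m)

  m2 <- toy_model(list(
    list(id = "EX_in", stoich = c(A = 1), ub = 10),
    list(id = "R_AB", stoich = c(A = -1, B = 1), ub = 10),
    list(id = "R_AX", stoich = c(A = -1, X = 1), ub = 10),
    list(id = "EX_out", stoich = c(B = -1), ub = 10)))
  red <- reduce_model(m2, "R_AX")
  expect_false("R_AX" %in% red$reactions$id)
  expect_false("X" %in% red$metabolites$id) # orphan removed with its reaction
  expect_error(reduce_model(m2, "nope"), "unknown reaction")

  # appending an isolated dead-end branch to the toy fixture and reducing
  # recovers the original fixture
  fx <- make_fig5_fixture()
  aug <- fx$model
  aug$metabolites <- rbind(aug$metabolites,
                           data.frame(id = "Met_X", name = "Met_X",
                                      compartment = "c"))
  aug$reactions <- rbind(aug$reactions,
                         data.frame(id = "R_dead",
                                    lower_bound = 0, upper_bound = 1000,
                                    reversible = FALSE, gpr = "Enz_9",
                                    subsystem = "toy", is_exchange = FALSE,
                                    stoich = I(list(c(Met_B = -1, Met_X = 1)))))
  blocked <- find_blocked(flux_variability(aug))
  expect_identical(blocked, "R_dead")
  red2 <- reduce_model(aug, blocked)
  expect_identical(red2$reactions$id, fx$model$reactions$id)
  expect_identical(red2$metabolites$id, fx$model$metabolites$id)
})

test_that("every reported-blocked reaction truly cannot carry flux", {
  # soundness: forcing epsilon flux through a blocked reaction makes the
  # steady-state system infeasible
  set.seed(51)
  for (seed in 1:5) {
    net <- generate_network(2, 2, 4, seed = seed)
    # graft a dead-end branch so something is blocked
    net$metabolites <- rbind(net$metabolites,
                             data.frame(id = "DEAD", name = "DEAD",
                                        compartment = "c"))
    net$reactions <- rbind(net$reactions,
                           data.frame(id = "R_dead", lower_bound = 0,
                                      upper_bound = 1000, reversible = FALSE,
                                      gpr = "", subsystem = "x",
                                      is_exchange = FALSE,
                                      stoich = I(list(c(M1_1 = -1, DEAD = 1)))))
    blocked <- find_blocked(flux_variability(net))
    expect_true("R_dead" %in% blocked)
    con <- fluxstate:::fba_constraints(net)
    for (b in blocked) {
      lb <- con$lb
      lb[net$reactions$id == b] <- 1
      expect_false(fluxstate:::lp_feasible(con$A, con$rel, con$rhs, lb, con$ub))
    }
  }
})

test_that("measured exchanges survive reduction and bounds are restored", {
  # a metabolite whose exchange pair would otherwise idle: the pass-through
  # cycle uptake -> secretion keeps it feasible once forced
  m <- to_irreversible(toy_model(list(
    list(id = "EX_glc", stoich = c(glc = 1), lb = -1000, ub = 1000),
    list(id = "R", stoich = c(glc = -1, pyr = 1)),
    list(id = "EX_pyr", stoich = c(pyr = -1)))))$model
  red <- reduce_pipeline(m, "glc")
  expect_true(all(grep("EX_glc", m$reactions$id, value = TRUE) %in%
                    red$model$reactions$id))
  # bounds restored to the pre-forcing values
  glc_ids <- grep("EX_glc", red$model$reactions$id, value = TRUE)
  orig <- m$reactions[match(glc_ids, m$reactions$id), ]
  now <- red$model$reactions[match(glc_ids, red$model$reactions$id), ]
  expect_identical(now$lower_bound, orig$lower_bound)
  expect_identical(now$upper_bound, orig$upper_bound)
})

test_that("the optimal activity objective is invariant under reduction", {
  set.seed(52)
  for (seed in 1:5) {
    net <- generate_network(2, 1, 4, seed = seed, chain_length = 3)
    net$metabolites <- rbind(net$metabolites,
                             data.frame(id = "DEAD", name = "DEAD",
                                        compartment = "c"))
    net$reactions <- rbind(net$reactions,
                           data.frame(id = "R_dead", lower_bound = 0,
                                      upper_bound = 1000, reversible = FALSE,
                                      gpr = "", subsystem = "x",
                                      is_exchange = FALSE,
                                      stoich = I(list(c(M2_1 = -1, DEAD = 1)))))
    red <- reduce_pipeline(net)
    cls <- random_classification(red$model, 6) # restricted to survivors
    before <- solve_imat(imat_problem(net, cls))$objective
    after <- solve_imat(imat_problem(red$model, cls))$objective
    expect_identical(before, after)
  }
})
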