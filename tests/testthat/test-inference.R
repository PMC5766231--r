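test_that("sensitivity calls reproduce the worked example", {
  pr <- worked_example()
  s <- sensitivity_call(pr, "R1")
  expect_identical(s$state, "ACTIVE")
  expect_equal(s$obj_forced_active, 2)
  expect_equal(s$obj_forced_inactive, 1)

  calls <- classify_all(pr)
  expect_identical(states_all <- setNames(calls$state, calls$id),
                   c(EX_A = "ACTIVE", R1 = "ACTIVE", R2 = "INACTIVE",
                     EX_B = "ACTIVE", EX_C = "INACTIVE"))

  # subset of size one agrees with the single call
  one <- classify_all(pr, reactions = "R2")
  expect_identical(nrow(one), 1L)
  s2 <- sensitivity_call(pr, "R2")
  expect_identical(one$state, s2$state)
  expect_equal(one$obj_active, s2$obj_forced_active)

  # order independence
  perm <- classify_all(pr, reactions = rev(pr$model$reactions$id))
  expect_identical(setNames(perm$state, perm$id)[names(states_all)],
                   states_all)

  # shortcut and full enumeration agree
  full <- classify_all(pr, shortcut = FALSE)
  expect_identical(calls$state, full$state)
  expect_equal(calls$obj_active, full$obj_active)
  expect_equal(calls$obj_inactive, full$obj_inactive)
})

test_that("a blocked reaction is INACTIVE with -Inf forced-active objective", {
  m <- toy_model(list(
    list(id = "EX_in", stoich = c(A = 1), ub = 10),
    list(id = "R_AB", stoich = c(A = -1, B = 1), ub = 10),
    list(id = "R_AX", stoich = c(A = -1, X = 1), ub = 10),
    list(id = "EX_out", stoich = c(B = -1), ub = 10)))
  pr <- imat_problem(m, manual_classification(m, R_H = "R_AB"))
  s <- sensitivity_call(pr, "R_AX")
  expect_identical(s$state, "INACTIVE")
  expect_identical(s$obj_forced_active, -Inf)
})

test_that("interchangeable parallel paths are UNDETERMINED", {
  m <- toy_model(list(
    list(id = "EX_in", stoich = c(A = 1)),
    list(id = "R0", stoich = c(A = -1, M = 1)),
    list(id = "P1", stoich = c(M = -1, B = 1)),
    list(id = "P2", stoich = c(M = -1, B = 1)),
    list(id = "EX_out", stoich = c(B = -1))))
  pr <- imat_problem(m, manual_classification(m, R_H = "R0"))
  s1 <- sensitivity_call(pr, "P1")
  expect_identical(s1$state, "UNDETERMINED")
  expect_equal(s1$obj_forced_active, s1$obj_forced_inactive)
  expect_identical(sensitivity_call(pr, "P2")$state, "UNDETERMINED")
  expect_identical(sensitivity_call(pr, "R0")$state, "ACTIVE")
})

test_that("sensitivity is coherent with the unconstrained optimum", {
  fx <- make_fig5_fixture()
  tab <- reaction_expression(fx$model, fx$expression)
  pr <- imat_problem(fx$model, classify_reactions(tab))
  base <- solve_imat(pr)$objective
  for (r in fx$model$reactions$id) {
    s <- sensitivity_call(pr, r)
    expect_equal(max(s$obj_forced_active, s$obj_forced_inactive), base)
  }
})

test_that("threshold-robustness consensus follows the unanimity rule", {
  fx <- make_fig5_fixture()
  tab <- reaction_expression(fx$model, fx$expression)
  rc <- robustness_consensus(fx$model, tab)
  expect_named(rc$per_pair, c("25/75", "33/66", "40/60"))
  # on this fixture the calls agree at every pair, so consensus equals them
  ref <- setNames(rc$per_pair[["33/66"]]$state, rc$per_pair[["33/66"]]$id)
  expect_identical(rc$consensus, ref)
  expect_identical(unname(rc$consensus[c("EX_Met_G", "EX_Met_H", "EX_Met_I")]),
                   c("INACTIVE", "INACTIVE", "ACTIVE"))

  # consensus-ACTIVE is always contained in each pair's ACTIVE set
  st <- generate_study(noise_flip_prob = 0.25, replicate_sd = 0.2, seed = 9)
  tabm <- reaction_expression(st$model, st$profiles$M)
  rc2 <- robustness_consensus(st$model, tabm)
  for (pp in rc2$per_pair) {
    pair_states <- setNames(pp$state, pp$id)
    expect_true(all(pair_states[names(rc2$consensus)[
      rc2$consensus == "ACTIVE"]] == "ACTIVE"))
    expect_true(all(pair_states[names(rc2$consensus)[
      rc2$consensus == "INACTIVE"]] == "INACTIVE"))
  }
  expect_error(robustness_consensus(fx$model, tab, list()), "at least one")
})

test_that("differential activity keeps only unambiguous disagreements", {
  a <- c(r1 = "ACTIVE", r2 = "INACTIVE", r3 = "ACTIVE", r4 = "UNDETERMINED")
  b <- c(r1 = "INACTIVE", r2 = "INACTIVE", r3 = "UNDETERMINED", r4 = "ACTIVE")
  subs <- c(r1 = "glycolysis", r2 = "glycolysis", r3 = "tca", r4 = "tca")
  d <- differential_activity(a, b, subs)
  expect_identical(d$specific_to_A, "r1")
  expect_identical(d$specific_to_B, character(0))
  expect_identical(d$pathway_counts$subsystem, "glycolysis")
  expect_identical(d$pathway_counts$count_A, 1L)

  # swapping conditions swaps the sets
  d2 <- differential_activity(b, a, subs)
  expect_identical(d2$specific_to_A, d$specific_to_B)
  expect_identical(d2$specific_to_B, d$specific_to_A)

  expect_error(differential_activity(a, b[1:3]), "universes")
})

test_that("Fisher exact matches the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact(matrix(c(1, 11, 9, 3), 2)), 0.00276, tolerance = 2e-3)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5),
               tolerance = 1e-9)
  expect_identical(fisher_exact(matrix(0, 2, 2)), 1)
  expect_identical(fisher_exact(matrix(c(0, 0, 3, 4), 2)), 1) # zero margin

  set.seed(71)
  for (i in 1:200) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    p <- fisher_exact(tab)
    expect_equal(p, fisher_enum_oracle(tab), tolerance = 1e-9)
    expect_equal(p, fisher_exact(t(tab)), tolerance = 1e-12)
  }
})

test_that("exchange validation builds the contingency table correctly", {
  fx <- make_fig5_fixture()
  states <- c(EX_Met_A = "ACTIVE", EX_Met_G = "INACTIVE",
              EX_Met_H = "UNDETERMINED", EX_Met_I = "ACTIVE")
  measured <- data.frame(
    metabolite = c("Met_A", "Met_G", "Met_H", "Met_I"),
    direction = c("uptake", "secretion", "secretion", "secretion"),
    status = c("active", "inactive", "active", "active"))
  v <- validate_exchanges(states, measured, fx$model)
  expect_identical(v$n_undetermined, 1L)
  expect_identical(sum(v$contingency), 3L)
  expect_identical(v$contingency["active", "active"], 2L)   # A uptake, I secr
  expect_identical(v$contingency["inactive", "inactive"], 1L) # G secretion
  expect_identical(v$true_positive_rate, 1)

  expect_error(validate_exchanges(states, data.frame(
    metabolite = "Met_B", direction = "secretion", status = "active"),
    fx$model), "Met_B/secretion")
  expect_error(validate_exchanges(states, data.frame(
    metabolite = "Met_G", direction = "sideways", status = "active"),
    fx$model), "direction")
})

test_that("pathway enrichment favours concentrated differential sets", {
  subs <- setNames(rep(c("p1", "p2"), each = 10), paste0("r", 1:20))
  concentrated <- paste0("r", 1:5)   # all in p1
  enr <- pathway_enrichment(concentrated, subs)
  expect_lt(enr$p[enr$subsystem == "p1"], enr$p[enr$subsystem == "p2"])
  expect_identical(enr$n_specific[enr$subsystem == "p1"], 5L)
})
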