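test_that("json_toy round trip is the identity", {
  m <- toy_model(list(
    list(id = "EX_in", stoich = c(A = 1)),
    list(id = "R1", stoich = c(A = -1, B = 1), gpr = "g1 and g2",
         subsystem = "s1"),
    list(id = "R2", stoich = c(B = -1, C = 1), lb = -10),
    list(id = "EX_out", stoich = c(C = -1))))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$metabolites, m$metabolites)
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_identical(m2$reactions$gpr, m$reactions$gpr)
  expect_identical(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_identical(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_equal(m2$reactions$stoich, m$reactions$stoich)
  expect_identical(m2$reactions$is_exchange, m$reactions$is_exchange)
})

test_that("the packaged toy fixture file matches the built-in constructor", {
  path <- system.file("extdata", "fig5_toy.json", package = "fluxstate")
  m <- read_model(path)
  fx <- make_fig5_fixture()
  expect_identical(m$metabolites$id, paste0("Met_", LETTERS[1:9]))
  expect_identical(m$reactions$id, fx$model$reactions$id)
  expect_equal(m$reactions$stoich, fx$model$reactions$stoich)
  expect_identical(sum(nzchar(m$reactions$gpr)), 7L)
})

test_that("validation errors name the offender", {
  mets <- data.frame(id = c("A", "A"), name = "A", compartment = "c")
  rx <- data.frame(id = "R", lower_bound = 0, upper_bound = 1,
                   stoich = I(list(c(A = 1))))
  expect_error(metabolic_model(mets, rx), "duplicate metabolite id: A")
  expect_error(
    toy_model(list(list(id = "R", stoich = c(ZZZ = -1, A = 1, B = 1),
                        exchange = FALSE)), mets = c("A", "B")),
    "unknown metabolite: ZZZ")
  expect_error(
    toy_model(list(list(id = "R", stoich = c(A = -1, B = 1), lb = 5, ub = 1))),
    "lower_bound > upper_bound")
  expect_error(
    toy_model(list(list(id = "EX", stoich = c(A = -1, B = 1),
                        exchange = TRUE))),
    "exactly one metabolite")
  expect_error(read_model("/nonexistent/file.json"), "not found")
})

test_that("irreversible conversion handles all sign cases", {
  m <- toy_model(list(
    list(id = "EX_A", stoich = c(A = 1)),
    list(id = "F", stoich = c(A = -1, B = 1), lb = 0, ub = 7),
    list(id = "REV", stoich = c(A = -1, B = 1), lb = -10, ub = 10),
    list(id = "BWD", stoich = c(A = -1, B = 1), lb = -5, ub = 0),
    list(id = "EX_B", stoich = c(B = -1))))
  conv <- to_irreversible(m)
  rx <- conv$model$reactions
  expect_true(all(rx$lower_bound >= 0))
  expect_identical(conv$mapping$F, "F")
  expect_identical(conv$mapping$REV, c("REV_fwd", "REV_bwd"))
  expect_identical(conv$mapping$BWD, "BWD_bwd")
  expect_equal(rx$upper_bound[rx$id == "REV_fwd"], 10)
  expect_equal(rx$upper_bound[rx$id == "REV_bwd"], 10)
  expect_equal(rx$stoich[[which(rx$id == "REV_bwd")]], c(A = 1, B = -1))
  expect_equal(rx$lower_bound[rx$id == "BWD_bwd"], 0)
  expect_equal(rx$upper_bound[rx$id == "BWD_bwd"], 5)

  # already-irreversible model comes back unchanged with identity mapping
  m0 <- chain_model()
  conv0 <- to_irreversible(m0)
  expect_identical(conv0$model$reactions$id, m0$reactions$id)
  expect_identical(unlist(conv0$mapping), setNames(m0$reactions$id,
                                                   m0$reactions$id))
})

test_that("splitting preserves the optimal net flux of every objective", {
  # flux-cone preservation checked by LP: for random objectives, the optimum
  # over the reversible model equals the optimum over the split model with
  # costs c on forward and -c on backward copies.
  set.seed(21)
  m <- toy_model(list(
    list(id = "EX_A", stoich = c(A = 1), ub = 10),
    list(id = "R1", stoich = c(A = -1, B = 1), lb = -10, ub = 10),
    list(id = "R2", stoich = c(B = -1, C = 1), lb = -4, ub = 8),
    list(id = "R3", stoich = c(A = -1, C = 1), lb = 0, ub = 5),
    list(id = "EX_C", stoich = c(C = -1), ub = 10),
    list(id = "EX_B", stoich = c(B = -1), lb = -3, ub = 3)))
  conv <- to_irreversible(m)
  S1 <- stoich_matrix(m)
  S2 <- stoich_matrix(conv$model)
  lp <- fluxstate:::lp_solve
  for (i in 1:20) {
    cc <- round(runif(ncol(S1), -2, 2), 2)
    o1 <- lp(cc, S1, rep("=", nrow(S1)), rep(0, nrow(S1)),
             m$reactions$lower_bound, m$reactions$upper_bound)
    cc2 <- numeric(ncol(S2))
    names(cc2) <- conv$model$reactions$id
    for (k in seq_along(cc)) {
      ids <- conv$mapping[[m$reactions$id[k]]]
      fwd <- ids[!grepl("_bwd$", ids)]
      bwd <- ids[grepl("_bwd$", ids)]
      if (length(fwd)) cc2[fwd] <- cc[k]
      if (length(bwd)) cc2[bwd] <- -cc[k]
    }
    o2 <- lp(cc2, S2, rep("=", nrow(S2)), rep(0, nrow(S2)),
             conv$model$reactions$lower_bound, conv$model$reactions$upper_bound)
    expect_equal(o1$objective, o2$objective, tolerance = 1e-8)
  }
})

test_that("forcing measured exchanges is reversible and validated", {
  m <- to_irreversible(toy_model(list(
    list(id = "EX_glc", stoich = c(glc = 1), lb = -1000, ub = 1000),
    list(id = "R", stoich = c(glc = -1, pyr = 1)),
    list(id = "EX_pyr", stoich = c(pyr = -1)))))$model
  expect_identical(force_measured_exchanges(m, character(0)), m)

  f <- force_measured_exchanges(m, "glc")
  glc_rx <- grep("EX_glc", f$reactions$id, value = TRUE)
  expect_length(glc_rx, 2) # split pair
  idx <- f$reactions$id %in% glc_rx
  expect_true(all(f$reactions$lower_bound[idx] == 0.001))
  expect_true(all(f$reactions$upper_bound[idx] == 1000))
  # non-measured exchange untouched
  expect_equal(f$reactions$lower_bound[f$reactions$id == "EX_pyr"], 0)

  restored <- restore_exchange_bounds(f)
  expect_identical(restored$reactions$lower_bound, m$reactions$lower_bound)
  expect_identical(restored$reactions$upper_bound, m$reactions$upper_bound)

  expect_error(force_measured_exchanges(m, c("glc", "nope")), "nope")
  expect_error(force_measured_exchanges(toy_model(list(
    list(id = "EX", stoich = c(A = 1), lb = -1, ub = 1))), "A"),
    "irreversible")
})

test_that("SBML round trip preserves structure, bounds, GPR semantics", {
  fx <- make_fig5_fixture()
  m <- fx$model
  m$reactions$gpr[1] <- "(Enz_1 and Enz_8) or Enz_9"
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_identical(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_identical(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_identical(m2$reactions$subsystem, m$reactions$subsystem)
  expect_identical(m2$reactions$is_exchange, m$reactions$is_exchange)
  for (k in seq_len(nrow(m$reactions))) {
    a <- m$reactions$stoich[[k]]
    b <- m2$reactions$stoich[[k]]
    expect_equal(a[sort(names(a))], b[sort(names(b))])
  }
  # GPR text is re-rendered from the association tree: semantics preserved
  lv <- setNames(runif(9, 0, 10), paste0("Enz_", 1:9))
  for (k in seq_len(nrow(m$reactions)))
    expect_identical(evaluate_gpr(parse_gpr(m2$reactions$gpr[k]), lv),
                     evaluate_gpr(parse_gpr(m$reactions$gpr[k]), lv))
  # a reaction without GPR stays without one
  expect_identical(m2$reactions$gpr[m2$reactions$id == "EX_Met_A"], "")
})
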