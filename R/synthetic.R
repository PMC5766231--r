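# Synthetic study generator: toy stoichiometric networks with planted
# activity states, two-condition replicate expression with controlled noise,
# and qualitative exchange labels derived from the planted flux witness.
# Every pipeline stage is testable against this ground truth without any
# external download. All generators are bit-reproducible from their seed.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' The worked toy network fixture
#'
#' A deterministic 9-metabolite network (Met_A ... Met_I) with seven
#' enzyme-catalyzed internal reactions (genes Enz_1 ... Enz_7), uptake of
#' Met_A and candidate secretions of Met_G, Met_H and Met_I. Met_A feeds a
#' branch point: two single-step branches lead to Met_G and Met_H through
#' lowly expressed enzymes, while a two-step branch through highly expressed
#' enzymes converts Met_B into Met_E + Met_F and condenses them into Met_I.
#' The exact stoichiometry of the published toy figure is not printed
#' anywhere, so this topology is the package's reconstruction, constrained to
#' reproduce the figure's stated outcome: with the bundled expression levels
#' the activity analysis predicts secretion of Met_I but not of Met_G or
#' Met_H.
#'
#' @return list with `model` (a `metabolic_model`), `expression` (named gene
#'   levels whose (33, 66) percentile classification makes Enz_1/6/7 high and
#'   Enz_2/4 low), and `expected_secretion` (named states of the three
#'   candidate secretions).
#' @export
make_fig5_fixture <- function() {
  mets <- data.frame(
    id = paste0("Met_", LETTERS[1:9]),
    name = paste0("Met_", LETTERS[1:9]),
    compartment = "c", stringsAsFactors = FALSE)
  rxn <- function(id, stoich, gpr = "", exch = FALSE, subsystem = "toy")
    data.frame(id = id, lower_bound = 0, upper_bound = 1000,
               reversible = FALSE, gpr = gpr, subsystem = subsystem,
               is_exchange = exch, stoich = I(list(stoich)),
               stringsAsFactors = FALSE)
  rxns <- rbind(
    rxn("R1", c(Met_A = -1, Met_B = 1), "Enz_1"),
    rxn("R2", c(Met_B = -1, Met_C = 1), "Enz_2"),
    rxn("R3", c(Met_C = -1, Met_G = 1), "Enz_3"),
    rxn("R4", c(Met_B = -1, Met_D = 1), "Enz_4"),
    rxn("R5", c(Met_D = -1, Met_H = 1), "Enz_5"),
    rxn("R6", c(Met_B = -1, Met_E = 1, Met_F = 1), "Enz_6"),
    rxn("R7", c(Met_E = -1, Met_F = -1, Met_I = 1), "Enz_7"),
    rxn("EX_Met_A", c(Met_A = 1), exch = TRUE, subsystem = "exchange"),
    rxn("EX_Met_G", c(Met_G = -1), exch = TRUE, subsystem = "exchange"),
    rxn("EX_Met_H", c(Met_H = -1), exch = TRUE, subsystem = "exchange"),
    rxn("EX_Met_I", c(Met_I = -1), exch = TRUE, subsystem = "exchange"))
  model <- metabolic_model(mets, rxns, id = "toy_network")
  expr <- c(Enz_1 = 10, Enz_2 = 1, Enz_3 = 5, Enz_4 = 1.5,
            Enz_5 = 5.5, Enz_6 = 11, Enz_7 = 12)
  list(model = model, expression = expr,
       expected_secretion = c(EX_Met_G = "INACTIVE", EX_Met_H = "INACTIVE",
                              EX_Met_I = "ACTIVE"))
}

#' Generate a random toy metabolic network
#'
#' Builds `n_linear_chains` independent pathways: each chain has one uptake
#' exchange, a linear trunk of internal conversions, and `branch_factor`
#' terminal branches each ending in its own secretion exchange (so every
#' reaction lies on a complete uptake-to-secretion path and nothing is
#' blocked by construction). Each internal reaction carries a single-gene GPR
#' with a unique gene name; the chain index is the subsystem label.
#' `n_exchanges` is a target total exchange count: the structurally required
#' exchanges always exist, and if the target exceeds them, extra secretion
#' exchanges are added on intermediate metabolites.
#'
#' @param n_linear_chains number of chains (>= 1).
#' @param branch_factor terminal branches per chain (>= 1).
#' @param n_exchanges target total number of exchange reactions.
#' @param seed integer seed; same seed, same network.
#' @param chain_length internal trunk length per chain (default 3).
#' @return a `metabolic_model`.
#' @export
generate_network <- function(n_linear_chains, branch_factor, n_exchanges,
                             seed, chain_length = 3) {
  stopifnot(n_linear_chains >= 1, branch_factor >= 1, n_exchanges >= 1,
            chain_length >= 1)
  with_seed(seed, {
    mets <- list()
    rxns <- list()
    gene_i <- 0L
    add_met <- function(id) mets[[length(mets) + 1L]] <<-
      data.frame(id = id, name = id, compartment = "c", stringsAsFactors = FALSE)
    add_rxn <- function(id, stoich, gpr = "", exch = FALSE, subsystem = "")
      rxns[[length(rxns) + 1L]] <<-
        data.frame(id = id, lower_bound = 0, upper_bound = 1000,
                   reversible = FALSE, gpr = gpr, subsystem = subsystem,
                   is_exchange = exch, stoich = I(list(stoich)),
                   stringsAsFactors = FALSE)
    for (c_i in seq_len(n_linear_chains)) {
      sub <- paste0("chain", c_i)
      trunk <- paste0("M", c_i, "_", seq_len(chain_length))
      for (m in trunk) add_met(m)
      add_rxn(paste0("EX_up_", c_i), setNames(1, trunk[1]), exch = TRUE,
              subsystem = "exchange")
      if (chain_length > 1) {
        for (s in seq_len(chain_length - 1)) {
          gene_i <- gene_i + 1L
          add_rxn(paste0("R", c_i, "_t", s),
                  setNames(c(-1, 1), c(trunk[s], trunk[s + 1])),
                  gpr = paste0("g", gene_i), subsystem = sub)
        }
      }
      for (b in seq_len(branch_factor)) {
        tip <- paste0("M", c_i, "_b", b)
        add_met(tip)
        gene_i <- gene_i + 1L
        add_rxn(paste0("R", c_i, "_b", b),
                setNames(c(-1, 1), c(trunk[chain_length], tip)),
                gpr = paste0("g", gene_i), subsystem = sub)
        add_rxn(paste0("EX_sec_", c_i, "_", b), setNames(-1, tip),
                exch = TRUE, subsystem = "exchange")
      }
    }
    rx <- do.call(rbind, rxns)
    n_base <- sum(rx$is_exchange)
    extra <- n_exchanges - n_base
    if (extra > 0) {
      # extra secretions on randomly chosen trunk intermediates
      trunk_mets <- unlist(lapply(seq_len(n_linear_chains), function(c_i)
        paste0("M", c_i, "_", seq_len(chain_length))))
      pick <- sample(trunk_mets, min(extra, length(trunk_mets)))
      for (m in pick)
        add_rxn(paste0("EX_extra_", m), setNames(-1, m), exch = TRUE,
                subsystem = "exchange")
      rx <- do.call(rbind, rxns)
    }
    metabolic_model(do.call(rbind, mets), rx,
                    id = sprintf("synthetic_seed%d", seed))
  })
}

# All complete uptake-to-secretion paths of a generated network, as lists of
# reaction ids. Works on any single-substrate/single-product irreversible
# network (which generate_network produces).
network_paths <- function(model) {
  rx <- model$reactions
  uptakes <- rx$id[rx$is_exchange &
                     vapply(rx$stoich, function(s) s[[1]] > 0, TRUE)]
  # adjacency: metabolite -> consuming internal reactions / secretions
  consumers <- function(met) rx$id[vapply(rx$stoich, function(s)
    met %in% names(s) && s[[met]] < 0, TRUE)]
  paths <- list()
  walk <- function(rxn_id, acc) {
    acc <- c(acc, rxn_id)
    k <- match(rxn_id, rx$id)
    st <- rx$stoich[[k]]
    prods <- names(st)[st > 0]
    if (!length(prods)) { # secretion: path complete
      paths[[length(paths) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (p in prods) for (nxt in consumers(p)) walk(nxt, acc)
  }
  for (u in uptakes) walk(u, character(0))
  paths
}

#' Plant a flux-consistent activity ground truth
#'
#' Selects a union of complete uptake-to-secretion paths covering
#' approximately `active_fraction` of the reactions; those reactions are
#' planted ACTIVE and all others INACTIVE. By construction an LP witness
#' exists carrying at least `epsilon` flux on every planted-active reaction
#' with every planted-inactive reaction at zero; the witness is verified and
#' stored in the `witness` attribute.
#'
#' @param model a network from [generate_network()] (or any
#'   single-substrate/product irreversible network).
#' @param active_fraction target fraction of reactions planted ACTIVE,
#'   in (0, 1).
#' @param seed integer seed.
#' @param epsilon activity flux threshold for the witness (default 1).
#' @param tol_fraction acceptable deviation from the target fraction
#'   (default 0.25) before erroring with the closest achievable value.
#' @return named character vector of planted states over all reactions, with
#'   attribute `witness` (the verifying flux vector).
#' @export
plant_states <- function(model, active_fraction, seed, epsilon = 1,
                         tol_fraction = 0.25) {
  stopifnot(active_fraction > 0, active_fraction < 1)
  paths <- network_paths(model)
  if (!length(paths)) stop("model has no complete uptake-to-secretion path")
  n <- nrow(model$reactions)
  with_seed(seed, {
    ord <- sample(seq_along(paths))
    acc <- character(0)
    cum <- vector("list", length(ord))
    for (i in seq_along(ord)) {
      acc <- union(acc, paths[[ord[i]]])
      cum[[i]] <- acc
    }
    fracs <- vapply(cum, length, 0L) / n
    best <- cum[[which.min(abs(fracs - active_fraction))]]
    achieved <- length(best) / n
    if (abs(achieved - active_fraction) > tol_fraction)
      stop(sprintf(paste0("no flux-consistent planting near fraction %.2f; ",
                          "closest achievable is %.2f"),
                   active_fraction, achieved))
    states <- setNames(rep("INACTIVE", n), model$reactions$id)
    states[best] <- "ACTIVE"
    witness <- planting_witness(model, states, epsilon)
    if (is.null(witness))
      stop("internal error: planted states admit no flux witness")
    attr(states, "witness") <- witness
    states
  })
}

# LP witness: flux >= epsilon on planted-active, zero on planted-inactive.
planting_witness <- function(model, states, epsilon = 1) {
  con <- fba_constraints(model)
  lb <- con$lb
  ub <- con$ub
  act <- states == "ACTIVE"
  lb[act] <- pmax(lb[act], epsilon)
  ub[!act] <- 0
  if (any(lb > ub)) return(NULL)
  res <- lp_solve(rep(0, ncol(con$A)), con$A, con$rel, con$rhs, lb, ub)
  if (res$status != "optimal") return(NULL)
  setNames(res$x, model$reactions$id)
}

#' Simulate replicate expression data from planted states
#'
#' Genes of planted-ACTIVE reactions draw their baseline level from a
#' well-separated high log-normal component (location log 100) and genes of
#' INACTIVE reactions from a low one (location log 1; both sdlog 0.25), so a
#' symmetric percentile split recovers the two groups at zero noise. With
#' probability `noise_flip_prob` a gene swaps components (label noise); the
#' flip decisions use one uniform draw per gene compared against the flip
#' probability, so the flipped sets are nested across noise levels for a
#' fixed seed. Replicates add independent Gaussian jitter (sd
#' `replicate_sd`), truncated at zero.
#'
#' @param model the network the states refer to (supplies the gene of each
#'   reaction).
#' @param states named planted states from [plant_states()].
#' @param noise_flip_prob probability in `[0, 0.5)` of swapping a gene's
#'   component.
#' @param replicate_sd standard deviation of the per-replicate jitter.
#' @param n_replicates replicates per condition (default 3).
#' @param seed integer seed.
#' @param condition condition label.
#' @return an `expression_profile`.
#' @export
expression_from_states <- function(model, states, noise_flip_prob = 0,
                                   replicate_sd = 0, n_replicates = 3,
                                   seed = 1, condition = "M") {
  stopifnot(noise_flip_prob >= 0, noise_flip_prob < 0.5)
  rx <- model$reactions
  has_gene <- nzchar(rx$gpr)
  genes <- vapply(which(has_gene), function(k) gpr_genes(parse_gpr(rx$gpr[k]))[1], "")
  gene_state <- setNames(states[rx$id[has_gene]], genes)
  with_seed(seed, {
    u <- runif(length(genes))
    flipped <- u < noise_flip_prob
    eff <- ifelse(xor(gene_state == "ACTIVE", flipped), "high", "low")
    base <- ifelse(eff == "high",
                   rlnorm(length(genes), meanlog = log(100), sdlog = 0.25),
                   rlnorm(length(genes), meanlog = log(1), sdlog = 0.25))
    reps <- vapply(seq_len(n_replicates), function(j)
      pmax(0, base + rnorm(length(genes), 0, replicate_sd)),
      numeric(length(genes)))
    rownames(reps) <- genes
    colnames(reps) <- paste0(condition, "_rep", seq_len(n_replicates))
    expression_profile(condition, reps)
  })
}

#' Generate a complete two-condition synthetic study
#'
#' Emulates the structure of a two-subpopulation study: one network, two
#' conditions ("M" and "S") with partially disjoint planted active
#' sub-networks, three noisy expression replicates per condition, and
#' qualitative measured-exchange labels derived from each planting's flux
#' witness. With `disjointness = 1` condition S takes the opposite
#' path-selection decision from M on every path; with `disjointness = 0` the
#' two conditions are identical.
#'
#' @param n_chains,branch_factor,chain_length network shape
#'   (see [generate_network()]); defaults 2 linear chains of length 5.
#' @param active_fraction target planted-active fraction for condition M.
#' @param disjointness fraction in `[0, 1]` of paths on which S's selection
#'   is flipped relative to M.
#' @param noise_flip_prob,replicate_sd expression noise
#'   (see [expression_from_states()]).
#' @param n_replicates replicates per condition.
#' @param epsilon activity flux threshold.
#' @param seed integer seed controlling everything.
#' @return object of class `study_fixture`: `model`, `profiles` (list M/S),
#'   `planted_states` (list M/S), `measured_exchanges` (list M/S of
#'   data.frames metabolite/direction/status), `seed`.
#' @export
generate_study <- function(n_chains = 2, branch_factor = 1, chain_length = 5,
                           active_fraction = 0.5, disjointness = 1,
                           noise_flip_prob = 0, replicate_sd = 0,
                           n_replicates = 3, epsilon = 1, seed = 1) {
  stopifnot(disjointness >= 0, disjointness <= 1)
  model <- generate_network(n_chains, branch_factor,
                            n_exchanges = n_chains * (1 + branch_factor),
                            seed = seed, chain_length = chain_length)
  paths <- network_paths(model)
  n <- nrow(model$reactions)
  with_seed(seed + 1L, {
    ord <- sample(seq_along(paths))
    sel_m <- rep(FALSE, length(paths))
    covered <- character(0)
    for (i in ord) {
      if (length(covered) / n >= active_fraction) break
      sel_m[i] <- TRUE
      covered <- union(covered, paths[[i]])
    }
    n_flip <- round(disjointness * length(paths))
    flip <- ord[seq_len(n_flip)]
    sel_s <- sel_m
    sel_s[flip] <- !sel_s[flip]
    if (!any(sel_s)) sel_s[ord[length(ord)]] <- TRUE # S must secrete something
  })
  states_from_sel <- function(sel) {
    act <- unique(unlist(paths[sel]))
    states <- setNames(rep("INACTIVE", n), model$reactions$id)
    states[act] <- "ACTIVE"
    w <- planting_witness(model, states, epsilon)
    if (is.null(w)) stop("internal error: inconsistent planting")
    attr(states, "witness") <- w
    states
  }
  planted <- list(M = states_from_sel(sel_m), S = states_from_sel(sel_s))
  profiles <- list(
    M = expression_from_states(model, planted$M, noise_flip_prob, replicate_sd,
                               n_replicates, seed = seed + 2L, condition = "M"),
    S = expression_from_states(model, planted$S, noise_flip_prob, replicate_sd,
                               n_replicates, seed = seed + 3L, condition = "S"))
  measured <- lapply(planted, function(st) {
    w <- attr(st, "witness")
    rx <- model$reactions
    rows <- lapply(which(rx$is_exchange), function(k) {
      st1 <- rx$stoich[[k]]
      data.frame(metabolite = names(st1),
                 direction = if (st1[[1]] < 0) "secretion" else "uptake",
                 status = if (w[[rx$id[k]]] >= epsilon - 1e-6) "active"
                          else "inactive",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  structure(list(model = model, profiles = profiles, planted_states = planted,
                 measured_exchanges = measured, seed = seed),
            class = "study_fixture")
}

#' @export
print.study_fixture <- function(x, ...) {
  cat("Synthetic study fixture (seed ", x$seed, ")\n", sep = "")
  print(x$model)
  for (cond in names(x$planted_states))
    cat(sprintf("  condition %s: %d planted ACTIVE / %d reactions\n", cond,
                sum(x$planted_states[[cond]] == "ACTIVE"),
                length(x$planted_states[[cond]])))
  invisible(x)
}

#' Write a study fixture as a plain-text bundle
#'
#' Writes the model (json_toy), one expression TSV per condition, the planted
#' ground truth and the measured-exchange labels into a directory.
#'
#' @param study a `study_fixture`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(study$model, file.path(dir, "model.json"), format = "json_toy")
  for (cond in names(study$profiles)) {
    p <- study$profiles[[cond]]
    tab <- data.frame(gene = rownames(p$replicates), p$replicates,
                      check.names = FALSE)
    write.table(tab, file.path(dir, paste0("expression_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(reaction = names(study$planted_states[[cond]]),
                           state = unname(study$planted_states[[cond]])),
                file.path(dir, paste0("planted_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(study$measured_exchanges[[cond]],
                file.path(dir, paste0("measured_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
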