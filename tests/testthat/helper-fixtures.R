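# Shared fixtures and independent oracles, all built in code.

# Minimal model builder: rxns is a list of lists with fields id, stoich,
# (lb, ub, gpr, subsystem, exchange optional).
toy_model <- function(rxns, mets = NULL, id = "toy") {
  if (is.null(mets))
    mets <- sort(unique(unlist(lapply(rxns, function(r) names(r$stoich)))))
  met_df <- data.frame(id = mets, name = mets, compartment = "c",
                       stringsAsFactors = FALSE)
  rx_df <- do.call(rbind, lapply(rxns, function(r) {
    data.frame(id = r$id,
               lower_bound = if (is.null(r$lb)) 0 else r$lb,
               upper_bound = if (is.null(r$ub)) 1000 else r$ub,
               reversible = if (is.null(r$lb)) FALSE else r$lb < 0,
               gpr = if (is.null(r$gpr)) "" else r$gpr,
               subsystem = if (is.null(r$subsystem)) "" else r$subsystem,
               is_exchange = if (is.null(r$exchange)) length(r$stoich) == 1L
                             else r$exchange,
               stoich = I(list(r$stoich)), stringsAsFactors = FALSE)
  }))
  metabolic_model(met_df, rx_df, id = id)
}

# Linear chain EX_in -> A -> B -> EX_out with given bounds.
chain_model <- function(ub = 10) {
  toy_model(list(
    list(id = "EX_in", stoich = c(A = 1), ub = ub),
    list(id = "R_AB", stoich = c(A = -1, B = 1), ub = ub),
    list(id = "EX_out", stoich = c(B = -1), ub = ub)))
}

# The two-labelled-reaction worked example: uptake A; R1: A->B (high);
# R2: A->C (low); secretions of B and C.
worked_example <- function() {
  model <- toy_model(list(
    list(id = "EX_A", stoich = c(A = 1)),
    list(id = "R1", stoich = c(A = -1, B = 1)),
    list(id = "R2", stoich = c(A = -1, C = 1)),
    list(id = "EX_B", stoich = c(B = -1)),
    list(id = "EX_C", stoich = c(C = -1))))
  cls <- manual_classification(model, R_H = "R1", R_L = "R2")
  imat_problem(model, cls)
}

# Build a reaction_classification by hand (bypassing percentiles).
manual_classification <- function(model, R_H = character(0), R_L = character(0),
                                  thresholds = c(33, 66)) {
  structure(list(R_H = R_H, R_L = R_L,
                 moderate = setdiff(model$reactions$id, c(R_H, R_L)),
                 thresholds = thresholds,
                 cutoffs = c(lower = NA_real_, upper = NA_real_)),
            class = "reaction_classification")
}

# Random classification over a model's reactions (for solver stress tests).
random_classification <- function(model, n_labelled) {
  ids <- model$reactions$id
  lab <- sample(ids, min(length(ids), n_labelled))
  high <- sample(c(TRUE, FALSE), length(lab), replace = TRUE)
  manual_classification(model, R_H = lab[high], R_L = lab[!high])
}

# Independent two-sided Fisher oracle: enumerate the hypergeometric
# distribution over all tables with the observed margins and sum the
# probabilities of tables at most as likely as the observed one.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(xs, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random GPR rule over the given genes (for parser/evaluator properties).
random_gpr_text <- function(genes, depth = 2) {
  if (depth == 0 || runif(1) < 0.35) return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  kids <- vapply(seq_len(k), function(i)
    random_gpr_text(genes, depth - 1), "")
  paste0("(", paste(kids, collapse = paste0(" ", op, " ")), ")")
}
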