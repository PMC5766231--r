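# Expression handling: replicate aggregation, GPR-based mapping of gene
# levels onto reactions, percentile thresholding into highly / lowly /
# moderately expressed reaction sets, and data-driven selection of the
# symmetric threshold pair.

#' Construct an expression profile
#'
#' One experimental condition with one or more replicates of gene-level
#' expression (e.g. RMA-normalized microarray intensities aggregated to genes
#' upstream of this package). All replicates must cover the same gene set.
#'
#' @param condition condition label, e.g. `"M"`.
#' @param replicates numeric matrix (genes in rows, named; replicates in
#'   columns) or a list of named numeric vectors.
#' @return an object of class `expression_profile`.
#' @export
expression_profile <- function(condition, replicates) {
  if (is.list(replicates) && !is.data.frame(replicates)) {
    genes <- names(replicates[[1]])
    for (r in replicates)
      if (!setequal(names(r), genes))
        stop("all replicates must share the same gene set")
    replicates <- vapply(replicates, function(r) r[genes], numeric(length(genes)))
    rownames(replicates) <- genes
  }
  replicates <- as.matrix(replicates)
  if (is.null(rownames(replicates))) stop("replicates must have gene row names")
  if (ncol(replicates) < 1) stop("need at least one replicate")
  if (anyNA(replicates))
    stop("gene(s) missing in some replicates: ",
         paste(head(rownames(replicates)[apply(is.na(replicates), 1, any)], 5),
               collapse = ", "))
  structure(list(condition = condition, replicates = replicates),
            class = "expression_profile")
}

#' Read an expression profile from TSV
#'
#' Expected layout: first column gene id, remaining columns one per
#' replicate; one file per condition.
#'
#' @param path TSV file path.
#' @param condition condition label (default: file name without extension).
#' @return an `expression_profile`.
#' @export
read_expression <- function(path, condition = NULL) {
  if (is.null(condition)) condition <- sub("\\.[^.]*$", "", basename(path))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  expression_profile(condition, m)
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("Expression profile '", x$condition, "': ", nrow(x$replicates),
      " genes x ", ncol(x$replicates), " replicates\n", sep = "")
  invisible(x)
}

#' Aggregate replicates to one expression value per gene
#'
#' Per-gene arithmetic mean across replicates. With a single replicate this
#' is the identity.
#'
#' @param profile an `expression_profile`.
#' @return named numeric vector of mean expression per gene.
#' @export
aggregate_replicates <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  rowMeans(profile$replicates)
}

#' Map gene expression onto reactions through GPR rules
#'
#' Each reaction with a non-empty GPR gets the min/max evaluation of its rule
#' ([evaluate_gpr()]); reactions without a GPR get `NA` ("no data").
#'
#' @param model a `metabolic_model`.
#' @param expression named numeric vector of gene levels, or an
#'   `expression_profile` (aggregated with [aggregate_replicates()] first).
#' @return named numeric vector over all reaction ids, `NA` where no data.
#' @export
reaction_expression <- function(model, expression) {
  if (inherits(expression, "expression_profile"))
    expression <- aggregate_replicates(expression)
  rx <- model$reactions
  vals <- vapply(seq_len(nrow(rx)), function(k) {
    evaluate_gpr(parse_gpr(rx$gpr[k]), expression)
  }, 0)
  setNames(vals, rx$id)
}

#' Partition reactions into highly / lowly / moderately expressed sets
#'
#' Percentile cutoffs are computed over the numeric entries of the
#' reaction-expression table (linear interpolation between order statistics,
#' R's default quantile type 7). A reaction strictly above the upper cutoff
#' goes to `R_H`, strictly below the lower cutoff to `R_L`; everything else
#' (including reactions without expression data) is moderate.
#'
#' @param table named numeric vector from [reaction_expression()].
#' @param thresholds numeric pair `c(lower, upper)` of percentiles in (0,100),
#'   lower < upper; default `c(33, 66)`.
#' @return an object of class `reaction_classification` with elements `R_H`,
#'   `R_L`, `moderate`, `thresholds`, `cutoffs`.
#' @export
classify_reactions <- function(table, thresholds = c(33, 66)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2],
            all(thresholds > 0), all(thresholds < 100))
  vals <- table[!is.na(table)]
  if (!length(vals)) stop("no reaction has expression data")
  cuts <- quantile(vals, thresholds / 100, names = FALSE, type = 7)
  r_h <- names(vals)[vals > cuts[2]]
  r_l <- names(vals)[vals < cuts[1]]
  structure(list(R_H = r_h, R_L = r_l,
                 moderate = setdiff(names(table), c(r_h, r_l)),
                 thresholds = thresholds,
                 cutoffs = setNames(cuts, c("lower", "upper"))),
            class = "reaction_classification")
}

#' @export
print.reaction_classification <- function(x, ...) {
  cat(sprintf("Reaction classification at percentiles (%g, %g):\n",
              x$thresholds[1], x$thresholds[2]))
  cat(sprintf("  R_H (high): %d   R_L (low): %d   moderate: %d\n",
              length(x$R_H), length(x$R_L), length(x$moderate)))
  cat(sprintf("  expression cutoffs: low < %.4g, high > %.4g\n",
              x$cutoffs[["lower"]], x$cutoffs[["upper"]]))
  invisible(x)
}

#' Select symmetric percentile thresholds from two conditions
#'
#' For each candidate lower percentile `q`, both conditions are classified at
#' `(q, 100 - q)` and the discordant reactions are counted: those highly
#' expressed in one condition and lowly expressed in the other (both
#' directions summed). The pair maximizing this count is returned; ties are
#' broken toward the pair closest to (33, 66), then toward the smaller `q`.
#'
#' @param table_A,table_B reaction-expression tables over the same reactions.
#' @param candidate_lowers candidate lower percentiles in (0, 50);
#'   default `c(25, 33, 40)`.
#' @return list with `thresholds` (the selected pair) and `counts` (named
#'   discordance count per candidate).
#' @export
select_thresholds <- function(table_A, table_B, candidate_lowers = c(25, 33, 40)) {
  if (!length(candidate_lowers)) stop("empty candidate list")
  stopifnot(all(candidate_lowers > 0), all(candidate_lowers < 50))
  if (!setequal(names(table_A), names(table_B)))
    stop("the two tables must cover the same reactions")
  counts <- vapply(candidate_lowers, function(q) {
    ca <- classify_reactions(table_A, c(q, 100 - q))
    cb <- classify_reactions(table_B, c(q, 100 - q))
    length(intersect(ca$R_H, cb$R_L)) + length(intersect(ca$R_L, cb$R_H))
  }, 0L)
  names(counts) <- as.character(candidate_lowers)
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    d <- abs(candidate_lowers[best] - 33)
    best <- best[d == min(d)]
    best <- best[which.min(candidate_lowers[best])]
  }
  q <- candidate_lowers[best]
  list(thresholds = c(q, 100 - q), counts = counts)
}
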