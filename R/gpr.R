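# Gene-protein-reaction (GPR) rules: "and/or" sentences over gene ids, where
# "and" encodes an enzyme complex (all subunits required) and "or" encodes
# isoenzymes (any suffices). For expression integration the rule is evaluated
# with "and" replaced by minimum and "or" by maximum: a complex is only as
# expressed as its least expressed subunit, while isoenzymes contribute their
# best-expressed member.

#' Parse a GPR rule
#'
#' Grammar: `expr := term ("or" term)*; term := factor ("and" factor)*;
#' factor := "(" expr ")" | gene`. "and" binds tighter than "or"; parentheses
#' override. Keywords are case-insensitive; any other token is a gene id.
#'
#' @param text GPR string, e.g. `"(geneA and geneB) or (geneC and geneD)"`.
#'   An empty (or all-whitespace) string yields `NULL` (no rule).
#' @return a rule tree: either `list(gene = id)` or
#'   `list(op = "and"|"or", children = list(...))`, of class `gpr_rule`.
#' @export
#' @examples
#' parse_gpr("(geneA and geneB) or (geneC and geneD)")
parse_gpr <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 0L
  peek <- function() if (pos < length(toks)) toks[pos + 1L] else NA_character_
  advance <- function() {
    pos <<- pos + 1L
    toks[pos]
  }
  expect <- function(what) {
    t <- peek()
    if (is.na(t) || t != what)
      stop(sprintf("GPR parse error at token %d: expected '%s', found '%s'",
                   pos + 1L, what, if (is.na(t)) "<end>" else t))
    advance()
  }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw
  parse_factor <- function() {
    t <- peek()
    if (is.na(t))
      stop(sprintf("GPR parse error at token %d: unexpected end of rule", pos + 1L))
    if (t == "(") {
      advance()
      e <- parse_expr()
      expect(")")
      return(e)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or"))
      stop(sprintf("GPR parse error at token %d: unexpected '%s'", pos + 1L, t))
    advance()
    list(gene = t)
  }
  parse_term <- function() {
    kids <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      advance()
      kids[[length(kids) + 1L]] <- parse_factor()
    }
    if (length(kids) == 1L) kids[[1L]] else list(op = "and", children = kids)
  }
  parse_expr <- function() {
    kids <- list(parse_term())
    while (is_kw(peek(), "or")) {
      advance()
      kids[[length(kids) + 1L]] <- parse_term()
    }
    if (length(kids) == 1L) kids[[1L]] else list(op = "or", children = kids)
  }
  rule <- parse_expr()
  if (pos < length(toks))
    stop(sprintf("GPR parse error at token %d: unexpected '%s'",
                 pos + 1L, toks[pos + 1L]))
  class(rule) <- c("gpr_rule", class(rule))
  rule
}

#' Render a GPR rule back to text
#'
#' Inverse of [parse_gpr()] up to whitespace and redundant parentheses:
#' `parse_gpr(render_gpr(r))` is semantically identical to `r`.
#'
#' @param rule a rule tree from [parse_gpr()] (or `NULL`).
#' @return a GPR string.
#' @export
render_gpr <- function(rule) {
  if (is.null(rule)) return("")
  if (!is.null(rule$gene)) return(rule$gene)
  parts <- vapply(rule$children, function(ch) {
    txt <- render_gpr(ch)
    if (rule$op == "and" && !is.null(ch$op) && ch$op == "or")
      paste0("(", txt, ")") else txt
  }, "")
  paste(parts, collapse = paste0(" ", rule$op, " "))
}

# All gene ids appearing in a rule.
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character(0))
  if (!is.null(rule$gene)) return(rule$gene)
  unique(unlist(lapply(rule$children, gpr_genes)))
}

#' Evaluate a GPR rule under the min/max substitution
#'
#' "and" nodes take the minimum of their children, "or" nodes the maximum. A
#' gene with no measurement is ignored within its parent node (the min/max is
#' taken over measured children only); a rule in which no gene is measured
#' evaluates to `NA` ("no data").
#'
#' @param rule a rule tree from [parse_gpr()] (or `NULL`, giving `NA`).
#' @param expression named numeric vector of gene expression levels.
#' @return a single numeric value, or `NA_real_` when no leaf is measured.
#' @export
#' @examples
#' r <- parse_gpr("(geneA and geneB) or (geneC and geneD)")
#' evaluate_gpr(r, c(geneA = 0.5, geneB = 3, geneC = 1, geneD = 0.1)) # 0.5
evaluate_gpr <- function(rule, expression) {
  if (is.null(rule)) return(NA_real_)
  if (!is.null(rule$gene)) {
    if (!(rule$gene %in% names(expression))) return(NA_real_)
    return(as.numeric(expression[[rule$gene]]))
  }
  vals <- vapply(rule$children, evaluate_gpr, 0, expression = expression)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  if (rule$op == "and") min(vals) else max(vals)
}
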