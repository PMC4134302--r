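#' Parse a gene-protein-reaction rule
#'
#' Accepts infix rules with case-insensitive `and`/`or` and parentheses,
#' e.g. `"g1 or (g2 and g3)"`. `and` binds tighter than `or`. The empty
#' string (or `NA`) yields `NULL`, the empty rule.
#'
#' @param text rule string.
#' @return `NULL`, or a tree of nested lists: `list(kind = "leaf", gene =
#'   id)` or `list(kind = "and"|"or", children = list(...))`; `and`/`or`
#'   nodes carry at least two children (chains are flattened).
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks$type))
    stop("GPR parse error at position ", st$toks$at[st$pos],
         ": unexpected '", st$toks$text[st$pos], "'")
  tree
}

gpr_tokenize <- function(text) {
  type <- character(); txt <- character(); at <- integer()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch == "(") { type <- c(type, "lpar"); txt <- c(txt, "("); at <- c(at, i); i <- i + 1L; next }
    if (ch == ")") { type <- c(type, "rpar"); txt <- c(txt, ")"); at <- c(at, i); i <- i + 1L; next }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[^\\s()]+", substr(text, i, n), perl = TRUE))
    word <- m[1]
    lw <- tolower(word)
    type <- c(type, if (lw == "and") "and" else if (lw == "or") "or" else "gene")
    txt <- c(txt, word); at <- c(at, i)
    i <- i + nchar(word)
  }
  list(type = type, text = txt, at = at)
}

gpr_peek <- function(st) if (st$pos <= length(st$toks$type)) st$toks$type[st$pos] else ""

gpr_parse_or <- function(st) {
  kids <- list(gpr_parse_and(st))
  while (gpr_peek(st) == "or") {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_and(st)))
  }
  gpr_node("or", kids)
}

gpr_parse_and <- function(st) {
  kids <- list(gpr_parse_atom(st))
  while (gpr_peek(st) == "and") {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_atom(st)))
  }
  gpr_node("and", kids)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (tk == "gene") {
    g <- st$toks$text[st$pos]
    st$pos <- st$pos + 1L
    return(list(kind = "leaf", gene = g))
  }
  if (tk == "lpar") {
    open_at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    tree <- gpr_parse_or(st)
    if (gpr_peek(st) != "rpar")
      stop("GPR parse error: unbalanced parenthesis opened at position ",
           open_at)
    st$pos <- st$pos + 1L
    return(tree)
  }
  pos <- if (st$pos <= length(st$toks$at)) st$toks$at[st$pos] else NA_integer_
  stop("GPR parse error at position ", pos, ": expected gene or '('")
}

gpr_node <- function(kind, kids) {
  # flatten same-operator chains so and/or nodes have >= 2 children
  flat <- list()
  for (k in kids) {
    if (!is.null(k$kind) && k$kind == kind) flat <- c(flat, k$children)
    else flat <- c(flat, list(k))
  }
  if (length(flat) == 1L) return(flat[[1]])
  list(kind = kind, children = flat)
}

#' Genes referenced by a GPR tree
#' @param tree result of [parse_gpr()].
#' @return character vector of gene ids (possibly empty).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$kind == "leaf") return(tree$gene)
  unique(unlist(lapply(tree$children, gpr_genes)))
}

#' Evaluate a GPR tree over tri-level gene states
#'
#' `and` takes the minimum of its children, `or` the maximum -- the natural
#' extension of Boolean GPR logic to the -1/0/+1 scale. Genes missing from
#' `levels` count as 0 (moderate).
#'
#' @param tree result of [parse_gpr()]; `NULL` evaluates to 0.
#' @param levels named numeric/integer vector of gene levels in
#'   \{-1, 0, 1\}.
#' @return integer level in \{-1, 0, 1\}.
#' @export
eval_gpr <- function(tree, levels) {
  if (is.null(tree)) return(0L)
  if (tree$kind == "leaf") {
    v <- levels[tree$gene]
    return(if (is.na(v) || !length(v)) 0L else as.integer(v))
  }
  vals <- vapply(tree$children, eval_gpr, 0L, levels = levels)
  if (tree$kind == "and") min(vals) else max(vals)
}

#' Render a GPR tree back to an infix string
#' @param tree result of [parse_gpr()].
#' @return rule string; empty for `NULL`.
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$kind == "leaf") return(tree$gene)
  parts <- vapply(tree$children, function(k) {
    s <- deparse_gpr(k)
    if (!is.null(k$kind) && k$kind != "leaf" && k$kind != tree$kind)
      s <- paste0("(", s, ")")
    s
  }, "")
  paste(parts, collapse = paste0(" ", tree$kind, " "))
}
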