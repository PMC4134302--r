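#' Discretize one sample's expression to tri-level gene states
#'
#' A gene is called highly expressed (+1) when its value exceeds the mean
#' plus `k` standard deviations of the values in that sample, lowly
#' expressed (-1) below mean minus `k` SD, and moderate (0) otherwise.
#' The mean and (n-1 denominator) SD are taken across genes within the
#' sample; ties exactly at a threshold are left at 0.
#'
#' @param values named numeric vector, one expression value per gene.
#' @param k SD multiplier (default 0.3).
#' @return named integer vector of levels in \{-1, 0, 1\}.
#' @export
discretize_sample <- function(values, k = 0.3) {
  stopifnot(length(values) >= 2L, k > 0, all(is.finite(values)))
  s <- stats::sd(values)
  if (s == 0) {
    warning("constant expression vector (SD = 0); all genes set to 0")
    return(stats::setNames(integer(length(values)), names(values)))
  }
  m <- mean(values)
  out <- integer(length(values))
  out[values > m + k * s] <- 1L
  out[values < m - k * s] <- -1L
  stats::setNames(out, names(values))
}

#' Discretize a full expression matrix
#'
#' @param mat genes x samples numeric matrix with rownames (gene ids).
#' @param k SD multiplier.
#' @param axis `"sample"` (default): mean/SD across genes within each
#'   sample; `"gene"`: across samples within each gene.
#' @return integer matrix of the same shape with levels in \{-1, 0, 1\}.
#' @export
discretize_matrix <- function(mat, k = 0.3, axis = c("sample", "gene")) {
  axis <- match.arg(axis)
  mat <- as.matrix(mat)
  out <- if (axis == "sample") {
    apply(mat, 2L, discretize_sample, k = k)
  } else {
    t(apply(mat, 1L, discretize_sample, k = k))
  }
  dimnames(out) <- dimnames(mat)
  out
}

#' Consensus gene states across samples
#'
#' A gene is called +1 (resp. -1) when the share of samples in which it is
#' +1 (resp. -1) is at least `fraction`; otherwise 0. For `fraction >
#' 0.5` the call is necessarily single-valued.
#'
#' @param states genes x samples integer matrix of per-sample levels, or a
#'   list of equally named level vectors.
#' @param fraction required share of samples (default 2/3).
#' @return named integer vector of consensus levels.
#' @export
consensus_states <- function(states, fraction = 2 / 3) {
  if (is.list(states) && !is.data.frame(states))
    states <- do.call(cbind, states)
  states <- as.matrix(states)
  if (ncol(states) == 0L) stop("consensus_states: no samples given")
  stopifnot(fraction > 0, fraction <= 1)
  hi <- rowMeans(states == 1L) >= fraction
  lo <- rowMeans(states == -1L) >= fraction
  out <- integer(nrow(states))
  out[hi] <- 1L
  out[lo & !hi] <- -1L
  stats::setNames(out, rownames(states))
}

#' Map consensus gene states to reaction states
#'
#' Each reaction's GPR is evaluated over the gene levels (`and` = min,
#' `or` = max); reactions with an empty GPR get level 0. Genes missing
#' from `gene_states` are treated as 0.
#'
#' @param model a `metabolic_model`.
#' @param gene_states named integer vector of levels in \{-1, 0, 1\}.
#' @return named integer vector of reaction levels, in reaction
#'   declaration order.
#' @export
map_genes_to_reactions <- function(model, gene_states) {
  lv <- vapply(model$reactions$id, function(rid)
    eval_gpr(model$gpr_trees[[rid]], gene_states), 0L)
  stats::setNames(as.integer(lv), model$reactions$id)
}

#' Extract the R_H / R_L cue sets from reaction states
#' @param reaction_states named integer vector from
#'   [map_genes_to_reactions()].
#' @return list with character vectors `R_H` (level +1) and `R_L`
#'   (level -1).
#' @export
cue_sets <- function(reaction_states) {
  list(R_H = names(reaction_states)[reaction_states == 1L],
       R_L = names(reaction_states)[reaction_states == -1L])
}

#' Full discretization stage: expression matrix to reaction states
#'
#' Restricts the matrix to the model's genes (mirroring the filtering of
#' expression data to metabolic genes), discretizes each sample, forms the
#' consensus and maps it through the GPRs.
#'
#' @inheritParams discretize_matrix
#' @param model a `metabolic_model`.
#' @param fraction consensus fraction (default 2/3).
#' @return list with `gene_states`, `reaction_states`, `cues` (the
#'   R_H/R_L list).
#' @export
reaction_states_from_expression <- function(model, mat, k = 0.3,
                                            fraction = 2 / 3,
                                            axis = c("sample", "gene")) {
  axis <- match.arg(axis)
  keep <- rownames(mat) %in% model$genes
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 2L) stop("fewer than 2 model genes present in matrix")
  disc <- discretize_matrix(mat, k = k, axis = axis)
  cons <- consensus_states(disc, fraction = fraction)
  rs <- map_genes_to_reactions(model, cons)
  list(gene_states = cons, reaction_states = rs, cues = cue_sets(rs))
}

#' Read a gene x sample expression TSV
#'
#' First column gene id, remaining columns one per sample.
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus samples")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values in '", path, "'")
  rownames(mat) <- as.character(df[[1L]])
  if (any(!is.finite(mat))) stop("non-finite expression values in '", path, "'")
  mat
}

#' Read a sample-to-condition map TSV
#'
#' Two columns: sample id, condition label.
#'
#' @param path TSV path.
#' @return named character vector (names = samples, values = conditions).
#' @export
read_conditions <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("condition TSV needs sample and condition columns")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
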