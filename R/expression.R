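# Fold-change categorization of expression dynamics between developmental
# stages and Spearman/Holm correlation analysis of per-individual scores.

#' Categorize an expression transition between two stages
#'
#' Classifies the change in expression between two stages from FPKM
#' values: a decrease with fold change strictly greater than
#' `fc_threshold` is "downregulated", an increase with fold change
#' strictly greater than the threshold is "upregulated", anything else
#' (including a fold change of exactly `fc_threshold`) is "stable". Genes
#' whose expression is below `low_threshold` FPKM at *both* stages are
#' flagged as low-expression. Fold changes are computed on
#' pseudocount-shifted values so zero FPKM is well defined.
#'
#' @param fpkm_from,fpkm_to Non-negative FPKM values (vectorised).
#' @param fc_threshold Fold-change threshold (default 2; strict
#'   inequality).
#' @param low_threshold FPKM below which expression counts as low
#'   (default 5).
#' @param pseudocount Added to both values before the ratio (default
#'   0.01).
#' @return Data frame with columns `fpkm_from`, `fpkm_to`, `fold_change`
#'   (>= 1, max/min orientation), `direction` (`"up"`, `"down"`, `"none"`),
#'   `category` (`"upregulated"`, `"stable"`, `"downregulated"`),
#'   `low_expression`.
#' @examples
#' categorize_transition(10, 4)   # downregulated, FC 2.5
#' categorize_transition(3, 4)    # stable, low-expression flag
#' @export
categorize_transition <- function(fpkm_from, fpkm_to, fc_threshold = 2,
                                  low_threshold = 5, pseudocount = 0.01) {
  if (any(fpkm_from < 0) || any(fpkm_to < 0))
    stop("FPKM values must be non-negative", call. = FALSE)
  n <- max(length(fpkm_from), length(fpkm_to))
  f1 <- rep_len(fpkm_from, n) + pseudocount
  f2 <- rep_len(fpkm_to, n) + pseudocount
  fc <- pmax(f1, f2) / pmin(f1, f2)
  direction <- ifelse(f2 > f1, "up", ifelse(f2 < f1, "down", "none"))
  category <- ifelse(fc > fc_threshold,
                     ifelse(direction == "up", "upregulated", "downregulated"),
                     "stable")
  low <- rep_len(fpkm_from, n) < low_threshold &
         rep_len(fpkm_to, n) < low_threshold
  data.frame(fpkm_from = rep_len(fpkm_from, n),
             fpkm_to = rep_len(fpkm_to, n),
             fold_change = fc, direction = direction,
             category = factor(category,
                               c("upregulated", "stable", "downregulated")),
             low_expression = low)
}

#' Category proportions for stage transitions of an expression table
#'
#' For each requested stage pair, categorizes every gene with
#' [categorize_transition()] and reports the proportions of upregulated /
#' stable / downregulated genes. Because it is ambiguous whether
#' low-expression genes belong in such denominators, proportions are
#' reported both over all genes (`prop_all`) and over genes above the
#' low-expression threshold in at least one of the two stages
#' (`prop_expressed`); low-expression genes are also listed.
#'
#' @param table Numeric matrix (genes x stages) with dimnames, FPKM.
#' @param pairs List of length-2 character vectors (from, to), or a
#'   2-column matrix of stage names.
#' @param ... Passed to [categorize_transition()].
#' @return An object of class `transition_summary`: list, one element per
#'   pair, each with `pair`, `records`, `prop_all`, `prop_expressed`,
#'   `low_expression_genes`.
#' @export
transition_summary <- function(table, pairs, ...) {
  if (!is.matrix(table) || nrow(table) == 0L)
    stop("expression table must be a non-empty genes x stages matrix",
         call. = FALSE)
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  out <- lapply(pairs, function(p) {
    if (!all(p %in% colnames(table)))
      stop("stage(s) not in table: ", paste(setdiff(p, colnames(table)),
                                            collapse = ", "), call. = FALSE)
    rec <- categorize_transition(table[, p[1L]], table[, p[2L]], ...)
    rec$gene <- rownames(table)
    prop_of <- function(r) {
      tab <- table(r$category) / nrow(r)
      as.numeric(tab[c("upregulated", "stable", "downregulated")])
    }
    expressed <- rec[!rec$low_expression, , drop = FALSE]
    list(pair = p,
         records = rec,
         prop_all = stats::setNames(prop_of(rec),
                                    c("upregulated", "stable", "downregulated")),
         prop_expressed = if (nrow(expressed) > 0)
           stats::setNames(prop_of(expressed),
                           c("upregulated", "stable", "downregulated"))
         else stats::setNames(rep(NA_real_, 3L),
                              c("upregulated", "stable", "downregulated")),
         low_expression_genes = rec$gene[rec$low_expression])
  })
  names(out) <- vapply(pairs, paste, character(1L), collapse = "->")
  structure(out, class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  for (nm in names(x)) {
    p <- x[[nm]]$prop_all
    cat(sprintf("%s: up %.2f / stable %.2f / down %.2f (%d low-expression)\n",
                nm, p[1L], p[2L], p[3L],
                length(x[[nm]]$low_expression_genes)))
  }
  invisible(x)
}

#' Spearman correlation matrix with Holm-adjusted p-values
#'
#' Computes pairwise Spearman rank correlations (average ranks for ties)
#' between the columns of a score matrix (individuals x variables), with
#' asymptotic p-values and Holm step-down adjustment across all unordered
#' variable pairs treated as one family. Constant columns have undefined
#' correlations; their pairs are flagged NA and excluded from the Holm
#' family.
#'
#' @param scores Numeric matrix, >= 3 rows (individuals) and >= 2 columns
#'   (variables/time points).
#' @param alpha Significance level applied to adjusted p-values
#'   (default 0.05).
#' @return An object of class `correlation_matrix`: list with `variables`,
#'   `rho`, `p_raw`, `p_holm` (symmetric matrices; unit diagonal for
#'   `rho`), `significant` (logical matrix on adjusted p < `alpha`).
#' @export
spearman_holm <- function(scores, alpha = 0.05) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  if (nrow(scores) < 3L) stop("need >= 3 individuals (rows)", call. = FALSE)
  if (ncol(scores) < 2L) stop("need >= 2 variables (columns)", call. = FALSE)
  vars <- colnames(scores)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(scores)))
  k <- ncol(scores)
  rho <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p_raw <- rho
  diag(rho) <- 1
  constant <- apply(scores, 2L, function(x) stats::sd(x) == 0)
  pairs <- utils::combn(k, 2L)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    if (constant[a] || constant[b]) next   # rho undefined; excluded from family
    ct <- suppressWarnings(
      stats::cor.test(scores[, a], scores[, b], method = "spearman",
                      exact = FALSE))
    rho[a, b] <- rho[b, a] <- unname(ct$estimate)
    p_raw[a, b] <- p_raw[b, a] <- ct$p.value
  }
  p_vec <- p_raw[lower.tri(p_raw)]
  adj <- rep(NA_real_, length(p_vec))
  ok <- !is.na(p_vec)
  adj[ok] <- stats::p.adjust(p_vec[ok], method = "holm")
  p_holm <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p_holm[lower.tri(p_holm)] <- adj
  p_holm[upper.tri(p_holm)] <- t(p_holm)[upper.tri(p_holm)]
  structure(list(variables = vars, rho = rho, p_raw = p_raw,
                 p_holm = p_holm,
                 significant = !is.na(p_holm) & p_holm < alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Spearman rho (Holm-adjusted significance, * p <", 0.05, "):\n")
  m <- format(round(x$rho, 3))
  m[x$significant] <- paste0(m[x$significant], "*")
  print(m, quote = FALSE)
  invisible(x)
}
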