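# Species x gene-family count matrices and Dollo-parsimony reconstruction
# of ancestral presence/absence on rooted (possibly polytomous) species
# trees.

#' Dollo-parsimony reconstruction of a gene family on a species tree
#'
#' Under Dollo parsimony a family is gained exactly once and can only be
#' lost thereafter. The gain is placed at the most recent common ancestor
#' (MRCA) of all species possessing the family; every node on a path from
#' that origin to a possessing leaf is inferred present; losses are the
#' edges from a present parent into an entirely family-free subtree. This
#' is the unique minimal-loss single-gain reconstruction. Polytomies are
#' treated as hard: a loss into each absent child of a present polytomy
#' node counts separately.
#'
#' @param tree Rooted `phylo` tree; leaf labels unique.
#' @param presence Logical/0-1 vector named by tip labels (every tip must
#'   be covered), TRUE where the species possesses the family.
#' @param family Optional family name carried in the result.
#' @return An object of class `dollo_reconstruction`: list with
#'   `node_states` (0/1 per node, tips first then internal nodes, ape
#'   numbering), `origin_node` (node id, or NA when the family is absent
#'   everywhere), `loss_edges` (2-column matrix of parent/child node ids),
#'   `n_losses`, `family`, `tree`.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' dollo_reconstruct(tr, c(A = 1, B = 0, C = 1))  # root origin, 1 loss
#' @export
dollo_reconstruct <- function(tree, presence, family = NA_character_) {
  check_rooted_tree(tree)
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop("leaf labels must be unique", call. = FALSE)
  if (is.null(names(presence)))
    stop("presence must be named by tip labels", call. = FALSE)
  unknown <- setdiff(names(presence), tips)
  if (length(unknown) > 0L)
    stop("presence names leaves not in the tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!all(tips %in% names(presence)))
    stop("presence must cover every leaf of the tree", call. = FALSE)
  pres <- as.logical(presence[tips])
  if (anyNA(pres)) stop("presence must be 0/1 per leaf", call. = FALSE)

  n_tip <- length(tips)
  n_all <- n_tip + tree$Nnode
  edge <- tree$edge

  # number of possessing leaves in each node's subtree (postorder sweep)
  cnt <- integer(n_all)
  cnt[seq_len(n_tip)] <- as.integer(pres)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po)))
    cnt[po[i, 1L]] <- cnt[po[i, 1L]] + cnt[po[i, 2L]]

  possessing <- which(pres)
  if (length(possessing) == 0L) {
    origin <- NA_integer_
    states <- integer(n_all)
  } else {
    origin <- if (length(possessing) == 1L) possessing
              else ape::getMRCA(tree, tips[possessing])
    # descendants-of-origin flags (preorder sweep)
    below <- logical(n_all)
    below[origin] <- TRUE
    pr <- ape::reorder.phylo(tree, "cladewise")$edge
    for (i in seq_len(nrow(pr)))
      if (below[pr[i, 1L]]) below[pr[i, 2L]] <- TRUE
    states <- as.integer(below & cnt > 0L)
  }
  loss <- edge[states[edge[, 1L]] == 1L & states[edge[, 2L]] == 0L, ,
               drop = FALSE]
  colnames(loss) <- c("parent", "child")
  structure(list(node_states = states, origin_node = origin,
                 loss_edges = loss, n_losses = nrow(loss),
                 family = family, tree = tree),
            class = "dollo_reconstruction")
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  fam <- if (is.na(x$family)) "" else paste0(" [", x$family, "]")
  if (is.na(x$origin_node)) {
    cat(sprintf("Dollo reconstruction%s: family absent from all leaves\n", fam))
  } else {
    lab <- node_label_of(x$tree, x$origin_node)
    cat(sprintf("Dollo reconstruction%s: origin at node %d%s, %d loss(es)\n",
                fam, x$origin_node,
                if (nzchar(lab)) paste0(" (", lab, ")") else "", x$n_losses))
  }
  invisible(x)
}

#' Plot a Dollo reconstruction on the tree
#'
#' Draws the species tree with inferred-present nodes filled and loss
#' edges marked.
#'
#' @param x A `dollo_reconstruction`.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.dollo_reconstruction <- function(x, ...) {
  tr <- x$tree
  ape::plot.phylo(tr, show.node.label = TRUE, ...)
  cols <- ifelse(x$node_states == 1L, "black", "white")
  n_tip <- length(tr$tip.label)
  ape::tiplabels(pch = 21, bg = cols[seq_len(n_tip)])
  ape::nodelabels(pch = 21, bg = cols[(n_tip + 1L):length(cols)])
  invisible(x)
}

# A phylo tree is interpreted as rooted at its top node (the outermost
# newick clade). A multifurcation there is a hard polytomy, not ape's
# "unrooted" convention; what is rejected is a tree without a unique top
# node.
check_rooted_tree <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("tree must be a 'phylo' object", call. = FALSE)
  roots <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(roots) != 1L)
    stop("tree must be rooted (exactly one root node)", call. = FALSE)
  invisible(tree)
}

# label of a node: tip label or internal node label if any
node_label_of <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label[node - n_tip]
    if (!is.na(lab)) return(lab)
  }
  ""
}

# resolve an internal-node label to its ape node id
resolve_node_label <- function(tree, node_label) {
  n_tip <- length(tree$tip.label)
  if (is.null(tree$node.label))
    stop("tree has no internal node labels", call. = FALSE)
  hit <- which(tree$node.label == node_label)
  if (length(hit) != 1L)
    stop("unknown (or ambiguous) internal node label: ", node_label,
         call. = FALSE)
  n_tip + hit
}

#' Ancestral gene-family repertoire at a named internal node
#'
#' Runs [dollo_reconstruct()] for every family of a species x family count
#' matrix (counts collapse to presence/absence) and reports the inferred
#' presence state at the requested internal node, e.g. the last common
#' ancestor of metazoans or bilaterians.
#'
#' @param tree Rooted `phylo` tree with internal node labels.
#' @param matrix Species x family matrix of non-negative counts (species
#'   rows must match tree tips).
#' @param node_label Label of an internal node.
#' @return An object of class `ancestral_repertoire`: list with `node`
#'   (label), `presence` (named logical per family), `present_families`
#'   (character vector), `reconstructions` (per-family
#'   `dollo_reconstruction`s).
#' @export
ancestral_repertoire <- function(tree, matrix, node_label) {
  matrix <- validate_repertoire_matrix(matrix, tree)
  node <- resolve_node_label(tree, node_label)
  recs <- lapply(colnames(matrix), function(f) {
    pres <- stats::setNames(matrix[, f] >= 1, rownames(matrix))
    dollo_reconstruct(tree, pres, family = f)
  })
  names(recs) <- colnames(matrix)
  presence <- vapply(recs, function(r) r$node_states[node] == 1L, logical(1L))
  structure(list(node = node_label, presence = presence,
                 present_families = names(presence)[presence],
                 reconstructions = recs),
            class = "ancestral_repertoire")
}

#' @export
print.ancestral_repertoire <- function(x, ...) {
  cat(sprintf("Ancestral repertoire at '%s': %d of %d families present\n",
              x$node, sum(x$presence), length(x$presence)))
  cat(" ", paste(x$present_families, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a species x family repertoire matrix
#'
#' @param matrix Species x family matrix of non-negative integer counts
#'   (or a data frame with species row names).
#' @return Data frame with one row per species: `total_genes` (sum of
#'   counts), `families_present` (count of families with >= 1 member),
#'   `single_copy_families` (families with exactly one member).
#' @export
repertoire_summary <- function(matrix) {
  matrix <- validate_repertoire_matrix(matrix)
  data.frame(species = rownames(matrix),
             total_genes = as.integer(rowSums(matrix)),
             families_present = as.integer(rowSums(matrix >= 1)),
             single_copy_families = as.integer(rowSums(matrix == 1)),
             row.names = NULL)
}

validate_repertoire_matrix <- function(matrix, tree = NULL) {
  if (is.data.frame(matrix)) matrix <- as.matrix(matrix)
  if (!is.matrix(matrix) || length(matrix) == 0L)
    stop("repertoire matrix must be a non-empty species x family matrix",
         call. = FALSE)
  storage.mode(matrix) <- "double"
  if (anyNA(matrix) || any(matrix < 0))
    stop("validation error: counts must be non-negative", call. = FALSE)
  if (!is.null(tree)) {
    missing <- setdiff(rownames(matrix), tree$tip.label)
    if (length(missing) > 0L)
      stop("species not in tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  matrix
}

#' Read a species x family count matrix from TSV
#'
#' Expects species in the first column and one column per family.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix with species row names.
#' @export
read_repertoire_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' The packaged annelid DNA-methylation/NuRD repertoire
#'
#' Returns the gene counts of the 17 DNA-methylation-machinery and NuRD
#' gene families/subfamilies of *Platynereis dumerilii*: one member each
#' for Dnmt1, Dnmt2, Dnmt3, Tet, Tdg, Uhrf, Mbd1/2/3, Mbd4, Chd1/2,
#' Chd6/7/8/9, Hdac1/2, Hdac3, Hdac8, Rbbp4/7, Mta1/2/3 and Gatad2, and
#' four members of the Chd3/4/5 subfamily.
#'
#' @return Named integer vector of length 17.
#' @export
pdum_repertoire <- function() {
  fam <- c("Dnmt1", "Dnmt2", "Dnmt3", "Tet", "Tdg", "Uhrf",
           "Mbd1/2/3", "Mbd4", "Chd1/2", "Chd3/4/5", "Chd6/7/8/9",
           "Hdac1/2", "Hdac3", "Hdac8", "Rbbp4/7", "Mta1/2/3", "Gatad2")
  counts <- rep(1L, 17L)
  counts[fam == "Chd3/4/5"] <- 4L
  stats::setNames(counts, fam)
}
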