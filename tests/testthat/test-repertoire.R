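# Dollo parsimony reconstruction, ancestral repertoires and matrix
# summaries.

test_that("dollo reconstruction matches hand-worked cases", {
  tr <- ape::read.tree(text = "((A,B),C);")
  root <- 4L
  r <- dollo_reconstruct(tr, c(A = 1, B = 0, C = 1))
  expect_identical(r$origin_node, root)
  expect_identical(r$node_states[root], 1L)
  expect_identical(r$n_losses, 1L)
  expect_identical(unname(r$loss_edges[, "child"]), 2L)   # edge into B

  r_all <- dollo_reconstruct(tr, c(A = 1, B = 1, C = 1))
  expect_true(all(r_all$node_states == 1L))
  expect_identical(r_all$n_losses, 0L)

  r_none <- dollo_reconstruct(tr, c(A = 0, B = 0, C = 0))
  expect_true(is.na(r_none$origin_node))
  expect_identical(r_none$n_losses, 0L)

  # hard polytomy: a loss into each absent child counts separately
  poly <- ape::read.tree(text = "(A,B,C,D);")
  rp <- dollo_reconstruct(poly, c(A = 1, B = 1, C = 0, D = 0))
  expect_identical(rp$origin_node, 5L)      # the polytomy root
  expect_identical(rp$n_losses, 2L)

  expect_error(dollo_reconstruct(tr, c(A = 1, B = 0, C = 1, Z = 1)),
               "not in the tree")
  expect_error(dollo_reconstruct(tr, c(A = 1, B = 0)), "every leaf")
})

test_that("dollo states form a single-gain presence subtree", {
  set.seed(91)
  for (i in 1:20) {
    tr <- random_test_tree(sample(4:8, 1))
    n_tip <- length(tr$tip.label)
    pres <- setNames(sample(0:1, n_tip, replace = TRUE), tr$tip.label)
    if (!any(pres == 1)) pres[1] <- 1
    r <- dollo_reconstruct(tr, pres)
    # leaf states reproduce the input
    expect_identical(r$node_states[seq_len(n_tip)], unname(as.integer(pres)))
    # no presence above the origin
    anc <- r$origin_node
    edge <- tr$edge
    repeat {
      up <- edge[edge[, 2] == anc, 1]
      if (length(up) == 0) break
      expect_identical(r$node_states[up], 0L)
      anc <- up
    }
    # gains: exactly one (the origin); counted as 0->1 edges plus the root
    root <- setdiff(edge[, 1], edge[, 2])
    gains <- sum(r$node_states[edge[, 1]] == 0 &
                   r$node_states[edge[, 2]] == 1) + r$node_states[root]
    expect_identical(gains, 1L)
  }
})

test_that("n_losses equals exhaustive single-gain minimization", {
  set.seed(97)
  n_checked <- 0L
  for (i in 1:50) {
    tr <- random_test_tree(sample(3:8, 1))
    n_tip <- length(tr$tip.label)
    oracle <- dollo_oracle_table(tr)
    for (key in seq_len(2^n_tip - 1L)) {     # skip the all-absent pattern
      bits <- as.integer(intToBits(key)[seq_len(n_tip)])
      pres <- setNames(bits, tr$tip.label)
      r <- dollo_reconstruct(tr, pres)
      expect_identical(as.numeric(r$n_losses), oracle[key + 1L])
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 50 * 7)
})

test_that("reconstruction is invariant to child order within polytomies", {
  tr <- ape::read.tree(text = "((A,B,C,D)N1,(E,F)N2)R;")
  tr_rot <- ape::read.tree(text = "((D,C,B,A)N1,(F,E)N2)R;")
  pres <- c(A = 1, B = 0, C = 0, D = 1, E = 0, F = 1)
  r1 <- dollo_reconstruct(tr, pres)
  r2 <- dollo_reconstruct(tr_rot, pres)
  expect_identical(r1$n_losses, r2$n_losses)
  lab <- function(r, node) methatlas:::node_label_of(r$tree, node)
  expect_identical(lab(r1, r1$origin_node), lab(r2, r2$origin_node))
})

test_that("adding an all-absent species never moves another origin", {
  tr <- ape::read.tree(text = "((A,B),(C,D))R;")
  pres <- c(A = 1, B = 1, C = 0, D = 0)
  r1 <- dollo_reconstruct(tr, pres)
  tr2 <- ape::read.tree(text = "(((A,B),(C,D))R,X);")
  r2 <- dollo_reconstruct(tr2, c(pres, X = 0))
  lab1 <- ape::extract.clade(tr, r1$origin_node)$tip.label
  lab2 <- ape::extract.clade(tr2, r2$origin_node)$tip.label
  expect_identical(sort(lab1), sort(lab2))
})

test_that("ancestral repertoires follow Dollo connectivity", {
  tr <- ape::read.tree(
    text = "(S,(C,((P,D)Prot,(H,X)Deut)Bilateria)Eumetazoa)Metazoa;")
  mat <- rbind(S = c(famA = 1, famB = 0, famC = 0),
               C = c(1, 0, 0), P = c(1, 1, 2), D = c(0, 1, 0),
               H = c(1, 0, 0), X = c(1, 0, 0))
  colnames(mat) <- c("famA", "famB", "famC")
  anc_root <- ancestral_repertoire(tr, mat, "Metazoa")
  # famA spans two root children -> present; famB confined to Prot clade;
  # famC only in one species
  expect_true(anc_root$presence["famA"])
  expect_false(anc_root$presence["famB"])
  expect_false(anc_root$presence["famC"])
  anc_prot <- ancestral_repertoire(tr, mat, "Prot")
  expect_true(anc_prot$presence["famB"])
  expect_error(ancestral_repertoire(tr, mat, "Nope"), "unknown|ambiguous")
})

test_that("packaged fixture places both mbd families at the metazoan root", {
  tr <- ape::read.tree(system.file("extdata", "metazoa_demo.nwk",
                                   package = "methatlas"))
  mat <- read_repertoire_matrix(system.file("extdata", "repertoire_demo.tsv",
                                            package = "methatlas"))
  anc <- ancestral_repertoire(tr, mat, "Metazoa")
  expect_true(anc$presence["Mbd1/2/3"])
  expect_true(anc$presence["Mbd4"])
})

test_that("repertoire summary counts totals, presence and single copies", {
  v <- pdum_repertoire()
  m <- matrix(v, nrow = 1, dimnames = list("Platynereis_dumerilii",
                                           names(v)))
  s <- repertoire_summary(m)
  expect_equal(s$families_present, 17L)
  expect_equal(s$single_copy_families, 16L)
  expect_equal(s$total_genes, 20L)
  chd <- grep("^Chd", names(v), value = TRUE)
  expect_equal(sum(v[chd]), 6L)
  bad <- m; bad[1, 1] <- -1
  expect_error(repertoire_summary(bad), "non-negative")
})
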