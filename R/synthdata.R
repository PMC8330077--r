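# Seeded generators for every input the pipeline consumes: CpG-depleted
# transcriptomes, genomes with placed restriction sites and methylation
# states, bisulfite read sets, pyrogram noise, and gene repertoires evolved
# on a species tree.

#' Simulate a CpG-depleted transcriptome
#'
#' Draws sequences from a first-order Markov chain whose stationary
#' mononucleotide composition matches `gc` and whose C->G transition
#' probability is scaled so that the expected CpG observed/expected ratio of
#' a long sequence equals `target_oe`. CpG depletion in methylated genomes
#' is the historical footprint of 5mC deamination (methylated CpG mutating
#' to TpG); the scaled transition probability reproduces its endpoint — a
#' deficit of CG dinucleotides relative to the product of C and G
#' frequencies — without simulating the mutational process itself.
#'
#' The transition matrix is built so the target composition is exactly
#' stationary: the C row has \eqn{P(G|C) = t\,p_G}{P(G|C) = t*pG} with the
#' remaining mass spread proportionally over A, C, T, and the shared
#' A/G/T row is solved from the stationarity constraints.
#'
#' @param n Number of transcripts (>= 1).
#' @param length_range Length-2 integer vector, min and max transcript
#'   length in bp (uniform draw, inclusive).
#' @param gc Stationary GC fraction, strictly between 0 and 1.
#' @param target_oe Target expected CpG o/e (> 0); 1 gives an undepleted
#'   i.i.d.-like chain, values below 1 deplete CpG.
#' @param seed Integer seed; identical arguments give identical output.
#' @return Named character vector of `n` sequences.
#' @examples
#' tx <- simulate_transcriptome(50, c(300, 600), gc = 0.4,
#'                              target_oe = 0.55, seed = 1)
#' @export
simulate_transcriptome <- function(n, length_range = c(500L, 3000L),
                                   gc = 0.4, target_oe = 0.55, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive integer", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  if (target_oe <= 0) stop("target_oe must be > 0", call. = FALSE)
  if (length(length_range) != 2L || any(length_range < 1) ||
      any(length_range > 1e6) || length_range[1] > length_range[2])
    stop("length_range must be (min, max) within [1, 1e6]", call. = FALSE)
  P <- cpg_transition_matrix(gc, target_oe)
  pstat <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  set.seed(as.integer(seed))
  lens <- length_range[1] - 1L +
    sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE)
  Lmax <- max(lens)
  cum <- t(apply(P, 1L, cumsum))
  cur <- sample.int(4L, n, replace = TRUE, prob = pstat)
  M <- matrix(1L, nrow = n, ncol = Lmax)
  M[, 1L] <- cur
  if (Lmax >= 2L) {
    for (j in 2:Lmax) {
      u <- stats::runif(n)
      cc <- cum[cur, , drop = FALSE]
      cur <- 1L + (u > cc[, 1L]) + (u > cc[, 2L]) + (u > cc[, 3L])
      M[, j] <- cur
    }
  }
  codes <- utf8ToInt("ACGT")
  seqs <- vapply(seq_len(n),
                 function(i) intToUtf8(codes[M[i, seq_len(lens[i])]]),
                 character(1L))
  names(seqs) <- sprintf("tx%05d", seq_len(n))
  seqs
}

# Transition matrix (rows/cols A,C,G,T) with stationary composition
# (pA,pC,pG,pT) and P(G|C) = target_oe * pG. Rows A, G, T share one
# distribution solved from stationarity.
cpg_transition_matrix <- function(gc, target_oe) {
  pA <- (1 - gc) / 2; pC <- gc / 2; pG <- gc / 2; pT <- (1 - gc) / 2
  t <- target_oe
  if (t * pG > 1)
    stop("target_oe too large: C->G transition probability would exceed 1",
         call. = FALSE)
  k <- (1 - t * pG) / (1 - pG)          # scale for C-row mass off G
  rowC <- c(pA * k, pC * k, t * pG, pT * k)
  S <- 1 - pC
  qG <- pG * (1 - t * pC) / S
  qO <- c(pA, pC, pT) * (1 - pC * k) / S
  rowO <- c(qO[1], qO[2], qG, qO[3])
  P <- rbind(rowO, rowC, rowO, rowO)
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  if (any(P < 0) || any(P > 1))
    stop("gc/target_oe combination yields invalid transition probabilities",
         call. = FALSE)
  P
}

#' Simulate a genome with placed CCGG and GAATTC sites
#'
#' Generates a linear, single-contig, N-free genome that contains exactly
#' `n_ccgg` non-overlapping CCGG (HpaII/MspI) sites and `n_ecori`
#' non-overlapping GAATTC (EcoRI) sites at seeded random positions, and no
#' accidental occurrence of either motif elsewhere (background occurrences
#' are destroyed by point substitution).
#'
#' @param length Genome length in bp.
#' @param n_ccgg,n_ecori Numbers of sites to place (>= 0).
#' @param gc Background GC fraction.
#' @param seed Integer seed.
#' @return An object of class `genome`: list with elements `seq` (character
#'   scalar), `length`, `ccgg_sites` and `ecori_sites` (0-based start
#'   offsets, sorted), `declared_ccgg_count`, `declared_ecori_count`.
#' @export
simulate_genome_with_sites <- function(length, n_ccgg, n_ecori = 0L,
                                       gc = 0.4, seed = 1L) {
  if (n_ccgg < 0 || n_ecori < 0) stop("site counts must be >= 0", call. = FALSE)
  if (4 * n_ccgg + 6 * n_ecori > length)
    stop("placement error: motifs cannot fit in ", length, " bp", call. = FALSE)
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p)

  # choose non-overlapping spans for the two motifs by rejection
  spans <- matrix(integer(0), ncol = 2L)     # 1-based [start, end]
  place <- function(width, count) {
    starts <- integer(0)
    attempts <- 0L
    while (base::length(starts) < count) {
      attempts <- attempts + 1L
      if (attempts > 200L * max(count, 1L))
        stop("placement error: could not place motifs without overlap",
             call. = FALSE)
      s <- sample.int(length - width + 1L, 1L)
      ok <- !any(s <= spans[, 2L] & (s + width - 1L) >= spans[, 1L])
      if (ok) {
        spans <<- rbind(spans, c(s, s + width - 1L))
        starts <- c(starts, s)
      }
    }
    sort(starts)
  }
  ccgg_starts <- if (n_ccgg > 0) place(4L, n_ccgg) else integer(0)
  ecori_starts <- if (n_ecori > 0) place(6L, n_ecori) else integer(0)
  for (s in ccgg_starts) chars[s:(s + 3L)] <- c("C", "C", "G", "G")
  for (s in ecori_starts) chars[s:(s + 5L)] <- c("G", "A", "A", "T", "T", "C")

  # destroy accidental motif occurrences outside declared spans
  protected <- logical(length)
  for (i in seq_len(nrow(spans))) protected[spans[i, 1L]:spans[i, 2L]] <- TRUE
  for (iter in seq_len(100L)) {
    seqstr <- paste(chars, collapse = "")
    occ_c <- find_sites(seqstr, "CCGG") + 1L       # 1-based
    occ_e <- find_sites(seqstr, "GAATTC") + 1L
    bad_c <- setdiff(occ_c, ccgg_starts)
    bad_e <- setdiff(occ_e, ecori_starts)
    bad <- c(bad_c, bad_e)
    if (base::length(bad) == 0L) break
    widths <- c(rep(4L, base::length(bad_c)), rep(6L, base::length(bad_e)))
    for (j in seq_along(bad)) {
      pos <- bad[j]:(bad[j] + widths[j] - 1L)
      free <- pos[!protected[pos]]
      if (base::length(free) == 0L) next  # fully inside declared spans: impossible by construction
      tgt <- free[1L]
      chars[tgt] <- sample(setdiff(c("A", "C", "G", "T"), chars[tgt]), 1L)
    }
  }
  seqstr <- paste(chars, collapse = "")
  if (!identical(find_sites(seqstr, "CCGG"), as.integer(ccgg_starts - 1L)) ||
      !identical(find_sites(seqstr, "GAATTC"), as.integer(ecori_starts - 1L)))
    stop("placement error: could not purge accidental motif occurrences",
         call. = FALSE)
  g <- structure(list(seq = seqstr,
                      length = as.integer(length),
                      ccgg_sites = as.integer(ccgg_starts - 1L),
                      ecori_sites = as.integer(ecori_starts - 1L),
                      declared_ccgg_count = as.integer(n_ccgg),
                      declared_ecori_count = as.integer(n_ecori)),
                 class = "genome")
  g
}

#' @export
print.genome <- function(x, ...) {
  cat("Simulated linear genome:", x$length, "bp;",
      x$declared_ccgg_count, "CCGG site(s),",
      x$declared_ecori_count, "GAATTC site(s)\n")
  invisible(x)
}

#' Assign methylation states to the CCGG sites of a genome
#'
#' Flags exactly `round(fraction * n_sites)` CCGG sites as methylated,
#' sampled uniformly without replacement, so the noise-free ground truth is
#' an exact count rather than a Bernoulli realisation.
#'
#' @param genome A `genome` object.
#' @param fraction Fraction of CCGG sites to methylate, in \[0, 1\].
#' @param seed Integer seed.
#' @return An object of class `methylome`: data frame with columns `pos`
#'   (0-based CCGG start) and `methylated` (logical), sorted by position.
#' @export
assign_ccgg_methylation <- function(genome, fraction, seed = 1L) {
  stopifnot(inherits(genome, "genome"))
  if (fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]", call. = FALSE)
  sites <- genome$ccgg_sites
  n_m <- round(fraction * length(sites))
  set.seed(as.integer(seed))
  idx <- if (n_m > 0) sample(seq_along(sites), n_m) else integer(0)
  meth <- logical(length(sites))
  meth[idx] <- TRUE
  structure(data.frame(pos = sites, methylated = meth),
            class = c("methylome", "data.frame"))
}

#' Simulate bisulfite-converted reads over a reference locus
#'
#' Forward model of bisulfite conversion followed by sequencing: in each
#' read, every CpG cytosine is methylated with its site-specific
#' probability; a methylated C stays C; an unmethylated C (CpG or not)
#' deaminates to T with probability `conversion_rate`; independent
#' substitution errors at `error_rate` are applied afterwards to all bases.
#' Reads are returned pre-aligned (same length as the reference).
#'
#' @param locus Character scalar, the reference sequence ({A,C,G,T}).
#' @param per_cpg_m Numeric vector of methylation probabilities, one per
#'   CpG cytosine in `locus` (in reference order).
#' @param n_reads Number of reads (> 0).
#' @param conversion_rate Bisulfite conversion efficiency in \[0, 1\].
#' @param error_rate Per-base substitution error rate in \[0, 1\].
#' @param seed Integer seed.
#' @return An object of class `bisulfite_reads`: list with `reference`,
#'   `cpg_positions` (0-based offsets of CpG cytosines), `reads`
#'   (character vector), `conversion_rate`, `error_rate`.
#' @export
simulate_bisulfite_reads <- function(locus, per_cpg_m, n_reads,
                                     conversion_rate = 0.98,
                                     error_rate = 0.001, seed = 1L) {
  if (!is.character(locus) || length(locus) != 1L || nchar(locus) == 0L)
    stop("locus must be a non-empty sequence", call. = FALSE)
  check_dna(locus, allow_n = FALSE)
  if (n_reads <= 0) stop("n_reads must be > 0", call. = FALSE)
  cpg0 <- find_sites(locus, "CG")              # 0-based C offsets
  if (length(per_cpg_m) != length(cpg0))
    stop("per_cpg_m must have one entry per CpG in the locus (",
         length(cpg0), " found)", call. = FALSE)
  if (any(per_cpg_m < 0 | per_cpg_m > 1))
    stop("per_cpg_m entries must be in [0, 1]", call. = FALSE)

  set.seed(as.integer(seed))
  refv <- strsplit(locus, "", fixed = TRUE)[[1L]]
  L <- length(refv)
  M <- matrix(rep(refv, each = n_reads), nrow = n_reads)
  cpg_cols <- cpg0 + 1L
  c_cols <- which(refv == "C")
  noncpg_c <- setdiff(c_cols, cpg_cols)
  for (k in seq_along(cpg_cols)) {
    j <- cpg_cols[k]
    meth <- stats::runif(n_reads) < per_cpg_m[k]
    conv <- stats::runif(n_reads) < conversion_rate
    M[!meth & conv, j] <- "T"
  }
  for (j in noncpg_c) {
    conv <- stats::runif(n_reads) < conversion_rate
    M[conv, j] <- "T"
  }
  if (error_rate > 0) {
    err <- which(stats::runif(n_reads * L) < error_rate)
    if (length(err)) {
      bases <- c("A", "C", "G", "T")
      M[err] <- vapply(M[err],
                       function(b) sample(setdiff(bases, b), 1L), character(1L))
    }
  }
  reads <- apply(M, 1L, paste, collapse = "")
  structure(list(reference = locus, cpg_positions = cpg0, reads = reads,
                 conversion_rate = conversion_rate, error_rate = error_rate),
            class = "bisulfite_reads")
}

#' Add multiplicative noise to a pyrogram
#'
#' Multiplies each peak by an independent positive factor with mean 1 and
#' coefficient of variation `cv` (Gaussian, truncated at 0), emulating
#' proportional light-intensity noise between technical replicates.
#'
#' @param pyro A `pyrogram` object (see [pyrogram_from_digest()]).
#' @param cv Coefficient of variation (>= 0).
#' @param seed Integer seed.
#' @return A `pyrogram` with perturbed peaks.
#' @export
add_pyrogram_noise <- function(pyro, cv, seed = 1L) {
  stopifnot(inherits(pyro, "pyrogram"))
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  f <- pmax(stats::rnorm(length(pyro$peaks), mean = 1, sd = cv), 0)
  pyro$peaks <- pyro$peaks * f
  pyro
}

#' Evolve gene-family counts down a species tree
#'
#' Starting from root copy numbers, each family evolves along every edge:
#' the whole family is lost with probability `loss_rate`; a surviving
#' family gains one copy with probability `dup_rate`. Families are never
#' re-gained after loss, so the histories are Dollo-compatible (single
#' origin at the root).
#'
#' @param tree Rooted `phylo` tree (polytomies allowed).
#' @param families Character vector of family names.
#' @param root_counts Integer vector of copy numbers at the root (>= 1),
#'   recycled to `length(families)`.
#' @param loss_rate,dup_rate Per-edge probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @return Integer matrix, species (tips) x families.
#' @export
simulate_repertoire_evolution <- function(tree, families, root_counts = 1L,
                                          loss_rate = 0.05, dup_rate = 0.05,
                                          seed = 1L) {
  check_rooted_tree(tree)
  if (loss_rate < 0 || loss_rate > 1 || dup_rate < 0 || dup_rate > 1)
    stop("rates must be in [0, 1]", call. = FALSE)
  root_counts <- rep_len(as.integer(root_counts), length(families))
  if (any(root_counts < 1)) stop("root_counts must be >= 1", call. = FALSE)

  set.seed(as.integer(seed))
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  root <- n_tip + 1L
  counts <- matrix(0L, nrow = n_tip + n_node, ncol = length(families))
  counts[root, ] <- root_counts
  edges <- ape::reorder.phylo(tree, "cladewise")$edge   # parents before children
  for (i in seq_len(nrow(edges))) {
    par <- edges[i, 1L]; child <- edges[i, 2L]
    cc <- counts[par, ]
    alive <- cc > 0L
    lost <- alive & (stats::runif(length(cc)) < loss_rate)
    dup <- alive & !lost & (stats::runif(length(cc)) < dup_rate)
    cc[lost] <- 0L
    cc[dup] <- cc[dup] + 1L
    counts[child, ] <- cc
  }
  out <- counts[seq_len(n_tip), , drop = FALSE]
  dimnames(out) <- list(tree$tip.label, families)
  out
}
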