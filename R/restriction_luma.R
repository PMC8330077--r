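# Deterministic forward model of methylation-sensitive restriction
# digestion (HpaII / MspI / EcoRI), virtual gel profiles, pyrosequencing
# fill-in peak generation, and the LUMA percent-methylation estimator.

LUMA_DISPENSATIONS <- c("dATP", "dGTP+dCTP", "dTTP", "H2O",
                        "dGTP+dCTP", "dATP", "dTTP")

#' Find motif occurrences on a sequence
#'
#' Returns 0-based start offsets of all (possibly overlapping) occurrences
#' of `motif` on the given strand, in ascending order.
#'
#' @param seq Character scalar or a `genome` object.
#' @param motif Motif over {A,C,G,T}.
#' @return Integer vector of 0-based starts.
#' @examples
#' find_sites("AAACCGGTT", "CCGG")  # 3
#' @export
find_sites <- function(seq, motif) {
  if (inherits(seq, "genome")) seq <- seq$seq
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L ||
      grepl("[^ACGT]", motif))
    stop("motif must be a non-empty string over {A,C,G,T}", call. = FALSE)
  # overlapping occurrences via lookahead
  m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Digest a genome with methylation-sensitive restriction enzymes
#'
#' MspI cuts every CCGG (C^CGG) regardless of methylation; its
#' methylation-sensitive isoschizomer HpaII cuts only CCGG sites whose
#' internal CpG is unmethylated; EcoRI cuts every GAATTC (G^AATTC).
#' Combined reactions take the union of cut sets. The molecule is linear,
#' so k cuts yield k + 1 fragments.
#'
#' @param genome A `genome` object (or character scalar sequence).
#' @param enzyme One of `"HpaII"`, `"MspI"`, `"EcoRI"`, `"HpaII+EcoRI"`,
#'   `"MspI+EcoRI"`.
#' @param methylome A `methylome` object giving the binary methylation
#'   state of each CCGG site, or NULL (all sites unmethylated).
#' @return An object of class `digest_result`: list with `enzyme`,
#'   `cut_positions` (0-based between-base indices, strictly increasing),
#'   `fragment_lengths`, `ccgg_cuts`, `ecori_cuts`, `genome_length`.
#' @examples
#' digest("AAACCGGAAACCGGAAA", "MspI")  # cuts 4, 11; fragments 4, 7, 6
#' @export
digest <- function(genome, enzyme = c("HpaII", "MspI", "EcoRI",
                                      "HpaII+EcoRI", "MspI+EcoRI"),
                   methylome = NULL) {
  enzyme <- match.arg(enzyme)
  if (is.character(genome)) {
    genome <- structure(list(seq = genome, length = nchar(genome),
                             ccgg_sites = find_sites(genome, "CCGG"),
                             ecori_sites = find_sites(genome, "GAATTC")),
                        class = "genome")
  }
  stopifnot(inherits(genome, "genome"))
  ccgg <- genome$ccgg_sites
  ecori <- genome$ecori_sites
  meth <- rep(FALSE, length(ccgg))
  if (!is.null(methylome)) {
    if (!all(methylome$pos %in% ccgg))
      stop("methylome references position(s) that are not CCGG sites",
           call. = FALSE)
    meth[match(methylome$pos, ccgg)] <- methylome$methylated
  }

  cuts_ccgg <- integer(0); cuts_ecori <- integer(0)
  uses_ccgg_cutter <- enzyme %in% c("HpaII", "MspI", "HpaII+EcoRI", "MspI+EcoRI")
  uses_ecori <- enzyme %in% c("EcoRI", "HpaII+EcoRI", "MspI+EcoRI")
  if (uses_ccgg_cutter) {
    sensitive <- enzyme %in% c("HpaII", "HpaII+EcoRI")
    cut_sites <- if (sensitive) ccgg[!meth] else ccgg
    cuts_ccgg <- cut_sites + 1L          # C^CGG
  }
  if (uses_ecori) cuts_ecori <- ecori + 1L   # G^AATTC
  cuts <- sort(unique(c(cuts_ccgg, cuts_ecori)))
  frag <- diff(c(0L, cuts, genome$length))
  structure(list(enzyme = enzyme, cut_positions = cuts,
                 fragment_lengths = as.integer(frag),
                 ccgg_cuts = length(cuts_ccgg),
                 ecori_cuts = length(cuts_ecori),
                 genome_length = genome$length),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("%s digest: %d cut(s), %d fragment(s) over %d bp\n",
              x$enzyme, length(x$cut_positions), length(x$fragment_lengths),
              x$genome_length))
  invisible(x)
}

#' Virtual gel profile of a digestion
#'
#' Bins fragment mass (sum of bp per bin, i.e. length-weighted as on an
#' ethidium-bromide gel) into log-spaced molecular-weight bins.
#' Out-of-range fragments accumulate in the edge bins, so total mass always
#' equals the genome length.
#'
#' @param result A `digest_result`.
#' @param n_bins Number of bins (>= 1).
#' @param range Length-2 numeric, bp range of the bins (default spans the
#'   observed fragment lengths).
#' @return An object of class `gel_profile`: list with `bin_edges`
#'   (length `n_bins + 1`) and `mass_per_bin`.
#' @export
virtual_gel <- function(result, n_bins = 30L, range = NULL) {
  stopifnot(inherits(result, "digest_result"))
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  fl <- result$fragment_lengths
  if (length(fl) == 0L) stop("no fragments to bin", call. = FALSE)
  if (is.null(range)) range <- c(max(min(fl), 1), max(fl))
  edges <- exp(seq(log(range[1L]), log(max(range[2L], range[1L] + 1e-9)),
                   length.out = n_bins + 1L))
  idx <- findInterval(fl, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)      # clamp out-of-range into edge bins
  mass <- vapply(seq_len(n_bins), function(b) sum(fl[idx == b]), numeric(1L))
  structure(list(bin_edges = edges, mass_per_bin = mass),
            class = "gel_profile")
}

#' Pyrosequencing fill-in peaks of a combined LUMA digestion
#'
#' Models the polymerase fill-in of the digestion overhangs under the LUMA
#' dispensation order dATP; dGTP + dCTP; dTTP; H2O (control); dGTP + dCTP;
#' dATP; dTTP, at one light unit per incorporation. Each CCGG cut leaves
#' two 5'-CG overhangs (one C + one G filled per end); each EcoRI cut
#' leaves two 5'-AATT overhangs (two A + two T per end). Totals are split
#' evenly across the two dispensations of each label; the split is
#' observationally irrelevant because the estimator uses sums.
#'
#' @param result A `digest_result` from a combined reaction
#'   (`"HpaII+EcoRI"` or `"MspI+EcoRI"`).
#' @return An object of class `pyrogram`: list with `reaction`,
#'   `dispensations` (the 7 labels) and `peaks`. A zero EcoRI cut count is
#'   flagged with a warning (the downstream ratio is undefined).
#' @export
pyrogram_from_digest <- function(result) {
  stopifnot(inherits(result, "digest_result"))
  if (!result$enzyme %in% c("HpaII+EcoRI", "MspI+EcoRI"))
    stop("pyrograms are defined for combined reactions (HpaII+EcoRI or MspI+EcoRI)",
         call. = FALSE)
  if (result$ecori_cuts == 0L)
    warning("no EcoRI cuts: LUMA ratio will be undefined", call. = FALSE)
  gc_total <- 4 * result$ccgg_cuts    # 2 ends x (1 C + 1 G)
  a_total <- 4 * result$ecori_cuts    # 2 ends x 2 A
  t_total <- 4 * result$ecori_cuts    # 2 ends x 2 T
  peaks <- c(a_total / 2, gc_total / 2, t_total / 2, 0,
             gc_total / 2, a_total / 2, t_total / 2)
  structure(list(reaction = result$enzyme,
                 dispensations = LUMA_DISPENSATIONS, peaks = peaks),
            class = "pyrogram")
}

#' @export
print.pyrogram <- function(x, ...) {
  cat(sprintf("Pyrogram (%s):\n", x$reaction))
  print(stats::setNames(round(x$peaks, 3), x$dispensations))
  invisible(x)
}

#' Plot a pyrogram as a peak bar chart
#'
#' @param x A `pyrogram` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.pyrogram <- function(x, ...) {
  graphics::barplot(x$peaks, names.arg = x$dispensations, las = 2,
                    ylab = "light units", main = x$reaction, ...)
  invisible(x)
}

#' LUMA peak ratio of a pyrogram
#'
#' Computes (dGTP + dCTP) / mean(dATP; dTTP): the summed heights of the two
#' dGTP+dCTP dispensations divided by the mean of the summed dATP and
#' summed dTTP heights. The EcoRI-driven denominator normalises for DNA
#' input.
#'
#' @param pyro A `pyrogram` object.
#' @return The ratio (numeric scalar).
#' @export
luma_ratio <- function(pyro) {
  stopifnot(inherits(pyro, "pyrogram"))
  lab <- pyro$dispensations
  gc <- sum(pyro$peaks[lab == "dGTP+dCTP"])
  a <- sum(pyro$peaks[lab == "dATP"])
  t <- sum(pyro$peaks[lab == "dTTP"])
  denom <- mean(c(a, t))
  if (denom <= 0)
    stop("undefined ratio: EcoRI control peaks are zero", call. = FALSE)
  gc / denom
}

#' LUMA percent methylation from paired pyrograms
#'
#' Applies the LUMA estimator
#' \deqn{100 \times \left[1 - \frac{HpaII/EcoRI}{MspI/EcoRI}\right]}
#' to the peak ratios of the HpaII+EcoRI and MspI+EcoRI reactions. The raw
#' percentage is clamped to \[0, 100\] (noise can push it outside), with
#' the unclamped value retained for QC.
#'
#' @param hpaii Pyrogram of the HpaII+EcoRI reaction.
#' @param mspi Pyrogram of the MspI+EcoRI reaction.
#' @return An object of class `luma_result`: list with `ratio_hpaii`,
#'   `ratio_mspi`, `percent_methylation`, `raw_percent`, `clamped`.
#' @export
luma_percent_methylation <- function(hpaii, mspi) {
  r_h <- luma_ratio(hpaii)
  r_m <- luma_ratio(mspi)
  if (r_m <= 0)
    stop("MspI/EcoRI ratio is zero: no CCGG sites detected", call. = FALSE)
  raw <- 100 * (1 - r_h / r_m)
  clamped <- raw < 0 || raw > 100
  if (clamped)
    warning(sprintf("raw percent %.2f outside [0, 100]; clamped", raw),
            call. = FALSE)
  structure(list(ratio_hpaii = r_h, ratio_mspi = r_m,
                 percent_methylation = min(max(raw, 0), 100),
                 raw_percent = raw, clamped = clamped),
            class = "luma_result")
}

#' @export
print.luma_result <- function(x, ...) {
  cat(sprintf("LUMA: HpaII/EcoRI = %.4f, MspI/EcoRI = %.4f\n",
              x$ratio_hpaii, x$ratio_mspi))
  cat(sprintf("  percent methylated CCGG = %.2f%%%s\n",
              x$percent_methylation,
              if (x$clamped) sprintf(" (raw %.2f, clamped)", x$raw_percent)
              else ""))
  invisible(x)
}

#' Fold decrease between two percent-methylation values
#'
#' Convenience for expressing a demethylation effect (e.g. after a
#' hypomethylating drug) as an x-fold decrease.
#'
#' @param before,after Percent methylation before and after treatment.
#' @return `before / after`.
#' @examples
#' fold_decrease(81.5, 32.4)  # ~2.5-fold
#' @export
fold_decrease <- function(before, after) {
  if (after <= 0) stop("'after' must be > 0", call. = FALSE)
  before / after
}

#' Simulate a full LUMA experiment on a methylated genome
#'
#' Runs the complete forward chain: HpaII+EcoRI and MspI+EcoRI digestion of
#' the genome given its methylome, pyrogram generation, optional
#' multiplicative peak noise per technical replicate, the peak-ratio
#' estimator per replicate, and the replicate mean. Percent methylation is
#' computed per replicate and then averaged.
#'
#' @param genome A `genome` object.
#' @param methylome A `methylome` object.
#' @param noise_cv Peak coefficient of variation (0 = noise-free).
#' @param n_replicates Number of technical replicates.
#' @param seed Integer seed.
#' @return An object of class `luma_experiment`: list with
#'   `percent_methylation` (replicate mean), `replicates` (per-replicate
#'   `luma_result`s), `noise_cv`, `n_replicates`.
#' @export
luma_simulate <- function(genome, methylome, noise_cv = 0, n_replicates = 1L,
                          seed = 1L) {
  d_h <- digest(genome, "HpaII+EcoRI", methylome)
  d_m <- digest(genome, "MspI+EcoRI", methylome)
  p_h0 <- pyrogram_from_digest(d_h)
  p_m0 <- pyrogram_from_digest(d_m)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    if (noise_cv > 0) {
      p_h <- add_pyrogram_noise(p_h0, noise_cv, seed = seed + 2L * r)
      p_m <- add_pyrogram_noise(p_m0, noise_cv, seed = seed + 2L * r + 1L)
    } else {
      p_h <- p_h0; p_m <- p_m0
    }
    reps[[r]] <- luma_percent_methylation(p_h, p_m)
  }
  structure(list(percent_methylation =
                   mean(vapply(reps, `[[`, numeric(1L), "percent_methylation")),
                 replicates = reps, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates)),
            class = "luma_experiment")
}

#' @export
print.luma_experiment <- function(x, ...) {
  cat(sprintf("LUMA experiment: %.2f%% methylated CCGG (mean of %d replicate(s), CV %.3f)\n",
              x$percent_methylation, x$n_replicates, x$noise_cv))
  invisible(x)
}
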