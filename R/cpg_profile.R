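# Per-sequence CpG observed/expected ratios, kernel density estimation of
# their distribution with bootstrap confidence intervals, mode detection,
# and gene-body methylation type classification.

#' CpG observed/expected statistics per sequence
#'
#' For each sequence computes the CpG o/e ratio
#' \deqn{\mathrm{o/e} = \frac{n_{CpG}}{n_C \, n_G} \cdot \frac{L^2}{L-1}}
#' where counts exclude N residues, CG dinucleotides are counted over
#' consecutive non-N pairs (a pair interrupted by an N does not count) and
#' \eqn{L} is the N-excluded length. The ratio is undefined (NA, flagged)
#' when \eqn{n_C = 0}, \eqn{n_G = 0} or \eqn{L < 2}.
#'
#' @param seqs Character vector of DNA sequences (named or not).
#' @return Data frame with columns `seq_id`, `n_cpg`, `n_c`, `n_g`,
#'   `L_eff`, `oe` (NA where undefined).
#' @examples
#' cpg_oe("CGCGCGCG")  # oe = (4/16) * (64/7)
#' @export
cpg_oe <- function(seqs) {
  check_dna(seqs)
  if (any(nchar(seqs) == 0L)) stop("empty sequence", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%05d", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  n_cpg <- Biostrings::dinucleotideFrequency(x)[, "CG"]
  lf <- Biostrings::letterFrequency(x, c("C", "G", "N"))
  n_c <- as.integer(lf[, "C"])
  n_g <- as.integer(lf[, "G"])
  L_eff <- Biostrings::width(x) - as.integer(lf[, "N"])
  oe <- ifelse(n_c > 0 & n_g > 0 & L_eff >= 2L,
               (n_cpg / (n_c * n_g)) * (L_eff^2 / (L_eff - 1)),
               NA_real_)
  data.frame(seq_id = ids, n_cpg = as.integer(n_cpg), n_c = n_c, n_g = n_g,
             L_eff = as.integer(L_eff), oe = oe, row.names = NULL)
}

#' Profile the CpG o/e distribution of a transcriptome
#'
#' Filters out sequences shorter than `min_len` (N-excluded length),
#' computes per-sequence CpG o/e, fits a Gaussian kernel density (Silverman
#' bandwidth, 512-point grid on \[0, max(2, max o/e)\], reflected at 0 so no
#' probability mass leaks to negative ratios), detects density modes, and
#' bootstraps a percentile confidence interval for the mean o/e.
#'
#' @param seqs Character vector of DNA sequences.
#' @param min_len Minimum N-excluded length in bp (default 200).
#' @param prominence Minimum mode prominence as a fraction of the global
#'   density maximum (default 0.1); passed to [find_modes()].
#' @param n_boot Number of bootstrap resamples for the CI of the mean.
#' @param conf_level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `oe_profile`: list with `stats` (the
#'   [cpg_oe()] table of surviving sequences), `values`, `grid`, `density`,
#'   `bw`, `modes` (data frame: `location`, `height`, `prominence`, sorted
#'   by height descending), `mean`, `ci`, `conf_level`, `n_boot`, `seed`,
#'   `min_len`, `n_input`, `n_used`.
#' @export
profile_sequences <- function(seqs, min_len = 200L, prominence = 0.1,
                              n_boot = 1000L, conf_level = 0.95, seed = 1L) {
  stats_all <- cpg_oe(seqs)
  keep <- stats_all$L_eff >= min_len & !is.na(stats_all$oe)
  if (!any(keep))
    stop("no sequence passes the length filter (min_len = ", min_len,
         ") with a defined o/e", call. = FALSE)
  st <- stats_all[keep, , drop = FALSE]
  v <- st$oe

  upper <- max(2, max(v))
  n_grid <- 512L
  if (length(v) > 1L && stats::sd(v) > 0) {
    bw <- stats::bw.nrd0(v)
  } else {
    bw <- max(upper / n_grid, 1e-3)  # point mass: nominal narrow kernel
  }
  d_pos <- stats::density(v, bw = bw, kernel = "gaussian",
                          from = 0, to = upper, n = n_grid)
  d_neg <- stats::density(v, bw = bw, kernel = "gaussian",
                          from = -upper, to = 0, n = n_grid)
  grid <- d_pos$x
  dens <- d_pos$y + rev(d_neg$y)      # reflect mass below 0 back onto [0, upper]
  step <- grid[2L] - grid[1L]
  total <- sum((dens[-1L] + dens[-n_grid]) / 2) * step
  dens <- dens / total

  modes <- find_modes(dens, grid = grid, prominence_threshold = prominence)

  set.seed(as.integer(seed))
  boot_means <- vapply(seq_len(n_boot), function(i)
    mean(v[sample.int(length(v), replace = TRUE)]), numeric(1L))
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boot_means, c(alpha, 1 - alpha), type = 7))

  structure(list(stats = st, values = v, grid = grid, density = dens,
                 bw = bw, modes = modes, mean = mean(v),
                 ci = ci, conf_level = conf_level,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 min_len = as.integer(min_len),
                 n_input = nrow(stats_all), n_used = nrow(st)),
            class = "oe_profile")
}

#' Locate modes of a density estimate
#'
#' Finds local maxima of a density evaluated on a grid and retains those
#' whose topographic prominence (height above the higher of the two key
#' saddles separating the peak from taller terrain) is at least
#' `prominence_threshold` times the global maximum. Ties in height are
#' broken towards the lower location.
#'
#' @param density Non-negative numeric vector (>= 3 points).
#' @param grid Numeric vector of evaluation points, same length.
#' @param prominence_threshold Fraction of the global maximum (default 0.1).
#' @return Data frame with columns `location`, `height`, `prominence`,
#'   sorted by height descending (ties: lower location first).
#' @export
find_modes <- function(density, grid = seq_along(density),
                       prominence_threshold = 0.1) {
  n <- length(density)
  if (n < 3L) stop("density must have at least 3 grid points", call. = FALSE)
  if (any(density < 0)) stop("density must be non-negative", call. = FALSE)
  if (all(density == 0)) stop("all-zero density: no modes", call. = FALSE)

  y <- density
  # local maxima; plateaus collapse to their first index
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i == 1L) -Inf else y[i - 1L]
    # skip forward over a plateau to find the next differing value
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    right <- if (j == n) -Inf else y[j + 1L]
    is_peak[i] <- (y[i] > left) && (y[i] > right)
  }
  peaks <- which(is_peak)
  if (length(peaks) == 0L) peaks <- which.max(y)

  prom <- vapply(peaks, function(p) {
    h <- y[p]
    # nearest strictly higher point on each side (or signal edge)
    li <- p; lmin <- h
    while (li > 1L) { li <- li - 1L; lmin <- min(lmin, y[li]); if (y[li] > h) break }
    lbase <- if (y[li] > h) lmin else min(y[seq_len(p)])
    ri <- p; rmin <- h
    while (ri < n) { ri <- ri + 1L; rmin <- min(rmin, y[ri]); if (y[ri] > h) break }
    rbase <- if (y[ri] > h) rmin else min(y[p:n])
    h - max(lbase, rbase)
  }, numeric(1L))

  keep <- prom >= prominence_threshold * max(y)
  peaks <- peaks[keep]; prom <- prom[keep]
  if (length(peaks) == 0L) {   # retain at least the global maximum
    peaks <- which.max(y); prom <- max(y) - min(y)
  }
  out <- data.frame(location = grid[peaks], height = y[peaks],
                    prominence = prom)
  out[order(-out$height, out$location), , drop = FALSE]
}

#' Classify the gene-body methylation type of a transcriptome
#'
#' Applies the four-type scheme for gene-body methylation to the modes of a
#' CpG o/e profile: two or more retained modes indicate mosaic methylation
#' (type 4); a single mode at o/e >= `type1_min` indicates ultra-low
#' methylation (type 1, no historical CpG depletion); a mode in
#' \[`type2_min`, `type1_min`) low methylation (type 2); and a mode below
#' `type2_min` substantial gene-body methylation (type 3).
#'
#' @param dist An `oe_profile` object (or a data frame of modes as returned
#'   by [find_modes()]).
#' @param type1_min Lower o/e bound for type 1 (default 0.90).
#' @param type2_min Lower o/e bound for type 2 (default 0.70).
#' @return An object of class `methylation_type_call`: list with `type`
#'   (integer 1-4), `rule_trace` (character), `modes`.
#' @export
classify_methylation_type <- function(dist, type1_min = 0.90,
                                      type2_min = 0.70) {
  modes <- if (inherits(dist, "oe_profile")) dist$modes else dist
  if (!is.data.frame(modes) || nrow(modes) == 0L)
    stop("no modes available for classification", call. = FALSE)
  if (nrow(modes) >= 2L) {
    type <- 4L
    trace <- sprintf("%d retained modes (>= 2) -> type 4 (mosaic methylation)",
                     nrow(modes))
  } else {
    m <- modes$location[1L]
    if (m >= type1_min) {
      type <- 1L
      trace <- sprintf("single mode %.3f >= %.2f -> type 1 (ultra-low)",
                       m, type1_min)
    } else if (m >= type2_min) {
      type <- 2L
      trace <- sprintf("single mode %.3f in [%.2f, %.2f) -> type 2 (low)",
                       m, type2_min, type1_min)
    } else {
      type <- 3L
      trace <- sprintf("single mode %.3f < %.2f -> type 3 (gene body methylation)",
                       m, type2_min)
    }
  }
  structure(list(type = type, rule_trace = trace, modes = modes),
            class = "methylation_type_call")
}

#' @export
print.methylation_type_call <- function(x, ...) {
  labels <- c("ultra-low gene body methylation", "low gene body methylation",
              "gene body methylation", "mosaic DNA methylation")
  cat(sprintf("Methylation type %d (%s)\n  rule: %s\n",
              x$type, labels[x$type], x$rule_trace))
  invisible(x)
}

#' @export
print.oe_profile <- function(x, ...) {
  cat(sprintf("CpG o/e profile: %d / %d sequences used (min_len = %d bp)\n",
              x$n_used, x$n_input, x$min_len))
  cat(sprintf("  mean o/e %.4f, %d%% bootstrap CI [%.4f, %.4f] (%d resamples)\n",
              x$mean, round(100 * x$conf_level), x$ci[1L], x$ci[2L], x$n_boot))
  cat(sprintf("  %d mode(s); principal mode at %.3f\n",
              nrow(x$modes), x$modes$location[1L]))
  invisible(x)
}

#' @export
summary.oe_profile <- function(object, ...) {
  out <- list(n_input = object$n_input, n_used = object$n_used,
              mean = object$mean, ci = object$ci, modes = object$modes,
              type_call = classify_methylation_type(object))
  class(out) <- "summary.oe_profile"
  out
}

#' @export
print.summary.oe_profile <- function(x, ...) {
  cat(sprintf("Sequences used: %d of %d\n", x$n_used, x$n_input))
  cat(sprintf("Mean o/e: %.4f  CI: [%.4f, %.4f]\n", x$mean, x$ci[1], x$ci[2]))
  cat("Modes:\n"); print(x$modes, row.names = FALSE)
  print(x$type_call)
  invisible(x)
}

#' Plot a CpG o/e density with its modes
#'
#' @param x An `oe_profile` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.oe_profile <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l", col = "red", lwd = 2,
                 xlab = "CpG o/e", ylab = "density", ...)
  graphics::abline(v = x$modes$location, lty = 2, col = "grey40")
  graphics::rug(x$values[seq_len(min(1000L, length(x$values)))])
  invisible(x)
}
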