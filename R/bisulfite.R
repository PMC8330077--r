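# Per-CpG methylation quantification from bisulfite read sets and
# replicate aggregation.

#' Quantify per-CpG methylation from bisulfite reads
#'
#' At each CpG cytosine of the reference, percent methylation is
#' 100 x (#reads with C) / (#reads with C or T); other residues at the
#' position (sequencing error) are excluded from the denominator, matching
#' pyrosequencing allele-quantification practice. Conversion efficiency is
#' monitored from non-CpG reference cytosines, which should read as T when
#' conversion is complete; profiles with `conversion_qc` below `qc_min`
#' are flagged.
#'
#' @param reads A `bisulfite_reads` object (see
#'   [simulate_bisulfite_reads()]), or a list with elements `reference`
#'   (character scalar), `reads` (character vector of aligned reads) and
#'   optionally `cpg_positions`.
#' @param locus_id Identifier recorded in the profile.
#' @param qc_min Minimum acceptable conversion rate before the profile is
#'   flagged (default 0.95).
#' @param correct_conversion If TRUE, additionally report the
#'   conversion-corrected estimate
#'   \eqn{\hat m = (p - (1-c))/c}{m = (p - (1-c))/c} (clamped to \[0, 1\])
#'   using the observed `conversion_qc` as \eqn{c}. Raw percentages are
#'   always reported.
#' @return An object of class `cpg_methylation_profile`: data frame with
#'   columns `pos` (0-based), `percent`, `coverage` (and
#'   `percent_corrected` if requested); attributes `locus_id`,
#'   `conversion_qc`, `qc_pass`.
#' @export
quantify_methylation <- function(reads, locus_id = "locus", qc_min = 0.95,
                                 correct_conversion = FALSE) {
  ref <- reads$reference
  rd <- reads$reads
  if (length(rd) < 1L) stop("need at least one read", call. = FALSE)
  if (any(nchar(rd) != nchar(ref)))
    stop("all reads must be aligned to (same length as) the reference",
         call. = FALSE)
  cpg0 <- reads$cpg_positions
  if (is.null(cpg0)) cpg0 <- find_sites(ref, "CG")
  if (length(cpg0) == 0L) stop("reference has no CpG positions", call. = FALSE)
  refv <- strsplit(ref, "", fixed = TRUE)[[1L]]
  if (any(refv[cpg0 + 1L] != "C"))
    stop("cpg_positions must point at C residues of the reference",
         call. = FALSE)

  M <- do.call(rbind, strsplit(rd, "", fixed = TRUE))
  count_at <- function(cols, base) colSums(M[, cols, drop = FALSE] == base)
  cpg_cols <- cpg0 + 1L
  nC <- count_at(cpg_cols, "C")
  nT <- count_at(cpg_cols, "T")
  inf <- nC + nT
  if (all(inf == 0L))
    stop("zero informative reads at every CpG", call. = FALSE)
  percent <- ifelse(inf > 0, 100 * nC / inf, NA_real_)

  noncpg_c <- setdiff(which(refv == "C"), cpg_cols)
  if (length(noncpg_c) > 0L) {
    qC <- sum(count_at(noncpg_c, "C"))
    qT <- sum(count_at(noncpg_c, "T"))
    conversion_qc <- if (qC + qT > 0) qT / (qC + qT) else NA_real_
  } else conversion_qc <- NA_real_

  out <- data.frame(pos = cpg0, percent = percent, coverage = as.integer(inf))
  if (correct_conversion) {
    c_hat <- conversion_qc
    if (is.na(c_hat) || c_hat <= 0)
      stop("conversion correction requested but conversion rate not estimable",
           call. = FALSE)
    m_hat <- (percent / 100 - (1 - c_hat)) / c_hat
    out$percent_corrected <- 100 * pmin(pmax(m_hat, 0), 1)
  }
  structure(out, locus_id = locus_id, conversion_qc = conversion_qc,
            qc_pass = is.na(conversion_qc) || conversion_qc >= qc_min,
            class = c("cpg_methylation_profile", "data.frame"))
}

#' Aggregate replicate per-CpG methylation profiles
#'
#' Computes the per-CpG arithmetic mean and sample standard deviation
#' across biological or technical replicates measured over the same CpG
#' positions (mean +/- SD reporting).
#'
#' @param profiles List of >= 2 `cpg_methylation_profile` objects with
#'   identical `pos`.
#' @return An object of class `replicate_summary`: data frame with `pos`,
#'   `mean`, `sd`, `n_replicates`.
#' @export
aggregate_replicates <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L)
    stop("need at least 2 replicate profiles", call. = FALSE)
  pos <- profiles[[1L]]$pos
  for (p in profiles[-1L]) {
    if (!identical(p$pos, pos))
      stop("replicates cover different CpG positions", call. = FALSE)
  }
  pm <- vapply(profiles, `[[`, numeric(length(pos)), "percent")
  pm <- matrix(pm, nrow = length(pos))
  structure(data.frame(pos = pos,
                       mean = rowMeans(pm),
                       sd = apply(pm, 1L, stats::sd),
                       n_replicates = length(profiles)),
            class = c("replicate_summary", "data.frame"))
}
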