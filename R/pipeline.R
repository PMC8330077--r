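# Orchestration: wiring the synthetic-data generators and the analysis
# stages into a single seeded, manifest-writing atlas run.

.ATLAS_STAGES <- c("simulate", "cpg_profile", "luma", "bisulfite",
                   "repertoire", "expression")

#' Default atlas configuration
#'
#' Returns the full configuration list understood by [run_atlas()], with
#' the packaged defaults: a 5,000-transcript CpG-depleted transcriptome
#' (lengths 500-3000 bp, GC 0.40, target o/e 0.55), a 200 kb genome with
#' 300 CCGG and 150 GAATTC sites of which 80% of CCGG are methylated, a
#' bisulfite locus read at 2 biological replicates, and the packaged
#' repertoire fixture. Any subset may be overridden.
#'
#' @param seed Global integer seed.
#' @return Nested named list of per-stage parameter blocks.
#' @export
atlas_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = .ATLAS_STAGES,
    simulate = list(n_transcripts = 5000L, length_range = c(500L, 3000L),
                    gc = 0.4, target_oe = 0.55,
                    genome_length = 200000L, n_ccgg = 300L, n_ecori = 150L,
                    meth_fraction = 0.8),
    cpg_profile = list(fasta = NULL, min_len = 200L, n_boot = 1000L,
                       prominence = 0.1),
    luma = list(noise_cv = 0.05, n_replicates = 2L),
    bisulfite = list(locus = NULL, per_cpg_m = NULL, n_reads = 500L,
                     conversion_rate = 0.98, error_rate = 0.001,
                     n_replicates = 2L),
    repertoire = list(tree = NULL, matrix = NULL, node = NULL),
    expression = list(table = NULL, pairs = NULL)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", nm, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the methylation-atlas pipeline
#'
#' Executes the requested stages in dependency order — synthetic-data
#' generation, CpG o/e profiling and type classification, LUMA digestion /
#' estimation, bisulfite quantification, Dollo repertoire reconstruction,
#' and expression-transition categorization — writing per-stage TSV/JSON
#' outputs and a manifest of inputs, outputs, parameters and seeds to
#' `out_dir`. Runs are deterministic: an identical configuration (and
#' seed) reproduces identical outputs.
#'
#' @param config Configuration list (see [atlas_config()]), a partial list
#'   of overrides, or the path to a JSON file of overrides.
#' @param out_dir Output directory (created if missing).
#' @return The run report: list with `config`, `results` (per-stage R
#'   objects) and `manifest` (files written), invisibly.
#' @export
run_atlas <- function(config = list(), out_dir = tempfile("atlas")) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- merge_config(atlas_config(), config)
  bad <- setdiff(cfg$stages, .ATLAS_STAGES)
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  results <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    files <<- c(files, path)
    path
  }

  if ("simulate" %in% cfg$stages) {
    s <- cfg$simulate
    tx <- simulate_transcriptome(s$n_transcripts, s$length_range, s$gc,
                                 s$target_oe, seed = cfg$seed)
    genome <- simulate_genome_with_sites(s$genome_length, s$n_ccgg,
                                         s$n_ecori, s$gc,
                                         seed = cfg$seed + 1L)
    methylome <- assign_ccgg_methylation(genome, s$meth_fraction,
                                         seed = cfg$seed + 2L)
    fa <- file.path(out_dir, "transcriptome.fasta")
    write_fasta(tx, fa); files <- c(files, fa)
    emit(as.data.frame(methylome), "methylome.tsv")
    results$simulate <- list(transcriptome = tx, genome = genome,
                             methylome = methylome)
  }

  if ("cpg_profile" %in% cfg$stages) {
    p <- cfg$cpg_profile
    seqs <- if (!is.null(p$fasta)) read_fasta(p$fasta)
            else results$simulate$transcriptome
    if (is.null(seqs))
      stop("dependency error: stage 'cpg_profile' requires stage 'simulate' or a fasta input",
           call. = FALSE)
    prof <- profile_sequences(seqs,
                              min_len = p$min_len, prominence = p$prominence,
                              n_boot = p$n_boot, seed = cfg$seed + 3L)
    call <- classify_methylation_type(prof)
    emit(prof$stats, "cpg_oe.tsv")
    js <- file.path(out_dir, "cpg_profile.json")
    jsonlite::write_json(list(mean = prof$mean, ci = prof$ci,
                              modes = prof$modes, type = call$type,
                              rule_trace = call$rule_trace),
                         js, auto_unbox = TRUE, digits = NA)
    files <- c(files, js)
    results$cpg_profile <- list(profile = prof, type_call = call)
  }

  if ("luma" %in% cfg$stages) {
    l <- cfg$luma
    if (is.null(results$simulate))
      stop("dependency error: stage 'luma' requires stage 'simulate'",
           call. = FALSE)
    exp <- luma_simulate(results$simulate$genome, results$simulate$methylome,
                         noise_cv = l$noise_cv,
                         n_replicates = l$n_replicates,
                         seed = cfg$seed + 4L)
    js <- file.path(out_dir, "luma.json")
    jsonlite::write_json(list(percent_methylation = exp$percent_methylation,
                              n_replicates = exp$n_replicates,
                              noise_cv = exp$noise_cv),
                         js, auto_unbox = TRUE, digits = NA)
    files <- c(files, js)
    results$luma <- exp
  }

  if ("bisulfite" %in% cfg$stages) {
    b <- cfg$bisulfite
    locus <- b$locus
    per_cpg_m <- b$per_cpg_m
    if (is.null(locus)) {   # packaged demo locus: a short CpG-dense stretch
      locus <- "ATTCGATCGGACGTTACGATCCGATACGTTACGGATTACG"
      per_cpg_m <- NULL
    }
    if (is.null(per_cpg_m))
      per_cpg_m <- rep(0.8, length(find_sites(locus, "CG")))
    profs <- lapply(seq_len(b$n_replicates), function(r) {
      rs <- simulate_bisulfite_reads(locus, per_cpg_m, b$n_reads,
                                     b$conversion_rate, b$error_rate,
                                     seed = cfg$seed + 10L + r)
      quantify_methylation(rs, locus_id = sprintf("replicate%d", r))
    })
    agg <- aggregate_replicates(profs)
    emit(as.data.frame(agg), "bisulfite_summary.tsv")
    results$bisulfite <- list(profiles = profs, summary = agg)
  }

  if ("repertoire" %in% cfg$stages) {
    r <- cfg$repertoire
    tree <- r$tree
    mat <- r$matrix
    node <- r$node
    if (is.null(tree)) {
      tree <- ape::read.tree(system.file("extdata", "metazoa_demo.nwk",
                                         package = "methatlas"))
      mat <- read_repertoire_matrix(system.file("extdata",
                                                "repertoire_demo.tsv",
                                                package = "methatlas"))
      node <- "Metazoa"
    } else {
      if (is.character(tree)) tree <- ape::read.tree(tree)
      if (is.character(mat)) mat <- read_repertoire_matrix(mat)
    }
    anc <- ancestral_repertoire(tree, mat, node)
    emit(repertoire_summary(mat), "repertoire_summary.tsv")
    js <- file.path(out_dir, "ancestral_repertoire.json")
    jsonlite::write_json(list(node = anc$node,
                              present_families = anc$present_families,
                              n_losses = vapply(anc$reconstructions,
                                                `[[`, numeric(1L),
                                                "n_losses")),
                         js, auto_unbox = TRUE, digits = NA)
    files <- c(files, js)
    results$repertoire <- anc
  }

  if ("expression" %in% cfg$stages) {
    e <- cfg$expression
    tab <- e$table
    prs <- e$pairs
    if (is.null(tab)) {     # demo table: 3 genes across 3 stages
      tab <- rbind(dnmt1 = c(12, 30, 4), dnmt3 = c(8, 7.5, 20),
                   mbd123 = c(1, 2, 3))
      colnames(tab) <- c("stage1", "stage2", "stage3")
      prs <- list(c("stage1", "stage2"), c("stage2", "stage3"))
    } else if (is.character(tab)) {
      df <- read_tsv(tab)
      tab <- as.matrix(df[, -1L, drop = FALSE]); rownames(tab) <- df[[1L]]
    }
    ts <- transition_summary(tab, prs)
    recs <- do.call(rbind, lapply(names(ts), function(nm) {
      d <- ts[[nm]]$records; d$pair <- nm; d
    }))
    emit(recs, "transitions.tsv")
    results$expression <- ts
  }

  manifest <- list(package = "methatlas",
                   version = as.character(utils::packageVersion("methatlas")),
                   seed = cfg$seed, stages = cfg$stages,
                   config = cfg[setdiff(names(cfg), "stages")],
                   files = basename(files))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(config = cfg, results = results,
                 manifest = c(files, mf)))
}
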