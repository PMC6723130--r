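#' Pipeline run configuration
#'
#' Bundles every stage threshold into one validated object. Sample
#' demultiplexing by the 16-bp sample index is assumed done upstream
#' (standard sequencer practice): inputs are per-sample FASTQ pairs.
#'
#' @param panel path to a panel TSV, or an `umivar_panel`.
#' @param test named list `list(r1 = , r2 = )` of FASTQ paths (or in-memory
#'   read vectors) for the test sample.
#' @param controls list of such pairs for the control samples used to build
#'   an internal background.
#' @param background one of `"internal"` (build the positional model from
#'   the co-run controls), `"external"` (load a serialized model from
#'   `background_path`), `"generic"` (context-only model from the co-run
#'   controls).
#' @param background_path serialized model prefix for `"external"`.
#' @param min_reads,agreement,max_mismatch consensus thresholds (defaults
#'   5, 0.75, 1).
#' @param min_capture_support capture-count support for calling (default 5).
#' @param align_max_mismatch alignment mismatch ceiling (default 10).
#' @param alpha confidence mass; alternatively give `alpha_nines`.
#' @param alpha_nines stringency as a count of trailing nines (overrides
#'   `alpha` when non-NULL).
#' @param umi_len UMI length (default 12).
#' @param seed integer seed for any stochastic step.
#' @param outdir output directory (NULL: nothing written).
#' @return a validated list of class `umivar_run_config`.
#' @export
run_config <- function(panel, test = NULL, controls = list(),
                       background = c("internal", "external", "generic"),
                       background_path = NULL, min_reads = 5L,
                       agreement = 0.75, max_mismatch = 1L,
                       min_capture_support = 5L, align_max_mismatch = 10L,
                       alpha = 0.99, alpha_nines = NULL, umi_len = 12L,
                       seed = NULL, outdir = NULL) {
  background <- match.arg(background)
  if (!is.null(alpha_nines)) alpha <- alpha_from_nines(alpha_nines)
  cfg <- list(panel = panel, test = test, controls = controls,
              background = background, background_path = background_path,
              min_reads = as.integer(min_reads), agreement = agreement,
              max_mismatch = as.integer(max_mismatch),
              min_capture_support = as.integer(min_capture_support),
              align_max_mismatch = as.integer(align_max_mismatch),
              alpha = alpha, umi_len = as.integer(umi_len), seed = seed,
              outdir = outdir)
  if (cfg$min_reads < 1 || cfg$min_capture_support < 1)
    stop("config error: thresholds must be positive")
  if (cfg$agreement <= 0.5 || cfg$agreement > 1)
    stop("config error: agreement must lie in (0.5, 1]")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config error: alpha must lie strictly between 0 and 1")
  if (background == "external" && is.null(background_path))
    stop("config error: external background requires background_path")
  structure(cfg, class = "umivar_run_config")
}

#' Write a run configuration as YAML
#'
#' Only serializable fields (paths and scalars) are written; in-memory
#' panels or read vectors must be saved to files first.
#'
#' @param config an `umivar_run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.character(cfg$panel))
    stop("config error: write_run_config needs a panel path, not an object")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML path written by [write_run_config()].
#' @return an `umivar_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

process_sample <- function(r1, r2, panel, cfg) {
  cons <- run_consensus(r1, r2, umi_len = cfg$umi_len,
                        min_reads = cfg$min_reads, agreement = cfg$agreement,
                        max_mismatch = cfg$max_mismatch)
  aligned <- align_consensus(cons, panel,
                             max_mismatch = cfg$align_max_mismatch)
  pile <- build_pileup(aligned, panel)
  calls <- call_variants(pile, panel,
                         min_capture_support = cfg$min_capture_support)
  list(consensus = cons, aligned = aligned, pileup = pile, calls = calls,
       qc = c(attr(cons, "qc"), attr(aligned, "qc")))
}

#' Run the full consensus-call-filter pipeline
#'
#' Composition of every stage: consensus collapsing, anchored alignment,
#' pileup, capture-supported calling, background construction from the
#' co-run controls (internal mode) and alpha filtering of the test calls.
#' Deterministic given the seed and inputs. When `outdir` is set, writes
#' consensus FASTA, raw and significant-call VCFs, the serialized
#' background and a one-row-per-metric QC TSV.
#'
#' @param config an `umivar_run_config`.
#' @return list of class `umivar_run`: `test` (per-stage objects),
#'   `controls` (per-control calls), `background` (the fitted model),
#'   `calls` (flagged test calls), `qc`, `paths` (written files, if any).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "umivar_run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  panel <- if (inherits(config$panel, "umivar_panel")) config$panel
           else load_panel(config$panel)

  ctl <- vector("list", length(config$controls))
  for (i in seq_along(config$controls))
    ctl[[i]] <- process_sample(config$controls[[i]]$r1,
                               config$controls[[i]]$r2, panel, config)

  model <- switch(config$background,
    internal = fit_background(lapply(ctl, `[[`, "calls"), panel,
                              alpha = config$alpha, kind = "positional",
                              provenance = "internal"),
    generic = fit_background(lapply(ctl, `[[`, "calls"), panel,
                             alpha = config$alpha, kind = "generic",
                             provenance = "internal"),
    external = read_background(config$background_path))

  test <- NULL
  calls <- NULL
  if (!is.null(config$test)) {
    test <- process_sample(config$test$r1, config$test$r2, panel, config)
    calls <- filter_variants(test$calls, model, alpha = config$alpha)
  }

  qc <- list(test = if (!is.null(test)) test$qc,
             controls = lapply(ctl, `[[`, "qc"),
             filter = if (!is.null(calls)) attr(calls, "filter_counts"))

  paths <- NULL
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      consensus = file.path(config$outdir, "test.consensus.fasta"),
      calls = file.path(config$outdir, "test.calls.vcf"),
      significant = file.path(config$outdir, "test.significant.vcf"),
      qc = file.path(config$outdir, "qc.tsv"))
    if (!is.null(test)) {
      write_consensus_fasta(test$consensus, paths[["consensus"]])
      write_vcf(calls, panel, paths[["calls"]])
      write_vcf(calls[calls$significant, , drop = FALSE], panel,
                paths[["significant"]])
    }
    bg_prefix <- file.path(config$outdir, "background")
    write_background(model, bg_prefix)
    qcflat <- unlist(qc)
    write.table(data.frame(metric = names(qcflat), value = unname(qcflat)),
                paths[["qc"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }

  structure(list(test = test, controls = ctl, background = model,
                 calls = calls, qc = qc, paths = paths, config = config),
            class = "umivar_run")
}

#' @export
print.umivar_run <- function(x, ...) {
  cat("umivar pipeline run\n")
  print(x$background)
  if (!is.null(x$calls)) {
    fc <- attr(x$calls, "filter_counts")
    cat(sprintf("  test calls: %d (%d significant at alpha %.15g)\n",
                fc$n_calls, fc$n_significant, fc$alpha))
  }
  invisible(x)
}
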