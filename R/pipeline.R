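#' Pipeline configuration
#'
#' Collects every input path and tunable of an end-to-end run. At least
#' one source of LCRs (the SEG-style detector or an annotation TSV) and
#' of ARs (the PSSM scanner with a matrix + threshold, or an annotation
#' TSV) must be configured.
#'
#' @param fasta protein FASTA path.
#' @param ar_tsv,lcr_tsv,disorder_tsv optional region-annotation TSVs
#'   (columns protein_id, kind, start, end, \[subsequence\]).
#' @param pssm_tsv optional PSSM TSV for the scanner (6 x 20).
#' @param threshold scanner score cutoff (required with `pssm_tsv`).
#' @param ss_fasta optional FASTA-like per-residue H/E/C annotations.
#' @param ss_baseline use the bundled Chou-Fasman stand-in when no
#'   secondary-structure annotation is supplied.
#' @param seg a [seg_params()] object for the LCR detector.
#' @param margin terminal window width in residues.
#' @param fit_stable fit stable laws to region lengths/contents (needs
#'   >= 50 values per variable; skipped with a note otherwise).
#' @param seed integer seed recorded in the report (all pipeline stages
#'   are deterministic; the seed matters for downstream simulation).
#' @param out_dir output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, out_dir,
                            ar_tsv = NULL, lcr_tsv = NULL,
                            disorder_tsv = NULL, pssm_tsv = NULL,
                            threshold = NULL, ss_fasta = NULL,
                            ss_baseline = FALSE, seg = seg_params(),
                            margin = 15L, fit_stable = TRUE,
                            seed = 1L) {
  cfg <- structure(list(
    fasta = fasta, out_dir = out_dir, ar_tsv = ar_tsv,
    lcr_tsv = lcr_tsv, disorder_tsv = disorder_tsv,
    pssm_tsv = pssm_tsv, threshold = threshold, ss_fasta = ss_fasta,
    ss_baseline = isTRUE(ss_baseline), seg = seg,
    margin = as.integer(margin), fit_stable = isTRUE(fit_stable),
    seed = as.integer(seed)), class = "pipeline_config")
  if (!file.exists(cfg$fasta))
    stop("configuration error: FASTA not found: ", cfg$fasta)
  if (!is.null(cfg$pssm_tsv) && is.null(cfg$threshold))
    stop("configuration error: a PSSM without a threshold")
  for (p in c(cfg$ar_tsv, cfg$lcr_tsv, cfg$disorder_tsv, cfg$pssm_tsv,
              cfg$ss_fasta))
    if (!file.exists(p)) stop("configuration error: file not found: ", p)
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Key-value file whose keys mirror the arguments of
#' [pipeline_config()]; `seg` may be a nested mapping with `window`,
#' `trigger_entropy`, `extension_entropy`, `refine`. Relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  seg <- if (is.null(y$seg)) seg_params() else do.call(seg_params, y$seg)
  pipeline_config(
    fasta = resolve(y$fasta), out_dir = y$out_dir,
    ar_tsv = resolve(y$ar_tsv), lcr_tsv = resolve(y$lcr_tsv),
    disorder_tsv = resolve(y$disorder_tsv),
    pssm_tsv = resolve(y$pssm_tsv), threshold = y$threshold,
    ss_fasta = resolve(y$ss_fasta),
    ss_baseline = isTRUE(y$ss_baseline), seg = seg,
    margin = if (is.null(y$margin)) 15L else y$margin,
    fit_stable = !isFALSE(y$fit_stable),
    seed = if (is.null(y$seed)) 1L else y$seed)
}

# Fits + discrete summaries of one variable, as a plain list for JSON.
fit_report_one <- function(values, do_stable) {
  out <- list(n = length(values))
  if (length(values)) out$discrete <- discrete_summary(values)
  if (do_stable && length(values) >= 50 && var(values) > 0) {
    fs <- fit_stable(values)
    out$stable <- list(alpha = fs$alpha, beta = fs$beta, mu = fs$mu,
                       sigma = fs$sigma, loglik = fs$loglik)
  } else {
    out$stable <- NULL
  }
  out
}

#' Run the full annotate-summarize-fit pipeline
#'
#' Reads the configured inputs, obtains AR and LCR regions (from
#' annotation TSVs or by running the bundled scanner/detector), then
#' writes into `out_dir`: `summary.tsv` (per-protein metrics),
#' `class_summary.tsv` (per disorder class, when disorder annotations
#' are available), `overlap.tsv` (AR x LCR overlap catalog),
#' `composition.tsv` (residue frequencies for the whole/AR/LCR
#' contexts), `ss_preference.tsv` (when secondary structure is
#' available), `fits.json` (discrete summaries, stable fits and the
#' hyperbolic length-content regressions) and `run_log.txt`. All stages
#' are deterministic: identical configuration gives byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()] or the path of a YAML file for
#'   [read_pipeline_config()].
#' @return The run report (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$ar_tsv) && is.null(config$pssm_tsv))
    stop("configuration error: no AR source (annotation TSV or PSSM)")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  log_add("idrscape pipeline run")
  log_add("seed: ", config$seed)
  proteins <- read_fasta(config$fasta)
  log_add("proteins: ", nrow(proteins))
  failures <- 0L
  empty_rt <- region_table(character(), character(), integer(), integer())

  per_protein_regions <- function(fun, label) {
    pieces <- lapply(seq_len(nrow(proteins)), function(i) {
      tryCatch(suppressWarnings(fun(proteins[i, ])),
               error = function(e) {
                 failures <<- failures + 1L
                 log_add("FAILED ", label, " on ", proteins$id[i], ": ",
                         conditionMessage(e))
                 NULL
               })
    })
    pieces <- Filter(function(p) !is.null(p) && nrow(p) > 0, pieces)
    if (length(pieces) == 0L) return(empty_rt)
    out <- do.call(rbind, lapply(pieces, function(p)
      p[, names(empty_rt), drop = FALSE]))
    rownames(out) <- NULL
    out
  }

  if (!is.null(config$lcr_tsv)) {
    lcrs <- read_region_table(config$lcr_tsv, proteins)
    lcrs <- lcrs[lcrs$kind == "LCR", , drop = FALSE]
    log_add("LCR source: annotation ", config$lcr_tsv)
  } else {
    lcrs <- per_protein_regions(
      function(r) detect_lcr(r, config$seg), "seg")
    log_add(sprintf(
      "LCR source: SEG engine (window %d, locut %.3g, hicut %.3g bits)",
      config$seg$window, config$seg$trigger_entropy,
      config$seg$extension_entropy))
  }
  if (!is.null(config$ar_tsv)) {
    ars <- read_region_table(config$ar_tsv, proteins)
    ars <- ars[ars$kind == "AR", , drop = FALSE]
    log_add("AR source: annotation ", config$ar_tsv)
  } else {
    mat <- read_pssm(config$pssm_tsv)
    ars <- per_protein_regions(
      function(r) scan_sequence(r, mat, config$threshold), "scan")
    log_add("AR source: PSSM scan (threshold ", config$threshold, ")")
  }
  disorder <- NULL
  if (!is.null(config$disorder_tsv)) {
    disorder <- read_region_table(config$disorder_tsv, proteins)
    disorder <- disorder[disorder$kind == "DISORDER", , drop = FALSE]
  }

  if (nrow(proteins) == 0L) {
    warning("empty FASTA: writing empty outputs")
    summaries <- summarize_proteins(proteins, empty_rt, empty_rt)
  } else {
    summaries <- summarize_proteins(proteins, ars, lcrs, disorder,
                                    margin = config$margin)
  }
  write.table(summaries, file.path(config$out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(disorder) && nrow(summaries)) {
    cs <- summarize_class(summaries)
    write.table(cs, file.path(config$out_dir, "class_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  catalogs <- lapply(unique(proteins$id), function(pid)
    overlap_catalog(ars[ars$protein_id == pid, , drop = FALSE],
                    lcrs[lcrs$protein_id == pid, , drop = FALSE]))
  catalog <- do.call(rbind, c(catalogs, list(overlap_catalog(
    empty_rt, empty_rt))))
  write.table(catalog, file.path(config$out_dir, "overlap.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  if (nrow(proteins)) {
    comp <- data.frame(aa = AA20,
                       whole = unname(composition_profile(proteins)))
    comp$ar <- if (nrow(ars))
      unname(composition_profile(proteins, ars)) else NA_real_
    comp$lcr <- if (nrow(lcrs))
      unname(composition_profile(proteins, lcrs)) else NA_real_
    write.table(comp, file.path(config$out_dir, "composition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ss <- NULL
  if (!is.null(config$ss_fasta)) {
    ss <- read_ss_annotation(config$ss_fasta, proteins)
  } else if (config$ss_baseline && nrow(proteins)) {
    ss <- setNames(vapply(seq_len(nrow(proteins)), function(i)
      chou_fasman_baseline(proteins[i, ]), character(1)), proteins$id)
    log_add("secondary structure: Chou-Fasman baseline (stand-in)")
  }
  if (!is.null(ss) && length(ss)) {
    rows <- list(data.frame(context = "WHOLE",
                            t(ss_preference(ss)),
                            stringsAsFactors = FALSE))
    if (nrow(ars))
      rows[[length(rows) + 1L]] <- data.frame(
        context = "AR", t(ss_preference(ss, ars)),
        stringsAsFactors = FALSE)
    if (nrow(lcrs))
      rows[[length(rows) + 1L]] <- data.frame(
        context = "LCR", t(ss_preference(ss, lcrs)),
        stringsAsFactors = FALSE)
    write.table(do.call(rbind, rows),
                file.path(config$out_dir, "ss_preference.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  fits <- list(
    ar_pct = fit_report_one(summaries$ar_pct[summaries$ar_count > 0],
                            config$fit_stable),
    lcr_pct = fit_report_one(summaries$lcr_pct[summaries$lcr_count > 0],
                             config$fit_stable),
    ar_len = fit_report_one(merge_regions(ars)$length, config$fit_stable),
    lcr_len = fit_report_one(merge_regions(lcrs)$length,
                             config$fit_stable))
  if (nrow(summaries) >= 3 && length(unique(summaries$length)) >= 2) {
    hy_ar <- fit_hyperbolic(summaries$length, summaries$ar_pct)
    hy_lcr <- fit_hyperbolic(summaries$length, summaries$lcr_pct)
    fits$hyperbolic <- list(
      ar = list(a = hy_ar$a, b = hy_ar$b, r_squared = hy_ar$r_squared),
      lcr = list(a = hy_lcr$a, b = hy_lcr$b,
                 r_squared = hy_lcr$r_squared))
  }
  jsonlite::write_json(fits, file.path(config$out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  report <- list(
    n_proteins = nrow(proteins), n_ar = nrow(ars), n_lcr = nrow(lcrs),
    n_overlap = nrow(catalog), n_failures = failures,
    parameters = list(
      seg_window = config$seg$window,
      seg_trigger_entropy = config$seg$trigger_entropy,
      seg_extension_entropy = config$seg$extension_entropy,
      scan_threshold = config$threshold,
      terminal_margin = config$margin,
      class_boundaries = c(PDP_max = 30, MDP_max = 70),
      seed = config$seed))
  log_add("ARs: ", nrow(ars), "  LCRs: ", nrow(lcrs),
          "  overlaps: ", nrow(catalog))
  log_add("per-protein failures: ", failures)
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(report)
}
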