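# Orchestration: simulate (or load) -> normalize -> differential expression
# -> orthologs -> cross-species comparison -> enrichment layers, driven by a
# single validated config, with a deterministic summary JSON and a
# timestamped, stage-tagged log.

PIPELINE_DEFAULTS <- list(
  fdr_threshold = 0.05, min_bits = 50, spike_weight = 50, span = 0.4,
  loess_iterations = 4, min_term_size = 1L, min_family_members = 5L,
  seed = 1L)

#' Build a pipeline configuration
#'
#' Either `synthetic` (a [synthetic_study_config()] or a list of its
#' arguments) or `input_dir` (a directory in [write_study()] layout) must be
#' given, not neither.
#'
#' @param out_dir output directory for all stage files.
#' @param synthetic synthetic-study settings, or `NULL` for real input.
#' @param input_dir directory with scans/, probes.tsv, hits_ab.tsv,
#'   hits_ba.tsv and bundle/, or `NULL`.
#' @param fdr_threshold,min_bits,spike_weight,span,loess_iterations,min_term_size,min_family_members,seed
#'   stage parameters; see the stage functions for meaning and defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, synthetic = NULL, input_dir = NULL,
                            fdr_threshold = 0.05, min_bits = 50,
                            spike_weight = 50, span = 0.4, loess_iterations = 4,
                            min_term_size = 1L, min_family_members = 5L,
                            seed = 1L) {
  if (is.null(synthetic) && is.null(input_dir))
    dx_error("pipeline_config needs either synthetic settings or input_dir",
             "dauerx_config_error")
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_study_config")) {
    synthetic <- do.call(synthetic_study_config,
                         c(synthetic, if (!("seed" %in% names(synthetic)))
                           list(seed = dx_child_seed(seed, 0L))))
  }
  structure(list(out_dir = out_dir, synthetic = synthetic, input_dir = input_dir,
                 fdr_threshold = fdr_threshold, min_bits = min_bits,
                 spike_weight = spike_weight, span = span,
                 loess_iterations = loess_iterations,
                 min_term_size = min_term_size,
                 min_family_members = min_family_members, seed = seed),
            class = "pipeline_config")
}

#' Validate a pipeline config file
#'
#' Reads a JSON key-value document, rejects unknown keys (typos fail loudly),
#' fills defaults, and returns a [pipeline_config()].
#'
#' @param path JSON file; top-level keys are [pipeline_config()] arguments,
#'   `synthetic` may be an object of [synthetic_study_config()] arguments.
#' @return a `pipeline_config`.
#' @export
validate_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    dx_error(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
             "dauerx_config_error")
  if (is.null(raw$out_dir))
    dx_error("missing required config key: out_dir", "dauerx_config_error")
  if (!is.null(raw$synthetic)) {
    unknown_s <- setdiff(names(raw$synthetic), names(formals(synthetic_study_config)))
    if (length(unknown_s))
      dx_error(sprintf("unknown synthetic config key(s): %s",
                       paste(unknown_s, collapse = ", ")), "dauerx_config_error")
    if (!is.null(raw$synthetic$class_counts))
      raw$synthetic$class_counts <- unlist(raw$synthetic$class_counts)
  }
  do.call(pipeline_config, raw)
}

read_study_inputs <- function(input_dir) {
  meta <- dx_read_tsv(file.path(input_dir, "scans", "arrays.tsv"), header = TRUE)
  scans <- lapply(seq_len(nrow(meta)), function(i)
    read_scan_table(file.path(input_dir, "scans", paste0(meta$array_id[i], ".tsv")),
                    meta$array_id[i], meta$species[i], meta$condition[i],
                    meta$dye_orientation[i]))
  bdir <- file.path(input_dir, "bundle")
  list(scans = scans,
       probes = read_probe_annotation(file.path(input_dir, "probes.tsv")),
       hits_ab = read_hit_table(file.path(input_dir, "hits_ab.tsv")),
       hits_ba = read_hit_table(file.path(input_dir, "hits_ba.tsv")),
       bundle = read_annotation_bundle(file.path(bdir, "ontology.obo"),
                                       file.path(bdir, "gene2term.tsv"),
                                       file.path(bdir, "clusters.tsv"),
                                       file.path(bdir, "gene2domain.tsv"),
                                       file.path(bdir, "pathway2gene.tsv"),
                                       file.path(bdir, "pioneer_genes.tsv")),
       truth = NULL)
}

#' Run the full pipeline
#'
#' Stages in dependency order; every stage writes its TSV outputs under
#' `config$out_dir` and the run ends with a deterministic `summary.json`
#' (identical bytes on rerun with the same config) plus a timestamped
#' `pipeline.log`. A stage failure halts with a stage-named error; outputs of
#' completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every stage's in-memory result and
#'   `summary` (the summary-JSON content).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "pipeline.log")
  cat(NULL, file = logfile)
  logmsg <- function(stage, msg, level = "INFO")
    cat(sprintf("%s [%s] %s: %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                level, stage, msg), file = logfile, append = TRUE)
  stage <- function(name, expr) {
    logmsg(name, "start")
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        logmsg(name, conditionMessage(e), "ERROR")
        stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        logmsg(name, conditionMessage(w), "WARN")
        invokeRestart("muffleWarning")
      })
    logmsg(name, "done")
    res
  }

  inputs <- stage("simulate", {
    if (!is.null(config$synthetic)) {
      study <- generate_study(config$synthetic)
      write_study(study, file.path(out, "input"))
      study
    } else read_study_inputs(config$input_dir)
  })

  arrays <- stage("normalize", {
    arrs <- lapply(inputs$scans, function(scan)
      normalize_scan(scan, inputs$probes, spike_weight = config$spike_weight,
                     span = config$span, iterations = config$loess_iterations))
    dir.create(file.path(out, "normalized"), showWarnings = FALSE)
    for (arr in arrs)
      dx_write_tsv(as.data.frame(arr)[c("probe_id", "M", "A", "weight")],
                   file.path(out, "normalized", paste0(attr(arr, "array_id"), ".tsv")))
    diag <- data.frame(
      array_id = vapply(arrs, attr, "", which = "array_id"),
      spike_median_offset = vapply(arrs, attr, 0, which = "spike_offset"),
      anchor_shift = vapply(arrs, attr, 0, which = "anchor_shift"))
    dx_write_tsv(diag, file.path(out, "normalized", "diagnostics.tsv"))
    arrs
  })

  de <- stage("diffexp", {
    res <- lapply(c(cel = "cel", ppa = "ppa"), function(sp) {
      sel <- vapply(arrays, function(a) attr(a, "species") == sp, TRUE)
      run_diffexp(arrays[sel], inputs$probes, fdr_threshold = config$fdr_threshold)
    })
    write_de_result(res$cel, file.path(out, "de_cel.tsv"))
    write_de_result(res$ppa, file.path(out, "de_ppa.tsv"))
    res
  })

  pairs <- stage("orthologs", {
    pr <- rbh_orthologs(inputs$hits_ab, inputs$hits_ba, min_bits = config$min_bits)
    pr <- restrict_to_arrays(pr, de$cel$gene_id, de$ppa$gene_id)
    dx_write_tsv(as.data.frame(pr), file.path(out, "pairs.tsv"))
    pr
  })

  comparison <- stage("compare", {
    cmp <- classify_orthologs(de$cel, de$ppa, pairs,
                              fdr_threshold = config$fdr_threshold)
    dx_write_tsv(as.data.frame(cmp), file.path(out, "cmp.tsv"))
    list(cmp = cmp, overlap = overlap_fisher(cmp),
         correlations = correlation_report(cmp))
  })

  enrichment <- stage("enrich", {
    cmp <- comparison$cmp
    bundle <- inputs$bundle
    closed <- propagate_to_ancestors(bundle$gene2term, bundle$ontology)
    background <- cmp$gene_a
    class_sets <- lapply(c(class1 = "1", class2 = "2", class3 = "3", class4 = "4"),
                         function(k) cmp$gene_a[cmp$class == k])
    go <- lapply(class_sets, term_enrichment, background = background,
                 gene2term_closed = closed, ontology = bundle$ontology,
                 min_term_size = config$min_term_size)
    dir.create(file.path(out, "enrich"), showWarnings = FALSE)
    for (nm in names(go))
      dx_write_tsv(as.data.frame(go[[nm]]),
                   file.path(out, "enrich", paste0("go_", nm, ".tsv")))
    b2a <- stats::setNames(cmp$gene_a, cmp$gene_b)
    direction_sets <- list(
      cel_dauer = cmp$gene_a[cmp$sig_a & cmp$logfc_a > 0],
      cel_exit = cmp$gene_a[cmp$sig_a & cmp$logfc_a < 0],
      ppa_dauer = unname(b2a[cmp$gene_b[cmp$sig_b & cmp$logfc_b > 0]]),
      ppa_exit = unname(b2a[cmp$gene_b[cmp$sig_b & cmp$logfc_b < 0]]))
    clusters <- cluster_enrichment(direction_sets, bundle$clusters, background)
    dx_write_tsv(data.frame(cluster_id = rownames(clusters),
                            as.data.frame(unclass(clusters))),
                 file.path(out, "enrich", "clusters.tsv"))
    pfam <- pfam_family_profile(de$cel, de$ppa, bundle$gene2domain,
                                min_members = config$min_family_members)
    dx_write_tsv(pfam$families, file.path(out, "enrich", "pfam_families.tsv"))
    kegg <- kegg_tabulate(de$cel, de$ppa, bundle$pathway2gene, pairs)
    dx_write_tsv(as.data.frame(kegg), file.path(out, "enrich", "pathways.tsv"))
    logfc_b <- stats::setNames(de$ppa$logFC, de$ppa$gene_id)
    pioneer <- subset_shift_test(logfc_b, bundle$pioneer_genes)
    dx_write_tsv(pioneer$cdf, file.path(out, "enrich", "pioneer_cdf.tsv"))
    list(go = go, clusters = clusters, pfam = pfam, kegg = kegg,
         pioneer = pioneer)
  })

  summary <- stage("summary", {
    cmp <- comparison$cmp
    de_summary <- lapply(de, function(d) as.list(attr(d, "summary")))
    s <- list(
      de = de_summary,
      n_pairs = nrow(pairs),
      class_counts = as.list(vapply(c("1", "2", "3", "4", "none"),
                                    function(k) sum(cmp$class == k), 0L)),
      quadrant_counts = as.list(vapply(c("I", "II", "III", "IV"),
                                       function(q) sum(cmp$quadrant == q), 0L)),
      overlap_fisher = comparison$overlap[c("a", "b", "c", "d", "odds_ratio", "p")],
      correlations = comparison$correlations,
      pfam_pearson_r = enrichment$pfam$pearson_r,
      pioneer_ks = enrichment$pioneer[c("D", "p", "direction")],
      files = list(de_cel = "de_cel.tsv", de_ppa = "de_ppa.tsv",
                   pairs = "pairs.tsv", cmp = "cmp.tsv",
                   enrich_dir = "enrich"))
    jsonlite::write_json(s, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    s
  })

  invisible(list(inputs = inputs, arrays = arrays, de = de, pairs = pairs,
                 comparison = comparison, enrichment = enrichment,
                 summary = summary, config = config))
}
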