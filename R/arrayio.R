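# Readers/writers for all external tables: two-color scan tables (GPR-like),
# probe annotations, 12-column tabular hit files, and the annotation bundle.
# All files are tab-separated UTF-8 with '#' comment lines ignored.

SCAN_COLUMNS <- c("probe_id", "fg_red", "bg_red", "fg_green", "bg_green", "flag")

#' Construct a two-color scan object
#'
#' Holds one array's spot-level red/green foreground/background intensities,
#' together with the array metadata needed downstream (which species and
#' condition the sample channel carries, and which dye it was labelled with).
#'
#' @param array_id character scalar identifying the hybridization.
#' @param species `"cel"` or `"ppa"`.
#' @param condition `"dauer"`, `"exit"` or `"mix_reference"`.
#' @param dye_orientation `"sample_in_red"` or `"sample_in_green"`.
#' @param spots data frame with columns `probe_id`, `fg_red`, `bg_red`,
#'   `fg_green`, `bg_green` (linear fluorescence units, non-negative) and
#'   `flag` (`"ok"`/`"bad"`).
#' @return An object of class `two_color_scan`.
#' @export
two_color_scan <- function(array_id, species, condition, dye_orientation, spots) {
  species <- match.arg(species, c("cel", "ppa"))
  condition <- match.arg(condition, c("dauer", "exit", "mix_reference"))
  dye_orientation <- match.arg(dye_orientation, c("sample_in_red", "sample_in_green"))
  stopifnot(is.data.frame(spots))
  missing_cols <- setdiff(SCAN_COLUMNS, names(spots))
  if (length(missing_cols))
    dx_format_error(sprintf("scan table missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  spots <- spots[SCAN_COLUMNS]
  if (anyDuplicated(spots$probe_id))
    dx_validation_error(sprintf("duplicated probe_id in array %s: %s", array_id,
                                spots$probe_id[duplicated(spots$probe_id)][1L]))
  ints <- as.matrix(spots[c("fg_red", "bg_red", "fg_green", "bg_green")])
  if (!all(is.finite(ints)))
    dx_validation_error(sprintf("non-finite intensity in array %s (row %d)",
                                array_id, which(!apply(is.finite(ints), 1, all))[1L]))
  if (any(ints < 0))
    dx_validation_error(sprintf("negative intensity in array %s (row %d)",
                                array_id, which(apply(ints < 0, 1, any))[1L]))
  spots$flag <- ifelse(spots$flag %in% c("ok", "0", "OK"), "ok", "bad")
  if (!any(spots$flag == "ok"))
    dx_validation_error(sprintf("array %s has no ok-flagged spot", array_id))
  structure(list(array_id = array_id, species = species, condition = condition,
                 dye_orientation = dye_orientation, spots = spots),
            class = "two_color_scan")
}

#' @export
print.two_color_scan <- function(x, ...) {
  cat(sprintf("<two_color_scan> %s  %s %s (%s)  %d spots (%d ok)\n",
              x$array_id, x$species, x$condition, x$dye_orientation,
              nrow(x$spots), sum(x$spots$flag == "ok")))
  invisible(x)
}

#' Read a scan table
#'
#' Reads a GPR-like tab-separated spot-intensity table (header naming
#' `probe_id`, `fg_red`, `bg_red`, `fg_green`, `bg_green`, `flag`) and
#' validates it. Rows with flag other than ok are retained but marked bad;
#' they receive weight 0 downstream rather than being deleted, preserving
#' matrix alignment.
#'
#' @inheritParams two_color_scan
#' @param path file path.
#' @return A validated [two_color_scan()].
#' @export
read_scan_table <- function(path, array_id, species, condition, dye_orientation) {
  tab <- dx_read_tsv(path, header = TRUE)
  missing_cols <- setdiff(SCAN_COLUMNS, names(tab))
  if (length(missing_cols))
    dx_format_error(sprintf("%s: missing column(s): %s", path,
                            paste(missing_cols, collapse = ", ")))
  for (col in c("fg_red", "bg_red", "fg_green", "bg_green"))
    tab[[col]] <- as.numeric(tab[[col]])
  tab$probe_id <- as.character(tab$probe_id)
  tab$flag <- as.character(tab$flag)
  two_color_scan(array_id, species, condition, dye_orientation, tab)
}

#' Write a scan table
#'
#' Inverse of [read_scan_table()]; full printed precision so round-trips are
#' value-exact.
#'
#' @param scan a [two_color_scan()].
#' @param path output path.
#' @export
write_scan_table <- function(scan, path) {
  stopifnot(inherits(scan, "two_color_scan"))
  df <- scan$spots
  for (col in c("fg_red", "bg_red", "fg_green", "bg_green"))
    df[[col]] <- format(df[[col]], digits = 17, scientific = FALSE, trim = TRUE)
  dx_write_tsv(df, path)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Maps probes to genes and flags spike-in control probes together with their
#' expected log2 ratio (relative to total RNA; 0 for spikes added in
#' proportion to total RNA in both channels).
#'
#' @param path TSV with header `probe_id`, `gene_id`, `is_spike`,
#'   `expected_spike_logratio`.
#' @return data frame of class `probe_annotation`.
#' @export
read_probe_annotation <- function(path) {
  tab <- dx_read_tsv(path, header = TRUE)
  need <- c("probe_id", "gene_id", "is_spike", "expected_spike_logratio")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    dx_format_error(sprintf("%s: missing column(s): %s", path,
                            paste(missing_cols, collapse = ", ")))
  tab$probe_id <- as.character(tab$probe_id)
  tab$gene_id <- as.character(tab$gene_id)
  tab$gene_id[is.na(tab$gene_id)] <- ""
  tab$is_spike <- as.logical(tab$is_spike)
  tab$expected_spike_logratio <- as.numeric(tab$expected_spike_logratio)
  probe_annotation(tab)
}

#' @rdname read_probe_annotation
#' @param tab data frame with the probe-annotation columns.
#' @export
probe_annotation <- function(tab) {
  if (any(tab$is_spike & !is.finite(tab$expected_spike_logratio)))
    dx_validation_error("spike probe without finite expected_spike_logratio")
  if (any(!tab$is_spike & tab$gene_id == ""))
    dx_validation_error("non-spike probe with empty gene_id")
  if (anyDuplicated(tab$probe_id))
    dx_validation_error("duplicated probe_id in probe annotation")
  class(tab) <- c("probe_annotation", "data.frame")
  tab
}

#' @export
write_probe_annotation <- function(probes, path) {
  dx_write_tsv(as.data.frame(probes), path)
  invisible(path)
}

#' Read a 12-column tabular hit file
#'
#' The outfmt-6 convention: no header, 12 tab-separated columns with
#' query id, subject id in columns 1-2 and e-value, bit score in columns
#' 11-12. `(query, subject)` pairs may repeat (multiple HSPs).
#'
#' @param path file path; an empty file yields an empty (valid) table.
#' @return data frame of class `hit_table` with columns `query_id`,
#'   `subject_id`, `bit_score`, `e_value`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) dx_format_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) return(hit_table(character(), character(), numeric(), numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 12L))
    dx_format_error(sprintf("%s: line %d has %d columns, expected 12",
                            path, which(ncols < 12L)[1L], min(ncols)))
  m <- do.call(rbind, parts)
  bits <- suppressWarnings(as.numeric(m[, 12L]))
  eval <- suppressWarnings(as.numeric(m[, 11L]))
  if (anyNA(bits))
    dx_validation_error(sprintf("%s: non-numeric bit score at line %d",
                                path, which(is.na(bits))[1L]))
  if (anyNA(eval))
    dx_validation_error(sprintf("%s: non-numeric e-value at line %d",
                                path, which(is.na(eval))[1L]))
  hit_table(m[, 1L], m[, 2L], bits, eval)
}

#' @rdname read_hit_table
#' @param query_id,subject_id,bit_score,e_value parallel vectors.
#' @export
hit_table <- function(query_id, subject_id, bit_score, e_value) {
  if (any(!is.finite(bit_score)) || any(bit_score < 0))
    dx_validation_error("bit scores must be finite and non-negative")
  if (any(!is.finite(e_value)) || any(e_value < 0))
    dx_validation_error("e-values must be finite and non-negative")
  structure(data.frame(query_id = as.character(query_id),
                       subject_id = as.character(subject_id),
                       bit_score = bit_score, e_value = e_value,
                       stringsAsFactors = FALSE),
            class = c("hit_table", "data.frame"))
}

#' Write a hit table in the 12-column tabular dialect
#'
#' Columns 3-10 (identity, alignment length, coordinates) are filled with
#' placeholder values; only columns 1, 2, 11, 12 are meaningful here.
#'
#' @param hits a `hit_table`.
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  n <- nrow(hits)
  df <- data.frame(hits$query_id, hits$subject_id,
                   rep(100, n), rep(100, n), rep(0, n), rep(0, n),
                   rep(1, n), rep(100, n), rep(1, n), rep(100, n),
                   format(hits$e_value, digits = 17, trim = TRUE),
                   format(hits$bit_score, digits = 17, trim = TRUE))
  dx_write_tsv(df, path, col.names = FALSE)
  invisible(path)
}

# ---- two-column association tables ------------------------------------------

# entity \t gene, no header
read_pair_map <- function(path) {
  tab <- dx_read_tsv(path, header = FALSE)
  if (nrow(tab) == 0L) return(list())
  if (ncol(tab) < 2L) dx_format_error(sprintf("%s: expected 2 columns", path))
  split(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

write_pair_map <- function(map, path) {
  ent <- rep(names(map), lengths(map))
  dx_write_tsv(data.frame(ent, unlist(map, use.names = FALSE)), path, col.names = FALSE)
  invisible(path)
}

#' Assemble and validate an annotation bundle
#'
#' The bundle carries every annotation layer used by the enrichment suite:
#' the ontology DAG, direct gene-to-term associations, expression-cluster
#' memberships, gene-to-PFAM-domain assignments, pathway memberships, and the
#' pioneer-gene set. All gene-keyed maps annotate species-A (C. elegans)
#' genes except `gene2domain`, which may mix both species' (disjoint) ids.
#'
#' @param ontology an `ontology` object from [read_obo()].
#' @param gene2term named list: gene id -> character vector of term ids.
#' @param clusters named list: cluster id -> character vector of gene ids.
#' @param gene2domain named list: gene id -> character vector of PFAM ids.
#' @param pathway2gene named list: pathway id -> character vector of gene ids.
#' @param pioneer_genes character vector of gene ids.
#' @return list of class `annotation_bundle`.
#' @export
annotation_bundle <- function(ontology, gene2term, clusters, gene2domain,
                              pathway2gene, pioneer_genes) {
  stopifnot(inherits(ontology, "ontology"))
  unknown <- setdiff(unique(unlist(gene2term, use.names = FALSE)), ontology$terms$id)
  if (length(unknown))
    dx_validation_error(sprintf("gene2term names unknown term(s): %s",
                                paste(utils::head(unknown, 3), collapse = ", ")))
  structure(list(ontology = ontology, gene2term = gene2term, clusters = clusters,
                 gene2domain = gene2domain, pathway2gene = pathway2gene,
                 pioneer_genes = as.character(pioneer_genes)),
            class = "annotation_bundle")
}

#' Read the full annotation bundle from disk
#'
#' @param ontology_path OBO 1.2 ontology file.
#' @param associations_path two-column TSV term -> gene.
#' @param clusters_path two-column TSV cluster -> gene.
#' @param domains_path two-column TSV domain -> gene.
#' @param pathways_path two-column TSV pathway -> gene.
#' @param pioneers_path one-column list of gene ids.
#' @return an [annotation_bundle()].
#' @export
read_annotation_bundle <- function(ontology_path, associations_path, clusters_path,
                                   domains_path, pathways_path, pioneers_path) {
  ontology <- read_obo(ontology_path)
  term2gene <- read_pair_map(associations_path)
  gene2term <- invert_map(term2gene)
  clusters <- read_pair_map(clusters_path)
  gene2domain <- invert_map(read_pair_map(domains_path))
  pathway2gene <- read_pair_map(pathways_path)
  pio <- dx_read_tsv(pioneers_path, header = FALSE)
  pioneer_genes <- if (nrow(pio)) as.character(pio[[1L]]) else character()
  annotation_bundle(ontology, gene2term, clusters, gene2domain, pathway2gene,
                    pioneer_genes)
}

#' Write an annotation bundle to a directory
#'
#' @param bundle an [annotation_bundle()].
#' @param dir output directory (created if absent).
#' @return named vector of the six file paths, invisibly.
#' @export
write_annotation_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ontology = file.path(dir, "ontology.obo"),
             associations = file.path(dir, "gene2term.tsv"),
             clusters = file.path(dir, "clusters.tsv"),
             domains = file.path(dir, "gene2domain.tsv"),
             pathways = file.path(dir, "pathway2gene.tsv"),
             pioneers = file.path(dir, "pioneer_genes.tsv"))
  write_obo(bundle$ontology, paths[["ontology"]])
  write_pair_map(invert_map(bundle$gene2term), paths[["associations"]])
  write_pair_map(bundle$clusters, paths[["clusters"]])
  write_pair_map(invert_map(bundle$gene2domain), paths[["domains"]])
  write_pair_map(bundle$pathway2gene, paths[["pathways"]])
  writeLines(bundle$pioneer_genes, paths[["pioneers"]])
  invisible(paths)
}

# invert a named list-of-vectors map (a -> set of b  ==>  b -> set of a),
# with sorted keys and values for deterministic round trips
invert_map <- function(map) {
  if (length(map) == 0L) return(list())
  a <- rep(names(map), lengths(map))
  b <- unlist(map, use.names = FALSE)
  out <- lapply(split(a, b), function(v) sort(unique(v)))
  out[order(names(out))]
}
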