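# Annotation-layer analyses: ortholog-based annotation transfer, GO term
# enrichment with DAG propagation (one-sided Fisher, deliberately without
# multiple-testing correction, matching the published analysis strategy),
# expression-cluster enrichment (per-column BH, -log10 scores), PFAM-family
# median fold-change profiles, KEGG pathway up/down/no-change tabulation, and
# the pioneer-gene distribution-shift (two-sample KS) test.

#' Transfer annotations to the second species via 1:1 orthologs
#'
#' Each species-B gene inherits exactly the term, cluster and pathway sets of
#' its 1:1 ortholog; unpaired B genes stay unannotated. The gene2domain map
#' and pioneer set are species-resolved already and pass through unchanged.
#'
#' @param bundle an [annotation_bundle()] annotating species-A genes.
#' @param pairs an `ortholog_pairs` data frame.
#' @return an [annotation_bundle()] whose gene-keyed maps use species-B ids.
#' @export
transfer_annotations <- function(bundle, pairs) {
  a2b <- stats::setNames(pairs$gene_b, pairs$gene_a)
  remap_genes <- function(gene2x) {
    keep <- names(gene2x) %in% names(a2b)
    out <- gene2x[keep]
    names(out) <- unname(a2b[names(out)])
    out
  }
  remap_sets <- function(x2gene) {
    lapply(x2gene, function(g) sort(unname(a2b[intersect(g, names(a2b))])))
  }
  annotation_bundle(bundle$ontology,
                    gene2term = remap_genes(bundle$gene2term),
                    clusters = remap_sets(bundle$clusters),
                    gene2domain = bundle$gene2domain,
                    pathway2gene = remap_sets(bundle$pathway2gene),
                    pioneer_genes = bundle$pioneer_genes)
}

#' Propagate gene annotations to ancestor terms
#'
#' True-path closure: every gene annotated to a term is also annotated to all
#' of that term's is_a/part_of ancestors.
#'
#' @param gene2term named list gene -> direct term ids.
#' @param ontology the `ontology` the terms live in.
#' @return named list gene -> closed term ids (sorted, unique).
#' @export
propagate_to_ancestors <- function(gene2term, ontology) {
  anc <- term_ancestors(ontology)
  lapply(gene2term, function(terms) {
    terms <- intersect(terms, names(anc))
    sort(unique(c(terms, unlist(anc[terms], use.names = FALSE))))
  })
}

#' Term enrichment by one-sided Fisher test
#'
#' The background is restricted to genes with at least one annotation in the
#' closed map; for each term with `annotated >= min_term_size` the p-value is
#' the hypergeometric upper tail `P[X >= significant]` for drawing `|study|`
#' genes from the background. `expected = annotated * |study| / |background|`.
#' No multiple-testing correction is applied (per the published strategy of
#' reporting all trends); rows with `p <= p_cutoff` are returned sorted by p.
#'
#' @param study character vector of study-set gene ids (subset of
#'   background).
#' @param background character vector of background gene ids.
#' @param gene2term_closed closed map from [propagate_to_ancestors()].
#' @param ontology optional `ontology` used to attach term names.
#' @param min_term_size smallest annotated count tested (default 1).
#' @param p_cutoff report rows with `p <= p_cutoff` (default 0.05; use 1 to
#'   obtain the full table).
#' @return data frame of class `enrichment_result`: `term_id`, `term_name`,
#'   `annotated`, `significant`, `expected`, `p`.
#' @export
term_enrichment <- function(study, background, gene2term_closed, ontology = NULL,
                            min_term_size = 1L, p_cutoff = 0.05) {
  background <- intersect(background, names(gene2term_closed)[lengths(gene2term_closed) > 0])
  study <- intersect(study, background)
  if (length(study) == 0L) {
    warning("term_enrichment: empty study set")
    return(structure(data.frame(term_id = character(), term_name = character(),
                                annotated = integer(), significant = integer(),
                                expected = numeric(), p = numeric()),
                     class = c("enrichment_result", "data.frame")))
  }
  g2t <- gene2term_closed[background]
  term_of <- unlist(g2t, use.names = FALSE)
  gene_of <- rep(names(g2t), lengths(g2t))
  annotated <- table(term_of)
  in_study <- gene_of %in% study
  signif_tab <- table(term_of[in_study])
  terms <- names(annotated)
  significant <- as.integer(signif_tab[terms])
  significant[is.na(significant)] <- 0L
  annotated <- as.integer(annotated)
  keep <- annotated >= min_term_size
  N <- length(background); k <- length(study)
  p <- stats::phyper(significant - 1L, annotated, N - annotated, k,
                     lower.tail = FALSE)
  out <- data.frame(term_id = terms, term_name = terms,
                    annotated = annotated, significant = significant,
                    expected = annotated * k / N, p = p,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (!is.null(ontology)) {
    idx <- match(out$term_id, ontology$terms$id)
    out$term_name[!is.na(idx)] <- ontology$terms$name[idx[!is.na(idx)]]
  }
  out <- out[out$p <= p_cutoff, , drop = FALSE]
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Expression-cluster enrichment score matrix
#'
#' For each cluster and each direction set (e.g. cel_dauer = genes up in the
#' C. elegans dauer), a one-sided Fisher test of cluster membership against
#' set membership over the background; BH adjustment within each column; the
#' score is `-log10(adjusted p)` when `adjusted p <= alpha`, else exactly 0.
#'
#' @param direction_sets named list of gene-id vectors, one per column.
#' @param clusters named list cluster id -> gene ids.
#' @param background character vector of background gene ids (clusters are
#'   restricted to it; empty-in-background clusters are skipped).
#' @param alpha significance cutoff on the adjusted p (default 0.05).
#' @return numeric matrix clusters x direction sets of class
#'   `cluster_score_matrix`.
#' @export
cluster_enrichment <- function(direction_sets, clusters, background, alpha = 0.05) {
  clusters <- lapply(clusters, intersect, background)
  empty <- lengths(clusters) == 0L
  if (any(empty))
    message(sprintf("cluster_enrichment: skipping %d cluster(s) with no background member",
                    sum(empty)))
  clusters <- clusters[!empty]
  N <- length(background)
  scores <- matrix(0, length(clusters), length(direction_sets),
                   dimnames = list(names(clusters), names(direction_sets)))
  for (j in seq_along(direction_sets)) {
    set <- intersect(direction_sets[[j]], background)
    k <- length(set)
    praw <- vapply(clusters, function(cl) {
      a <- length(intersect(cl, set))
      stats::phyper(a - 1L, length(cl), N - length(cl), k, lower.tail = FALSE)
    }, 0)
    padj <- adjust_fdr(praw)
    scores[, j] <- ifelse(padj <= alpha, -log10(padj), 0)
  }
  structure(scores, class = c("cluster_score_matrix", class(scores)))
}

#' PFAM-family median fold-change profile
#'
#' Genes are stratified into (possibly overlapping) families by PFAM domain;
#' a gene contributes to every domain it carries. Families with at least
#' `min_members` members represented on each species' array are represented
#' by the per-species median dauer-vs-exit log2 fold change (positive = up in
#' dauer); the cross-species Pearson r over families is reported alongside.
#'
#' @param de_a,de_b `de_result` objects for the two species.
#' @param gene2domain named list gene id -> domain ids (both species' genes
#'   may share the map; membership is resolved against each DE table).
#' @param min_members minimum family size per species (default 5).
#' @return list with `families` (data frame `domain_id`, `n_a`, `n_b`,
#'   `median_logfc_a`, `median_logfc_b`) and `pearson_r` (`NA` when fewer
#'   than 3 qualifying families).
#' @export
pfam_family_profile <- function(de_a, de_b, gene2domain, min_members = 5L) {
  dom_of <- unlist(gene2domain, use.names = FALSE)
  gene_of <- rep(names(gene2domain), lengths(gene2domain))
  per_species <- function(de) {
    idx <- match(gene_of, de$gene_id)
    ok <- !is.na(idx)
    split(de$logFC[idx[ok]], dom_of[ok])
  }
  fa <- per_species(de_a); fb <- per_species(de_b)
  doms <- sort(intersect(names(fa)[lengths(fa) >= min_members],
                         names(fb)[lengths(fb) >= min_members]))
  families <- data.frame(
    domain_id = doms,
    n_a = lengths(fa[doms]), n_b = lengths(fb[doms]),
    median_logfc_a = vapply(fa[doms], stats::median, 0),
    median_logfc_b = vapply(fb[doms], stats::median, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  r <- if (nrow(families) < 3L) NA_real_
       else stats::cor(families$median_logfc_a, families$median_logfc_b)
  list(families = families, pearson_r = r)
}

#' KEGG-style pathway up/down/no-change tabulation
#'
#' Pathway membership is defined on species-A genes and transferred to
#' species B through the 1:1 pairs; per pathway and species the member
#' orthologs are counted as up, down or no_change (not significant) from the
#' DE calls.
#'
#' @param de_a,de_b `de_result` objects.
#' @param pathway2gene named list pathway id -> species-A gene ids.
#' @param pairs an `ortholog_pairs` data frame.
#' @return data frame of class `pathway_tabulation`: `pathway_id`, `n_up_a`,
#'   `n_down_a`, `n_no_change_a`, `n_up_b`, `n_down_b`, `n_no_change_b`.
#' @export
kegg_tabulate <- function(de_a, de_b, pathway2gene, pairs) {
  a2b <- stats::setNames(pairs$gene_b, pairs$gene_a)
  count3 <- function(calls) c(up = sum(calls == "up"), down = sum(calls == "down"),
                              no_change = sum(calls == "ns"))
  rows <- lapply(names(pathway2gene), function(pw) {
    ga <- intersect(pathway2gene[[pw]], names(a2b)) # member 1:1 orthologs
    gb <- unname(a2b[ga])
    ca <- count3(de_a$call[match(ga, de_a$gene_id)][!is.na(match(ga, de_a$gene_id))])
    cb <- count3(de_b$call[match(gb, de_b$gene_id)][!is.na(match(gb, de_b$gene_id))])
    data.frame(pathway_id = pw, n_up_a = ca[["up"]], n_down_a = ca[["down"]],
               n_no_change_a = ca[["no_change"]], n_up_b = cb[["up"]],
               n_down_b = cb[["down"]], n_no_change_b = cb[["no_change"]],
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("pathway_tabulation", "data.frame"))
}

#' Distribution-shift test for a gene subset
#'
#' Two-sample Kolmogorov-Smirnov test between the fold-change distributions
#' of a gene subset (e.g. pioneer genes) and its complement; the direction is
#' decided by comparing medians. Both empirical CDFs are exported for
#' cumulative plots.
#'
#' @param logfc named numeric vector gene id -> log2 fold change.
#' @param subset character vector of gene ids.
#' @param min_n minimum size of subset and complement (default 20).
#' @return list of class `ks_report`: `D`, `p`, `direction`
#'   (`subset_higher` / `subset_lower` / `none`), `n_subset`, `n_complement`
#'   and `cdf` (data frame `value`, `cdf_subset`, `cdf_complement`).
#' @export
subset_shift_test <- function(logfc, subset, min_n = 20L) {
  subset <- intersect(subset, names(logfc))
  x <- logfc[subset]
  y <- logfc[setdiff(names(logfc), subset)]
  if (length(x) < min_n || length(y) < min_n)
    dx_validation_error(sprintf("subset/complement too small (%d/%d, need >= %d)",
                                length(x), length(y), min_n))
  ks <- suppressWarnings(stats::ks.test(x, y))
  med_x <- stats::median(x); med_y <- stats::median(y)
  direction <- if (med_x > med_y) "subset_higher" else
               if (med_x < med_y) "subset_lower" else "none"
  grid <- sort(unique(c(x, y)))
  structure(list(D = unname(ks$statistic), p = ks$p.value, direction = direction,
                 n_subset = length(x), n_complement = length(y),
                 cdf = data.frame(value = grid,
                                  cdf_subset = stats::ecdf(x)(grid),
                                  cdf_complement = stats::ecdf(y)(grid))),
            class = "ks_report")
}

#' @export
print.ks_report <- function(x, ...) {
  cat(sprintf("<ks_report> D=%.4f p=%.3g %s (n=%d vs %d)\n",
              x$D, x$p, x$direction, x$n_subset, x$n_complement))
  invisible(x)
}
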