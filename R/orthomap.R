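# 1:1 orthology as reciprocal best hits between two directional similarity
# searches, with a bit-score floor, and restriction to genes present on both
# arrays.

#' Best hit per query
#'
#' Rows below `min_bits` are discarded; multiple HSPs for one (query,
#' subject) pair are first collapsed to their maximum bit score (minimum
#' e-value); per query the single best subject is kept by descending bit
#' score, then ascending e-value, then lexicographically smallest subject id.
#' Self hits (query == subject) are ignored.
#'
#' @param hits a [hit_table()].
#' @param min_bits bit-score cutoff (default 50).
#' @return named character vector query id -> subject id.
#' @export
best_hits <- function(hits, min_bits = 50) {
  h <- hits[hits$bit_score >= min_bits & hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(h) == 0L) return(stats::setNames(character(), character()))
  # collapse HSPs per (query, subject)
  key <- paste(h$query_id, h$subject_id, sep = "\r")
  agg_bits <- tapply(h$bit_score, key, max)
  agg_e <- tapply(h$e_value, key, min)
  qs <- do.call(rbind, strsplit(names(agg_bits), "\r", fixed = TRUE))
  d <- data.frame(query = qs[, 1L], subject = qs[, 2L],
                  bits = as.numeric(agg_bits), e = as.numeric(agg_e),
                  stringsAsFactors = FALSE)
  d <- d[order(d$query, -d$bits, d$e, d$subject), ]
  d <- d[!duplicated(d$query), ]
  stats::setNames(d$subject, d$query)
}

#' Reciprocal best hits
#'
#' Pair `(a, b)` is included iff `map_ab[a] == b` and `map_ba[b] == a`.
#'
#' @param map_ab,map_ba named vectors from [best_hits()] in the two search
#'   directions.
#' @return data frame of class `ortholog_pairs` with columns `gene_a`,
#'   `gene_b`, sorted by `gene_a`.
#' @export
reciprocal_best <- function(map_ab, map_ba) {
  a <- names(map_ab)
  b <- unname(map_ab)
  keep <- !is.na(match(b, names(map_ba))) & map_ba[b] == a
  keep[is.na(keep)] <- FALSE
  out <- data.frame(gene_a = a[keep], gene_b = b[keep], stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ortholog_pairs", "data.frame"))
}

#' Restrict ortholog pairs to genes represented on both arrays
#'
#' @param pairs an `ortholog_pairs` data frame.
#' @param genes_on_array_a,genes_on_array_b character vectors of gene ids.
#' @return the filtered `ortholog_pairs`.
#' @export
restrict_to_arrays <- function(pairs, genes_on_array_a, genes_on_array_b) {
  keep <- pairs$gene_a %in% genes_on_array_a & pairs$gene_b %in% genes_on_array_b
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute 1:1 orthologs from two hit tables
#'
#' [best_hits()] in both directions followed by [reciprocal_best()].
#'
#' @param hits_ab,hits_ba directional [hit_table()]s.
#' @param min_bits bit-score cutoff (default 50).
#' @return an `ortholog_pairs` data frame.
#' @export
rbh_orthologs <- function(hits_ab, hits_ba, min_bits = 50) {
  reciprocal_best(best_hits(hits_ab, min_bits), best_hits(hits_ba, min_bits))
}
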