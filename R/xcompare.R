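# Cross-species comparison over 1:1 orthologs: join the two species' DE
# results, classify pairs into four classes (concordant-significant,
# discordant-significant, A-only, B-only), test the overlap of significance
# with a one-sided Fisher exact test, and report Pearson correlations of the
# log2 fold changes for the relevant subsets.

#' Classify ortholog pairs by cross-species differential expression
#'
#' Class 1: significant in both species with the same fold-change sign;
#' class 2: significant in both with opposite signs; class 3: significant in
#' species A only; class 4: in species B only; otherwise none. Quadrants are
#' assigned among both-significant pairs by the signs of `(logFC_a, logFC_b)`:
#' I = (+,+), II = (-,+), III = (-,-), IV = (+,-).
#'
#' @param de_a,de_b `de_result` objects for species A (C. elegans) and B
#'   (P. pacificus).
#' @param pairs an `ortholog_pairs` data frame.
#' @param fdr_threshold significance cutoff on the stored `fdr` (default
#'   0.05).
#' @return data frame of class `ortholog_comparison`: `gene_a`, `gene_b`,
#'   `logfc_a`, `logfc_b`, `sig_a`, `sig_b`, `class` in `{1,2,3,4,none}`,
#'   `quadrant` in `{I,II,III,IV,none}`.
#' @export
classify_orthologs <- function(de_a, de_b, pairs, fdr_threshold = 0.05) {
  ia <- match(pairs$gene_a, de_a$gene_id)
  ib <- match(pairs$gene_b, de_b$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  if (any(!keep))
    message(sprintf("classify_orthologs: dropping %d pair(s) missing from a DE result",
                    sum(!keep)))
  ia <- ia[keep]; ib <- ib[keep]
  cmp <- data.frame(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
                    logfc_a = de_a$logFC[ia], logfc_b = de_b$logFC[ib],
                    sig_a = !is.na(de_a$fdr[ia]) & de_a$fdr[ia] <= fdr_threshold,
                    sig_b = !is.na(de_b$fdr[ib]) & de_b$fdr[ib] <= fdr_threshold,
                    stringsAsFactors = FALSE)
  zero_sig <- (cmp$sig_a & cmp$logfc_a == 0) | (cmp$sig_b & cmp$logfc_b == 0)
  if (any(zero_sig))
    message(sprintf("classify_orthologs: %d significant pair(s) with logFC exactly 0 -> class none",
                    sum(zero_sig)))
  cls <- rep("none", nrow(cmp))
  both <- cmp$sig_a & cmp$sig_b & !zero_sig
  cls[both & sign(cmp$logfc_a) == sign(cmp$logfc_b)] <- "1"
  cls[both & sign(cmp$logfc_a) != sign(cmp$logfc_b)] <- "2"
  cls[cmp$sig_a & !cmp$sig_b & !zero_sig] <- "3"
  cls[!cmp$sig_a & cmp$sig_b & !zero_sig] <- "4"
  quad <- rep("none", nrow(cmp))
  quad[both & cmp$logfc_a > 0 & cmp$logfc_b > 0] <- "I"
  quad[both & cmp$logfc_a < 0 & cmp$logfc_b > 0] <- "II"
  quad[both & cmp$logfc_a < 0 & cmp$logfc_b < 0] <- "III"
  quad[both & cmp$logfc_a > 0 & cmp$logfc_b < 0] <- "IV"
  cmp$class <- cls
  cmp$quadrant <- quad
  structure(cmp, class = c("ortholog_comparison", "data.frame"),
            fdr_threshold = fdr_threshold)
}

#' @export
print.ortholog_comparison <- function(x, ...) {
  cat(sprintf("<ortholog_comparison> %d pairs; classes: %s\n", nrow(x),
              paste(sprintf("%s=%d", c("1", "2", "3", "4"),
                            vapply(c("1", "2", "3", "4"),
                                   function(k) sum(x$class == k), 0L)),
                    collapse = " ")))
  invisible(x)
}

#' One-sided Fisher test on the cross-species significance overlap
#'
#' Builds the 2x2 table (significant in A) x (significant in B) over the
#' joined pairs and computes the hypergeometric upper tail `P[X >= a]`
#' (enrichment alternative) plus the sample odds ratio `(a d)/(b c)`. The
#' one-sided test is the default because it is the test that reproduces the
#' published worked example from its marginal counts; `alternative =
#' "two.sided"` delegates to [stats::fisher.test()].
#'
#' @param cmp an [classify_orthologs()] result, or a numeric vector
#'   `c(a, b, c, d)` of both/A-only/B-only/neither counts.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return list of class `overlap_test`: `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p`.
#' @export
overlap_fisher <- function(cmp, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (inherits(cmp, "ortholog_comparison")) {
    a <- sum(cmp$sig_a & cmp$sig_b); b <- sum(cmp$sig_a & !cmp$sig_b)
    cc <- sum(!cmp$sig_a & cmp$sig_b); d <- sum(!cmp$sig_a & !cmp$sig_b)
  } else {
    stopifnot(is.numeric(cmp), length(cmp) == 4L)
    a <- cmp[1L]; b <- cmp[2L]; cc <- cmp[3L]; d <- cmp[4L]
  }
  if ((a + b) == 0L || (a + cc) == 0L || (b + d) == 0L || (cc + d) == 0L) {
    warning("overlap_fisher: a zero margin; p set to 1")
    p <- 1
  } else if (alternative == "greater") {
    # X ~ Hypergeometric(N = a+b+c+d, K = a+c successes, n = a+b draws)
    p <- stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
  } else {
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
  }
  structure(list(a = a, b = b, c = cc, d = d,
                 odds_ratio = (a * d) / (b * cc), p = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("<overlap_test> a=%d b=%d c=%d d=%d  OR=%.3g  p=%.3g\n",
              x$a, x$b, x$c, x$d, x$odds_ratio, x$p))
  invisible(x)
}

#' Pearson correlations of cross-species fold changes
#'
#' Standard Pearson r of `(logfc_a, logfc_b)` over: all joined pairs, the
#' both-significant set, class 1 and class 2. Subsets with fewer than 3 pairs
#' or zero variance report `NA`.
#'
#' @param cmp an [classify_orthologs()] result.
#' @return data frame of class `correlation_report` with columns `subset`,
#'   `r`, `n`.
#' @export
correlation_report <- function(cmp) {
  sub <- list(all = rep(TRUE, nrow(cmp)),
              both_sig = cmp$sig_a & cmp$sig_b,
              class1 = cmp$class == "1",
              class2 = cmp$class == "2")
  rows <- lapply(names(sub), function(nm) {
    idx <- sub[[nm]]
    n <- sum(idx)
    r <- if (n < 3L || stats::sd(cmp$logfc_a[idx]) == 0 ||
             stats::sd(cmp$logfc_b[idx]) == 0) NA_real_
         else stats::cor(cmp$logfc_a[idx], cmp$logfc_b[idx])
    data.frame(subset = nm, r = r, n = n, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("correlation_report", "data.frame"))
}
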