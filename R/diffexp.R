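# Gene-level differential expression on the common-reference design: probes
# are summarized to genes, a per-gene two-condition linear model is fit to the
# M values (dauer and exit arrays both measured against the mixed-stage
# reference), gene-wise variances are moderated by empirical Bayes, and calls
# are made under Benjamini-Hochberg FDR control.

#' Summarize probe-level M values to genes
#'
#' Per gene per array, M is the median over that gene's probes with weight
#' > 0; the cell weight is the count of contributing probes (0 = missing).
#' Spike probes are excluded. Genes with no usable probe on any array are
#' dropped with a message.
#'
#' @param arrays list of `normalized_array` objects (same probe set).
#' @param probes a [probe_annotation()].
#' @return An object of class `gene_expression_set`: list with `M` and
#'   `weights` (genes x arrays matrices) and `arrays` (data frame `array_id`,
#'   `species`, `condition`).
#' @export
summarize_probes <- function(arrays, probes) {
  stopifnot(length(arrays) >= 1L)
  gene_probes <- probes[!probes$is_spike & probes$gene_id != "", ]
  genes <- sort(unique(gene_probes$gene_id))
  meta <- data.frame(
    array_id = vapply(arrays, attr, "", which = "array_id"),
    species = vapply(arrays, attr, "", which = "species"),
    condition = vapply(arrays, attr, "", which = "condition"),
    stringsAsFactors = FALSE)
  M <- matrix(NA_real_, length(genes), length(arrays),
              dimnames = list(genes, meta$array_id))
  W <- matrix(0, length(genes), length(arrays), dimnames = dimnames(M))
  for (j in seq_along(arrays)) {
    arr <- arrays[[j]]
    idx <- match(gene_probes$probe_id, arr$probe_id)
    ok <- !is.na(idx) & arr$weight[idx] > 0
    if (!any(ok)) next
    gi <- gene_probes$gene_id[ok]
    m <- arr$M[idx[ok]]
    med <- vapply(split(m, gi), stats::median, 0)
    cnt <- vapply(split(m, gi), length, 0L)
    row <- match(names(med), genes)
    M[row, j] <- med
    W[row, j] <- cnt
  }
  empty <- rowSums(W) == 0
  if (any(empty)) {
    message(sprintf("summarize_probes: dropping %d gene(s) with no usable probe",
                    sum(empty)))
    M <- M[!empty, , drop = FALSE]
    W <- W[!empty, , drop = FALSE]
  }
  structure(list(M = M, weights = W, arrays = meta), class = "gene_expression_set")
}

#' Fit the per-gene two-condition model
#'
#' For each gene, `beta_c` is the weighted mean of M over arrays of condition
#' `c` (dauer, exit); the residual variance is the weighted residual sum of
#' squares divided by `d_g = n_dauer + n_exit - 2`, where the n's count
#' arrays with positive weight for that gene. The dauer-vs-exit contrast has
#' unscaled variance `v = 1/sum(w_dauer) + 1/sum(w_exit)` (the
#' weighted-least-squares variance of the difference of weighted means; with
#' unit weights this is the familiar `1/n_dauer + 1/n_exit`). The
#' dauer-vs-mix log fold change is `beta_dauer` itself (the reference channel
#' is the mixed-stage pool). Genes with `d_g <= 0` or fewer than 2 usable
#' arrays in either condition are marked unestimable.
#'
#' @param ges a [summarize_probes()] result (one species).
#' @return data frame of class `gene_fits`: `gene_id`, `logFC` (dauer vs
#'   exit), `logFC_mix` (dauer vs mix), `s2` (residual variance), `df`
#'   (residual d.f.), `v` (unscaled contrast variance), `estimable`.
#' @export
fit_gene_model <- function(ges) {
  cond <- ges$arrays$condition
  if (!all(cond %in% c("dauer", "exit")))
    dx_validation_error("fit_gene_model expects only dauer/exit arrays")
  jd <- which(cond == "dauer"); je <- which(cond == "exit")
  M <- ges$M; W <- ges$weights
  M[W == 0] <- NA_real_
  wmean <- function(cols) {
    w <- W[, cols, drop = FALSE]; m <- M[, cols, drop = FALSE]
    rowSums(w * m, na.rm = TRUE) / rowSums(w)
  }
  beta_d <- wmean(jd); beta_e <- wmean(je)
  n_d <- rowSums(W[, jd, drop = FALSE] > 0)
  n_e <- rowSums(W[, je, drop = FALSE] > 0)
  fitted <- matrix(NA_real_, nrow(M), ncol(M))
  fitted[, jd] <- beta_d; fitted[, je] <- beta_e
  rss <- rowSums(W * (M - fitted)^2, na.rm = TRUE)
  df <- n_d + n_e - 2L
  estimable <- n_d >= 2L & n_e >= 2L & df > 0L
  s2 <- ifelse(estimable, rss / pmax(df, 1L), NA_real_)
  sw_d <- rowSums(W[, jd, drop = FALSE])
  sw_e <- rowSums(W[, je, drop = FALSE])
  structure(data.frame(gene_id = rownames(M), logFC = beta_d - beta_e,
                       logFC_mix = beta_d, s2 = s2, df = as.numeric(df),
                       v = 1 / sw_d + 1 / sw_e, estimable = estimable,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("gene_fits", "data.frame"))
}

# solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Hyperparameters by the method of moments on
#' `e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)`:
#' `trigamma(d0/2)` is matched to the excess variance of `e_g` over the
#' sampling contribution `trigamma(d_g/2)` (Newton inversion of trigamma;
#' non-positive excess gives `d0 = Inf`), and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. The posterior variance
#' is `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)` (equal to `s0^2` at `d0 = Inf`);
#' the moderated t is `logFC / (s_tilde sqrt(v))` with `d0 + d_g` degrees of
#' freedom and a two-sided p-value. Genes with `s_g^2 = 0` are excluded from
#' hyperparameter estimation but still moderated with the fitted prior.
#'
#' @param fits a [fit_gene_model()] result.
#' @param min_genes minimum genes with positive variance (default 50).
#' @return list with `hyper` (list `d0`, `s0_sq`) and `table` (the input plus
#'   `s2_post`, `t_mod`, `df_total`, `p`).
#' @export
ebayes_moderate <- function(fits, min_genes = 50L) {
  use <- fits$estimable & is.finite(fits$s2) & fits$s2 > 0 & fits$df > 0
  if (sum(use) < min_genes)
    dx_error(sprintf("only %d genes with positive variance, need >= %d",
                     sum(use), min_genes), "dauerx_moderation_error")
  s2 <- fits$s2[use]; dg <- fits$df[use]
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  n <- length(e); ebar <- mean(e)
  excess <- mean((e - ebar)^2 * n / (n - 1) - trigamma(dg / 2))
  d0 <- if (excess <= 0) Inf else 2 * trigamma_inverse(excess)
  s0_sq <- if (is.infinite(d0)) exp(ebar) else exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  tab <- as.data.frame(fits)
  s2g <- ifelse(fits$estimable & is.finite(fits$s2), fits$s2, NA_real_)
  tab$s2_post <- if (is.infinite(d0)) rep(s0_sq, nrow(tab)) else
    (d0 * s0_sq + fits$df * s2g) / (d0 + fits$df)
  tab$s2_post[is.na(s2g)] <- NA_real_
  tab$df_total <- d0 + fits$df
  tab$t_mod <- tab$logFC / sqrt(tab$s2_post * fits$v)
  tab$p <- 2 * stats::pt(-abs(tab$t_mod), df = tab$df_total)
  list(hyper = list(d0 = d0, s0_sq = s0_sq), table = tab)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: sort ascending, `q_(i) = min_{j >= i} p_(j) n / j`,
#' capped at 1, returned in input order.
#'
#' @param p vector of raw p-values in `[0, 1]` (NA allowed, passed through).
#' @return adjusted values, same order as the input.
#' @export
adjust_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    dx_validation_error("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  n <- length(pv)
  if (n > 0L) {
    o <- order(pv)
    q <- pmin(1, rev(cummin(rev(pv[o] * n / seq_len(n)))))
    out[ok][o] <- q
  }
  out
}

#' Call differential expression at an FDR threshold
#'
#' @param moderated a [ebayes_moderate()] result.
#' @param fdr_threshold FDR cutoff (default 0.05; calls use `fdr <= threshold`).
#' @return data frame of class `de_result`: `gene_id`, `logFC` (dauer vs
#'   exit, positive = up in dauer), `logFC_mix` (dauer vs mix), `t_mod`, `p`,
#'   `fdr`, `call` in `{up, down, ns}`; attributes `summary` (n_up, n_down,
#'   n_total, n_on_array) and `hyper`.
#' @export
call_de <- function(moderated, fdr_threshold = 0.05) {
  tab <- moderated$table
  tab$fdr <- adjust_fdr(tab$p)
  call <- rep("ns", nrow(tab))
  sig <- !is.na(tab$fdr) & tab$fdr <= fdr_threshold
  call[sig & tab$logFC > 0] <- "up"
  call[sig & tab$logFC < 0] <- "down"
  if (any(sig & tab$logFC == 0))
    message(sprintf("call_de: %d significant gene(s) with logFC exactly 0 kept ns",
                    sum(sig & tab$logFC == 0)))
  tab$call <- call
  res <- tab[c("gene_id", "logFC", "logFC_mix", "t_mod", "p", "fdr", "call")]
  structure(res, class = c("de_result", "data.frame"),
            summary = c(n_up = sum(call == "up"), n_down = sum(call == "down"),
                        n_total = sum(call != "ns"), n_on_array = nrow(tab)),
            hyper = moderated$hyper, fdr_threshold = fdr_threshold)
}

#' @export
print.de_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<de_result> %d genes: %d up, %d down (FDR <= %g)\n",
              s[["n_on_array"]], s[["n_up"]], s[["n_down"]],
              attr(x, "fdr_threshold")))
  invisible(x)
}

#' Run the full gene-level DE path for one species
#'
#' [summarize_probes()] -> [fit_gene_model()] -> [ebayes_moderate()] ->
#' [call_de()].
#'
#' @param arrays list of normalized arrays (dauer and exit, one species).
#' @param probes a [probe_annotation()].
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return a `de_result`.
#' @export
run_diffexp <- function(arrays, probes, fdr_threshold = 0.05) {
  ges <- summarize_probes(arrays, probes)
  fits <- fit_gene_model(ges)
  call_de(ebayes_moderate(fits), fdr_threshold = fdr_threshold)
}

#' Write a DE result as TSV
#'
#' Columns: gene_id, logFC_D0_D12, logFC_D0_Mix, t_mod, p, fdr, call.
#'
#' @param de a `de_result`.
#' @param path output path.
#' @export
write_de_result <- function(de, path) {
  out <- data.frame(gene_id = de$gene_id, logFC_D0_D12 = de$logFC,
                    logFC_D0_Mix = de$logFC_mix, t_mod = de$t_mod,
                    p = de$p, fdr = de$fdr, call = de$call)
  dx_write_tsv(out, path)
  invisible(path)
}
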