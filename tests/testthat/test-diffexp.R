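# builds a normalized_array by hand (bypassing scans) for gene-level tests
fake_array <- function(id, condition, M, weight = rep(1, length(M)),
                       probe_ids = names(M), species = "cel") {
  structure(data.frame(probe_id = probe_ids, M = unname(M), A = 10,
                       weight = weight, is_spike = FALSE,
                       expected_spike_logratio = 0, stringsAsFactors = FALSE),
            class = c("normalized_array", "data.frame"),
            array_id = id, species = species, condition = condition,
            dye_orientation = "sample_in_red")
}

fake_probes <- function(probe_ids, gene_ids) {
  probe_annotation(data.frame(probe_id = probe_ids, gene_id = gene_ids,
                              is_spike = FALSE, expected_spike_logratio = NA_real_))
}

# genes x arrays matrix -> gene_expression_set via one probe per gene
ges_from_matrix <- function(M, conditions) {
  arrays <- lapply(seq_len(ncol(M)), function(j)
    fake_array(paste0("a", j), conditions[j],
               setNames(M[, j], rownames(M))))
  summarize_probes(arrays, fake_probes(rownames(M), rownames(M)))
}

test_that("probe summarization takes weighted medians per gene", {
  probes <- fake_probes(c("g1_p1", "g1_p2", "g2_p1", "g2_p2"),
                        c("g1", "g1", "g2", "g2"))
  arr <- fake_array("a1", "dauer", c(g1_p1 = 1, g1_p2 = 3, g2_p1 = 0.5, g2_p2 = 9),
                    weight = c(1, 1, 1, 0))
  ges <- summarize_probes(list(arr), probes)
  expect_equal(ges$M["g1", 1], 2)        # median of {1, 3}
  expect_equal(ges$M["g2", 1], 0.5)      # bad probe ignored
  expect_equal(ges$weights["g2", 1], 1)
  # brute-force oracle on a random fixture
  set.seed(9)
  n_g <- 40; n_p <- 3
  pid <- paste0(rep(paste0("g", 1:n_g), each = n_p), "_p", 1:n_p)
  gid <- rep(paste0("g", 1:n_g), each = n_p)
  m <- setNames(rnorm(n_g * n_p), pid)
  ges2 <- summarize_probes(list(fake_array("a1", "dauer", m)), fake_probes(pid, gid))
  oracle <- tapply(unname(m), gid, median)
  expect_equal(ges2$M[names(oracle), 1],
               setNames(as.vector(oracle), names(oracle)))
})

test_that("the per-gene model matches its closed forms and an OLS oracle", {
  M <- rbind(g1 = c(1, 1, 1, 1, 0, 0, 0, 0))
  ges <- ges_from_matrix(M, rep(c("dauer", "exit"), each = 4))
  fit <- fit_gene_model(ges)
  expect_equal(fit$logFC, 1)
  expect_equal(fit$logFC_mix, 1)
  expect_equal(fit$s2, 0)
  expect_equal(fit$df, 6)
  # unbalanced 3 vs 4 arrays
  M2 <- rbind(g1 = c(1, 2, 3, 0, 0, 1, 1))
  ges2 <- ges_from_matrix(M2, c(rep("dauer", 3), rep("exit", 4)))
  expect_equal(fit_gene_model(ges2)$v, 1 / 3 + 1 / 4)
  # OLS oracle on random data
  set.seed(11)
  M3 <- matrix(rnorm(50 * 8), 50, dimnames = list(paste0("g", 1:50), NULL))
  cond <- rep(c("dauer", "exit"), each = 4)
  fit3 <- fit_gene_model(ges_from_matrix(M3, cond))
  for (i in c(1, 17, 50)) {
    ols <- lm(M3[i, ] ~ 0 + factor(cond))
    row <- match(paste0("g", i), fit3$gene_id)
    expect_equal(fit3$logFC[row], unname(coef(ols)[1] - coef(ols)[2]),
                 tolerance = 1e-10)
    expect_equal(fit3$s2[row], sum(resid(ols)^2) / 6, tolerance = 1e-10)
  }
})

test_that("empirical-Bayes moderation obeys its limits and shrinkage bounds", {
  set.seed(13)
  n <- 2000; dg <- 6
  # homogeneous variances: excess <= 0 -> d0 = Inf, posterior = prior
  s2_hom <- rep(0.05, n) * exp(rnorm(n, 0, 0.01))
  fits <- data.frame(gene_id = paste0("g", 1:n), logFC = rnorm(n),
                     logFC_mix = 0, s2 = s2_hom, df = dg, v = 0.5,
                     estimable = TRUE)
  mod <- ebayes_moderate(fits)
  # (chi-square sampling spread alone exceeds this dispersion, so no excess)
  expect_true(is.infinite(mod$hyper$d0))
  expect_equal(unique(round(mod$table$s2_post, 12)),
               round(mod$hyper$s0_sq, 12))
  # heterogeneous: shrinkage lies between s2 and s0_sq for every gene
  s2_het <- 0.05 * rf(n, dg, 4)
  fits$s2 <- s2_het
  mod2 <- ebayes_moderate(fits)
  s0 <- mod2$hyper$s0_sq
  expect_true(all(mod2$table$s2_post >= pmin(fits$s2, s0) - 1e-12))
  expect_true(all(mod2$table$s2_post <= pmax(fits$s2, s0) + 1e-12))
  # p-values consistent with the stated t distribution
  i <- 7
  tt <- mod2$table
  expect_equal(tt$p[i], 2 * pt(-abs(tt$t_mod[i]), df = mod2$hyper$d0 + dg))
  expect_error(ebayes_moderate(fits[1:10, ]), class = "dauerx_moderation_error")
})

test_that("moderation matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(17)
  n <- 3000; dg <- 5
  s2 <- 0.08 * rf(n, dg, 6)
  fits <- data.frame(gene_id = paste0("g", 1:n), logFC = rnorm(n),
                     logFC_mix = 0, s2 = s2, df = dg, v = 0.5, estimable = TRUE)
  mod <- ebayes_moderate(fits)
  sq <- limma::squeezeVar(s2, df = dg)
  expect_equal(mod$hyper$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$hyper$s0_sq, sq$var.prior, tolerance = 1e-6)
  expect_equal(mod$table$s2_post, sq$var.post, tolerance = 1e-8)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_fdr(0.03), 0.03)
  set.seed(19)
  p <- runif(500)^2
  expect_equal(adjust_fdr(p), p.adjust(p, "BH"))
  expect_true(all(adjust_fdr(p) >= p))
  expect_error(adjust_fdr(c(0.5, 1.2)), class = "dauerx_validation_error")
})

test_that("DE calls respect threshold, sign, and the negation symmetry", {
  set.seed(23)
  M <- matrix(rnorm(300 * 8, 0, 0.3), 300, dimnames = list(paste0("g", 1:300), NULL))
  M[1:30, 1:4] <- M[1:30, 1:4] + 2
  M[31:50, 1:4] <- M[31:50, 1:4] - 2
  cond <- rep(c("dauer", "exit"), each = 4)
  de <- call_de(ebayes_moderate(fit_gene_model(ges_from_matrix(M, cond))))
  expect_true(all(de$fdr >= de$p))
  expect_true(all(de$call[de$fdr <= 0.05 & de$logFC > 0] == "up"))
  expect_true(all(de$call[de$fdr > 0.05] == "ns"))
  s <- attr(de, "summary")
  expect_equal(s[["n_total"]], s[["n_up"]] + s[["n_down"]])
  # negating every M value negates logFC and swaps the up/down counts
  de_neg <- call_de(ebayes_moderate(fit_gene_model(ges_from_matrix(-M, cond))))
  expect_equal(de_neg$logFC, -de$logFC)
  s_neg <- attr(de_neg, "summary")
  expect_equal(s_neg[["n_up"]], s[["n_down"]])
  expect_equal(s_neg[["n_down"]], s[["n_up"]])
})
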