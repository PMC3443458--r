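test_that("normexp parameter estimation is robust and guarded", {
  sp <- tiny_spots(100L)
  sp$bg_red <- 100; sp$fg_red <- 300
  p <- estimate_normexp(tiny_scan(spots = sp), "red")
  expect_equal(p$mu, 100)
  expect_equal(p$sigma, 1e-6 * 100)   # MAD floor on constant background
  expect_equal(p$alpha, 200)

  set.seed(5)
  n <- 1e4
  sp <- tiny_spots(n)
  sp$bg_green <- rnorm(n, 100, 10)
  sp$fg_green <- sp$bg_green + rexp(n, 1 / 300)
  p <- estimate_normexp(tiny_scan(spots = sp), "green")
  expect_equal(p$mu, 100, tolerance = 1 / 100)
  expect_equal(p$sigma, 10, tolerance = 1 / 10)
  expect_equal(p$alpha, 300, tolerance = 0.05)

  sp <- tiny_spots(40L); sp$flag <- c("ok", rep("bad", 39L))
  expect_error(estimate_normexp(tiny_scan(spots = sp), "red"),
               class = "dauerx_estimation_error")
})

test_that("normexp correction matches quadrature, its limits, and stays stable", {
  # sigma -> 0 limit: correction tends to x - mu
  expect_equal(normexp_correct(150, normexp_params(100, 1e-4, 200)), 50,
               tolerance = 1e-6)
  # quadrature oracle across a grid of (x, mu, sigma, alpha)
  grid <- expand.grid(x = c(50, 90, 100, 120, 150, 300, 1000, 5000),
                      mu = c(80, 100), sigma = c(5, 20), alpha = c(100, 500))
  mine <- mapply(function(x, mu, s, a)
    normexp_correct(x, normexp_params(mu, s, a)),
    grid$x, grid$mu, grid$sigma, grid$alpha)
  oracle <- mapply(normexp_quadrature, grid$x, grid$mu, grid$sigma, grid$alpha)
  expect_equal(mine, oracle, tolerance = 1e-6)
  # deep left tail: positive, finite, no overflow
  p <- normexp_params(100, 10, 200)
  lo <- normexp_correct(100 - 10 * 10, p)
  expect_true(is.finite(lo) && lo > 0)
  # strictly monotone in x
  xs <- seq(-200, 5000, by = 0.5)
  expect_true(all(diff(normexp_correct(xs, p)) > 0))
  expect_error(normexp_correct(NaN, p), class = "dauerx_validation_error")
})

test_that("normexp correction agrees with the reference implementation", {
  skip_if_not_installed("limma")
  x <- c(1, 50, 100, 150, 500, 1e4)
  mine <- normexp_correct(x, normexp_params(100, 10, 200))
  ref <- limma::normexp.signal(c(100, log(10), log(200)), x)
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("M/A computation honours the dye-orientation sign convention", {
  # near-zero background so corrected intensity ~ fg - mu
  sp <- tiny_spots(60L)
  sp$bg_red <- 0; sp$bg_green <- 0
  sp$fg_red <- 400; sp$fg_green <- 100
  prm <- normexp_params(mu = 1e-9, sigma = 1e-9, alpha = 1e6)
  scan_red <- tiny_scan(spots = sp, dye_orientation = "sample_in_red")
  scan_green <- tiny_scan(spots = sp, dye_orientation = "sample_in_green")
  arr_red <- compute_ma(scan_red, prm, prm)
  arr_green <- compute_ma(scan_green, prm, prm)
  expect_equal(arr_red$M, rep(2, 60), tolerance = 1e-6)    # R = 4 G
  expect_equal(arr_green$M, rep(-2, 60), tolerance = 1e-6) # sample in green
  expect_equal(arr_red$A, arr_green$A)                     # A dye-invariant
  sp$fg_green <- sp$fg_red
  arr0 <- compute_ma(tiny_scan(spots = sp), prm, prm)
  expect_equal(arr0$M, rep(0, 60), tolerance = 1e-9)
  # bad spots get weight 0
  sp$flag[3] <- "bad"
  expect_equal(compute_ma(tiny_scan(spots = sp), prm, prm)$weight[3], 0)
})

test_that("spike-anchored loess recovers a planted dye bias at f = 1", {
  # DE-free world so the residual measures dye-bias removal alone; E[M|A] is
  # estimated by pooling all 8 replicate arrays (per-array decile means are
  # dominated by estimator variance at this scale)
  cfg <- synthetic_study_config(
    n_genes_per_species = 2000L, n_orthologs = 600L, repression_factor = 1,
    class_counts = c(class1_up = 0L, class1_down = 0L, class2 = 0L,
                     cel_only = 0L, ppa_only = 0L),
    n_specific_de = 0L, n_domains = 1L, domain_members = 1L, n_pioneers = 0L,
    dye_bias_coefficients = c(-1.7, 0.5, -0.03), seed = 21L)
  truth <- generate_truth(cfg)
  sc <- generate_scans(truth, cfg)
  g <- truth$genes
  nulls <- g$gene_id[g$species == "cel" & g$de_label == "null"]
  Ms <- c(); As <- c()
  for (scan in Filter(function(s) s$species == "cel", sc$scans)) {
    arr <- normalize_scan(scan, sc$probes)
    idx <- !arr$is_spike & probe_gene(arr$probe_id) %in% nulls & arr$weight > 0
    Ms <- c(Ms, arr$M[idx]); As <- c(As, arr$A[idx])
  }
  expect_equal(median(Ms), 0, tolerance = 0.05)
  dec <- cut(As, quantile(As, 0:10 / 10), include.lowest = TRUE)
  r <- tapply(Ms, dec, mean)
  # interior deciles meet the 0.05 contract; the extreme deciles suffer the
  # known errors-in-variables edge compression of loess normalization (gene
  # abundances end at the range boundary while spikes extend past it) and
  # are bounded at 0.1
  expect_lt(max(abs(r[2:9])), 0.05)
  expect_lt(max(abs(r[c(1, 10)])), 0.1)
})

test_that("spike guards fire on degenerate inputs", {
  sp <- tiny_spots(200L)
  set.seed(8)
  sp$fg_red <- rexp(200, 1 / 500) + rnorm(200, 100, 10)
  sp$fg_green <- rexp(200, 1 / 500) + rnorm(200, 100, 10)
  scan <- tiny_scan(spots = sp)
  probes <- probe_annotation(data.frame(
    probe_id = sp$probe_id, gene_id = paste0("g", seq_len(200)),
    is_spike = c(rep(TRUE, 5), rep(FALSE, 195)),
    expected_spike_logratio = c(rep(0, 5), rep(NA, 195))))
  expect_error(normalize_scan(scan, probes), class = "dauerx_spike_error")
  # spikes clumped in a corner of the A range -> warning + anchor-only
  probes2 <- probes
  probes2$is_spike <- FALSE; probes2$gene_id <- paste0("g", seq_len(200))
  ord <- order(sp$fg_red + sp$fg_green)
  probes2$is_spike[ord[1:12]] <- TRUE
  probes2$expected_spike_logratio[ord[1:12]] <- 0
  probes2$gene_id[ord[1:12]] <- ""
  expect_warning(normalize_scan(scan, probe_annotation(probes2)),
                 "span")
})
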