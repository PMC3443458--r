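# Shared fixtures and independent oracles. Oracles deliberately use
# different algorithms (enumeration, brute force, quadrature) from the
# implementation paths they check.

# small well-formed scan spot table
tiny_spots <- function(n = 3L) {
  data.frame(probe_id = sprintf("p%02d", seq_len(n)),
             fg_red = 200 + seq_len(n), bg_red = rep(100, n),
             fg_green = 300 + seq_len(n), bg_green = rep(100, n),
             flag = rep("ok", n), stringsAsFactors = FALSE)
}

tiny_scan <- function(n = 3L, ...) {
  args <- list(array_id = "arr1", species = "cel", condition = "dauer",
               dye_orientation = "sample_in_red", spots = tiny_spots(n))
  args[names(list(...))] <- list(...)
  do.call(two_color_scan, args)
}

# memoized default synthetic study, shared by the heavier tests
.study_cache <- new.env(parent = emptyenv())
default_study <- function(seed = 7L) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- generate_study(synthetic_study_config(seed = seed))
  .study_cache[[key]]
}

# a reduced config for fast pipeline runs
small_config <- function(seed = 3L) {
  synthetic_study_config(
    n_genes_per_species = 400L, n_orthologs = 200L,
    class_counts = c(class1_up = 10L, class1_down = 10L, class2 = 10L,
                     cel_only = 30L, ppa_only = 40L),
    n_specific_de = 40L, n_domains = 10L, domain_members = 5L,
    n_pioneers = 60L, n_weak_orthologs = 5L, n_off_array_pairs = 5L,
    seed = seed)
}

# hypergeometric upper tail P[X >= a] by log-factorial enumeration
# (2x2 table with margins fixed: a+b draws, a+c successes, N total)
hyper_upper_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  js <- max(0, n - (N - K)):min(n, K)
  logp <- lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)
  sum(exp(logp[js >= a]))
}

# exhaustive two-sample KS statistic from the two ECDFs
ks_D_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), 0)
  Fy <- vapply(grid, function(g) mean(y <= g), 0)
  max(abs(Fx - Fy))
}

# brute-force best hit per query over a hit table (independent of best_hits)
best_hits_oracle <- function(hits, min_bits = 50) {
  out <- character()
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q & hits$bit_score >= min_bits &
                hits$subject_id != q, , drop = FALSE]
    if (nrow(h) == 0L) next
    best <- NULL
    for (s in unique(h$subject_id)) {
      hs <- h[h$subject_id == s, ]
      cand <- list(subject = s, bits = max(hs$bit_score), e = min(hs$e_value))
      if (is.null(best) || cand$bits > best$bits ||
          (cand$bits == best$bits && cand$e < best$e) ||
          (cand$bits == best$bits && cand$e == best$e && cand$subject < best$subject))
        best <- cand
    }
    out[q] <- best$subject
  }
  out
}

# transitive-closure oracle by repeated one-step expansion of parent edges
closure_oracle <- function(parents, start) {
  seen <- character()
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)), seen)
    seen <- c(seen, frontier)
    frontier <- nxt
  }
  sort(unique(seen))
}

# numerical quadrature oracle for E[S | X = x] under the normexp model
normexp_quadrature <- function(x, mu, sigma, alpha) {
  mus <- x - mu - sigma^2 / alpha
  lo <- max(0, mus - 12 * sigma)
  hi <- max(0, mus) + 12 * sigma
  f <- function(s) exp(stats::dnorm(x - s, mu, sigma, log = TRUE) - s / alpha)
  num <- stats::integrate(function(s) s * f(s), lo, hi, rel.tol = 1e-12)$value
  den <- stats::integrate(f, lo, hi, rel.tol = 1e-12)$value
  num / den
}

# strip probe suffix -> gene id
probe_gene <- function(probe_id) sub("_p[0-9]+$", "", probe_id)
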