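# Synthetic two-species dauer study with known ground truth. The generator
# states a world with the statistical structure the pipeline assumes: a
# global mRNA-fraction repression in the dauer branch that only spike-ins can
# reveal, intensity-dependent dye bias, normexp-compatible noise (truncated
# normal background plus multiplicative-lognormal signal), a planted
# cross-species ortholog class structure, decoy-laden similarity searches,
# and planted enrichments in every annotation layer.
#
# Modelling note on the repression factor f: f is the mRNA fraction of total
# RNA in the dauer branch relative to the mixed-stage reference. Spike-ins
# are added in proportion to total RNA, so gene channels are scaled by f
# while spikes are not; a spike-anchored normalization therefore shows every
# null gene at M = log2(f) against the reference. f is applied to both the
# dauer and the 12-h exit samples (the mRNA fraction has not yet recovered at
# that point), which keeps the dauer-vs-exit contrast centred so the planted
# per-gene effects are exactly the dauer-vs-exit truth.

#' Configuration for a synthetic two-species study
#'
#' Defaults state the simulated world; they are not tuning knobs. Sizes are
#' desk-scale (2000 genes/species) while keeping the design of the emulated
#' experiment: two conditions against a mixed-stage common reference, four
#' replicates per contrast including a pair of dye swaps, ~40 spike-ins
#' spaced log-uniformly across the intensity range.
#'
#' @param n_genes_per_species genes per species (default 2000).
#' @param n_orthologs 1:1 ortholog pairs among them (default 600).
#' @param probes_per_gene probes per gene (default 2).
#' @param n_spikes distinct spike-in concentration levels (default 40).
#' @param spike_replicates replicate probes per spike level (default 2;
#'   commercial spike-in probe sets are replicated on the array, and the 80
#'   spike spots balance the loess weight of spikes against the gene spots).
#' @param replicates_per_contrast arrays per condition, half per dye
#'   orientation (default 4).
#' @param repression_factor mRNA fraction f in (0, 1] of dauer-branch samples
#'   relative to the reference (default 0.5: "reduced to about half").
#' @param class_counts named counts `class1_up`, `class1_down`, `class2`,
#'   `cel_only`, `ppa_only` of planted ortholog classes; must sum to at most
#'   `n_orthologs`.
#' @param effect_size mean |log2 fold change| of planted DE genes (default
#'   1.5).
#' @param effect_jitter_sd s.d. of the per-gene effect-size jitter (default
#'   0.3; magnitudes floored at 0.4).
#' @param cross_species_fc_correlation copula correlation of effect sizes
#'   within class 1/2 pairs (default 0.8).
#' @param dye_bias_coefficients polynomial coefficients `(c0, c1, c2)` of the
#'   log2 dye bias in A (default gives a smooth +-0.3 trend over the A range).
#' @param bg_mu,bg_sigma background mean and s.d. (linear units; defaults
#'   100, 15).
#' @param log_sd multiplicative signal noise, s.d. of the natural-log factor
#'   (default 0.2, i.e. ~20% coefficient of variation per channel).
#' @param log2_abundance_range range of per-gene log2 base abundance
#'   (default c(8, 14), clear of the ~100-unit background).
#' @param bad_spot_rate fraction of spots flagged bad (default 0.01).
#' @param n_specific_de species-specific (non-ortholog) DE genes per species
#'   (default 100, half up).
#' @param n_weak_orthologs intended pairs scored below the 50-bit cutoff, so
#'   unrecoverable by reciprocal best hits (default 10).
#' @param n_off_array_pairs null pairs whose species-B gene is left off the
#'   array (default 10).
#' @param n_domains,domain_members PFAM-style families built from dedicated
#'   non-ortholog genes (defaults 40 families of 6 members per species).
#' @param pfam_concordance cross-species correlation of family effects
#'   (default 0.5).
#' @param n_pioneers species-B pioneer genes (default 150).
#' @param pioneer_shift mean log2 fold-change shift of pioneer genes
#'   (default 0.9; they sit higher in dauer).
#' @param go_fold_enrichment fold enrichment of the planted GO term in the
#'   class-1 study set (default 10).
#' @param go_term_size annotated size of the planted term (default 20).
#' @param seed integer random seed.
#' @return list of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_genes_per_species = 2000L,
                                   n_orthologs = 600L,
                                   probes_per_gene = 2L,
                                   n_spikes = 40L,
                                   spike_replicates = 2L,
                                   replicates_per_contrast = 4L,
                                   repression_factor = 0.5,
                                   class_counts = c(class1_up = 25L, class1_down = 25L,
                                                    class2 = 30L, cel_only = 60L,
                                                    ppa_only = 120L),
                                   effect_size = 1.5,
                                   effect_jitter_sd = 0.3,
                                   cross_species_fc_correlation = 0.8,
                                   dye_bias_coefficients = c(-1.7, 0.5, -0.03),
                                   bg_mu = 100, bg_sigma = 15, log_sd = 0.2,
                                   log2_abundance_range = c(8, 14),
                                   bad_spot_rate = 0.01,
                                   n_specific_de = 100L,
                                   n_weak_orthologs = 10L,
                                   n_off_array_pairs = 10L,
                                   n_domains = 40L, domain_members = 6L,
                                   pfam_concordance = 0.5,
                                   n_pioneers = 150L, pioneer_shift = 0.9,
                                   go_fold_enrichment = 10,
                                   go_term_size = 20L,
                                   seed = 1L) {
  cfg <- as.list(environment())
  need <- c("class1_up", "class1_down", "class2", "cel_only", "ppa_only")
  if (!all(need %in% names(cfg$class_counts)))
    dx_error("class_counts must name class1_up, class1_down, class2, cel_only, ppa_only",
             "dauerx_config_error")
  if (sum(cfg$class_counts) > cfg$n_orthologs)
    dx_error("class counts exceed n_orthologs", "dauerx_config_error")
  if (cfg$repression_factor <= 0 || cfg$repression_factor > 1)
    dx_error("repression_factor must lie in (0, 1]", "dauerx_config_error")
  counts <- c(cfg$n_genes_per_species, cfg$n_orthologs, cfg$probes_per_gene,
              cfg$n_spikes, cfg$spike_replicates, cfg$replicates_per_contrast)
  if (any(counts <= 0)) dx_error("all counts must be positive", "dauerx_config_error")
  n_free <- cfg$n_genes_per_species - cfg$n_orthologs
  if (cfg$n_domains * cfg$domain_members + cfg$n_pioneers + cfg$n_specific_de > n_free)
    dx_error("family + pioneer + specific-DE blocks exceed the non-ortholog gene count",
             "dauerx_config_error")
  if (cfg$replicates_per_contrast %% 2L != 0L)
    dx_error("replicates_per_contrast must be even (paired dye swaps)",
             "dauerx_config_error")
  structure(cfg, class = "synthetic_study_config")
}

# truncated-at-zero normal draws
rtnorm0 <- function(n, mu, sigma) pmax(stats::rnorm(n, mu, sigma), 0)

# bivariate standard normal with correlation rho
rbvn <- function(n, rho) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}

#' Generate the ground truth of a synthetic study
#'
#' Assigns gene ids, base abundances, planted dauer-vs-exit effects, ortholog
#' classes, family/pioneer/specific blocks, and per-pair recoverability
#' flags. Consumes `config$seed`; everything downstream is deterministic
#' given the truth.
#'
#' @param config a [synthetic_study_config()].
#' @return list of class `study_truth` with `genes` (per-gene data frame),
#'   `pairs` (per-ortholog-pair data frame), `domain_effects`, `planted`, and
#'   the config.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  set.seed(config$seed)
  cc <- config$class_counts
  n <- config$n_genes_per_species
  no <- config$n_orthologs
  ids <- function(sp) sprintf("%s_g%05d", sp, seq_len(n))
  cel <- ids("cel"); ppa <- ids("ppa")

  mk_genes <- function(gid, sp) {
    data.frame(gene_id = gid, species = sp,
               base = 2^stats::runif(n, config$log2_abundance_range[1L],
                                     config$log2_abundance_range[2L]),
               delta = 0, role = "null", on_array = TRUE,
               stringsAsFactors = FALSE)
  }
  ga <- mk_genes(cel, "cel"); gb <- mk_genes(ppa, "ppa")

  mag <- function(z) pmax(config$effect_size + config$effect_jitter_sd * z, 0.4)
  rho <- config$cross_species_fc_correlation
  i <- 0L
  take <- function(k) { out <- i + seq_len(k); i <<- i + k; out }
  cls <- rep("none", no)

  idx <- take(cc[["class1_up"]])
  z <- rbvn(length(idx), rho)
  ga$delta[idx] <- mag(z[, 1L]); gb$delta[idx] <- mag(z[, 2L])
  cls[idx] <- "1"
  idx <- take(cc[["class1_down"]])
  z <- rbvn(length(idx), rho)
  ga$delta[idx] <- -mag(z[, 1L]); gb$delta[idx] <- -mag(z[, 2L])
  cls[idx] <- "1"
  idx <- take(cc[["class2"]])
  z <- rbvn(length(idx), rho)
  s <- sample(c(-1, 1), length(idx), replace = TRUE)
  ga$delta[idx] <- s * mag(z[, 1L]); gb$delta[idx] <- -s * mag(z[, 2L])
  cls[idx] <- "2"
  idx <- take(cc[["cel_only"]])
  s <- rep_len(c(1, -1), length(idx))
  ga$delta[idx] <- s * mag(stats::rnorm(length(idx)))
  cls[idx] <- "3"
  idx <- take(cc[["ppa_only"]])
  s <- rep_len(c(1, 1, -1), length(idx)) # ppa skews up, like the emulated study
  gb$delta[idx] <- s * mag(stats::rnorm(length(idx)))
  cls[idx] <- "4"
  ga$role[seq_len(i)] <- paste0("class", cls[seq_len(i)])
  gb$role[seq_len(i)] <- paste0("class", cls[seq_len(i)])

  # non-ortholog blocks: families, pioneers (ppa), species-specific DE
  free_a <- (no + 1L):n
  free_b <- (no + 1L):n
  nfam <- config$n_domains * config$domain_members
  fam_a <- free_a[seq_len(nfam)]; free_a <- setdiff(free_a, fam_a)
  fam_b <- free_b[seq_len(nfam)]; free_b <- setdiff(free_b, fam_b)
  tau <- 1.2
  u <- stats::rnorm(config$n_domains, 0, tau * sqrt(config$pfam_concordance))
  e_sd <- tau * sqrt(1 - config$pfam_concordance)
  v_a <- u + stats::rnorm(config$n_domains, 0, e_sd)
  v_b <- u + stats::rnorm(config$n_domains, 0, e_sd)
  dom_of <- rep(seq_len(config$n_domains), each = config$domain_members)
  ga$delta[fam_a] <- v_a[dom_of] + stats::rnorm(nfam, 0, 0.3)
  gb$delta[fam_b] <- v_b[dom_of] + stats::rnorm(nfam, 0, 0.3)
  ga$role[fam_a] <- sprintf("family_PF%05d", dom_of)
  gb$role[fam_b] <- sprintf("family_PF%05d", dom_of)

  pio_b <- free_b[seq_len(config$n_pioneers)]
  free_b <- setdiff(free_b, pio_b)
  gb$delta[pio_b] <- stats::rnorm(config$n_pioneers, config$pioneer_shift, 0.5)
  gb$role[pio_b] <- "pioneer"

  spec_a <- free_a[seq_len(config$n_specific_de)]
  spec_b <- free_b[seq_len(config$n_specific_de)]
  sgn <- rep_len(c(1, -1), config$n_specific_de)
  ga$delta[spec_a] <- sgn * mag(stats::rnorm(config$n_specific_de))
  gb$delta[spec_b] <- sgn * mag(stats::rnorm(config$n_specific_de))
  ga$role[spec_a] <- "specific"; gb$role[spec_b] <- "specific"

  label <- function(d) ifelse(d > 0, "up", ifelse(d < 0, "down", "null"))
  f <- config$repression_factor
  finish <- function(g) {
    g$de_label <- label(g$delta)
    g$true_logfc_dauer_vs_exit <- g$delta
    g$true_logfc_dauer_vs_mix <- g$delta + log2(f)
    g
  }
  ga <- finish(ga); gb <- finish(gb)

  pairs <- data.frame(gene_a = cel[seq_len(no)], gene_b = ppa[seq_len(no)],
                      class_label = cls, stringsAsFactors = FALSE)
  null_pairs <- which(cls == "none")
  weak <- sort(sample(null_pairs, config$n_weak_orthologs))
  off <- sort(sample(setdiff(null_pairs, weak), config$n_off_array_pairs))
  pairs$rbh_recoverable <- !(seq_len(no) %in% weak)
  gb$on_array[off] <- FALSE
  pairs$on_array_both <- ga$on_array[seq_len(no)] & gb$on_array[seq_len(no)]

  structure(list(genes = rbind(ga, gb), pairs = pairs,
                 domain_effects = data.frame(domain_id = sprintf("PF%05d",
                                                                 seq_len(config$n_domains)),
                                             effect_a = v_a, effect_b = v_b),
                 planted = list(go_term = "GO:0000100", cluster = "CL_planted",
                                pathway = "PW_repressed"),
                 config = config),
            class = "study_truth")
}

#' Generate directional hit tables exercising the reciprocal-best-hit filter
#'
#' Every intended ortholog pair is a mutual best hit with bit score >= 50,
#' except the configured weak pairs which score 45 bits in both directions
#' (below the cutoff, so unrecoverable). Decoy second-best hits (20 bits
#' lower), sub-threshold hits (30 bits) and duplicate lower-scoring HSPs are
#' injected around them.
#'
#' @param truth a [generate_truth()] result.
#' @param config the same [synthetic_study_config()].
#' @return list of two [hit_table()]s, `ab` (cel query) and `ba`.
#' @export
generate_hit_tables <- function(truth, config = truth$config) {
  set.seed(dx_child_seed(config$seed, 1L))
  p <- truth$pairs
  no <- nrow(p)
  bits <- ifelse(p$rbh_recoverable, 100 + stats::runif(no, 0, 200), 45)
  ev <- 2^(-bits)
  q_ab <- p$gene_a; s_ab <- p$gene_b
  q_ba <- p$gene_b; s_ba <- p$gene_a
  b_ab <- bits; b_ba <- bits
  e_ab <- ev; e_ba <- ev
  add <- function(side, q, s, b) {
    b <- rep_len(b, length(q))
    if (side == "ab") {
      q_ab <<- c(q_ab, q); s_ab <<- c(s_ab, s); b_ab <<- c(b_ab, b)
      e_ab <<- c(e_ab, 2^(-b))
    } else {
      q_ba <<- c(q_ba, q); s_ba <<- c(s_ba, s); b_ba <<- c(b_ba, b)
      e_ba <<- c(e_ba, 2^(-b))
    }
  }
  dec <- which(seq_len(no) %% 5L == 0L & p$rbh_recoverable)  # decoy second-best
  other <- p$gene_b[(match(dec, seq_len(no)) %% no) + 1L]
  add("ab", p$gene_a[dec], other, pmax(bits[dec] - 20, 50))
  sub <- which(seq_len(no) %% 7L == 0L)                      # sub-threshold noise
  add("ab", p$gene_a[sub], p$gene_b[(sub %% no) + 1L], 30)
  add("ba", p$gene_b[sub], p$gene_a[(sub %% no) + 1L], 30)
  hsp <- which(seq_len(no) %% 10L == 0L & p$rbh_recoverable) # duplicate HSPs
  add("ab", p$gene_a[hsp], p$gene_b[hsp], bits[hsp] * 0.6)
  add("ba", p$gene_b[hsp], p$gene_a[hsp], bits[hsp] * 0.6)
  list(ab = hit_table(q_ab, s_ab, b_ab, e_ab),
       ba = hit_table(q_ba, s_ba, b_ba, e_ba))
}

#' Generate the annotation bundle with planted enrichments
#'
#' Builds a small GO-like DAG (one root, 5 mid-level terms, 24 leaves) over
#' the species-A ortholog genes, expression clusters, PFAM families on the
#' dedicated family genes, KEGG-style pathways, and the pioneer-gene set.
#' Planted structures: the configured GO term enriched in the class-1 set at
#' `go_fold_enrichment`; one cluster drawn from species-A-only up genes (so
#' it lights up only the cel_dauer column); one pathway drawn largely from
#' species-B-only down pairs (a pathway repressed only in species B).
#'
#' @param truth a [generate_truth()] result.
#' @param config the same [synthetic_study_config()].
#' @return an [annotation_bundle()].
#' @export
generate_annotation_bundle <- function(truth, config = truth$config) {
  set.seed(dx_child_seed(config$seed, 2L))
  p <- truth$pairs
  ga <- truth$genes[truth$genes$species == "cel", ]
  gb <- truth$genes[truth$genes$species == "ppa", ]
  orth_a <- p$gene_a

  # ontology: root <- 5 mids <- 24 leaves
  mids <- sprintf("GO:%07d", 10:14)
  leaves <- sprintf("GO:%07d", 100:123)
  terms <- data.frame(id = c("GO:0000001", mids, leaves),
                      name = c("biological_process", paste0("mid_", 1:5),
                               paste0("leaf_", seq_along(leaves))),
                      namespace = "biological_process", stringsAsFactors = FALSE)
  parents <- c(list("GO:0000001" = character()),
               stats::setNames(rep(list("GO:0000001"), 5), mids),
               stats::setNames(as.list(mids[rep_len(1:5, length(leaves))]), leaves))
  ontology <- structure(list(terms = terms, parents = parents), class = "ontology")

  # background annotation: every ortholog cel gene gets 1-3 random leaves
  # (excluding the planted term, whose membership is controlled below)
  open_leaves <- setdiff(leaves, truth$planted$go_term)
  gene2term <- lapply(stats::setNames(orth_a, orth_a), function(g)
    sample(open_leaves, sample(1:3, 1)))
  class1_a <- p$gene_a[p$class_label == "1"]
  n_bg <- length(orth_a)
  target <- round(config$go_fold_enrichment * config$go_term_size *
                    length(class1_a) / n_bg)
  n_in <- min(target, config$go_term_size, length(class1_a))
  members <- c(sample(class1_a, n_in),
               sample(setdiff(orth_a, class1_a), config$go_term_size - n_in))
  for (g in members) gene2term[[g]] <- c(gene2term[[g]], truth$planted$go_term)

  # clusters: 10 random + 1 planted from cel-only up genes
  clusters <- lapply(stats::setNames(sprintf("CL%02d", 1:10), sprintf("CL%02d", 1:10)),
                     function(cl) sample(orth_a, 25))
  cel_only_up <- p$gene_a[p$class_label == "3" &
                            ga$delta[match(p$gene_a, ga$gene_id)] > 0]
  null_a <- p$gene_a[p$class_label == "none"]
  clusters[[truth$planted$cluster]] <- c(sample(cel_only_up, 15), sample(null_a, 10))

  # PFAM families from the dedicated family blocks; ~10% of family genes
  # carry a second random domain so families overlap
  fam <- truth$genes[startsWith(truth$genes$role, "family_"), ]
  gene2domain <- stats::setNames(as.list(sub("^family_", "", fam$role)), fam$gene_id)
  extra <- sample(fam$gene_id, ceiling(nrow(fam) * 0.1))
  all_dom <- sprintf("PF%05d", seq_len(config$n_domains))
  for (g in extra) gene2domain[[g]] <- unique(c(gene2domain[[g]], sample(all_dom, 1)))

  # pathways: 8 random + 1 planted repressed-in-B
  pathway2gene <- lapply(stats::setNames(sprintf("PW%02d", 1:8), sprintf("PW%02d", 1:8)),
                         function(pw) sample(orth_a, 20))
  ppa_down_pairs <- p$gene_a[p$class_label == "4" &
                               gb$delta[match(p$gene_b, gb$gene_id)] < 0]
  pathway2gene[[truth$planted$pathway]] <- c(sample(ppa_down_pairs, 12),
                                             sample(null_a, 8))

  pioneers <- truth$genes$gene_id[truth$genes$role == "pioneer"]
  annotation_bundle(ontology, gene2term, clusters, gene2domain, pathway2gene,
                    pioneers)
}

# polynomial dye bias in A
dye_bias <- function(a, coefs) {
  out <- 0
  for (k in seq_along(coefs)) out <- out + coefs[k] * a^(k - 1L)
  out
}

#' Generate the two-color scans of a synthetic study
#'
#' Per spot: channel intensity = truncated-normal background + signal, with
#' signal = abundance x 2^(+-dye_bias(A)/2) x lognormal noise. Gene sample
#' channels are scaled by the repression factor f; spikes are not (they are
#' added in proportion to total RNA), which is what makes the global
#' repression identifiable. Dye-swap arrays have the channels exchanged.
#'
#' @param truth a [generate_truth()] result.
#' @param config the same [synthetic_study_config()].
#' @return list with `scans` (list of [two_color_scan()]) and `probes`
#'   (a [probe_annotation()], shared across species).
#' @export
generate_scans <- function(truth, config = truth$config) {
  set.seed(dx_child_seed(config$seed, 3L))
  f <- config$repression_factor
  lvl <- rep(seq_len(config$n_spikes), each = config$spike_replicates)
  spike_ids <- sprintf("SPIKE_%02d_r%d", lvl,
                       rep(seq_len(config$spike_replicates), config$n_spikes))
  spike_base_lvl <- 2^seq(config$log2_abundance_range[1L] - 0.5,
                          config$log2_abundance_range[2L] + 0.5,
                          length.out = config$n_spikes)
  spike_base <- spike_base_lvl[lvl]
  probes_of <- function(g) {
    gene_probe_ids <- paste0(rep(g$gene_id, each = config$probes_per_gene), "_p",
                             seq_len(config$probes_per_gene))
    data.frame(probe_id = c(gene_probe_ids, spike_ids),
                  gene_id = c(rep(g$gene_id, each = config$probes_per_gene),
                           rep("", length(spike_ids))),
               is_spike = c(rep(FALSE, length(gene_probe_ids)),
                            rep(TRUE, length(spike_ids))),
               expected_spike_logratio = c(rep(NA_real_, length(gene_probe_ids)),
                                           rep(0, length(spike_ids))),
               stringsAsFactors = FALSE)
  }
  scans <- list()
  probes_all <- list()
  for (sp in c("cel", "ppa")) {
    g <- truth$genes[truth$genes$species == sp & truth$genes$on_array, ]
    pr <- probes_of(g)
    probes_all[[sp]] <- pr
    n_probe <- nrow(pr)
    gi <- match(pr$gene_id, g$gene_id) # NA for spikes
    base <- ifelse(pr$is_spike, spike_base[match(pr$probe_id, spike_ids)], g$base[gi])
    for (cond in c("dauer", "exit")) {
      delta <- if (cond == "dauer") ifelse(pr$is_spike, 0, g$delta[gi]) else 0
      a_sample <- base * 2^delta * ifelse(pr$is_spike, 1, f)
      a_ref <- base
      a0 <- (log2(a_sample) + log2(a_ref)) / 2
      bias <- dye_bias(a0, config$dye_bias_coefficients)
      for (r in seq_len(config$replicates_per_contrast)) {
        orient <- if (r %% 2L == 1L) "sample_in_red" else "sample_in_green"
        a_red <- if (orient == "sample_in_red") a_sample else a_ref
        a_green <- if (orient == "sample_in_red") a_ref else a_sample
        fg_red <- rtnorm0(n_probe, config$bg_mu, config$bg_sigma) +
          a_red * 2^(bias / 2) * exp(stats::rnorm(n_probe, 0, config$log_sd))
        fg_green <- rtnorm0(n_probe, config$bg_mu, config$bg_sigma) +
          a_green * 2^(-bias / 2) * exp(stats::rnorm(n_probe, 0, config$log_sd))
        flags <- ifelse(stats::runif(n_probe) < config$bad_spot_rate, "bad", "ok")
        scans[[length(scans) + 1L]] <- two_color_scan(
          array_id = sprintf("%s_%s_r%d", sp, cond, r),
          species = sp, condition = cond, dye_orientation = orient,
          spots = data.frame(probe_id = pr$probe_id,
                             fg_red = fg_red,
                             bg_red = rtnorm0(n_probe, config$bg_mu, config$bg_sigma),
                             fg_green = fg_green,
                             bg_green = rtnorm0(n_probe, config$bg_mu, config$bg_sigma),
                             flag = flags, stringsAsFactors = FALSE))
      }
    }
  }
  probes <- do.call(rbind, probes_all)
  probes <- probes[!duplicated(probes$probe_id), ]
  rownames(probes) <- NULL
  list(scans = scans, probes = probe_annotation(probes))
}

#' Generate a complete synthetic study
#'
#' Truth, scans, probe annotation, directional hit tables and the annotation
#' bundle, all reproducible from `config$seed`.
#'
#' @param config a [synthetic_study_config()].
#' @return list of class `synthetic_study` with elements `scans`, `probes`,
#'   `hits_ab`, `hits_ba`, `bundle`, `truth`, `config`.
#' @export
generate_study <- function(config = synthetic_study_config()) {
  truth <- generate_truth(config)
  hits <- generate_hit_tables(truth, config)
  bundle <- generate_annotation_bundle(truth, config)
  sc <- generate_scans(truth, config)
  structure(list(scans = sc$scans, probes = sc$probes,
                 hits_ab = hits$ab, hits_ba = hits$ba,
                 bundle = bundle, truth = truth, config = config),
            class = "synthetic_study")
}

#' Write a synthetic study to disk in the pipeline's file formats
#'
#' Scan TSVs, probe annotation, 12-column hit tables, the annotation bundle
#' directory and a JSON ground-truth sidecar.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "scans"), showWarnings = FALSE, recursive = TRUE)
  for (scan in study$scans)
    write_scan_table(scan, file.path(dir, "scans", paste0(scan$array_id, ".tsv")))
  meta <- data.frame(
    array_id = vapply(study$scans, function(s) s$array_id, ""),
    species = vapply(study$scans, function(s) s$species, ""),
    condition = vapply(study$scans, function(s) s$condition, ""),
    dye_orientation = vapply(study$scans, function(s) s$dye_orientation, ""))
  dx_write_tsv(meta, file.path(dir, "scans", "arrays.tsv"))
  write_probe_annotation(study$probes, file.path(dir, "probes.tsv"))
  write_hit_table(study$hits_ab, file.path(dir, "hits_ab.tsv"))
  write_hit_table(study$hits_ba, file.path(dir, "hits_ba.tsv"))
  write_annotation_bundle(study$bundle, file.path(dir, "bundle"))
  truth <- study$truth
  jsonlite::write_json(list(genes = truth$genes, pairs = truth$pairs,
                            domain_effects = truth$domain_effects,
                            planted = truth$planted),
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
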