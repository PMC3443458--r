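toy_ontology <- function() {
  structure(list(
    terms = data.frame(id = c("root", "A", "B"),
                       name = c("root", "a", "b"),
                       namespace = "bp", stringsAsFactors = FALSE),
    parents = list(root = character(), A = "root", B = "A")),
    class = "ontology")
}

test_that("annotation transfer maps exactly the paired genes", {
  bundle <- annotation_bundle(
    toy_ontology(),
    gene2term = list(a1 = c("B"), a2 = c("A"), a3 = c("root")),
    clusters = list(cl1 = c("a1", "a2"), cl2 = "a3"),
    gene2domain = list(a1 = "PF1"),
    pathway2gene = list(pw1 = c("a1", "a3")),
    pioneer_genes = "x9")
  pairs <- structure(data.frame(gene_a = c("a1", "a3"), gene_b = c("b1", "b3")),
                     class = c("ortholog_pairs", "data.frame"))
  tb <- transfer_annotations(bundle, pairs)
  expect_equal(tb$gene2term, list(a1 = "B", a3 = "root") |>
                 setNames(c("b1", "b3")))
  expect_equal(tb$clusters$cl1, "b1")      # a2 unpaired -> dropped
  expect_equal(tb$pathway2gene$pw1, c("b1", "b3"))
  # transferred sizes equal source sizes restricted to paired genes
  expect_equal(lengths(tb$clusters),
               vapply(bundle$clusters,
                      function(g) length(intersect(g, pairs$gene_a)), 0L))
})

test_that("ancestor propagation equals the reachability oracle", {
  closed <- propagate_to_ancestors(list(g1 = "B", g2 = "root"), toy_ontology())
  expect_setequal(closed$g1, c("B", "A", "root"))
  expect_equal(closed$g2, "root")
  # random DAG: layered parents, closure checked against repeated expansion
  set.seed(53)
  ids <- paste0("t", 1:40)
  parents <- setNames(vector("list", 40), ids)
  for (i in 2:40)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1)], sample(0:2, 1))
  onto <- structure(list(terms = data.frame(id = ids, name = ids, namespace = "bp"),
                         parents = parents), class = "ontology")
  g2t <- list(gA = sample(ids, 3), gB = sample(ids, 1))
  closed2 <- propagate_to_ancestors(g2t, onto)
  for (g in names(g2t))
    expect_setequal(closed2[[g]], closure_oracle(parents, g2t[[g]]))
  # monotonicity: annotated counts never shrink going up the DAG
  study <- default_study()
  closed3 <- propagate_to_ancestors(study$bundle$gene2term, study$bundle$ontology)
  counts <- table(unlist(closed3, use.names = FALSE))
  for (term in names(study$bundle$ontology$parents))
    for (par in study$bundle$ontology$parents[[term]])
      expect_gte(counts[par], counts[term])
})

test_that("term enrichment matches combinatorial oracles", {
  # background of 20, one term of 5, study = exactly those 5
  genes <- paste0("g", 1:20)
  g2t <- lapply(setNames(genes, genes), function(g) "root")
  for (g in genes[1:5]) g2t[[g]] <- c("root", "A")
  res <- term_enrichment(genes[1:5], genes, g2t, min_term_size = 1, p_cutoff = 1)
  expect_equal(res$p[res$term_id == "A"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$significant[res$term_id == "A"], 5L)
  expect_equal(res$expected[res$term_id == "A"], 5 * 5 / 20)
  # a term equal to the whole background is never enriched
  expect_equal(res$p[res$term_id == "root"], 1)
  expect_warning(out <- term_enrichment(character(), genes, g2t), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("null enrichment p-values are approximately uniform", {
  set.seed(59)
  genes <- paste0("g", 1:800)
  terms <- paste0("t", 1:200)
  g2t <- lapply(setNames(genes, genes), function(g) sample(terms, 8))
  study <- sample(genes, 120)
  res <- term_enrichment(study, genes, g2t, p_cutoff = 1)
  expect_gt(suppressWarnings(ks.test(res$p, "punif")$p.value), 0.01)
})

test_that("cluster scores light up only where planted", {
  genes <- paste0("g", 1:200)
  set20 <- genes[1:20]
  clusters <- list(hit = set20, miss = genes[101:120])
  scores <- cluster_enrichment(list(colA = set20, colB = genes[51:70]),
                               clusters, genes)
  expect_gt(scores["hit", "colA"], 10)   # identical set: hypergeometric tail tiny
  expect_equal(scores["hit", "colB"], 0)
  expect_equal(scores["miss", "colA"], 0)
  expect_true(all(scores >= 0))
  # cluster with no background member is skipped with a message
  expect_message(
    s2 <- cluster_enrichment(list(colA = set20),
                             c(clusters, list(ghost = "zzz")), genes),
    "skipping")
  expect_false("ghost" %in% rownames(s2))
})

test_that("PFAM family profiles take medians over qualifying families", {
  de_a <- structure(data.frame(gene_id = paste0("a", 1:9),
                               logFC = c(-1, 0, 1, 2, 3, 5, 5, 5, 5),
                               stringsAsFactors = FALSE),
                    class = c("de_result", "data.frame"))
  de_b <- structure(data.frame(gene_id = paste0("b", 1:9),
                               logFC = rep(1.5, 9), stringsAsFactors = FALSE),
                    class = c("de_result", "data.frame"))
  g2d <- c(lapply(setNames(paste0("a", 1:5), paste0("a", 1:5)), function(g) "PF1"),
           lapply(setNames(paste0("b", 1:5), paste0("b", 1:5)), function(g) "PF1"),
           lapply(setNames(paste0("a", 6:9), paste0("a", 6:9)), function(g) "PF2"),
           lapply(setNames(paste0("b", 6:9), paste0("b", 6:9)), function(g) "PF2"))
  prof <- pfam_family_profile(de_a, de_b, g2d)
  expect_equal(prof$families$domain_id, "PF1")      # PF2 has only 4 members
  expect_equal(prof$families$median_logfc_a, 1)     # median of {-1,0,1,2,3}
  expect_equal(prof$families$median_logfc_b, 1.5)
  expect_true(is.na(prof$pearson_r))                # < 3 qualifying families
})

test_that("planted family concordance is recovered across seeds", {
  # Monte-Carlo recovery of the configured cross-species family correlation,
  # evaluated on the true fold changes (no array noise) for speed
  rs <- vapply(1:20, function(seed) {
    cfg <- small_config(seed = 100L + seed)
    truth <- generate_truth(cfg)
    bundle <- generate_annotation_bundle(truth, cfg)
    mk_de <- function(sp) {
      g <- truth$genes[truth$genes$species == sp, ]
      structure(data.frame(gene_id = g$gene_id, logFC = g$true_logfc_dauer_vs_exit,
                           stringsAsFactors = FALSE),
                class = c("de_result", "data.frame"))
    }
    pfam_family_profile(mk_de("cel"), mk_de("ppa"), bundle$gene2domain)$pearson_r
  }, 0)
  expect_equal(mean(rs), 0.5, tolerance = 0.15)
})

test_that("pathway tabulation counts calls among member orthologs", {
  de_a <- structure(data.frame(gene_id = paste0("a", 1:10),
                               call = c("up", "up", "down", "down", "down",
                                        rep("ns", 5)), stringsAsFactors = FALSE),
                    class = c("de_result", "data.frame"))
  de_b <- structure(data.frame(gene_id = paste0("b", 1:10),
                               call = rep("ns", 10), stringsAsFactors = FALSE),
                    class = c("de_result", "data.frame"))
  pairs <- structure(data.frame(gene_a = paste0("a", 1:10),
                                gene_b = paste0("b", 1:10)),
                     class = c("ortholog_pairs", "data.frame"))
  tab <- kegg_tabulate(de_a, de_b, list(pw = paste0("a", 1:10), empty = character()),
                       pairs)
  expect_equal(unlist(tab[tab$pathway_id == "pw", 2:7], use.names = FALSE),
               c(2, 3, 5, 0, 0, 10))
  expect_equal(unlist(tab[tab$pathway_id == "empty", 2:7], use.names = FALSE),
               rep(0, 6))
})

test_that("the subset shift test matches the exhaustive ECDF computation", {
  lf <- setNames(rep(c(-1, 0, 1), each = 20), paste0("g", 1:60))
  same <- subset_shift_test(lf, paste0("g", seq(1, 60, by = 2)), min_n = 10)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(same$direction, "none")

  set.seed(61)
  x <- rnorm(500); y <- rnorm(500) + 1
  lf2 <- setNames(c(y, x), paste0("g", 1:1000))
  shifted <- subset_shift_test(lf2, paste0("g", 1:500))
  expect_lt(shifted$p, 1e-10)
  expect_equal(shifted$direction, "subset_higher")
  expect_equal(shifted$D, ks_D_oracle(y, x))

  # tiny all-distinct case against the enumeration oracle
  lf3 <- setNames(c(0.1, 0.7, 2.2, -0.5, 0.9, 1.4), paste0("g", 1:6))
  tiny <- subset_shift_test(lf3, paste0("g", 1:3), min_n = 3)
  expect_equal(tiny$D, ks_D_oracle(lf3[1:3], lf3[4:6]))
  expect_error(subset_shift_test(lf3, paste0("g", 1:3), min_n = 20),
               class = "dauerx_validation_error")
})
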