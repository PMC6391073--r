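test_that("protein-group filters remove exactly the planned entries", {
  # constructed 200-protein table with a known pass set of 120
  set.seed(2)
  n <- 200
  groups <- c("g1", "g2", "g3")
  reps <- 4
  samples <- tibble::tibble(
    sample = paste0(rep(groups, each = reps), "_", seq_len(reps)),
    group = rep(groups, each = reps))
  lfq <- matrix(rlnorm(n * nrow(samples), log(1e7), 1), n)
  status <- rep("pass", n)
  status[1:25] <- "contaminant"
  status[26:45] <- "reverse"
  status[46:70] <- "low_peptide"
  status[71:80] <- "all_groups_incomplete"
  for (i in 71:80) {
    lfq[i, ] <- NA
    lfq[i, c(1, 5, 9)] <- 1e7    # one value per group: never complete
  }
  im <- intensity_matrix(
    tibble::tibble(protein_id = sprintf("p%03d", 1:n),
                   peptides = ifelse(status == "low_peptide", 1L, 3L),
                   contaminant = status == "contaminant",
                   reverse = status == "reverse"),
    samples, lfq)
  filt <- filter_protein_groups(im)
  expect_identical(nrow(filt$proteins), 120L)
  expect_setequal(filt$proteins$protein_id,
                  sprintf("p%03d", which(status == "pass")))
  counts <- attr(filt, "filter_counts")
  expect_equal(setNames(counts$removed, counts$rule),
               c(reverse = 20, contaminant = 25, min_peptides = 25,
                 missing_values = 10))
  # the strict reading drops any protein with an incomplete group
  lfq2 <- lfq
  lfq2[81, 1] <- NA           # one missing value in one group
  im2 <- intensity_matrix(im$proteins, samples, lfq2)
  strict <- filter_protein_groups(im2, missing_rule = "complete_in_all_groups")
  lax <- filter_protein_groups(im2)
  expect_true("p081" %in% lax$proteins$protein_id)
  expect_false("p081" %in% strict$proteins$protein_id)
})

test_that("pairwise rank test: degenerate ties, exact enumeration, invariance", {
  expect_identical(pairwise_kw_p(rep(2, 4), rep(2, 5)), 1)
  # exact permutation p equals the exact two-sided Wilcoxon (no ties)
  set.seed(21)
  for (i in 1:6) {
    x <- rnorm(3)
    y <- rnorm(4, mean = runif(1, 0, 2))
    expect_equal(pairwise_kw_p(x, y, exact = TRUE),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # rank test is invariant under strictly monotone transforms
  x <- rlnorm(5); y <- rlnorm(5) * 1.5
  expect_equal(pairwise_kw_p(x, y), pairwise_kw_p(log2(x), log2(y)))
  expect_equal(pairwise_kw_p(x, y, exact = TRUE),
               pairwise_kw_p(x^3, y^3, exact = TRUE))
})

test_that("growth-dependence classification finds planted trends and partitions", {
  set.seed(5)
  sim <- simulate_proteomics(n_proteins = 120, dependent_fraction = 0.5,
                             noise_cv = 0.1, missing_rate = 0, seed = 5)
  calls <- classify_growth_dependence(filter_protein_groups(sim$matrix))
  truth <- sim$truth[match(calls$protein_id, sim$truth$protein_id), ]
  # planted 2-fold monotone trends are detected
  up <- truth$archetype %in% "up_linear"
  expect_true(all(calls$dependent[up]))
  counts <- attr(calls, "counts")
  expect_identical(sum(counts), nrow(calls))
  # constant-profile proteins stay mostly independent (null rate only)
  expect_lt(mean(calls$dependent[!truth$dependent]), 0.5)
  # untestable proteins: fewer than two groups with >= 3 samples
  im <- sim$matrix
  im$lfq[1, im$samples$group != "27.5"] <- NA
  calls2 <- classify_growth_dependence(im)
  expect_identical(calls2$status[1], "untestable")
  expect_true(is.na(calls2$dependent[1]))
})

test_that("elbow picks one cluster for identical profiles", {
  lfq <- matrix(rep(c(1e6, 2e6, 3e6, 2e6, 1e6, 3e6), each = 8), nrow = 8)
  im <- tiny_matrix(lfq = lfq, groups = c("a", "b"), reps = 3,
                    ids = sprintf("p%d", 1:8))
  cl <- cluster_profiles(im)
  expect_identical(cl$k, 1L)
  expect_true(all(tidy(cl)$cluster == 1))
})

test_that("well-separated planted archetypes are recovered by elbow + k-means", {
  # three archetypes, noiseless: exact recovery
  sim3 <- simulate_proteomics(n_proteins = 90, dependent_fraction = 1,
                              noise_cv = 0, missing_rate = 0, seed = 3)
  keep <- sim3$truth$archetype %in% c("up_linear", "down_linear",
                                      "spike_high_light")
  im3 <- cyanogrowth:::im_subset(sim3$matrix, which(keep))
  cl3 <- cluster_profiles(im3)
  expect_identical(cl3$k, 3L)
  truth3 <- sim3$truth$archetype[match(cl3$assignments$protein_id,
                                       sim3$truth$protein_id)]
  expect_equal(mclust::adjustedRandIndex(cl3$assignments$cluster, truth3), 1)
  # centroids equal member means
  g <- glance(cl3)
  expect_identical(g$k, 3L)
  prof <- cl3$profiles
  for (k in 1:3) {
    members <- prof[cl3$assignments$cluster == k, , drop = FALSE]
    cent <- cl3$centroids$value[cl3$centroids$cluster == k]
    expect_equal(unname(colMeans(members)), cent, tolerance = 1e-10)
  }
})

test_that("GO-slim mapping uses set semantics and flags unannotated proteins", {
  ann <- tibble::tibble(
    protein_id = c("p1", "p1", "p2", "p3", "p4"),
    go_id = c("GO:1", "GO:2", "GO:3", "GO:9", "GO:4"))
  slim <- tibble::tibble(
    go_id = c("GO:1", "GO:2", "GO:3", "GO:4"),
    slim = c("translation", "translation", "photosynthesis", "unknown"))
  mapped <- map_go_slim(ann, slim)
  # two GO terms collapsing to one slim category count once
  expect_identical(nrow(mapped[mapped$protein_id == "p1", ]), 1L)
  expect_identical(mapped$slim[mapped$protein_id == "p2"], "photosynthesis")
  expect_identical(attr(mapped, "unmapped_go"), "GO:9")
  # p3 (unmapped term) and p4 (only trivial category) are unannotated
  expect_setequal(attr(mapped, "unannotated"), c("p3", "p4"))
  # three-level fixture: hand-computed category counts
  ann2 <- tibble::tibble(protein_id = rep(sprintf("q%d", 1:6), each = 2),
                         go_id = rep(c("GO:1", "GO:3"), 6))
  counts <- table(map_go_slim(ann2, slim)$slim)
  expect_equal(unname(counts[c("translation", "photosynthesis")]),
               c(6L, 6L), ignore_attr = TRUE)
})

test_that("GO-slim enrichment reproduces the translation table and the null", {
  # translation category: 40/779 dependent vs 13/577 independent
  calls <- tibble::tibble(
    protein_id = sprintf("p%04d", 1:1356),
    dependent = rep(c(TRUE, FALSE), c(779, 577)))
  ann <- tibble::tibble(
    protein_id = c(sprintf("p%04d", 1:40), sprintf("p%04d", 780:792)),
    slim = "translation")
  enr <- enrich_go_slim(calls, ann)
  expect_equal(unlist(enr[1, c("a", "b", "c", "d")]),
               c(a = 40, b = 13, c = 739, d = 564))
  expect_lt(enr$p, 0.05)
  expect_equal(enr$odds_ratio, (40 * 564) / (13 * 739), tolerance = 1e-12)
  expect_equal(enr$odds_ratio, 2.35, tolerance = 2e-3)
  # a perfectly balanced table is null
  calls_b <- tibble::tibble(protein_id = sprintf("b%02d", 1:40),
                            dependent = rep(c(TRUE, FALSE), each = 20))
  ann_b <- tibble::tibble(protein_id = sprintf("b%02d", c(1:10, 21:30)),
                          slim = "x")
  enr_b <- enrich_go_slim(calls_b, ann_b)
  expect_equal(enr_b$p, 1)
  expect_equal(enr_b$odds_ratio, 1)
})

test_that("Fisher p equals direct hypergeometric enumeration on small tables", {
  set.seed(14)
  for (i in 1:10) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    cc <- sample(1:15, 1); d <- sample(1:15, 1)
    p_pkg <- stats::fisher.test(matrix(c(a, b, cc, d), 2))$p.value
    expect_equal(p_pkg, fisher_p_enum(a, b, cc, d), tolerance = 1e-9)
  }
  # invariance under swapping rows and columns simultaneously
  calls <- tibble::tibble(protein_id = sprintf("p%02d", 1:30),
                          dependent = rep(c(TRUE, FALSE), c(12, 18)))
  ann <- tibble::tibble(protein_id = sprintf("p%02d", c(1:5, 13:16)),
                        slim = "term")
  p1 <- enrich_go_slim(calls, ann)$p
  calls2 <- calls
  calls2$dependent <- !calls2$dependent
  ann2 <- tibble::tibble(protein_id = setdiff(calls$protein_id,
                                              ann$protein_id),
                         slim = "term")
  p2 <- enrich_go_slim(calls2, ann2)$p
  expect_equal(p1, p2, tolerance = 1e-12)
})
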