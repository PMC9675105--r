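test_that("precision and recall follow the set arithmetic", {
  expect_equal(precision_recall(c("f1", "f2"), c("f1", "f2")),
               c(precision = 1, recall = 1))
  expect_equal(precision_recall(c("f1"), c("f2")),
               c(precision = 0, recall = 0))
  expect_equal(precision_recall(c("f1", "f2", "f3"), c("f1", "f4")),
               c(precision = 1 / 3, recall = 1 / 2))
  expect_equal(precision_recall(character(0), "f1"),
               c(precision = 0, recall = 0))
  expect_error(precision_recall("f1", character(0)), "empty")
})

test_that("F-measure is the harmonic mean, matching the printed arithmetic", {
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0, 0), 0)
  expect_equal(round(f_measure(0.504, 0.523), 3), 0.513)
  expect_equal(round(f_measure(0.584, 0.604), 3), 0.594)
})

test_that("leave-one-out on zero-noise planted data is perfect", {
  ds <- generate_dataset(synthetic_config(
    p_intra = 1, p_background = 0, domain_leakage = 0, term_noise = 0,
    seed = 201))
  fit <- phn(ds$graph, ds$complexes, ds$domains)
  ev <- leave_one_out(fit, ds$annotations)
  expect_equal(ev$f_measure, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # top-ranked partner of any complex member is a complex-mate
  for (cid in names(ds$complexes$complexes)[1:2]) {
    u <- ds$complexes$complexes[[cid]][1]
    pr0 <- initial_scores(fit$mpp, fit$mpd, u)
    pr <- propagate(fit$transition, pr0)
    pscores <- pr$scores[seq_len(length(fit$proteins))]
    pscores <- pscores[names(pscores) != u]
    top <- names(which.max(pscores))
    expect_true(top %in% ds$complexes$complexes[[cid]])
  }
})

test_that("leave-one-out beats its permutation null on planted data", {
  ds <- generate_dataset(synthetic_config(seed = 211))
  fit <- phn(ds$graph, ds$complexes, ds$domains)
  real <- leave_one_out(fit, ds$annotations)
  null <- leave_one_out(fit, permute_annotations(ds$annotations, 1))
  expect_gt(real$f_measure, null$f_measure + 0.2)
})

test_that("per-protein metrics on a hand-worked single-complex dataset", {
  # clique of 4, one complex, identical planted terms; one extra protein
  g <- ppi_graph(c("a", "b", "c", "d", "e"),
                 t(combn(c("a", "b", "c", "d"), 2)))
  cx <- complex_catalog(list(c1 = c("a", "b", "c", "d")))
  ann <- annotation_catalog("BP", list(a = c("f1", "f2"), b = c("f1", "f2"),
                                       c = c("f1", "f2"),
                                       d = c("f1", "f3")))
  fit <- phn(g, cx, NULL)
  ev <- leave_one_out(fit, ann)
  pp <- ev$per_protein
  # a, b, c recover {f1, f2}; d predicts {f1, f2} against {f1, f3}
  expect_equal(pp$precision[pp$protein == "a"], 1)
  expect_equal(pp$recall[pp$protein == "a"], 1)
  expect_equal(pp$precision[pp$protein == "d"], 0.5)
  expect_equal(pp$recall[pp$protein == "d"], 0.5)
  expect_equal(ev$precision, mean(pp$precision))
  expect_equal(ev$f_measure, f_measure(ev$precision, ev$recall))
})

test_that("k-fold with singleton folds reduces to leave-one-out", {
  ds <- generate_dataset(synthetic_config(
    n_proteins = 20, n_complexes = 3, complex_size_range = c(4, 5),
    n_domains = 6, n_terms = 9, seed = 221))
  fit <- phn(ds$graph, ds$complexes, ds$domains)
  n_ann <- length(intersect(names(ds$annotations$annotations),
                            fit$proteins))
  loo <- leave_one_out(fit, ds$annotations)
  kf <- k_fold(fit, ds$annotations, folds = n_ann, seed = 5)
  expect_equal(kf$precision, loo$precision, tolerance = 1e-12)
  expect_equal(kf$recall, loo$recall, tolerance = 1e-12)
})

test_that("k-fold is reproducible from its seed and validates folds", {
  ds <- generate_dataset(synthetic_config(seed = 231))
  fit <- phn(ds$graph, ds$complexes, ds$domains)
  a <- k_fold(fit, ds$annotations, folds = 5, seed = 9)
  b <- k_fold(fit, ds$annotations, folds = 5, seed = 9)
  expect_identical(a, b)
  expect_error(k_fold(fit, ds$annotations, folds = 1000), "folds")
  expect_error(k_fold(fit, ds$annotations, folds = 1), "folds")
  # planted signal: k-fold F in the neighbourhood of the LOOCV F
  loo <- leave_one_out(fit, ds$annotations)
  expect_lt(abs(a$f_measure - loo$f_measure), 0.15)
})

test_that("ROC ladder handles perfect, hand-enumerated and random cases", {
  universe <- sprintf("t%02d", 1:10)
  truths <- annotation_catalog("BP", list(u = c("t01", "t02")))
  ranked <- list(u = c("t01", "t02", universe[3:10]))
  roc <- roc_curve(ranked, truths, universe)
  expect_equal(roc$points$tpr[2], 1)
  expect_equal(roc$points$fpr[2], 0)
  expect_equal(roc$auroc, 1)

  # 3-term micro-case enumerated by hand: truth {A}, ranking B, A, C
  tru <- annotation_catalog("BP", list(u = "A"))
  roc3 <- roc_curve(list(u = c("B", "A", "C")), tru, c("A", "B", "C"))
  expect_equal(roc3$points$tpr, c(0, 1, 1))
  expect_equal(roc3$points$fpr, c(0.5, 0.5, 1))
  expect_equal(roc3$auroc, 0.5)

  # random rankings calibrate to 0.5
  set.seed(241)
  U <- sprintf("r%02d", 1:20)
  truths2 <- annotation_catalog("BP", stats::setNames(
    lapply(1:200, function(i) sample(U, 3)), sprintf("p%03d", 1:200)))
  aucs <- replicate(30, {
    rl <- stats::setNames(lapply(1:200, function(i) sample(U)),
                          sprintf("p%03d", 1:200))
    roc_curve(rl, truths2)$auroc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  expect_true(all(abs(aucs - 0.5) < 0.05))
})

test_that("ROC rates are monotone and AUROC is rank-invariant", {
  ds <- generate_dataset(synthetic_config(seed = 251))
  fit <- phn(ds$graph, ds$complexes, ds$domains)
  ev <- leave_one_out(fit, ds$annotations)
  roc <- roc_curve(ev$ranked, ds$annotations)
  expect_true(!is.unsorted(roc$points$tpr))
  expect_true(!is.unsorted(roc$points$fpr))
  expect_gte(roc$auroc, 0)
  expect_lte(roc$auroc, 1)
  # short ranked lists are padded deterministically
  short <- lapply(ev$ranked, utils::head, 2L)
  roc_s <- roc_curve(short, ds$annotations)
  expect_equal(nrow(roc_s$points), length(ds$annotations$term_universe))
  expect_error(roc_curve(ev$ranked, ds$annotations, character(0)), "universe")
  expect_error(roc_curve(ev$ranked, ds$annotations, k_max = 999), "k_max")
})

test_that("beta sweep reproduces and shows the module term helping", {
  ds <- generate_dataset(synthetic_config(seed = 261))
  tab <- beta_sweep(ds$graph, ds$complexes, ds$domains, ds$annotations,
                    betas = c(0.2, 0.8, 1))
  tab2 <- beta_sweep(ds$graph, ds$complexes, ds$domains, ds$annotations,
                     betas = c(0.2, 0.8, 1))
  expect_identical(tab, tab2)
  expect_equal(tab$beta, c(0.2, 0.8, 1))
  expect_true(all(tab$f_measure >= 0 & tab$f_measure <= 1))
  # on planted data the module similarity carries signal: some beta < 1
  # does at least as well as topology alone
  expect_gte(max(tab$f_measure[tab$beta < 1]), tab$f_measure[tab$beta == 1])
  expect_error(beta_sweep(ds$graph, ds$complexes, ds$domains,
                          ds$annotations, betas = 2), "beta")
})
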