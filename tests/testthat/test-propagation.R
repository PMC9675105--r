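build_layers <- function(ds, alpha = 0.8, beta = 0.8) {
  mpp <- build_weighted_ppi(ds$graph, ds$complexes, alpha = alpha,
                            beta = beta)
  mpd <- build_domain_incidence(ds$domains, ds$graph$proteins)
  mdd <- build_domain_similarity(mpp, mpd)
  list(mpp = mpp, mpd = mpd, mdd = mdd,
       hbm = assemble_hbm(mpp, mpd, mdd))
}

test_that("block matrix layout is proteins-then-domains and symmetric", {
  g <- ppi_graph(c("a", "b"), rbind(c("a", "b")))
  mpp <- build_weighted_ppi(g, NULL, alpha = 0.4, beta = 1)
  mpd <- build_domain_incidence(domain_table(data.frame(
    protein = "a", domain = "d1")), g$proteins)
  mdd <- build_domain_similarity(mpp, mpd)
  hbm <- assemble_hbm(mpp, mpd, mdd)
  H <- as.matrix(hbm$matrix)
  expect_equal(dim(H), c(3L, 3L))
  expect_equal(rownames(H), c("a", "b", "d1"))
  expect_equal(H["a", "d1"], 1)
  expect_equal(H["d1", "a"], 1)
  expect_equal(H, t(H))

  # no domains: the combined matrix reduces to the protein block
  mpd0 <- build_domain_incidence(domain_table(), g$proteins)
  hbm0 <- assemble_hbm(mpp, mpd0, build_domain_similarity(mpp, mpd0))
  expect_equal(as.matrix(hbm0$matrix), as.matrix(mpp$weights),
               ignore_attr = TRUE)
})

test_that("block placement matches element indexing on a random instance", {
  ds <- generate_dataset(synthetic_config(seed = 91))
  ly <- build_layers(ds)
  H <- as.matrix(ly$hbm$matrix)
  np <- length(ds$graph$proteins)
  expect_equal(H[seq_len(np), seq_len(np)], as.matrix(ly$mpp$weights),
               ignore_attr = TRUE)
  expect_equal(H[seq_len(np), -seq_len(np)], as.matrix(ly$mpd$matrix),
               ignore_attr = TRUE)
  expect_equal(H[-seq_len(np), -seq_len(np)], ly$mdd$matrix,
               ignore_attr = TRUE)
  expect_equal(H, t(H))
})

test_that("transition rows split (1-lambda):lambda and sum to one", {
  # protein u: two equal-weight neighbours and one domain, lambda = 0.2
  g <- ppi_graph(c("u", "v", "w"), rbind(c("u", "v"), c("u", "w")))
  mpp <- build_weighted_ppi(g, NULL, alpha = 0.5, beta = 1)
  mpd <- build_domain_incidence(domain_table(data.frame(
    protein = "u", domain = "d1")), g$proteins)
  hbm <- assemble_hbm(mpp, mpd, build_domain_similarity(mpp, mpd))
  Tm <- as.matrix(build_transition(hbm, lambda = 0.2)$matrix)
  expect_equal(Tm["u", "v"], 0.4)
  expect_equal(Tm["u", "w"], 0.4)
  expect_equal(Tm["u", "d1"], 0.2)
  expect_equal(sum(Tm["u", ]), 1)
  # v has neighbours but no domain: its protein entries sum to 1
  expect_equal(sum(Tm["v", c("u", "w")]), 1)
  expect_equal(Tm["v", "d1"], 0)
  expect_error(build_transition(hbm, lambda = 1.5), "lambda")
})

test_that("transition matrix equals the brute-force row-normalization oracle", {
  for (seed in c(101, 102)) {
    ds <- generate_dataset(synthetic_config(
      n_proteins = 14, n_complexes = 3, complex_size_range = c(3, 4),
      n_domains = 5, n_terms = 8, seed = seed))
    ly <- build_layers(ds)
    got <- as.matrix(build_transition(ly$hbm, lambda = 0.2)$matrix)
    want <- oracle_transition(as.matrix(ly$mpp$weights),
                              as.matrix(ly$mpd$matrix), ly$mdd$matrix, 0.2)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("every transition row sums to one or zero across random instances", {
  for (seed in 111:115) {
    ds <- generate_dataset(synthetic_config(seed = seed))
    ly <- build_layers(ds)
    tr <- build_transition(ly$hbm, lambda = 0.2)
    rs <- Matrix::rowSums(tr$matrix)
    expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
    np <- tr$n_proteins
    dom_mass <- Matrix::rowSums(tr$matrix[seq_len(np), -seq_len(np),
                                          drop = FALSE])
    both <- Matrix::rowSums(ly$mpd$matrix) > 0 &
      Matrix::rowSums(ly$mpp$weights) > 0
    expect_true(all(abs(dom_mass[both] - 0.2) < 1e-12))
  }
})

test_that("restart vector matches the direct evaluation", {
  inst <- small_instance(seed = 121)
  mpp <- build_weighted_ppi(inst$graph, inst$catalog)
  mpd <- build_domain_incidence(inst$domains, inst$proteins)
  dense_pp <- as.matrix(mpp$weights)
  dense_pd <- as.matrix(mpd$matrix)
  for (u in inst$proteins[1:5]) {
    got <- initial_scores(mpp, mpd, u)
    want <- oracle_initial_scores(dense_pp, dense_pd, u)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    expect_equal(got[[u]], 0)  # zero diagonal
  }
  # a domain whose carriers are all unconnected to u gets 0
  g <- ppi_graph(c("u", "v", "z"), rbind(c("u", "v")))
  mpp2 <- build_weighted_ppi(g, NULL, alpha = 0.9, beta = 1)
  mpd2 <- build_domain_incidence(domain_table(data.frame(
    protein = c("z", "v"), domain = c("dz", "dv"))), g$proteins)
  h <- initial_scores(mpp2, mpd2, "u")
  expect_equal(h[["dz"]], 0)
  expect_equal(h[["dv"]], 0.9)  # singleton max over v, Eq-14 style
  expect_error(initial_scores(mpp2, mpd2, "nope"), "unknown protein")
})

test_that("propagation degenerates and symmetrizes as expected", {
  ds <- generate_dataset(synthetic_config(seed = 131))
  ly <- build_layers(ds)
  tr <- build_transition(ly$hbm)
  pr0 <- initial_scores(ly$mpp, ly$mpd, ds$graph$proteins[1])
  one <- propagate(tr, pr0, gamma = 1)
  expect_true(one$converged)
  expect_equal(unname(one$scores), unname(pr0))

  # two symmetric proteins with equal restart mass end with equal scores
  g <- ppi_graph(c("a", "b", "c"), rbind(c("a", "b"), c("a", "c")))
  mpp <- build_weighted_ppi(g, NULL, alpha = 0.6, beta = 1)
  mpd <- build_domain_incidence(domain_table(), g$proteins)
  tr2 <- build_transition(assemble_hbm(mpp, mpd,
                                       build_domain_similarity(mpp, mpd)))
  pr <- propagate(tr2, initial_scores(mpp, mpd, "a"), epsilon = 1e-10)
  expect_equal(pr$scores[["b"]], pr$scores[["c"]], tolerance = 1e-12)

  # zero restart stays zero
  z <- propagate(tr, rep(0, length(pr0)))
  expect_equal(unname(z$scores), rep(0, length(pr0)))
  expect_error(propagate(tr, pr0, gamma = 2), "gamma")
  expect_error(propagate(tr, rep(-1, length(pr0))), "nonnegative")
})

test_that("iterative propagation agrees with the direct linear solve", {
  for (seed in c(141, 142, 143)) {
    ds <- generate_dataset(synthetic_config(
      n_proteins = 40, n_complexes = 6, complex_size_range = c(4, 6),
      n_domains = 10, seed = seed))
    ly <- build_layers(ds)
    tr <- build_transition(ly$hbm)
    pr0 <- initial_scores(ly$mpp, ly$mpd, ds$graph$proteins[3])
    it <- propagate(tr, pr0, gamma = 0.5, epsilon = 1e-12)
    direct <- solve_stationary(tr, pr0, gamma = 0.5)
    expect_true(it$converged)
    expect_lt(sum(abs(it$scores - direct)), 1e-8)
  }
  # closed-form degenerate cases
  g <- ppi_graph(c("a", "b"), rbind(c("a", "b")))
  mpp <- build_weighted_ppi(g, NULL, beta = 1)
  mpd <- build_domain_incidence(domain_table(), g$proteins)
  tr <- build_transition(assemble_hbm(mpp, mpd,
                                      build_domain_similarity(mpp, mpd)))
  pr0 <- c(a = 0.3, b = 0.7)
  expect_equal(solve_stationary(tr, pr0, gamma = 1), pr0)
  expect_error(solve_stationary(tr, pr0, gamma = 0), "gamma")
})

test_that("L1 differences contract at rate (1 - gamma)", {
  ds <- generate_dataset(synthetic_config(seed = 151))
  ly <- build_layers(ds)
  tr <- build_transition(ly$hbm)
  Tm <- tr$matrix
  gamma <- 0.5
  pr0 <- initial_scores(ly$mpp, ly$mpd, ds$graph$proteins[5])
  pr <- as.numeric(pr0)
  prev_delta <- NULL
  for (i in 1:30) {
    nxt <- (1 - gamma) * as.numeric(Tm %*% pr) + gamma * as.numeric(pr0)
    delta <- sum(abs(nxt - pr))
    if (!is.null(prev_delta) && prev_delta > 0)
      expect_lte(delta, (1 - gamma) * prev_delta * (1 + 1e-9))
    prev_delta <- delta
    pr <- nxt
  }
  # the iteration count respects the implied bound
  eps <- 1e-12
  it <- propagate(tr, pr0, gamma = gamma, epsilon = eps)
  d1 <- sum(abs(((1 - gamma) * as.numeric(Tm %*% pr0) + gamma * pr0) - pr0))
  bound <- log(eps / d1) / log(1 - gamma) + 1
  expect_lte(it$iterations, ceiling(bound))
})
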