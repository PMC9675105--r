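# Brute-force oracles, written independently of the package internals:
# everything here enumerates definitions directly with plain loops over
# dense structures, so tests can compare the pipeline against them.

# random simple graph as an edge data.frame over given labels
random_edges <- function(labels, n_edges, seed) {
  set.seed(seed)
  all_pairs <- t(combn(labels, 2L))
  all_pairs[sample(nrow(all_pairs), min(n_edges, nrow(all_pairs))), ,
            drop = FALSE]
}

oracle_neighbors <- function(edges, u) {
  nb <- function(x) unique(c(edges[edges[, 1L] == x, 2L],
                             edges[edges[, 2L] == x, 1L]))
  s1 <- nb(u)
  s2 <- character(0)
  for (w in s1) for (v in nb(w)) if (v != u) s2 <- union(s2, v)
  list(S1 = s1, S2 = s2)
}

oracle_fs <- function(edges, u, v, alpha) {
  ns <- oracle_neighbors(edges, u)
  in1 <- v %in% ns$S1
  in2 <- v %in% ns$S2
  if (in1 && in2) 1 else if (in1) alpha else if (in2) 1 - alpha else 0
}

oracle_ms <- function(members, u, v) {
  # members: named list complex -> member vector
  cu <- names(members)[vapply(members, function(m) u %in% m, logical(1))]
  cv <- names(members)[vapply(members, function(m) v %in% m, logical(1))]
  if (!length(cu) || !length(cv)) return(0)
  length(intersect(cu, cv))^2 / (length(cu) * length(cv))
}

# dense all-pairs weighted PPI matrix by direct evaluation
oracle_mpp <- function(proteins, edges, members, alpha, beta) {
  n <- length(proteins)
  m <- matrix(0, n, n, dimnames = list(proteins, proteins))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    m[i, j] <- beta * oracle_fs(edges, proteins[i], proteins[j], alpha) +
      (1 - beta) * oracle_ms(members, proteins[i], proteins[j])
  }
  m
}

oracle_spd <- function(mpp_dense, u, pl) {
  max(vapply(pl, function(p) mpp_dense[u, p], numeric(1)))
}

oracle_mdd <- function(mpp_dense, pl_list, dn_i, dn_j) {
  pli <- pl_list[[dn_i]]
  plj <- pl_list[[dn_j]]
  num <- sum(vapply(pli, function(p) oracle_spd(mpp_dense, p, pli),
                    numeric(1))) +
    sum(vapply(plj, function(p) oracle_spd(mpp_dense, p, plj), numeric(1)))
  num / (length(pli) + length(plj))
}

# dense transition matrix by per-row normalization of the stated rules
oracle_transition <- function(mpp_dense, mpd_dense, mdd_dense, lambda) {
  np <- nrow(mpp_dense); nd <- ncol(mpd_dense)
  out <- matrix(0, np + nd, np + nd)
  for (i in seq_len(np)) {
    spp <- sum(mpp_dense[i, ]); spd <- sum(mpd_dense[i, ])
    if (spp > 0)
      out[i, seq_len(np)] <- mpp_dense[i, ] / spp *
        (if (spd > 0) 1 - lambda else 1)
    if (spd > 0)
      out[i, np + seq_len(nd)] <- mpd_dense[i, ] / spd *
        (if (spp > 0) lambda else 1)
  }
  for (i in seq_len(nd)) {
    sdd <- sum(mdd_dense[i, ]); sdp <- sum(mpd_dense[, i])
    if (sdd > 0)
      out[np + i, np + seq_len(nd)] <- mdd_dense[i, ] / sdd *
        (if (sdp > 0) 1 - lambda else 1)
    if (sdp > 0)
      out[np + i, seq_len(np)] <- mpd_dense[, i] / sdp *
        (if (sdd > 0) lambda else 1)
  }
  out
}

oracle_initial_scores <- function(mpp_dense, mpd_dense, u) {
  h_p <- mpp_dense[u, ]
  h_d <- apply(mpd_dense, 2L, function(col) {
    pl <- which(col > 0)
    if (length(pl)) max(h_p[pl]) else 0
  })
  c(h_p, h_d)
}

oracle_term_scores <- function(scores_p, ann_list, target) {
  out <- numeric(0)
  for (p in names(scores_p)) {
    if (p == target || scores_p[[p]] <= 0) next
    for (tm in ann_list[[p]]) {
      out[tm] <- (if (tm %in% names(out)) out[[tm]] else 0) + scores_p[[p]]
    }
  }
  out
}

# small fixture used by several domain/propagation tests
small_instance <- function(seed = 3, n = 10, n_edges = 14, n_dom = 4) {
  set.seed(seed)
  proteins <- sprintf("q%02d", seq_len(n))
  edges <- random_edges(proteins, n_edges, seed)
  members <- list(c1 = proteins[1:4], c2 = proteins[3:7])
  graph <- ppi_graph(proteins, edges)
  catalog <- complex_catalog(members)
  recs <- data.frame(
    protein = sample(proteins, 3L * n_dom, replace = TRUE),
    domain = rep(sprintf("d%d", seq_len(n_dom)), each = 3L))
  list(graph = graph, catalog = catalog, members = members, edges = edges,
       proteins = proteins, domains = domain_table(recs))
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

gaf_row <- function(id, term, aspect, qualifier = "") {
  paste("DB", id, id, qualifier, term, "REF:1", "IEA", "", aspect, "", "",
        "protein", "taxon:1", "20220101", "DB", "", "", sep = "\t")
}
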