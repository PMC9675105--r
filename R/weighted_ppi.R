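# Weighted protein layer: topology similarity over direct and level-2
# neighbourhoods, complex co-membership module similarity, and their
# beta-blend.

adjacency_list <- function(graph) {
  e <- graph$edges
  adj <- stats::setNames(vector("list", length(graph$proteins)),
                         graph$proteins)
  if (nrow(e)) {
    ends <- c(e[, 1L], e[, 2L])
    other <- c(e[, 2L], e[, 1L])
    byu <- split(other, factor(ends, levels = graph$proteins))
    for (u in names(byu)) adj[[u]] <- unique(byu[[u]])
  }
  adj
}

adjacency_matrix <- function(graph) {
  n <- length(graph$proteins)
  e <- graph$edges
  i <- match(e[, 1L], graph$proteins)
  j <- match(e[, 2L], graph$proteins)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n),
                       dimnames = list(graph$proteins, graph$proteins))
}

#' Direct and level-2 neighbour sets
#'
#' `S1` is the set of direct neighbours of `u`; `S2` is the set of proteins
#' reachable from `u` by a path of exactly two edges (through any
#' intermediate node), excluding `u` itself.  A protein may belong to both
#' sets.
#'
#' @param graph a [ppi_graph()].
#' @param u protein ID.
#' @return list with character vectors `S1` and `S2`.
#' @export
neighbor_sets <- function(graph, u) {
  if (!u %in% graph$proteins) stop("unknown protein: ", u)
  adj <- adjacency_list(graph)
  s1 <- adj[[u]]
  s2 <- setdiff(unique(unlist(adj[s1], use.names = FALSE)), u)
  list(S1 = if (is.null(s1)) character(0) else s1,
       S2 = if (is.null(s2)) character(0) else s2)
}

#' Topology-based functional similarity between two proteins
#'
#' Classifies `v` relative to the direct (`S1`) and level-2 (`S2`)
#' neighbourhoods of `u` and scores the pair: 1 if `v` is in both sets,
#' `alpha` if only a direct neighbour, `1 - alpha` if only a level-2
#' neighbour, and 0 otherwise.  `alpha` in (0, 1) weights the importance of
#' direct neighbours.
#'
#' @param graph a [ppi_graph()].
#' @param u,v distinct protein IDs.
#' @param alpha weight of exclusive direct neighbours, in (0, 1).
#' @return similarity in `{0, alpha, 1 - alpha, 1}`.
#' @export
topology_similarity <- function(graph, u, v, alpha = 0.8) {
  if (u == v) stop("topology similarity is undefined for u == v")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!v %in% graph$proteins) stop("unknown protein: ", v)
  ns <- neighbor_sets(graph, u)
  in1 <- v %in% ns$S1
  in2 <- v %in% ns$S2
  if (in1 && in2) 1 else if (in1) alpha else if (in2) 1 - alpha else 0
}

#' Module similarity from complex co-membership
#'
#' `|C_u n C_v|^2 / (|C_u| * |C_v|)` where `C_u`, `C_v` are the sets of
#' complexes containing each protein; 0 when either protein belongs to no
#' complex.
#'
#' @param catalog a [complex_catalog()].
#' @param u,v protein IDs.
#' @return similarity in \[0, 1\].
#' @export
module_similarity <- function(catalog, u, v) {
  cu <- complex_membership(catalog, u)
  cv <- complex_membership(catalog, v)
  if (!length(cu) || !length(cv)) return(0)
  length(intersect(cu, cv))^2 / (length(cu) * length(cv))
}

#' Build the weighted protein-protein layer
#'
#' Every unordered protein pair with positive topology similarity `fs`
#' (direct or level-2 neighbours) or positive module similarity `ms`
#' (complex co-members) receives the blended weight
#' `mpp(u, v) = beta * fs(u, v) + (1 - beta) * ms(u, v)`; all other entries,
#' including the diagonal, are zero.  The support is deliberately wider than
#' the original edge set: pure level-2 pairs and complex co-members without
#' a detected interaction are connected too.
#'
#' @param graph a [ppi_graph()].
#' @param catalog a [complex_catalog()], or `NULL` for no module term.
#'   Catalog proteins absent from the graph are ignored with a warning.
#' @param alpha exclusive-direct-neighbour weight, in (0, 1).
#' @param beta blend weight in \[0, 1\]; 1 uses topology only, 0 modules only.
#' @return object of class `"weighted_ppi"`: list with the symmetric sparse
#'   `weights` matrix (dimnames = protein IDs), `proteins`, `alpha`, `beta`.
#' @export
build_weighted_ppi <- function(graph, catalog = NULL, alpha = 0.8,
                               beta = 0.8) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  proteins <- graph$proteins
  n <- length(proteins)
  A <- adjacency_matrix(graph)
  S2 <- Matrix::drop0((A %*% A) > 0) * 1
  Matrix::diag(S2) <- 0
  S2 <- Matrix::drop0(S2)
  # value is alpha on S1-only pairs, 1-alpha on S2-only, and their sum 1 on both
  fs <- alpha * A + (1 - alpha) * S2

  ms <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(n, n),
                             dimnames = list(proteins, proteins))
  if (!is.null(catalog) && length(catalog$complexes)) {
    cx <- names(catalog$complexes)
    mem_p <- unlist(lapply(cx, function(cid) catalog$complexes[[cid]]),
                    use.names = FALSE)
    mem_c <- rep(cx, lengths(catalog$complexes))
    known <- mem_p %in% proteins
    if (any(!known))
      warning(sprintf("%d complex members absent from the PPI graph ignored",
                      sum(!known)))
    M <- Matrix::sparseMatrix(i = match(mem_p[known], proteins),
                              j = match(mem_c[known], cx),
                              x = 1, dims = c(n, length(cx)))
    shared <- methods::as(methods::as(Matrix::tcrossprod(M),
                                      "generalMatrix"), "TsparseMatrix")
    sz <- Matrix::rowSums(M)
    keep <- shared@i != shared@j & shared@x > 0
    ii <- shared@i[keep] + 1L
    jj <- shared@j[keep] + 1L
    ms <- Matrix::sparseMatrix(i = ii, j = jj,
                               x = shared@x[keep]^2 / (sz[ii] * sz[jj]),
                               dims = c(n, n),
                               dimnames = list(proteins, proteins))
  }
  w <- Matrix::drop0(beta * fs + (1 - beta) * ms)
  structure(list(weights = w, proteins = proteins, alpha = alpha,
                 beta = beta),
            class = "weighted_ppi")
}

#' @export
print.weighted_ppi <- function(x, ...) {
  nz <- Matrix::drop0(x$weights)@x
  cat(sprintf("weighted_ppi: %d proteins, %d weighted pairs (alpha=%g, beta=%g)\n",
              length(x$proteins), length(nz) / 2L, x$alpha, x$beta))
  invisible(x)
}

#' Dump a weighted matrix as a 3-column edge list
#'
#' One row per unordered pair with positive weight: `id1`, `id2`, `weight`.
#' @param x a `"weighted_ppi"` or `"domain_similarity"` object.
#' @param path output path.
#' @export
write_weighted_edgelist <- function(x, path) {
  m <- methods::as(methods::as(Matrix::drop0(Matrix::Matrix(x$matrix %||%
         x$weights, sparse = TRUE)), "generalMatrix"), "TsparseMatrix")
  ids <- rownames(m)
  keep <- m@i < m@j
  df <- data.frame(a = ids[m@i[keep] + 1L], b = ids[m@j[keep] + 1L],
                   w = sprintf("%.17g", m@x[keep]))
  ord <- order(df$a, df$b)
  writeLines(paste(df$a[ord], df$b[ord], df$w[ord], sep = "\t"), path)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
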