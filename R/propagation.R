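# Heterogeneous block matrix, lambda-reserved transition matrix, restart
# vector construction and the propagation iteration.

#' Assemble the heterogeneous block adjacency matrix
#'
#' Combined node order is proteins then domains, with block layout
#' `[[MPP, MPD], [MPD', MDD]]`; the result is symmetric because `MPP` and
#' `MDD` are.
#'
#' @param mpp a `"weighted_ppi"` object.
#' @param mpd a `"domain_incidence"` object on the same protein index.
#' @param mdd a `"domain_similarity"` object on the same domain index.
#' @return object of class `"hetero_network"`: list with the sparse combined
#'   `matrix`, the three blocks, `proteins` and `domains`.
#' @export
assemble_hbm <- function(mpp, mpd, mdd) {
  if (!identical(mpp$proteins, mpd$proteins))
    stop("protein indices of MPP and MPD differ")
  if (!identical(mpd$domains, mdd$domains))
    stop("domain indices of MPD and MDD differ")
  Wpp <- methods::as(mpp$weights, "generalMatrix")
  Wpd <- methods::as(mpd$matrix, "generalMatrix")
  Wdd <- Matrix::Matrix(mdd$matrix, sparse = TRUE)
  H <- rbind(cbind(Wpp, Wpd), cbind(Matrix::t(Wpd), Wdd))
  nodes <- c(mpp$proteins, mpd$domains)
  dimnames(H) <- list(nodes, nodes)
  structure(list(matrix = H, mpp = mpp, mpd = mpd, mdd = mdd,
                 proteins = mpp$proteins, domains = mpd$domains),
            class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat(sprintf("hetero_network: %d proteins + %d domains\n",
              length(x$proteins), length(x$domains)))
  invisible(x)
}

#' Build the row-stochastic transition matrix with layer-move probability
#'
#' Each block of the heterogeneous matrix is row-normalized; a node whose
#' row has mass in both its own layer and the cross layer splits it
#' `(1 - lambda) : lambda` between them; a node with mass in only one layer
#' sends all of it there, so every row sums to exactly 1 (or 0 for isolated
#' nodes).  `lambda` is the probability of moving between the protein and
#' domain layers.
#'
#' @param hbm a `"hetero_network"` from [assemble_hbm()].
#' @param lambda move probability in \[0, 1\].
#' @return object of class `"transition_matrix"`: list with the sparse
#'   `matrix`, `lambda`, `n_proteins`, `n_domains` and `nodes`.
#' @export
build_transition <- function(hbm, lambda = 0.2) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  Wpp <- methods::as(hbm$mpp$weights, "generalMatrix")
  Wpd <- methods::as(hbm$mpd$matrix, "generalMatrix")
  Wdd <- Matrix::Matrix(hbm$mdd$matrix, sparse = TRUE)
  if (any(Wpp@x < 0) || any(Wpd@x < 0) || any(hbm$mdd$matrix < 0))
    stop("negative weights in heterogeneous network")
  rpp <- Matrix::rowSums(Wpp)
  rpd <- Matrix::rowSums(Wpd)
  rdd <- Matrix::rowSums(Wdd)
  rdp <- Matrix::colSums(Wpd)

  scale_rows <- function(W, rs, scale) {
    d <- ifelse(rs > 0, scale / rs, 0)
    Matrix::Diagonal(x = d) %*% W
  }
  # protein rows
  spp <- ifelse(rpd > 0, 1 - lambda, 1)
  spd <- ifelse(rpp > 0, lambda, 1)
  PPt <- scale_rows(Wpp, rpp, spp)
  PDt <- scale_rows(Wpd, rpd, spd)
  # domain rows (an indexed domain always has >= 1 protein, but the branch
  # is kept for robustness)
  sdd <- ifelse(rdp > 0, 1 - lambda, 1)
  sdp <- ifelse(rdd > 0, lambda, 1)
  DDt <- scale_rows(Wdd, rdd, sdd)
  DPt <- scale_rows(Matrix::t(Wpd), rdp, sdp)

  Tm <- rbind(cbind(PPt, PDt), cbind(DPt, DDt))
  nodes <- c(hbm$proteins, hbm$domains)
  dimnames(Tm) <- list(nodes, nodes)
  structure(list(matrix = Tm, lambda = lambda,
                 n_proteins = length(hbm$proteins),
                 n_domains = length(hbm$domains), nodes = nodes),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d protein + %d domain rows, lambda=%g\n",
              x$n_proteins, x$n_domains, x$lambda))
  invisible(x)
}

#' Restart vector for a target protein
#'
#' Protein part: `h(p) = mpp(u, p)` (so `h(u) = 0` through the zero
#' diagonal).  Domain part: `h(d) = max` of `h(p)` over the proteins
#' carrying `d`.  The vector is used unnormalized.
#'
#' @param mpp a `"weighted_ppi"` object.
#' @param mpd a `"domain_incidence"` object on the same protein index.
#' @param u target protein ID.
#' @return named numeric vector over proteins-then-domains order.
#' @export
initial_scores <- function(mpp, mpd, u) {
  if (!identical(mpp$proteins, mpd$proteins))
    stop("protein indices of MPP and MPD differ")
  i <- match(u, mpp$proteins)
  if (is.na(i)) stop("unknown protein: ", u)
  h_p <- as.numeric(mpp$weights[i, ])
  nd <- length(mpd$domains)
  h_d <- numeric(nd)
  for (j in seq_len(nd)) {
    pl <- which(mpd$matrix[, j] > 0)
    if (length(pl)) h_d[j] <- max(h_p[pl])
  }
  stats::setNames(c(h_p, h_d), c(mpp$proteins, mpd$domains))
}

#' Propagate scores with restart to convergence
#'
#' Iterates `pr <- (1 - gamma) * T %*% pr + gamma * pr0` starting from
#' `pr = pr0` until the L1 change drops below `epsilon` or `max_iter` is
#' reached.  For `gamma` in (0, 1\] the iteration is a contraction toward
#' the unique fixed point (see [solve_stationary()]).
#'
#' @param transition a `"transition_matrix"`.
#' @param pr0 nonnegative restart vector, length `n_proteins + n_domains`.
#' @param gamma restart weight in \[0, 1\].
#' @param epsilon positive L1 convergence tolerance.
#' @param max_iter iteration cap; reaching it returns `converged = FALSE`
#'   rather than an error.
#' @return object of class `"score_vector"`: list with named `scores`,
#'   `iterations`, `converged`, `gamma`, `epsilon`, `pr0`, `n_proteins`.
#' @export
propagate <- function(transition, pr0, gamma = 0.5, epsilon = 1e-6,
                      max_iter = 1000L) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (any(pr0 < 0) || any(!is.finite(pr0)))
    stop("pr0 must be nonnegative and finite")
  Tm <- transition$matrix
  if (length(pr0) != nrow(Tm))
    stop("pr0 length does not match the transition matrix")
  pr <- as.numeric(pr0)
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    nxt <- (1 - gamma) * as.numeric(Tm %*% pr) + gamma * as.numeric(pr0)
    if (any(!is.finite(nxt))) stop("non-finite values during propagation")
    delta <- sum(abs(nxt - pr))
    pr <- nxt
    iterations <- iterations + 1L
    if (delta < epsilon) {
      converged <- TRUE
      break
    }
  }
  structure(list(scores = stats::setNames(pr, transition$nodes),
                 iterations = iterations, converged = converged,
                 gamma = gamma, epsilon = epsilon,
                 pr0 = stats::setNames(as.numeric(pr0), transition$nodes),
                 n_proteins = transition$n_proteins),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector: %d nodes, %d iterations (%s)\n",
              length(x$scores), x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Closed-form fixed point of the propagation iteration
#'
#' Solves `(I - (1 - gamma) T) pr = gamma pr0` directly; the solution
#' exists and is unique for `gamma > 0` because the iteration matrix has
#' spectral radius at most `1 - gamma` times that of the row-substochastic
#' `T`.  Serves as an independent oracle for [propagate()].
#'
#' @inheritParams propagate
#' @return named numeric vector of stationary scores.
#' @export
solve_stationary <- function(transition, pr0, gamma = 0.5) {
  if (gamma <= 0 || gamma > 1)
    stop("gamma must lie in (0, 1]: the system can be singular at gamma = 0")
  Tm <- transition$matrix
  n <- nrow(Tm)
  x <- Matrix::solve(Matrix::Diagonal(n) - (1 - gamma) * Tm,
                     gamma * as.numeric(pr0))
  stats::setNames(as.numeric(x), transition$nodes)
}
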