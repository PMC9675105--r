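# Model-object interface: phn() builds the heterogeneous network once and
# returns a classed bundle that predict/evaluation functions reuse.

default_beta <- c(BP = 0.8, MF = 0.7, CC = 0.9)

#' Fit a heterogeneous protein-domain propagation network
#'
#' Builds the three layers in sequence — weighted protein layer (topology +
#' complex co-membership, [build_weighted_ppi()]), protein-domain incidence
#' ([build_domain_incidence()]), domain-domain similarity
#' ([build_domain_similarity()]) — assembles them into one block matrix
#' ([assemble_hbm()]) and derives the row-stochastic transition matrix
#' ([build_transition()]).  The returned object is the reusable "fitted"
#' network: predictions for any target protein are obtained with
#' [predict()].
#'
#' @param graph a [ppi_graph()].
#' @param complexes a [complex_catalog()] or `NULL`.
#' @param domains a [domain_table()] or `NULL`.
#' @param ontology ontology the fit is intended for; only sets the default
#'   `beta` (0.8 for BP, 0.7 for MF, 0.9 for CC).
#' @param alpha exclusive-direct-neighbour weight in (0, 1); default 0.8,
#'   reflecting that most function sharing happens between direct
#'   neighbours.
#' @param beta topology/module blend weight in \[0, 1\]; `NULL` picks the
#'   per-ontology default.
#' @param lambda protein/domain layer-move probability; default 0.2.
#' @return object of class `"phn"`: list with `proteins`, `domains`, the
#'   layer objects `mpp`, `mpd`, `mdd`, the assembled `hbm` and
#'   `transition`, the parameters and the matched call.
#' @examples
#' ds <- generate_dataset(synthetic_config(seed = 7))
#' fit <- phn(ds$graph, ds$complexes, ds$domains)
#' fit
#' pred <- predict(fit, ds$graph$proteins[1], ds$annotations)
#' pred
#' @export
phn <- function(graph, complexes = NULL, domains = NULL,
                ontology = c("BP", "MF", "CC"), alpha = 0.8, beta = NULL,
                lambda = 0.2) {
  ontology <- match.arg(ontology)
  if (is.null(beta)) beta <- default_beta[[ontology]]
  mpp <- build_weighted_ppi(graph, complexes, alpha = alpha, beta = beta)
  if (is.null(domains)) domains <- domain_table()
  mpd <- build_domain_incidence(domains, graph$proteins)
  mdd <- build_domain_similarity(mpp, mpd)
  hbm <- assemble_hbm(mpp, mpd, mdd)
  transition <- build_transition(hbm, lambda = lambda)
  structure(list(proteins = graph$proteins, domains = mpd$domains,
                 graph = graph, complexes = complexes,
                 mpp = mpp, mpd = mpd, mdd = mdd, hbm = hbm,
                 transition = transition, ontology = ontology,
                 alpha = alpha, beta = beta, lambda = lambda,
                 call = match.call()),
            class = "phn")
}

#' @export
print.phn <- function(x, ...) {
  cat("Heterogeneous protein-domain propagation network\n")
  cat(sprintf("  proteins: %d   domains: %d\n",
              length(x$proteins), length(x$domains)))
  cat(sprintf("  ontology: %s   alpha = %g, beta = %g, lambda = %g\n",
              x$ontology, x$alpha, x$beta, x$lambda))
  invisible(x)
}

#' @export
summary.phn <- function(object, ...) {
  w <- Matrix::drop0(object$mpp$weights)
  nz <- length(w@x) / 2
  out <- list(n_proteins = length(object$proteins),
              n_domains = length(object$domains),
              n_weighted_pairs = nz,
              mean_weight = if (nz) mean(w@x) else 0,
              n_associations = sum(object$mpd$matrix),
              alpha = object$alpha, beta = object$beta,
              lambda = object$lambda, ontology = object$ontology)
  class(out) <- "summary.phn"
  out
}

#' @export
print.summary.phn <- function(x, ...) {
  cat("Heterogeneous protein-domain propagation network\n")
  cat(sprintf("  proteins              %d\n", x$n_proteins))
  cat(sprintf("  domains               %d\n", x$n_domains))
  cat(sprintf("  weighted pairs        %d (mean weight %.4f)\n",
              x$n_weighted_pairs, x$mean_weight))
  cat(sprintf("  domain associations   %d\n", x$n_associations))
  cat(sprintf("  parameters            alpha=%g beta=%g lambda=%g (%s)\n",
              x$alpha, x$beta, x$lambda, x$ontology))
  invisible(x)
}

#' @export
coef.phn <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, lambda = object$lambda)
}

#' Predict GO terms for target proteins
#'
#' @param object a `"phn"` fit.
#' @param targets one or more protein IDs.
#' @param annotations an [annotation_catalog()].
#' @param ... passed to [predict_functions()] (`gamma`, `epsilon`,
#'   `max_iter`, `threshold`).
#' @return a `"phn_prediction"` for a single target, otherwise a named list
#'   of them.
#' @export
predict.phn <- function(object, targets, annotations, ...) {
  preds <- lapply(targets, predict_functions, fit = object,
                  annotations = annotations, ...)
  names(preds) <- targets
  if (length(preds) == 1L) preds[[1L]] else preds
}

#' Histogram of positive weights in the fitted protein layer
#' @param x a `"phn"` fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.phn <- function(x, ...) {
  w <- Matrix::drop0(x$mpp$weights)@x
  graphics::hist(w, main = "Weighted protein layer",
                 xlab = "edge weight mpp(u, v)", ...)
  invisible(x)
}
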