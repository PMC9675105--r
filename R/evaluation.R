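# Cross-validation protocols, precision/recall/F-measure with the
# averaged-then-harmonic convention, top-K ROC ladders and the beta sweep.

#' Precision and recall of a predicted term set
#'
#' Precision is the fraction of predicted terms found in the truth set
#' (0 when nothing is predicted); recall is the fraction of true terms that
#' were predicted.  The truth set must be nonempty — proteins without
#' benchmark annotations are excluded upstream.
#'
#' @param predicted character vector of predicted term IDs.
#' @param truth nonempty character vector of true term IDs.
#' @return named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(predicted, truth) {
  if (!length(truth)) stop("truth set is empty: protein must be excluded upstream")
  predicted <- unique(predicted)
  truth <- unique(truth)
  hit <- length(intersect(predicted, truth))
  c(precision = if (length(predicted)) hit / length(predicted) else 0,
    recall = hit / length(truth))
}

#' F-measure (harmonic mean of precision and recall)
#' @param precision,recall values in \[0, 1\].
#' @return `2 P R / (P + R)`, or 0 when both are 0.
#' @export
f_measure <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

evaluate_proteins <- function(fit, annotations, test_sets, gamma, epsilon,
                              max_iter, threshold) {
  rows <- list()
  ranked <- list()
  for (set_idx in seq_along(test_sets)) {
    test <- test_sets[[set_idx]]
    visible <- hide_annotations(annotations, test)
    for (u in test) {
      truth <- protein_terms(annotations, u)
      if (!length(truth) || !u %in% fit$proteins) next
      pred <- predict_functions(u, fit, visible, gamma = gamma,
                                epsilon = epsilon, max_iter = max_iter,
                                threshold = threshold)
      pr <- precision_recall(pred$terms$term, truth)
      rows[[length(rows) + 1L]] <-
        data.frame(protein = u, fold = set_idx,
                   precision = pr[["precision"]], recall = pr[["recall"]],
                   L = pred$L, n_predicted = nrow(pred$terms),
                   stringsAsFactors = FALSE)
      ranked[[u]] <- pred$ranked$term
    }
  }
  list(per_protein = do.call(rbind, rows), ranked = ranked)
}

make_report <- function(protocol, per_protein, ranked, fit, extra = list()) {
  P <- mean(per_protein$precision)
  R <- mean(per_protein$recall)
  structure(c(list(protocol = protocol, per_protein = per_protein,
                   precision = P, recall = R, f_measure = f_measure(P, R),
                   ranked = ranked, n_proteins = nrow(per_protein),
                   ontology = fit$ontology,
                   config = coef(fit)),
              extra),
            class = "phn_evaluation")
}

#' @export
print.phn_evaluation <- function(x, ...) {
  cat(sprintf("phn_evaluation (%s, %s): %d proteins\n",
              x$protocol, x$ontology, x$n_proteins))
  cat(sprintf("  precision = %.3f  recall = %.3f  F-measure = %.3f\n",
              x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' For each annotated protein in the network, its annotations are hidden
#' from the catalog, its functions are predicted from the remaining
#' annotations, and precision/recall are computed against the hidden set.
#' The report carries the dataset-averaged precision `P` and recall `R` and
#' their harmonic mean as the F-measure (the averaged-then-harmonic
#' convention), plus the full ranked candidate list per protein for ROC
#' analysis.
#'
#' @param fit a `"phn"` fit.
#' @param annotations an [annotation_catalog()].
#' @param gamma,epsilon,max_iter,threshold propagation settings, see
#'   [predict_functions()].
#' @return object of class `"phn_evaluation"`.
#' @export
leave_one_out <- function(fit, annotations, gamma = 0.5, epsilon = 1e-6,
                          max_iter = 1000L, threshold = 0) {
  testable <- intersect(names(annotations$annotations), fit$proteins)
  if (length(testable) < 2L)
    stop("leave-one-out needs at least two annotated proteins")
  ev <- evaluate_proteins(fit, annotations, as.list(testable), gamma,
                          epsilon, max_iter, threshold)
  make_report("loocv", ev$per_protein, ev$ranked, fit)
}

#' k-fold cross-validation
#'
#' Annotated proteins are randomly partitioned into `folds` equal sets; for
#' each fold, the annotations of all its proteins are hidden simultaneously
#' and each is predicted from the remaining training annotations.  Metrics
#' average over all proteins of all folds and repeats; the partition is
#' reproducible from `seed`.
#'
#' @inheritParams leave_one_out
#' @param folds number of folds (>= 2, at most the annotated-protein count).
#' @param repeats number of independent repetitions of the whole partition.
#' @param seed integer seed for the fold assignment.
#' @return object of class `"phn_evaluation"`.
#' @export
k_fold <- function(fit, annotations, folds = 10L, repeats = 1L, seed = 1L,
                   gamma = 0.5, epsilon = 1e-6, max_iter = 1000L,
                   threshold = 0) {
  testable <- intersect(names(annotations$annotations), fit$proteins)
  if (folds < 2L) stop("folds must be at least 2")
  if (folds > length(testable))
    stop("more folds than annotated proteins")
  per <- list()
  ranked <- list()
  assignments <- with_seed(seed, {
    lapply(seq_len(repeats), function(r)
      sample(rep_len(seq_len(folds), length(testable))))
  })
  for (r in seq_len(repeats)) {
    sets <- split(testable, assignments[[r]])
    ev <- evaluate_proteins(fit, annotations, sets, gamma, epsilon,
                            max_iter, threshold)
    ev$per_protein$repeat_ <- r
    per[[r]] <- ev$per_protein
    if (r == 1L) ranked <- ev$ranked
  }
  make_report("kfold", do.call(rbind, per), ranked, fit,
              extra = list(folds = folds, repeats = repeats, seed = seed))
}

#' Top-K ROC ladder and AUROC over ranked term lists
#'
#' For each protein and each cutoff `K = 1..k_max`, the top-K ranked terms
#' form the positive set (ranked lists shorter than `K` are padded with the
#' remaining universe terms in term-ID order), giving
#' `TPR = |pos n truth| / |truth|` and
#' `FPR = |pos - truth| / |universe - truth|`.  Rates are averaged over
#' proteins per `K` and the AUROC is the trapezoidal area over the averaged
#' `(FPR, TPR)` points anchored at (0, 0) and (1, 1).
#'
#' @param ranked_lists named list mapping protein ID to its ranked character
#'   vector of candidate terms (e.g. the `ranked` element of a
#'   `"phn_evaluation"`).
#' @param truths an [annotation_catalog()] with the benchmark annotations.
#' @param term_universe ordered character vector of all terms; defaults to
#'   the truth catalog's universe.
#' @param k_max ladder cap, at most `length(term_universe)`; defaults to it.
#' @return object of class `"roc_curve"`: list with `points` (data.frame
#'   `K`, `fpr`, `tpr`), `auroc`, `k_max`, `n_proteins`.
#' @export
roc_curve <- function(ranked_lists, truths, term_universe = NULL,
                      k_max = NULL) {
  if (is.null(term_universe)) term_universe <- truths$term_universe
  if (!length(term_universe)) stop("empty term universe")
  if (is.null(k_max)) k_max <- length(term_universe)
  if (k_max > length(term_universe))
    stop("k_max exceeds the term universe size")
  universe_sorted <- sort(unique(term_universe))
  tpr <- matrix(0, nrow = k_max, ncol = 0L)
  fpr <- matrix(0, nrow = k_max, ncol = 0L)
  used <- character(0)
  for (u in names(ranked_lists)) {
    truth <- protein_terms(truths, u)
    if (!length(truth)) next
    rk <- ranked_lists[[u]]
    full <- c(rk, setdiff(universe_sorted, rk))[seq_len(k_max)]
    hit <- cumsum(full %in% truth)
    k <- seq_len(k_max)
    tpr <- cbind(tpr, hit / length(truth))
    fpr <- cbind(fpr, (k - hit) / (length(universe_sorted) - length(truth)))
    used <- c(used, u)
  }
  if (!ncol(tpr)) stop("no protein with nonempty truth in ranked_lists")
  pts <- data.frame(K = seq_len(k_max),
                    fpr = rowMeans(fpr), tpr = rowMeans(tpr))
  xs <- c(0, pts$fpr, 1)
  ys <- c(0, pts$tpr, 1)
  auroc <- sum(diff(xs) * (utils::head(ys, -1L) + utils::tail(ys, -1L)) / 2)
  structure(list(points = pts, auroc = auroc, k_max = k_max,
                 n_proteins = length(used)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: K = 1..%d over %d proteins, AUROC = %.4f\n",
              x$k_max, x$n_proteins, x$auroc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(c(0, x$points$fpr, 1), c(0, x$points$tpr, 1), type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("AUROC = %.3f", x$auroc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Sweep the topology/module blend weight beta
#'
#' Rebuilds the network and reruns the chosen cross-validation protocol for
#' each `beta`, producing the precision/recall/F-measure grid.
#'
#' @param graph,complexes,domains,annotations the dataset, as for [phn()].
#' @param betas numeric vector of blend weights in \[0, 1\].
#' @param protocol `"loocv"` or `"kfold"`.
#' @param alpha,lambda network parameters, see [phn()].
#' @param gamma,epsilon,max_iter propagation settings.
#' @param folds,repeats,seed k-fold settings (ignored for loocv).
#' @param ontology ontology label for the fits.
#' @return data.frame with columns `beta`, `precision`, `recall`,
#'   `f_measure`.
#' @export
beta_sweep <- function(graph, complexes, domains, annotations,
                       betas = seq(0, 1, by = 0.1),
                       protocol = c("loocv", "kfold"),
                       ontology = c("BP", "MF", "CC"),
                       alpha = 0.8, lambda = 0.2, gamma = 0.5,
                       epsilon = 1e-6, max_iter = 1000L,
                       folds = 10L, repeats = 1L, seed = 1L) {
  protocol <- match.arg(protocol)
  ontology <- match.arg(ontology)
  if (any(betas < 0 | betas > 1)) stop("beta values must lie in [0, 1]")
  rows <- lapply(betas, function(b) {
    fit <- phn(graph, complexes, domains, ontology = ontology,
               alpha = alpha, beta = b, lambda = lambda)
    rep <- if (protocol == "loocv")
      leave_one_out(fit, annotations, gamma = gamma, epsilon = epsilon,
                    max_iter = max_iter)
    else
      k_fold(fit, annotations, folds = folds, repeats = repeats,
             seed = seed, gamma = gamma, epsilon = epsilon,
             max_iter = max_iter)
    data.frame(beta = b, precision = rep$precision, recall = rep$recall,
               f_measure = rep$f_measure)
  })
  do.call(rbind, rows)
}
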