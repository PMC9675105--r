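# Term scoring from propagated partner scores and the top-L selection rule.

partner_scores <- function(pr, target, threshold = 0) {
  p <- pr$scores[seq_len(pr$n_proteins)]
  p <- p[p > threshold]
  p[names(p) != target]
}

#' Aggregate term scores from propagated partners
#'
#' The functional partners of `target` are the proteins with propagated
#' score above `threshold` (default exactly 0), excluding the target
#' itself.  Each candidate term's score is the sum of the scores of the
#' partners annotated with it; partners without annotations contribute no
#' terms but still count as partners.  Domain nodes never carry terms and
#' enter only through propagation.
#'
#' @param pr a `"score_vector"` from [propagate()].
#' @param annotations an [annotation_catalog()]; in evaluation settings it
#'   must already exclude the target's own annotations.
#' @param target target protein ID.
#' @param threshold partner score floor (exclusive), default 0.
#' @return object of class `"ranked_functions"`: list with `table`
#'   (data.frame `term`, `score`, ordered score descending then term ID
#'   ascending), `n_partners` and `candidates`.
#' @export
aggregate_function_scores <- function(pr, annotations, target,
                                      threshold = 0) {
  partners <- partner_scores(pr, target, threshold)
  tab <- data.frame(term = character(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  if (length(partners)) {
    terms_by_partner <- lapply(names(partners), protein_terms,
                               catalog = annotations)
    len <- lengths(terms_by_partner)
    if (sum(len)) {
      contrib <- rowsum(rep(unname(partners), len),
                        unlist(terms_by_partner, use.names = FALSE))
      tab <- data.frame(term = rownames(contrib), score = contrib[, 1L],
                        stringsAsFactors = FALSE)
      tab <- tab[order(-tab$score, tab$term), , drop = FALSE]
      rownames(tab) <- NULL
    }
  }
  structure(list(table = tab, n_partners = length(partners),
                 candidates = tab$term),
            class = "ranked_functions")
}

#' @export
print.ranked_functions <- function(x, ...) {
  cat(sprintf("ranked_functions: %d candidate terms from %d partners\n",
              nrow(x$table), x$n_partners))
  if (nrow(x$table)) print(utils::head(x$table, 10L))
  invisible(x)
}

#' Number of terms to predict (the L rule)
#'
#' `L` is the annotation count of the most functionally similar annotated
#' partner: among positive-score partners carrying at least one annotation,
#' the one with maximal propagated score; when several are tied at the top
#' score, the largest annotation count among them.  Returns 0 when no
#' annotated partner exists.
#'
#' @inheritParams aggregate_function_scores
#' @return integer count L.
#' @export
determine_L <- function(pr, annotations, target, threshold = 0) {
  partners <- partner_scores(pr, target, threshold)
  counts <- lengths(lapply(names(partners), protein_terms,
                           catalog = annotations))
  annotated <- counts > 0L
  if (!any(annotated)) return(0L)
  s <- partners[annotated]
  counts <- counts[annotated]
  top <- s == max(s)
  as.integer(max(counts[top]))
}

#' Predict functions for a target protein
#'
#' Full pipeline for one protein: restart vector ([initial_scores()]),
#' propagation ([propagate()]), term aggregation
#' ([aggregate_function_scores()]) and top-L selection ([determine_L()]).
#' The selected terms are the first `min(L, number of candidates)` rows of
#' the ranked list.
#'
#' @param target target protein ID.
#' @param fit a `"phn"` network bundle from [phn()].
#' @param annotations an [annotation_catalog()].  The target's own
#'   annotations are hidden automatically before scoring, so they can
#'   never leak into their own prediction.
#' @param gamma restart weight in \[0, 1\].
#' @param epsilon L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @param threshold partner score floor (exclusive).
#' @return object of class `"phn_prediction"`: list with `target`, `L`,
#'   `terms` (data.frame `rank`, `term`, `score`), the full `ranked` table,
#'   `n_partners`, `iterations`, `converged` and per-term `provenance`
#'   (contributing partners).
#' @export
predict_functions <- function(target, fit, annotations, gamma = 0.5,
                              epsilon = 1e-6, max_iter = 1000L,
                              threshold = 0) {
  if (!target %in% fit$proteins)
    stop("unknown protein: ", target)
  annotations <- hide_annotations(annotations, target)
  pr0 <- initial_scores(fit$mpp, fit$mpd, target)
  pr <- propagate(fit$transition, pr0, gamma = gamma, epsilon = epsilon,
                  max_iter = max_iter)
  ranked <- aggregate_function_scores(pr, annotations, target, threshold)
  L <- determine_L(pr, annotations, target, threshold)
  sel <- utils::head(ranked$table, L)
  terms <- if (nrow(sel))
    data.frame(rank = seq_len(nrow(sel)), term = sel$term, score = sel$score,
               stringsAsFactors = FALSE)
  else
    data.frame(rank = integer(0), term = character(0), score = numeric(0),
               stringsAsFactors = FALSE)
  partners <- partner_scores(pr, target, threshold)
  provenance <- lapply(terms$term, function(tm) {
    names(partners)[vapply(names(partners), function(p)
      tm %in% protein_terms(annotations, p), logical(1))]
  })
  names(provenance) <- terms$term
  structure(list(target = target, L = L, terms = terms,
                 ranked = ranked$table, n_partners = ranked$n_partners,
                 iterations = pr$iterations, converged = pr$converged,
                 provenance = provenance),
            class = "phn_prediction")
}

#' @export
print.phn_prediction <- function(x, ...) {
  cat(sprintf("phn_prediction for %s: L = %d, %d candidate terms, %d partners\n",
              x$target, x$L, nrow(x$ranked), x$n_partners))
  if (nrow(x$terms)) print(x$terms)
  invisible(x)
}
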