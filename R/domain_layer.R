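# Domain-side layers: binary protein-domain incidence and the domain-domain
# similarity derived from the weighted protein layer.

#' Build the binary protein-domain incidence matrix
#'
#' Records whose protein is absent from the protein index (i.e. not in the
#' PPI graph) are dropped with a warning, mirroring the restriction of
#' domain data to network proteins.  Domains are indexed in order of first
#' appearance among the retained records; every indexed domain therefore
#' has a nonempty protein list.
#'
#' @param table a [domain_table()].
#' @param proteins ordered protein index (e.g. `graph$proteins`).
#' @return object of class `"domain_incidence"`: list with the sparse binary
#'   `matrix` (proteins x domains, dimnames set), `proteins` and `domains`.
#' @export
build_domain_incidence <- function(table, proteins) {
  rec <- table$records
  known <- rec$protein %in% proteins
  if (any(!known))
    warning(sprintf("%d domain associations to proteins outside the network dropped",
                    sum(!known)))
  rec <- rec[known, , drop = FALSE]
  domains <- unique(rec$domain)
  m <- Matrix::sparseMatrix(i = match(rec$protein, proteins),
                            j = match(rec$domain, domains),
                            x = 1,
                            dims = c(length(proteins), length(domains)),
                            dimnames = list(proteins, domains))
  structure(list(matrix = m, proteins = proteins, domains = domains),
            class = "domain_incidence")
}

#' @export
print.domain_incidence <- function(x, ...) {
  cat(sprintf("domain_incidence: %d proteins x %d domains, %d associations\n",
              length(x$proteins), length(x$domains), sum(x$matrix)))
  invisible(x)
}

#' Protein list of a domain
#' @param mpd a `"domain_incidence"` object.
#' @param dn domain ID.
#' @return character vector of proteins carrying the domain.
#' @export
domain_protein_list <- function(mpd, dn) {
  j <- match(dn, mpd$domains)
  if (is.na(j)) stop("unknown domain: ", dn)
  mpd$proteins[mpd$matrix[, j] > 0]
}

#' Affinity between a protein and a protein list
#'
#' Maximum weighted-PPI weight between `u` and any member of `pl`.  When
#' `u` itself is in `pl` the self term contributes 0 through the zero
#' diagonal of the weighted matrix.
#'
#' @param mpp a `"weighted_ppi"` object.
#' @param u protein ID.
#' @param pl nonempty character vector of protein IDs.
#' @return the maximum weight (0 if no member is connected to `u`).
#' @export
protein_set_affinity <- function(mpp, u, pl) {
  if (!length(pl)) stop("protein list is empty: a domain must have proteins")
  if (!u %in% mpp$proteins) stop("unknown protein: ", u)
  if (any(!pl %in% mpp$proteins)) stop("protein list contains unknown proteins")
  max(mpp$weights[u, pl])
}

# per-domain aggregates of Eq 5: a = sum over PL of the within-list affinity,
# s = |PL|
domain_affinity_aggregates <- function(mpp, mpd) {
  if (!identical(mpp$proteins, mpd$proteins))
    stop("protein indices of weighted PPI and domain incidence differ")
  nd <- length(mpd$domains)
  a <- numeric(nd)
  s <- numeric(nd)
  for (j in seq_len(nd)) {
    pl <- which(mpd$matrix[, j] > 0)
    s[j] <- length(pl)
    sub <- as.matrix(mpp$weights[pl, pl, drop = FALSE])
    a[j] <- sum(apply(sub, 1L, max))
  }
  list(a = a, s = s)
}

#' Similarity between two domains
#'
#' `(sum_{p in PL_i} S_PD(p, PL_i) + sum_{q in PL_j} S_PD(q, PL_j)) /
#' (|PL_i| + |PL_j|)` where `S_PD` is [protein_set_affinity()].  Note the
#' formula compares each protein only to its own domain's list, so the value
#' depends on the two domains only through their per-domain aggregates.
#' Defined for `i == j` as well (the within-domain cohesion).
#'
#' @param mpp a `"weighted_ppi"` object.
#' @param mpd a `"domain_incidence"` object on the same protein index.
#' @param dn_i,dn_j domain IDs.
#' @return similarity in \[0, 1\].
#' @export
domain_similarity <- function(mpp, mpd, dn_i, dn_j) {
  i <- match(dn_i, mpd$domains)
  j <- match(dn_j, mpd$domains)
  if (is.na(i)) stop("unknown domain: ", dn_i)
  if (is.na(j)) stop("unknown domain: ", dn_j)
  ag <- domain_affinity_aggregates(mpp, mpd)
  (ag$a[i] + ag$a[j]) / (ag$s[i] + ag$s[j])
}

#' Build the domain-domain similarity layer
#'
#' Evaluates [domain_similarity()] for every domain pair.  The diagonal is
#' computed by the same formula but set to 0 before use: self-transitions
#' would trap probability mass during propagation, and the layer feeds a
#' transition matrix that models inter-domain movement (standard practice
#' for random walks with restart).
#'
#' @param mpp a `"weighted_ppi"` object.
#' @param mpd a `"domain_incidence"` object on the same protein index.
#' @return object of class `"domain_similarity"`: list with the symmetric
#'   dense `matrix` (dimnames = domain IDs, zero diagonal) and `domains`.
#' @export
build_domain_similarity <- function(mpp, mpd) {
  ag <- domain_affinity_aggregates(mpp, mpd)
  nd <- length(mpd$domains)
  m <- (outer(ag$a, ag$a, `+`)) / (outer(ag$s, ag$s, `+`))
  if (!nd) m <- matrix(numeric(0), 0L, 0L)
  diag(m) <- 0
  dimnames(m) <- list(mpd$domains, mpd$domains)
  structure(list(matrix = m, domains = mpd$domains),
            class = "domain_similarity")
}

#' @export
print.domain_similarity <- function(x, ...) {
  cat(sprintf("domain_similarity: %d domains, mean off-diagonal %.4f\n",
              length(x$domains),
              if (length(x$domains) > 1L)
                mean(x$matrix[row(x$matrix) != col(x$matrix)]) else 0))
  invisible(x)
}
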