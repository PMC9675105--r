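# Planted-module synthetic data generator.
#
# Emulates the statistical structure the propagation model assumes: proteins
# grouped into function-coherent complexes (dense intra-complex interaction),
# domains correlated with complex membership, and GO terms shared within a
# complex.  Noise knobs (background edges, domain leakage, term noise) let
# tests move continuously from a perfectly recoverable planted signal to a
# null regime.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a small yeast-like benchmark: 60 proteins, 8
#' non-overlapping complexes of 5-7 members, dense intra-complex interaction
#' (`p_intra = 0.9`) over a sparse background (`p_background = 0.02`), two
#' Pfam-like domains and three GO terms planted per complex, with 10% of
#' domain assignments leaking to random proteins and 10% of annotations
#' replaced by random terms.
#'
#' @param n_proteins number of proteins.
#' @param n_complexes number of planted complexes.
#' @param complex_size_range integer `(min, max)` of complex sizes; sizes are
#'   drawn uniformly from this range.
#' @param p_intra probability of an edge between two co-complex proteins.
#' @param p_background probability of an edge between any other pair.
#' @param n_domains size of the domain pool.
#' @param domains_per_complex domains planted per complex.
#' @param domain_leakage probability that a single protein-domain assignment
#'   is rerouted to a uniformly random protein.
#' @param n_terms size of the GO term pool.
#' @param terms_per_complex terms planted per complex.
#' @param term_noise probability that a single annotation is replaced by a
#'   uniformly random term; also the probability that a protein outside all
#'   complexes receives one random annotation.
#' @param seed integer seed; the same seed always yields a byte-identical
#'   dataset.
#' @param allow_overlap if `TRUE` each complex additionally adopts one
#'   member from outside its block, so complexes overlap.
#' @return object of class `"synthetic_config"` (a validated list).
#' @export
synthetic_config <- function(n_proteins = 60, n_complexes = 8,
                             complex_size_range = c(5, 7),
                             p_intra = 0.9, p_background = 0.02,
                             n_domains = 16, domains_per_complex = 2,
                             domain_leakage = 0.1,
                             n_terms = 24, terms_per_complex = 3,
                             term_noise = 0.1, seed = 1,
                             allow_overlap = FALSE) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_complexes = as.integer(n_complexes),
              complex_size_range = as.integer(complex_size_range),
              p_intra = p_intra, p_background = p_background,
              n_domains = as.integer(n_domains),
              domains_per_complex = as.integer(domains_per_complex),
              domain_leakage = domain_leakage,
              n_terms = as.integer(n_terms),
              terms_per_complex = as.integer(terms_per_complex),
              term_noise = term_noise, seed = as.integer(seed),
              allow_overlap = isTRUE(allow_overlap))
  probs <- c(cfg$p_intra, cfg$p_background, cfg$domain_leakage, cfg$term_noise)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  counts <- c(cfg$n_proteins, cfg$n_complexes, cfg$n_domains, cfg$n_terms,
              cfg$domains_per_complex, cfg$terms_per_complex)
  if (any(counts < 1L)) stop("counts must be positive")
  if (length(cfg$complex_size_range) != 2L ||
      cfg$complex_size_range[1L] < 1L ||
      cfg$complex_size_range[1L] > cfg$complex_size_range[2L])
    stop("complex_size_range must be an increasing positive pair")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic dataset with planted functional modules
#'
#' Proteins are partitioned into complexes whose sizes are drawn from the
#' configured range; edges are sampled Bernoulli(`p_intra`) within a complex
#' and Bernoulli(`p_background`) elsewhere; each complex is assigned
#' `domains_per_complex` domains and `terms_per_complex` terms which are
#' given to all of its members, with the configured leakage/noise applied
#' per assignment.  Proteins left outside every complex receive only
#' background edges and (with probability `term_noise`) one random
#' annotation, so the empty-membership code paths are always exercised.
#'
#' @param config a [synthetic_config()].
#' @return object of class `"phn_dataset"`: a list with elements `graph`
#'   ([ppi_graph()]), `complexes` ([complex_catalog()]), `domains`
#'   ([domain_table()]), `annotations` ([annotation_catalog()], aspect BP)
#'   and the `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    proteins <- sprintf("P%03d", seq_len(config$n_proteins))
    domains <- sprintf("PF%05d", seq_len(config$n_domains))
    terms <- sprintf("GO:%07d", seq_len(config$n_terms))
    cids <- sprintf("CPX%02d", seq_len(config$n_complexes))

    size_values <- seq(config$complex_size_range[1L],
                       config$complex_size_range[2L])
    sizes <- size_values[sample.int(length(size_values), config$n_complexes,
                                    replace = TRUE)]
    if (sum(sizes) > config$n_proteins)
      stop(sprintf("infeasible config: drawn complex sizes sum to %d > %d proteins",
                   sum(sizes), config$n_proteins))
    shuffled <- sample(proteins)
    stops <- cumsum(sizes)
    members <- lapply(seq_along(sizes), function(k) {
      shuffled[(c(0L, stops)[k] + 1L):stops[k]]
    })
    names(members) <- cids
    if (config$allow_overlap) {
      members <- lapply(cids, function(cid) {
        outside <- setdiff(proteins, members[[cid]])
        c(members[[cid]], sample(outside, 1L))
      })
      names(members) <- cids
    }
    catalog <- complex_catalog(members)

    # edges over all unordered pairs; co-complex pairs use p_intra
    pair <- utils::combn(proteins, 2L)
    share <- vapply(seq_len(ncol(pair)), function(k) {
      length(intersect(complex_membership(catalog, pair[1L, k]),
                       complex_membership(catalog, pair[2L, k]))) > 0L
    }, logical(1))
    p <- ifelse(share, config$p_intra, config$p_background)
    drawn <- runif(ncol(pair)) < p
    graph <- ppi_graph(proteins, t(pair[, drawn, drop = FALSE]))

    # domains planted per complex (pool cycled in shuffled order)
    need <- config$n_complexes * config$domains_per_complex
    pool <- sample(domains)[(seq_len(need) - 1L) %% config$n_domains + 1L]
    cx_domains <- split(pool, rep(cids, each = config$domains_per_complex))
    rec_p <- character(0); rec_d <- character(0)
    for (cid in cids) {
      m <- members[[cid]]
      for (d in cx_domains[[cid]]) {
        rec_p <- c(rec_p, m)
        rec_d <- c(rec_d, rep(d, length(m)))
      }
    }
    leak <- runif(length(rec_p)) < config$domain_leakage
    if (any(leak))
      rec_p[leak] <- sample(proteins, sum(leak), replace = TRUE)
    dom_tab <- domain_table(data.frame(protein = rec_p, domain = rec_d,
                                       stringsAsFactors = FALSE))

    # terms planted per complex, same pattern
    need_t <- config$n_complexes * config$terms_per_complex
    pool_t <- sample(terms)[(seq_len(need_t) - 1L) %% config$n_terms + 1L]
    cx_terms <- split(pool_t, rep(cids, each = config$terms_per_complex))
    ann_p <- character(0); ann_t <- character(0)
    for (cid in cids) {
      m <- members[[cid]]
      for (tm in cx_terms[[cid]]) {
        ann_p <- c(ann_p, m)
        ann_t <- c(ann_t, rep(tm, length(m)))
      }
    }
    noisy <- runif(length(ann_t)) < config$term_noise
    if (any(noisy))
      ann_t[noisy] <- sample(terms, sum(noisy), replace = TRUE)
    leftovers <- setdiff(proteins, unlist(members, use.names = FALSE))
    for (p0 in leftovers) {
      if (runif(1L) < config$term_noise) {
        ann_p <- c(ann_p, p0)
        ann_t <- c(ann_t, sample(terms, 1L))
      }
    }
    annotations <- annotation_catalog("BP", split(ann_t, ann_p))

    structure(list(graph = graph, complexes = catalog, domains = dom_tab,
                   annotations = annotations, config = config),
              class = "phn_dataset")
  })
}

#' @export
print.phn_dataset <- function(x, ...) {
  s <- dataset_summary(x)
  cat("phn_dataset (synthetic)\n")
  for (k in names(s)) cat(sprintf("  %-20s %s\n", k, format(s[[k]])))
  invisible(x)
}

#' Summarise a synthetic dataset
#'
#' Counts of proteins, edges, complexes, distinct associated domains and
#' annotated terms, plus the annotation density, i.e. the number of
#' (protein, term) pairs divided by `n_proteins * |term universe|` (0 when
#' the catalog is empty).
#'
#' @param dataset a `"phn_dataset"` from [generate_dataset()].
#' @return named list of counts.
#' @export
dataset_summary <- function(dataset) {
  ann <- dataset$annotations
  n_pairs <- sum(lengths(ann$annotations))
  n_terms <- length(ann$term_universe)
  n_prot <- length(dataset$graph$proteins)
  list(proteins = n_prot,
       edges = nrow(dataset$graph$edges),
       complexes = length(dataset$complexes$complexes),
       domains = length(unique(dataset$domains$records$domain)),
       terms = n_terms,
       annotated_proteins = length(ann$annotations),
       annotation_density = if (n_terms == 0L) 0 else
         n_pairs / (n_prot * n_terms))
}

#' Write a synthetic dataset to the four standard files
#'
#' Writes `ppi.tsv`, `complexes.tsv`, `domains.tsv`, `annotations.gaf` and a
#' JSON sidecar `config.json` recording the generating configuration.
#' @param dataset a `"phn_dataset"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             complexes = file.path(dir, "complexes.tsv"),
             domains = file.path(dir, "domains.tsv"),
             gaf = file.path(dir, "annotations.gaf"),
             config = file.path(dir, "config.json"))
  write_ppi_edgelist(dataset$graph, paths[["ppi"]])
  write_complex_catalog(dataset$complexes, paths[["complexes"]])
  write_domain_associations(dataset$domains, paths[["domains"]])
  write_gaf(dataset$annotations, paths[["gaf"]])
  jsonlite::write_json(unclass(dataset$config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
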