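# ---- constructors ---------------------------------------------------------

#' Protein-protein interaction graph
#'
#' An undirected simple graph over opaque, case-sensitive protein IDs.
#' Edges are stored canonically (lexicographically smaller endpoint first);
#' self-pairs and duplicate pairs are rejected.  Isolated proteins are
#' allowed so that synthetic datasets can carry unconnected proteins.
#'
#' @param proteins character vector of unique protein IDs; their order fixes
#'   all downstream matrix row/column indices.
#' @param edges two-column character matrix (or data.frame) of endpoints.
#' @return An object of class `"ppi_graph"` with elements `proteins` and
#'   `edges` (canonical two-column character matrix).
#' @export
ppi_graph <- function(proteins, edges = NULL) {
  proteins <- as.character(proteins)
  if (anyDuplicated(proteins))
    stop("duplicate protein IDs in protein list")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2L) stop("edges must have two columns")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-pairs are not allowed")
    lo <- pmin(edges[, 1L], edges[, 2L])
    hi <- pmax(edges[, 1L], edges[, 2L])
    edges <- cbind(lo, hi, deparse.level = 0L)
    if (anyDuplicated(paste(lo, hi, sep = "\r")))
      stop("duplicate edges are not allowed")
    missing <- setdiff(c(lo, hi), proteins)
    if (length(missing))
      stop("edge endpoints absent from protein list: ",
           paste(utils::head(missing, 5L), collapse = ", "))
  }
  dimnames(edges) <- NULL
  structure(list(proteins = proteins, edges = edges), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("ppi_graph: %d proteins, %d undirected edges\n",
              length(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' Protein complex catalog
#'
#' @param complexes named list mapping complex ID to a character vector of
#'   member protein IDs (each complex must have at least one member).
#' @return Object of class `"complex_catalog"` with the complex list and the
#'   inverse `membership` index (protein ID -> complex IDs).
#' @export
complex_catalog <- function(complexes) {
  if (length(complexes) && is.null(names(complexes)))
    stop("complexes must be a named list")
  complexes <- lapply(complexes, function(m) unique(as.character(m)))
  if (any(lengths(complexes) == 0L))
    stop("every complex must have at least one member")
  membership <- list()
  for (cid in names(complexes)) {
    for (p in complexes[[cid]]) membership[[p]] <- c(membership[[p]], cid)
  }
  structure(list(complexes = complexes, membership = membership),
            class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("complex_catalog: %d complexes, %d member proteins\n",
              length(x$complexes), length(x$membership)))
  invisible(x)
}

#' Complex membership of a protein
#'
#' Set of complex IDs containing `u`; empty for proteins in no complex.
#' @param catalog a [complex_catalog()].
#' @param u protein ID.
#' @return character vector of complex IDs (possibly empty).
#' @export
complex_membership <- function(catalog, u) {
  m <- catalog$membership[[u]]
  if (is.null(m)) character(0) else m
}

#' Gene Ontology annotation catalog
#'
#' Flat protein -> term-set map for one ontology aspect.  Term sets are kept
#' sorted and the term universe is the sorted union of all sets, so equal
#' contents always produce identical objects.
#'
#' @param ontology one of `"BP"`, `"MF"`, `"CC"`.
#' @param annotations named list mapping protein ID to a character vector of
#'   GO term IDs; proteins with empty sets are dropped.
#' @return Object of class `"annotation_catalog"`.
#' @export
annotation_catalog <- function(ontology = c("BP", "MF", "CC"),
                               annotations = list()) {
  ontology <- match.arg(ontology)
  annotations <- lapply(annotations, function(t) sort(unique(as.character(t))))
  annotations <- annotations[lengths(annotations) > 0L]
  if (length(annotations)) annotations <- annotations[order(names(annotations))]
  universe <- sort(unique(unlist(annotations, use.names = FALSE)))
  if (is.null(universe)) universe <- character(0)
  structure(list(ontology = ontology, annotations = annotations,
                 term_universe = universe),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("annotation_catalog [%s]: %d annotated proteins, %d terms\n",
              x$ontology, length(x$annotations), length(x$term_universe)))
  invisible(x)
}

#' Terms annotated to a protein
#' @param catalog an [annotation_catalog()].
#' @param u protein ID.
#' @return sorted character vector of term IDs (possibly empty).
#' @export
protein_terms <- function(catalog, u) {
  t <- catalog$annotations[[u]]
  if (is.null(t)) character(0) else t
}

#' Hide the annotations of a set of proteins
#'
#' Used by the cross-validation protocols: the returned catalog carries no
#' annotations for `proteins`, so term scoring cannot see the test set.
#' @param catalog an [annotation_catalog()].
#' @param proteins protein IDs whose annotations are removed.
#' @return a new [annotation_catalog()].
#' @export
hide_annotations <- function(catalog, proteins) {
  keep <- setdiff(names(catalog$annotations), proteins)
  annotation_catalog(catalog$ontology, catalog$annotations[keep])
}

#' Permute annotation sets across proteins
#'
#' Null model for calibration: the per-protein term sets are randomly
#' reassigned among the annotated proteins, destroying any relationship
#' between network position and function while preserving the annotation
#' size distribution and the term universe.
#' @param catalog an [annotation_catalog()].
#' @param seed integer seed for the permutation.
#' @return a permuted [annotation_catalog()].
#' @export
permute_annotations <- function(catalog, seed) {
  with_seed(seed, {
    ids <- names(catalog$annotations)
    perm <- sample(ids)
    ann <- catalog$annotations
    names(ann) <- perm
    annotation_catalog(catalog$ontology, ann)
  })
}

#' Protein-domain association table
#'
#' @param records data.frame (or two-column object) with columns `protein`
#'   and `domain`; duplicate pairs are collapsed.
#' @return Object of class `"domain_table"` with the deduplicated `records`
#'   data.frame.
#' @export
domain_table <- function(records = NULL) {
  if (is.null(records) || NROW(records) == 0L) {
    records <- data.frame(protein = character(0), domain = character(0),
                          stringsAsFactors = FALSE)
  } else {
    records <- data.frame(protein = as.character(records[[1L]]),
                          domain = as.character(records[[2L]]),
                          stringsAsFactors = FALSE)
    records <- records[!duplicated(paste(records$protein, records$domain,
                                         sep = "\r")), , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(records = records), class = "domain_table")
}

#' @export
print.domain_table <- function(x, ...) {
  cat(sprintf("domain_table: %d protein-domain associations (%d domains)\n",
              nrow(x$records), length(unique(x$records$domain))))
  invisible(x)
}

# ---- readers --------------------------------------------------------------

read_tsv_lines <- function(path, comment = "#") {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, comment)
  list(lines = lines[keep], numbers = which(keep))
}

#' Read a PPI edge list
#'
#' Two(or more)-column tab-separated file, one undirected interaction per
#' line; extra columns are ignored.  Self-interactions are dropped and
#' repeated interactions (in either orientation) are collapsed, mirroring
#' the standard preparation of interaction downloads.  Protein order is the
#' order of first appearance in the file, which makes every downstream
#' matrix deterministic.
#'
#' @param path file path.
#' @return a [ppi_graph()].
#' @export
read_ppi_edgelist <- function(path) {
  tl <- read_tsv_lines(path)
  if (!length(tl$lines))
    stop("empty PPI edge list: ", path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop(sprintf("malformed PPI line %d in %s: expected >= 2 tab-separated fields",
                 tl$numbers[bad], path))
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  proteins <- unique(as.vector(rbind(a, b)))
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  first <- !duplicated(paste(lo, hi, sep = "\r"))
  ppi_graph(proteins, cbind(lo[first], hi[first]))
}

#' Write a PPI edge list
#'
#' Inverse of [read_ppi_edgelist()]; isolated proteins cannot be represented
#' in the two-column format and are silently omitted.
#' @param graph a [ppi_graph()].
#' @param path output path.
#' @export
write_ppi_edgelist <- function(graph, path) {
  writeLines(paste(graph$edges[, 1L], graph$edges[, 2L], sep = "\t"), path)
  invisible(NULL)
}

#' Read a protein complex catalog
#'
#' One complex per line: first tab-separated field is the complex ID, the
#' remaining fields are member protein IDs (CYC2008-style).
#' @param path file path.
#' @return a [complex_catalog()].
#' @export
read_complex_catalog <- function(path) {
  tl <- read_tsv_lines(path)
  if (!length(tl$lines)) return(complex_catalog(list()))
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop(sprintf("complex with zero members at line %d in %s",
                 tl$numbers[bad], path))
  }
  complexes <- stats::setNames(lapply(fields, `[`, -1L),
                               vapply(fields, `[[`, character(1), 1L))
  complex_catalog(complexes)
}

#' Write a protein complex catalog
#' @param catalog a [complex_catalog()].
#' @param path output path.
#' @export
write_complex_catalog <- function(catalog, path) {
  writeLines(vapply(names(catalog$complexes), function(cid) {
    paste(c(cid, catalog$complexes[[cid]]), collapse = "\t")
  }, character(1)), path)
  invisible(NULL)
}

#' Read GO annotations from a GAF 2.x file
#'
#' Keeps only rows whose aspect column matches the requested ontology
#' (`BP` -> `P`, `MF` -> `F`, `CC` -> `C`), drops rows whose qualifier
#' contains `NOT` (standard GAF semantics), and collapses duplicates.
#' Comment lines start with `!`.  Terms are treated as flat labels: no
#' ontology-hierarchy propagation is performed.
#'
#' @param path file path.
#' @param ontology one of `"BP"`, `"MF"`, `"CC"`.
#' @return an [annotation_catalog()].
#' @export
read_gaf <- function(path, ontology = c("BP", "MF", "CC")) {
  ontology <- match.arg(ontology)
  aspect_wanted <- c(BP = "P", MF = "F", CC = "C")[[ontology]]
  tl <- read_tsv_lines(path, comment = "!")
  ann <- list()
  if (length(tl$lines)) {
    fields <- strsplit(tl$lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9L)) {
      bad <- which(nf < 9L)[1L]
      stop(sprintf("malformed GAF line %d in %s: expected >= 9 columns",
                   tl$numbers[bad], path))
    }
    id <- vapply(fields, `[[`, character(1), 2L)
    qualifier <- vapply(fields, `[[`, character(1), 4L)
    term <- vapply(fields, `[[`, character(1), 5L)
    aspect <- vapply(fields, `[[`, character(1), 9L)
    unknown <- !aspect %in% c("P", "F", "C")
    if (any(unknown)) {
      bad <- which(unknown)[1L]
      stop(sprintf("unknown GAF aspect code '%s' at line %d in %s",
                   aspect[bad], tl$numbers[bad], path))
    }
    negated <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                      function(q) any(q == "NOT"), logical(1))
    keep <- aspect == aspect_wanted & !negated
    ann <- split(term[keep], id[keep])
  }
  annotation_catalog(ontology, ann)
}

#' Write an annotation catalog as a minimal GAF 2.2 file
#' @param catalog an [annotation_catalog()].
#' @param path output path.
#' @export
write_gaf <- function(catalog, path) {
  aspect <- c(BP = "P", MF = "F", CC = "C")[[catalog$ontology]]
  rows <- unlist(lapply(names(catalog$annotations), function(p) {
    paste("SYN", p, p, "", catalog$annotations[[p]], "SYN:0000001", "IEA",
          "", aspect, "", "", "protein", "taxon:559292", "20220825", "SYN",
          "", "", sep = "\t")
  }), use.names = FALSE)
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(NULL)
}

#' Read a protein-domain association table
#'
#' Two-column tab-separated file (protein ID, domain accession); duplicate
#' pairs are collapsed.
#' @param path file path.
#' @return a [domain_table()].
#' @export
read_domain_associations <- function(path) {
  tl <- read_tsv_lines(path)
  if (!length(tl$lines)) return(domain_table())
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop(sprintf("missing column at line %d in %s: expected protein and domain",
                 tl$numbers[bad], path))
  }
  domain_table(data.frame(protein = vapply(fields, `[[`, character(1), 1L),
                          domain = vapply(fields, `[[`, character(1), 2L),
                          stringsAsFactors = FALSE))
}

#' Write a protein-domain association table
#' @param table a [domain_table()].
#' @param path output path.
#' @export
write_domain_associations <- function(table, path) {
  writeLines(paste(table$records$protein, table$records$domain, sep = "\t"),
             path)
  invisible(NULL)
}

#' Write ranked per-protein predictions
#'
#' Four-column TSV (`protein`, `rank`, `term`, `score`).  Within a protein
#' the rows are ordered by score descending, ties broken by term ID
#' ascending; proteins appear in input order.  Scores are printed with 17
#' significant digits so that a round trip reproduces the doubles exactly.
#'
#' @param predictions a named list mapping protein ID to a data.frame with
#'   columns `term` and `score`, or a single `phn_prediction` /
#'   list of `phn_prediction` objects.
#' @param path output path.
#' @export
write_prediction_table <- function(predictions, path) {
  if (inherits(predictions, "phn_prediction")) predictions <- list(predictions)
  tabs <- lapply(predictions, function(p) {
    if (inherits(p, "phn_prediction")) p$terms[, c("term", "score")] else
      as.data.frame(p)[, c("term", "score")]
  })
  ids <- names(predictions)
  if (is.null(ids))
    ids <- vapply(predictions, function(p) p$target, character(1))
  header <- "protein\trank\tterm\tscore"
  rows <- unlist(lapply(seq_along(tabs), function(i) {
    tab <- tabs[[i]]
    if (!nrow(tab)) return(character(0))
    if (any(!is.finite(tab$score)) || any(tab$score < 0))
      stop("prediction scores must be finite and nonnegative")
    ord <- order(-tab$score, tab$term)
    tab <- tab[ord, , drop = FALSE]
    paste(ids[i], seq_len(nrow(tab)), tab$term,
          sprintf("%.17g", tab$score), sep = "\t")
  }), use.names = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(NULL)
}

#' Read a prediction table written by [write_prediction_table()]
#' @param path file path.
#' @return named list of data.frames with columns `term` and `score`.
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "numeric"))
  out <- lapply(split(df[, c("term", "score")], factor(df$protein,
                levels = unique(df$protein))), function(d) {
    rownames(d) <- NULL
    d
  })
  out[unique(df$protein)]
}
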