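#' Read a minimal OBO 1.2 ontology
#'
#' Parses \code{[Term]} stanzas for \code{id}, \code{name} and \code{is_a}
#' parent relations (trailing \code{! comment} stripped). Obsolete terms are
#' dropped. Only \code{is_a} edges are kept; \code{part_of} and other
#' relationship types are ignored, giving the smallest defensible ancestor
#' closure.
#'
#' @param path Path to an OBO file.
#' @return List of class \code{ontology}: \code{terms} (character vector of
#'   ids), \code{names} (named character), \code{parents} (named list of
#'   character vectors of direct is_a parents).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) pc_stop("OBO file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  terms <- character(0); nm <- character(0)
  parents <- list()
  cur_id <- NA_character_; cur_name <- NA_character_
  cur_parents <- character(0); cur_obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (in_term && !is.na(cur_id) && !cur_obsolete) {
      terms[[length(terms) + 1L]] <<- cur_id
      nm[[cur_id]] <<- if (is.na(cur_name)) cur_id else cur_name
      parents[[cur_id]] <<- cur_parents
    }
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur_id <- NA_character_; cur_name <- NA_character_
      cur_parents <- character(0); cur_obsolete <- FALSE
    } else if (grepl("^\\[", ln)) {   # [Typedef] etc.
      flush(); in_term <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id: ")) cur_id <- sub("^id: *", "", ln)
      else if (startsWith(ln, "name: ")) cur_name <- sub("^name: *", "", ln)
      else if (startsWith(ln, "is_a: ")) {
        p <- sub("^is_a: *", "", ln)
        p <- sub(" *!.*$", "", p)
        cur_parents <- c(cur_parents, trimws(p))
      } else if (grepl("^is_obsolete: *true", ln)) cur_obsolete <- TRUE
    }
  }
  flush()
  structure(list(terms = unlist(terms), names = nm, parents = parents),
            class = "ontology")
}

#' All ancestors of a term (is_a closure, excluding the term itself)
#'
#' @param term_id Term identifier.
#' @param ontology An \code{ontology} object.
#' @return Character vector of ancestor term ids.
#' @export
term_ancestors <- function(term_id, ontology) {
  seen <- character(0)
  frontier <- ontology$parents[[term_id]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
  }
  seen
}

#' Read a two-column gene-to-term mapping
#'
#' @param path Tab-separated file: gene id, term id. Lines starting
#'   \code{#} are skipped.
#' @return data.frame with columns \code{gene_id}, \code{term_id}
#'   (duplicates removed).
#' @export
read_gene2term <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           colClasses = "character",
                           col.names = c("gene_id", "term_id"))
  unique(tab)
}

#' Gene-to-term mapping with ancestor propagation
#'
#' Annotations are propagated upward: a gene annotated to a term is also
#' counted for every is_a ancestor of that term, the standard convention for
#' GO over-representation.
#'
#' @param gene2term data.frame from \code{\link{read_gene2term}}.
#' @param ontology Optional \code{ontology}; when \code{NULL}, no
#'   propagation is done.
#' @return Named list: gene id -> character vector of (closed) term ids.
#' @export
gene_term_closure <- function(gene2term, ontology = NULL) {
  direct <- split(gene2term$term_id, gene2term$gene_id)
  if (is.null(ontology)) return(lapply(direct, unique))
  anc_cache <- new.env(parent = emptyenv())
  closed_terms <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    v <- c(t, term_ancestors(t, ontology))
    anc_cache[[t]] <- v
    v
  }
  lapply(direct, function(ts) unique(unlist(lapply(unique(ts), closed_terms))))
}

#' Nearest-gene set of a locus set
#'
#' @param contexts A \code{locus_context} data.frame.
#' @param label Label for the gene set.
#' @return List of class \code{gene_set}: \code{label}, \code{gene_ids}
#'   (deduplicated, \code{NA} dropped).
#' @export
nearest_gene_set <- function(contexts, label = "genes") {
  ids <- unique(contexts$nearest_gene)
  ids <- ids[!is.na(ids)]
  structure(list(label = label, gene_ids = ids), class = "gene_set")
}

#' Term-for-term GO over-representation
#'
#' For each term, tests over-representation of the term among the study
#' genes relative to the population genes with a one-sided hypergeometric
#' test: \eqn{p = P(X \ge study\_hits)} when drawing \code{study_size} genes
#' from a population of \code{pop_size} containing \code{pop_hits} annotated
#' genes. Terms are tested independently of the GO graph structure
#' (term-for-term); annotations are first propagated to ancestors when an
#' ontology is supplied. P-values are Benjamini-Hochberg adjusted across the
#' tested terms and results are sorted by p-value.
#'
#' Both gene sets are intersected with the mapped genes; study genes absent
#' from the population are dropped with a warning.
#'
#' @param study,population \code{gene_set} objects (or character vectors of
#'   gene ids); the study set should be a subset of the population.
#' @param gene2term data.frame from \code{\link{read_gene2term}}.
#' @param ontology Optional \code{ontology} for ancestor propagation.
#' @return data.frame with one row per term with \code{pop_hits >= 1}:
#'   \code{term_id}, \code{term_name}, \code{study_hits},
#'   \code{study_size}, \code{pop_hits}, \code{pop_size}, \code{p_value},
#'   \code{p_adjusted}, sorted by \code{p_value}.
#' @export
term_for_term <- function(study, population, gene2term, ontology = NULL) {
  study_ids <- if (inherits(study, "gene_set")) study$gene_ids else unique(as.character(study))
  pop_ids <- if (inherits(population, "gene_set")) population$gene_ids else unique(as.character(population))
  closure <- gene_term_closure(gene2term, ontology)
  mapped <- names(closure)
  pop_ids <- intersect(pop_ids, mapped)
  study_ids <- intersect(study_ids, mapped)
  lost <- setdiff(study_ids, pop_ids)
  if (length(lost)) {
    pc_warn("%d study gene(s) absent from the population were dropped", length(lost))
    study_ids <- intersect(study_ids, pop_ids)
  }
  if (length(pop_ids) == 0L) pc_stop("empty effective population gene set")
  if (length(study_ids) == 0L) pc_stop("empty effective study gene set")
  pop_size <- length(pop_ids); study_size <- length(study_ids)

  term_genes <- .invert_closure(closure, pop_ids)
  study_lookup <- stats::setNames(rep(TRUE, study_size), study_ids)
  rows <- lapply(names(term_genes), function(t) {
    genes <- term_genes[[t]]
    pop_hits <- length(genes)
    study_hits <- sum(!is.na(study_lookup[genes]))
    p <- stats::phyper(study_hits - 1, m = pop_hits, n = pop_size - pop_hits,
                       k = study_size, lower.tail = FALSE)
    data.frame(term_id = t, study_hits = study_hits, study_size = study_size,
               pop_hits = pop_hits, pop_size = pop_size, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  term_name <- if (!is.null(ontology)) {
    unname(ifelse(res$term_id %in% names(ontology$names),
                  ontology$names[res$term_id], res$term_id))
  } else res$term_id
  res$term_name <- term_name
  res$p_adjusted <- adjust_pvalues(res$p_value, method = "bh")
  res <- res[order(res$p_value, res$term_id), ]
  rownames(res) <- NULL
  res[, c("term_id", "term_name", "study_hits", "study_size",
          "pop_hits", "pop_size", "p_value", "p_adjusted")]
}

# term id -> vector of population genes annotated (after closure) to it
.invert_closure <- function(closure, pop_ids) {
  closure <- closure[pop_ids]
  genes <- rep(names(closure), vapply(closure, length, integer(1)))
  terms <- unlist(closure, use.names = FALSE)
  split(genes, terms)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up or Bonferroni correction, input order
#' preserved and adjusted values clipped to [0, 1].
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method \code{"bh"} or \code{"bonferroni"}.
#' @return Adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) pc_stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}
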