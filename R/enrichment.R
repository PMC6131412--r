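# GO-term enrichment by the Parent-Child-Union test: each term's
# hypergeometric test is conditioned on the genes annotated to the union of
# its parent terms, which corrects the inheritance cascade that plain
# term-by-term testing suffers from.  Minimal OBO I/O, true-path propagation
# and BH correction included.

#' Construct and validate an is_a ontology DAG
#'
#' @param terms character vector of term ids.
#' @param parents named list mapping each term to its parent term ids; exactly
#'   one term (the root) has no parents, and every term must reach the root.
#' @return list of class `ontology` with `terms`, `parents`, `root`.
#' @export
ontology <- function(terms, parents) {
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) if (is.null(p)) character() else p)
  roots <- terms[lengths(parents) == 0]
  if (length(roots) != 1)
    stop("ontology: expected exactly one root, found ", length(roots))
  unknown <- setdiff(unlist(parents), terms)
  if (length(unknown))
    stop("ontology: parent term(s) not in term list: ",
         paste(unknown, collapse = ", "))
  ont <- structure(list(terms = terms, parents = parents, root = roots),
                   class = "ontology")
  .ancestors(ont)  # errors on cycles
  ont
}

# memoized ancestor sets (exclusive of the term itself); DFS with cycle
# detection that names an offending edge
.ancestors <- function(ont) {
  anc <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  visit <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    if (isTRUE(state[[t]]))
      stop("ontology: cycle detected through edge into '", t, "'")
    state[[t]] <- TRUE
    ps <- ont$parents[[t]]
    res <- unique(c(ps, unlist(lapply(ps, visit))))
    state[[t]] <- FALSE
    anc[[t]] <- res
    res
  }
  out <- lapply(ont$terms, visit)
  names(out) <- ont$terms
  out
}

#' Propagate annotations up the DAG (true-path rule)
#'
#' A gene directly annotated to a term becomes annotated to all of its
#' ancestors.  Idempotent.
#'
#' @param ont an [ontology()].
#' @param annotations data.frame with columns `gene`, `term`.
#' @return data.frame `gene`, `term` of the propagated (closed) annotation.
#' @export
propagate <- function(ont, annotations) {
  anc <- .ancestors(ont)
  n_up <- lengths(anc)[annotations$term]
  ext <- data.frame(
    gene = rep(annotations$gene, n_up),
    term = unlist(anc[annotations$term], use.names = FALSE),
    stringsAsFactors = FALSE)
  out <- unique(rbind(annotations[, c("gene", "term")], ext))
  out <- out[order(out$gene, out$term), ]
  rownames(out) <- NULL
  out
}

#' Parent-Child-Union enrichment test
#'
#' For a term t with parents P(t), the universe is restricted to genes
#' annotated (after propagation) to the union of P(t): with M such genes in
#' the population, K of them annotated to t, and m of them in the study set,
#' the p-value is the upper-tail hypergeometric probability of observing at
#' least k study genes annotated to t.  The root term is assigned p = 1.
#' Terms with m = 0 or K = 0 are reported as untestable (NA p-value).
#'
#' @param study,population character vectors of gene ids
#'   (`study` must be contained in `population`).
#' @param ont an [ontology()].
#' @param annotations direct annotations (`gene`, `term`); propagated
#'   internally.
#' @return data.frame: `term`, `k`, `m`, `K`, `M`, `pvalue`, `p_adj`
#'   (BH over testable terms), sorted by p-value.
#' @export
parent_child_union_test <- function(study, population, ont, annotations) {
  if (!all(study %in% population))
    stop("parent_child_union_test: study gene(s) absent from population: ",
         paste(utils::head(setdiff(study, population), 5), collapse = ", "))
  ann <- propagate(ont, annotations)
  ann <- ann[ann$gene %in% population, , drop = FALSE]
  genes_of <- split(ann$gene, ann$term)
  terms <- intersect(ont$terms, names(genes_of))
  study <- unique(study); population <- unique(population)
  res <- lapply(terms, function(t) {
    tg <- genes_of[[t]]
    if (t == ont$root) {
      return(data.frame(term = t, k = sum(study %in% tg),
                        m = length(study), K = length(tg),
                        M = length(population), pvalue = 1))
    }
    pu <- unique(unlist(genes_of[ont$parents[[t]]]))
    M <- length(pu)
    K <- length(intersect(pu, tg))      # = |tg| under the true-path rule
    su <- intersect(study, pu)
    m <- length(su)
    k <- sum(su %in% tg)
    p <- if (m == 0 || K == 0) NA_real_
         else stats::phyper(k - 1, K, M - K, m, lower.tail = FALSE)
    data.frame(term = t, k = k, m = m, K = K, M = M, pvalue = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, out$term), ]
  rownames(out) <- NULL
  out
}

#' Filter enrichment results at an adjusted-p threshold
#' @param results output of [parent_child_union_test()].
#' @param alpha adjusted-p threshold (conventional choices 0.01 or 0.05).
#' @export
enriched_terms <- function(results, alpha = 0.05) {
  results[!is.na(results$p_adj) & results$p_adj <= alpha, , drop = FALSE]
}

## ---- minimal OBO I/O ----------------------------------------------------

#' Write an ontology as minimal OBO (`[Term]`, `id`, `is_a` stanzas)
#' @param ont an [ontology()]
#' @param path output file
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in ont$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    for (p in ont$parents[[t]])
      writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Read a minimal OBO file (id and is_a tags only)
#' @param path OBO file
#' @return an [ontology()]
#' @export
read_obo <- function(path) {
  ln <- trimws(readLines(path))
  terms <- character(); parents <- list()
  cur <- NULL
  for (l in ln) {
    if (l == "[Term]") {
      cur <- NULL
    } else if (startsWith(l, "id: ")) {
      cur <- sub("^id: ", "", l)
      terms <- c(terms, cur)
      parents[[cur]] <- character()
    } else if (startsWith(l, "is_a: ") && !is.null(cur)) {
      p <- sub(" !.*$", "", sub("^is_a: ", "", l))
      parents[[cur]] <- c(parents[[cur]], p)
    }
  }
  ontology(terms, parents)
}

#' Read/write 2-column gene-to-term annotation TSV
#' @param annotations data.frame `gene`, `term`
#' @param path file path
#' @export
write_annotations_tsv <- function(annotations, path) {
  utils::write.table(annotations[, c("gene", "term")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_tsv
#' @export
read_annotations_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    col.names = c("gene", "term"))
}
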