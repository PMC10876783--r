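#' Propagate GO annotations up the DAG (true-path rule)
#'
#' Each gene is annotated to every ancestor of each of its direct terms.
#'
#' @param gene2go named list gene -> character vector of term ids.
#' @param dag a `go_dag`.
#' @return named list gene -> propagated term closure.
#' @export
propagate_annotations <- function(gene2go, dag) {
  known <- dag$terms$id
  unknown <- setdiff(unique(unlist(gene2go)), known)
  if (length(unknown))
    stopf("annotation uses term(s) absent from the ontology: %s",
          paste(head(unknown, 5L), collapse = ", "))
  anc_cache <- new.env(parent = emptyenv())
  closure_of <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    val <- c(t, go_ancestors(dag, t))
    anc_cache[[t]] <- val
    val
  }
  lapply(gene2go, function(terms) {
    unique(unlist(lapply(unique(terms), closure_of)))
  })
}

#' Classic Fisher GO enrichment
#'
#' One-sided Fisher exact test (hypergeometric upper tail) per term with
#' at least one study gene, on the 2x2 table of study/non-study x
#' term/non-term over the propagated closure.
#'
#' @param study character vector of study gene ids (subset of
#'   `population`).
#' @param population character vector of population (universe) gene ids.
#' @param closure propagated annotation list from
#'   [propagate_annotations()].
#' @param alpha significance flag threshold.
#' @return data.frame of class `enrichment_table`: `term_id`,
#'   `study_count`, `study_size`, `population_count`, `population_size`,
#'   `p_fisher`, `significant`, sorted by p.
#' @export
fisher_enrich <- function(study, population, closure, alpha = 0.05) {
  study <- unique(study)
  population <- unique(population)
  if (!all(study %in% population))
    stopf("study genes must be a subset of the population")
  if (!length(study)) {
    return(structure(data.frame(term_id = character(0),
                                study_count = integer(0),
                                study_size = integer(0),
                                population_count = integer(0),
                                population_size = integer(0),
                                p_fisher = numeric(0),
                                significant = logical(0)),
                     class = c("enrichment_table", "data.frame")))
  }
  closure <- closure[intersect(names(closure), population)]
  term_genes <- split(rep(names(closure), lengths(closure)),
                      unlist(closure, use.names = FALSE))
  n_pop <- length(population)
  n_study <- length(study)
  rows <- lapply(names(term_genes), function(t) {
    tg <- term_genes[[t]]
    k <- sum(study %in% tg)
    if (k == 0L) return(NULL)
    m <- length(unique(tg))
    p <- hyper_tail_p(k, m, n_pop - m, n_study)
    data.frame(term_id = t, study_count = k, study_size = n_study,
               population_count = m, population_size = n_pop,
               p_fisher = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_fisher, out$term_id), , drop = FALSE]
  out$significant <- out$p_fisher < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' One-sided Fisher exact p for a 2x2 enrichment table
#'
#' The hypergeometric upper tail P(X >= x) with `x` study genes in the
#' term, `m` term genes, `n` non-term genes and `k` study genes — the
#' p-value [fisher_enrich()] assigns to every term.
#'
#' @param x observed overlap.
#' @param m,n term / non-term gene counts in the population.
#' @param k study size.
#' @return numeric p-value.
#' @export
hyper_tail_p <- function(x, m, n, k) {
  phyper(x - 1, m, n, k, lower.tail = FALSE)
}

## shortest-path depth of every term from its namespace root (root = 0)
go_depths <- function(dag) {
  ids <- dag$terms$id
  par <- lapply(setNames(ids, ids),
                function(t) intersect(go_parents(dag, t), ids))
  depth <- setNames(rep(NA_integer_, length(ids)), ids)
  roots <- ids[lengths(par) == 0L]
  depth[roots] <- 0L
  frontier <- roots
  d <- 0L
  children <- setNames(vector("list", length(ids)), ids)
  for (ch in ids) for (p in par[[ch]]) children[[p]] <- c(children[[p]], ch)
  while (length(frontier)) {
    d <- d + 1L
    nxt <- setdiff(unique(unlist(children[frontier])), ids[!is.na(depth)])
    depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

#' Roll significant terms up to shallow parent terms
#'
#' Maps each significant term to its ancestor at shortest-path depth
#' `max_depth` from the namespace root (terms at or above that depth map
#' to themselves). When several ancestors sit at the target depth the
#' lexicographically smallest id is taken, which keeps the grouping
#' deterministic.
#'
#' @param rows an `enrichment_table`.
#' @param dag a `go_dag`.
#' @param max_depth rollup depth.
#' @return `rows` with a `parent_term` column, plus a `groups` attribute
#'   (data.frame parent term -> member count).
#' @export
rollup_terms <- function(rows, dag, max_depth = 2L) {
  depth <- go_depths(dag)
  parent_of <- vapply(rows$term_id, function(t) {
    if (is.na(depth[t])) return(t)
    if (depth[t] <= max_depth) return(t)
    anc <- go_ancestors(dag, t)
    cand <- anc[!is.na(depth[anc]) & depth[anc] == max_depth]
    if (!length(cand)) return(t)
    sort(cand)[1L]
  }, character(1))
  rows$parent_term <- unname(parent_of)
  sig <- rows[rows$significant, , drop = FALSE]
  groups <- as.data.frame(table(parent_term = sig$parent_term),
                          stringsAsFactors = FALSE)
  names(groups)[2] <- "n_terms"
  attr(rows, "groups") <- groups
  rows
}
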