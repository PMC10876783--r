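#' Read a Gene Ontology OBO file (1.2 subset)
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace` and `is_a`
#' relations, returning a directed acyclic graph child -> parent. Obsolete
#' terms are dropped. A cycle among `is_a` edges is an error.
#'
#' @param path path to an OBO file.
#' @return object of class `go_dag`: a list with `terms` (data.frame of
#'   `id`, `name`, `namespace`) and `parents` (named list of parent id
#'   vectors).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stopf("OBO not found: %s", path)
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stopf("no [Term] stanzas in %s", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); nsp <- character(0)
  parents <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[!startsWith(chunk, "[")]
    getf <- function(key) sub(paste0("^", key, ": "), "",
                              grep(paste0("^", key, ": "), chunk, value = TRUE))
    if (length(grep("^is_obsolete: true", chunk))) next
    id <- getf("id")[1]
    if (is.na(id) || !nzchar(id)) stopf("[Term] stanza without id in %s", path)
    ids <- c(ids, id)
    nm <- getf("name"); nms <- c(nms, if (length(nm)) nm[1] else "")
    ns <- getf("namespace")
    nsp <- c(nsp, if (length(ns)) ns[1] else "biological_process")
    isa <- getf("is_a")
    parents[[id]] <- sub(" !.*$", "", isa)
  }
  dag <- structure(
    list(terms = data.frame(id = ids, name = nms, namespace = nsp,
                            stringsAsFactors = FALSE),
         parents = parents),
    class = "go_dag")
  assert_acyclic(dag)
  dag
}

## Kahn's algorithm over is_a edges; leftovers mean a cycle
assert_acyclic <- function(dag) {
  ids <- dag$terms$id
  par <- lapply(dag$parents[ids], function(p) intersect(p, ids))
  indeg <- setNames(lengths(par), ids)   # edges child -> parent, count parents
  children <- setNames(vector("list", length(ids)), ids)
  for (ch in ids) for (p in par[[ch]]) children[[p]] <- c(children[[p]], ch)
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) stopf("cycle detected in OBO is_a graph")
  invisible(TRUE)
}

#' Direct parents of a term
#' @param dag a `go_dag`.
#' @param term term id.
#' @return character vector of parent ids (empty for roots).
#' @export
go_parents <- function(dag, term) {
  p <- dag$parents[[term]]
  if (is.null(p)) character(0) else p
}

#' All ancestors of a term (excluding itself)
#' @param dag a `go_dag`.
#' @param term term id.
#' @return character vector of ancestor ids.
#' @export
go_ancestors <- function(dag, term) {
  out <- character(0)
  frontier <- go_parents(dag, term)
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), out)
  }
  out
}

#' Write an OBO file from a term table and parent map
#'
#' Minimal OBO 1.2 emitter used by the simulator; [read_obo()] round-trips
#' its output.
#'
#' @param dag a `go_dag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines("[Term]", con)
    writeLines(sprintf("id: %s", id), con)
    writeLines(sprintf("name: %s", dag$terms$name[i]), con)
    writeLines(sprintf("namespace: %s", dag$terms$namespace[i]), con)
    for (p in go_parents(dag, id)) writeLines(sprintf("is_a: %s", p), con)
    writeLines("", con)
  }
  invisible(path)
}
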