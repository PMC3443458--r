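# Minimal OBO 1.2 parser and DAG utilities. Only is_a and part_of edges are
# traversed (standard enrichment practice); every other relationship type is
# ignored and obsolete terms are dropped at load.

#' Read an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas, keeping id, name, namespace and the parent edges
#' given by `is_a:` and `relationship: part_of`. Obsolete terms are dropped,
#' as are edges pointing to dropped/unknown terms. The resulting graph must
#' be acyclic; a cycle raises a validation error naming one cycle.
#'
#' @param path OBO file path.
#' @return An object of class `ontology`: a list with `terms` (data frame
#'   `id`, `name`, `namespace`) and `parents` (named list id -> parent ids).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) dx_format_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  ids <- character(); names_ <- character(); ns <- character()
  parents <- list(); obsolete <- logical()
  ends <- c(stanza_starts[-1L] - 1L, length(lines))
  for (k in seq_along(stanza_starts)) {
    block <- lines[stanza_starts[k]:ends[k]]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ": "), block, value = TRUE))
      if (length(v)) v[1L] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) next
    isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a: ", block, value = TRUE)))
    po <- grep("^relationship: part_of ", block, value = TRUE)
    po <- sub(" *!.*$", "", sub("^relationship: part_of *", "", po))
    ids <- c(ids, id)
    names_ <- c(names_, get1("name"))
    ns <- c(ns, get1("namespace"))
    parents[[id]] <- unique(c(isa, po))
    obsolete <- c(obsolete, identical(get1("is_obsolete"), "true"))
  }
  keep <- !obsolete & !duplicated(ids)
  ids <- ids[keep]; names_ <- names_[keep]; ns <- ns[keep]
  parents <- parents[ids]
  parents <- lapply(parents, function(p) intersect(p, ids))
  ns[is.na(ns)] <- "default"
  onto <- structure(list(terms = data.frame(id = ids, name = names_, namespace = ns,
                                            stringsAsFactors = FALSE),
                         parents = parents),
                    class = "ontology")
  cyc <- find_cycle(parents)
  if (!is.null(cyc))
    dx_validation_error(sprintf("ontology contains a cycle: %s",
                                paste(cyc, collapse = " -> ")))
  onto
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d edges, namespaces: %s\n",
              nrow(x$terms), sum(lengths(x$parents)),
              paste(unique(x$terms$namespace), collapse = ", ")))
  invisible(x)
}

#' Write an ontology as OBO 1.2
#'
#' @param ontology an `ontology` object.
#' @param path output path.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(ontology$terms))) {
    id <- ontology$terms$id[i]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", ontology$terms$name[i]),
                 paste0("namespace: ", ontology$terms$namespace[i]),
                 paste0("is_a: ", ontology$parents[[id]])), con)
  }
  invisible(path)
}

# iterative DFS cycle detection; returns one cycle (vector of ids) or NULL
find_cycle <- function(parents) {
  color <- stats::setNames(rep(0L, length(parents)), names(parents)) # 0 new 1 open 2 done
  for (start in names(parents)) {
    if (color[[start]] != 0L) next
    stack <- list(list(node = start, i = 0L))
    path <- character()
    while (length(stack)) {
      top <- stack[[length(stack)]]
      node <- top$node
      if (top$i == 0L) { color[[node]] <- 1L; path <- c(path, node) }
      ps <- parents[[node]]
      if (top$i < length(ps)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- ps[top$i + 1L]
        if (color[[nxt]] == 1L)
          return(c(path[which(path == nxt):length(path)], nxt))
        if (color[[nxt]] == 0L)
          stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
      } else {
        color[[node]] <- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

# ancestor closure per term (excluding the term itself), memoized
term_ancestors <- function(ontology) {
  parents <- ontology$parents
  anc <- vector("list", length(parents))
  names(anc) <- names(parents)
  done <- stats::setNames(rep(FALSE, length(parents)), names(parents))
  visit <- function(id) {
    if (done[[id]]) return(anc[[id]])
    ps <- parents[[id]]
    res <- ps
    for (p in ps) res <- c(res, visit(p))
    anc[[id]] <<- unique(res)
    done[[id]] <<- TRUE
    anc[[id]]
  }
  for (id in names(parents)) visit(id)
  anc
}
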