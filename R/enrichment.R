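#' Read a GMT gene-set file
#'
#' Each line is `term_id <tab> description <tab> gene1 <tab> gene2 ...`.
#' Duplicate genes within a set are removed with a warning; empty lines are
#' skipped.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (term -> genes), with the
#'   descriptions in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1]))
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(parts, function(p) p[-(1:2)])
  dup <- vapply(sets, anyDuplicated, numeric(1)) > 0
  if (any(dup)) {
    warning(sprintf("duplicate genes in %d sets; deduplicated", sum(dup)))
    sets <- lapply(sets, unique)
  }
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors; descriptions may be given
#'   via the `"description"` attribute (defaults to the term id).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an OBO-format ontology subset
#'
#' Parses the minimal OBO fields used here: `[Term]` stanzas with `id`,
#' `name`, `namespace` and `is_a` lines (trailing `! comment` text is
#' stripped). The parent-child graph must be acyclic; a cycle raises an
#' error naming an involved term.
#'
#' @param path Path to the OBO file.
#' @return A list with `terms` (data.frame: `term_id`, `name`, `namespace`)
#'   and `edges` (data.frame: `parent`, `child`).
#' @export
read_obo <- function(path) {
  lines <- trimws(readLines(path))
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  edges_parent <- character(0)
  edges_child <- character(0)
  flush <- function(cur) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <<- cur
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      flush(cur)
      cur <- list(name = NA_character_, namespace = NA_character_)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(cur)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) == 3) {
        val <- sub("\\s*!.*$", "", kv[3])
        if (kv[2] == "id") cur$id <- val
        if (kv[2] == "name") cur$name <- val
        if (kv[2] == "namespace") cur$namespace <- val
        if (kv[2] == "is_a") {
          edges_parent <- c(edges_parent, val)
          edges_child <- c(edges_child, cur$id)
        }
      }
    }
  }
  flush(cur)
  terms_df <- data.frame(
    term_id = vapply(terms, `[[`, character(1), "id"),
    name = vapply(terms, `[[`, character(1), "name"),
    namespace = vapply(terms, `[[`, character(1), "namespace"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(parent = edges_parent, child = edges_child,
                      stringsAsFactors = FALSE)
  check_acyclic(edges)
  list(terms = terms_df, edges = edges)
}

#' Write an OBO-format ontology subset
#'
#' @param ontology A list with `terms` and `edges` as returned by
#'   [read_obo()] or [simulate_ontology()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(ontology$terms))) {
    t <- ontology$terms[i, ]
    parents <- ontology$edges$parent[ontology$edges$child == t$term_id]
    writeLines(c("", "[Term]",
                 paste0("id: ", t$term_id),
                 paste0("name: ", t$name),
                 paste0("namespace: ", t$namespace),
                 if (length(parents)) paste0("is_a: ", parents)), con)
  }
  invisible(path)
}

# Kahn topological check; errors on a cycle.
check_acyclic <- function(edges) {
  if (nrow(edges) == 0) return(invisible(TRUE))
  nodes <- unique(c(edges$parent, edges$child))
  indeg <- table(factor(edges$child, levels = nodes))
  active <- rep(TRUE, nrow(edges))
  queue <- nodes[indeg == 0]
  removed <- character(0)
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    removed <- c(removed, v)
    out <- which(active & edges$parent == v)
    for (e in out) {
      active[e] <- FALSE
      ch <- edges$child[e]
      indeg[ch] <- indeg[ch] - 1
      if (indeg[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(removed) < length(nodes)) {
    stop(sprintf("ontology graph contains a cycle (involving e.g. '%s')",
                 setdiff(nodes, removed)[1]))
  }
  invisible(TRUE)
}

#' Hypergeometric overrepresentation of gene sets in a target list
#'
#' Tests each term for overrepresentation of the target within the
#' background universe. Term membership is intersected with the background
#' before sizing; terms smaller than `min_size` in the background are
#' excluded. The p-value is the upper-tail hypergeometric probability of
#' the observed overlap; Benjamini-Hochberg adjustment is applied per
#' namespace when one is supplied, otherwise across all tested terms.
#'
#' @param target Character vector of gene symbols; must lie in `background`.
#' @param background Character vector, the universe of quantified genes.
#' @param sets Named list of gene vectors (e.g. from [read_gmt()]).
#' @param min_size Minimum background-restricted term size (default 5).
#' @param namespaces Optional named character vector term -> namespace.
#'
#' @return data.frame: `term_id`, `overlap`, `size` (term in background),
#'   `p`, `p_adj`, sorted by `p`.
#' @export
hypergeometric_enrichment <- function(target, background, sets, min_size = 5,
                                      namespaces = NULL) {
  target <- unique(target)
  background <- unique(background)
  extra <- setdiff(target, background)
  if (length(extra) > 0) stop("target contains genes absent from background")
  if (length(target) == 0) {
    return(data.frame(term_id = character(0), overlap = integer(0),
                      size = integer(0), p = numeric(0), p_adj = numeric(0)))
  }
  N <- length(background)
  n <- length(target)
  restricted <- lapply(sets, intersect, background)
  size <- lengths(restricted)
  keep <- size >= min_size
  restricted <- restricted[keep]
  size <- size[keep]
  overlap <- vapply(restricted, function(s) length(intersect(s, target)),
                    integer(1))
  p <- stats::phyper(overlap - 1, size, N - size, n, lower.tail = FALSE)
  res <- data.frame(term_id = names(restricted), overlap = overlap,
                    size = size, p = p, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(namespaces)) {
    ns <- namespaces[res$term_id]
    ns[is.na(ns)] <- "unknown"
    res$p_adj <- stats::ave(res$p, ns,
                            FUN = function(v) stats::p.adjust(v, "BH"))
  } else {
    res$p_adj <- stats::p.adjust(res$p, "BH")
  }
  res[order(res$p, res$term_id), , drop = FALSE]
}

#' Best-per-parent reduction of enrichment results
#'
#' Implements the "strongest sibling" hierarchical filter: a significant
#' term is retained when, for at least one of its parents, it attains the
#' smallest p-value among that parent's significant children. Significant
#' terms with no parent in the DAG (roots) are always retained. Ties are
#' broken towards the larger overlap, then the lexicographically smaller
#' term id.
#'
#' @param results data.frame from [hypergeometric_enrichment()].
#' @param edges DAG edges (data.frame: `parent`, `child`); must be acyclic.
#' @param alpha Significance threshold applied to `p_adj` (default 0.05).
#'
#' @return The subset of `results` rows retained, with a `best_per_parent`
#'   column added to the input-order copy in attribute `"flagged"`.
#' @export
best_per_parent <- function(results, edges, alpha = 0.05) {
  check_acyclic(edges)
  sig <- results[!is.na(results$p_adj) & results$p_adj < alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- results[0, , drop = FALSE]
    attr(out, "flagged") <- transform(results, best_per_parent = FALSE)
    return(out)
  }
  # rank key: smaller p wins, then larger overlap, then smaller id
  keep <- stats::setNames(rep(FALSE, nrow(sig)), sig$term_id)
  parents_of <- split(edges$parent, edges$child)
  for (i in seq_len(nrow(sig))) {
    tid <- sig$term_id[i]
    pars <- parents_of[[tid]]
    if (is.null(pars) || length(pars) == 0) {
      keep[tid] <- TRUE  # significant root
      next
    }
    for (pa in pars) {
      sibs <- edges$child[edges$parent == pa]
      cand <- sig[sig$term_id %in% sibs, , drop = FALSE]
      ord <- order(cand$p, -cand$overlap, cand$term_id)
      if (cand$term_id[ord[1]] == tid) {
        keep[tid] <- TRUE
        break
      }
    }
  }
  out <- sig[keep[sig$term_id], , drop = FALSE]
  flagged <- results
  flagged$best_per_parent <- results$term_id %in% out$term_id
  attr(out, "flagged") <- flagged
  out
}

#' Partition a gene list by ontology subtrees
#'
#' Assigns each target gene to every requested root whose subtree (the root
#' and all its descendants) contains a term annotating the gene.
#' Multi-assignment is allowed; genes annotated under no subtree are
#' returned as `unannotated`.
#'
#' @param target Character vector of gene symbols.
#' @param edges DAG edges (`parent`, `child`).
#' @param sets Named list term -> genes.
#' @param root_ids Character vector of subtree roots (must appear in the
#'   DAG or in `sets`).
#'
#' @return A list with `members` (named list root -> genes), `counts`
#'   (named integer vector) and `unannotated` (character vector).
#' @export
partition_by_subtree <- function(target, edges, sets, root_ids) {
  known <- unique(c(edges$parent, edges$child, names(sets)))
  missing_roots <- setdiff(root_ids, known)
  if (length(missing_roots) > 0) {
    stop(sprintf("roots not in ontology: %s",
                 paste(missing_roots, collapse = ", ")))
  }
  children_of <- split(edges$child, edges$parent)
  members <- lapply(root_ids, function(root) {
    subtree <- root
    frontier <- root
    while (length(frontier) > 0) {
      nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, subtree)
      subtree <- c(subtree, nxt)
      frontier <- nxt
    }
    annotated <- unique(unlist(sets[intersect(subtree, names(sets))],
                               use.names = FALSE))
    intersect(target, annotated)
  })
  names(members) <- root_ids
  assigned <- unique(unlist(members, use.names = FALSE))
  list(members = members,
       counts = vapply(members, length, integer(1)),
       unannotated = setdiff(target, assigned))
}
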