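# NCBI-style taxonomy: loading, lineages, LCA, rank projection.
#
# The taxonomy is a parent-pointer tree kept as named vectors keyed by the
# taxid as a character string. That makes every lookup O(1) and the whole
# structure trivially serialisable, which matters more here than tabular
# ergonomics: classification touches the tree millions of times but users
# rarely look at it directly.

new_taxonomy <- function(parent, rank, name = character(), merged = integer(),
                         deleted = integer(), root = 1L) {
  structure(
    list(
      parent = parent, rank = rank, name = name,
      merged = merged, deleted = as.integer(deleted), root = as.integer(root)
    ),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(
    "<taxonomy> ", length(x$parent), " nodes, root ", x$root,
    ", ", length(x$merged), " merged, ", length(x$deleted), " deleted\n",
    sep = ""
  )
  invisible(x)
}

#' Number of nodes in a taxonomy
#' @param x A `taxonomy` object.
#' @param ... Ignored.
#' @export
length.taxonomy <- function(x) length(x$parent)

validate_taxonomy <- function(tax) {
  ids <- names(tax$parent)
  if (!as.character(tax$root) %in% ids) {
    abort(paste0("root taxid ", tax$root, " is not a node"))
  }
  if (tax$parent[[as.character(tax$root)]] != tax$root) {
    abort("root must be its own parent")
  }
  orphans <- setdiff(as.character(tax$parent), ids)
  if (length(orphans) > 0) {
    abort(paste0(
      "orphan parent taxid(s) referenced but not defined: ",
      paste(sort(orphans), collapse = ", ")
    ))
  }
  # Cycle check: every chain must reach the root within n steps.
  n <- length(tax$parent)
  for (id in ids) {
    cur <- id
    steps <- 0L
    root_chr <- as.character(tax$root)
    while (cur != root_chr) {
      cur <- as.character(tax$parent[[cur]])
      steps <- steps + 1L
      if (steps > n) abort(paste0("cycle detected in parent chain at taxid ", id))
    }
  }
  missing_rank <- setdiff(ids, names(tax$rank))
  if (length(missing_rank) > 0) {
    abort(paste0("taxid(s) without a rank: ", paste(missing_rank, collapse = ", ")))
  }
  overlap <- intersect(names(tax$merged), ids)
  if (length(overlap) > 0) {
    abort(paste0(
      "merged old-taxid(s) collide with live nodes: ",
      paste(overlap, collapse = ", ")
    ))
  }
  tax
}

split_dmp_line <- function(line) {
  # taxdump dialect: fields separated by "\t|\t", line terminated by "\t|".
  strsplit(sub("\t\\|$", "", line), "\t\\|\t")[[1]]
}

#' Load an NCBI taxonomy dump
#'
#' Reads `nodes.dmp` and `names.dmp` (and optionally `merged.dmp` /
#' `delnodes.dmp`) in the NCBI taxdump dialect: fields separated by
#' `"\t|\t"`, lines terminated by `"\t|"`. Only names of class
#' `"scientific name"` are kept. The resulting tree is validated: a missing
#' parent or a cycle in the parent chain is an error.
#'
#' @param nodes_path Path to `nodes.dmp` (taxid, parent taxid, rank, ...).
#' @param names_path Path to `names.dmp`; `NULL` to skip names.
#' @param merged_path Optional path to `merged.dmp` (old taxid, new taxid).
#' @param delnodes_path Optional path to `delnodes.dmp` (deleted taxids).
#' @return A `taxonomy` object.
#' @export
load_taxdump <- function(nodes_path, names_path = NULL, merged_path = NULL,
                         delnodes_path = NULL) {
  lines <- readLines(nodes_path)
  n <- length(lines)
  ids <- character(n)
  parents <- integer(n)
  ranks <- character(n)
  for (i in seq_len(n)) {
    f <- split_dmp_line(lines[[i]])
    if (length(f) < 3) {
      abort(paste0("malformed nodes.dmp line ", i, ": fewer than 3 fields"))
    }
    tid <- suppressWarnings(as.integer(f[[1]]))
    pid <- suppressWarnings(as.integer(f[[2]]))
    if (is.na(tid) || is.na(pid)) {
      abort(paste0("malformed nodes.dmp line ", i, ": non-integer taxid"))
    }
    ids[[i]] <- f[[1]]
    parents[[i]] <- pid
    ranks[[i]] <- f[[3]]
  }
  parent <- setNames(parents, ids)
  rank <- setNames(ranks, ids)

  name <- character()
  if (!is.null(names_path)) {
    nl <- readLines(names_path)
    for (i in seq_along(nl)) {
      f <- split_dmp_line(nl[[i]])
      if (length(f) < 4) {
        abort(paste0("malformed names.dmp line ", i, ": fewer than 4 fields"))
      }
      if (f[[4]] == "scientific name") name[[f[[1]]]] <- f[[2]]
    }
  }

  merged <- integer()
  if (!is.null(merged_path)) {
    ml <- readLines(merged_path)
    for (i in seq_along(ml)) {
      f <- split_dmp_line(ml[[i]])
      if (length(f) < 2) {
        abort(paste0("malformed merged.dmp line ", i, ": fewer than 2 fields"))
      }
      merged[[f[[1]]]] <- as.integer(f[[2]])
    }
  }

  deleted <- integer()
  if (!is.null(delnodes_path)) {
    dl <- readLines(delnodes_path)
    deleted <- vapply(dl, function(l) as.integer(split_dmp_line(l)[[1]]), integer(1),
      USE.NAMES = FALSE
    )
  }

  # Root: the node that is its own parent (NCBI uses taxid 1).
  self <- which(parents == as.integer(ids))
  if (length(self) != 1) {
    abort(paste0("expected exactly one self-parented root, found ", length(self)))
  }
  validate_taxonomy(new_taxonomy(
    parent = parent, rank = rank, name = name,
    merged = merged, deleted = deleted, root = as.integer(ids[[self]])
  ))
}

#' Resolve a taxid through merges and deletions
#'
#' Follows `merged.dmp` redirects transitively; taxids listed in
#' `delnodes.dmp` or absent from the tree resolve to `NA` (missing is a
#' value, not an error).
#'
#' @param tax A `taxonomy` object.
#' @param taxid Integer taxid(s).
#' @return Integer vector: the resolved taxid, or `NA` if deleted/unknown.
#' @export
resolve_taxid <- function(tax, taxid) {
  vapply(as.integer(taxid), function(t) {
    cur <- t
    seen <- 0L
    repeat {
      key <- as.character(cur)
      if (key %in% names(tax$parent)) return(cur)
      if (key %in% names(tax$merged)) {
        cur <- tax$merged[[key]]
        seen <- seen + 1L
        if (seen > length(tax$merged)) return(NA_integer_)
        next
      }
      return(NA_integer_)
    }
  }, integer(1))
}

#' Root-to-taxon lineage
#'
#' @param tax A `taxonomy` object.
#' @param taxid A single taxid; merged taxids are redirected first.
#' @return Integer vector of taxids from the root down to `taxid` inclusive.
#' @export
lineage <- function(tax, taxid) {
  t <- resolve_taxid(tax, taxid)
  if (is.na(t)) abort(paste0("taxid ", taxid, " does not resolve in the taxonomy"))
  out <- integer()
  cur <- t
  root <- tax$root
  while (cur != root) {
    out <- c(cur, out)
    cur <- tax$parent[[as.character(cur)]]
  }
  c(root, out)
}

#' Last common ancestor of a set of taxids
#'
#' The deepest node common to the lineages of all input taxids;
#' `lca(tax, x)` is `x` itself for a single taxid.
#'
#' @param tax A `taxonomy` object.
#' @param taxids Non-empty vector of taxids (duplicates collapse).
#' @return A single taxid.
#' @export
lca <- function(tax, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0) abort("lca() needs at least one taxid")
  paths <- lapply(taxids, function(t) lineage(tax, t))
  k <- min(lengths(paths))
  common <- tax$root
  for (i in seq_len(k)) {
    nodes <- vapply(paths, `[[`, integer(1), i)
    if (all(nodes == nodes[[1]])) common <- nodes[[1]] else break
  }
  common
}

#' Project a taxid onto the official ranks
#'
#' Walks the lineage of `taxid` and returns, for each of the seven official
#' ranks present on it, the node carrying that rank. Ranks absent from the
#' lineage are absent from the result, so e.g. the root projects to an
#' empty vector and a "no rank" strain node projects exactly as its species
#' parent does.
#'
#' @param tax A `taxonomy` object.
#' @param taxid A single taxid.
#' @return Named integer vector, names in `official_ranks()` order
#'   (deepest first) restricted to the ranks present.
#' @export
official_rank_projection <- function(tax, taxid) {
  path <- lineage(tax, taxid)
  ranks <- tax$rank[as.character(path)]
  keep <- ranks %in% official_ranks()
  proj <- setNames(path[keep], ranks[keep])
  proj[intersect(official_ranks(), names(proj))]
}

#' Display name for a taxid
#'
#' Unnamed nodes render as `"taxid:<n>"`; names are presentation only and
#' classification never depends on them.
#'
#' @param tax A `taxonomy` object.
#' @param taxid Taxid vector.
#' @return Character vector of scientific names (or the fallback).
#' @export
taxon_name <- function(tax, taxid) {
  vapply(as.integer(taxid), function(t) {
    key <- as.character(t)
    if (key %in% names(tax$name)) tax$name[[key]] else paste0("taxid:", t)
  }, character(1))
}
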