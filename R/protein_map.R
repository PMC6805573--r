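# Protein accession -> taxid mapping (prot.accession2taxid dialect).

#' Build a protein accession to taxid map
#'
#' Reads a `prot.accession2taxid`-style file. Two layouts are accepted: the
#' 4-column NCBI layout with a header naming `accession.version` and
#' `taxid`, and a minimal headerless 2-column layout (accession, taxid).
#' Keys are stored both with and without the version suffix; lookups prefer
#' the versioned form.
#'
#' A protein entry in a non-redundant database can list several source
#' organisms, so the same accession may occur on multiple lines with
#' different taxids. With `lca_correct = TRUE` (the default) such an
#' accession is mapped to the LCA of all its taxids, which makes the map
#' independent of line order; with `lca_correct = FALSE` the first
#' occurrence wins. Lines whose taxid does not resolve in the taxonomy are
#' dropped with a warning giving the count.
#'
#' @param path Path to the mapping file (TSV).
#' @param tax A `taxonomy` object used to resolve and LCA-correct taxids.
#' @param lca_correct Collapse multi-taxid accessions to their LCA?
#' @return A `protein_map`: named integer vector accession -> taxid.
#' @export
build_protein_map <- function(path, tax, lca_correct = TRUE) {
  first <- readLines(path, n = 1)
  has_header <- grepl("accession", first, ignore.case = TRUE)
  df <- utils::read.table(path,
    sep = "\t", header = has_header, quote = "",
    comment.char = "", stringsAsFactors = FALSE
  )
  if (has_header) {
    cols <- tolower(names(df))
    acc_col <- which(cols == "accession.version")
    if (length(acc_col) == 0) acc_col <- which(cols == "accession")
    tax_col <- which(cols == "taxid")
    if (length(acc_col) == 0 || length(tax_col) == 0) {
      abort("mapping file must have accession(.version) and taxid columns")
    }
    acc <- as.character(df[[acc_col[[1]]]])
    tid <- as.integer(df[[tax_col[[1]]]])
  } else {
    if (ncol(df) < 2) abort("headerless mapping file must have 2 columns")
    acc <- as.character(df[[1]])
    tid <- as.integer(df[[2]])
  }

  resolved <- resolve_taxid(tax, tid)
  n_drop <- sum(is.na(resolved))
  if (n_drop > 0) {
    warn(paste0(n_drop, " mapping line(s) dropped: taxid not in taxonomy"))
    acc <- acc[!is.na(resolved)]
    resolved <- resolved[!is.na(resolved)]
  }

  if (lca_correct) {
    by_acc <- split(resolved, acc)
    m <- vapply(by_acc, function(ts) {
      ts <- unique(ts)
      if (length(ts) == 1) ts else lca(tax, ts)
    }, integer(1))
  } else {
    first_idx <- !duplicated(acc)
    m <- setNames(resolved[first_idx], acc[first_idx])
  }
  # Alias each versioned key by its bare accession (versioned form wins on
  # lookup; among versions of one accession the first in sorted order wins).
  m <- m[sort(names(m))]
  bare <- strip_accession_version(names(m))
  alias <- !(bare %in% names(m)) & bare != names(m) & !duplicated(bare)
  if (any(alias)) {
    m <- c(m, setNames(unname(m[alias]), bare[alias]))
  }
  new_protein_map(m)
}

new_protein_map <- function(m) {
  structure(as.integer(m), names = names(m), class = "protein_map")
}

#' @export
print.protein_map <- function(x, ...) {
  cat("<protein_map> ", length(x), " accessions\n", sep = "")
  invisible(x)
}

strip_accession_version <- function(acc) sub("\\.\\d+$", "", acc)

#' Look up the taxid of a protein accession
#'
#' Tries the accession as given first (typically the versioned form), then
#' with a trailing `.N` version suffix stripped.
#'
#' @param protmap A `protein_map`.
#' @param accession Character vector of accessions.
#' @return Integer taxids, `NA` where unmapped.
#' @export
resolve_accession <- function(protmap, accession) {
  keys <- names(protmap)
  idx <- match(accession, keys)
  miss <- is.na(idx)
  if (any(miss)) {
    idx[miss] <- match(strip_accession_version(accession[miss]), keys)
  }
  out <- rep(NA_integer_, length(accession))
  hit <- !is.na(idx)
  out[hit] <- unclass(protmap)[idx[hit]]
  out
}

#' Write a protein map in prot.accession2taxid layout
#'
#' Emits the 4-column NCBI layout (`accession`, `accession.version`,
#' `taxid`, `gi`) so the file round-trips through [build_protein_map()].
#'
#' @param protmap A `protein_map` (versioned or unversioned keys).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_map <- function(protmap, path) {
  acc <- names(protmap)
  lines <- c(
    "accession\taccession.version\ttaxid\tgi",
    paste(strip_accession_version(acc), acc, unclass(protmap), seq_along(acc),
      sep = "\t"
    )
  )
  writeLines(lines, path)
  invisible(path)
}
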