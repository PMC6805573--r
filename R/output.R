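# Classification writers, name annotation, and summaries.
#
# All writers are deterministic: fixed column order, fixed sort keys, and
# 4-decimal half-even rounding for support fractions, so identical inputs
# give byte-identical files.

fmt_support <- function(x) sprintf("%.4f", round(x, 4))

#' Write the ORF-level classification file
#'
#' One line per ORF: its LCA taxon and registered (top-hit) bit-score when
#' classified, or the reason it was not. Sorted by contig then ORF index.
#'
#' @param orfs ORF-level tibble from [classify_orfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf2lca <- function(orfs, path) {
  orfs <- arrange(orfs, .data$contig_id, .data$orf_index, .data$orf_id)
  lca_col <- ifelse(is.na(orfs$lca_taxid), orfs$reason, as.character(orfs$lca_taxid))
  bits_col <- ifelse(is.na(orfs$bitscore), "NA", format(orfs$bitscore, trim = TRUE, scientific = FALSE))
  lines <- c(
    "# orf_id\tcontig_id\tlca_taxid\tbitscore\tn_hits_in_range",
    paste(orfs$orf_id, orfs$contig_id, lca_col, bits_col, orfs$n_hits_in_range,
      sep = "\t"
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Re-read an ORF-level classification file
#'
#' Inverse of [write_orf2lca()]; reconstructs the ORF-level tibble.
#'
#' @param path Path written by [write_orf2lca()].
#' @return A tibble with the same columns as [classify_orfs()] output.
#' @export
read_orf2lca <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) {
    return(tibble(
      orf_id = character(), contig_id = character(), orf_index = integer(),
      lca_taxid = integer(), bitscore = numeric(), n_hits_in_range = integer(),
      reason = character()
    ))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  lca_raw <- vapply(f, `[[`, character(1), 3)
  is_tax <- grepl("^[0-9]+$", lca_raw)
  orf_id <- vapply(f, `[[`, character(1), 1)
  tibble(
    orf_id = orf_id,
    contig_id = vapply(f, `[[`, character(1), 2),
    orf_index = parse_orf_id(orf_id)$orf_index,
    lca_taxid = ifelse(is_tax, suppressWarnings(as.integer(lca_raw)), NA_integer_),
    bitscore = suppressWarnings(as.numeric(vapply(f, `[[`, character(1), 4))),
    n_hits_in_range = as.integer(vapply(f, `[[`, character(1), 5)),
    reason = ifelse(is_tax, NA_character_, lca_raw)
  )
}

#' Write the query-level classification file
#'
#' One line per reported lineage; a query with multiple qualifying lineages
#' occupies multiple lines sharing its id. The lineage is a
#' semicolon-joined taxid path from the root, with a parallel
#' semicolon-joined column of support fractions (4 decimals).
#'
#' @param queries Query-level tibble from [classify_contigs()] /
#'   [classify_bins()] (or after [reduce_to_majority()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(queries, path) {
  queries <- arrange(queries, .data$query_id, .data$taxid)
  status_col <- ifelse(queries$status == "no-hits", "no ORFs with hits", queries$status)
  lineage_col <- vapply(queries$lineage, function(p) paste(p, collapse = ";"), character(1))
  support_col <- vapply(queries$support, function(s) paste(fmt_support(s), collapse = ";"), character(1))
  lines <- c(
    "# query_id\tstatus\tn_orfs_total\tn_orfs_classified\tlineage\tsupport",
    paste(queries$query_id, status_col, queries$n_orfs_total,
      queries$n_orfs_classified, lineage_col, support_col,
      sep = "\t"
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Add taxon names to a classification file
#'
#' Appends a name column to a file written by [write_classification()] (or
#' the ORF-level file). In full-lineage mode every taxid in the path gets
#' its scientific name suffixed with its rank in parentheses. With
#' `only_official = TRUE` the lineage is projected onto the seven official
#' ranks, with `"not classified"` placeholders for ranks the lineage does
#' not reach or skips.
#'
#' @param path Classification file to annotate.
#' @param tax A `taxonomy` object.
#' @param out_path Output path.
#' @param only_official Project onto official ranks only?
#' @param tolerant If `TRUE`, taxids absent from the taxonomy render as
#'   `"unknown taxid"` instead of raising an error.
#' @return `out_path`, invisibly.
#' @export
add_names <- function(path, tax, out_path, only_official = FALSE,
                      tolerant = FALSE) {
  lines <- readLines(path)
  header <- grepl("^#", lines)
  name_one <- function(t) {
    rt <- resolve_taxid(tax, t)
    if (is.na(rt)) {
      if (!tolerant) abort(paste0("taxid ", t, " not found in taxonomy"))
      return("unknown taxid")
    }
    paste0(taxon_name(tax, rt), " (", tax$rank[[as.character(rt)]], ")")
  }
  out <- character(length(lines))
  for (i in seq_along(lines)) {
    if (header[[i]]) {
      suffix <- if (only_official) {
        paste(paste0(official_ranks(), collapse = "\t"))
      } else {
        "names"
      }
      out[[i]] <- paste(lines[[i]], suffix, sep = "\t")
      next
    }
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    # lineage column: the field of ';'-joined integers (5th in query files,
    # 3rd single taxid in ORF files).
    lin_idx <- which(grepl("^[0-9]+(;[0-9]+)*$", fields))
    lin_idx <- if (length(lin_idx) > 0) lin_idx[[length(lin_idx)]] else 0L
    if (lin_idx == 0L) {
      filler <- if (only_official) {
        paste(rep("not classified", 7), collapse = "\t")
      } else {
        "not classified"
      }
      out[[i]] <- paste(lines[[i]], filler, sep = "\t")
      next
    }
    path_ids <- as.integer(strsplit(fields[[lin_idx]], ";", fixed = TRUE)[[1]])
    if (only_official) {
      proj <- official_rank_projection(tax, path_ids[[length(path_ids)]])
      cells <- vapply(official_ranks(), function(rk) {
        if (rk %in% names(proj)) name_one(proj[[rk]]) else "not classified"
      }, character(1))
      out[[i]] <- paste(lines[[i]], paste(cells, collapse = "\t"), sep = "\t")
    } else {
      nm <- vapply(path_ids, name_one, character(1))
      out[[i]] <- paste(lines[[i]], paste(nm, collapse = ";"), sep = "\t")
    }
  }
  writeLines(out, out_path)
  invisible(out_path)
}

#' Summarise a classification per taxon
#'
#' In contig mode, reports the total length of the contigs classified to
#' each terminal taxon (requires contig lengths, e.g. from
#' [fasta_lengths()]); in bin mode, the number of bins per taxon.
#' Unclassified queries are totalled under `"unclassified"`; totals
#' conserve the input sums.
#'
#' @param queries Query-level tibble (use [reduce_to_majority()] first when
#'   `f < 0.5` so each query has one line).
#' @param mode `"contig"` or `"bin"`.
#' @param lengths Named vector of contig lengths (contig mode only).
#' @param tax Optional `taxonomy` for name annotation.
#' @return A tibble `taxid`, `name`, `value` (total bp or bin count),
#'   sorted by decreasing value.
#' @export
summarise_classification <- function(queries, mode = c("contig", "bin"),
                                     lengths = NULL, tax = NULL) {
  mode <- match.arg(mode)
  one <- queries |> distinct(.data$query_id, .keep_all = TRUE)
  if (mode == "contig") {
    if (is.null(lengths)) abort("contig mode requires contig lengths")
    missing <- setdiff(one$query_id, names(lengths))
    if (length(missing) > 0) {
      abort(paste0(
        "contig(s) in classification absent from lengths: ",
        paste(missing, collapse = ", ")
      ))
    }
    one$value <- unname(lengths[one$query_id])
  } else {
    one$value <- 1
  }
  key <- ifelse(one$status == "classified", as.character(one$taxid), "unclassified")
  out <- tibble(key = key, value = one$value) |>
    group_by(.data$key) |>
    summarise(value = sum(.data$value), .groups = "drop")
  out$taxid <- suppressWarnings(as.integer(out$key))
  out$name <- ifelse(is.na(out$taxid), "unclassified",
    if (!is.null(tax)) taxon_name(tax, ifelse(is.na(out$taxid), 1L, out$taxid)) else out$key
  )
  out |>
    select("taxid", "name", "value") |>
    arrange(desc(.data$value), .data$taxid)
}
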