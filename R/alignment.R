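# Alignment table parsing and per-ORF / per-contig / per-bin grouping.

#' Split an ORF identifier into contig id and ORF index
#'
#' Gene callers in the Prodigal style name the proteins of a contig by
#' appending `"_<n>"` to the contig id, so the split is on the *last*
#' underscore, and only when the suffix is an integer. Identifiers without
#' an integer suffix are kept whole (orf_index 1) with a warning.
#'
#' @param orf_id Character vector of ORF identifiers.
#' @return A tibble with columns `orf_id`, `contig_id`, `orf_index`.
#' @export
parse_orf_id <- function(orf_id) {
  m <- regmatches(orf_id, regexpr("_[0-9]+$", orf_id))
  has_suffix <- grepl("_[0-9]+$", orf_id)
  contig_id <- orf_id
  orf_index <- rep(1L, length(orf_id))
  contig_id[has_suffix] <- sub("_[0-9]+$", "", orf_id[has_suffix])
  orf_index[has_suffix] <- as.integer(sub("^_", "", m))
  if (any(!has_suffix)) {
    warn(paste0(
      sum(!has_suffix),
      " ORF id(s) without an integer suffix; using the whole id as contig id"
    ))
  }
  tibble(orf_id = orf_id, contig_id = contig_id, orf_index = orf_index)
}

default_subject_strip <- function(sseqid) {
  # "ref|P1.1|" style decorations: take the token after the first pipe.
  piped <- grepl("|", sseqid, fixed = TRUE)
  out <- sseqid
  out[piped] <- vapply(strsplit(sseqid[piped], "|", fixed = TRUE), function(p) {
    p <- p[nzchar(p)]
    if (length(p) >= 2) p[[2]] else p[[1]]
  }, character(1))
  out
}

#' Read a BLAST/DIAMOND tabular alignment file
#'
#' Parses the 12-column `outfmt 6` dialect (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' Hits with e-value above `evalue_cutoff` are discarded at parse time.
#' The subject accession is the sseqid stripped of database decorations
#' (`"ref|P1.1|"` becomes `"P1.1"`); pass a different `strip` function for
#' other databases.
#'
#' @param path Path to the tabular file.
#' @param evalue_cutoff Maximum e-value to keep (default 0.001).
#' @param qseqid_col,sseqid_col,evalue_col,bitscore_col 1-based column
#'   indices, for non-standard layouts.
#' @param strip Function mapping raw sseqid strings to accessions.
#' @param tolerant If `TRUE`, malformed lines are skipped with a warning
#'   instead of raising an error.
#' @return A tibble of hits: `orf_id`, `subject`, `bitscore`, `evalue`,
#'   in file order.
#' @export
read_alignment <- function(path, evalue_cutoff = 0.001,
                           qseqid_col = 1L, sseqid_col = 2L,
                           evalue_col = 11L, bitscore_col = 12L,
                           strip = default_subject_strip,
                           tolerant = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n_cols_needed <- max(qseqid_col, sseqid_col, evalue_col, bitscore_col)
  orf <- character(0)
  subj <- character(0)
  bits <- numeric(0)
  eval_ <- numeric(0)
  bad <- 0L
  if (length(lines) > 0) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(fields) >= n_cols_needed
    if (any(!ok)) {
      if (!tolerant) {
        abort(paste0(
          "alignment line ", which(!ok)[[1]], ": expected at least ",
          n_cols_needed, " tab-separated columns"
        ))
      }
      bad <- sum(!ok)
      fields <- fields[ok]
    }
    orf <- vapply(fields, `[[`, character(1), qseqid_col)
    subj <- strip(vapply(fields, `[[`, character(1), sseqid_col))
    eval_ <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), evalue_col)))
    bits <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), bitscore_col)))
    nonnum <- is.na(eval_) | is.na(bits)
    if (any(nonnum)) {
      if (!tolerant) {
        abort(paste0(
          "alignment line ", which(ok)[which(nonnum)[[1]]],
          ": non-numeric evalue or bitscore"
        ))
      }
      bad <- bad + sum(nonnum)
      orf <- orf[!nonnum]; subj <- subj[!nonnum]
      eval_ <- eval_[!nonnum]; bits <- bits[!nonnum]
    }
  }
  if (bad > 0) warn(paste0(bad, " malformed alignment line(s) skipped"))
  keep <- eval_ <= evalue_cutoff
  tibble(
    orf_id = orf[keep], subject = subj[keep],
    bitscore = bits[keep], evalue = eval_[keep]
  )
}

#' Group alignment hits per ORF and contig
#'
#' Attaches contig ids via [parse_orf_id()], keeps only the best-scoring
#' line per (ORF, subject) pair so that one database protein cannot vote
#' twice for an ORF, and sorts each ORF's hits by descending bit-score
#' (stable: ties keep file order). The input need not be pre-sorted.
#'
#' @param hits A tibble as returned by [read_alignment()].
#' @return A tibble `orf_id`, `contig_id`, `orf_index`, `subject`,
#'   `bitscore`, `evalue`, sorted by contig, ORF index, then descending
#'   bit-score.
#' @export
group_hits <- function(hits) {
  parsed <- parse_orf_id(hits$orf_id)
  out <- hits
  out$contig_id <- parsed$contig_id
  out$orf_index <- parsed$orf_index
  out <- out |>
    group_by(.data$orf_id, .data$subject) |>
    slice(which.max(.data$bitscore)) |>
    ungroup() |>
    arrange(.data$contig_id, .data$orf_index, desc(.data$bitscore))
  out[, c("orf_id", "contig_id", "orf_index", "subject", "bitscore", "evalue")]
}

#' Load bin (MAG) membership
#'
#' Accepts either a directory of FASTA files — one bin per file, contig ids
#' taken from the header token before the first whitespace — or a 2-column
#' TSV mapping `contig_id` to `bin_id`. A contig may belong to at most one
#' bin.
#'
#' @param path A directory of FASTA files (`.fa`, `.fna`, `.fasta`) or a
#'   TSV file.
#' @return A tibble with columns `bin_id`, `contig_id`.
#' @export
load_bins <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|fna|fasta)$", full.names = TRUE)
    if (length(files) == 0) abort(paste0("no FASTA files found in ", path))
    out <- bind_rows(lapply(sort(files), function(f) {
      headers <- grep("^>", readLines(f), value = TRUE)
      ids <- sub("^>", "", vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1))
      tibble(bin_id = sub("\\.(fa|fna|fasta)$", "", basename(f)), contig_id = ids)
    }))
  } else {
    df <- utils::read.table(path,
      sep = "\t", header = FALSE, quote = "",
      comment.char = "", stringsAsFactors = FALSE
    )
    if (ncol(df) < 2) abort("bin table must have 2 columns: contig_id, bin_id")
    out <- tibble(bin_id = as.character(df[[2]]), contig_id = as.character(df[[1]]))
  }
  dup <- out$contig_id[duplicated(out$contig_id)]
  if (length(dup) > 0) {
    abort(paste0(
      "contig(s) assigned to more than one bin: ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  arrange(out, .data$bin_id, .data$contig_id)
}

#' Sequence lengths from a FASTA file
#'
#' @param path FASTA path.
#' @return Named integer vector of sequence lengths.
#' @export
fasta_lengths <- function(path) {
  lines <- readLines(path)
  is_header <- grepl("^>", lines)
  if (!any(is_header)) abort(paste0("no FASTA headers in ", path))
  ids <- sub("^>", "", vapply(strsplit(lines[is_header], "\\s+"), `[[`, character(1), 1))
  grp <- cumsum(is_header)
  lens <- vapply(split(nchar(lines[!is_header]), grp[!is_header]), sum, numeric(1))
  out <- setNames(rep(0L, length(ids)), ids)
  out[as.integer(names(lens))] <- as.integer(lens)
  out
}

#' ORF identifiers from a protein FASTA
#'
#' The id is the header token before the first whitespace, the Prodigal
#' convention. Used to count ORFs that received no hits at all.
#'
#' @param path Protein FASTA path.
#' @return Character vector of ORF ids.
#' @export
read_protein_ids <- function(path) {
  headers <- grep("^>", readLines(path), value = TRUE)
  sub("^>", "", vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1))
}
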