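# Core classifier: per-ORF LCA within a bit-score range of the top hit,
# then bit-score-weighted voting over all ORFs of a contig or bin.

#' Classifier parameter sets
#'
#' `r` is the percentage below the top hit's bit-score within which hits are
#' included in an ORF's LCA; `f` is the minimum fraction of the summed
#' top-hit bit-scores (B_sum) a taxon must accumulate to be reported
#' (mbs = f x B_sum). Contig mode defaults to `r = 10`, `f = 0.5`; bin
#' (MAG) mode, which pools evidence over many contigs and can afford to be
#' more specific, defaults to `r = 5`, `f = 0.3`.
#'
#' @param r Bit-score range, percent in \[0, 100\].
#' @param f Minimum support fraction, in (0, 1\].
#' @param evalue_cutoff Maximum alignment e-value, applied at parse time.
#' @return A list with class `taxvote_params`.
#' @export
contig_params <- function(r = 10, f = 0.5, evalue_cutoff = 0.001) {
  new_params(r, f, evalue_cutoff, mode = "contig")
}

#' @rdname contig_params
#' @export
bin_params <- function(r = 5, f = 0.3, evalue_cutoff = 0.001) {
  new_params(r, f, evalue_cutoff, mode = "bin")
}

new_params <- function(r, f, evalue_cutoff, mode) {
  if (r < 0 || r > 100) abort("r must be in [0, 100]")
  if (f <= 0 || f > 1) abort("f must be in (0, 1]")
  structure(
    list(r = r, f = f, evalue_cutoff = evalue_cutoff, mode = mode),
    class = "taxvote_params"
  )
}

#' Classify each ORF by the LCA of its near-top hits
#'
#' For each ORF, hits whose accession resolves to a taxid are considered;
#' the best resolvable bit-score is the top score, and every resolvable hit
#' with `bitscore >= top * (1 - r/100)` (boundary inclusive — a tie with
#' the top hit is never excluded) contributes its taxid. The ORF is
#' assigned the LCA of the distinct taxids, and the top bit-score is
#' registered as the ORF's vote weight. ORFs with no hits, or none whose
#' accession maps to a taxid, are reported unclassified with a reason.
#'
#' @param hits A grouped hit tibble from [group_hits()] (or any tibble with
#'   `orf_id`, `contig_id`, `subject`, `bitscore`).
#' @param tax A `taxonomy` object.
#' @param protmap A `protein_map`.
#' @param r Bit-score range, percent.
#' @param all_orf_ids Optional character vector of every predicted ORF id
#'   (e.g. from the protein FASTA); ORFs absent from `hits` are appended as
#'   unclassified with reason `"no hits"`.
#' @return A tibble: `orf_id`, `contig_id`, `orf_index`, `lca_taxid`
#'   (`NA` when unclassified), `bitscore` (registered top-hit score),
#'   `n_hits_in_range`, `reason` (`NA` when classified).
#' @export
classify_orfs <- function(hits, tax, protmap, r = 10, all_orf_ids = NULL) {
  stopifnot(r >= 0, r <= 100)
  if (!all(c("contig_id", "orf_index") %in% names(hits))) hits <- group_hits(hits)
  hits <- hits |> mutate(taxid = resolve_accession(protmap, .data$subject))
  rows <- hits |>
    group_by(.data$orf_id, .data$contig_id, .data$orf_index) |>
    summarise(res = list(classify_one_orf(.data$bitscore, .data$taxid, r, tax)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("res")

  if (!is.null(all_orf_ids)) {
    missing <- setdiff(all_orf_ids, rows$orf_id)
    if (length(missing) > 0) {
      parsed <- parse_orf_id(missing)
      rows <- bind_rows(rows, tibble(
        orf_id = missing, contig_id = parsed$contig_id,
        orf_index = parsed$orf_index, lca_taxid = NA_integer_,
        bitscore = NA_real_, n_hits_in_range = 0L, reason = "no hits"
      ))
    }
  }
  arrange(rows, .data$contig_id, .data$orf_index, .data$orf_id)
}

classify_one_orf <- function(bitscore, taxid, r, tax) {
  ok <- !is.na(taxid)
  if (!any(ok)) {
    reason <- if (length(bitscore) == 0) "no hits" else "no taxid for hits"
    return(list(
      lca_taxid = NA_integer_, bitscore = NA_real_,
      n_hits_in_range = 0L, reason = reason
    ))
  }
  b <- bitscore[ok]
  t <- taxid[ok]
  top <- max(b)
  thr <- top * (1 - r / 100)
  in_range <- b >= thr * (1 - .taxvote_eps)
  list(
    lca_taxid = lca(tax, unique(t[in_range])),
    bitscore = top,
    n_hits_in_range = sum(in_range),
    reason = NA_character_
  )
}

#' Sum ORF vote weights over the taxonomy
#'
#' Each classified ORF adds its registered top-hit bit-score to its LCA
#' taxon and to every ancestor up to the root. Unclassified ORFs contribute
#' nothing. The root's total therefore equals `b_sum`, the sum of
#' registered bit-scores over classified ORFs.
#'
#' @param orfs A tibble from [classify_orfs()] (columns `lca_taxid`,
#'   `bitscore`).
#' @param tax A `taxonomy` object.
#' @return A `vote_table`: named numeric vector taxid -> summed bits, with
#'   attribute `b_sum`.
#' @export
vote <- function(orfs, tax) {
  support <- numeric()
  b_sum <- 0
  ok <- !is.na(orfs$lca_taxid)
  for (i in which(ok)) {
    s <- orfs$bitscore[[i]]
    b_sum <- b_sum + s
    for (node in as.character(lineage(tax, orfs$lca_taxid[[i]]))) {
      support[[node]] <- (if (node %in% names(support)) support[[node]] else 0) + s
    }
  }
  structure(support, b_sum = b_sum, class = "vote_table")
}

#' @export
print.vote_table <- function(x, ...) {
  cat("<vote_table> ", length(x), " taxa, b_sum = ", attr(x, "b_sum"), "\n", sep = "")
  invisible(x)
}

#' Assign a query to its deepest supported lineages
#'
#' Computes the minimum bit-score support `mbs = f * b_sum` and reports the
#' set of deepest taxa whose summed support reaches `mbs`: a node qualifies
#' only if none of its descendants does, so the walk stops at the lowest
#' rank that is still reliable. With `f > 0.5` at most one lineage can
#' qualify; with smaller `f`, several lineages may pass the threshold and
#' all are reported, each with per-node support fractions of `b_sum`.
#'
#' @param query_id Query (contig or bin) identifier.
#' @param votes A `vote_table` from [vote()].
#' @param f Minimum support fraction, in (0, 1].
#' @param tax A `taxonomy` object.
#' @param n_orfs_total,n_orfs_classified ORF counts carried into the output.
#' @return A tibble with one row per reported lineage: `query_id`,
#'   `status` (`"classified"` / `"no-hits"`), `n_orfs_total`,
#'   `n_orfs_classified`, `b_sum`, `taxid` (terminal node), `lineage`
#'   (list-column of taxid paths), `support` (list-column of fractions).
#' @export
assign_query <- function(query_id, votes, f, tax,
                         n_orfs_total = NA_integer_,
                         n_orfs_classified = NA_integer_) {
  if (f <= 0 || f > 1) abort("f must be in (0, 1]")
  b_sum <- attr(votes, "b_sum")
  if (length(votes) == 0 || b_sum <= 0) {
    return(tibble(
      query_id = query_id, status = "no-hits",
      n_orfs_total = as.integer(n_orfs_total),
      n_orfs_classified = as.integer(n_orfs_classified),
      b_sum = 0, taxid = NA_integer_,
      lineage = list(integer()), support = list(numeric())
    ))
  }
  mbs <- f * b_sum
  qualifies <- unclass(votes) >= mbs * (1 - .taxvote_eps)
  qual_ids <- as.integer(names(votes)[qualifies])
  # Deepest qualifying nodes: those that are not a proper ancestor of
  # another qualifying node.
  qual_paths <- lapply(qual_ids, function(t) lineage(tax, t))
  ancestors <- unique(unlist(lapply(qual_paths, function(p) p[-length(p)])))
  terminal <- qual_ids[!(qual_ids %in% ancestors)]
  terminal <- sort(terminal)

  rows <- lapply(terminal, function(t) {
    path <- lineage(tax, t)
    tibble(
      query_id = query_id, status = "classified",
      n_orfs_total = as.integer(n_orfs_total),
      n_orfs_classified = as.integer(n_orfs_classified),
      b_sum = b_sum, taxid = t,
      lineage = list(path),
      support = list(unname(unclass(votes)[as.character(path)] / b_sum))
    )
  })
  bind_rows(rows)
}

#' Classify contigs from a hit table
#'
#' Runs the full pipeline per contig: per-ORF LCA ([classify_orfs()]),
#' bit-score voting ([vote()]) and threshold assignment ([assign_query()]).
#'
#' @param hits A grouped hit tibble from [group_hits()].
#' @param tax A `taxonomy` object.
#' @param protmap A `protein_map`.
#' @param params A `taxvote_params`, default [contig_params()].
#' @param all_orf_ids Optional vector of all predicted ORF ids, so hitless
#'   ORFs are counted and reported.
#' @return A list with `orfs` (the ORF-level tibble) and `queries` (the
#'   query-level tibble, one row per reported lineage).
#' @export
classify_contigs <- function(hits, tax, protmap, params = contig_params(),
                             all_orf_ids = NULL) {
  orfs <- classify_orfs(hits, tax, protmap, r = params$r, all_orf_ids = all_orf_ids)
  queries <- orfs |>
    group_by(.data$contig_id) |>
    group_split() |>
    lapply(function(g) {
      assign_query(
        g$contig_id[[1]], vote(g, tax), params$f, tax,
        n_orfs_total = nrow(g),
        n_orfs_classified = sum(!is.na(g$lca_taxid))
      )
    }) |>
    bind_rows()
  list(orfs = orfs, queries = queries)
}

#' Classify bins (MAGs) from a hit table and bin membership
#'
#' Identical to [classify_contigs()] but pools the ORFs of all contigs of a
#' bin before voting. Contigs not assigned to any bin are ignored.
#'
#' @inheritParams classify_contigs
#' @param bins A tibble `bin_id`, `contig_id` from [load_bins()].
#' @param params A `taxvote_params`, default [bin_params()].
#' @return A list with `orfs` and `queries` (one row per reported lineage,
#'   `query_id` = bin id).
#' @export
classify_bins <- function(hits, bins, tax, protmap, params = bin_params(),
                          all_orf_ids = NULL) {
  orfs <- classify_orfs(hits, tax, protmap, r = params$r, all_orf_ids = all_orf_ids)
  orfs_b <- left_join(orfs, bins, by = "contig_id")
  queries <- orfs_b |>
    filter(!is.na(.data$bin_id)) |>
    group_by(.data$bin_id) |>
    group_split() |>
    lapply(function(g) {
      assign_query(
        g$bin_id[[1]], vote(g, tax), params$f, tax,
        n_orfs_total = nrow(g),
        n_orfs_classified = sum(!is.na(g$lca_taxid))
      )
    }) |>
    bind_rows()
  list(orfs = orfs, queries = queries)
}

#' Reduce multi-lineage classifications to the majority lineage
#'
#' When `f < 0.5` a query may carry several qualifying lineages. For
#' scoring (and optionally for output) each query is reduced to the single
#' deepest node whose support fraction exceeds 0.5 — the classification
#' that a majority of the summed bit-score supports, as if `f = 0.5` had
#' been used. The root always qualifies, so every classified query keeps
#' one lineage. Queries computed at `f >= 0.5` are generically unchanged.
#'
#' @param queries A query-level tibble from [classify_contigs()] /
#'   [classify_bins()].
#' @return A tibble of the same shape with exactly one row per classified
#'   query.
#' @export
reduce_to_majority <- function(queries) {
  queries |>
    group_by(.data$query_id) |>
    group_split() |>
    lapply(function(g) {
      if (g$status[[1]] != "classified") return(g[1, ])
      # Pool (node, fraction) pairs over all reported lineages; majority
      # nodes form a root-anchored chain, so the longest path wins.
      best_i <- 0L
      best_len <- -1L
      best_path <- integer()
      best_sup <- numeric()
      for (i in seq_len(nrow(g))) {
        path <- g$lineage[[i]]
        sup <- g$support[[i]]
        keep <- sup > 0.5 * (1 + .taxvote_eps)
        len <- max(which(keep))  # root is always > 0.5
        if (len > best_len) {
          best_len <- len
          best_path <- path[seq_len(len)]
          best_sup <- sup[seq_len(len)]
        }
      }
      out <- g[1, ]
      out$taxid <- best_path[[best_len]]
      out$lineage <- list(best_path)
      out$support <- list(best_sup)
      out
    }) |>
    bind_rows()
}
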