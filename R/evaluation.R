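# Benchmark scoring: lineage-subset correctness over contig sets, and
# base-pair precision/recall in the style of community binning challenges.

#' Integer value of an official rank
#'
#' Species through superkingdom map to 0 through 6, so mean/median rank of
#' classification summarises how deep calls are on average.
#'
#' @param rank_name Character vector of official rank names.
#' @return Integer vector (species = 0, ..., superkingdom = 6).
#' @export
rank_to_int <- function(rank_name) {
  idx <- match(rank_name, official_ranks())
  if (anyNA(idx)) {
    abort(paste0(
      "not an official rank: ",
      paste(unique(rank_name[is.na(idx)]), collapse = ", ")
    ))
  }
  idx - 1L
}

#' Is a predicted lineage correct for a known truth?
#'
#' A prediction is correct when its whole lineage is a subset of the true
#' lineage, regardless of the rank of classification — equivalently, when
#' the predicted terminal node lies on the true lineage. A prediction
#' deeper than the truth (classified too specifically, e.g. at species rank
#' when the query represents a novel family) is incorrect.
#'
#' @param predicted_taxid Terminal taxid of the predicted lineage.
#' @param true_taxid The query's true taxid.
#' @param tax A `taxonomy` object.
#' @return Logical.
#' @export
is_correct <- function(predicted_taxid, true_taxid, tax) {
  p <- resolve_taxid(tax, predicted_taxid)
  if (is.na(p)) return(FALSE)
  p %in% lineage(tax, true_taxid)
}

# Deepest official-rank ancestor-or-self of a taxid; NA when the lineage
# carries no official rank (e.g. the root).
project_official <- function(tax, taxid) {
  proj <- official_rank_projection(tax, taxid)
  if (length(proj) == 0) return(NA_integer_)
  proj[[1]]
}

#' Score a classified contig set against known truth
#'
#' Computes the four whole-set measures: fraction of classified contigs,
#' sensitivity (correct / total), precision (correct / classified), and
#' mean and median rank of classification. Predictions at unofficial ranks
#' are projected to their deepest official ancestor first; predictions
#' above superkingdom (root, "cellular organisms") count as unclassified
#' since they are trivially informative. Correctness is the lineage-subset
#' rule of [is_correct()]. A per-rank breakdown scores each official rank
#' independently: at each rank, a prediction is correct when the truth has
#' a node at that rank and the projected prediction matches it, so only the
#' too-specific part of a lineage is penalised.
#'
#' @param predictions Query-level tibble with one row per query (apply
#'   [reduce_to_majority()] first when `f < 0.5`).
#' @param truth A tibble `query_id`, `true_taxid` (and optionally `length`).
#' @param tax A `taxonomy` object.
#' @return A list of class `contig_set_scores`: `n`, `fraction_classified`,
#'   `sensitivity`, `precision`, `mean_rank`, `median_rank`, and `per_rank`
#'   (a tibble with the same measures per official rank).
#' @export
score_contig_set <- function(predictions, truth, tax) {
  missing <- setdiff(predictions$query_id, truth$query_id)
  if (length(missing) > 0) {
    abort(paste0("query missing from truth: ", paste(missing, collapse = ", ")))
  }
  df <- left_join(truth, predictions, by = "query_id")
  n <- nrow(df)
  proj <- vapply(seq_len(n), function(i) {
    if (is.na(df$status[[i]]) || df$status[[i]] != "classified") return(NA_integer_)
    project_official(tax, df$taxid[[i]])
  }, integer(1))
  classified <- !is.na(proj)
  correct <- vapply(seq_len(n), function(i) {
    classified[[i]] && is_correct(proj[[i]], df$true_taxid[[i]], tax)
  }, logical(1))
  ranks <- rep(NA_integer_, n)
  ranks[classified] <- rank_to_int(tax$rank[as.character(proj[classified])])

  per_rank <- bind_rows(lapply(official_ranks(), function(rk) {
    pred_at <- vapply(seq_len(n), function(i) {
      if (!classified[[i]]) return(NA_integer_)
      pr <- official_rank_projection(tax, proj[[i]])
      if (rk %in% names(pr)) pr[[rk]] else NA_integer_
    }, integer(1))
    true_at <- vapply(seq_len(n), function(i) {
      tr <- official_rank_projection(tax, df$true_taxid[[i]])
      if (rk %in% names(tr)) tr[[rk]] else NA_integer_
    }, integer(1))
    cls <- !is.na(pred_at)
    cor <- cls & !is.na(true_at) & pred_at == true_at
    tibble(
      rank = rk,
      fraction_classified = sum(cls) / n,
      sensitivity = sum(cor) / n,
      precision = if (sum(cls) > 0) sum(cor) / sum(cls) else NA_real_
    )
  }))

  structure(
    list(
      n = n,
      fraction_classified = sum(classified) / n,
      sensitivity = sum(correct) / n,
      precision = if (any(classified)) sum(correct) / sum(classified) else NA_real_,
      mean_rank = if (any(classified)) mean(ranks[classified]) else NA_real_,
      median_rank = if (any(classified)) median(ranks[classified]) else NA_real_,
      per_rank = per_rank
    ),
    class = "contig_set_scores"
  )
}

#' @export
print.contig_set_scores <- function(x, ...) {
  cat("<contig_set_scores> n = ", x$n, "\n", sep = "")
  cat(sprintf(
    "  fraction classified %.4f | sensitivity %.4f | precision %.4f\n",
    x$fraction_classified, x$sensitivity, x$precision
  ))
  cat(sprintf("  mean rank %.3f | median rank %.1f\n", x$mean_rank, x$median_rank))
  invisible(x)
}

#' Base-pair classification measures at one rank
#'
#' Scores predictions the way community taxonomic-binning challenges do:
#' every measure is a function of classified base pairs, evaluated at one
#' official rank at a time. Accuracy is correctly classified bp over total
#' bp; misclassification is incorrectly classified bp over total bp.
#' Average precision is the mean purity of predicted taxon bins (correct bp
#' / assigned bp per predicted taxon); average recall is the mean
#' completeness of real taxon bins, including real taxa that received no
#' correct assignment (recall 0). Queries predicted at `rank` whose gold
#' standard lineage has no node at `rank` are not taken into account — an
#' over-specific call is not penalised.
#'
#' @param predictions Query-level tibble, one row per query.
#' @param truth A tibble `query_id`, `true_taxid`, `length` (bp).
#' @param tax A `taxonomy` object.
#' @param rank Official rank name at which to evaluate.
#' @param small_bin_fraction When non-zero, also recompute average
#'   precision after dropping the smallest predicted bins summing to at
#'   most this fraction of the data (see [filter_small_bins()]).
#' @return A list of class `cami_scores`: `rank`, `accuracy`,
#'   `misclassification`, `average_precision`, `average_recall`,
#'   `average_precision_filtered`, plus the per-bin tibbles.
#' @export
cami_score <- function(predictions, truth, tax, rank,
                       small_bin_fraction = 0.01) {
  if (!rank %in% official_ranks()) abort(paste0("not an official rank: ", rank))
  if (!"length" %in% names(truth) || anyNA(truth$length)) {
    abort("cami_score() requires a length for every query")
  }
  df <- left_join(truth, predictions, by = "query_id")
  n <- nrow(df)
  pred_at <- vapply(seq_len(n), function(i) {
    if (is.na(df$status[[i]]) || df$status[[i]] != "classified") return(NA_integer_)
    pr <- official_rank_projection(tax, df$taxid[[i]])
    if (rank %in% names(pr)) pr[[rank]] else NA_integer_
  }, integer(1))
  true_at <- vapply(seq_len(n), function(i) {
    tr <- official_rank_projection(tax, df$true_taxid[[i]])
    if (rank %in% names(tr)) tr[[rank]] else NA_integer_
  }, integer(1))

  # Predictions at a rank absent from the gold standard are excluded.
  considered <- !(!is.na(pred_at) & is.na(true_at))
  d <- tibble(
    query_id = df$query_id[considered],
    length = df$length[considered],
    pred = pred_at[considered],
    truth = true_at[considered]
  )
  assigned <- !is.na(d$pred)
  correct <- assigned & !is.na(d$truth) & d$pred == d$truth
  total_bp <- sum(d$length)

  pred_bins <- d |>
    filter(!is.na(.data$pred)) |>
    group_by(taxid = .data$pred) |>
    summarise(
      assigned_bp = sum(.data$length),
      correct_bp = sum(.data$length[!is.na(.data$truth) & .data$truth == .data$taxid[[1]]]),
      .groups = "drop"
    ) |>
    mutate(precision = .data$correct_bp / .data$assigned_bp)

  real_bins <- d |>
    filter(!is.na(.data$truth)) |>
    group_by(taxid = .data$truth) |>
    summarise(
      real_bp = sum(.data$length),
      correct_bp = sum(.data$length[!is.na(.data$pred) & .data$pred == .data$taxid[[1]]]),
      .groups = "drop"
    ) |>
    mutate(recall = .data$correct_bp / .data$real_bp)

  avg_prec_filt <- NA_real_
  if (small_bin_fraction > 0 && nrow(pred_bins) > 0) {
    kept <- filter_small_bins(pred_bins, small_bin_fraction)
    avg_prec_filt <- if (nrow(kept) > 0) mean(kept$precision) else NA_real_
  }

  structure(
    list(
      rank = rank,
      accuracy = if (total_bp > 0) sum(d$length[correct]) / total_bp else NA_real_,
      misclassification = if (total_bp > 0) {
        sum(d$length[assigned & !correct]) / total_bp
      } else {
        NA_real_
      },
      average_precision = if (nrow(pred_bins) > 0) mean(pred_bins$precision) else NA_real_,
      average_recall = if (nrow(real_bins) > 0) mean(real_bins$recall) else NA_real_,
      average_precision_filtered = avg_prec_filt,
      predicted_bins = pred_bins,
      real_bins = real_bins
    ),
    class = "cami_scores"
  )
}

#' @export
print.cami_scores <- function(x, ...) {
  cat("<cami_scores> rank: ", x$rank, "\n", sep = "")
  cat(sprintf(
    "  accuracy %.4f | misclassification %.4f\n  avg precision %.4f (99%% of data: %.4f) | avg recall %.4f\n",
    x$accuracy, x$misclassification, x$average_precision,
    x$average_precision_filtered, x$average_recall
  ))
  invisible(x)
}

#' Drop the smallest predicted bins up to a data fraction
#'
#' Removes predicted bins in ascending order of assigned base pairs while
#' the cumulative removed length stays at or below
#' `threshold_fraction x total length`. Used to recompute average
#' precision on 99% of the data, since per-bin precision is very sensitive
#' to tiny erroneous bins. Ties between equal-size bins break
#' lexicographically on the taxid, for determinism.
#'
#' @param pred_bins Tibble with columns `taxid` and `assigned_bp` (as in
#'   the `predicted_bins` element of [cami_score()]).
#' @param threshold_fraction Fraction of the total assigned length allowed
#'   to be removed, in \[0, 1); default 0.01.
#' @return The surviving rows of `pred_bins`.
#' @export
filter_small_bins <- function(pred_bins, threshold_fraction = 0.01) {
  if (threshold_fraction < 0 || threshold_fraction >= 1) {
    abort("threshold_fraction must be in [0, 1)")
  }
  if (threshold_fraction == 0 || nrow(pred_bins) == 0) return(pred_bins)
  total <- sum(pred_bins$assigned_bp)
  ord <- order(pred_bins$assigned_bp, as.character(pred_bins$taxid))
  cum <- cumsum(pred_bins$assigned_bp[ord])
  drop_idx <- ord[cum <= threshold_fraction * total]
  if (length(drop_idx) == 0) return(pred_bins)
  pred_bins[-drop_idx, , drop = FALSE]
}
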