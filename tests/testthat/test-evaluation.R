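tax <- fixture_tax()

pred_row <- function(query_id, taxid) {
  tibble::tibble(
    query_id = query_id,
    status = ifelse(is.na(taxid), "no-hits", "classified"),
    taxid = as.integer(taxid)
  )
}

test_that("is_correct implements the lineage-subset rule", {
  # predicted genus, truth a species under it: correct
  expect_true(is_correct(50L, 60L, tax))
  # sibling species: incorrect
  expect_false(is_correct(61L, 60L, tax))
  # prediction deeper than the truth (novel clade): too specific, incorrect
  expect_false(is_correct(60L, 50L, tax))
  # equal is correct; root is trivially a subset
  expect_true(is_correct(60L, 60L, tax))
  expect_true(is_correct(1L, 60L, tax))
})

test_that("rank_to_int maps species..superkingdom to 0..6", {
  expect_equal(rank_to_int("species"), 0L)
  expect_equal(rank_to_int("genus"), 1L)
  expect_equal(rank_to_int("phylum"), 5L)
  expect_equal(rank_to_int("superkingdom"), 6L)
  expect_error(rank_to_int("no rank"), "official")
})

test_that("score_contig_set reproduces hand-computed whole-set measures", {
  # 10 contigs, all truly species 60; 8 classified, of which 6 correct
  preds <- dplyr::bind_rows(
    pred_row("q1", 60L), # species, correct
    pred_row("q2", 60L),
    pred_row("q3", 50L), # genus, correct
    pred_row("q4", 40L), # family, correct
    pred_row("q5", 2L), # superkingdom, correct
    pred_row("q6", 10L), # phylum, correct
    pred_row("q7", 61L), # sibling species, incorrect
    pred_row("q8", 62L), # other genus, incorrect
    pred_row("q9", NA), # unclassified
    pred_row("q10", 1L) # root call counts as unclassified
  )
  truth <- tibble::tibble(query_id = paste0("q", 1:10), true_taxid = 60L)
  s <- score_contig_set(preds, truth, tax)
  expect_equal(s$fraction_classified, 0.8)
  expect_equal(s$precision, 6 / 8)
  expect_equal(s$sensitivity, 0.6)
  # ranks of the 8 classified: 0,0,1,2,6,5,0,0
  expect_equal(s$mean_rank, mean(c(0, 0, 1, 2, 6, 5, 0, 0)))
  expect_equal(s$median_rank, 0.5)

  # per-rank breakdown at genus: q1,q2,q3,q7,q8 carry a genus node; q7's
  # wrong species still projects to the right genus (only the too-specific
  # part of a lineage is penalised), q8's genus is wrong
  per_genus <- s$per_rank[s$per_rank$rank == "genus", ]
  expect_equal(per_genus$fraction_classified, 5 / 10)
  expect_equal(per_genus$precision, 4 / 5)

  expect_error(
    score_contig_set(pred_row("nope", 60L), truth, tax),
    "nope"
  )
})

test_that("mean rank of a species and a phylum call is 2.5", {
  preds <- dplyr::bind_rows(pred_row("q1", 60L), pred_row("q2", 10L))
  truth <- tibble::tibble(query_id = c("q1", "q2"), true_taxid = 60L)
  s <- score_contig_set(preds, truth, tax)
  expect_equal(s$mean_rank, 2.5)
})

test_that("sensitivity equals fraction_classified times precision", {
  cfg <- synth_config(seed = 3)
  stax <- synth_taxonomy(cfg)
  ids <- taxa_at_rank(stax, "species")
  nodes <- as.integer(names(stax$parent))
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    truth <- tibble::tibble(
      query_id = paste0("q", 1:n), true_taxid = sample(ids, n, replace = TRUE)
    )
    preds <- dplyr::bind_rows(lapply(1:n, function(j) {
      if (runif(1) < 0.2) {
        pred_row(paste0("q", j), NA)
      } else if (runif(1) < 0.5) {
        pred_row(paste0("q", j), sample(lineage(stax, truth$true_taxid[[j]]), 1))
      } else {
        pred_row(paste0("q", j), sample(nodes, 1))
      }
    }))
    s <- score_contig_set(preds, truth, stax)
    expect_equal(s$sensitivity, s$fraction_classified * s$precision,
      tolerance = 1e-12
    )
  }
})

cami_fixture <- function() {
  # at genus rank: predicted bin 50 is 1000 bp pure; predicted bin 51 is
  # 500 bp, half correct; q4 is unclassified
  preds <- dplyr::bind_rows(
    pred_row("q1", 60L), # genus 50, truth genus 50: correct, 1000 bp
    pred_row("q2", 62L), # genus 51, truth genus 51: correct, 250 bp
    pred_row("q3", 62L), # genus 51, truth genus 50: incorrect, 250 bp
    pred_row("q4", NA) # unclassified, 100 bp
  )
  truth <- tibble::tibble(
    query_id = paste0("q", 1:4),
    true_taxid = c(60L, 62L, 60L, 61L),
    length = c(1000, 250, 250, 100)
  )
  list(preds = preds, truth = truth)
}

test_that("cami_score reproduces hand-computed base-pair measures", {
  fx <- cami_fixture()
  cs <- cami_score(fx$preds, fx$truth, tax, rank = "genus", small_bin_fraction = 0)
  expect_equal(cs$accuracy, 1250 / 1600)
  expect_equal(cs$misclassification, 250 / 1600)
  expect_equal(cs$average_precision, (1 + 0.5) / 2)
  # real genus bins: 50 has 1350 bp of which 1000 correct; 51 has 250/250
  expect_equal(cs$average_recall, (1000 / 1350 + 1) / 2)

  # perfect single-taxon case
  p1 <- pred_row("q1", 60L)
  t1 <- tibble::tibble(query_id = "q1", true_taxid = 60L, length = 500)
  c1 <- cami_score(p1, t1, tax, rank = "species")
  expect_equal(c1$accuracy, 1)
  expect_equal(c1$misclassification, 0)
  expect_equal(c1$average_precision, 1)
  expect_equal(c1$average_recall, 1)

  # an unclassified query counts against accuracy but not misclassification
  expect_lt(cs$accuracy + cs$misclassification, 1)

  expect_error(
    cami_score(p1, tibble::tibble(query_id = "q1", true_taxid = 60L), tax, "species"),
    "length"
  )
})

test_that("predictions at ranks absent from the gold standard are ignored", {
  # truth known only to genus; species-level prediction is not penalised
  preds <- dplyr::bind_rows(pred_row("q1", 60L), pred_row("q2", 60L))
  truth <- tibble::tibble(
    query_id = c("q1", "q2"),
    true_taxid = c(50L, 60L), # q1's truth has no species rank
    length = c(400, 600)
  )
  cs <- cami_score(preds, truth, tax, rank = "species")
  expect_equal(cs$accuracy, 1) # only q2 is taken into account
  expect_equal(cs$misclassification, 0)
})

test_that("accuracy is invariant to how queries group into bins", {
  fx <- cami_fixture()
  cs <- cami_score(fx$preds, fx$truth, tax, rank = "genus")
  # direct per-query computation, no binning involved
  correct_bp <- sum(vapply(1:4, function(i) {
    p <- fx$preds$taxid[[i]]
    if (is.na(p)) return(0)
    pg <- official_rank_projection(tax, p)[["genus"]]
    tg <- official_rank_projection(tax, fx$truth$true_taxid[[i]])[["genus"]]
    if (identical(pg, tg)) fx$truth$length[[i]] else 0
  }, numeric(1)))
  expect_equal(cs$accuracy, correct_bp / sum(fx$truth$length))
})

test_that("filter_small_bins removes smallest bins up to the data fraction", {
  bins <- tibble::tibble(
    taxid = c(1L, 2L, 3L), assigned_bp = c(1, 1, 98), precision = c(0, 0, 1)
  )
  kept <- filter_small_bins(bins, 0.01)
  expect_equal(nrow(kept), 2) # removing both 1-bp bins would exceed 1%
  expect_setequal(kept$assigned_bp, c(1, 98))

  expect_equal(filter_small_bins(bins, 0), bins)
  equal <- tibble::tibble(taxid = 1:3, assigned_bp = c(50, 50, 50))
  expect_equal(filter_small_bins(equal, 0.01), equal)

  # recomputed average precision after dropping a tiny impure bin
  fx <- cami_fixture()
  preds2 <- dplyr::bind_rows(fx$preds, pred_row("q5", 70L)) # 5 bp wrong-genus bin
  truth2 <- dplyr::bind_rows(
    fx$truth,
    tibble::tibble(query_id = "q5", true_taxid = 60L, length = 5)
  )
  cs <- cami_score(preds2, truth2, tax, rank = "genus", small_bin_fraction = 0.01)
  expect_lt(cs$average_precision, cs$average_precision_filtered)
})
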