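tax <- fixture_tax()
pm <- fixture_protmap()

test_that("classify_orfs takes the LCA of hits within the bit-score range", {
  # top 100, r = 10 -> threshold 90: species 60 and 61 included, LCA genus 50
  h <- orf_hits("c1_1", c("P60", "P61", "P70"), c(100, 95, 85))
  o10 <- classify_orfs(h, tax, pm, r = 10)
  expect_equal(o10$lca_taxid, 50L)
  expect_equal(o10$bitscore, 100)
  expect_equal(o10$n_hits_in_range, 2L)
  expect_true(is.na(o10$reason))

  # r = 20 -> threshold 80: 70 (another genus, same family) joins, LCA family 40
  o20 <- classify_orfs(h, tax, pm, r = 20)
  expect_equal(o20$lca_taxid, 40L)
  expect_equal(o20$n_hits_in_range, 3L)

  # singleton hit: LCA is the hit's own taxon at any r
  o1 <- classify_orfs(orf_hits("c1_1", "P60", 100), tax, pm, r = 50)
  expect_equal(o1$lca_taxid, 60L)
  expect_equal(o1$bitscore, 100)

  # boundary inclusive: a hit exactly at top * (1 - r/100) is included
  hb <- orf_hits("c1_1", c("P60", "P61"), c(100, 90))
  expect_equal(classify_orfs(hb, tax, pm, r = 10)$n_hits_in_range, 2L)
})

test_that("unmappable hits are skipped before the top bit-score is set", {
  # best hit unmapped: top comes from the best *resolvable* hit
  h <- orf_hits("c1_1", c("UNKNOWN", "P60", "P61"), c(200, 100, 95))
  o <- classify_orfs(h, tax, pm, r = 10)
  expect_equal(o$bitscore, 100)
  expect_equal(o$lca_taxid, 50L)

  # nothing resolvable -> unclassified with a reason
  h2 <- orf_hits("c1_1", "UNKNOWN", 200)
  o2 <- classify_orfs(h2, tax, pm, r = 10)
  expect_true(is.na(o2$lca_taxid))
  expect_equal(o2$reason, "no taxid for hits")

  # hitless ORFs known from the protein FASTA are reported too
  o3 <- classify_orfs(h, tax, pm, r = 10, all_orf_ids = c("c1_1", "c1_2"))
  expect_equal(nrow(o3), 2)
  expect_equal(o3$reason[o3$orf_id == "c1_2"], "no hits")
})

test_that("vote sums registered bit-scores up every ancestral lineage", {
  orfs <- tibble::tibble(
    lca_taxid = c(60L, 61L, 50L), bitscore = c(100, 80, 60)
  )
  v <- vote(orfs, tax)
  expect_equal(attr(v, "b_sum"), 240)
  expect_equal(unname(v[["50"]]), 240)
  expect_equal(unname(v[["60"]]), 100)
  expect_equal(unname(v[["61"]]), 80)
  expect_equal(unname(v[[as.character(tax$root)]]), 240)

  # zero classified ORFs
  v0 <- vote(tibble::tibble(lca_taxid = NA_integer_, bitscore = NA_real_), tax)
  expect_length(v0, 0)
  expect_equal(attr(v0, "b_sum"), 0)

  # single vote: every node on the lineage carries the full score
  v1 <- vote(tibble::tibble(lca_taxid = 60L, bitscore = 55), tax)
  expect_equal(attr(v1, "b_sum"), 55)
  expect_true(all(unclass(v1)[as.character(lineage(tax, 60L))] == 55))

  # child support never exceeds parent support
  for (node in names(v)) {
    if (as.integer(node) == tax$root) next
    p <- as.character(tax$parent[[node]])
    expect_lte(v[[node]], v[[p]])
  }
})

test_that("assign_query stops at the deepest sufficiently supported taxon", {
  orfs <- tibble::tibble(lca_taxid = c(60L, 61L, 50L), bitscore = c(100, 80, 60))
  v <- vote(orfs, tax)

  # f = 0.5 -> mbs 120: genus 50 is the deepest qualifying node
  q5 <- assign_query("c1", v, 0.5, tax)
  expect_equal(nrow(q5), 1)
  expect_equal(q5$taxid, 50L)
  expect_equal(q5$support[[1]][length(q5$support[[1]])], 1.0)

  # f = 0.3 -> mbs 72: both species qualify, two lineages reported
  q3 <- assign_query("c1", v, 0.3, tax)
  expect_equal(nrow(q3), 2)
  expect_setequal(q3$taxid, c(60L, 61L))
  expect_equal(
    q3$support[[which(q3$taxid == 60L)]][8], 100 / 240,
    tolerance = 1e-12
  )

  # unanimity at f = 1
  vu <- vote(tibble::tibble(lca_taxid = c(60L, 60L), bitscore = c(10, 20)), tax)
  q1 <- assign_query("c1", vu, 1.0, tax)
  expect_equal(q1$taxid, 60L)
  expect_true(all(abs(q1$support[[1]] - 1) < 1e-12))

  expect_error(assign_query("c1", v, 0, tax), "f must be")
  expect_error(assign_query("c1", v, 1.5, tax), "f must be")

  # support fractions are non-increasing root -> terminal
  for (s in q3$support) expect_true(all(diff(s) <= 1e-12))
})

test_that("classify_contigs composes ORF LCA, voting and assignment", {
  h <- dplyr::bind_rows(
    orf_hits("c1_1", c("P60", "P61", "P70"), c(100, 95, 85)), # genus 50
    orf_hits("c1_2", "P60", 80), # species 60
    orf_hits("c1_3", "P61", 60) # species 61
  )
  res <- classify_contigs(h, tax, pm, contig_params())
  expect_equal(res$queries$taxid, 50L)
  expect_equal(res$queries$n_orfs_total, 3L)
  expect_equal(res$queries$n_orfs_classified, 3L)

  # a contig whose only ORF has no resolvable hits
  res0 <- classify_contigs(orf_hits("c9_1", "UNKNOWN", 50), tax, pm)
  expect_equal(res0$queries$status, "no-hits")

  # single classified ORF: contig terminal equals the ORF's LCA
  res1 <- classify_contigs(orf_hits("c2_1", "P62", 120), tax, pm)
  expect_equal(res1$queries$taxid, 62L)
})

test_that("classify_bins pools ORFs across a bin's contigs", {
  one <- dplyr::bind_rows(
    orf_hits("c1_1", c("P60", "P61", "P70"), c(100, 95, 85)),
    orf_hits("c1_2", "P60", 80),
    orf_hits("c1_3", "P61", 60)
  )
  two <- one |> dplyr::mutate(orf_id = sub("^c1", "c2", orf_id))
  bins <- tibble::tibble(bin_id = "b1", contig_id = c("c1", "c2"))
  res <- classify_bins(dplyr::bind_rows(one, two), bins, tax, pm, bin_params())
  res1 <- classify_contigs(one, tax, pm, contig_params(r = bin_params()$r, f = 0.5))

  # doubling the evidence does not move the majority taxon, b_sum doubles
  maj <- reduce_to_majority(res$queries)
  expect_equal(maj$taxid, res1$queries$taxid)
  expect_equal(unique(res$queries$b_sum), 2 * res1$queries$b_sum)

  # a single-contig bin equals contig classification at bin-mode params
  res_single <- classify_bins(one, bins[1, ], tax, pm, bin_params())
  res_contig <- classify_contigs(one, tax, pm,
    contig_params(r = bin_params()$r, f = bin_params()$f)
  )
  expect_equal(res_single$queries$taxid, res_contig$queries$taxid)
  expect_equal(res_single$queries$b_sum, res_contig$queries$b_sum)
})

test_that("bins with a 70/30 species split report both, majority picks the 70", {
  h <- dplyr::bind_rows(
    orf_hits("c1_1", "P60", 700),
    orf_hits("c1_2", "P61", 300)
  )
  bins <- tibble::tibble(bin_id = "b1", contig_id = "c1")
  res <- classify_bins(h, bins, tax, pm, bin_params()) # f = 0.3
  expect_equal(nrow(res$queries), 2)
  expect_setequal(res$queries$taxid, c(60L, 61L))
  expect_equal(reduce_to_majority(res$queries)$taxid, 60L)
})

test_that("reduce_to_majority keeps the deepest majority-supported node", {
  # two species at 0.42 / 0.33 under one genus at 1.0 -> genus
  orfs <- tibble::tibble(lca_taxid = c(60L, 61L, 50L), bitscore = c(42, 33, 25))
  q <- assign_query("c1", vote(orfs, tax), 0.3, tax)
  expect_equal(nrow(q), 2)
  red <- reduce_to_majority(q)
  expect_equal(nrow(red), 1)
  expect_equal(red$taxid, 50L)

  # computed at f = 0.5: idempotent
  q5 <- assign_query("c1", vote(orfs, tax), 0.5, tax)
  expect_equal(reduce_to_majority(q5)$taxid, q5$taxid)

  # all bits on one species: retained
  qa <- assign_query("c1", vote(tibble::tibble(lca_taxid = 60L, bitscore = 9), tax), 0.3, tax)
  expect_equal(reduce_to_majority(qa)$taxid, 60L)

  # equal-support sibling tie at f <= 0.5: both reported, majority stops at parent
  tie <- vote(tibble::tibble(lca_taxid = c(60L, 61L), bitscore = c(50, 50)), tax)
  qt <- assign_query("c1", tie, 0.5, tax)
  expect_setequal(qt$taxid, c(60L, 61L))
  expect_equal(reduce_to_majority(qt)$taxid, 50L)
})

test_that("ORF LCA rises weakly with r and query terminal with f", {
  cfg <- synth_config(seed = 11)
  stax <- synth_taxonomy(cfg)
  spm <- synth_protein_map(stax, cfg)
  sp <- taxa_at_rank(stax, "species")
  set.seed(11)
  for (i in 1:10) {
    q <- synth_query(stax, spm, sample(sp, 1), cfg, query_id = "c1", seed = 100 + i)
    prev <- NULL
    for (r in c(0, 5, 10, 25, 50)) {
      o <- classify_orfs(q$hits, stax, spm, r = r)
      o <- o[o$orf_index == 1, ]
      if (!is.null(prev)) {
        expect_true(is_ancestor_or_equal(stax, o$lca_taxid, prev))
      }
      prev <- o$lca_taxid
    }
    orfs <- classify_orfs(q$hits, stax, spm, r = 10)
    v <- vote(orfs, stax)
    prev_t <- NULL
    for (f in c(0.1, 0.3, 0.5, 0.9)) {
      qq <- reduce_to_majority(assign_query("c1", v, f, stax))
      if (f >= 0.5) {
        expect_lte(nrow(assign_query("c1", v, f, stax)), 1)
      }
      if (!is.null(prev_t)) {
        expect_true(is_ancestor_or_equal(stax, qq$taxid, prev_t))
      }
      prev_t <- qq$taxid
    }
  }
})
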