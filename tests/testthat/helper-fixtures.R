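# Shared fixtures and independent oracles.

# Hand-built taxonomy used across tests:
#   1 root
#   2 superkingdom
#   10 phylum, 20 class, 30 order
#   40 family        41 family
#   50 genus  51 genus  55 genus (under 40)   56 genus (under 41)
#   60,61 species (genus 50); 62 species (genus 51); 70 species (genus 55);
#   71 species (genus 56)
#   600 "no rank" strain under species 60
# merged: 500 -> 60; deleted: 999
fixture_tax <- function() {
  parent <- c(
    "1" = 1L, "2" = 1L, "10" = 2L, "20" = 10L, "30" = 20L,
    "40" = 30L, "41" = 30L,
    "50" = 40L, "51" = 40L, "55" = 40L, "56" = 41L,
    "60" = 50L, "61" = 50L, "62" = 51L, "70" = 55L, "71" = 56L,
    "600" = 60L
  )
  rank <- c(
    "1" = "no rank", "2" = "superkingdom", "10" = "phylum", "20" = "class",
    "30" = "order", "40" = "family", "41" = "family",
    "50" = "genus", "51" = "genus", "55" = "genus", "56" = "genus",
    "60" = "species", "61" = "species", "62" = "species", "70" = "species",
    "71" = "species", "600" = "no rank"
  )
  name <- c(
    "1" = "root", "2" = "Bacteria", "40" = "Famone", "41" = "Famtwo",
    "50" = "Genone", "60" = "Genone specone", "61" = "Genone spectwo"
  )
  taxvote:::validate_taxonomy(taxvote:::new_taxonomy(
    parent = parent, rank = rank, name = name,
    merged = c("500" = 60L), deleted = 999L
  ))
}

fixture_protmap <- function() {
  taxvote:::new_protein_map(c(
    P50 = 50L, P60 = 60L, P61 = 61L, P62 = 62L, P70 = 70L, P71 = 71L
  ))
}

# A hit tibble for one ORF.
orf_hits <- function(orf_id, subjects, bitscores, contig_id = NULL) {
  h <- tibble::tibble(
    orf_id = orf_id, subject = subjects,
    bitscore = bitscores, evalue = 1e-10
  )
  group_hits(h)
}

# Independent LCA oracle: intersect full lineage node sets, take the node
# with the longest lineage.
brute_lca <- function(tax, taxids) {
  paths <- lapply(taxids, function(t) lineage(tax, t))
  common <- Reduce(intersect, paths)
  common[[which.max(vapply(common, function(n) length(lineage(tax, n)), numeric(1)))]]
}

# Independent assignment oracle: enumerate every taxonomy node, sum support
# directly from ORF classifications, filter by mbs, keep nodes with no
# qualifying descendant.
brute_assign <- function(orfs, f, tax) {
  ok <- !is.na(orfs$lca_taxid)
  b_sum <- sum(orfs$bitscore[ok])
  if (b_sum <= 0) return(integer())
  all_nodes <- as.integer(names(tax$parent))
  orf_paths <- lapply(orfs$lca_taxid[ok], function(t) lineage(tax, t))
  support <- vapply(all_nodes, function(n) {
    sum(orfs$bitscore[ok][vapply(orf_paths, function(p) n %in% p, logical(1))])
  }, numeric(1))
  mbs <- f * b_sum
  qual <- all_nodes[support >= mbs * (1 - 1e-9)]
  keep <- vapply(qual, function(n) {
    !any(vapply(setdiff(qual, n), function(m) n %in% head(lineage(tax, m), -1), logical(1)))
  }, logical(1))
  sort(qual[keep])
}

# Conventional best-hit competitor: a contig takes the taxon of its single
# best resolvable hit.
best_hit_classify <- function(hits, tax, protmap) {
  g <- group_hits(hits)
  g$taxid <- resolve_accession(protmap, g$subject)
  g <- g[!is.na(g$taxid), ]
  if (nrow(g) == 0) {
    return(tibble::tibble(
      query_id = hits$orf_id[1], status = "no-hits", taxid = NA_integer_,
      lineage = list(integer()), support = list(numeric())
    ))
  }
  top <- g[which.max(g$bitscore), ]
  path <- lineage(tax, top$taxid)
  tibble::tibble(
    query_id = top$contig_id, status = "classified", taxid = top$taxid,
    lineage = list(path), support = list(rep(1, length(path)))
  )
}

is_ancestor_or_equal <- function(tax, a, b) a %in% lineage(tax, b)

write_taxdump_chain <- function(dir, lines_nodes, lines_names = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(lines_nodes, file.path(dir, "nodes.dmp"))
  writeLines(lines_names, file.path(dir, "names.dmp"))
  dir
}
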