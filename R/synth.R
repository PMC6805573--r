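# Seeded synthetic data: taxonomies, protein maps, alignment tables,
# genome fragmentation and clade-excluded databases. Everything the
# pipeline consumes can be generated at toy scale, in the same file
# dialects real inputs use, so every parser and every classification step
# is testable offline.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-data generator
#'
#' The generator emulates what the classifier sees after a protein search:
#' per ORF, a top hit to a protein of the true species and progressively
#' weaker hits to relatives, with bit-scores decaying linearly per rank
#' step of divergence, plus occasional high-scoring off-target hits that
#' model conserved or horizontally transferred genes landing in the wrong
#' clade.
#'
#' @param seed Integer; fully determines every generated artifact.
#' @param children Named integer vector: children per node at each rank,
#'   names `superkingdom` ... `species`.
#' @param proteins_per_species Number of database proteins per species.
#' @param orfs_per_contig Number of ORFs per synthetic query.
#' @param bitscore_mean Mean top-hit bit-score for a same-species hit.
#' @param bitscore_decay Bit-score drop per rank step of divergence
#'   (species sibling = 1 step, other genus in the family = 2, other family
#'   in the order = 3). Keep it larger than
#'   `bitscore_mean * r / 100` so divergence steps are separable at the
#'   default `r`.
#' @param bitscore_sd Gaussian noise on every bit-score.
#' @param off_target_rate Per-ORF probability of one additional hit to a
#'   uniformly random species at full (same-species) score.
#' @param strain_nodes If `TRUE`, add a "no rank" strain node under each
#'   species.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         children = c(
                           superkingdom = 2, phylum = 2, class = 2,
                           order = 2, family = 3, genus = 3, species = 3
                         ),
                         proteins_per_species = 3,
                         orfs_per_contig = 10,
                         bitscore_mean = 300,
                         bitscore_decay = 60,
                         bitscore_sd = 5,
                         off_target_rate = 0.1,
                         strain_nodes = FALSE) {
  stopifnot(all(children >= 1), proteins_per_species >= 1, orfs_per_contig >= 0)
  structure(
    list(
      seed = seed, children = children,
      proteins_per_species = proteins_per_species,
      orfs_per_contig = orfs_per_contig,
      bitscore_mean = bitscore_mean, bitscore_decay = bitscore_decay,
      bitscore_sd = bitscore_sd, off_target_rate = off_target_rate,
      strain_nodes = strain_nodes
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic taxonomy
#'
#' Builds a full seven-official-rank tree (root taxid 1, then
#' superkingdoms down to species, optionally with "no rank" strain nodes
#' below species) with the branching factors of `cfg$children`.
#' Deterministic per `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A `taxonomy` object.
#' @export
synth_taxonomy <- function(cfg = synth_config()) {
  ranks <- rev(official_ranks()) # superkingdom first
  parent <- c("1" = 1L)
  rank <- c("1" = "no rank")
  name <- c("1" = "root")
  nxt <- 2L
  frontier <- 1L
  for (rk in ranks) {
    k <- cfg$children[[rk]]
    new_frontier <- integer()
    for (p in frontier) {
      for (j in seq_len(k)) {
        id <- nxt
        nxt <- nxt + 1L
        parent[[as.character(id)]] <- p
        rank[[as.character(id)]] <- rk
        name[[as.character(id)]] <- paste0(substr(rk, 1, 2), "_", id)
        new_frontier <- c(new_frontier, id)
      }
    }
    frontier <- new_frontier
  }
  if (isTRUE(cfg$strain_nodes)) {
    for (sp in frontier) {
      id <- nxt
      nxt <- nxt + 1L
      parent[[as.character(id)]] <- sp
      rank[[as.character(id)]] <- "no rank"
      name[[as.character(id)]] <- paste0("strain_", id)
    }
  }
  validate_taxonomy(new_taxonomy(parent = parent, rank = rank, name = name))
}

#' Taxids at a given rank
#'
#' @param tax A `taxonomy` object.
#' @param rank Rank name (e.g. `"species"`).
#' @return Sorted integer vector of taxids carrying that rank.
#' @export
taxa_at_rank <- function(tax, rank) {
  sort(as.integer(names(tax$rank)[tax$rank == rank]))
}

children_map <- function(tax) {
  kids <- split(as.integer(names(tax$parent)), tax$parent)
  kids[[as.character(tax$root)]] <- setdiff(kids[[as.character(tax$root)]], tax$root)
  kids
}

descendant_species <- function(tax, node) {
  kids <- children_map(tax)
  out <- integer()
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[[1]]
    stack <- stack[-1]
    if (tax$rank[[as.character(cur)]] == "species") out <- c(out, cur)
    stack <- c(stack, kids[[as.character(cur)]] %||% integer())
  }
  sort(out)
}

#' Serialize a taxonomy in NCBI taxdump dialect
#'
#' Writes `nodes.dmp`, `names.dmp` and, when non-empty, `merged.dmp` and
#' `delnodes.dmp` into `dir`, in the `"\t|\t"`-separated dialect that
#' [load_taxdump()] reads, so generated taxonomies exercise the real
#' loaders.
#'
#' @param tax A `taxonomy` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_taxdump <- function(tax, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(tax$parent)
  ids <- ids[order(as.integer(ids))]
  writeLines(
    paste0(ids, "\t|\t", tax$parent[ids], "\t|\t", tax$rank[ids], "\t|"),
    file.path(dir, "nodes.dmp")
  )
  named <- intersect(ids, names(tax$name))
  writeLines(
    paste0(named, "\t|\t", tax$name[named], "\t|\t\t|\tscientific name\t|"),
    file.path(dir, "names.dmp")
  )
  if (length(tax$merged) > 0) {
    writeLines(
      paste0(names(tax$merged), "\t|\t", tax$merged, "\t|"),
      file.path(dir, "merged.dmp")
    )
  }
  if (length(tax$deleted) > 0) {
    writeLines(paste0(tax$deleted, "\t|"), file.path(dir, "delnodes.dmp"))
  }
  invisible(dir)
}

#' Generate a synthetic protein database map
#'
#' Gives each species `cfg$proteins_per_species` accessions named
#' `P<taxid>.<i>` (versioned, as in real accession maps), each mapped to
#' its species. Proteins shared between clades are deliberately modelled as
#' separate accessions, so clade exclusion reduces cleanly to removing
#' accessions that map inside the excluded subtree.
#'
#' @param tax A `taxonomy` object.
#' @param cfg A [synth_config()].
#' @return A `protein_map`.
#' @export
synth_protein_map <- function(tax, cfg = synth_config()) {
  species <- taxa_at_rank(tax, "species")
  acc <- unlist(lapply(species, function(s) {
    paste0("P", s, ".", seq_len(cfg$proteins_per_species))
  }))
  tid <- rep(species, each = cfg$proteins_per_species)
  new_protein_map(setNames(tid, acc))
}

species_accessions <- function(protmap, species) {
  names(protmap)[unclass(protmap) == species]
}

#' Generate alignment hits for one synthetic query
#'
#' Emits, for each of `cfg$orfs_per_contig` ORFs on a query of known
#' species: hits to two proteins of the true species at
#' `Normal(bitscore_mean, bitscore_sd)`; one hit to a protein of every
#' other species in the genus at one decay step down; one hit into each
#' other genus of the family (two steps down) and each other family of the
#' order (three steps down); and, with probability `off_target_rate`, one
#' full-score hit to a uniformly random species. The generative truth is
#' returned alongside, so recovery tests are meaningful.
#'
#' @param tax A `taxonomy` object.
#' @param protmap A `protein_map` from [synth_protein_map()].
#' @param true_species Species taxid the query is drawn from.
#' @param cfg A [synth_config()].
#' @param query_id Contig identifier; ORFs are named `<query_id>_<j>`.
#' @param seed Seed for this query (defaults to `cfg$seed`).
#' @return A list: `hits` (tibble as from [read_alignment()]), `truth`
#'   (tibble `query_id`, `true_taxid`).
#' @export
synth_query <- function(tax, protmap, true_species, cfg = synth_config(),
                        query_id = "contig_1", seed = cfg$seed) {
  proj <- official_rank_projection(tax, true_species)
  stopifnot(all(c("species", "genus", "family", "order") %in% names(proj)))
  genus <- proj[["genus"]]
  family <- proj[["family"]]
  ord <- proj[["order"]]
  kids <- children_map(tax)
  sib_species <- setdiff(descendant_species(tax, genus), true_species)
  other_genera <- setdiff(kids[[as.character(family)]], genus)
  other_families <- setdiff(kids[[as.character(ord)]], family)
  all_species <- taxa_at_rank(tax, "species")

  with_seed(seed, {
    rows <- list()
    for (j in seq_len(cfg$orfs_per_contig)) {
      orf <- paste0(query_id, "_", j)
      add <- function(species, step, n_prot = 1) {
        accs <- species_accessions(protmap, species)
        accs <- accs[seq_len(min(n_prot, length(accs)))]
        b <- rnorm(length(accs), cfg$bitscore_mean - step * cfg$bitscore_decay,
          cfg$bitscore_sd
        )
        tibble(
          orf_id = orf, subject = accs, bitscore = round(pmax(b, 30), 1),
          evalue = 1e-20
        )
      }
      orf_rows <- list(add(true_species, 0, n_prot = 2))
      for (s in sib_species) orf_rows <- c(orf_rows, list(add(s, 1)))
      for (g in other_genera) {
        s <- descendant_species(tax, g)
        orf_rows <- c(orf_rows, list(add(s[sample.int(length(s), 1)], 2)))
      }
      for (fam in other_families) {
        s <- descendant_species(tax, fam)
        orf_rows <- c(orf_rows, list(add(s[sample.int(length(s), 1)], 3)))
      }
      if (stats::runif(1) < cfg$off_target_rate) {
        s <- all_species[sample.int(length(all_species), 1)]
        orf_rows <- c(orf_rows, list(add(s, 0)))
      }
      rows <- c(rows, orf_rows)
    }
    hits <- bind_rows(rows)
    list(
      hits = hits,
      truth = tibble(query_id = query_id, true_taxid = true_species)
    )
  })
}

#' Write hits as a 12-column BLAST tabular file
#'
#' Fills the coordinate columns with placeholders; only qseqid, sseqid,
#' evalue and bitscore carry signal, matching what the classifier consumes.
#'
#' @param hits Hit tibble (`orf_id`, `subject`, `bitscore`, `evalue`).
#' @param path Output path.
#' @param decorate If `TRUE`, wrap subjects as `ref|ACC|` to exercise
#'   decoration stripping.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(hits, path, decorate = FALSE) {
  subj <- if (decorate) paste0("ref|", hits$subject, "|") else hits$subject
  writeLines(
    paste(hits$orf_id, subj, "90.0", "100", "10", "0", "1", "100", "1", "100",
      format(hits$evalue, trim = TRUE, scientific = TRUE),
      format(hits$bitscore, trim = TRUE, scientific = FALSE),
      sep = "\t"
    ),
    path
  )
  invisible(path)
}

#' Fragment a genome sequence into non-overlapping contigs
#'
#' Cuts a sequence into at most `max_fragments` non-overlapping pieces with
#' lengths drawn from `length_sampler` (default: lognormal with median
#' 1 kb), truncated to `[min_len, remaining]`. Fragmentation stops when
#' fewer than `min_len` nucleotides remain.
#'
#' @param sequence A single character string (the genome).
#' @param length_sampler Function `n -> numeric` drawing fragment lengths.
#' @param min_len Minimum fragment length (default 300 nt).
#' @param max_fragments Maximum number of fragments (default 65).
#' @param seed Integer seed.
#' @param id_prefix Prefix for contig ids.
#' @return A tibble `contig_id`, `start`, `end`, `length`, `seq`.
#' @export
fragment_genome <- function(sequence,
                            length_sampler = function(n) rlnorm(n, log(1000), 0.7),
                            min_len = 300, max_fragments = 65,
                            seed = 1, id_prefix = "contig") {
  total <- nchar(sequence)
  if (total < min_len) {
    abort(paste0("sequence length ", total, " is below min_len ", min_len))
  }
  with_seed(seed, {
    pos <- 1L
    rows <- list()
    i <- 0L
    while (i < max_fragments && total - pos + 1L >= min_len) {
      remaining <- total - pos + 1L
      len <- as.integer(round(length_sampler(1)))
      len <- max(min_len, min(len, remaining))
      i <- i + 1L
      rows[[i]] <- tibble(
        contig_id = paste0(id_prefix, "_", i),
        start = pos, end = pos + len - 1L, length = len,
        seq = substr(sequence, pos, pos + len - 1L)
      )
      pos <- pos + len
    }
    bind_rows(rows)
  })
}

#' Remove database proteins confined to a query's clade
#'
#' Simulates a novel species, genus or family: every accession whose taxid
#' lies within the query's ancestor at `level` is removed from the map, as
#' if that clade had never been sequenced. Removed sets nest: family-level
#' exclusion removes at least everything species-level exclusion does.
#'
#' @param protmap A `protein_map`.
#' @param tax A `taxonomy` object.
#' @param query_taxid The query's (true) taxid.
#' @param level `"species"`, `"genus"` or `"family"`.
#' @return The reduced `protein_map`.
#' @export
clade_exclusion_reduce <- function(protmap, tax, query_taxid,
                                   level = c("species", "genus", "family")) {
  level <- match.arg(level)
  proj <- official_rank_projection(tax, query_taxid)
  if (!level %in% names(proj)) {
    abort(paste0("query lineage has no node at rank ", level))
  }
  clade <- proj[[level]]
  inside <- vapply(unclass(protmap), function(t) clade %in% lineage(tax, t), logical(1))
  new_protein_map(unclass(protmap)[!inside] |> setNames(names(protmap)[!inside]))
}
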