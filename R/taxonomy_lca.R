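# Taxonomy tree handling, bitscore-margin LCA gene assignment and rank-level
# summaries.

.RANKS <- c("root", "superkingdom", "phylum", "class", "order", "family",
            "genus", "species")

#' Validate and class a taxonomy node table
#'
#' @param nodes data.frame with `taxon_id`, `parent_id`, `rank`, `name`; the
#'   single root has `parent_id == taxon_id`.
#' @return `dm_taxonomy` data.frame.
#' @export
taxonomy_tree <- function(nodes) {
  need <- c("taxon_id", "parent_id", "rank", "name")
  .dm_assert(all(need %in% names(nodes)), "taxonomy table needs columns %s",
             paste(need, collapse = ", "))
  .dm_assert(!anyDuplicated(nodes$taxon_id), "duplicate taxon ids")
  roots <- nodes$taxon_id == nodes$parent_id
  .dm_assert(sum(roots) == 1L, "taxonomy must have exactly one root")
  .dm_assert(all(nodes$parent_id %in% nodes$taxon_id),
             "parent taxon missing from table")
  # acyclicity: every node must reach the root within n steps
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  root <- nodes$taxon_id[roots]
  for (t in nodes$taxon_id) {
    x <- t
    for (i in seq_len(nrow(nodes) + 1L)) {
      if (x == root) break
      x <- parent[[x]]
    }
    .dm_assert(x == root, "cycle detected at taxon %s", t)
  }
  out <- as.data.frame(nodes, stringsAsFactors = FALSE)
  class(out) <- c("dm_taxonomy", "data.frame")
  out
}

#' Read a taxonomy table from TSV
#' @param path TSV with columns `taxon_id`, `parent_id`, `rank`, `name`.
#' @return `dm_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  taxonomy_tree(utils::read.delim(path, colClasses = "character"))
}

#' Root-to-node lineage
#' @param tree `dm_taxonomy`.
#' @param taxon_id taxon identifier.
#' @return character vector of taxon ids, root first.
#' @export
tax_lineage <- function(tree, taxon_id) {
  parent <- setNames(tree$parent_id, tree$taxon_id)
  .dm_assert(taxon_id %in% names(parent), "unknown taxon %s", taxon_id)
  path <- taxon_id
  x <- taxon_id
  while (parent[[x]] != x) {
    x <- parent[[x]]
    path <- c(x, path)
  }
  path
}

#' Ancestor of a taxon at a given rank
#' @param tree `dm_taxonomy`.
#' @param taxon_id taxon identifier.
#' @param rank target rank.
#' @return taxon id at `rank`, or `NA` when the lineage does not reach it.
#' @export
tax_ancestor_at_rank <- function(tree, taxon_id, rank) {
  lin <- tax_lineage(tree, taxon_id)
  ranks <- tree$rank[match(lin, tree$taxon_id)]
  hit <- lin[ranks == rank]
  if (length(hit)) hit[1] else NA_character_
}

#' Lowest common ancestor of a taxon set
#'
#' The deepest node that is an ancestor-or-self of every input taxon.
#'
#' @param taxa non-empty character vector of taxon ids.
#' @param tree `dm_taxonomy`.
#' @return taxon id.
#' @export
lca <- function(taxa, tree) {
  .dm_assert(length(taxa) >= 1L, "empty taxon set")
  taxa <- unique(taxa)
  common <- tax_lineage(tree, taxa[1])
  for (t in taxa[-1]) {
    lin <- tax_lineage(tree, t)
    n <- min(length(common), length(lin))
    eq <- common[seq_len(n)] == lin[seq_len(n)]
    keep <- if (all(eq)) n else which(!eq)[1] - 1L
    .dm_assert(keep >= 1L, "taxa do not share a root")
    common <- common[seq_len(keep)]
  }
  common[length(common)]
}

#' Assign genes by bitscore-margin LCA
#'
#' Hits are filtered to `evalue <= max_evalue`; hits with bitscore within
#' `score_margin` of the per-gene best are retained and the assignment is
#' their LCA. Genes with no surviving hit are UNCLASSIFIED (`NA`). Hits to
#' taxa absent from the tree are dropped with a warning.
#'
#' @param hits data.frame (`gene_id`, `taxon_id`, `bitscore`, `evalue`).
#' @param tree `dm_taxonomy`.
#' @param max_evalue e-value cut-off.
#' @param score_margin fraction of the best bitscore a hit must reach.
#' @return data.frame (`gene_id`, `taxon_id` (`NA` = UNCLASSIFIED), `rank`,
#'   `n_hits_used`), one row per input gene id.
#' @export
assign_genes <- function(hits, tree, max_evalue = 1e-5, score_margin = 0.90) {
  gene_ids <- unique(hits$gene_id)
  unknown <- !(hits$taxon_id %in% tree$taxon_id)
  if (any(unknown)) {
    warning(sprintf("%d hits to taxa absent from the tree were dropped",
                    sum(unknown)))
    hits <- hits[!unknown, , drop = FALSE]
  }
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  res <- data.frame(gene_id = gene_ids, taxon_id = NA_character_,
                    rank = NA_character_, n_hits_used = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(hits)) {
    by_gene <- split(hits, hits$gene_id)
    for (gid in names(by_gene)) {
      h <- by_gene[[gid]]
      kept <- h[h$bitscore >= score_margin * max(h$bitscore), , drop = FALSE]
      tid <- lca(kept$taxon_id, tree)
      i <- match(gid, res$gene_id)
      res$taxon_id[i] <- tid
      res$rank[i] <- tree$rank[match(tid, tree$taxon_id)]
      res$n_hits_used[i] <- nrow(kept)
    }
  }
  res
}

#' Rank-level distribution of gene assignments
#'
#' Each assignment is projected to its ancestor at the requested rank;
#' assignments above that rank (and UNCLASSIFIED genes) count as
#' "unclassified" at the rank. Percentages are over all genes, two decimals.
#'
#' @param assignments output of [assign_genes()].
#' @param tree `dm_taxonomy`.
#' @param rank one of superkingdom, phylum, class, order, family, genus,
#'   species.
#' @return data.frame (`name`, `taxon_id`, `count`, `percentage`), counts
#'   descending, "unclassified" last.
#' @export
rank_summary <- function(assignments, tree, rank) {
  .dm_assert(rank %in% setdiff(.RANKS, "root"), "invalid rank '%s'", rank)
  n <- nrow(assignments)
  .dm_assert(n > 0L, "no assignments")
  proj <- vapply(assignments$taxon_id, function(t) {
    if (is.na(t)) NA_character_ else tax_ancestor_at_rank(tree, t, rank)
  }, "", USE.NAMES = FALSE)
  tab <- table(proj, useNA = "no")
  out <- data.frame(taxon_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$name <- tree$name[match(out$taxon_id, tree$taxon_id)]
  out <- out[order(-out$count, out$name), , drop = FALSE]
  uncl <- n - sum(out$count)
  out <- rbind(out, data.frame(taxon_id = NA_character_, count = uncl,
                               name = "unclassified", stringsAsFactors = FALSE))
  out$percentage <- percentage(out$count, n)
  rownames(out) <- NULL
  out[, c("name", "taxon_id", "count", "percentage")]
}

#' Percentage of classified genes in a subset
#'
#' @param assignments output of [assign_genes()].
#' @param ids optional subset of gene ids (default: all).
#' @return percentage (two decimals) of non-UNCLASSIFIED genes.
#' @export
classified_fraction <- function(assignments, ids = NULL) {
  sub <- if (is.null(ids)) assignments else
    assignments[assignments$gene_id %in% ids, , drop = FALSE]
  .dm_assert(nrow(sub) > 0L, "empty subset")
  percentage(sum(!is.na(sub$taxon_id)), nrow(sub))
}
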