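# Rank-labelled taxonomy: loading, lineage resolution with deterministic
# placeholder nodes, and the subtree/ancestor queries the cascade relies on.

#' Load a taxonomy table
#'
#' Reads a tab-separated node table (columns `taxon_id`, `name`, `rank`,
#' `parent_id`; the root row has `parent_id = "-"`) into a validated taxonomy
#' tree. Nodes with rank `"organism"` are registered as sequenced organisms;
#' if a file contains none, its species leaves are treated as organisms so
#' that minimal hand-written taxonomies remain usable.
#'
#' Ranks outside the canonical ladder (see [canonical_ranks()]) are kept as
#' unranked pass-through nodes: lineages are resolved onto the canonical
#' ranks only, and a canonical rank absent from a lineage is represented by a
#' deterministic placeholder node named
#' `"unclassified <nearest-named-ancestor>_<rank>"`.
#'
#' @param path path to the TSV file.
#' @return a `taxonomy_tree` object.
#' @seealso [ancestor_at_rank()], [descendants()], [write_taxonomy()]
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop_input("taxonomy file not found: ", path)
  nodes <- data.table::fread(path, sep = "\t", colClasses = "character",
                             na.strings = NULL)
  need <- c("taxon_id", "name", "rank", "parent_id")
  if (!all(need %in% names(nodes)))
    stop_input("taxonomy TSV must have columns: ", paste(need, collapse = ", "))
  taxonomy_tree(nodes[, need, with = FALSE])
}

#' Build a taxonomy tree from a node table
#'
#' @param nodes data.frame with columns `taxon_id`, `name`, `rank`,
#'   `parent_id` (root marked by `parent_id = "-"`).
#' @return a `taxonomy_tree`: list with the node table, the organism ids and
#'   a fully resolved per-organism lineage table (one row per organism and
#'   canonical level, placeholders included).
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- data.table::as.data.table(nodes)
  nodes[, names(nodes) := lapply(.SD, as.character)]
  if (anyNA(nodes$taxon_id) || any(nodes$taxon_id == ""))
    stop_input("taxon_id must be non-empty")
  if (anyDuplicated(nodes$taxon_id))
    stop_input("duplicate taxon_id: ",
               paste(unique(nodes$taxon_id[duplicated(nodes$taxon_id)]),
                     collapse = ", "))
  if (anyNA(nodes$rank) || any(nodes$rank == ""))
    stop_input("every node needs a non-empty rank")
  roots <- nodes$taxon_id[nodes$parent_id == "-"]
  if (length(roots) != 1L)
    stop_input("taxonomy must have exactly one root (parent_id = \"-\"), found ",
               length(roots))
  known <- c(nodes$taxon_id, "-")
  orphan <- setdiff(nodes$parent_id, known)
  if (length(orphan))
    stop_input("parent_id not found in table: ", paste(orphan, collapse = ", "))

  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  rank <- stats::setNames(nodes$rank, nodes$taxon_id)
  name <- stats::setNames(nodes$name, nodes$taxon_id)

  # cycle check: every node must reach the root in < n steps
  n <- nrow(nodes)
  for (id in nodes$taxon_id) {
    cur <- id
    steps <- 0L
    while (cur != "-") {
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > n)
        stop_input("cycle detected in taxonomy at node ", id)
    }
  }

  organisms <- nodes$taxon_id[nodes$rank == "organism"]
  if (!length(organisms)) {
    # species leaves double as organisms in minimal taxonomies
    leaves <- setdiff(nodes$taxon_id, nodes$parent_id)
    organisms <- leaves[rank[leaves] == "species"]
  }

  tree <- structure(
    list(nodes = nodes, root = roots, organism_ids = sort(organisms),
         parent = parent, rank = rank, name = name),
    class = "taxonomy_tree")
  tree$lineage <- .build_lineage(tree)
  tree
}

# Resolve each organism's chain onto the canonical levels, minting
# deterministic placeholder nodes for missing ranks. Placeholder identifiers
# depend only on (nearest named canonical ancestor, rank).
.build_lineage <- function(tree) {
  out <- vector("list", length(tree$organism_ids))
  for (i in seq_along(tree$organism_ids)) {
    org <- tree$organism_ids[[i]]
    chain_ids <- character()
    cur <- org
    while (cur != "-") {
      chain_ids <- c(chain_ids, cur)
      cur <- tree$parent[[cur]]
    }
    chain_rank <- tree$rank[chain_ids]
    lin_id <- lin_name <- stats::setNames(rep(NA_character_, length(ALL_LEVELS)),
                                          ALL_LEVELS)
    keep <- chain_rank %in% ALL_LEVELS & !duplicated(chain_rank)
    lin_id[chain_rank[keep]] <- chain_ids[keep]
    lin_name[chain_rank[keep]] <- tree$name[chain_ids[keep]]
    if (is.na(lin_id[["organism"]])) {
      lin_id[["organism"]] <- org
      lin_name[["organism"]] <- tree$name[[org]]
    }
    # fill gaps from deep to shallow with deterministic placeholders
    for (r in rev(seq_along(CANONICAL_RANKS))) {
      rk <- CANONICAL_RANKS[[r]]
      if (!is.na(lin_id[[rk]])) next
      # nearest named ancestor strictly shallower than rk
      anc <- NA_character_
      for (r2 in rev(seq_len(r - 1L))) {
        cand <- lin_id[[CANONICAL_RANKS[[r2]]]]
        if (!is.na(cand) && !startsWith(cand, "unclassified:")) {
          anc <- cand
          break
        }
      }
      if (is.na(anc)) anc <- tree$root
      anc_name <- if (anc %in% names(tree$name)) tree$name[[anc]] else anc
      lin_id[[rk]] <- paste0("unclassified:", anc, ":", rk)
      lin_name[[rk]] <- paste0("unclassified ", anc_name, "_", rk)
    }
    out[[i]] <- data.table::data.table(
      organism_id = org, rank = ALL_LEVELS,
      taxon_id = unname(lin_id), name = unname(lin_name))
  }
  lineage <- data.table::rbindlist(out)
  data.table::setkey(lineage, organism_id, rank)
  lineage
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "nodes,",
      length(x$organism_ids), "organisms\n")
  tab <- table(x$nodes$rank)
  cat("  ranks:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.check_organisms <- function(tree, organisms) {
  bad <- setdiff(organisms, tree$organism_ids)
  if (length(bad))
    stop_input("unknown organism(s): ", paste(bad, collapse = ", "))
}

#' Ancestor of an organism at a given rank
#'
#' Returns the unique ancestor of `organism` at the requested canonical rank.
#' Lineages missing that rank resolve to the deterministic
#' `"unclassified <ancestor>_<rank>"` placeholder minted at load time.
#'
#' @param tree a `taxonomy_tree`.
#' @param organism a registered organism identifier.
#' @param rank one of [canonical_ranks()] or `"organism"`.
#' @return one-row data.table with `taxon_id`, `name`, `rank`.
#' @export
ancestor_at_rank <- function(tree, organism, rank) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (!rank %in% ALL_LEVELS) stop_input("unknown rank: ", rank)
  .check_organisms(tree, organism)
  key <- data.table::data.table(organism_id = organism, rank = rank)
  row <- tree$lineage[key, on = c("organism_id", "rank")]
  data.table::data.table(taxon_id = row$taxon_id, name = row$name, rank = rank)
}

#' Organisms descending from a set of taxa
#'
#' Union of organism leaves below the given taxa (placeholder identifiers
#' included). Passing organism identifiers returns them unchanged, so the
#' operation is idempotent on organism sets.
#'
#' @param tree a `taxonomy_tree`.
#' @param taxa character vector of taxon identifiers.
#' @return sorted character vector of organism identifiers.
#' @export
descendants <- function(tree, taxa) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (!length(taxa)) return(character())
  known <- unique(c(tree$nodes$taxon_id, tree$lineage$taxon_id))
  bad <- setdiff(taxa, known)
  if (length(bad))
    stop_input("unknown taxon(s): ", paste(bad, collapse = ", "))
  hit <- tree$lineage[taxon_id %in% taxa, unique(organism_id)]
  # internal nodes of non-canonical rank do not appear in the lineage table;
  # resolve them by walking each organism's full parent chain
  rest <- setdiff(taxa, tree$lineage$taxon_id)
  if (length(rest)) {
    for (org in tree$organism_ids) {
      cur <- org
      while (cur != "-") {
        if (cur %in% rest) {
          hit <- c(hit, org)
          break
        }
        cur <- tree$parent[[cur]]
      }
    }
  }
  sort(unique(hit))
}

#' Distinct rank-level ancestors of a set of organisms
#'
#' Maps each organism to its ancestor at `rank` and returns the distinct
#' ancestors. The result has a single row exactly when all organisms share
#' that ancestor, which is the specificity test used for spePEP accounting.
#'
#' @inheritParams ancestor_at_rank
#' @param organisms non-empty character vector of organism identifiers.
#' @return data.table with columns `taxon_id`, `name`, `rank`, one row per
#'   distinct ancestor.
#' @export
lca_rank_set <- function(tree, organisms, rank) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (!length(organisms)) stop_input("organisms must be non-empty")
  if (!rank %in% ALL_LEVELS) stop_input("unknown rank: ", rank)
  .check_organisms(tree, organisms)
  key <- data.table::data.table(organism_id = unique(organisms), rank = rank)
  res <- unique(tree$lineage[key, on = c("organism_id", "rank"),
                             .(taxon_id, name)])
  res[, rank := rank]
  res[]
}

#' Write a taxonomy tree back to TSV
#'
#' Inverse of [load_taxonomy()]: only originally loaded nodes are written
#' (placeholders are re-derived on load).
#'
#' @param tree a `taxonomy_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tree, path) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  data.table::fwrite(tree$nodes, path, sep = "\t", quote = FALSE)
  invisible(path)
}
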