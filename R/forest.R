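#' Phylogeny forest of one patient's deconvoluted lineages
#'
#' A `be_forest` holds one or more rooted trees (multifurcations allowed)
#' whose tips are (biopsy, lineage) pairs with inferred cell fractions.
#' Branch lengths are counts of assigned SNVs.  Disjoint trees represent
#' lineage groups sharing fewer than the origin threshold of SNVs,
#' consistent with independent origins of the segment.
#'
#' @param patient_id patient identifier.
#' @param nodes node table (see `R/utils-tree.R` for the columns).
#' @param status `"ok"` or `"unresolvable"` (patient excluded from
#'   statistics when the partition set admits no consistent forest).
#' @param dropped_biopsies biopsy codes removed by the thin-biopsy filter.
#' @return An object of class `be_forest`.
#' @export
be_forest <- function(patient_id, nodes, status = "ok",
                      dropped_biopsies = character()) {
  structure(
    list(patient_id = patient_id, nodes = nodes, status = status,
         dropped_biopsies = dropped_biopsies),
    class = "be_forest"
  )
}

#' @export
print.be_forest <- function(x, ...) {
  ntree <- length(forest_roots(x$nodes))
  ntip <- sum(x$nodes$type == "tip")
  cat(sprintf("be_forest: patient %s, %d tree(s), %d tip(s), status %s\n",
              x$patient_id, ntree, ntip, x$status))
  invisible(x)
}

#' Number of independent origins in a forest
#'
#' Counts disjoint trees, excluding trees all of whose tips lie in
#' biopsies removed by the thin-biopsy filter (biopsies in which no
#' partition, including private SNVs, reached the SNV threshold).
#'
#' @param forest a [be_forest()].
#' @return Integer origin count.
#' @export
count_origins <- function(forest) {
  nodes <- forest$nodes
  if (!nrow(nodes)) return(0L)
  dtips <- desc_tip_ids(nodes)
  n <- 0L
  for (r in forest_roots(nodes)) {
    tips <- dtips[[as.character(r)]]
    bio <- nodes$biopsy[match(tips, nodes$id)]
    if (any(!bio %in% forest$dropped_biopsies)) n <- n + 1L
  }
  n
}

# Recursive Newick serialization of one tree; branch lengths are SNV counts.
newick_of_tree <- function(nodes, root, kids) {
  fmt_len <- function(x) format(x, scientific = FALSE, trim = TRUE)
  build <- function(id) {
    row <- nodes[nodes$id == id, ]
    if (row$type == "tip") {
      sprintf("%s-%d:%s", row$biopsy, row$lineage, fmt_len(row$n_snvs))
    } else {
      inner <- paste(vapply(kids[[as.character(id)]], build, character(1)),
                     collapse = ",")
      sprintf("(%s):%s", inner, fmt_len(row$n_snvs))
    }
  }
  paste0(build(root), ";")
}

#' Serialize a forest to Newick plus a JSON sidecar
#'
#' Writes `<out_prefix>.nwk` (one Newick string per disjoint tree, tip
#' labels `<biopsy>-<lineage>`, branch lengths = assigned SNV counts) and
#' `<out_prefix>.json` carrying everything the Newick cannot: per-tip cell
#' fractions, per-branch SNV counts and supporting partitions, genome
#' doubling flags, dropped biopsies, status and origin count.
#'
#' @param forest a [be_forest()].
#' @param out_prefix output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_forest <- function(forest, out_prefix) {
  nodes <- forest$nodes
  kids <- node_children(nodes)
  nwk <- vapply(forest_roots(nodes), function(r) newick_of_tree(nodes, r, kids),
                character(1))
  nwk_path <- paste0(out_prefix, ".nwk")
  json_path <- paste0(out_prefix, ".json")
  writeLines(nwk, nwk_path)
  side <- list(
    patient_id = forest$patient_id,
    status = forest$status,
    dropped_biopsies = forest$dropped_biopsies,
    origin_count = count_origins(forest),
    nodes = nodes
  )
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(nwk_path, json_path))
}

#' Read a forest written by [write_forest()]
#'
#' The JSON sidecar is authoritative; the Newick file is parsed with
#' \pkg{ape} and checked for agreement on tip labels.
#'
#' @param prefix the path prefix used when writing.
#' @return A [be_forest()].
#' @export
read_forest <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  nodes <- normalize_nodes(as.data.frame(side$nodes, stringsAsFactors = FALSE))
  forest <- be_forest(side$patient_id, nodes, side$status,
                      as.character(unlist(side$dropped_biopsies)))
  nwk <- readLines(paste0(prefix, ".nwk"))
  tips_nwk <- sort(unlist(lapply(nwk, function(s) ape::read.tree(text = s)$tip.label)))
  tips_json <- sort(tip_label(nodes)[nodes$type == "tip"])
  if (!identical(tips_nwk, tips_json)) {
    stop("forest round-trip mismatch between Newick and JSON sidecar", call. = FALSE)
  }
  forest
}

#' Convert one tree of a forest to an \pkg{ape} `phylo` object
#'
#' @param forest a [be_forest()].
#' @param root id of the tree root (default: first root).
#' @return A `phylo` object with SNV-count edge lengths.  Trees with a
#'   single tip cannot be represented and raise an error.
#' @export
forest_to_phylo <- function(forest, root = forest_roots(forest$nodes)[1]) {
  nodes <- forest$nodes
  kids <- node_children(nodes)
  dtips <- desc_tip_ids(nodes)
  ids <- c(root, setdiff(unlist(dtips[[as.character(root)]]), root))
  # collect all nodes of this tree
  in_tree <- vapply(nodes$id, function(i) {
    i == root || root %in% ancestor_ids(nodes, i)
  }, logical(1))
  sub <- nodes[in_tree, , drop = FALSE]
  tips <- sub$id[sub$type == "tip"]
  internals <- sub$id[sub$type == "internal"]
  if (length(tips) < 2) stop("tree has fewer than 2 tips", call. = FALSE)
  tip_no <- setNames(seq_along(tips), tips)
  int_no <- setNames(length(tips) + seq_along(c(root, setdiff(internals, root))),
                     c(root, setdiff(internals, root)))
  num <- function(id) {
    id <- as.character(id)
    ifelse(id %in% names(tip_no), tip_no[id], int_no[id])
  }
  has_parent <- sub$id[!is.na(sub$parent) & sub$parent %in% sub$id]
  edge <- cbind(num(sub$parent[match(has_parent, sub$id)]), num(has_parent))
  phy <- list(
    edge = matrix(as.integer(edge), ncol = 2),
    edge.length = sub$n_snvs[match(has_parent, sub$id)],
    tip.label = tip_label(sub)[match(tips, sub$id)],
    Nnode = length(int_no)
  )
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

# Nontrivial rooted clades of every tree, as sorted tip-label keys.
forest_clades <- function(forest) {
  nodes <- forest$nodes
  dtips <- desc_tip_ids(nodes)
  labels <- tip_label(nodes)
  roots <- forest_roots(nodes)
  trees <- tree_of(nodes)
  out <- character(0)
  for (i in which(nodes$type == "internal")) {
    id <- nodes$id[i]
    if (id %in% roots) next
    tips <- dtips[[as.character(id)]]
    if (length(tips) < 2) next
    root_tips <- dtips[[as.character(trees[as.character(id)])]]
    if (length(tips) == length(root_tips)) next  # redundant with the root
    out <- c(out, paste(sort(labels[match(tips, nodes$id)]), collapse = "|"))
  }
  unique(out)
}

#' Rooted Robinson-Foulds style comparison of two forests
#'
#' Trees are matched between the forests by their tip-label sets; the
#' distance for a matched pair is the size of the symmetric difference of
#' their nontrivial rooted clades.  Returns `NA` when the forests do not
#' have the same trees-by-tip-set decomposition (different origin counts
#' or tip sets), which callers should treat as disagreement.
#'
#' @param f1,f2 [be_forest()] objects with comparable tip labels.
#' @return Integer distance, or `NA_integer_`.
#' @export
forest_rf <- function(f1, f2) {
  key_trees <- function(f) {
    nodes <- f$nodes
    dtips <- desc_tip_ids(nodes)
    labels <- tip_label(nodes)
    sapply(forest_roots(nodes), function(r) {
      paste(sort(labels[match(dtips[[as.character(r)]], nodes$id)]), collapse = "|")
    })
  }
  k1 <- sort(key_trees(f1)); k2 <- sort(key_trees(f2))
  if (!identical(k1, k2)) return(NA_integer_)
  c1 <- forest_clades(f1); c2 <- forest_clades(f2)
  length(setdiff(c1, c2)) + length(setdiff(c2, c1))
}
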