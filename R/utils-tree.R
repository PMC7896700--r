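# Shared helpers for the node-table representation of a phylogeny forest.
#
# A forest is stored as a data.frame with one row per node:
#   id       integer node id (1-based, unique)
#   parent   id of the parent node, NA for a tree root
#   type     "tip" or "internal"
#   sample   sample id (tips only)
#   biopsy   biopsy letter code (tips only)
#   lineage  lineage ordinal within the biopsy (tips only)
#   cf       cell fraction (tips only)
#   n_snvs   SNVs assigned to the edge above this node (branch length)
#   gd       TRUE if a genome doubling is placed on the edge above
#   claim_key partition sample-set key supporting the edge (internal)
# Multifurcations are legal; disjoint trees are separate roots.

# Coerce a node table read from JSON/TSV back to the canonical column
# types (all-NA columns deserialize as logical otherwise).
normalize_nodes <- function(nodes) {
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$lineage <- as.integer(nodes$lineage)
  nodes$cf <- as.numeric(nodes$cf)
  nodes$n_snvs <- as.numeric(nodes$n_snvs)
  nodes$gd <- as.logical(nodes$gd)
  for (col in c("type", "sample", "biopsy", "claim_key")) {
    nodes[[col]] <- as.character(nodes[[col]])
  }
  nodes
}

empty_nodes <- function() {
  data.frame(
    id = integer(), parent = integer(), type = character(),
    sample = character(), biopsy = character(), lineage = integer(),
    cf = numeric(), n_snvs = numeric(), gd = logical(),
    claim_key = character(), stringsAsFactors = FALSE
  )
}

add_node <- function(nodes, parent = NA_integer_, type = "internal",
                     sample = NA_character_, biopsy = NA_character_,
                     lineage = NA_integer_, cf = NA_real_, n_snvs = 0,
                     gd = FALSE, claim_key = NA_character_) {
  id <- if (nrow(nodes) == 0L) 1L else max(nodes$id) + 1L
  rbind(nodes, data.frame(
    id = id, parent = as.integer(parent), type = type, sample = sample,
    biopsy = biopsy, lineage = as.integer(lineage), cf = cf,
    n_snvs = n_snvs, gd = gd, claim_key = claim_key,
    stringsAsFactors = FALSE
  ))
}

node_children <- function(nodes) {
  kids <- vector("list", nrow(nodes))
  names(kids) <- as.character(nodes$id)
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent[i]
    if (!is.na(p)) kids[[as.character(p)]] <- c(kids[[as.character(p)]], nodes$id[i])
  }
  kids
}

forest_roots <- function(nodes) nodes$id[is.na(nodes$parent)]

# Postorder traversal (children before parents) over all trees.
postorder_ids <- function(nodes) {
  kids <- node_children(nodes)
  out <- integer(0)
  walk <- function(id) {
    for (k in kids[[as.character(id)]]) walk(k)
    out <<- c(out, id)
  }
  for (r in forest_roots(nodes)) walk(r)
  out
}

# For every node, the tip ids in its subtree (a node is its own tip if a tip).
desc_tip_ids <- function(nodes) {
  out <- vector("list", nrow(nodes))
  names(out) <- as.character(nodes$id)
  kids <- node_children(nodes)
  for (id in postorder_ids(nodes)) {
    key <- as.character(id)
    if (nodes$type[nodes$id == id] == "tip") {
      out[[key]] <- id
    } else {
      out[[key]] <- unlist(lapply(kids[[key]], function(k) out[[as.character(k)]]))
    }
  }
  out
}

# Sorted-unique biopsy set below each node, as a "A|B|C" key.
biopsy_keys <- function(nodes, dtips = desc_tip_ids(nodes)) {
  vapply(as.character(nodes$id), function(key) {
    tips <- dtips[[key]]
    paste(sort(unique(nodes$biopsy[match(tips, nodes$id)])), collapse = "|")
  }, character(1))
}

sample_keys <- function(nodes, dtips = desc_tip_ids(nodes)) {
  vapply(as.character(nodes$id), function(key) {
    tips <- dtips[[key]]
    paste(sort(unique(nodes$sample[match(tips, nodes$id)])), collapse = "|")
  }, character(1))
}

# Root-path (ancestor ids, nearest first, excluding the node itself).
ancestor_ids <- function(nodes, id) {
  out <- integer(0)
  p <- nodes$parent[nodes$id == id]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- nodes$parent[nodes$id == p]
  }
  out
}

# Tree membership: root id for every node.
tree_of <- function(nodes) {
  memo <- setNames(rep(NA_integer_, nrow(nodes)), as.character(nodes$id))
  for (id in nodes$id) {
    anc <- ancestor_ids(nodes, id)
    memo[as.character(id)] <- if (length(anc)) anc[length(anc)] else id
  }
  memo
}

#' Tip labels of a forest node table
#'
#' `"<biopsy>-<lineage>"` for tips, `NA` for internal nodes.
#'
#' @param nodes the `nodes` data.frame of a [be_forest()].
#' @return Character vector aligned with the rows of `nodes`.
#' @export
tip_label <- function(nodes) {
  ifelse(nodes$type == "tip", paste0(nodes$biopsy, "-", nodes$lineage), NA_character_)
}
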