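#' Rooted sample tree
#'
#' A rooted binary tree whose leaves are the sequenced samples.  Nodes are
#' indexed `1..n` for the tips (in the order of `labels`) and `n+1..2n-1`
#' for internal nodes; `parent[i]` gives each node's parent, with `0`
#' marking the root.  The edge above the root (the trunk) is a real edge:
#' it carries the truncal mutations and its origin is the ancestral clone.
#' After scoring, `support[i]` holds the number of mutations supporting the
#' edge above node `i` (the trunk support sits at the root index).
#'
#' @param parent Integer parent vector of length `2n - 1`.
#' @param labels Character tip labels (length `n`).
#' @param support Optional integer edge-support vector (length `2n - 1`).
#' @return A `sample_tree` object.
#' @export
sample_tree <- function(parent, labels, support = NULL) {
  n <- length(labels)
  parent <- as.integer(parent)
  if (n < 2) .stop_invalid("a sample tree needs at least 2 tips")
  if (length(parent) != 2L * n - 1L)
    .stop_invalid("'parent' must have length 2n-1")
  if (sum(parent == 0L) != 1L) .stop_invalid("exactly one root required")
  nchild <- tabulate(parent[parent != 0L], nbins = 2L * n - 1L)
  if (any(nchild[seq_len(n)] != 0L))
    .stop_invalid("tips may not have children")
  if (any(nchild[-seq_len(n)] != 2L))
    .stop_invalid("internal nodes must have exactly two children")
  structure(list(n_tip = n, labels = as.character(labels), parent = parent,
                 support = support, score = NULL,
                 homoplasy = character(0), assignment = NULL),
            class = "sample_tree")
}

.tree_root <- function(parent) which(parent == 0L)

.tree_children <- function(parent) {
  kids <- vector("list", length(parent))
  for (v in seq_along(parent))
    if (parent[v] != 0L) kids[[parent[v]]] <- c(kids[[parent[v]]], v)
  kids
}

# Bitmask of tips below each node (bit i-1 = tip i).
.clade_masks <- function(parent, n_tip) {
  masks <- integer(length(parent))
  for (i in seq_len(n_tip)) {
    bit <- bitwShiftL(1L, i - 1L)
    x <- i
    while (x != 0L) {
      masks[x] <- bitwOr(masks[x], bit)
      x <- parent[x]
    }
  }
  masks
}

.popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Leaf sets of all clades of a sample tree
#'
#' @param tree A [sample_tree()].
#' @return A list, indexed by node, of character vectors of tip labels.
#' @export
clade_leafsets <- function(tree) {
  masks <- .clade_masks(tree$parent, tree$n_tip)
  lapply(masks, function(m) tree$labels[bitwAnd(bitwShiftR(m, seq_len(tree$n_tip) - 1L), 1L) == 1L])
}

# Canonical recursive newick: children ordered by their smallest tip label.
.newick_node <- function(v, kids, labels, support) {
  if (is.null(kids[[v]])) {
    lab <- labels[v]
    str <- if (is.null(support)) lab else paste0(lab, ":", support[v])
    return(list(str = str, min = lab))
  }
  parts <- lapply(kids[[v]], .newick_node, kids = kids, labels = labels,
                  support = support)
  ord <- order(vapply(parts, `[[`, "", "min"))
  parts <- parts[ord]
  str <- paste0("(", paste(vapply(parts, `[[`, "", "str"), collapse = ","), ")")
  if (!is.null(support)) str <- paste0(str, ":", support[v])
  list(str = str, min = parts[[1L]]$min)
}

#' Serialize a sample tree as newick
#'
#' Branch lengths are the per-edge supporting-mutation counts (omitted when
#' the tree is unscored); the trunk support is written on the root.  Child
#' order is canonical (sorted by smallest tip label) so equal topologies
#' always serialize identically.
#'
#' @param tree A [sample_tree()].
#' @param lengths Include branch lengths when supports are available.
#' @return A newick string, e.g. `"(A:2,B:3):5;"`.
#' @export
to_newick <- function(tree, lengths = TRUE) {
  stopifnot(inherits(tree, "sample_tree"))
  support <- if (lengths && !is.null(tree$support)) tree$support else NULL
  kids <- .tree_children(tree$parent)
  paste0(.newick_node(.tree_root(tree$parent), kids, tree$labels,
                      support)$str, ";")
}

.canonical_newick <- function(parent, labels) {
  kids <- .tree_children(parent)
  paste0(.newick_node(.tree_root(parent), kids, labels, NULL)$str, ";")
}

#' Convert a sample tree to an ape "phylo" object
#'
#' @param x A [sample_tree()].
#' @param ... Unused.
#' @return An [ape::as.phylo] tree with edge lengths taken from the edge
#'   supports (when scored) and the trunk stored as `root.edge`.
#' @importFrom ape as.phylo
#' @export
as.phylo.sample_tree <- function(x, ...) {
  n <- x$n_tip
  root <- .tree_root(x$parent)
  # renumber internals in preorder with the root first (ape convention)
  newid <- integer(length(x$parent))
  newid[seq_len(n)] <- seq_len(n)
  kids <- .tree_children(x$parent)
  nxt <- n + 1L
  stack <- root
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    newid[v] <- nxt; nxt <- nxt + 1L
    stack <- c(Filter(function(k) k > n, kids[[v]]), stack)
  }
  nonroot <- setdiff(seq_along(x$parent), root)
  edge <- cbind(newid[x$parent[nonroot]], newid[nonroot])
  phy <- list(edge = edge, tip.label = x$labels, Nnode = n - 1L)
  if (!is.null(x$support)) {
    phy$edge.length <- as.numeric(x$support[nonroot])
    phy$root.edge <- as.numeric(x$support[root])
  }
  class(phy) <- "phylo"
  stats::reorder(phy)
}

#' Build a sample tree from other tree representations
#'
#' @param x An [ape::read.tree] `phylo` object (binary, rooted), an
#'   `hclust` object, or a newick string.
#' @return A [sample_tree()].
#' @export
as_sample_tree <- function(x) {
  if (inherits(x, "sample_tree")) return(x)
  if (is.character(x)) x <- ape::read.tree(text = x)
  if (inherits(x, "hclust")) {
    m <- x$merge
    n <- nrow(m) + 1L
    parent <- integer(2L * n - 1L)
    for (i in seq_len(nrow(m))) {
      node <- n + i  # hclust merge i -> internal node n+i; final merge = root
      for (ch in m[i, ])
        parent[if (ch < 0) -ch else n + ch] <- node
    }
    parent[2L * n - 1L] <- 0L
    return(sample_tree(parent, x$labels))
  }
  if (!inherits(x, "phylo")) .stop_invalid("cannot convert to sample_tree")
  n <- length(x$tip.label)
  if (!ape::is.binary(x) || !ape::is.rooted(x))
    .stop_invalid("need a rooted binary tree")
  parent <- integer(2L * n - 1L)
  for (i in seq_len(nrow(x$edge)))
    parent[x$edge[i, 2L]] <- x$edge[i, 1L]
  support <- NULL
  if (!is.null(x$edge.length)) {
    support <- integer(2L * n - 1L)
    support[x$edge[, 2L]] <- as.integer(round(x$edge.length))
    support[.tree_root(parent)] <-
      if (!is.null(x$root.edge)) as.integer(round(x$root.edge)) else 0L
  }
  sample_tree(parent, x$tip.label, support)
}

#' Draw a uniform random rooted binary topology
#'
#' Built by sequential random leaf insertion (each new leaf attaches to a
#' uniformly chosen edge, including the trunk), which samples rooted binary
#' leaf-labeled topologies uniformly.
#'
#' @param labels Tip labels (length >= 2).
#' @param seed Optional integer seed.
#' @return A [sample_tree()] without supports.
#' @export
random_topology <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  if (n < 2) .stop_invalid("need at least 2 labels")
  parent <- integer(2L * n - 1L)
  parent[1L] <- parent[2L] <- n + 1L
  parent[n + 1L] <- 0L
  if (n >= 3L) {
    for (k in 3:n) {
      active <- c(seq_len(k - 1L), n + seq_len(k - 2L))
      x <- active[sample.int(length(active), 1L)]
      newint <- n + k - 1L
      parent[newint] <- parent[x]
      parent[x] <- newint
      parent[k] <- newint
    }
  }
  sample_tree(parent, labels)
}

# All nearest-neighbor-interchange neighbors of a rooted topology: for every
# internal non-root node, swap its sibling with each of its children.
.nni_neighbors <- function(parent, n_tip) {
  kids <- .tree_children(parent)
  out <- list()
  for (v in seq_along(parent)) {
    if (v <= n_tip || parent[v] == 0L) next
    u <- parent[v]
    s <- setdiff(kids[[u]], v)
    for (ch in kids[[v]]) {
      p2 <- parent
      p2[s] <- v
      p2[ch] <- u
      out[[length(out) + 1L]] <- p2
    }
  }
  out
}

# Leaf prune-and-regraft neighbors: detach each leaf (suppressing its
# parent) and reinsert it on every edge of the reduced tree, reusing the
# suppressed internal node.
.leaf_spr_neighbors <- function(parent, n_tip) {
  kids <- .tree_children(parent)
  out <- list()
  for (l in seq_len(n_tip)) {
    p <- parent[l]
    sib <- setdiff(kids[[p]], l)
    g <- parent[p]
    base <- parent
    base[sib] <- g  # g == 0 makes the sibling the new root
    for (x in seq_along(parent)) {
      if (x == l || x == p) next
      p2 <- base
      p2[p] <- base[x]
      p2[x] <- p
      p2[l] <- p
      out[[length(out) + 1L]] <- p2
    }
  }
  out
}

# Re-root the topology on the edge above node x; NULL when the move is a
# no-op (x adjacent to the current root).
.reroot <- function(parent, n_tip, x) {
  root <- .tree_root(parent)
  if (x == root || parent[x] == root) return(NULL)
  adj <- vector("list", length(parent))
  addedge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (v in seq_along(parent))
    if (parent[v] != 0L && v != root) addedge(v, parent[v])
  # splice out the old root
  rk <- adj[[root]]
  adj[[rk[1L]]] <- setdiff(adj[[rk[1L]]], root)
  adj[[rk[2L]]] <- setdiff(adj[[rk[2L]]], root)
  addedge(rk[1L], rk[2L])
  adj[[root]] <- integer(0)
  # re-insert it on the edge (x, old parent of x)
  p <- parent[x]
  if (p == root) p <- setdiff(rk, x)  # unreachable given the guard above
  adj[[x]] <- setdiff(adj[[x]], p)
  adj[[p]] <- setdiff(adj[[p]], x)
  addedge(root, x)
  addedge(root, p)
  # orient parents away from the new root
  p2 <- integer(length(parent))
  p2[root] <- 0L
  queue <- root
  seen <- logical(length(parent))
  seen[root] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        p2[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  p2
}

#' @exportS3Method base::print
print.sample_tree <- function(x, ...) {
  cat("Rooted sample tree:", to_newick(x), "\n")
  if (!is.null(x$score))
    cat("  score:", x$score, "compatible;",
        length(x$homoplasy), "homoplastic\n")
  invisible(x)
}
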