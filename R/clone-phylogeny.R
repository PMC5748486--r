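#' Construct a clone phylogeny
#'
#' A clone phylogeny is a rooted tree over tumor subclones.  The root is the
#' ancestral clone (the clone in which the first somatic mutation occurred);
#' every other clone arises from its parent by acquiring the mutations on its
#' incoming branch.
#'
#' @param parent Integer vector; `parent[i]` is the index of clone `i`'s
#'   parent, with `0` marking the root.  Exactly one entry must be `0`.
#' @param nodes Optional character vector of clone identifiers; defaults to
#'   `"C1"`, `"C2"`, ...
#' @return An object of class `clone_phylogeny` with fields `nodes`,
#'   `parent` and `root`.
#' @examples
#' clone_phylogeny(c(0L, 1L, 1L, 2L))
#' @export
clone_phylogeny <- function(parent, nodes = NULL) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (n < 1L) .stop_invalid("a clone phylogeny needs at least one clone")
  if (is.null(nodes)) nodes <- paste0("C", seq_len(n))
  if (length(nodes) != n) .stop_invalid("'nodes' must match length of 'parent'")
  root <- which(parent == 0L)
  if (length(root) != 1L) .stop_invalid("exactly one clone must have parent 0 (the root)")
  if (any(parent < 0L | parent > n)) .stop_invalid("parent indices out of range")
  # reachability from root doubles as the acyclicity check
  seen <- rep(FALSE, n)
  seen[root] <- TRUE
  frontier <- root
  while (length(frontier)) {
    frontier <- which(parent %in% frontier & !seen)
    seen[frontier] <- TRUE
  }
  if (!all(seen)) .stop_invalid("parent map is cyclic or disconnected from the root")
  structure(list(nodes = nodes, parent = parent, root = root),
            class = "clone_phylogeny")
}

#' Simulate a random clone phylogeny
#'
#' Draws a uniform random recursive tree: clones are added one at a time and
#' each new clone attaches to a uniformly chosen earlier clone.
#'
#' @param n_clones Number of clones (>= 1).
#' @param seed Optional integer seed; identical seeds give identical trees.
#' @return A [clone_phylogeny()].
#' @export
simulate_clone_phylogeny <- function(n_clones, seed = NULL) {
  if (length(n_clones) != 1L || is.na(n_clones) || n_clones < 1)
    .stop_invalid("'n_clones' must be a single integer >= 1")
  n_clones <- as.integer(n_clones)
  if (!is.null(seed)) set.seed(seed)
  parent <- integer(n_clones)
  if (n_clones >= 2L)
    for (k in 2:n_clones) parent[k] <- sample.int(k - 1L, 1L)
  clone_phylogeny(parent)
}

# Indices of `clone` and all clones below it.
clone_subtree <- function(tree, clone) {
  idx <- if (is.character(clone)) match(clone, tree$nodes) else as.integer(clone)
  if (is.na(idx) || idx < 1L || idx > length(tree$nodes))
    .stop_invalid("unknown clone: ", clone)
  members <- idx
  frontier <- idx
  while (length(frontier)) {
    frontier <- which(tree$parent %in% frontier)
    members <- c(members, frontier)
  }
  sort(members)
}

#' @exportS3Method base::print
print.clone_phylogeny <- function(x, ...) {
  cat("Clone phylogeny with", length(x$nodes), "clones; root:",
      x$nodes[x$root], "\n")
  if (length(x$nodes) > 1L) {
    edges <- paste0(x$nodes[x$parent[x$parent != 0L]], " -> ",
                    x$nodes[x$parent != 0L])
    cat("  ", paste(edges, collapse = ", "), "\n")
  }
  invisible(x)
}
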