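# Insert `leaf` at every position of nested-list tree `t` (leaf = label,
# internal = list(left, right)); the first position is above t's root.
.insert_everywhere <- function(t, leaf) {
  res <- list(list(t, leaf))
  if (is.list(t)) {
    for (l1 in .insert_everywhere(t[[1L]], leaf))
      res[[length(res) + 1L]] <- list(l1, t[[2L]])
    for (r1 in .insert_everywhere(t[[2L]], leaf))
      res[[length(res) + 1L]] <- list(t[[1L]], r1)
  }
  res
}

.nested_to_parent <- function(t, n) {
  parent <- integer(2L * n - 1L)
  nxt <- n
  walk <- function(node) {
    if (!is.list(node)) return(node)
    nxt <<- nxt + 1L
    me <- nxt
    for (ch in node) {
      id <- walk(ch)
      parent[id] <<- me
    }
    me
  }
  root <- walk(t)
  parent[root] <- 0L
  parent
}

#' Enumerate all rooted binary leaf-labeled topologies
#'
#' Generates every rooted binary topology over the given tips exactly once
#' by sequential leaf insertion; there are `(2n-3)!!` of them.
#'
#' @param labels Tip labels, or a single integer `n` (tips `t1..tn`).
#' @param limit Maximum number of tips for exhaustive enumeration
#'   (default 9, i.e. at most 2,027,025 topologies); beyond this use the
#'   hill-climbing search in [best_tree()].
#' @return A list of [sample_tree()] objects.
#' @export
enumerate_rooted_trees <- function(labels, limit = 9) {
  if (is.numeric(labels) && length(labels) == 1L)
    labels <- paste0("t", seq_len(labels))
  n <- length(labels)
  if (n < 2) .stop_invalid("enumeration needs at least 2 tips")
  if (n > limit)
    .stop_invalid("refusing to enumerate ", n, " tips (limit ", limit,
                  "); use best_tree(method = \"hill_climb\")")
  trees <- list(list(1L, 2L))
  if (n >= 3L) {
    for (k in 3:n) {
      trees <- unlist(lapply(trees, .insert_everywhere, leaf = k),
                      recursive = FALSE)
    }
  }
  lapply(trees, function(t) sample_tree(.nested_to_parent(t, n), labels))
}

#' Number of rooted binary topologies
#'
#' The double factorial `(2n-3)!!`.
#'
#' @param n Number of tips (>= 2).
#' @return A numeric count.
#' @export
n_rooted_topologies <- function(n) {
  if (n < 2) .stop_invalid("'n' must be >= 2")
  prod(seq(1, 2 * n - 3, by = 2))
}
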