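#' Substitution spectra
#'
#' A substitution spectrum is a probability vector over the six
#' pyrimidine-reference substitution classes, with the three C-reference
#' classes optionally split by CpG context.  Category names are the class
#' (`"C>T"`, `"T>A"`, ...) or the class with a `":CpG"` suffix for mutated
#' Cs immediately followed by G (`"C>T:CpG"`).  T-reference classes cannot
#' occur at a CpG and may not carry mass under a `":CpG"` name.
#'
#' @param probs Named numeric vector of category probabilities summing to 1.
#' @return A `substitution_spectrum` (named numeric vector).
#' @seealso [default_truncal_spectrum()], [default_regional_spectrum()]
#' @export
substitution_spectrum <- function(probs) {
  valid <- c(SUB_CLASSES, paste0(c("C>A", "C>G", "C>T"), ":CpG"))
  if (is.null(names(probs)) || !all(names(probs) %in% valid))
    .stop_invalid("spectrum categories must be among: ", paste(valid, collapse = ", "))
  if (anyDuplicated(names(probs)))
    .stop_invalid("duplicated spectrum categories")
  if (any(probs < 0)) .stop_invalid("spectrum probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-8)
    .stop_invalid("spectrum probabilities must sum to 1 (got ", sum(probs), ")")
  structure(as.numeric(probs), names = names(probs),
            class = "substitution_spectrum")
}

#' @describeIn substitution_spectrum Default truncal spectrum, dominated by
#'   C>T at CpG sites (the age-related deamination pattern expected on the
#'   trunk).  The weights are simulator configuration values, not estimates.
#' @export
default_truncal_spectrum <- function() {
  substitution_spectrum(c(
    "C>T:CpG" = 0.45, "C>T" = 0.15, "C>A" = 0.12, "C>G" = 0.06,
    "T>A" = 0.05, "T>C" = 0.12, "T>G" = 0.05))
}

#' @describeIn substitution_spectrum Default regional (subclonal) spectrum,
#'   with a lower C>T-at-CpG weight and more C>A.
#' @export
default_regional_spectrum <- function() {
  substitution_spectrum(c(
    "C>T:CpG" = 0.15, "C>T" = 0.15, "C>A" = 0.25, "C>G" = 0.08,
    "T>A" = 0.10, "T>C" = 0.17, "T>G" = 0.10))
}

# Draw n mutations from a spectrum: returns data.frame(class, cpg).
.draw_spectrum <- function(n, spectrum, labels = names(spectrum)) {
  pick <- labels[sample.int(length(spectrum), n, replace = TRUE, prob = spectrum)]
  data.frame(class = sub(":CpG$", "", pick), cpg = grepl(":CpG$", pick),
             stringsAsFactors = FALSE)
}

# Build ref/alt/trinucleotide context for drawn classes; half the sites are
# emitted on the purine strand so downstream normalization is exercised.
.contexts_for <- function(class, cpg) {
  n <- length(class)
  ref <- substr(class, 1L, 1L)
  alt <- substr(class, 3L, 3L)
  up <- sample(.BASES, n, replace = TRUE)
  down <- character(n)
  is_c <- ref == "C"
  down[is_c & cpg] <- "G"
  down[is_c & !cpg] <- sample(c("A", "C", "T"), sum(is_c & !cpg), replace = TRUE)
  down[!is_c] <- sample(.BASES, sum(!is_c), replace = TRUE)
  context <- paste0(up, ref, down)
  flip <- runif(n) < 0.5
  if (any(flip)) {
    context[flip] <- .revcomp(context[flip])
    ref[flip] <- .comp(ref[flip])
    alt[flip] <- .comp(alt[flip])
  }
  data.frame(ref = ref, alt = alt, context = context, stringsAsFactors = FALSE)
}

#' Assign simulated mutations to clone-tree branches
#'
#' Places `n_truncal` mutations on the root (trunk) edge, drawn from the
#' truncal spectrum, and `n_per_branch` mutations on every non-root edge,
#' drawn from the regional spectrum.  A mutation assigned to a branch is
#' carried by that clone and all of its descendants.  Coding classes are
#' drawn from a configurable multinomial (default: equal silent / missense /
#' nonsense).
#'
#' @param tree A [clone_phylogeny()].
#' @param n_truncal Number of truncal mutations (>= 0).
#' @param n_per_branch Mutations per non-root branch; a single count or a
#'   vector named by clone identifier.
#' @param truncal_spectrum,regional_spectrum [substitution_spectrum()]s.
#' @param coding_probs Probabilities for silent / missense / nonsense.
#' @param seed Optional integer seed.
#' @return A `mutation_assignment`: a data.frame with one row per mutation
#'   (`id`, `branch`, `class`, `cpg`, `coding_class`, `chrom`, `pos`,
#'   `ref`, `alt`, `context`, `gene`).
#' @export
assign_mutations <- function(tree, n_truncal, n_per_branch,
                             truncal_spectrum = default_truncal_spectrum(),
                             regional_spectrum = default_regional_spectrum(),
                             coding_probs = c(silent = 1 / 3, missense = 1 / 3,
                                              nonsense = 1 / 3),
                             seed = NULL) {
  stopifnot(inherits(tree, "clone_phylogeny"))
  if (n_truncal < 0) .stop_invalid("'n_truncal' must be >= 0")
  if (any(n_per_branch < 0)) .stop_invalid("'n_per_branch' must be >= 0")
  truncal_spectrum <- substitution_spectrum(truncal_spectrum)
  regional_spectrum <- substitution_spectrum(regional_spectrum)
  if (abs(sum(coding_probs) - 1) > 1e-8)
    .stop_invalid("'coding_probs' must sum to 1")
  if (!is.null(seed)) set.seed(seed)

  non_root <- setdiff(seq_along(tree$nodes), tree$root)
  per_branch <- if (length(n_per_branch) == 1L) {
    setNames(rep(as.integer(n_per_branch), length(non_root)),
             tree$nodes[non_root])
  } else {
    if (!all(tree$nodes[non_root] %in% names(n_per_branch)))
      .stop_invalid("'n_per_branch' must name every non-root clone")
    setNames(as.integer(n_per_branch[tree$nodes[non_root]]), tree$nodes[non_root])
  }

  branch <- c(rep(tree$nodes[tree$root], n_truncal),
              rep(names(per_branch), per_branch))
  n <- length(branch)
  truncal <- seq_len(n) <= n_truncal
  spec <- rbind(
    if (n_truncal > 0) .draw_spectrum(n_truncal, truncal_spectrum),
    if (n - n_truncal > 0) .draw_spectrum(n - n_truncal, regional_spectrum))
  ctx <- if (n > 0) .contexts_for(spec$class, spec$cpg) else
    data.frame(ref = character(), alt = character(), context = character())
  coding <- if (n > 0)
    names(coding_probs)[sample.int(length(coding_probs), n, replace = TRUE,
                                   prob = coding_probs)] else character()
  out <- data.frame(
    id = sprintf("mut%04d", seq_len(n)),
    branch = branch,
    class = if (n > 0) spec$class else character(),
    cpg = if (n > 0) spec$cpg else logical(),
    coding_class = coding,
    chrom = rep("chr1", n),
    pos = 10000L + seq_len(n) * 50L,
    ref = ctx$ref, alt = ctx$alt, context = ctx$context,
    gene = if (n > 0) sprintf("GENE%03d", sample.int(400L, n, replace = TRUE))
           else character(),
    stringsAsFactors = FALSE)
  class(out) <- c("mutation_assignment", "data.frame")
  out
}

# Clone-index carrier sets per mutation: list of integer vectors.
mutation_carriers <- function(tree, assignment) {
  subtrees <- lapply(seq_along(tree$nodes), function(i) clone_subtree(tree, i))
  names(subtrees) <- tree$nodes
  subtrees[assignment$branch]
}
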