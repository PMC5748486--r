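#' Multi-region sampling design
#'
#' Describes which samples were taken, their role (biopsy, spheroid, or
#' lymph-node metastasis), the tumor area they came from, their cancer-cell
#' purity, and the clone mixture (cancer-cell fractions) of each sample.
#'
#' @param samples data.frame with columns `sample`, `role` (one of
#'   `"biopsy"`, `"spheroid"`, `"lnm"`), `area`, `purity` (in (0, 1]).
#' @param mixtures Numeric matrix, clones x samples; each column is a
#'   non-negative clone mixture summing to 1.  Row names are clone
#'   identifiers, column names sample labels.
#' @param mean_depth Mean sequencing depth per site (default 79, the
#'   whole-exome coverage scale the simulator emulates).
#' @param depth_dispersion Negative-binomial size parameter for per-site
#'   depth; the default 8 spreads typical site depths over roughly 30-170x.
#' @param error_rate Per-read probability of observing the alt allele at a
#'   site whose mutation is not carried (default 0.001), so that germline
#'   and negative-sample filters see occasional stray reads.
#' @return A `sampling_design` object.
#' @export
sampling_design <- function(samples, mixtures, mean_depth = 79,
                            depth_dispersion = 8, error_rate = 0.001) {
  req <- c("sample", "role", "area", "purity")
  if (!all(req %in% names(samples)))
    .stop_invalid("'samples' needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(samples$sample)) .stop_invalid("duplicate sample labels")
  if (!all(samples$role %in% c("biopsy", "spheroid", "lnm")))
    .stop_invalid("sample roles must be biopsy, spheroid or lnm")
  if (any(samples$purity <= 0 | samples$purity > 1))
    .stop_invalid("purity must lie in (0, 1]")
  if (is.null(rownames(mixtures)) || is.null(colnames(mixtures)))
    .stop_invalid("'mixtures' needs clone row names and sample column names")
  if (!identical(sort(colnames(mixtures)), sort(samples$sample)))
    .stop_invalid("mixture columns must match sample labels")
  if (any(mixtures < 0)) .stop_invalid("mixture fractions must be non-negative")
  if (any(abs(colSums(mixtures) - 1) > 1e-8))
    .stop_invalid("each sample's clone mixture must sum to 1")
  if (error_rate < 0 || error_rate >= 0.5)
    .stop_invalid("'error_rate' must be in [0, 0.5)")
  structure(list(samples = as.data.frame(samples),
                 mixtures = mixtures[, samples$sample, drop = FALSE],
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 error_rate = error_rate),
            class = "sampling_design")
}

# Negative-binomial site depths; size = Inf degenerates to Poisson-free fixed
# mean (used for "saturating depth" checks).
.draw_depth <- function(n, mean_depth, dispersion) {
  if (!is.finite(dispersion)) rep(as.integer(round(mean_depth)), n)
  else rnbinom(n, mu = mean_depth, size = dispersion)
}

#' Simulate read counts for a cohort
#'
#' Per sample and mutation, site depth is negative-binomial with the design's
#' mean and dispersion; alt reads are binomial with success probability
#' `0.5 * purity * f + error_rate`, where `f` is the summed mixture fraction
#' of the clones carrying the mutation (the diploid heterozygous model).
#' The matched germline column receives its own depths with alt reads at the
#' error rate only.
#'
#' @param tree A [clone_phylogeny()].
#' @param assignment A [assign_mutations()] result for `tree`.
#' @param design A [sampling_design()] whose mixture rows name clones of
#'   `tree`.
#' @param seed Optional integer seed.
#' @return A list with elements `counts` (a `read_counts` object) and
#'   `truth` (a `cohort_truth` recording all latent values: the clone tree,
#'   the mutation assignment, the design, per-sample carrier fractions and
#'   the true incidence matrix).
#' @export
simulate_read_counts <- function(tree, assignment, design, seed = NULL) {
  stopifnot(inherits(tree, "clone_phylogeny"),
            inherits(design, "sampling_design"))
  if (!all(rownames(design$mixtures) %in% tree$nodes))
    .stop_invalid("mixture rows reference clones absent from the tree")
  if (!is.null(seed)) set.seed(seed)

  n_mut <- nrow(assignment)
  samp <- design$samples
  n_s <- nrow(samp)
  carriers <- mutation_carriers(tree, assignment)
  mix <- matrix(0, nrow = length(tree$nodes), ncol = n_s,
                dimnames = list(tree$nodes, samp$sample))
  mix[rownames(design$mixtures), ] <- design$mixtures

  f <- matrix(0, n_mut, n_s, dimnames = list(assignment$id, samp$sample))
  for (m in seq_len(n_mut))
    f[m, ] <- colSums(mix[carriers[[m]], , drop = FALSE])

  depth <- matrix(.draw_depth(n_mut * n_s, design$mean_depth,
                              design$depth_dispersion),
                  n_mut, n_s, dimnames = dimnames(f))
  p_alt <- pmin(1, 0.5 * sweep(f, 2, samp$purity, "*") + design$error_rate)
  alt <- matrix(rbinom(n_mut * n_s, as.vector(depth), as.vector(p_alt)),
                n_mut, n_s, dimnames = dimnames(f))
  ref <- depth - alt

  g_depth <- .draw_depth(n_mut, design$mean_depth, design$depth_dispersion)
  g_alt <- rbinom(n_mut, g_depth, design$error_rate)

  counts <- read_counts(alt = alt, ref = ref,
                        germline_alt = setNames(g_alt, assignment$id),
                        germline_ref = setNames(g_depth - g_alt, assignment$id),
                        mutations = as.data.frame(assignment),
                        samples = samp)
  truth <- structure(list(tree = tree, assignment = assignment,
                          design = design, carrier_fraction = f,
                          incidence = f > 0,
                          expected_af = 0.5 * sweep(f, 2, samp$purity, "*")),
                     class = "cohort_truth")
  list(counts = counts, truth = truth)
}

#' Read-count container
#'
#' Holds per sample x mutation ref/alt read counts plus the matched-germline
#' column and the mutation / sample metadata.
#'
#' @param alt,ref Integer matrices (mutations x samples) with matching
#'   dimnames.
#' @param germline_alt,germline_ref Integer vectors named by mutation id.
#' @param mutations data.frame keyed by `id` with at least `chrom`, `pos`,
#'   `ref`, `alt`; usually also `gene`, `context`, `coding_class`.
#' @param samples data.frame with `sample`, `role`, `area`.
#' @return A `read_counts` object.
#' @export
read_counts <- function(alt, ref, germline_alt, germline_ref,
                        mutations, samples) {
  if (!identical(dim(alt), dim(ref)))
    .stop_invalid("'alt' and 'ref' must have identical dimensions")
  if (any(alt < 0) || any(ref < 0) || any(germline_alt < 0) ||
      any(germline_ref < 0))
    .stop_invalid("read counts must be non-negative")
  if (!identical(rownames(alt), mutations$id))
    .stop_invalid("matrix rows must match mutations$id")
  structure(list(alt = alt, ref = ref,
                 germline_alt = germline_alt, germline_ref = germline_ref,
                 mutations = mutations, samples = samples),
            class = "read_counts")
}

#' @exportS3Method base::print
print.read_counts <- function(x, ...) {
  cat("read_counts:", nrow(x$alt), "mutations x", ncol(x$alt), "samples",
      "(+ matched germline)\n")
  invisible(x)
}

#' Simulate a default multi-region biopsy/spheroid cohort
#'
#' Emulates the multi-region sampling scheme the package targets: 3-5
#' spatially distinct tumor regions, each contributing a biopsy and a
#' matched spheroid culture.  The clone tree has a truncal (ancestral)
#' clone, one subclone per region, and two further subclones under each
#' region clone; the biopsy samples the region clone plus one child, the
#' spheroid subsamples the biopsy's clones (keeping the region clone,
#' enriching the other child, dropping the biopsy-private one).  Spheroid
#' purity is the matched biopsy purity plus a positive culture-enrichment
#' uplift.
#'
#' @param n_regions Number of tumor regions (3-5).
#' @param n_truncal Truncal mutations on the trunk.
#' @param n_per_branch Mutations per subclonal branch.
#' @param mean_depth,depth_dispersion,error_rate See [sampling_design()].
#' @param biopsy_purity Range (length 2) from which biopsy purities are
#'   drawn uniformly.
#' @param purity_uplift Range of the spheroid purity increment.
#' @param seed Optional integer seed.
#' @return A list with `tree`, `assignment`, `design`, `counts`, `truth`.
#' @export
simulate_cohort <- function(n_regions = 3, n_truncal = 80, n_per_branch = 12,
                            mean_depth = 79, depth_dispersion = 8,
                            error_rate = 0.001,
                            biopsy_purity = c(0.4, 0.7),
                            purity_uplift = c(0.15, 0.3),
                            seed = NULL) {
  if (n_regions < 2 || n_regions > 5)
    .stop_invalid("'n_regions' must be between 2 and 5")
  if (!is.null(seed)) set.seed(seed)
  k <- n_regions
  # clones: 1 root, k region clones, 2k region-subclones
  parent <- c(0L, rep(1L, k), rep(1L + seq_len(k), each = 2L))
  tree <- clone_phylogeny(parent)
  region_clone <- tree$nodes[1L + seq_len(k)]
  child_a <- tree$nodes[1L + k + 2L * seq_len(k) - 1L]  # biopsy-private
  child_b <- tree$nodes[1L + k + 2L * seq_len(k)]       # spheroid-enriched

  assignment <- assign_mutations(tree, n_truncal, n_per_branch)

  areas <- paste0("A", seq_len(k))
  samples <- data.frame(
    sample = c(paste0("T", seq_len(k)), paste0("S", seq_len(k))),
    role = rep(c("biopsy", "spheroid"), each = k),
    area = rep(areas, 2L),
    purity = NA_real_, stringsAsFactors = FALSE)
  bp <- runif(k, biopsy_purity[1], biopsy_purity[2])
  sp <- pmin(1, bp + runif(k, purity_uplift[1], purity_uplift[2]))
  samples$purity <- c(bp, sp)

  mixtures <- matrix(0, length(tree$nodes), nrow(samples),
                     dimnames = list(tree$nodes, samples$sample))
  for (i in seq_len(k)) {
    mixtures[c(tree$nodes[1], region_clone[i], child_a[i]),
             paste0("T", i)] <- c(0.20, 0.55, 0.25)
    mixtures[c(tree$nodes[1], region_clone[i], child_b[i]),
             paste0("S", i)] <- c(0.05, 0.75, 0.20)
  }
  design <- sampling_design(samples, mixtures, mean_depth = mean_depth,
                            depth_dispersion = depth_dispersion,
                            error_rate = error_rate)
  sim <- simulate_read_counts(tree, assignment, design)
  c(list(tree = tree, assignment = assignment, design = design), sim)
}

#' Simulate a lymph-node-metastasis seeding cohort
#'
#' Emulates the metastatic-seeding scenario: the metastatic clone seeds all
#' lymph-node metastases but is present in only one of the tumor regions,
#' while a distinct nonmetastatic subclone is present in every tumor region
#' and in none of the metastases.  The truth object therefore contains a
#' "metastatic block" (mutations on the metastatic clone's branch) and a
#' "nonmetastatic block" (mutations on the nonmetastatic clone's branch).
#'
#' @param n_regions Number of tumor regions (default 3).
#' @param n_lnm Number of lymph-node metastases (>= 2, default 2).
#' @param seeding_region Index of the region carrying the metastatic clone
#'   (default 2).
#' @param n_truncal,n_per_branch Mutation counts as in [assign_mutations()].
#' @param mean_depth,depth_dispersion,error_rate See [sampling_design()].
#' @param seed Optional integer seed.
#' @return A list with `tree`, `assignment`, `design`, `counts`, `truth`,
#'   plus `metastatic_clone`, `nonmetastatic_clone` and the corresponding
#'   mutation-id sets `metastatic_block`, `nonmetastatic_block`.
#' @export
simulate_lnm_cohort <- function(n_regions = 3, n_lnm = 2, seeding_region = 2,
                                n_truncal = 60, n_per_branch = 10,
                                mean_depth = 79, depth_dispersion = 8,
                                error_rate = 0.001, seed = NULL) {
  if (n_lnm < 2) .stop_invalid("'n_lnm' must be >= 2")
  if (seeding_region < 1 || seeding_region > n_regions)
    .stop_invalid("'seeding_region' out of range")
  if (!is.null(seed)) set.seed(seed)
  k <- n_regions
  # clones: 1 root, 2 nonmetastatic/metastatic, k region-privates (under the
  # nonmetastatic clone), n_lnm LNM-privates (under the metastatic clone)
  parent <- c(0L, 1L, 1L, rep(2L, k), rep(3L, n_lnm))
  tree <- clone_phylogeny(parent)
  nonmet <- tree$nodes[2L]
  met <- tree$nodes[3L]
  region_priv <- tree$nodes[3L + seq_len(k)]
  lnm_priv <- tree$nodes[3L + k + seq_len(n_lnm)]

  assignment <- assign_mutations(tree, n_truncal, n_per_branch)

  samples <- data.frame(
    sample = c(paste0("T", seq_len(k)), paste0("L", seq_len(n_lnm))),
    role = c(rep("biopsy", k), rep("lnm", n_lnm)),
    area = c(paste0("A", seq_len(k)), paste0("LN", seq_len(n_lnm))),
    purity = c(runif(k, 0.4, 0.7), runif(n_lnm, 0.3, 0.6)),
    stringsAsFactors = FALSE)

  mixtures <- matrix(0, length(tree$nodes), nrow(samples),
                     dimnames = list(tree$nodes, samples$sample))
  for (i in seq_len(k)) {
    s <- paste0("T", i)
    if (i == seeding_region) {
      mixtures[c(tree$nodes[1], nonmet, region_priv[i], met), s] <-
        c(0.10, 0.35, 0.30, 0.25)
    } else {
      mixtures[c(tree$nodes[1], nonmet, region_priv[i]), s] <-
        c(0.10, 0.45, 0.45)
    }
  }
  for (j in seq_len(n_lnm))
    mixtures[c(met, lnm_priv[j]), paste0("L", j)] <- c(0.4, 0.6)

  design <- sampling_design(samples, mixtures, mean_depth = mean_depth,
                            depth_dispersion = depth_dispersion,
                            error_rate = error_rate)
  sim <- simulate_read_counts(tree, assignment, design)
  c(list(tree = tree, assignment = assignment, design = design), sim,
    list(metastatic_clone = met, nonmetastatic_clone = nonmet,
         metastatic_block = assignment$id[assignment$branch == met],
         nonmetastatic_block = assignment$id[assignment$branch == nonmet]))
}

#' Simulate a tree-like cohort with a known induced sample tree
#'
#' Validation design in which every sample is a pure draw from a distinct
#' subclone and the clone tree is isomorphic to a random rooted binary tree
#' over the samples, so the sample-level carrier sets form a perfect
#' phylogeny and the true sample tree (with its per-branch mutation counts)
#' is known exactly.
#'
#' @param labels Sample labels (length >= 2).
#' @param n_truncal Mutations on the trunk.
#' @param muts_per_edge Mutations on every other edge of the sample tree.
#' @param purity Range from which sample purities are drawn.
#' @param mean_depth,depth_dispersion,error_rate See [sampling_design()];
#'   defaults are deep, error-free sequencing so presence calling is exact.
#' @param seed Optional integer seed.
#' @return A list with `counts`, `truth`, and `truth_tree`, a
#'   [sample_tree()] carrying the true topology and per-edge mutation
#'   counts.
#' @export
simulate_treelike_cohort <- function(labels = paste0("S", 1:6),
                                     n_truncal = 30, muts_per_edge = 8,
                                     purity = c(0.5, 0.9),
                                     mean_depth = 200, depth_dispersion = 8,
                                     error_rate = 0, seed = NULL) {
  n <- length(labels)
  if (n < 2) .stop_invalid("need at least two samples")
  if (!is.null(seed)) set.seed(seed)
  topo <- random_topology(labels)

  # clone per sample-tree node, clone i <-> node i of the topology
  tree <- clone_phylogeny(topo$parent,
                          nodes = paste0("N", seq_along(topo$parent)))
  per_branch <- setNames(rep(muts_per_edge, length(tree$nodes) - 1L),
                         tree$nodes[-tree$root])
  assignment <- assign_mutations(tree, n_truncal, per_branch)

  samples <- data.frame(sample = labels, role = "biopsy",
                        area = paste0("A", seq_len(n)),
                        purity = runif(n, purity[1], purity[2]),
                        stringsAsFactors = FALSE)
  mixtures <- matrix(0, length(tree$nodes), n,
                     dimnames = list(tree$nodes, labels))
  for (i in seq_len(n)) mixtures[paste0("N", i), labels[i]] <- 1
  design <- sampling_design(samples, mixtures, mean_depth = mean_depth,
                            depth_dispersion = depth_dispersion,
                            error_rate = error_rate)
  sim <- simulate_read_counts(tree, assignment, design)

  truth_tree <- topo
  truth_tree$support <- as.integer(
    c(rep(muts_per_edge, length(topo$parent))))
  truth_tree$support[truth_tree$parent == 0L] <- as.integer(n_truncal)
  c(sim, list(truth_tree = truth_tree, tree = tree, assignment = assignment,
              design = design))
}
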