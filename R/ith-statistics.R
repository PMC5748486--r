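#' Binary (Jaccard-mismatch) distance between samples
#'
#' `d(x, y)` is the fraction of mutations carried by exactly one of the two
#' samples among the mutations carried by at least one, computed over cells
#' where both samples are non-missing (the "binary" distance of standard
#' statistical software; joint absences are ignored).  The distance is 0
#' when no mutation is carried by either sample, and missing (`NA`, with a
#' warning) for a pair with no jointly observed cells.
#'
#' @param presence A `presence_matrix` with >= 2 samples.
#' @return A symmetric sample x sample distance matrix with zero diagonal.
#' @export
binary_distance_matrix <- function(presence) {
  stopifnot(inherits(presence, "presence_matrix"))
  state <- presence$state
  if (ncol(state) < 2) .stop_invalid("need at least 2 samples")
  s <- colnames(state)
  d <- matrix(0, length(s), length(s), dimnames = list(s, s))
  pres <- state == "present"
  obs <- state != "missing"
  for (i in seq_along(s)) {
    for (j in seq_len(i - 1L)) {
      both <- obs[, i] & obs[, j]
      if (!any(both)) {
        warning("samples ", s[i], " and ", s[j],
                " share no observed cells; distance set missing",
                call. = FALSE)
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      either <- sum((pres[, i] | pres[, j]) & both)
      mism <- sum(xor(pres[, i], pres[, j]) & both)
      d[i, j] <- d[j, i] <- if (either == 0) 0 else mism / either
    }
  }
  d
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Unweighted average linkage on a complete distance matrix; merge heights
#' are non-decreasing and ties resolve deterministically by label order.
#' The leaf order of the returned object is the heatmap rendering order.
#'
#' @param dist A symmetric distance matrix (e.g.
#'   [binary_distance_matrix()]); missing entries are an error.
#' @return An [stats::hclust] object.
#' @export
average_linkage <- function(dist) {
  if (anyNA(dist)) .stop_invalid("distance matrix contains missing entries")
  hclust(as.dist(dist), method = "average")
}

#' Biopsy-spheroid concordance statistics
#'
#' For each tumor area with a matched biopsy/spheroid pair, mutations
#' present in either member are partitioned into four classes: *tumor-only*
#' (biopsy alone), *spheroid-only* (spheroid alone), *pairwise-private*
#' (both members and no other sample in the cohort), and
#' *concordant-elsewhere* (both members plus at least one other sample);
#' their fractions over the pair's union sum to 1.  The headline
#' concordance is the fraction present in both members (pairwise-private +
#' concordant-elsewhere).  Cohort-level statistics are the per-sample
#' private fraction (mutations present in exactly one sample cohort-wide,
#' over that sample's mutations) and the per-area pairwise-private
#' fraction.
#'
#' @param presence A `presence_matrix`.
#' @param pairing Named list `area -> c(biopsy, spheroid)`; by default
#'   derived from the sample table's `area`/`role` columns.  Areas missing
#'   a member are skipped with a warning.
#' @param coding_only Restrict to coding mutations (silent, missense and
#'   nonsense all count as coding point mutations).
#' @return A `concordance_report`: list with data.frames `per_area` and
#'   `per_sample`.
#' @export
concordance_stats <- function(presence, pairing = NULL, coding_only = FALSE) {
  stopifnot(inherits(presence, "presence_matrix"))
  if (is.null(pairing)) {
    smp <- presence$samples
    areas <- unique(smp$area[smp$role %in% c("biopsy", "spheroid")])
    pairing <- list()
    for (a in areas) {
      b <- smp$sample[smp$area == a & smp$role == "biopsy"]
      s <- smp$sample[smp$area == a & smp$role == "spheroid"]
      if (length(b) == 1L && length(s) == 1L) pairing[[a]] <- c(b, s)
      else warning("area ", a, " lacks a full biopsy/spheroid pair; skipped",
                   call. = FALSE)
    }
  }
  if (!length(pairing)) .stop_invalid("no complete biopsy/spheroid pairs")

  pres <- presence$state == "present"
  if (coding_only) {
    coding <- presence$mutations$coding_class %in%
      c("silent", "missense", "nonsense")
    pres <- pres[coding, , drop = FALSE]
  }
  cohort_count <- rowSums(pres)

  per_area <- do.call(rbind, lapply(names(pairing), function(a) {
    pair <- pairing[[a]]
    if (!all(pair %in% colnames(pres)))
      .stop_invalid("pairing references unknown sample(s): ",
                    paste(setdiff(pair, colnames(pres)), collapse = ", "))
    b <- pres[, pair[1L]]
    s <- pres[, pair[2L]]
    union_n <- sum(b | s)
    both <- b & s
    pairwise_private <- both & cohort_count == 2L
    data.frame(
      area = a, biopsy = pair[1L], spheroid = pair[2L],
      n_union = union_n,
      n_tumor_only = sum(b & !s),
      n_spheroid_only = sum(s & !b),
      n_pairwise_private = sum(pairwise_private),
      n_concordant_elsewhere = sum(both & !pairwise_private),
      stringsAsFactors = FALSE)
  }))
  u <- pmax(per_area$n_union, 1L)
  per_area$frac_tumor_only <- per_area$n_tumor_only / u
  per_area$frac_spheroid_only <- per_area$n_spheroid_only / u
  per_area$frac_pairwise_private <- per_area$n_pairwise_private / u
  per_area$frac_concordant_elsewhere <- per_area$n_concordant_elsewhere / u
  per_area$concordance <-
    (per_area$n_pairwise_private + per_area$n_concordant_elsewhere) / u

  per_sample <- data.frame(
    sample = colnames(pres),
    n_present = colSums(pres),
    n_private = colSums(pres & cohort_count == 1L),
    stringsAsFactors = FALSE)
  per_sample$private_fraction <-
    per_sample$n_private / pmax(per_sample$n_present, 1L)

  structure(list(per_area = per_area, per_sample = per_sample,
                 coding_only = coding_only),
            class = "concordance_report")
}

#' Extract mutation blocks defined by presence patterns
#'
#' Returns, per named pattern, the mutations present in every sample of the
#' pattern's `present_all` set and absent (explicitly called absent) in
#' every sample of its `absent_all` set; other samples are unconstrained.
#' This reproduces clone-level blocks such as the metastatic block
#' (present in all lymph-node metastases and the seeding tumor region,
#' absent in the other regions) and the nonmetastatic block (present in
#' all tumor regions, absent in all metastases).  An empty pattern matches
#' every mutation.
#'
#' @param presence A `presence_matrix`.
#' @param patterns Named list; each element is a list with character
#'   vectors `present_all` and/or `absent_all` of sample labels.
#' @return Named list of mutation-id character vectors.
#' @export
clone_blocks <- function(presence, patterns) {
  stopifnot(inherits(presence, "presence_matrix"))
  state <- presence$state
  lapply(patterns, function(p) {
    known <- c(p$present_all, p$absent_all)
    if (!all(known %in% colnames(state)))
      .stop_invalid("pattern references unknown sample(s): ",
                    paste(setdiff(known, colnames(state)), collapse = ", "))
    sel <- rep(TRUE, nrow(state))
    for (s in p$present_all) sel <- sel & state[, s] == "present"
    for (s in p$absent_all) sel <- sel & state[, s] == "absent"
    rownames(state)[sel]
  })
}

#' Estimate sample purity from truncal allele fractions
#'
#' Under the diploid heterozygous model a clonal mutation in a sample of
#' purity `p` has expected allele fraction `p / 2`, so purity is estimated
#' as `min(1, 2 * median AF)` over the truncal mutations.  Samples with
#' fewer than `min_truncal` usable truncal AFs get a missing estimate with
#' a warning.
#'
#' @param af AF matrix (mutations x samples) or a `presence_matrix`.
#' @param truncal_ids Mutation ids to treat as truncal (clonal in every
#'   sample).
#' @param min_truncal Minimum usable truncal AFs per sample (default 3).
#' @return data.frame with `sample`, `estimate`, `n_truncal_used`,
#'   `method`.
#' @export
purity_from_af <- function(af, truncal_ids, min_truncal = 3) {
  if (inherits(af, "presence_matrix")) af <- af$af
  truncal_ids <- intersect(truncal_ids, rownames(af))
  out <- data.frame(sample = colnames(af), estimate = NA_real_,
                    n_truncal_used = 0L, method = "af_median",
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(af))) {
    v <- af[truncal_ids, i]
    v <- v[!is.na(v)]
    out$n_truncal_used[i] <- length(v)
    if (length(v) < min_truncal) {
      warning("sample ", colnames(af)[i], ": fewer than ", min_truncal,
              " usable truncal AFs; purity estimate missing", call. = FALSE)
    } else {
      out$estimate[i] <- min(1, 2 * median(v))
    }
  }
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided comparison of two independent groups.  The exact null
#' distribution is used whenever the pooled values are tie-free; with ties
#' the normal approximation with tie-corrected variance (and continuity
#' correction) applies.  Identical constant groups return p = 1 with a
#' warning.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `statistic` (Mann-Whitney W for `group_a`), `p.value`
#'   and `exact`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    .stop_invalid("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; p = 1", call. = FALSE)
    return(list(statistic = length(group_a) * length(group_b) / 2,
                p.value = 1, exact = FALSE))
  }
  exact <- !anyDuplicated(pooled)
  ht <- suppressWarnings(wilcox.test(group_a, group_b, exact = exact,
                                     correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value, exact = exact)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired comparison; zero differences are dropped.  The exact
#' null is used when the non-zero absolute differences are tie-free, else
#' the tie-corrected normal approximation.  All-zero differences return
#' p = 1 with a warning.
#'
#' @param paired_a,paired_b Equal-length numeric vectors.
#' @return List with `statistic` (signed-rank V), `p.value`, `exact` and
#'   `n_used` (pairs with non-zero difference).
#' @export
signed_rank_test <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b) || !length(paired_a))
    .stop_invalid("need equal-length, non-empty paired vectors")
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, p.value = 1, exact = FALSE, n_used = 0L))
  }
  exact <- !anyDuplicated(abs(d))
  ht <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       exact = exact, n_used = length(d))
}

#' Path-length distance between samples on a scored tree
#'
#' The number of mutations distinguishing two samples: the sum of edge
#' supports along the path connecting their tips (the trunk does not lie on
#' any tip-to-tip path).
#'
#' @param tree A scored [sample_tree()].
#' @return Symmetric matrix of path lengths.
#' @export
tree_distance_matrix <- function(tree) {
  stopifnot(inherits(tree, "sample_tree"))
  if (is.null(tree$support)) .stop_invalid("tree must be scored first")
  n <- tree$n_tip
  anc <- function(v) {
    path <- integer(0)
    while (v != 0L) {
      path <- c(path, v)
      v <- tree$parent[v]
    }
    path
  }
  paths <- lapply(seq_len(n), anc)
  d <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      shared <- intersect(paths[[i]], paths[[j]])
      on_path <- c(setdiff(paths[[i]], shared), setdiff(paths[[j]], shared))
      d[i, j] <- d[j, i] <- sum(tree$support[on_path])
    }
  }
  d
}

#' Compare matched-pair against cross-area tree distances
#'
#' Tests whether matched biopsy/spheroid pairs are closer on the sample
#' tree (path-length distance) than pairs drawn from different areas,
#' using the two-sided rank-sum test.
#'
#' @param tree A scored [sample_tree()].
#' @param presence The `presence_matrix` used for pairing metadata.
#' @return List with `matched`, `cross` (distance vectors), `statistic`,
#'   `p.value`.
#' @export
matched_pair_distance_test <- function(tree, presence) {
  d <- tree_distance_matrix(tree)
  smp <- presence$samples
  smp <- smp[smp$sample %in% rownames(d) &
               smp$role %in% c("biopsy", "spheroid"), , drop = FALSE]
  matched <- character(0)
  pairs <- split(smp$sample, smp$area)
  labs <- rownames(d)
  is_matched <- matrix(FALSE, nrow(d), ncol(d), dimnames = dimnames(d))
  for (p in pairs)
    if (length(p) == 2L) is_matched[p[1L], p[2L]] <-
      is_matched[p[2L], p[1L]] <- TRUE
  ut <- upper.tri(d)
  sel <- labs %in% smp$sample
  keep <- outer(sel, sel, "&")
  matched_d <- d[ut & is_matched & keep]
  cross_d <- d[ut & !is_matched & keep]
  if (!length(matched_d) || !length(cross_d))
    .stop_invalid("need both matched and cross-area pairs")
  ht <- rank_sum_test(matched_d, cross_d)
  list(matched = matched_d, cross = cross_d,
       statistic = ht$statistic, p.value = ht$p.value)
}
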