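test_that("binary distance follows the Jaccard-mismatch definition", {
  st <- rbind(m1 = c("present", "present", "present"),
              m2 = c("present", "absent", "present"),
              m3 = c("absent", "present", "present"))
  colnames(st) <- c("A", "B", "C")
  d <- binary_distance_matrix(mk_presence(st))
  expect_equal(diag(d), setNames(rep(0, 3), c("A", "B", "C")))
  expect_equal(d["A", "B"], 2 / 3)
  expect_equal(d, t(d))

  # identical rows -> 0; complementary support -> 1
  st2 <- cbind(X = c("present", "present", "absent"),
               Y = c("present", "present", "absent"),
               Z = c("absent", "absent", "present"))
  rownames(st2) <- paste0("m", 1:3)
  d2 <- binary_distance_matrix(mk_presence(st2))
  expect_equal(d2["X", "Y"], 0)
  expect_equal(d2["X", "Z"], 1)

  # joint absences are ignored (distance over the union only)
  st3 <- cbind(X = c("present", "absent", "absent", "absent"),
               Y = c("present", "present", "absent", "absent"))
  rownames(st3) <- paste0("m", 1:4)
  expect_equal(binary_distance_matrix(mk_presence(st3))["X", "Y"], 1 / 2)

  # missing cells are excluded pairwise; fully disjoint observation warns
  st4 <- cbind(X = c("present", "missing"), Y = c("missing", "present"))
  rownames(st4) <- c("m1", "m2")
  expect_warning(d4 <- binary_distance_matrix(mk_presence(st4)),
                 "no observed cells")
  expect_true(is.na(d4["X", "Y"]))
})

test_that("average linkage merges by hand-traced heights with stable ties", {
  d <- matrix(c(0, 0.1, 0.8,
                0.1, 0, 0.8,
                0.8, 0.8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- average_linkage(d)
  expect_equal(hc$height, c(0.1, 0.8))
  expect_equal(hc$merge[1, ], c(-1, -2))  # A joins B first

  # equal distances merge at identical heights deterministically
  d2 <- matrix(0.5, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d2) <- 0
  h1 <- average_linkage(d2)
  h2 <- average_linkage(d2)
  expect_identical(h1$merge, h2$merge)
  expect_true(all(h1$height == 0.5))

  d[1, 2] <- NA; d[2, 1] <- NA
  expect_error(average_linkage(d), "missing")

  # matched biopsy/spheroid pairs join before cross-area pairs
  co <- simulate_cohort(n_regions = 3, seed = 19)
  pm <- call_presence(co$counts)
  hc3 <- average_linkage(binary_distance_matrix(pm))
  first_pairs <- hc3$merge[hc3$merge[, 1] < 0 & hc3$merge[, 2] < 0, ,
                           drop = FALSE]
  smp <- co$design$samples
  for (r in seq_len(nrow(first_pairs))) {
    pair <- hc3$labels[-first_pairs[r, ]]
    expect_equal(smp$area[smp$sample == pair[1]],
                 smp$area[smp$sample == pair[2]])
  }
})

test_that("concordance partitions each pair's union per the worked toy", {
  samples <- c("T1", "S1", "T2", "S2")
  st <- rbind(
    m1 = c("present", "present", "present", "present"),
    m2 = c("present", "present", "absent", "absent"),
    m3 = c("present", "absent", "absent", "absent"),
    m4 = c("absent", "present", "absent", "absent"),
    m5 = c("absent", "absent", "present", "present"))
  colnames(st) <- samples
  pm <- mk_presence(st,
    samples = data.frame(sample = samples,
                         role = c("biopsy", "spheroid", "biopsy", "spheroid"),
                         area = c("A1", "A1", "A2", "A2")))
  rep <- concordance_stats(pm)
  a1 <- rep$per_area[rep$per_area$area == "A1", ]
  # union {m1..m4}: m3 tumor-only, m4 spheroid-only, m2 pairwise-private,
  # m1 concordant-and-elsewhere; concordance = 2/4
  expect_equal(a1$n_union, 4)
  expect_equal(a1$frac_tumor_only, 1 / 4)
  expect_equal(a1$frac_spheroid_only, 1 / 4)
  expect_equal(a1$frac_pairwise_private, 1 / 4)
  expect_equal(a1$frac_concordant_elsewhere, 1 / 4)
  expect_equal(a1$concordance, 2 / 4)
  # fractions partition the union exactly
  expect_equal(a1$frac_tumor_only + a1$frac_spheroid_only +
                 a1$frac_pairwise_private + a1$frac_concordant_elsewhere, 1)

  # m5 is pairwise private for area 2
  a2 <- rep$per_area[rep$per_area$area == "A2", ]
  expect_equal(a2$n_pairwise_private, 1)  # m5; m1 is seen elsewhere
  # identical rows -> full concordance
  expect_equal(a2$concordance, 1)

  # private mutations: m3 for T1, m4 for S1
  ps <- rep$per_sample
  expect_equal(ps$n_private[ps$sample == "T1"], 1)
  expect_equal(ps$n_private[ps$sample == "S1"], 1)
  expect_equal(ps$n_private[ps$sample == "T2"], 0)
  expect_equal(ps$private_fraction[ps$sample == "T1"], 1 / 3)
})

test_that("identical pair rows give 100% concordance and zero one-sided calls", {
  samples <- c("T1", "S1")
  st <- rbind(m1 = c("present", "present"), m2 = c("present", "present"))
  colnames(st) <- samples
  pm <- mk_presence(st, samples = data.frame(
    sample = samples, role = c("biopsy", "spheroid"), area = c("A1", "A1")))
  rep <- concordance_stats(pm)
  expect_equal(rep$per_area$concordance, 1)
  expect_equal(rep$per_area$n_tumor_only, 0)
  expect_equal(rep$per_area$n_spheroid_only, 0)
})

test_that("coding_only restricts the concordance denominator", {
  samples <- c("T1", "S1")
  st <- rbind(m1 = c("present", "present"), m2 = c("present", "absent"))
  colnames(st) <- samples
  pm <- mk_presence(st,
    samples = data.frame(sample = samples, role = c("biopsy", "spheroid"),
                         area = c("A1", "A1")),
    mutations = data.frame(id = c("m1", "m2"),
                           coding_class = c("missense", "noncoding")))
  rep <- concordance_stats(pm, coding_only = TRUE)
  expect_equal(rep$per_area$n_union, 1)
  expect_equal(rep$per_area$concordance, 1)
})

test_that("clone blocks recover pattern-defined mutation sets", {
  lc <- simulate_lnm_cohort(seed = 5, error_rate = 0, mean_depth = 300)
  pm <- call_presence(lc$counts)
  smp <- lc$design$samples
  lnms <- smp$sample[smp$role == "lnm"]
  tums <- smp$sample[smp$role == "biopsy"]
  blocks <- clone_blocks(pm, list(
    met = list(present_all = c(lnms, "T2"),
               absent_all = setdiff(tums, "T2")),
    nonmet = list(present_all = tums, absent_all = lnms),
    all = list()))
  expect_setequal(blocks$met, lc$metastatic_block)
  expect_setequal(blocks$nonmet, lc$nonmetastatic_block)
  expect_setequal(blocks$all, rownames(pm$state))  # empty pattern = all

  expect_error(clone_blocks(pm, list(x = list(present_all = "nope"))),
               "unknown sample")
})

test_that("purity estimation doubles the truncal AF median with clipping", {
  af <- cbind(S = c(0.25, 0.25, 0.25, 0.3, 0.2))
  rownames(af) <- paste0("m", 1:5)
  est <- purity_from_af(af, paste0("m", 1:5))
  expect_equal(est$estimate, 0.5)

  af2 <- cbind(S = rep(0.6, 5))
  rownames(af2) <- paste0("m", 1:5)
  expect_equal(purity_from_af(af2, paste0("m", 1:5))$estimate, 1)

  af3 <- cbind(S = c(0.3, 0.3, NA, NA, NA))
  rownames(af3) <- paste0("m", 1:5)
  expect_warning(e3 <- purity_from_af(af3, paste0("m", 1:5)), "fewer than")
  expect_true(is.na(e3$estimate))
})

test_that("purity estimator is nearly unbiased at saturating depth", {
  set.seed(61)
  tr <- simulate_clone_phylogeny(1)
  a <- assign_mutations(tr, 200, 0)
  for (p in c(0.3, 0.6, 0.9)) {
    smp <- data.frame(sample = "X", role = "biopsy", area = "A", purity = p)
    mix <- matrix(1, 1, 1, dimnames = list(tr$nodes, "X"))
    des <- sampling_design(smp, mix, mean_depth = 10000,
                           depth_dispersion = Inf, error_rate = 0)
    est <- replicate(50, {
      sim <- simulate_read_counts(tr, a, des)
      af <- compute_af(sim$counts$ref, sim$counts$alt)
      purity_from_af(matrix(af, ncol = 1,
                            dimnames = list(a$id, "X")), a$id)$estimate
    })
    expect_lt(abs(median(est) - p), 0.02)
  }
})

test_that("rank tests match small worked examples and handle degenerate input", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p.value, 1 / 3)
  expect_warning(r <- rank_sum_test(c(2, 2), c(2, 2)), "identical")
  expect_equal(r$p.value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")

  expect_equal(signed_rank_test(c(2, 4, 6), c(1, 2, 3))$p.value, 0.25)
  expect_warning(s <- signed_rank_test(c(1, 2), c(1, 2)), "zero")
  expect_equal(s$p.value, 1)
  # identical groups -> no separation
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
})

test_that("matched pairs sit closer than cross-area pairs on simulated cohorts", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    co <- simulate_cohort(n_regions = 3, seed = 1000 + s)
    pm <- call_presence(co$counts)
    tm <- apply_coverage_mask(pm, co$counts, mode = "missing")
    bt <- best_tree(tm, seed = s)
    mt <- matched_pair_distance_test(bt, tm)
    expect_lt(mean(mt$matched), mean(mt$cross))
    if (mt$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * n_seeds)
})

test_that("tree distances sum branch supports along tip paths", {
  pm <- mk_presence_sets(list(m1 = c("A", "B", "C"), m2 = c("A", "B"),
                              m3 = "A", m4 = "C"), c("A", "B", "C"))
  bt <- best_tree(pm)
  d <- tree_distance_matrix(bt)
  expect_equal(d["A", "B"], 1)  # private A only (B has no privates)
  expect_equal(d["A", "C"], 3)  # A private + AB edge + C private
  expect_equal(d["B", "C"], 2)
})
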