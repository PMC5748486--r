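test_that("clone phylogeny simulation is valid, deterministic, and handles degenerate sizes", {
  t1 <- simulate_clone_phylogeny(1)
  expect_length(t1$nodes, 1)
  expect_identical(t1$parent, 0L)

  t2 <- simulate_clone_phylogeny(2)
  expect_identical(t2$parent, c(0L, 1L))

  a <- simulate_clone_phylogeny(6, seed = 7)
  b <- simulate_clone_phylogeny(6, seed = 7)
  expect_identical(a$parent, b$parent)

  # every clone reachable from the root, across many random trees
  for (s in 1:20) {
    tr <- simulate_clone_phylogeny(sample(1:12, 1), seed = s)
    expect_true(all(clone_subtree(tr, tr$root) == seq_along(tr$nodes)))
  }

  expect_error(simulate_clone_phylogeny(0), "n_clones")
})

test_that("mutation assignment respects counts, spectra and degenerate cases", {
  tr <- simulate_clone_phylogeny(4, seed = 1)

  # truncal-only: every mutation on the root edge, carried by every clone
  a <- assign_mutations(tr, n_truncal = 10, n_per_branch = 0, seed = 2)
  expect_equal(nrow(a), 10)
  expect_true(all(a$branch == tr$nodes[tr$root]))

  # degenerate spectrum: all mass on C>T at CpG
  spec <- substitution_spectrum(c("C>T:CpG" = 1))
  b <- assign_mutations(tr, 25, 0, truncal_spectrum = spec, seed = 3)
  expect_true(all(b$class == "C>T"))
  expect_true(all(b$cpg))
  # emitted ref/alt/context reclassify to the same category
  cls <- substitution_class(b$ref, b$alt, b$context)
  expect_true(all(cls$class == "C>T" & cls$cpg))

  expect_error(assign_mutations(tr, -1, 0), "n_truncal")
  expect_error(assign_mutations(tr, 1, 0,
                                truncal_spectrum = c("C>T" = 0.5)),
               "sum to 1")
})

test_that("drawn class frequencies match the multinomial expectation", {
  tr <- simulate_clone_phylogeny(2, seed = 1)
  n <- 500
  for (make in list(default_truncal_spectrum, default_regional_spectrum)) {
    spec <- make()
    a <- assign_mutations(tr, n, 0, truncal_spectrum = spec, seed = 11)
    key <- paste0(a$class, ifelse(a$cpg, ":CpG", ""))
    obs <- table(factor(key, levels = names(spec)))
    # each category within 3 standard errors of n * p
    se <- sqrt(n * spec * (1 - spec))
    expect_true(all(abs(obs - n * spec) <= 3 * pmax(se, 1)))
  }
})

test_that("read-count model matches its closed form", {
  # single clone, purity 1, no error: expected AF is exactly 0.5
  tr <- simulate_clone_phylogeny(1)
  a <- assign_mutations(tr, 50, 0, seed = 4)
  smp <- data.frame(sample = "X", role = "biopsy", area = "A1", purity = 1)
  mix <- matrix(1, 1, 1, dimnames = list(tr$nodes, "X"))
  des <- sampling_design(smp, mix, mean_depth = 5000,
                         depth_dispersion = Inf, error_rate = 0)
  sim <- simulate_read_counts(tr, a, des, seed = 5)
  af <- compute_af(sim$counts$ref[, 1], sim$counts$alt[, 1])
  expect_true(abs(mean(af) - 0.5) < 3 * sqrt(0.25 / 5000 / 50))

  # mutation carried by no clone in the sample: zero alt reads at error 0
  tr2 <- simulate_clone_phylogeny(2, seed = 1)
  a2 <- assign_mutations(tr2, 0, 20, seed = 6)  # all on clone C2's branch
  mix2 <- matrix(c(1, 0), 2, 1, dimnames = list(tr2$nodes, "X"))
  des2 <- sampling_design(smp, mix2, mean_depth = 100, error_rate = 0)
  sim2 <- simulate_read_counts(tr2, a2, des2, seed = 7)
  expect_true(all(sim2$counts$alt == 0))
  expect_true(all(sim2$truth$carrier_fraction == 0))

  # Monte-Carlo vs closed form: depth 79, purity 0.8, f = 1 -> mean AF 0.4
  a3 <- assign_mutations(tr, 10000, 0, seed = 8)
  smp3 <- data.frame(sample = "X", role = "biopsy", area = "A1", purity = 0.8)
  des3 <- sampling_design(smp3, mix, mean_depth = 79, error_rate = 0)
  sim3 <- simulate_read_counts(tr, a3, des3, seed = 9)
  af3 <- compute_af(sim3$counts$ref[, 1], sim3$counts$alt[, 1])
  se <- sqrt(0.4 * 0.6 / 79 / 10000)
  expect_true(abs(mean(af3, na.rm = TRUE) - 0.4) < 3 * se * 1.5)

  expect_error(sampling_design(transform(smp, purity = 1.2), mix), "purity")
})

test_that("carrier sets are laminar by construction (perfect phylogeny)", {
  for (s in 1:10) {
    tr <- simulate_clone_phylogeny(8, seed = s)
    a <- assign_mutations(tr, 5, 3, seed = s + 100)
    carriers <- lapply(unique(a$branch), function(b)
      clone_subtree(tr, b))
    for (i in seq_along(carriers)) {
      for (j in seq_len(i - 1)) {
        common <- intersect(carriers[[i]], carriers[[j]])
        nested <- length(common) == min(length(carriers[[i]]),
                                        length(carriers[[j]]))
        expect_true(length(common) == 0 || nested)
      }
    }
  }
})

test_that("identical seeds give bit-identical cohorts", {
  x <- simulate_cohort(n_regions = 3, seed = 21)
  y <- simulate_cohort(n_regions = 3, seed = 21)
  expect_identical(x$counts$alt, y$counts$alt)
  expect_identical(x$counts$germline_alt, y$counts$germline_alt)
  expect_identical(x$design$samples$purity, y$design$samples$purity)
})

test_that("default cohort matches its stated study conditions", {
  co <- simulate_cohort(n_regions = 3, seed = 31)
  smp <- co$design$samples
  # biopsy/spheroid pair per region, spheroids purer under defaults
  expect_equal(sum(smp$role == "biopsy"), 3)
  expect_equal(sum(smp$role == "spheroid"), 3)
  for (a in unique(smp$area)) {
    bp <- smp$purity[smp$role == "biopsy" & smp$area == a]
    sp <- smp$purity[smp$role == "spheroid" & smp$area == a]
    expect_gte(sp, bp)
  }
  # mixtures are proper distributions
  expect_true(all(abs(colSums(co$design$mixtures) - 1) < 1e-8))
  # depth model centers near 79x
  depth <- co$counts$ref + co$counts$alt
  expect_true(abs(mean(depth) - 79) < 3)
})

test_that("with no error and saturating depth presence calling recovers truth", {
  co <- simulate_cohort(n_regions = 3, error_rate = 0, mean_depth = 1000,
                        depth_dispersion = Inf, seed = 41)
  pm <- call_presence(co$counts)
  truth <- co$truth$incidence[rownames(pm$state), colnames(pm$state)]
  expect_identical(unname(pm$state == "present"), unname(truth))
  # nothing excluded at zero error
  expect_length(pm$filter_log$germline_excluded, 0)
})
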