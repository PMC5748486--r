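test_that("a written cohort round-trips through per-sample VCFs exactly", {
  co <- simulate_cohort(n_regions = 3, seed = 51)
  dir <- withr_local_tempdir()
  man <- write_cohort(co$counts, dir, truth = co$truth)
  back <- read_cohort(man)
  ord <- rownames(co$counts$alt)
  expect_equal(unname(back$alt[ord, colnames(co$counts$alt)]),
               unname(co$counts$alt))
  expect_equal(unname(back$ref[ord, colnames(co$counts$ref)]),
               unname(co$counts$ref))
  expect_equal(unname(back$germline_alt[ord]),
               unname(as.integer(co$counts$germline_alt)))
  expect_identical(back$mutations$context[match(ord, back$mutations$id)],
                   co$counts$mutations$context)
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("TSV and VCF inputs yield identical matrices", {
  co <- simulate_cohort(n_regions = 2, seed = 52)
  dir <- withr_local_tempdir()
  man_path <- write_cohort(co$counts, dir)
  vcf_counts <- read_cohort(man_path)

  man <- read_manifest(man_path)
  tsv_man <- rbind(man[man$role != "germline", ],
                   data.frame(sample = "MATRIX", role = "matrix", area = ".",
                              path = "counts.tsv"))
  attr(tsv_man, "dir") <- dir
  tsv_counts <- read_cohort(tsv_man)
  ord <- rownames(tsv_counts$alt)
  expect_equal(unname(vcf_counts$alt[ord, colnames(tsv_counts$alt)]),
               unname(tsv_counts$alt))
  expect_equal(unname(vcf_counts$germline_alt[ord]),
               unname(tsv_counts$germline_alt[ord]))
})

test_that("manifest validation catches structural errors", {
  dir <- withr_local_tempdir()
  write_mani <- function(df) {
    p <- file.path(dir, "manifest.tsv")
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  base <- data.frame(sample = c("T1", "NORMAL"),
                     role = c("biopsy", "germline"),
                     area = c("A1", "."),
                     path = c("T1.vcf", "NORMAL.vcf"))
  expect_silent(read_manifest(write_mani(base)))

  no_germ <- base[base$role != "germline", ]
  expect_error(read_manifest(write_mani(no_germ)), "germline")

  dup <- rbind(base, base[1, ])
  expect_error(read_manifest(write_mani(dup)), "duplicate")
})

test_that("sites absent from one sample's VCF default to depth zero with warning", {
  co <- simulate_cohort(n_regions = 2, seed = 53)
  dir <- withr_local_tempdir()
  man <- write_cohort(co$counts, dir)
  # drop the first data line from one sample's VCF
  f <- file.path(dir, "T1.vcf")
  lines <- readLines(f)
  first_data <- which(!grepl("^#", lines))[1]
  writeLines(lines[-first_data], f)
  expect_warning(back <- read_cohort(man), "depth 0")
  dropped_id <- co$counts$mutations$id[1]
  expect_equal(unname(back$alt[dropped_id, "T1"]), 0L)
  expect_equal(unname(back$ref[dropped_id, "T1"]), 0L)
})

test_that("multi-allelic ALT fields keep the first alternate with a warning", {
  co <- simulate_cohort(n_regions = 2, seed = 54)
  dir <- withr_local_tempdir()
  man <- write_cohort(co$counts, dir)
  f <- file.path(dir, "T1.vcf")
  lines <- readLines(f)
  i <- which(!grepl("^#", lines))[1]
  parts <- strsplit(lines[i], "\t")[[1]]
  parts[5] <- paste0(parts[5], ",G")
  if (parts[4] == "G") parts[5] <- paste0(strsplit(parts[5], ",")[[1]][1], ",C")
  lines[i] <- paste(parts, collapse = "\t")
  writeLines(lines, f)
  expect_warning(read_cohort(man), "multi-allelic")
})

test_that("the pipeline emits its outputs and is byte-deterministic", {
  co <- simulate_cohort(n_regions = 3, seed = 55)
  out1 <- withr_local_tempdir()
  out2 <- withr_local_tempdir()
  res <- suppressMessages(
    run_pipeline(co$counts, pipeline_config(seed = 2), out1))
  for (f in c("tree.nwk", "spectrum.tsv", "spectrum_test.json",
              "edge_support.tsv", "distance.tsv", "heatmap_matrix.tsv",
              "concordance_areas.tsv", "purity.tsv", "summary.json",
              "presence_matrix.tsv"))
    expect_true(file.exists(file.path(out1, f)), label = f)

  suppressMessages(run_pipeline(co$counts, pipeline_config(seed = 2), out2))
  expect_identical(readLines(file.path(out1, "summary.json")),
                   readLines(file.path(out2, "summary.json")))
  expect_identical(readLines(file.path(out1, "tree.nwk")),
                   readLines(file.path(out2, "tree.nwk")))

  # mutation accounting: every candidate lands in exactly one category
  s <- res$summary
  expect_equal(s$filters$admitted + s$filters$germline_excluded +
                 s$filters$uncalled, s$n_candidate_mutations)

  # outputs re-parse (self-consistency)
  expect_silent(read.delim(file.path(out1, "spectrum.tsv")))
  expect_silent(read.delim(file.path(out1, "concordance_areas.tsv")))
  tr <- as_sample_tree(readLines(file.path(out1, "tree.nwk")))
  expect_s3_class(tr, "sample_tree")
})

test_that("a small exhaustive limit makes the pipeline fall back to hill climbing", {
  co <- simulate_cohort(n_regions = 3, seed = 56)
  out <- withr_local_tempdir()
  msgs <- capture.output(
    run_pipeline(co$counts, pipeline_config(seed = 1, exhaustive_limit = 4),
                 out), type = "message")
  expect_true(any(grepl("falling back to hill_climb", msgs)))
})

test_that("yaml config files override defaults and reject unknown keys", {
  dir <- withr_local_tempdir()
  p <- file.path(dir, "config.yaml")
  writeLines(c("seed: 7", "min_depth: 15", "mask_mode_heatmap: missing"), p)
  cfg <- read_config(p)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$min_depth, 15)
  expect_equal(cfg$mask_mode_heatmap, "missing")
  expect_equal(cfg$restarts, 10)

  writeLines("not_an_option: 1", p)
  expect_error(read_config(p), "unknown config")
})
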