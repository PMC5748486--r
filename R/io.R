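#' Write one sample's somatic calls as a single-sample VCF
#'
#' VCF v4.2 with `GT:AD:DP` in the sample column and the mutation metadata
#' (trinucleotide context, gene, coding class) in INFO, so a written cohort
#' round-trips through [read_cohort()] without loss.
#'
#' @param counts A [read_counts()] object.
#' @param sample Sample label, or `"germline"` for the matched-germline
#'   column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(counts, sample, path) {
  stopifnot(inherits(counts, "read_counts"))
  mut <- counts$mutations
  if (identical(sample, "germline")) {
    alt <- counts$germline_alt
    ref <- counts$germline_ref
  } else {
    if (!sample %in% colnames(counts$alt))
      .stop_invalid("unknown sample: ", sample)
    alt <- counts$alt[, sample]
    ref <- counts$ref[, sample]
  }
  info <- sprintf("CONTEXT=%s;GENE=%s;CLASS=%s",
                  if (!is.null(mut$context)) mut$context else ".",
                  if (!is.null(mut$gene)) mut$gene else ".",
                  if (!is.null(mut$coding_class)) mut$coding_class else ".")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=regionith",
    "##INFO=<ID=CONTEXT,Number=1,Type=String,Description=\"Reference trinucleotide context\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Coding class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT:AD:DP\t0/1:%d,%d:%d",
                  mut$chrom, mut$pos, mut$id, mut$ref, mut$alt, info,
                  ref, alt, ref + alt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write/read the full cohort count matrix as TSV
#'
#' Mutations as rows: `id, chrom, pos, ref, alt, gene, context,
#' coding_class, germline_ref, germline_alt`, then `<sample>_ref` /
#' `<sample>_alt` pairs.
#'
#' @param counts A [read_counts()] object.
#' @param path TSV file.
#' @return `write_counts_tsv`: `path` invisibly; `read_counts_tsv`: a
#'   [read_counts()] (sample roles/areas are re-derived by
#'   [read_cohort()] from the manifest; stand-alone reads default them).
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "read_counts"))
  mut <- counts$mutations
  out <- data.frame(id = mut$id, chrom = mut$chrom, pos = mut$pos,
                    ref = mut$ref, alt = mut$alt,
                    gene = if (!is.null(mut$gene)) mut$gene else ".",
                    context = if (!is.null(mut$context)) mut$context else ".",
                    coding_class = if (!is.null(mut$coding_class))
                      mut$coding_class else ".",
                    germline_ref = counts$germline_ref,
                    germline_alt = counts$germline_alt,
                    stringsAsFactors = FALSE)
  for (s in colnames(counts$alt)) {
    out[[paste0(s, "_ref")]] <- counts$ref[, s]
    out[[paste0(s, "_alt")]] <- counts$alt[, s]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param samples Optional sample metadata data.frame (`sample`, `role`,
#'   `area`); defaulted when absent.
#' @export
read_counts_tsv <- function(path, samples = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("id", "chrom", "pos", "ref", "alt", "gene", "context",
             "coding_class", "germline_ref", "germline_alt")
  if (!all(fixed %in% names(tab)))
    .stop_invalid(path, ": missing columns ",
                  paste(setdiff(fixed, names(tab)), collapse = ", "))
  scols <- grep("_(ref|alt)$", setdiff(names(tab), fixed), value = TRUE)
  slabs <- unique(sub("_(ref|alt)$", "", scols))
  if (!length(slabs)) .stop_invalid(path, ": no per-sample count columns")
  alt <- sapply(slabs, function(s) tab[[paste0(s, "_alt")]])
  ref <- sapply(slabs, function(s) tab[[paste0(s, "_ref")]])
  dimnames(alt) <- dimnames(ref) <- list(tab$id, slabs)
  if (is.null(samples))
    samples <- data.frame(sample = slabs, role = "biopsy",
                          area = paste0("A", seq_along(slabs)),
                          stringsAsFactors = FALSE)
  read_counts(alt = alt, ref = ref,
              germline_alt = setNames(tab$germline_alt, tab$id),
              germline_ref = setNames(tab$germline_ref, tab$id),
              mutations = tab[fixed[1:8]], samples = samples)
}

#' Write a simulated cohort to disk
#'
#' Emits one single-sample VCF per tumor/spheroid/LNM sample plus the
#' matched germline, the full TSV count matrix, a manifest, and (when a
#' truth object is supplied) the latent simulation truth as JSON.
#'
#' @param counts A [read_counts()] object.
#' @param dir Output directory (created if needed).
#' @param truth Optional `cohort_truth`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(counts, dir, truth = NULL) {
  stopifnot(inherits(counts, "read_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smp <- counts$samples
  manifest <- data.frame(sample = c(smp$sample, "NORMAL"),
                         role = c(smp$role, "germline"),
                         area = c(smp$area, "."),
                         path = c(paste0(smp$sample, ".vcf"), "NORMAL.vcf"),
                         stringsAsFactors = FALSE)
  for (s in smp$sample)
    write_sample_vcf(counts, s, file.path(dir, paste0(s, ".vcf")))
  ## germline VCF written under the label in its column header
  g <- counts
  write_sample_vcf(g, "germline", file.path(dir, "NORMAL.vcf"))
  write_counts_tsv(counts, file.path(dir, "counts.tsv"))
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(list(
      clone_parent = truth$tree$parent,
      clone_nodes = truth$tree$nodes,
      assignment = truth$assignment[, c("id", "branch", "class", "cpg",
                                        "coding_class")],
      purity = setNames(as.list(truth$design$samples$purity),
                        truth$design$samples$sample),
      mixtures = truth$design$mixtures,
      incidence = truth$incidence),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      matrix = "rowmajor")
  }
  invisible(mpath)
}

#' Read a cohort manifest
#'
#' @param path Manifest TSV with columns `sample`, `role`, `area`, `path`
#'   (paths relative to the manifest's directory).
#' @return data.frame of sample records; errors on duplicate labels or a
#'   missing/duplicated germline.
#' @export
read_manifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "role", "area", "path")
  if (!all(req %in% names(man)))
    .stop_invalid(path, ": manifest needs columns ",
                  paste(req, collapse = ", "))
  if (anyDuplicated(man$sample))
    .stop_invalid(path, ": duplicate sample label(s): ",
                  paste(unique(man$sample[duplicated(man$sample)]),
                        collapse = ", "))
  if (sum(man$role == "germline") != 1L)
    .stop_invalid(path, ": manifest must list exactly one germline sample")
  attr(man, "dir") <- dirname(path)
  man
}

# Parse one single-sample VCF into a per-mutation table.
.read_sample_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(vcf, element = "AD")[, 1L]
  parts <- strsplit(ad, ",", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    .stop_invalid(path, ": malformed AD field at data line ",
                  which(bad)[1L])
  ref_n <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  alt_n <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  if (anyNA(ref_n) || anyNA(alt_n))
    .stop_invalid(path, ": non-integer AD at data line ",
                  which(is.na(ref_n) | is.na(alt_n))[1L])
  alt_allele <- fix[, "ALT"]
  multi <- grepl(",", alt_allele, fixed = TRUE)
  if (any(multi)) {
    warning(path, ": multi-allelic site(s); keeping the first alternate",
            call. = FALSE)
    alt_allele <- sub(",.*$", "", alt_allele)
  }
  data.frame(
    id = fix[, "ID"],
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = alt_allele,
    context = vcfR::extract.info(vcf, element = "CONTEXT"),
    gene = vcfR::extract.info(vcf, element = "GENE"),
    coding_class = vcfR::extract.info(vcf, element = "CLASS"),
    ref_n = ref_n, alt_n = alt_n, stringsAsFactors = FALSE)
}

#' Read a cohort of per-sample VCFs (or a TSV matrix) into read counts
#'
#' Sites are keyed by `(chrom, pos, ref, alt)`; a mutation present in any
#' sample's VCF is looked up in all others, and records absent from a
#' sample default to depth 0 with a per-sample warning.  A `counts.tsv`
#' entry in the manifest (role `matrix`) takes precedence and supplies
#' complete counts directly.
#'
#' @param manifest Path to a manifest TSV (see [read_manifest()]) or an
#'   already-read manifest data.frame.
#' @return A [read_counts()] object.
#' @export
read_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  base <- attr(manifest, "dir")
  if (is.null(base)) base <- "."
  full <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))

  mx <- manifest[manifest$role == "matrix", , drop = FALSE]
  smp <- manifest[!manifest$role %in% c("germline", "matrix"), , drop = FALSE]
  if (nrow(mx) == 1L) {
    return(read_counts_tsv(full(mx$path),
                           samples = smp[c("sample", "role", "area")]))
  }

  tabs <- lapply(full(smp$path), .read_sample_vcf)
  names(tabs) <- smp$sample
  gl <- manifest[manifest$role == "germline", , drop = FALSE]
  gtab <- .read_sample_vcf(full(gl$path))

  keyof <- function(t) paste(t$chrom, t$pos, t$ref, t$alt, sep = ":")
  keys <- unique(unlist(lapply(tabs, keyof)))
  n <- length(keys)
  alt <- ref <- matrix(0L, n, nrow(smp), dimnames = list(keys, smp$sample))
  for (s in smp$sample) {
    k <- keyof(tabs[[s]])
    miss <- setdiff(keys, k)
    if (length(miss))
      warning(s, ": ", length(miss),
              " site(s) absent from VCF treated as depth 0", call. = FALSE)
    idx <- match(k, keys)
    alt[idx, s] <- tabs[[s]]$alt_n
    ref[idx, s] <- tabs[[s]]$ref_n
  }
  g_alt <- setNames(integer(n), keys)
  g_ref <- setNames(integer(n), keys)
  gk <- keyof(gtab)
  gi <- match(gk, keys)
  hit <- !is.na(gi)
  g_alt[gi[hit]] <- gtab$alt_n[hit]
  g_ref[gi[hit]] <- gtab$ref_n[hit]
  if (any(!keys %in% gk))
    warning("germline: ", sum(!keys %in% gk),
            " site(s) absent from VCF treated as depth 0", call. = FALSE)

  meta <- do.call(rbind, tabs)
  meta <- meta[!duplicated(paste(meta$chrom, meta$pos, meta$ref, meta$alt,
                                 sep = ":")), , drop = FALSE]
  mk <- keyof(meta)
  meta <- meta[match(keys, mk), , drop = FALSE]
  # keep VCF IDs as mutation ids when they are informative and unique
  ids <- meta$id
  if (anyNA(ids) || any(ids == ".") || anyDuplicated(ids)) ids <- keys
  rownames(alt) <- rownames(ref) <- ids
  names(g_alt) <- names(g_ref) <- ids
  mutations <- data.frame(id = ids, chrom = meta$chrom, pos = meta$pos,
                          ref = meta$ref, alt = meta$alt, gene = meta$gene,
                          context = meta$context,
                          coding_class = meta$coding_class,
                          stringsAsFactors = FALSE)
  read_counts(alt = alt, ref = ref, germline_alt = g_alt,
              germline_ref = g_ref, mutations = mutations,
              samples = smp[c("sample", "role", "area")])
}
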