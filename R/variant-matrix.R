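#' Allele fraction from read counts
#'
#' `alt / (ref + alt)`, undefined (`NA`) at zero depth.
#'
#' @param ref,alt Non-negative integer vectors (recycled).
#' @return Numeric vector of fractions in `[0, 1]`, `NA` where depth is 0.
#' @examples
#' compute_af(ref = 75, alt = 25)  # 0.25
#' @export
compute_af <- function(ref, alt) {
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
    .stop_invalid("read counts must be non-negative")
  depth <- ref + alt
  ifelse(depth > 0, alt / depth, NA_real_)
}

#' Call per-sample mutation presence
#'
#' A mutation is admitted to the matrix only if the matched germline shows
#' at most `max_germline_alt` alt reads (default 1, i.e. "absent in the
#' matched germline (0-1 read)").  Within admitted mutations, a sample is
#' called *present* when its alt reads reach `min_alt` (default 2) and
#' *absent* otherwise; the coverage mask ([apply_coverage_mask()]) may later
#' turn low-depth absences into *missing*.  Mutations called in no sample
#' are flagged uncalled and excluded.  Sharing labels are attached via
#' [classify_sharing()].
#'
#' @param counts A [read_counts()] object (must include the germline column).
#' @param min_alt Minimum alt reads for a present call (default 2).
#' @param max_germline_alt Maximum germline alt reads for admission
#'   (default 1).
#' @return A `presence_matrix`: state matrix (`present` / `absent` /
#'   `missing`), AF matrix, mutation and sample tables, per-mutation
#'   `sharing` ("shared" / "regional") and `carrier_n`, and a `filter_log`
#'   recording germline-excluded and uncalled mutation ids.
#' @export
call_presence <- function(counts, min_alt = 2, max_germline_alt = 1) {
  stopifnot(inherits(counts, "read_counts"))
  if (is.null(counts$germline_alt))
    .stop_invalid("no matched germline column in the count data")

  germline_bad <- counts$germline_alt > max_germline_alt
  keep <- !germline_bad
  alt <- counts$alt[keep, , drop = FALSE]
  ref <- counts$ref[keep, , drop = FALSE]
  state <- ifelse(alt >= min_alt, "present", "absent")
  af <- matrix(compute_af(as.vector(ref), as.vector(alt)),
               nrow(alt), ncol(alt), dimnames = dimnames(alt))
  carrier_n <- rowSums(state == "present")
  uncalled <- carrier_n == 0L

  pm <- structure(list(
    state = state[!uncalled, , drop = FALSE],
    af = af[!uncalled, , drop = FALSE],
    mutations = counts$mutations[keep, , drop = FALSE][!uncalled, , drop = FALSE],
    samples = counts$samples,
    sharing = NULL,
    carrier_n = carrier_n[!uncalled],
    filter_log = list(
      admitted = sum(keep) - sum(uncalled),
      germline_excluded = counts$mutations$id[germline_bad],
      uncalled = rownames(alt)[uncalled],
      mask_dropped = character(0))),
    class = "presence_matrix")
  classify_sharing(pm)
}

#' Classify mutations as shared or regional
#'
#' A mutation present in `n` or `n - 1` of the `n` samples is *shared*;
#' a mutation present in at least one but fewer than `n - 1` samples is
#' *regional*.  Missing cells do not count as carriers.
#'
#' @param presence A `presence_matrix`.
#' @param n_samples Total number of samples (defaults to the matrix width;
#'   must be >= 2).
#' @return The presence matrix with `sharing` and `carrier_n` updated.
#' @export
classify_sharing <- function(presence, n_samples = ncol(presence$state)) {
  stopifnot(inherits(presence, "presence_matrix"))
  if (n_samples < 2) .stop_invalid("sharing needs at least 2 samples")
  presence$carrier_n <- rowSums(presence$state == "present")
  presence$sharing <- ifelse(presence$carrier_n >= n_samples - 1L,
                             "shared", "regional")
  presence
}

#' Apply the low-coverage mask to regional mutations
#'
#' To avoid false negatives, a *regional* mutation whose absent ("negative")
#' samples include one with site depth below `min_depth` is either dropped
#' from the matrix (`mode = "drop"`, the heatmap rule) or has those cells
#' set to *missing* (`mode = "missing"`, the tree-scoring variant, where a
#' missing cell constrains nothing).  Shared mutations are unaffected.
#'
#' @param presence A `presence_matrix` with sharing labels.
#' @param counts The [read_counts()] the matrix was called from.
#' @param min_depth Minimum depth for a trustworthy negative call
#'   (default 10).
#' @param mode `"drop"` or `"missing"`.
#' @return The filtered/masked presence matrix.
#' @export
apply_coverage_mask <- function(presence, counts, min_depth = 10,
                                mode = c("drop", "missing")) {
  stopifnot(inherits(presence, "presence_matrix"),
            inherits(counts, "read_counts"))
  mode <- match.arg(mode)
  if (is.null(presence$sharing))
    .stop_invalid("sharing labels must be computed before masking")
  ids <- rownames(presence$state)
  depth <- (counts$ref + counts$alt)[ids, colnames(presence$state),
                                     drop = FALSE]
  lowneg <- presence$state == "absent" & depth < min_depth
  affected <- presence$sharing == "regional" & rowSums(lowneg) > 0L

  if (mode == "drop") {
    presence$filter_log$mask_dropped <-
      union(presence$filter_log$mask_dropped, ids[affected])
    presence$state <- presence$state[!affected, , drop = FALSE]
    presence$af <- presence$af[!affected, , drop = FALSE]
    presence$mutations <- presence$mutations[!affected, , drop = FALSE]
    presence$sharing <- presence$sharing[!affected]
    presence$carrier_n <- presence$carrier_n[!affected]
    presence$filter_log$admitted <- nrow(presence$state)
  } else {
    presence$state[lowneg & affected] <- "missing"
  }
  presence
}

#' Annotate mutations with gene-list categories
#'
#' Copies per-gene category flags (e.g. CRC-driver, other-driver,
#' druggable) from a user-supplied gene list onto the mutation table;
#' genes not in the list are flagged `"none"`.  Duplicate genes keep the
#' first category listed, with a warning.
#'
#' @param presence A `presence_matrix` whose mutations carry gene symbols.
#' @param gene_list A data.frame with columns `gene` and `category`, or the
#'   path of a two-column tab-separated file with that header.
#' @return The presence matrix with a `category` column on `$mutations`.
#' @export
annotate_genes <- function(presence, gene_list) {
  stopifnot(inherits(presence, "presence_matrix"))
  if (is.character(gene_list)) {
    nf <- count.fields(gene_list, sep = "\t", quote = "")
    if (any(nf != 2L))
      .stop_invalid("malformed gene list at line ",
                    which(nf != 2L)[1L], ": expected 2 tab-separated fields")
    gene_list <- read.delim(gene_list, stringsAsFactors = FALSE)
  }
  if (!all(c("gene", "category") %in% names(gene_list)))
    .stop_invalid("gene list needs columns 'gene' and 'category'")
  dup <- duplicated(gene_list$gene)
  if (any(dup)) {
    warning("duplicated gene(s) in list, keeping first entry: ",
            paste(unique(gene_list$gene[dup]), collapse = ", "),
            call. = FALSE)
    gene_list <- gene_list[!dup, , drop = FALSE]
  }
  idx <- match(presence$mutations$gene, gene_list$gene)
  presence$mutations$category <- ifelse(is.na(idx), "none",
                                        gene_list$category[idx])
  presence
}

#' @exportS3Method base::print
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x$state), "mutations x", ncol(x$state),
      "samples\n")
  if (!is.null(x$sharing))
    cat("  shared:", sum(x$sharing == "shared"),
        " regional:", sum(x$sharing == "regional"), "\n")
  lg <- x$filter_log
  cat("  filtered: germline", length(lg$germline_excluded),
      "| uncalled", length(lg$uncalled),
      "| mask-dropped", length(lg$mask_dropped), "\n")
  invisible(x)
}

#' Write the presence/AF matrix as TSV
#'
#' One row per mutation: `chrom, pos, ref, alt, gene, coding_class,
#' sharing`, then per-sample AF (`<sample>_af`) and state
#' (`<sample>_state`) columns.
#'
#' @param presence A `presence_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(presence, path) {
  mut <- presence$mutations
  out <- data.frame(chrom = mut$chrom, pos = mut$pos, ref = mut$ref,
                    alt = mut$alt,
                    gene = if (!is.null(mut$gene)) mut$gene else NA,
                    coding_class = if (!is.null(mut$coding_class))
                      mut$coding_class else NA,
                    sharing = presence$sharing,
                    stringsAsFactors = FALSE)
  af <- round(presence$af, 4)
  colnames(af) <- paste0(colnames(af), "_af")
  st <- presence$state
  colnames(st) <- paste0(colnames(st), "_state")
  write.table(cbind(out, af, st), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
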