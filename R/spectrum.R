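#' Classify a substitution into the six pyrimidine-reference classes
#'
#' Purine-reference changes are reverse-complemented so every substitution
#' is reported with a C or T reference (`C>A, C>G, C>T, T>A, T>C, T>G`).
#' The CpG flag is true when, after this normalization, the mutated C is
#' immediately followed by G in the reference trinucleotide context.
#' Ambiguous bases or a context that does not match the reference base
#' leave the mutation unclassifiable (`NA` class) with a warning.
#'
#' @param ref,alt Single reference / alternate bases (vectors accepted;
#'   must differ position-wise).
#' @param context Reference trinucleotide centered on the site.
#' @return data.frame with columns `class` (character or `NA`) and `cpg`
#'   (logical).
#' @examples
#' substitution_class("G", "A", "CGT")  # C>T at CpG (via the minus strand)
#' @export
substitution_class <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- toupper(rep_len(ref, n))
  alt <- toupper(rep_len(alt, n))
  context <- toupper(rep_len(context, n))
  if (any(ref == alt)) .stop_invalid("ref and alt must differ")

  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    nchar(context) == 3L & substr(context, 2L, 2L) == ref &
    !grepl("[^ACGT]", context)
  if (any(!ok))
    warning(sum(!ok), " unclassifiable substitution(s) (ambiguous base or ",
            "context mismatch)", call. = FALSE)

  purine <- ref %in% c("A", "G")
  ref2 <- ifelse(purine, .comp(ref), ref)
  alt2 <- ifelse(purine, .comp(alt), alt)
  ctx2 <- context
  if (any(purine & ok)) ctx2[purine & ok] <- .revcomp(context[purine & ok])

  cls <- ifelse(ok, paste0(ref2, ">", alt2), NA_character_)
  cpg <- ok & ref2 == "C" & substr(ctx2, 3L, 3L) == "G"
  data.frame(class = cls, cpg = cpg, stringsAsFactors = FALSE)
}

#' Tabulate the mutational spectrum by sharing group
#'
#' Counts mutations per substitution class x CpG flag x group (shared vs
#' regional).  Accepts a scored `presence_matrix` (classes are derived from
#' its mutation table) or a data.frame with `ref`, `alt`, `context`
#' columns plus a vector of group labels.
#'
#' @param x A `presence_matrix` or mutation data.frame.
#' @param group Group label per mutation (ignored for a `presence_matrix`,
#'   whose sharing labels are used).
#' @return A `spectrum_table`: data.frame with columns `class`, `cpg` and
#'   one count column per group, plus attributes `fractions` (per-group
#'   column fractions) and `n_unclassified`.
#' @export
spectrum_table <- function(x, group = NULL) {
  if (inherits(x, "presence_matrix")) {
    group <- x$sharing
    x <- x$mutations
  }
  if (!all(c("ref", "alt", "context") %in% names(x)))
    .stop_invalid("mutation table needs ref, alt and context columns")
  if (length(group) != nrow(x))
    .stop_invalid("'group' must label every mutation")
  groups <- c("shared", "regional")
  if (!all(group %in% groups))
    .stop_invalid("groups must be 'shared' or 'regional'")

  if (nrow(x) == 0L) {
    cls <- data.frame(class = character(), cpg = logical())
  } else {
    cls <- substitution_class(x$ref, x$alt, x$context)
  }
  usable <- !is.na(cls$class)
  grid <- expand.grid(cpg = c(FALSE, TRUE), class = SUB_CLASSES,
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, c("class", "cpg")]
  grid <- grid[!(grid$cpg & substr(grid$class, 1, 1) == "T"), ]
  tab <- grid
  for (g in groups) {
    sel <- usable & group == g
    key <- paste(cls$class[sel], cls$cpg[sel])
    tab[[g]] <- as.integer(table(factor(key,
      levels = paste(grid$class, grid$cpg)))[paste(grid$class, grid$cpg)])
  }
  if (any(colSums(tab[groups]) == 0L))
    warning("empty mutation group(s): ",
            paste(groups[colSums(tab[groups]) == 0L], collapse = ", "),
            call. = FALSE)
  frac <- tab
  for (g in groups) {
    tot <- sum(tab[[g]])
    frac[[g]] <- if (tot > 0) tab[[g]] / tot else 0
  }
  structure(tab, fractions = frac, n_unclassified = sum(!usable),
            class = c("spectrum_table", "data.frame"))
}

#' Test for C>T-at-CpG enrichment in shared mutations
#'
#' Collapses the spectrum to a 2x2 table, {C>T at CpG, all else} x
#' {shared, regional}, and applies Pearson's chi-squared test (1 df,
#' without continuity correction by default).
#'
#' @param table A [spectrum_table()].
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A list with `statistic`, `df`, `p.value` and the collapsed 2x2
#'   `table`.
#' @export
cpg_enrichment_test <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "spectrum_table"))
  groups <- c("shared", "regional")
  is_ct_cpg <- table$class == "C>T" & table$cpg
  m <- rbind(`C>T at CpG` = colSums(table[is_ct_cpg, groups, drop = FALSE]),
             `other` = colSums(table[!is_ct_cpg, groups, drop = FALSE]))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    .stop_invalid("cannot test: a margin of the collapsed 2x2 table is zero ",
                  "(need both groups and both outcome rows populated)")
  ht <- chisq.test(m, correct = correct)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, table = m)
}

#' Write a spectrum table as TSV
#'
#' @param table A [spectrum_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(table, path) {
  frac <- attr(table, "fractions")
  out <- cbind(as.data.frame(table),
               shared_frac = round(frac$shared, 5),
               regional_frac = round(frac$regional, 5))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
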