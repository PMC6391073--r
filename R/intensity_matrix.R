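#' Proteins-by-samples intensity container
#'
#' Holds a label-free proteomics quantification: per-protein metadata
#' (peptide counts, contaminant/reverse flags), the sample-to-condition
#' design, and LFQ and iBAQ intensity layers as proteins x samples matrices
#' (zero or `NA` entries are missing values).
#'
#' @param proteins Tibble with columns `protein_id` (unique), `peptides`
#'   (integer), `contaminant` and `reverse` (logical).
#' @param samples Tibble with columns `sample` (unique, matching the matrix
#'   columns) and `group` (condition label, e.g. light intensity).
#' @param lfq,ibaq Numeric matrices (proteins x samples); `ibaq` may be
#'   `NULL`. Zeros are converted to `NA` (missing).
#' @return An object of class `intensity_matrix`.
#' @seealso [load_protein_groups()], [simulate_proteomics()],
#'   [filter_protein_groups()]
#' @export
intensity_matrix <- function(proteins, samples, lfq, ibaq = NULL) {
  need_p <- c("protein_id", "peptides", "contaminant", "reverse")
  miss <- setdiff(need_p, names(proteins))
  if (length(miss) > 0) {
    abort(paste("`proteins` is missing columns:", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(proteins$protein_id)) {
    abort("duplicated protein ids")
  }
  miss <- setdiff(c("sample", "group"), names(samples))
  if (length(miss) > 0) {
    abort(paste("`samples` is missing columns:", paste(miss, collapse = ", ")))
  }
  fix <- function(m, nm) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != nrow(proteins) || ncol(m) != nrow(samples)) {
      abort(sprintf("`%s` must be %d x %d", nm, nrow(proteins), nrow(samples)))
    }
    if (any(m < 0, na.rm = TRUE)) abort(sprintf("`%s` has negative intensities", nm))
    m[!is.na(m) & m == 0] <- NA
    dimnames(m) <- list(proteins$protein_id, samples$sample)
    m
  }
  structure(
    list(proteins = as_tibble(proteins), samples = as_tibble(samples),
         lfq = fix(lfq, "lfq"), ibaq = fix(ibaq, "ibaq")),
    class = "intensity_matrix"
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("<intensity_matrix>", nrow(x$proteins), "proteins x",
      nrow(x$samples), "samples in", length(unique(x$samples$group)),
      "groups\n")
  cat("  layers:", paste(c("lfq", if (!is.null(x$ibaq)) "ibaq"),
                         collapse = ", "),
      sprintf("(%.1f%% missing LFQ)\n", 100 * mean(is.na(x$lfq))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) c(nrow(x$proteins), nrow(x$samples))

# subset an intensity matrix by protein index
im_subset <- function(im, idx) {
  intensity_matrix(im$proteins[idx, , drop = FALSE], im$samples,
                   im$lfq[idx, , drop = FALSE],
                   if (!is.null(im$ibaq)) im$ibaq[idx, , drop = FALSE])
}

# list of column indices per condition group
im_group_cols <- function(im) {
  split(seq_len(nrow(im$samples)), im$samples$group)
}

#' Filter a protein-groups table
#'
#' Applies the standard post-identification filters: removes reverse-decoy
#' and potential-contaminant entries, proteins identified by fewer than
#' `min_peptides` different peptides, and proteins that fail the
#' missing-value rule on the LFQ layer. The default rule retains proteins
#' with complete (no missing) LFQ values in at least one condition group;
#' the published filter sentence is grammatically ambiguous, so the
#' alternative reading (complete values in every group) is available as
#' `missing_rule = "complete_in_all_groups"`.
#'
#' @param im An [intensity_matrix()].
#' @param min_peptides Minimum number of different peptides (default 2).
#' @param missing_rule `"complete_in_any_group"` (default) or
#'   `"complete_in_all_groups"`.
#' @return The filtered [intensity_matrix()]; removal counts per rule are
#'   attached as attribute `"filter_counts"` (a tibble).
#' @export
filter_protein_groups <- function(im, min_peptides = 2,
                                  missing_rule = c("complete_in_any_group",
                                                   "complete_in_all_groups")) {
  stopifnot(inherits(im, "intensity_matrix"))
  missing_rule <- match.arg(missing_rule)
  keep <- rep(TRUE, nrow(im$proteins))
  counts <- list()
  drop_rule <- function(bad, label) {
    counts[[label]] <<- sum(bad & keep)
    keep <<- keep & !bad
  }
  drop_rule(im$proteins$reverse, "reverse")
  drop_rule(im$proteins$contaminant, "contaminant")
  drop_rule(im$proteins$peptides < min_peptides, "min_peptides")
  groups <- im_group_cols(im)
  complete <- vapply(groups, function(cols) {
    rowSums(is.na(im$lfq[, cols, drop = FALSE])) == 0
  }, logical(nrow(im$proteins)))
  ok <- if (missing_rule == "complete_in_any_group") {
    rowSums(complete) >= 1
  } else {
    rowSums(complete) == length(groups)
  }
  drop_rule(!ok, "missing_values")
  out <- im_subset(im, which(keep))
  attr(out, "filter_counts") <- tibble(
    rule = names(counts), removed = unlist(counts, use.names = FALSE)
  )
  out
}
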