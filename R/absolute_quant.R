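#' Calibration specification for absolute quantification
#'
#' Describes how iBAQ intensities are turned into molecules per cell: a set
#' of stable reference proteins for between-sample normalization, one anchor
#' protein whose absolute amount is known independently (e.g. from
#' quantitative immunoblotting), and the cell concentration of the measured
#' extract.
#'
#' @param reference_ids Accessions of the normalization reference proteins
#'   (default: the four stable reference proteins used in the original
#'   analysis).
#' @param anchor_id Accession of the anchor protein.
#' @param anchor_amount Absolute anchor amount (fmol uL^-1; default 104, the
#'   immunoblot mean for the PsaC anchor).
#' @param cells_per_volume Cells per uL of the measured extract; required
#'   for copies-per-cell conversion.
#' @return A list of class `calibration_spec`.
#' @export
calibration_spec <- function(reference_ids = c("Q55806", "P72587",
                                               "P73505", "Q59978"),
                             anchor_id,
                             anchor_amount = 104,
                             cells_per_volume) {
  if (length(reference_ids) < 1) abort("`reference_ids` must be non-empty")
  if (missing(anchor_id)) abort("`anchor_id` is required")
  if (anchor_amount <= 0) abort("`anchor_amount` must be > 0")
  if (missing(cells_per_volume) || cells_per_volume <= 0) {
    abort("`cells_per_volume` (cells per uL) must be supplied and > 0")
  }
  structure(list(reference_ids = reference_ids, anchor_id = anchor_id,
                 anchor_amount = anchor_amount,
                 cells_per_volume = cells_per_volume),
            class = "calibration_spec")
}

#' Normalize iBAQ intensities on a reference-protein sum
#'
#' Divides each sample's iBAQ intensities by that sample's summed intensity
#' of the reference proteins, removing per-sample scale differences (loading
#' and instrument response). After normalization the reference sum is
#' exactly 1 in every sample, so the operation is idempotent and invariant
#' to any per-sample rescaling of the input.
#'
#' @param im An [intensity_matrix()] with an iBAQ layer.
#' @param spec A [calibration_spec()].
#' @return The [intensity_matrix()] with the iBAQ layer normalized;
#'   per-sample factors are attached as attribute `"normalization_factors"`.
#' @export
normalize_ibaq <- function(im, spec) {
  stopifnot(inherits(im, "intensity_matrix"),
            inherits(spec, "calibration_spec"))
  if (is.null(im$ibaq)) abort("intensity matrix has no iBAQ layer")
  missing_ref <- setdiff(spec$reference_ids, im$proteins$protein_id)
  if (length(missing_ref) > 0) {
    abort(paste("reference proteins absent from the matrix:",
                paste(missing_ref, collapse = ", ")))
  }
  ref <- im$ibaq[spec$reference_ids, , drop = FALSE]
  bad <- colnames(ref)[colSums(is.na(ref)) > 0]
  if (length(bad) > 0) {
    abort(paste("reference intensities missing in sample(s):",
                paste(bad, collapse = ", ")))
  }
  factors <- colSums(ref)
  if (any(factors <= 0)) abort("non-positive reference sum")
  out <- im
  out$ibaq <- sweep(im$ibaq, 2, factors, "/")
  attr(out, "normalization_factors") <- factors
  out
}

#' Calibrate normalized iBAQ intensities to copies per cell
#'
#' One global factor maps the anchor protein's grand mean normalized iBAQ
#' intensity to its independently measured absolute amount
#' (fmol uL^-1); amounts are then converted to molecules per cell with
#' Avogadro's number and the cell concentration of the extract. The result
#' is linear in `anchor_amount` and inversely linear in `cells_per_volume`.
#'
#' @param im An [intensity_matrix()] whose iBAQ layer has been normalized
#'   with [normalize_ibaq()].
#' @param spec A [calibration_spec()].
#' @return A long tibble with columns `protein_id`, `sample`, `group`,
#'   `copies_per_cell`; the scalar calibration factor (fmol uL^-1 per
#'   normalized intensity unit) is attached as attribute
#'   `"calibration_factor"`.
#' @export
calibrate_absolute <- function(im, spec) {
  stopifnot(inherits(im, "intensity_matrix"),
            inherits(spec, "calibration_spec"))
  if (is.null(im$ibaq)) abort("intensity matrix has no iBAQ layer")
  if (!spec$anchor_id %in% im$proteins$protein_id) {
    abort(sprintf("anchor protein %s absent from the matrix", spec$anchor_id))
  }
  anchor <- im$ibaq[spec$anchor_id, ]
  anchor_mean <- mean(anchor, na.rm = TRUE)
  if (!is.finite(anchor_mean) || anchor_mean <= 0) {
    abort("anchor protein has no positive intensities")
  }
  factor_fmol <- spec$anchor_amount / anchor_mean
  per_fmol_cells <- .molecules_per_fmol / spec$cells_per_volume
  long <- as_tibble(im$ibaq, rownames = "protein_id") |>
    tidyr::pivot_longer(-"protein_id", names_to = "sample",
                        values_to = "ibaq") |>
    dplyr::left_join(im$samples, by = "sample") |>
    dplyr::mutate(
      copies_per_cell = .data$ibaq * factor_fmol * per_fmol_cells
    ) |>
    dplyr::select("protein_id", "sample", "group", "copies_per_cell")
  attr(long, "calibration_factor") <- factor_fmol
  long
}

# ---- stoichiometry grammar --------------------------------------------------

# tokenizer for complex formulas: names, commas, parens, integers
stoich_tokens <- function(text) {
  s <- gsub("\\s+", "", text)
  pat <- "[A-Za-z][A-Za-z0-9]*|[0-9]+|[(),]"
  m <- gregexpr(pat, s)[[1]]
  toks <- regmatches(s, gregexpr(pat, s))[[1]]
  if (length(toks) == 0 || sum(attr(m, "match.length")) != nchar(s)) {
    bad <- if (length(m) > 0 && m[1] > 1) 1 else sum(attr(m, "match.length")) + 1
    abort(sprintf("cannot parse stoichiometry '%s' near position %d",
                  text, bad))
  }
  toks
}

#' Parse a protein-complex stoichiometry formula
#'
#' Parses the compact complex notation used in tables of protein-complex
#' composition into per-subunit copy numbers. The grammar:
#' * comma-separated subunit lists: `"PsbA, PsbB"`;
#' * parenthesized groups with an integer multiplier applying to every
#'   member, nestable: `"(RbcL, RbcS)8"`, `"((CpcA,B)18,C1,C2,D,G)6"`;
#' * short subunit subscripts inherit the letter prefix of the most recent
#'   full name: `"(PsaA,B,C)3"` reads as PsaA, PsaB, PsaC. Trailing digits
#'   are part of the subunit name (`"PsbA1"`); multiplicity is expressed
#'   only by group multipliers, so a homodimer is written `"(SodB)2"`.
#'
#' @param text Formula string.
#' @param name Optional complex name (defaults to the formula).
#' @return A list of class `complex_definition` with elements `name` and
#'   `subunits` (named integer vector of copies per complex).
#' @examples
#' parse_stoichiometry("(RbcL, RbcS)8")
#' parse_stoichiometry("(PsaA,B,C,D,E,F,I,J,K,L,M,X)3")
#' @export
parse_stoichiometry <- function(text, name = text) {
  toks <- stoich_tokens(text)
  pos <- 1
  prefix <- ""
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() {
    t <- peek()
    pos <<- pos + 1
    t
  }
  is_full_name <- function(tok) grepl("^[A-Z][a-z]", tok)
  parse_list <- function() {
    acc <- list()
    repeat {
      t <- take()
      if (t == "(") {
        inner <- parse_list()
        if (peek() != ")") abort(sprintf("unbalanced parentheses in '%s'", text))
        take()
        mult <- 1L
        if (grepl("^[0-9]+$", peek())) mult <- as.integer(take())
        acc[[length(acc) + 1]] <- inner * mult
      } else if (grepl("^[A-Za-z]", t) || grepl("^[0-9]+$", t)) {
        nm <- t
        if (is_full_name(t)) {
          prefix <<- sub("^([A-Z][a-z]+).*$", "\\1", t)
        } else {
          if (grepl("^[0-9]+$", t) && grepl("^[A-Za-z]", peek())) {
            # digit-led subunit subscript such as "1B" splits into two tokens
            nm <- paste0(t, take())
          }
          nm <- paste0(prefix, nm)
        }
        acc[[length(acc) + 1]] <- setNames(1L, nm)
      } else {
        abort(sprintf("cannot parse stoichiometry '%s' at token %d ('%s')",
                      text, pos - 1, t))
      }
      if (peek() == ",") {
        take()
        next
      }
      break
    }
    v <- unlist(acc)
    tapply(v, names(v), sum)[unique(names(v))]
  }
  subunits <- parse_list()
  if (pos <= length(toks)) {
    abort(sprintf("trailing input in stoichiometry '%s' at token %d", text, pos))
  }
  structure(list(name = name,
                 subunits = setNames(as.integer(subunits), names(subunits))),
            class = "complex_definition")
}

#' @export
print.complex_definition <- function(x, ...) {
  cat("<complex_definition>", x$name, "\n ",
      paste(sprintf("%s x%d", names(x$subunits), x$subunits), collapse = ", "),
      "\n")
  invisible(x)
}

#' Complex copies per cell from subunit copy numbers
#'
#' Combines per-subunit copies per cell into a per-complex estimate using
#' the subunit stoichiometry: the default estimator is the
#' stoichiometry-weighted mean `sum(copies) / sum(s)` over quantified
#' subunits (robust to single-subunit ionization bias); the minimum of
#' `copies_i / s_i` is also reported as a conservative bound, and the
#' maximum for the spread. The weighted estimate always lies between the
#' min and max bounds.
#'
#' @param copies Named numeric vector: copies per cell per protein (names
#'   are subunit identifiers).
#' @param cx A [parse_stoichiometry()] complex definition.
#' @return One-row tibble: `complex`, `copies` (weighted estimate),
#'   `copies_min`, `copies_max`, `n_subunits_quantified`, `n_subunits`,
#'   `missing_subunits` (comma-separated). All copy estimates are `NA` with
#'   a note when no subunit is quantified.
#' @examples
#' cx <- parse_stoichiometry("(GlnB)3", name = "PII")
#' complex_copy_number(c(GlnB = 120000), cx)
#' @export
complex_copy_number <- function(copies, cx) {
  stopifnot(inherits(cx, "complex_definition"))
  have <- intersect(names(cx$subunits), names(copies))
  have <- have[!is.na(copies[have])]
  missing_sub <- setdiff(names(cx$subunits), have)
  if (length(have) == 0) {
    return(tibble(complex = cx$name, copies = NA_real_,
                  copies_min = NA_real_, copies_max = NA_real_,
                  n_subunits_quantified = 0L,
                  n_subunits = length(cx$subunits),
                  missing_subunits = paste(missing_sub, collapse = ",")))
  }
  s <- cx$subunits[have]
  per <- copies[have] / s
  tibble(complex = cx$name,
         copies = sum(copies[have]) / sum(s),
         copies_min = min(per), copies_max = max(per),
         n_subunits_quantified = length(have),
         n_subunits = length(cx$subunits),
         missing_subunits = paste(missing_sub, collapse = ","))
}

#' Read a complex-definition library from TSV
#'
#' The TSV must have columns `complex` and `formula` (the
#' [parse_stoichiometry()] grammar). A small library of photosynthetic and
#' housekeeping complexes ships with the package:
#' `system.file("extdata", "complex_library.tsv", package = "cyanogrowth")`.
#'
#' @param path TSV file.
#' @return A named list of `complex_definition` objects.
#' @export
read_complex_library <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  miss <- setdiff(c("complex", "formula"), names(d))
  if (length(miss) > 0) {
    abort(paste("complex library missing columns:", paste(miss, collapse = ", ")))
  }
  defs <- purrr::map2(d$formula, d$complex, parse_stoichiometry)
  setNames(defs, d$complex)
}

#' Per-complex abundance table across conditions
#'
#' Applies [complex_copy_number()] per condition group (using the per-group
#' mean copies of each subunit) and summarizes each complex by its minimum
#' and maximum estimate across conditions.
#'
#' @param copies_tbl Output of [calibrate_absolute()].
#' @param complexes A named list of complex definitions, e.g. from
#'   [read_complex_library()].
#' @return A tibble with one row per complex: `complex`, `copies_min`,
#'   `copies_max` (range of the weighted estimate across condition groups),
#'   `n_subunits_quantified`, `n_subunits`.
#' @export
complex_abundance_table <- function(copies_tbl, complexes) {
  by_group <- copies_tbl |>
    dplyr::group_by(.data$protein_id, .data$group) |>
    dplyr::summarise(copies = mean(.data$copies_per_cell, na.rm = TRUE),
                     .groups = "drop")
  rows <- purrr::map(complexes, function(cx) {
    per_group <- by_group |>
      dplyr::group_by(.data$group) |>
      dplyr::group_map(function(d, key) {
        complex_copy_number(setNames(d$copies, d$protein_id), cx)
      })
    est <- dplyr::bind_rows(per_group)
    est <- est[!is.na(est$copies), ]
    if (nrow(est) == 0) {
      return(tibble(complex = cx$name, copies_min = NA_real_,
                    copies_max = NA_real_, n_subunits_quantified = 0L,
                    n_subunits = length(cx$subunits)))
    }
    tibble(complex = cx$name,
           copies_min = min(est$copies), copies_max = max(est$copies),
           n_subunits_quantified = max(est$n_subunits_quantified),
           n_subunits = length(cx$subunits))
  })
  dplyr::bind_rows(rows)
}
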