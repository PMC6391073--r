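# tie-corrected Kruskal-Wallis statistic for two groups
kw_statistic <- function(x, y) {
  v <- c(x, y)
  n <- length(v)
  r <- rank(v)
  ties <- table(r)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction <= 0) return(0)          # everything tied
  rb <- c(mean(r[seq_along(x)]), mean(r[length(x) + seq_along(y)]))
  h <- 12 / (n * (n + 1)) *
    sum(c(length(x), length(y)) * (rb - (n + 1) / 2)^2)
  h / correction
}

#' Two-sample Kruskal-Wallis p-value
#'
#' The pairwise building block of the growth-dependence classification: a
#' rank-based comparison of two condition groups. The default p-value is the
#' usual chi-squared approximation (as in [stats::kruskal.test()]); with
#' `exact = TRUE` the full permutation distribution of the tie-corrected
#' statistic is enumerated (all assignments of the pooled values to the two
#' groups), which is feasible for the small group sizes of replicated
#' proteomics designs.
#'
#' @param x,y Numeric vectors of intensities for the two groups.
#' @param exact Enumerate the exact permutation distribution instead of the
#'   chi-squared approximation.
#' @return A p-value in (0, 1].
#' @export
pairwise_kw_p <- function(x, y, exact = FALSE) {
  if (length(x) < 1 || length(y) < 1) abort("both groups must be non-empty")
  v <- c(x, y)
  if (length(unique(v)) == 1) return(1)   # degenerate: all values tied
  if (!exact) {
    g <- factor(rep(1:2, c(length(x), length(y))))
    return(unname(kruskal.test(v, g)$p.value))
  }
  h_obs <- kw_statistic(x, y)
  idx <- utils::combn(length(v), length(x))
  h_all <- apply(idx, 2, function(i) kw_statistic(v[i], v[-i]))
  mean(h_all >= h_obs - 1e-12)
}

#' Classify proteins as growth-dependent or growth-independent
#'
#' For every protein, compares each pair of condition groups with a
#' two-sample Kruskal-Wallis test, using only groups with at least
#' `min_samples` non-missing intensities. A protein is called
#' growth-dependent if any pairwise p-value falls below `alpha`. No
#' multiple-testing correction is applied by default (matching the original
#' analysis); `p_adjust = "BH"` applies a Benjamini-Hochberg correction
#' across all pairs of all proteins before thresholding. The test is
#' rank-based, so the classification is invariant under strictly monotone
#' transformations of the intensities (log2 scaling upstream does not change
#' the calls).
#'
#' @param im An [intensity_matrix()] (normally after
#'   [filter_protein_groups()]).
#' @param alpha Significance level for the pairwise tests (default 0.05).
#' @param min_samples Minimum non-missing replicates per group for a group
#'   to enter the pairwise comparisons (default 3).
#' @param exact Use exact permutation p-values (see [pairwise_kw_p()]).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A tibble with columns `protein_id`, `dependent` (logical, `NA`
#'   when fewer than two groups are testable), `min_pair_p`,
#'   `n_pairs_tested` and `status`. Counts of dependent, independent and
#'   untestable proteins are attached as attribute `"counts"`.
#' @export
classify_growth_dependence <- function(im, alpha = 0.05, min_samples = 3,
                                       exact = FALSE,
                                       p_adjust = c("none", "BH")) {
  stopifnot(inherits(im, "intensity_matrix"))
  p_adjust <- match.arg(p_adjust)
  groups <- im_group_cols(im)
  res <- purrr::map(seq_len(nrow(im$proteins)), function(i) {
    vals <- purrr::map(groups, function(cols) {
      v <- im$lfq[i, cols]
      v[!is.na(v)]
    })
    vals <- vals[vapply(vals, length, integer(1)) >= min_samples]
    if (length(vals) < 2) {
      return(tibble(protein_id = im$proteins$protein_id[i],
                    min_pair_p = NA_real_, n_pairs_tested = 0L,
                    pvals = list(numeric(0))))
    }
    pairs <- utils::combn(length(vals), 2)
    pv <- apply(pairs, 2, function(jk) {
      pairwise_kw_p(vals[[jk[1]]], vals[[jk[2]]], exact = exact)
    })
    tibble(protein_id = im$proteins$protein_id[i],
           min_pair_p = min(pv), n_pairs_tested = ncol(pairs),
           pvals = list(pv))
  })
  calls <- dplyr::bind_rows(res)
  if (p_adjust == "BH") {
    all_p <- unlist(calls$pvals)
    adj <- stats::p.adjust(all_p, method = "BH")
    lens <- vapply(calls$pvals, length, integer(1))
    idx <- rep(seq_len(nrow(calls)), lens)
    calls$min_pair_p <- vapply(seq_len(nrow(calls)), function(i) {
      v <- adj[idx == i]
      if (length(v) == 0) NA_real_ else min(v)
    }, numeric(1))
  }
  calls$dependent <- ifelse(calls$n_pairs_tested == 0, NA,
                            calls$min_pair_p < alpha)
  calls$status <- ifelse(calls$n_pairs_tested == 0, "untestable", "tested")
  calls$pvals <- NULL
  calls <- calls[, c("protein_id", "dependent", "min_pair_p",
                     "n_pairs_tested", "status")]
  attr(calls, "counts") <- c(
    dependent = sum(calls$dependent, na.rm = TRUE),
    independent = sum(!calls$dependent, na.rm = TRUE),
    untestable = sum(is.na(calls$dependent))
  )
  calls
}

#' Normalized per-group abundance profiles
#'
#' For each protein, the profile is the per-group median across replicates
#' of the LFQ intensities, divided by the mean of the profile -- the
#' normalization used for cluster analysis, making profiles comparable
#' across proteins of different absolute abundance.
#'
#' @param im An [intensity_matrix()].
#' @return A proteins x groups matrix; proteins whose profile cannot be
#'   completed (a group with all values missing, or a zero mean) are dropped
#'   with a warning and recorded in attribute `"dropped"`.
#' @export
abundance_profiles <- function(im) {
  groups <- im_group_cols(im)
  prof <- vapply(groups, function(cols) {
    apply(im$lfq[, cols, drop = FALSE], 1, median, na.rm = TRUE)
  }, numeric(nrow(im$proteins)))
  prof <- matrix(prof, nrow = nrow(im$proteins),
                 dimnames = list(im$proteins$protein_id, names(groups)))
  means <- rowMeans(prof)
  ok <- complete.cases(prof) & is.finite(means) & means > 0
  if (any(!ok)) {
    warn(sprintf("%d proteins dropped: incomplete or degenerate profiles",
                 sum(!ok)))
  }
  out <- prof[ok, , drop = FALSE] / means[ok]
  attr(out, "dropped") <- rownames(prof)[!ok]
  out
}

# kmeans with the Hartigan-Wong convergence chatter on duplicated profiles
# silenced (a valid partition is still returned; common for noiseless or
# heavily tied profiles)
km_quiet <- function(x, centers, nstart) {
  withCallingHandlers(
    kmeans(x, centers = centers, nstart = nstart, iter.max = 100),
    warning = function(w) {
      if (grepl("did not converge|Quick-TRANSfer", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# within-cluster sum of squares over a range of k
elbow_wss <- function(profiles, k_max, nstart, seed) {
  k_max <- min(k_max, nrow(unique(as.data.frame(profiles))))
  tot <- sum(scale(profiles, scale = FALSE)^2)
  wss <- vapply(seq_len(k_max), function(k) {
    if (k == 1) return(tot)
    set.seed(seed + k)
    km_quiet(profiles, k, nstart)$tot.withinss
  }, numeric(1))
  tibble(k = seq_len(k_max), wss = wss)
}

# elbow rule: point of diminishing decrease of the WSS curve -- the smallest
# k whose next cluster improves the within-cluster SS by less than
# `min_improvement` (relative). A plain largest-second-difference rule locks
# onto the first dominant split when profiles are hierarchically structured
# (up- vs down-regulated families), underestimating k.
choose_k_elbow <- function(wss_tbl, min_improvement = 0.1) {
  wss <- wss_tbl$wss
  if (wss[1] <= 1e-12) return(1L)
  if (length(wss) < 2) return(1L)
  improvement <- -diff(wss) / head(wss, -1)
  small <- which(improvement < min_improvement)
  k1 <- if (length(small) == 0) length(wss) else small[1]
  # once the WSS hits the numerical floor, further splits are meaningless
  floored <- which(wss <= 1e-9 * wss[1])
  k2 <- if (length(floored) == 0) length(wss) else floored[1]
  as.integer(min(k1, k2))
}

#' Cluster growth-dependent abundance profiles
#'
#' Groups normalized abundance profiles (per-group medians scaled by their
#' mean, see [abundance_profiles()]) by k-means with Euclidean distance and
#' multiple restarts. When `k` is not supplied it is chosen by the elbow
#' method, read as the point of diminishing decrease: the within-cluster sum
#' of squares is computed for k = 1..`k_max` and the smallest k is selected
#' whose next cluster improves it by less than `min_improvement`
#' (relative).
#'
#' @param im An [intensity_matrix()], typically restricted to
#'   growth-dependent proteins.
#' @param k Number of clusters; `NULL` to select by the elbow method.
#' @param k_max Largest k scanned by the elbow method (default 12).
#' @param nstart Number of k-means restarts (default 50).
#' @param min_improvement Elbow threshold: relative WSS improvement below
#'   which adding a cluster no longer pays (default 0.1).
#' @param seed Seed for the k-means initializations (default 42).
#' @return An object of class `cluster_result`: `k`, `assignments`
#'   (tibble `protein_id`, `cluster`), `centroids` (tibble, one row per
#'   cluster and group), `profiles`, `wss` (elbow table) and `k_given`.
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @export
cluster_profiles <- function(im, k = NULL, k_max = 12, nstart = 50, seed = 42,
                             min_improvement = 0.1) {
  profiles <- abundance_profiles(im)
  if (nrow(profiles) < 2) abort("need at least two complete profiles")
  wss_tbl <- elbow_wss(profiles, k_max, nstart, seed)
  k_given <- !is.null(k)
  if (!k_given) k <- choose_k_elbow(wss_tbl, min_improvement)
  if (k > nrow(profiles)) abort("more clusters than proteins")
  if (k == 1) {
    assignment <- rep(1L, nrow(profiles))
    centers <- matrix(colMeans(profiles), nrow = 1,
                      dimnames = list(NULL, colnames(profiles)))
    wss_val <- sum(scale(profiles, scale = FALSE)^2)
  } else {
    set.seed(seed + k)
    km <- km_quiet(profiles, k, nstart)
    assignment <- unname(km$cluster)
    centers <- km$centers
    wss_val <- km$tot.withinss
  }
  centroids <- as_tibble(centers) |>
    dplyr::mutate(cluster = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"cluster", names_to = "group", values_to = "value")
  out <- list(
    k = k,
    assignments = tibble(protein_id = rownames(profiles),
                         cluster = assignment),
    centroids = centroids,
    profiles = profiles,
    wss = wss_tbl,
    tot_withinss = wss_val,
    k_given = k_given,
    dropped = attr(profiles, "dropped")
  )
  structure(out, class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", nrow(x$assignments), "proteins in", x$k,
      if (x$k_given) "clusters (k supplied)\n" else "clusters (elbow)\n")
  print(table(x$assignments$cluster))
  invisible(x)
}

#' @rdname cluster_profiles
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) x$assignments

#' @rdname cluster_profiles
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(k = x$k, n_proteins = nrow(x$assignments),
         tot_withinss = x$tot_withinss, k_given = x$k_given)
}

#' Map protein GO annotations to GO-slim categories
#'
#' Each protein is mapped to the union of the slim categories of its GO
#' terms (set semantics: a slim category is counted once per protein, and a
#' protein may carry several categories). Slim categories listed in
#' `trivial` (e.g. "unknown") do not count as annotation; proteins left
#' without a non-trivial category are reported as unannotated.
#'
#' @param annotations Tibble with columns `protein_id`, `go_id`.
#' @param slim_map Tibble with columns `go_id`, `slim`.
#' @param trivial Slim categories treated as non-informative.
#' @return A tibble (`protein_id`, `slim`), one row per distinct pair.
#'   Attributes: `"unmapped_go"` (GO ids without a slim entry, skipped) and
#'   `"unannotated"` (protein ids with no non-trivial category).
#' @export
map_go_slim <- function(annotations, slim_map,
                        trivial = c("unknown", "putative")) {
  stopifnot(all(c("protein_id", "go_id") %in% names(annotations)),
            all(c("go_id", "slim") %in% names(slim_map)))
  unmapped <- setdiff(annotations$go_id, slim_map$go_id)
  mapped <- annotations |>
    dplyr::inner_join(slim_map, by = "go_id",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$protein_id, .data$slim)
  informative <- mapped[!(mapped$slim %in% trivial), ]
  unannotated <- setdiff(unique(annotations$protein_id),
                         unique(informative$protein_id))
  attr(informative, "unmapped_go") <- unmapped
  attr(informative, "unannotated") <- unannotated
  informative
}

#' GO-slim enrichment of growth-dependent proteins
#'
#' For each GO-slim category, builds the 2x2 contingency table of
#' growth-dependent versus growth-independent proteins inside versus outside
#' the category (the universe is every classified protein, annotated or
#' not) and computes a two-sided Fisher's exact p-value. The reported odds
#' ratio is the sample cross-product ratio `(a*d) / (b*c)`.
#'
#' @param calls Output of [classify_growth_dependence()] (untestable
#'   proteins are excluded from the universe).
#' @param slim_annotations Output of [map_go_slim()]: tibble `protein_id`,
#'   `slim`.
#' @param alpha Significance threshold for the `significant` flag.
#' @return A tibble with one row per category: counts `a` (dependent, in
#'   category), `b` (independent, in category), `c` (dependent, not in
#'   category), `d` (independent, not), `odds_ratio`, `p`, `significant`;
#'   sorted by `p`. Categories without any classified member are omitted and
#'   listed in attribute `"omitted"`.
#' @export
enrich_go_slim <- function(calls, slim_annotations, alpha = 0.05) {
  stopifnot(all(c("protein_id", "dependent") %in% names(calls)),
            all(c("protein_id", "slim") %in% names(slim_annotations)))
  universe <- calls[!is.na(calls$dependent), c("protein_id", "dependent")]
  n_dep <- sum(universe$dependent)
  n_ind <- sum(!universe$dependent)
  ann <- slim_annotations[slim_annotations$protein_id %in% universe$protein_id, ]
  cats <- sort(unique(slim_annotations$slim))
  omitted <- setdiff(cats, unique(ann$slim))
  rows <- purrr::map(setdiff(cats, omitted), function(cat) {
    ids <- unique(ann$protein_id[ann$slim == cat])
    a <- sum(universe$dependent[universe$protein_id %in% ids])
    b <- length(ids) - a
    cc <- n_dep - a
    d <- n_ind - b
    p <- fisher.test(matrix(c(a, b, cc, d), nrow = 2))$p.value
    tibble(term = cat, a = a, b = b, c = cc, d = d,
           odds_ratio = (a * d) / (b * cc), p = p)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(significant = .data$p < alpha) |>
    dplyr::arrange(.data$p)
  attr(out, "omitted") <- omitted
  attr(out, "universe") <- c(dependent = n_dep, independent = n_ind)
  out
}
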