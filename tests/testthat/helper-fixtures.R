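# shared fixtures built in code

default_p <- model_parameters()

# small hand-built intensity matrix: 2 groups x 3 replicates
tiny_matrix <- function(lfq = NULL, ibaq = NULL, groups = c("low", "high"),
                        reps = 3, ids = c("A", "B", "C"), peptides = NULL) {
  samples <- tibble::tibble(
    sample = paste0(rep(groups, each = reps), "_", rep(seq_len(reps),
                                                       length(groups))),
    group = rep(groups, each = reps)
  )
  n <- length(ids)
  if (is.null(lfq)) {
    lfq <- matrix(seq_len(n * nrow(samples)) * 100, nrow = n)
  }
  intensity_matrix(
    tibble::tibble(protein_id = ids,
                   peptides = peptides %||% rep(5L, n),
                   contaminant = FALSE, reverse = FALSE),
    samples, lfq, ibaq
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent hypergeometric two-sided Fisher p: sum the probabilities of all
# tables (with fixed margins) no more likely than the observed one
fisher_p_enum <- function(a, b, c, d) {
  m <- a + c          # dependent total
  n <- b + d          # independent total
  k <- a + b          # category size
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
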