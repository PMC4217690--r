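# Interpolated Markov model (IMM). Blends maximum-likelihood Markov chains
# of orders 0..max_order with context-specific weights, in the style
# familiar from gene finders: a context backed by at least `count_threshold`
# observations trusts its own order fully; a sparser context mixes with the
# next lower order in proportion to a chi-square confidence that its
# next-base distribution genuinely differs from the lower-order one.

#' Train an interpolated Markov model
#'
#' Per-order count tables are obtained by trailing-base marginalisation of
#' a single `(max_order + 1)`-mer count table over the training sequences,
#' making the orders mutually consistent. Interpolation weights per context
#' `c` at order `j`:
#' \itemize{
#'   \item if `count(c) >= count_threshold`, lambda = 1;
#'   \item else lambda = conf * count(c) / count_threshold, where `conf` is
#'     the chi-square confidence (`pchisq(stat, df = 3)`) that the observed
#'     next-base counts differ from the order-(j-1) interpolated
#'     distribution; lambda = 0 when `conf < conf_cutoff`.
#' }
#' The emitted conditional is
#' `lambda * ML_j + (1 - lambda) * conditional_(j-1)(suffix)`.
#'
#' @param seqs character vector of training sequences.
#' @param max_order top chain order (default 5).
#' @param count_threshold context count at which the order is fully trusted
#'   (default 400).
#' @param conf_cutoff minimum chi-square confidence (default 0.5).
#' @param pseudocount additive pseudocount in the per-order ML estimates
#'   (default 0.01; keeps every emitted probability positive).
#' @param strand_policy strand policy for counting (default "both").
#' @return an object of class `imm_model`; shares the `logcond` layout of
#'   [train_markov_chain()] so scoring code is common, and retains the raw
#'   per-order count tables.
#' @export
train_imm <- function(seqs, max_order = 5L, count_threshold = 400,
                      conf_cutoff = 0.5, pseudocount = 0.01,
                      strand_policy = "both") {
  stopifnot(length(seqs) > 0L)
  top <- count_kmers(seqs, max_order + 1L, strand_policy = strand_policy)
  train_imm_from_table(top, max_order = max_order,
                       count_threshold = count_threshold,
                       conf_cutoff = conf_cutoff, pseudocount = pseudocount)
}

#' @rdname train_imm
#' @param table a `kmer_table` with `k = max_order + 1` (alternative entry
#'   point when counts are already available).
#' @export
train_imm_from_table <- function(table, max_order = 5L, count_threshold = 400,
                                 conf_cutoff = 0.5, pseudocount = 0.01) {
  stopifnot(inherits(table, "kmer_table"), table$k == max_order + 1L)
  counts <- lapply(0:max_order, function(j) {
    matrix(marginalize_kmer_table(table, j + 1L), ncol = 4L, byrow = TRUE)
  })
  logcond <- vector("list", max_order + 1L)
  lambdas <- vector("list", max_order + 1L)

  # order 0: ML with pseudocount
  c0 <- counts[[1L]]
  p0 <- (c0 + pseudocount) / sum(c0 + pseudocount)
  if (sum(c0) == 0 && pseudocount == 0) p0 <- matrix(0.25, 1L, 4L)
  cond_prev <- matrix(p0, nrow = 1L)
  logcond[[1L]] <- as.vector(t(log(cond_prev)))
  lambdas[[1L]] <- 1

  for (j in seq_len(max_order)) {
    obs <- counts[[j + 1L]]                   # 4^j x 4
    n <- rowSums(obs)
    ml <- (obs + pseudocount) / (n + 4 * pseudocount)
    zero <- n + 4 * pseudocount == 0
    ml[zero, ] <- 0.25
    suffix <- (0:(nrow(obs) - 1L)) %% 4^(j - 1L)
    lower <- cond_prev[suffix + 1L, , drop = FALSE]
    expd <- lower * n
    stat <- rowSums((obs - expd)^2 / pmax(expd, .Machine$double.eps))
    conf <- stats::pchisq(stat, df = 3)
    lambda <- ifelse(n >= count_threshold, 1,
                     ifelse(conf >= conf_cutoff, conf * n / count_threshold, 0))
    lambda[n == 0] <- 0
    cond <- lambda * ml + (1 - lambda) * lower
    logcond[[j + 1L]] <- as.vector(t(log(cond)))
    lambdas[[j + 1L]] <- lambda
    cond_prev <- cond
  }

  structure(list(order = as.integer(max_order), logcond = logcond,
                 counts = counts, lambda = lambdas,
                 count_threshold = count_threshold,
                 conf_cutoff = conf_cutoff, pseudocount = pseudocount),
            class = "imm_model")
}
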