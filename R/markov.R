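# Fixed-order Markov chain over DNA, trained from a (possibly smoothed)
# k-mer count table with k = order + 1. Lower-order conditionals for the
# first `order` bases of a scored sequence are built by the same rule from
# trailing-base marginalisations of the table, so a sequence of any length
# above `order` has a well-defined likelihood.

#' Train a fixed-order Markov chain from a k-mer count table
#'
#' Conditional probabilities are
#' `P(b | ctx) = (N(ctx.b) + pseudocount) / sum_b' (N(ctx.b') + pseudocount)`
#' at every order 0..`order`, with the order-j table obtained by
#' marginalising the input table over trailing bases. Contexts with zero
#' total count fall back to the uniform distribution when
#' `pseudocount = 0`.
#'
#' @param table a `kmer_table` with `k = order + 1` (typically smoothed, see
#'   [smooth_kmer_counts()]).
#' @param order chain order (default 5).
#' @param pseudocount additive pseudocount per word (default 0.01).
#' @return an object of class `markov_model` with per-order log-conditional
#'   lookup tables.
#' @export
train_markov_chain <- function(table, order = 5L, pseudocount = 0.01) {
  stopifnot(inherits(table, "kmer_table"), table$k == order + 1L,
            pseudocount >= 0)
  if (sum(table$counts) == 0 && pseudocount == 0) {
    stop("all-zero count table with pseudocount 0", call. = FALSE)
  }
  logcond <- vector("list", order + 1L)
  for (j in 0:order) {
    cnt <- marginalize_kmer_table(table, j + 1L) + pseudocount
    mat <- matrix(cnt, ncol = 4L, byrow = TRUE)  # rows = contexts
    tot <- rowSums(mat)
    zero <- tot == 0
    mat[zero, ] <- 1      # unseen context with pseudocount 0: uniform
    tot[zero] <- 4
    p <- mat / tot
    logcond[[j + 1L]] <- as.vector(t(log(p)))  # indexed by (j+1)-mer code+1
  }
  structure(list(order = as.integer(order), logcond = logcond,
                 pseudocount = pseudocount),
            class = "markov_model")
}

#' @keywords internal
conditional_probs <- function(model, j = model$order) {
  # 4^j x 4 matrix of conditional probabilities at order j
  matrix(exp(model$logcond[[j + 1L]]), ncol = 4L, byrow = TRUE,
         dimnames = list(NULL, BASES))
}

# Log-likelihood of an integer-encoded sequence under a model holding
# per-order logcond tables (markov_model or imm_model). Positions whose
# word (context + base) overlaps an N contribute 0; the same positions are
# skipped for every model, keeping log-likelihood ratios comparable.
#' @keywords internal
chain_loglik <- function(model, v) {
  order <- model$order
  L <- length(v)
  if (L == 0L) return(0)
  ll <- 0
  head_n <- min(order, L)
  for (i in seq_len(head_n)) {            # bases scored at order i-1
    code <- kmer_codes(v[1:i], i)
    if (!is.na(code)) ll <- ll + model$logcond[[i]][code + 1L]
  }
  if (L > order) {
    codes <- kmer_codes(v, order + 1L)
    codes <- codes[!is.na(codes)]
    if (length(codes)) {
      ll <- ll + sum(model$logcond[[order + 1L]][codes + 1L])
    }
  }
  ll
}

#' Log-likelihood of a sequence under a trained chain or IMM
#'
#' @param model a `markov_model` or `imm_model`.
#' @param seq a DNA string.
#' @return the log-likelihood (natural log). Positions overlapping N are
#'   skipped.
#' @export
sequence_loglik <- function(model, seq) {
  chain_loglik(model, dna_to_int(seq))
}
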