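# ScorerPair: the user-facing training surface. A scorer pair bundles a
# positive model (trained on the CRM set) and, for the likelihood-ratio
# scorers, a negative model trained on background, under a common window
# score. All three window scores are made strand-invariant by averaging
# the forward and reverse-complement scores (CRMs act in either
# orientation; PAC-rc is strand-invariant by rc-collapsing already).

#' Train a CRM scorer
#'
#' @param kind one of `"mshexmcd"`, `"msimm"`, `"pacrc"`.
#' @param crms character vector of training CRM sequences (and, if desired,
#'   their orthologs -- assembling orthologs is the caller's business).
#' @param background character vector of background sequences.
#' @param k word length for counting (default 6, i.e. order 5 chains).
#' @param smoothing_alpha mismatch-smoothing weight for the msHexMCD
#'   positive/negative chains (default 0.25).
#' @param pseudocount chain pseudocount (default 0.01).
#' @param count_threshold,conf_cutoff IMM interpolation knobs, see
#'   [train_imm()].
#' @param rc_collapsed PAC-rc reverse-complement collapsing (default TRUE).
#' @param scorer_id label carried into score profiles (defaults to `kind`).
#' @return an object of class `crm_scorer`.
#' @export
train_scorer <- function(kind = c("mshexmcd", "msimm", "pacrc"),
                         crms, background,
                         k = 6L, smoothing_alpha = 0.25, pseudocount = 0.01,
                         count_threshold = 400, conf_cutoff = 0.5,
                         rc_collapsed = TRUE, scorer_id = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(crms) > 0L)
  order <- k - 1L
  if (kind == "mshexmcd") {
    stopifnot(length(background) > 0L)
    pos <- train_markov_chain(
      smooth_kmer_counts(count_kmers(crms, k), alpha = smoothing_alpha),
      order = order, pseudocount = pseudocount)
    neg <- train_markov_chain(
      smooth_kmer_counts(count_kmers(background, k), alpha = smoothing_alpha),
      order = order, pseudocount = pseudocount)
  } else if (kind == "msimm") {
    stopifnot(length(background) > 0L)
    pos <- train_imm(crms, max_order = order, count_threshold = count_threshold,
                     conf_cutoff = conf_cutoff, pseudocount = pseudocount)
    neg <- train_imm(background, max_order = order,
                     count_threshold = count_threshold,
                     conf_cutoff = conf_cutoff, pseudocount = pseudocount)
  } else {
    pos <- train_pac(crms, background, k = k, rc_collapsed = rc_collapsed)
    neg <- NULL
  }
  structure(list(kind = kind, positive = pos, negative = neg, k = as.integer(k),
                 scorer_id = if (is.null(scorer_id)) kind else scorer_id),
            class = "crm_scorer")
}

#' Score one window with a trained scorer
#'
#' For the two likelihood-ratio scorers this is the mean over both strands
#' of `log Pr[S | positive] - log Pr[S | negative]`; for PAC-rc it is the
#' mean Poisson-CDF overrepresentation score (already strand-invariant).
#'
#' @param scorer a `crm_scorer`.
#' @param seq DNA string.
#' @return a single numeric score.
#' @export
score_window <- function(scorer, seq) {
  stopifnot(inherits(scorer, "crm_scorer"))
  if (scorer$kind == "pacrc") {
    return(pac_rc_score(scorer$positive, seq))
  }
  v <- dna_to_int(seq)
  vr <- revcomp_int(v)
  fwd <- chain_loglik(scorer$positive, v) - chain_loglik(scorer$negative, v)
  rev <- chain_loglik(scorer$positive, vr) - chain_loglik(scorer$negative, vr)
  (fwd + rev) / 2
}

#' @export
print.crm_scorer <- function(x, ...) {
  cat("<crm_scorer>", x$kind, " k =", x$k, "\n")
  invisible(x)
}
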