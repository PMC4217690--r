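# PAC-rc: Poisson additive word-count overrepresentation score. For every
# word w the training count n_w is compared with a background mean
# lambda_w scaled to the training set's total length ("size-matched"
# emulation by deterministic length-ratio scaling). The score of a window
# S is the mean Poisson CDF F(lambda_w, n_w - 1) over the distinct
# (reverse-complement-collapsed) words of S: a word much more frequent in
# the training CRMs than expected from background pushes the score
# towards 1.

#' Train the Poisson word-count model
#'
#' @param train_c character vector of training CRM sequences (set C).
#' @param background character vector of background sequences.
#' @param k word length (default 6).
#' @param rc_collapsed pool each word with its reverse complement under the
#'   lexicographically smaller key (default TRUE; the "-rc" in the name).
#' @param lambda_floor lower bound on the background mean (default 1e-6).
#' @param strand_policy strand policy for counting (default "forward";
#'   reverse-strand evidence enters through `rc_collapsed`).
#' @return an object of class `pac_model` with per-word `n` (training
#'   counts), `lambda` (scaled background means) and the precomputed
#'   per-word CDF values `F(lambda_w, n_w - 1)`.
#' @export
train_pac <- function(train_c, background, k = 6L, rc_collapsed = TRUE,
                      lambda_floor = 1e-6, strand_policy = "forward") {
  stopifnot(length(train_c) > 0L, length(background) > 0L)
  tab_c <- count_kmers(train_c, k, strand_policy = strand_policy)
  tab_b <- count_kmers(background, k, strand_policy = strand_policy)
  n <- tab_c$counts
  len_c <- sum(nchar(train_c))
  len_b <- sum(nchar(background))
  lambda <- tab_b$counts * (len_c / len_b)

  canon <- seq_along(n) - 1  # identity map, code scale
  if (rc_collapsed) {
    rc <- revcomp_code(0:(4^k - 1), k)
    canon <- pmin(0:(4^k - 1), rc)
    n <- as.vector(rowsum(n, canon))[match(canon, sort(unique(canon)))]
    lambda <- as.vector(rowsum(lambda, canon))[match(canon,
                                                     sort(unique(canon)))]
    # n/lambda now live on all 4^k slots, replicated onto both members of
    # each rc pair for O(1) lookup during scanning
  }
  lambda <- pmax(lambda, lambda_floor)
  fval <- ifelse(n >= 1, stats::ppois(n - 1, lambda), 0)  # F(lambda, -1) = 0
  structure(list(k = as.integer(k), n = n, lambda = lambda, fval = fval,
                 canon = canon, rc_collapsed = rc_collapsed,
                 lambda_floor = lambda_floor),
            class = "pac_model")
}

#' PAC-rc score of a sequence window
#'
#' `W` is the set of distinct (rc-collapsed) k-mers occurring in `S`; the
#' score is `mean over W of F(lambda_w, n_w - 1)` and always lies in
#' `[0, 1]`.
#'
#' @param model a `pac_model`.
#' @param seq DNA string with at least `k` unambiguous bases.
#' @return score in `[0, 1]`.
#' @export
pac_rc_score <- function(model, seq) {
  v <- dna_to_int(seq)
  codes <- kmer_codes(v, model$k)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) {
    stop("no scoreable words in sequence (all N or shorter than k)",
         call. = FALSE)
  }
  keys <- unique(model$canon[codes + 1L])
  mean(model$fval[keys + 1L])
}
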