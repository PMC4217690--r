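# k-mer count tables.
#
# A word of length k over {A,C,G,T} is encoded as an integer code in
# 0..4^k-1 with the FIRST base in the most significant position:
#   code(w) = sum_j (base_j - 1) * 4^(k - j).
# Count tables are dense numeric vectors of length 4^k indexed by code + 1,
# so every word is present (zero-filled) by construction.

#' @keywords internal
kmer_codes <- function(v, k) {
  n <- length(v) - k + 1L
  if (n < 1L) return(numeric(0))
  code <- numeric(n)
  for (j in seq_len(k)) {
    code <- code * 4 + (v[j:(j + n - 1L)] - 1)
  }
  code  # NA wherever the word overlaps an N
}

#' @keywords internal
code_to_word <- function(code, k) {
  out <- character(length(code))
  for (i in seq_along(code)) {
    c0 <- code[i]
    b <- integer(k)
    for (j in k:1) {
      b[j] <- c0 %% 4
      c0 <- c0 %/% 4
    }
    out[i] <- paste(BASES[b + 1L], collapse = "")
  }
  out
}

#' @keywords internal
word_to_code <- function(w) {
  vapply(w, function(x) {
    v <- dna_to_int(x)
    sum((v - 1) * 4^(rev(seq_along(v)) - 1))
  }, 0, USE.NAMES = FALSE)
}

# code of the reverse complement of each code (vectorised)
#' @keywords internal
revcomp_code <- function(code, k) {
  out <- numeric(length(code))
  c0 <- code
  for (j in seq_len(k)) {
    out <- out * 4 + (3 - c0 %% 4)
    c0 <- c0 %/% 4
  }
  out
}

#' Count overlapping k-mers in a set of sequences
#'
#' Words overlapping an N are skipped. With `strand_policy = "both"` the
#' counts of the reverse-complemented sequences are added, so a word and
#' its reverse complement end up with pooled evidence.
#'
#' @param seqs character vector of sequences (a training set or background).
#' @param k word length.
#' @param strand_policy `"forward"` or `"both"`.
#' @return an object of class `kmer_table`: list with elements `k`,
#'   `counts` (numeric vector of length `4^k`), `strand_policy`, `total`.
#' @export
count_kmers <- function(seqs, k, strand_policy = c("both", "forward")) {
  strand_policy <- match.arg(strand_policy)
  stopifnot(k >= 1L)
  counts <- numeric(4^k)
  for (s in seqs) {
    v <- dna_to_int(s)
    code <- kmer_codes(v, k)
    code <- code[!is.na(code)]
    if (length(code)) {
      tab <- tabulate(as.integer(code) + 1L, nbins = 4^k)
      counts <- counts + tab
    }
    if (strand_policy == "both") {
      vr <- revcomp_int(v)
      code <- kmer_codes(vr, k)
      code <- code[!is.na(code)]
      if (length(code)) {
        counts <- counts + tabulate(as.integer(code) + 1L, nbins = 4^k)
      }
    }
  }
  structure(list(k = as.integer(k), counts = counts,
                 strand_policy = strand_policy, total = sum(counts)),
            class = "kmer_table")
}

#' Mismatch-neighbour smoothing of k-mer counts
#'
#' Each word's smoothed count is its raw count plus `alpha` times the summed
#' counts of its `3k` single-mismatch neighbours:
#' \deqn{\tilde N_w = N_w + \alpha \sum_{w'} N_{w'}.}
#' With the default `alpha = 0.25` and hexamers this is the smoothing used
#' to stabilise sparse 6-mer counts before Markov-chain training.
#'
#' @param table a `kmer_table`.
#' @param alpha smoothing weight per mismatch neighbour (default 0.25).
#' @return a `kmer_table` with fractional smoothed counts.
#' @export
smooth_kmer_counts <- function(table, alpha = 0.25) {
  stopifnot(inherits(table, "kmer_table"))
  k <- table$k
  N <- table$counts
  nw <- length(N)
  all_codes <- 0:(nw - 1L)
  acc <- numeric(nw)
  # For each position p, sum counts over the 4 variants at that position.
  for (p in seq_len(k)) {
    stride <- 4^(k - p)
    key <- (all_codes %/% (4 * stride)) * stride + all_codes %% stride
    tot <- rowsum(N, key)        # ordered by sorted unique key = 0..4^(k-1)-1
    acc <- acc + tot[key + 1L]
  }
  # acc includes the word itself once per position; neighbours = acc - k*N
  sm <- N + alpha * (acc - k * N)
  structure(list(k = k, counts = sm, strand_policy = table$strand_policy,
                 total = sum(sm)),
            class = "kmer_table")
}

# Marginalise a k-mer table to word length m <= k by summing over the
# trailing k-m bases. Keeps context/extension counts mutually consistent
# across orders.
#' @keywords internal
marginalize_kmer_table <- function(table, m) {
  stopifnot(m >= 1L, m <= table$k)
  if (m == table$k) return(table$counts)
  div <- 4^(table$k - m)
  key <- (0:(length(table$counts) - 1L)) %/% div
  as.vector(rowsum(table$counts, key))
}
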