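# Naive reference implementations, deliberately written with string keys
# and scalar loops, independent of the package's integer-coded fast
# paths. They are the oracles the fast implementations are tested
# against.

ALL_BASES <- c("A", "C", "G", "T")

naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

all_words <- function(k) {
  w <- ""
  for (i in seq_len(k)) {
    w <- as.vector(outer(w, ALL_BASES, paste0))
  }
  sort(w)
}

# overlapping word counts with N-masking, named-vector table
naive_count_kmers <- function(seqs, k, both_strands = TRUE) {
  tab <- stats::setNames(numeric(4^k), all_words(k))
  add <- function(s) {
    for (i in seq_len(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (!grepl("N", w, fixed = TRUE)) tab[w] <<- tab[w] + 1
    }
  }
  for (s in seqs) {
    add(s)
    if (both_strands) add(naive_revcomp(s))
  }
  tab
}

# one-mismatch neighbour smoothing by explicit neighbour enumeration
naive_smooth <- function(tab, alpha = 0.25) {
  words <- names(tab)
  k <- nchar(words[1])
  out <- tab
  for (w in words) {
    s <- 0
    for (p in seq_len(k)) {
      for (b in ALL_BASES) {
        if (b != substr(w, p, p)) {
          nb <- w
          substr(nb, p, p) <- b
          s <- s + tab[[nb]]
        }
      }
    }
    out[[w]] <- tab[[w]] + alpha * s
  }
  out
}

# marginalise a word table to length m by summing over trailing bases
naive_marginalize <- function(tab, m) {
  words <- names(tab)
  out <- stats::setNames(numeric(4^m), all_words(m))
  for (w in words) {
    out[substr(w, 1, m)] <- out[substr(w, 1, m)] + tab[[w]]
  }
  out
}

# conditional P(b | ctx) from a (|ctx|+1)-mer table with pseudocount
naive_conditional <- function(tab, ctx, b, pc) {
  tot <- 0
  for (bb in ALL_BASES) tot <- tot + tab[[paste0(ctx, bb)]] + pc
  if (tot == 0) return(0.25)
  (tab[[paste0(ctx, b)]] + pc) / tot
}

# a reusable naive chain scorer: marginalised tables computed once
naive_chain_scorer <- function(tab6, order = 5, pc = 0.01) {
  tabs <- lapply(1:(order + 1), function(m) naive_marginalize(tab6, m))
  function(s) {
    ll <- 0
    for (i in seq_len(nchar(s))) {
      j <- min(i - 1, order)
      word <- substr(s, i - j, i)
      if (grepl("N", word, fixed = TRUE)) next
      ctx <- substr(word, 1, j)
      b <- substr(word, j + 1, j + 1)
      ll <- ll + log(naive_conditional(tabs[[j + 1]], ctx, b, pc))
    }
    ll
  }
}

naive_mshexmcd_scorer <- function(tab6_pos_sm, tab6_neg_sm, order = 5,
                                  pc = 0.01) {
  pos <- naive_chain_scorer(tab6_pos_sm, order, pc)
  neg <- naive_chain_scorer(tab6_neg_sm, order, pc)
  function(s) {
    one <- function(x) pos(x) - neg(x)
    (one(s) + one(naive_revcomp(s))) / 2
  }
}

# a reusable naive IMM scorer with a per-context memo of the recursive
# interpolated conditional
naive_imm_scorer_one <- function(tab6, order = 5, pc = 0.01, thr = 400,
                                 cut = 0.5) {
  tabs <- lapply(1:(order + 1), function(m) naive_marginalize(tab6, m))
  memo <- new.env(parent = emptyenv())
  cond <- function(ctx) {
    key <- paste0(".", ctx)
    if (!is.null(memo[[key]])) return(memo[[key]])
    j <- nchar(ctx)
    obs <- vapply(ALL_BASES, function(b) tabs[[j + 1]][[paste0(ctx, b)]],
                  0)
    out <- if (j == 0) {
      tot <- sum(obs) + 4 * pc
      if (tot == 0) stats::setNames(rep(0.25, 4), ALL_BASES)
      else stats::setNames((obs + pc) / tot, ALL_BASES)
    } else {
      lower <- cond(substr(ctx, 2, j))
      n <- sum(obs)
      ml <- (obs + pc) / (n + 4 * pc)
      if (n + 4 * pc == 0) ml <- rep(0.25, 4)
      if (n >= thr) {
        lambda <- 1
      } else if (n == 0) {
        lambda <- 0
      } else {
        expd <- lower * n
        stat <- sum((obs - expd)^2 / pmax(expd, .Machine$double.eps))
        conf <- stats::pchisq(stat, df = 3)
        lambda <- if (conf >= cut) conf * n / thr else 0
      }
      stats::setNames(lambda * ml + (1 - lambda) * lower, ALL_BASES)
    }
    memo[[key]] <- out
    out
  }
  function(s) {
    ll <- 0
    for (i in seq_len(nchar(s))) {
      j <- min(i - 1, order)
      word <- substr(s, i - j, i)
      if (grepl("N", word, fixed = TRUE)) next
      ll <- ll + log(cond(substr(word, 1, j))[[substr(word, j + 1,
                                                      j + 1)]])
    }
    ll
  }
}

naive_msimm_scorer <- function(tab6_pos, tab6_neg, order = 5, pc = 0.01,
                               thr = 400, cut = 0.5) {
  pos <- naive_imm_scorer_one(tab6_pos, order, pc, thr, cut)
  neg <- naive_imm_scorer_one(tab6_neg, order, pc, thr, cut)
  function(s) {
    one <- function(x) pos(x) - neg(x)
    (one(s) + one(naive_revcomp(s))) / 2
  }
}

naive_pacrc_scorer <- function(train_c, background, k = 6,
                               lambda_floor = 1e-6) {
  nc <- naive_count_kmers(train_c, k, both_strands = FALSE)
  nb <- naive_count_kmers(background, k, both_strands = FALSE)
  ratio <- sum(nchar(train_c)) / sum(nchar(background))
  canon <- function(w) min(w, naive_revcomp(w))
  function(s) {
    # distinct words of the window, pooled under canonical keys
    words <- character(0)
    for (i in seq_len(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (!grepl("N", w, fixed = TRUE)) words <- c(words, canon(w))
    }
    words <- unique(words)
    vals <- vapply(words, function(w) {
      wr <- naive_revcomp(w)
      n_w <- nc[[w]] + (if (wr != w) nc[[wr]] else 0)
      l_w <- max((nb[[w]] + (if (wr != w) nb[[wr]] else 0)) * ratio,
                 lambda_floor)
      if (n_w < 1) 0 else stats::ppois(n_w - 1, l_w)
    }, 0)
    mean(vals)
  }
}

# exhaustive hypergeometric upper tail by enumerating all draws
naive_hypergeom_tail <- function(n, P, G, U) {
  draws <- utils::combn(U, P)
  succ <- colSums(draws <= G)  # first G elements are the successes
  mean(succ >= n)
}

random_dna <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(ALL_BASES, n, replace = TRUE, prob = freqs), collapse = "")
}
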