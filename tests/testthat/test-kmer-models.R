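test_that("k-mer counting matches hand counts and masks N", {
  tb <- count_kmers("ACGTAC", 2, "forward")
  get <- function(tb, w) tb$counts[word_to_code(w) + 1]
  expect_equal(get(tb, c("AC", "CG", "GT", "TA")), c(2, 1, 1, 1))
  expect_equal(tb$total, 5)

  tbn <- count_kmers("ACNGT", 2, "forward")
  expect_equal(get(tbn, c("AC", "GT")), c(1, 1))
  expect_equal(tbn$total, 2)

  tb2 <- count_kmers("ACGTAC", 2, "both")  # adds counts of "GTACGT"
  expect_equal(get(tb2, c("AC", "CG", "GT", "TA")), c(3, 2, 3, 2))
})

test_that("k-mer counting agrees with the naive string-based counter", {
  set.seed(21)
  for (rep in 1:5) {
    seqs <- vapply(1:3, function(i) random_dna(sample(20:60, 1)), "")
    for (k in c(2, 3)) {
      tb <- count_kmers(seqs, k, "both")
      naive <- naive_count_kmers(seqs, k, both_strands = TRUE)
      expect_equal(unname(tb$counts[word_to_code(names(naive)) + 1]),
                   unname(naive))
    }
  }
})

test_that("mismatch smoothing follows the 0.25-weighted neighbour rule", {
  # one word with count 4, every neighbour zero: smoothed count unchanged
  tb0 <- structure(list(k = 6L, counts = numeric(4^6),
                        strand_policy = "forward", total = 0),
                   class = "kmer_table")
  tb <- tb0
  tb$counts[word_to_code("AAAAAA") + 1] <- 4
  sm <- smooth_kmer_counts(tb)
  expect_equal(sm$counts[word_to_code("AAAAAA") + 1], 4)

  # a zero-count word with one neighbour at 8 smooths to 0.25 * 8 = 2
  tb0$counts[word_to_code("CAAAAA") + 1] <- 8
  sm0 <- smooth_kmer_counts(tb0)
  expect_equal(sm0$counts[word_to_code("AAAAAA") + 1], 2)

  # uniform table: every smoothed count is c * (1 + 0.25 * 18) = 5.5c
  tbu <- tb0
  tbu$counts <- rep(3, 4^6)
  smu <- smooth_kmer_counts(tbu)
  expect_equal(unique(smu$counts), 3 * 5.5)
})

test_that("smoothing agrees with explicit neighbour enumeration", {
  set.seed(22)
  seqs <- vapply(1:3, function(i) random_dna(40), "")
  for (k in 2:3) {
    tb <- count_kmers(seqs, k, "forward")
    sm <- smooth_kmer_counts(tb)
    naive <- naive_smooth(naive_count_kmers(seqs, k, both_strands = FALSE))
    expect_equal(unname(sm$counts[word_to_code(names(naive)) + 1]),
                 unname(naive))
  }
})

test_that("Markov conditionals normalise and reproduce hand examples", {
  # context AAAAA with counts A:3, C/G/T:1 each, pseudocount 0
  tb <- structure(list(k = 6L, counts = numeric(4^6),
                       strand_policy = "forward", total = 6),
                  class = "kmer_table")
  tb$counts[word_to_code(c("AAAAAA", "AAAAAC", "AAAAAG", "AAAAAT")) + 1] <-
    c(3, 1, 1, 1)
  m <- train_markov_chain(tb, order = 5, pseudocount = 0)
  cond <- conditional_probs(m)
  expect_equal(unname(cond[word_to_code("AAAAA") + 1, "A"]), 0.5)

  # unseen context with pseudocount > 0: uniform
  m2 <- train_markov_chain(tb, order = 5, pseudocount = 0.01)
  cond2 <- conditional_probs(m2)
  expect_equal(unname(cond2[word_to_code("CCCCC") + 1, ]), rep(0.25, 4))

  expect_error(train_markov_chain(
    structure(list(k = 3L, counts = numeric(64), strand_policy = "forward",
                   total = 0), class = "kmer_table"),
    order = 2, pseudocount = 0), "all-zero")
})

test_that("conditional distributions sum to 1 for random tables", {
  set.seed(23)
  for (rep in 1:20) {
    counts <- rpois(4^3, lambda = sample(c(0.2, 2, 20), 1))
    tb <- structure(list(k = 3L, counts = as.numeric(counts),
                         strand_policy = "forward", total = sum(counts)),
                    class = "kmer_table")
    m <- train_markov_chain(tb, order = 2, pseudocount = 0.01)
    for (j in 0:2) {
      expect_equal(unname(rowSums(conditional_probs(m, j))),
                   rep(1, 4^j), tolerance = 1e-9)
    }
    imm <- train_imm_from_table(tb, max_order = 2)
    for (j in 0:2) {
      cond <- matrix(exp(imm$logcond[[j + 1]]), ncol = 4, byrow = TRUE)
      expect_equal(unname(rowSums(cond)), rep(1, 4^j), tolerance = 1e-9)
    }
  }
})

test_that("likelihood-ratio scorers are zero when both models coincide", {
  set.seed(24)
  seqs <- vapply(1:5, function(i) random_dna(100), "")
  for (kind in c("mshexmcd", "msimm")) {
    sc <- train_scorer(kind, seqs, seqs)
    for (i in 1:5) {
      expect_equal(score_window(sc, random_dna(60)), 0, tolerance = 1e-12)
    }
  }
})

test_that("order-0 chain pair yields the closed-form LLR", {
  # P+(A) = 0.4 vs P-(A) = 0.25, S = "A" x 20: LLR = 20 * ln(0.4 / 0.25)
  mk_tab <- function(freqs, n = 1000) {
    structure(list(k = 1L, counts = freqs * n, strand_policy = "forward",
                   total = n), class = "kmer_table")
  }
  pos <- train_markov_chain(mk_tab(c(0.4, 0.2, 0.2, 0.2)), order = 0,
                            pseudocount = 0)
  neg <- train_markov_chain(mk_tab(rep(0.25, 4)), order = 0,
                            pseudocount = 0)
  s <- strrep("A", 20)
  llr <- sequence_loglik(pos, s) - sequence_loglik(neg, s)
  expect_equal(llr, 20 * log(0.4 / 0.25), tolerance = 1e-12)
})

test_that("chain scoring equals a brute-force chain-rule product", {
  set.seed(25)
  seqs <- vapply(1:4, function(i) random_dna(80), "")
  tb <- smooth_kmer_counts(count_kmers(seqs, 6, "both"))
  m <- train_markov_chain(tb, order = 5, pseudocount = 0.01)
  for (rep in 1:10) {
    s <- random_dna(8)
    # naive: product of conditionals looked up in the model's tables
    ll <- 0
    for (i in 1:8) {
      j <- min(i - 1, 5)
      cond <- conditional_probs(m, j)
      ctx_code <- if (j == 0) 0 else word_to_code(substr(s, i - j, i - 1))
      b <- match(substr(s, i, i), c("A", "C", "G", "T"))
      ll <- ll + log(unname(cond[ctx_code + 1, b]))
    }
    expect_equal(sequence_loglik(m, s), ll, tolerance = 1e-9)
  }
})

test_that("IMM reduces to the fixed-order ML chain under saturation", {
  set.seed(26)
  # enough data that every order-5 context occurs >= 400 times
  seqs <- vapply(1:10, function(i) random_dna(200000), "")
  tb <- count_kmers(seqs, 6, "both")
  expect_gte(min(rowsum(tb$counts,
                        rep(0:(4^5 - 1), each = 4))), 400)
  imm <- train_imm_from_table(tb, max_order = 5)
  mc <- train_markov_chain(tb, order = 5, pseudocount = 0.01)
  for (i in 1:10) {
    s <- random_dna(60)
    expect_equal(sequence_loglik(imm, s), sequence_loglik(mc, s),
                 tolerance = 1e-9)
  }
})

test_that("IMM trained on a single 6-bp sequence falls back gracefully", {
  imm <- train_imm("ACGTAC", max_order = 5)
  expect_true(is.finite(sequence_loglik(imm, "TTTTGGGG")))
})

test_that("msIMM score grows with a word's training frequency", {
  set.seed(27)
  bg <- vapply(1:10, function(i) random_dna(700), "")
  word <- "ACGGTA"
  scores <- vapply(c(0, 5, 20), function(n_extra) {
    crms <- vapply(1:10, function(i) {
      s <- random_dna(700)
      if (n_extra > 0) {
        pos <- seq(1, by = 30, length.out = n_extra)
        for (p in pos) substr(s, p, p + 5) <- word
      }
      s
    }, "")
    sc <- train_scorer("msimm", crms, bg)
    score_window(sc, strrep(word, 8))
  }, 0)
  expect_true(all(diff(scores) > 0))
})

test_that("PAC-rc training applies length scaling, floor and rc pooling", {
  # background twice the length of C: counts scale by 1/2
  set.seed(28)
  train_c <- "ACGGTAACGGTAACGGTAACGGTA"           # 24 bp
  background <- paste(rep("ACGGTA", 8), collapse = "")  # 48 bp
  m <- train_pac(train_c, background, k = 6, rc_collapsed = FALSE)
  code <- word_to_code("ACGGTA") + 1
  expect_equal(m$lambda[code], sum(count_kmers(background, 6,
                                               "forward")$counts[code]) / 2)

  # absent word floors at 1e-6
  expect_equal(min(m$lambda), 1e-6)

  # rc collapsing pools AAAAAA with TTTTTT
  m2 <- train_pac("AAAAAAAA", "TTTTTTTTAAAAAAAA", k = 6)
  ca <- word_to_code("AAAAAA") + 1
  ct <- word_to_code("TTTTTT") + 1
  expect_equal(m2$canon[ct], m2$canon[ca])
  expect_equal(m2$n[ca], 3)  # 3 occurrences of AAAAAA in the training seq
})

test_that("PAC-rc score reproduces closed forms and stays in [0, 1]", {
  # single distinct word with n_w = 1, lambda_w = 1: F(1, 0) = exp(-1)
  m <- structure(list(k = 6L, n = rep(0, 4^6), lambda = rep(1e-6, 4^6),
                      fval = rep(0, 4^6), canon = 0:(4^6 - 1),
                      rc_collapsed = FALSE, lambda_floor = 1e-6),
                 class = "pac_model")
  code <- word_to_code("AAAAAA") + 1
  m$n[code] <- 1
  m$lambda[code] <- 1
  m$fval[code] <- stats::ppois(0, 1)
  expect_equal(pac_rc_score(m, "AAAAAA"), exp(-1), tolerance = 1e-12)

  # words with n_w = 0 contribute 0
  expect_equal(pac_rc_score(m, "CCCCCC"), 0)

  # the mean of two distinct words' F values
  m$n[word_to_code("CCCCCC") + 1] <- 5
  m$fval[word_to_code("CCCCCC") + 1] <- 0.5
  m$fval[code] <- 0.9
  expect_equal(pac_rc_score(m, "AAAAAACCCCCC"),
               mean(c(0.9, 0.5, 0, 0, 0, 0, 0)), tolerance = 1e-12)

  expect_error(pac_rc_score(m, "NNNNNNNN"), "no scoreable words")

  set.seed(29)
  crms <- vapply(1:5, function(i) random_dna(200), "")
  bg <- vapply(1:5, function(i) random_dna(400), "")
  sc <- train_scorer("pacrc", crms, bg)
  for (i in 1:10) {
    s <- score_window(sc, random_dna(50))
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})
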