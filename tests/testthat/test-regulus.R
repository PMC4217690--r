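# small random HMM factory for property checks
random_hmm <- function(n_motifs = 1L, phi = 5, dominance = 0.9) {
  pwms <- synthetic_pwms(n_motifs, dominance = dominance)
  dens <- stats::runif(n_motifs, 5e-4, 5e-3)
  build_regulus_hmm(pwms, dens, bg_freqs = rep(0.25, 4), phi = phi)
}

test_that("transition scaling follows the k x 0.001 rule", {
  pwms <- synthetic_pwms(3)
  hmm <- build_regulus_hmm(pwms, c(0.002, 0.001, 0.0006),
                           bg_freqs = rep(0.25, 4))
  expect_equal(unname(hmm$trans), c(0.0016667, 0.0008333, 0.0005),
               tolerance = 1e-4)
  expect_equal(sum(hmm$trans), 3 * 0.001, tolerance = 1e-12)
  expect_equal(mean(hmm$trans), 0.001, tolerance = 1e-12)
  expect_equal(hmm$bg_trans + sum(hmm$trans), 1, tolerance = 1e-12)

  # a single motif always gets exactly the target mean
  h1 <- build_regulus_hmm(pwms[1], 0.037, bg_freqs = rep(0.25, 4))
  expect_equal(unname(h1$trans), 0.001)

  expect_error(build_regulus_hmm(pwms, c(1, 1, 1), bg_freqs = rep(0.25, 4),
                                 target_mean = 0.4), "sum to >= 1")
})

test_that("forward likelihood matches closed forms and enumeration", {
  # zero motifs, uniform background: plain chain rule
  h0 <- build_regulus_hmm(list(), bg_freqs = rep(0.25, 4))
  expect_equal(forward_loglik(h0, "AC"), log(0.25^2), tolerance = 1e-12)

  # motif longer than the sequence: background-only chain rule
  h1 <- random_hmm(1)
  expect_equal(forward_loglik(h1, "ACGT"),
               4 * log(0.25) + 4 * log(h1$bg_trans), tolerance = 1e-12)

  # brute-force path enumeration on short sequences
  set.seed(51)
  for (rep in 1:10) {
    nm <- sample(1:2, 1)
    hmm <- random_hmm(nm)
    x <- random_dna(sample(9:12, 1))
    pp <- crmscout:::.regulus_prep(hmm, crmscout:::dna_to_int(x))
    # enumerate segmentations: background base or whole site at each step
    total <- local({
      rec <- function(i) {
        if (i > nchar(x)) return(1)
        acc <- hmm$bg_trans * 0.25 * rec(i + 1)
        for (m in seq_len(nm)) {
          km <- pp$kk[m]
          if (i + km - 1 <= nchar(x)) {
            acc <- acc + hmm$trans[m] * exp(pp$se[[m]][i]) * rec(i + km)
          }
        }
        acc
      }
      rec(1)
    })
    expect_equal(forward_loglik(hmm, x), log(unname(total)),
                 tolerance = 1e-9)
  }
})

test_that("count distributions marginalise to the forward likelihood", {
  set.seed(52)
  for (rep in 1:10) {
    hmm <- random_hmm(sample(1:3, 1))
    x <- random_dna(sample(15:50, 1))
    for (m in names(hmm$pwms)) {
      g <- motif_count_distribution(hmm, x, m, cap = 6, mode = "emission")
      expect_equal(g$logtotal, forward_loglik(hmm, x), tolerance = 1e-9)
      expect_equal(sum(g$prob), 1, tolerance = 1e-9)
    }
  }

  # a sequence shorter than the motif puts all mass on zero sites
  hmm <- random_hmm(1)
  g <- motif_count_distribution(hmm, "ACGT", "synthM1", cap = 4)
  expect_equal(g$prob[1], 1)
  expect_equal(g$prob[-1], rep(0, 4))
})

test_that("phi = 1 collapses the homology model onto the null", {
  set.seed(53)
  for (rep in 1:50) {
    hmm <- random_hmm(sample(1:4, 1), phi = 1)
    x <- random_dna(sample(10:40, 1))
    y <- random_dna(sample(10:40, 1))
    expect_equal(regulus_score(hmm, x, y)$llr, 0, tolerance = 1e-10)
  }
  hmm <- random_hmm(1, phi = 1)
  expect_equal(regulus_brute_force(hmm, "ACGTACGTAC", "TTGACGCATT"), 0,
               tolerance = 1e-12)
})

test_that("the score is exactly symmetric in its two sequences", {
  set.seed(54)
  for (rep in 1:20) {
    hmm <- random_hmm(sample(1:4, 1))
    x <- random_dna(sample(10:30, 1))
    y <- random_dna(sample(10:30, 1))
    expect_identical(regulus_score(hmm, x, y)$llr,
                     regulus_score(hmm, y, x)$llr)
  }
})

test_that("single-motif scoring equals brute-force enumeration", {
  set.seed(55)
  for (rep in 1:30) {
    hmm <- random_hmm(1, phi = sample(c(2, 5, 10), 1))
    x <- random_dna(sample(8:12, 1))
    y <- random_dna(sample(8:12, 1))
    bf <- regulus_brute_force(hmm, x, y)
    expect_lt(abs(regulus_score(hmm, x, y, mode = "factorized")$llr - bf),
              1e-9)
    expect_lt(abs(regulus_score(hmm, x, y, mode = "exact")$llr - bf),
              1e-9)
  }
})

test_that("exact and brute-force modes agree with two motifs", {
  set.seed(56)
  for (rep in 1:15) {
    hmm <- random_hmm(2, phi = 5)
    x <- random_dna(sample(8:12, 1))
    y <- random_dna(sample(8:12, 1))
    expect_lt(abs(regulus_score(hmm, x, y, mode = "exact")$llr -
                    regulus_brute_force(hmm, x, y)), 1e-9)
  }
})

test_that("factorized llr is the sum of per-motif contributions", {
  set.seed(57)
  hmm <- random_hmm(4)
  x <- random_dna(60)
  y <- random_dna(70)
  sc <- regulus_score(hmm, x, y, mode = "factorized")
  expect_equal(sc$llr, sum(sc$per_motif))
  expect_equal(sc$mode, "factorized")
})

test_that("shared planted sites raise the score", {
  set.seed(58)
  pwms <- synthetic_pwms(1)
  hmm <- build_regulus_hmm(pwms, 0.002, bg_freqs = rep(0.25, 4), phi = 5)
  wins <- 0
  for (rep in 1:20) {
    x <- implant_sites(random_dna(150), pwms, 3)$seq
    y_sites <- implant_sites(random_dna(150), pwms, 3)$seq
    y_empty <- random_dna(150)
    s_shared <- regulus_score(hmm, x, y_sites)$llr
    s_empty <- regulus_score(hmm, x, y_empty)$llr
    wins <- wins + (s_shared > s_empty)
  }
  expect_gte(wins, 18)
})

test_that("Baum-Welch density estimation recovers planted densities", {
  set.seed(59)
  pwm <- synthetic_pwms(1)[[1]]
  # 2 sites in 500 bp ~ density 0.004 per transition
  dens <- vapply(1:10, function(i) {
    seqs <- replicate(3, implant_sites(random_dna(500), list(m = pwm),
                                       2)$seq)
    as.numeric(estimate_motif_density(seqs, pwm))
  }, 0)
  target <- 2 / (500 - 2 * 8 + 2)
  expect_gt(mean(dens), target / 2)
  expect_lt(mean(dens), target * 2)

  # log-likelihood is non-decreasing across EM iterations
  seqs <- replicate(3, implant_sites(random_dna(400), list(m = pwm),
                                     2)$seq)
  d <- estimate_motif_density(seqs, pwm)
  ll <- attr(d, "loglik")
  expect_true(all(diff(ll) > -1e-8))

  # site-free sequences fit a negligible density
  set.seed(60)
  d0 <- estimate_motif_density(replicate(3, random_dna(500)), pwm)
  expect_lt(as.numeric(d0), 1e-4)
})

test_that("locus mapping ranks the homologous locus first", {
  set.seed(61)
  pwms <- synthetic_pwms(5)
  train <- replicate(10, implant_sites(random_dna(400), pwms, 6)$seq)
  hmm <- train_regulus_hmm(pwms, train)
  case <- generate_regulus_case(seed = 777)
  rk <- map_crm_to_loci(case$crm, case$loci, hmm)
  expect_equal(rk$gene_id[1], case$correct_gene)
  expect_equal(nrow(rk), 10L)
  expect_length(attr(rk, "top2"), 2L)

  # identical loci tie, broken by input order and flagged
  loci <- c(gA = case$loci[[1]], gB = case$loci[[1]])
  rk2 <- map_crm_to_loci(case$crm, loci, hmm)
  expect_equal(rk2$gene_id, c("gA", "gB"))
  expect_true(attr(rk2, "ties"))
})

test_that("HMM and scorer models survive a serialisation round-trip", {
  set.seed(62)
  crms <- replicate(6, random_dna(200))
  bg <- replicate(6, random_dna(200))
  f <- withr::local_tempfile(fileext = ".json")
  for (kind in c("mshexmcd", "msimm", "pacrc")) {
    sc <- train_scorer(kind, crms, bg)
    write_model(sc, f)
    sc2 <- read_model(f)
    s <- random_dna(60)
    expect_equal(score_window(sc2, s), score_window(sc, s),
                 tolerance = 1e-12)
  }
  hmm <- random_hmm(2)
  write_model(hmm, f)
  hmm2 <- read_model(f)
  x <- random_dna(30); y <- random_dna(30)
  expect_equal(regulus_score(hmm2, x, y)$llr, regulus_score(hmm, x, y)$llr,
               tolerance = 1e-12)
})
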