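# Regulus: a probabilistic, alignment-free score of motif-composition
# similarity between two sequences x and y.
#
# Both sequences are modelled as emissions of a zeroth-order HMM with one
# state per motif (emitting a whole PWM-distributed site, either
# orientation with probability 1/2) and one background state (emitting a
# single base). Transition probabilities depend only on the entered state.
# Under the null model the two sequences are generated independently;
# under the homology model the probability of a hidden state path T over
# both sequences is re-weighted by
#     phi(T) = phi ^ sum_m min(n_m^x, n_m^y),
# the exponential of the number of sites shared motif-by-motif. Both
# models condition on the observed sequence lengths, so the score
#     LLR = log Pr(S | homology) - log Pr(S | null)
# reduces to sums/ratios of expectations of phi(T) under the
# length-conditioned path distribution with (emission mode) and without
# (path mode) the sequence emissions. phi = 1 collapses the homology
# model onto the null and gives LLR = 0 identically.

# elementwise log-sum-exp over a list of equal-length vectors
#' @keywords internal
.lse_vecs <- function(vl) {
  if (length(vl) == 1L) return(vl[[1L]])
  m <- do.call(pmax, vl)
  acc <- 0
  for (v in vl) acc <- acc + exp(v - m)
  out <- m + log(acc)
  out[!is.finite(m)] <- -Inf
  out
}

#' @keywords internal
.lse <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

# log site-emission per start position: average of the two orientations
#' @keywords internal
.site_logemission <- function(pwm, v) {
  k <- pwm$width
  n <- length(v) - k + 1L
  if (n < 1L) return(numeric(0))
  lmat <- log(pwm$mat)
  lmat_rc <- lmat[4:1, rev(seq_len(k)), drop = FALSE]
  fwd <- numeric(n)
  rev <- numeric(n)
  for (j in seq_len(k)) {
    b <- v[j:(j + n - 1L)]
    fwd <- fwd + lmat[cbind(b, j)]
    rev <- rev + lmat_rc[cbind(b, j)]
  }
  out <- .lse_vecs(list(fwd + log(0.5), rev + log(0.5)))
  out[is.na(out)] <- -Inf  # sites overlapping N are impossible
  out
}

#' Build a Regulus HMM
#'
#' Estimated per-motif densities are rescaled by a common constant so that
#' their mean equals `target_mean` (with `k` motifs the motif transition
#' probabilities then sum to `k * target_mean`); the remaining probability
#' mass goes to the background state. Background emission probabilities
#' are the nucleotide frequencies of `seqs_for_bg` (with a +1 Laplace
#' count so no base has probability zero), unless `bg_freqs` is given.
#'
#' @param pwms named list of `pwm` objects (the motif states).
#' @param densities per-motif transition densities, e.g. from
#'   [estimate_motif_density()]; recycled order must match `pwms`.
#' @param seqs_for_bg sequences whose base composition defines the
#'   background emission (ignored when `bg_freqs` given).
#' @param phi homology coupling constant (default 5).
#' @param target_mean mean motif transition probability after scaling
#'   (default 0.001).
#' @param bg_freqs optional explicit background base probabilities
#'   (A, C, G, T).
#' @return an object of class `regulus_hmm`.
#' @export
build_regulus_hmm <- function(pwms, densities = numeric(0),
                              seqs_for_bg = NULL, phi = 5,
                              target_mean = 0.001, bg_freqs = NULL) {
  stopifnot(length(densities) == length(pwms), all(densities > 0), phi > 0)
  trans <- if (length(pwms)) densities * (target_mean / mean(densities))
    else numeric(0)
  if (sum(trans) >= 1) {
    stop("scaled motif transition probabilities sum to >= 1 ",
         "(too many motifs for target_mean)", call. = FALSE)
  }
  if (is.null(bg_freqs)) {
    stopifnot(!is.null(seqs_for_bg))
    cnt <- numeric(4)
    for (s in seqs_for_bg) {
      v <- dna_to_int(s)
      cnt <- cnt + tabulate(v[!is.na(v)], nbins = 4L)
    }
    bg_freqs <- (cnt + 1) / sum(cnt + 1)
  }
  stopifnot(length(bg_freqs) == 4L, abs(sum(bg_freqs) - 1) < 1e-6)
  names(trans) <- names(pwms)
  structure(list(pwms = pwms, trans = trans, bg_trans = 1 - sum(trans),
                 bg_emission = bg_freqs, phi = phi,
                 target_mean = target_mean, densities = densities),
            class = "regulus_hmm")
}

#' Estimate a motif's density by Baum--Welch
#'
#' Fits the transition probability into the motif state of a two-state
#' (motif, background) segmental HMM by expectation-maximisation on a set
#' of training CRMs. The background emission is held fixed.
#'
#' @param seqs character vector of training sequences.
#' @param pwm the motif's `pwm`.
#' @param bg_freqs background base probabilities (A, C, G, T).
#' @param init initial motif transition probability (default 1e-3).
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @param max_iter iteration cap (default 200; non-convergence returns the
#'   last iterate with a warning).
#' @return the fitted density (a probability), with attributes
#'   `loglik` (trace) and `converged`.
#' @export
estimate_motif_density <- function(seqs, pwm, bg_freqs = c(.25, .25, .25, .25),
                                   init = 1e-3, tol = 1e-6, max_iter = 200L) {
  stopifnot(length(seqs) > 0L)
  k <- pwm$width
  lbe <- log(bg_freqs)
  enc <- lapply(seqs, dna_to_int)
  se <- lapply(enc, function(v) .site_logemission(pwm, v))
  lbe_seq <- lapply(enc, function(v) ifelse(is.na(v), 0, lbe[v]))

  p <- init
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lq1 <- log(p)
    lq0 <- log1p(-p)
    ll <- 0
    e_motif <- 0
    e_bg <- 0
    for (si in seq_along(enc)) {
      v <- enc[[si]]
      L <- length(v)
      lf <- rep(-Inf, L + 1L)
      lf[1L] <- 0
      for (i in seq_len(L)) {
        t1 <- lf[i] + lq0 + lbe_seq[[si]][i]
        if (i >= k) {
          t2 <- lf[i - k + 1L] + lq1 + se[[si]][i - k + 1L]
          lf[i + 1L] <- .lse(c(t1, t2))
        } else lf[i + 1L] <- t1
      }
      lb <- rep(-Inf, L + 1L)
      lb[L + 1L] <- 0
      for (i in L:1) {
        t1 <- lq0 + lbe_seq[[si]][i] + lb[i + 1L]
        if (i + k - 1L <= L) {
          t2 <- lq1 + se[[si]][i] + lb[i + k]
          lb[i] <- .lse(c(t1, t2))
        } else lb[i] <- t1
      }
      llx <- lf[L + 1L]
      ll <- ll + llx
      # expected transition counts
      i_all <- seq_len(L)
      e_bg <- e_bg + sum(exp(lf[i_all] + lq0 + lbe_seq[[si]][i_all] +
                               lb[i_all + 1L] - llx))
      i_m <- seq_len(max(0L, L - k + 1L))
      if (length(i_m)) {
        e_motif <- e_motif +
          sum(exp(lf[i_m] + lq1 + se[[si]][i_m] + lb[i_m + k] - llx))
      }
    }
    ll_trace <- c(ll_trace, ll)
    p_new <- e_motif / (e_motif + e_bg)
    p_new <- min(max(p_new, 1e-12), 1 - 1e-12)
    if (iter > 1L && abs(ll - ll_trace[iter - 1L]) < tol) {
      converged <- TRUE
      p <- p_new
      break
    }
    p <- p_new
  }
  if (!converged && max_iter > 1L) {
    warning("Baum-Welch did not converge in ", max_iter, " iterations")
  }
  structure(p, loglik = ll_trace, converged = converged)
}

#' Train a Regulus HMM from sequences
#'
#' Convenience wrapper: estimates each motif's density by
#' [estimate_motif_density()] on `train_seqs` and builds the combined HMM
#' with [build_regulus_hmm()].
#'
#' @inheritParams build_regulus_hmm
#' @param train_seqs training CRM sequences for density estimation.
#' @export
train_regulus_hmm <- function(pwms, train_seqs, phi = 5,
                              target_mean = 0.001) {
  cnt <- numeric(4)
  for (s in train_seqs) {
    v <- dna_to_int(s)
    cnt <- cnt + tabulate(v[!is.na(v)], nbins = 4L)
  }
  bg <- (cnt + 1) / sum(cnt + 1)
  dens <- vapply(pwms, function(p) {
    as.numeric(estimate_motif_density(train_seqs, p, bg_freqs = bg))
  }, 0)
  build_regulus_hmm(pwms, dens, bg_freqs = bg, phi = phi,
                    target_mean = target_mean)
}

# per-sequence precomputations shared by the DPs
#' @keywords internal
.regulus_prep <- function(hmm, v) {
  lbe_seq <- {
    lbe <- log(hmm$bg_emission)
    ifelse(is.na(v), 0, lbe[v])
  }
  se <- lapply(hmm$pwms, function(p) .site_logemission(p, v))
  list(v = v,
       lq0 = log(hmm$bg_trans),
       lq = log(hmm$trans),
       kk = vapply(hmm$pwms, function(p) p$width, 0L),
       lbe_seq = lbe_seq,
       se = se,
       # linear-space weights for the scaled marginal DP
       be_lin = exp(lbe_seq),
       sw_lin = lapply(seq_along(se), function(m) {
         exp(log(hmm$trans[m]) + se[[m]])
       }))
}

#' Forward log-likelihood of one sequence under the Regulus HMM
#'
#' Sum over all state paths emitting exactly `nchar(x)` bases; a motif
#' state emits a whole site (averaged over both orientations), the
#' background state one base. Not length-conditioned: this is the raw
#' forward sum.
#'
#' @param hmm a `regulus_hmm`.
#' @param x DNA string.
#' @return log-likelihood (natural log).
#' @export
forward_loglik <- function(hmm, x) {
  v <- dna_to_int(x)
  pp <- .regulus_prep(hmm, v)
  L <- length(v)
  lf <- rep(-Inf, L + 1L)
  lf[1L] <- 0
  nm <- length(hmm$pwms)
  for (i in seq_len(L)) {
    terms <- lf[i] + pp$lq0 + pp$lbe_seq[i]
    for (m in seq_len(nm)) {
      km <- pp$kk[m]
      if (i >= km) {
        terms <- c(terms, lf[i - km + 1L] + pp$lq[m] + pp$se[[m]][i - km + 1L])
      }
    }
    lf[i + 1L] <- .lse(terms)
  }
  lf[L + 1L]
}

# shift a log-weight vector by one focal-motif visit, pooling at the cap
#' @keywords internal
.count_shift <- function(vec) {
  n <- length(vec)
  out <- c(-Inf, vec[-n])
  out[n] <- .lse(c(out[n], vec[n]))
  out
}

#' Distribution of the number of focal-motif sites in a sequence
#'
#' Dynamic program over (position, number of visits to the focal motif
#' state), all other motifs marginalised. In `"emission"` mode path
#' weights include the sequence emissions (so the total equals the
#' forward likelihood); in `"path"` mode emissions are replaced by 1,
#' giving the length-conditioned path-count weights used in the homology
#' normaliser. Counts at or above `cap` are pooled into the last bin.
#'
#' @param hmm a `regulus_hmm`.
#' @param x DNA string.
#' @param motif_id name of the focal motif.
#' @param cap count cap (default 8).
#' @param mode `"emission"` or `"path"`.
#' @return a `count_distribution`: list(motif_id, logg (log joint weights
#'   for 0..cap sites), logtotal, prob (normalised), cap, mode).
#' @export
motif_count_distribution <- function(hmm, x, motif_id, cap = 8L,
                                     mode = c("emission", "path")) {
  mode <- match.arg(mode)
  stopifnot(cap >= 1L, motif_id %in% names(hmm$pwms))
  v <- dna_to_int(x)
  pp <- .regulus_prep(hmm, v)
  .marginal_count_dist(hmm, pp, match(motif_id, names(hmm$pwms)), cap, mode)
}

# Scaled linear-space DP: row i holds weights relative to a per-row log
# offset, so underflow over long sequences is impossible while the inner
# loop stays in plain arithmetic.
#' @keywords internal
.marginal_count_dist <- function(hmm, pp, focal, cap, mode) {
  L <- length(pp$v)
  nm <- length(hmm$pwms)
  em <- mode == "emission"
  nc <- cap + 1L
  q0 <- hmm$bg_trans
  qm <- hmm$trans
  f <- matrix(0, nrow = L + 1L, ncol = nc)
  off <- numeric(L + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(L)) {
    ref <- off[i]
    acc <- f[i, ] * (q0 * (if (em) pp$be_lin[i] else 1))
    for (m in seq_len(nm)) {
      km <- pp$kk[m]
      if (i >= km) {
        src <- i - km + 1L
        w <- if (em) pp$sw_lin[[m]][src] else qm[m]
        if (w > 0) {
          sc <- exp(off[src] - ref)
          v <- f[src, ] * (w * sc)
          if (m == focal) {
            v2 <- c(0, v[-nc])
            v2[nc] <- v2[nc] + v[nc]
            v <- v2
          }
          acc <- acc + v
        }
      }
    }
    s <- max(acc)
    if (s > 0 && (s < 1e-100 || s > 1e100)) {
      f[i + 1L, ] <- acc / s
      off[i + 1L] <- ref + log(s)
    } else {
      f[i + 1L, ] <- acc
      off[i + 1L] <- ref
    }
  }
  g <- f[L + 1L, ]
  tot <- sum(g)
  logg <- log(g) + off[L + 1L]
  structure(list(motif_id = names(hmm$pwms)[focal], logg = logg,
                 logtotal = log(tot) + off[L + 1L],
                 prob = g / tot,
                 cap = as.integer(cap), mode = mode),
            class = "count_distribution")
}

# joint count-vector distribution over all motifs (exact mode, <=3 motifs)
# state index s encodes counts (c_1, ..., c_nm) in base (cap+1),
# motif 1 least significant
#' @keywords internal
.joint_count_dist <- function(hmm, pp, cap, mode) {
  L <- length(pp$v)
  nm <- length(hmm$pwms)
  em <- mode == "emission"
  ns <- (cap + 1L)^nm
  # per-motif shift index maps with pooling at cap
  digits <- function(s, m) (s %/% (cap + 1L)^(m - 1L)) %% (cap + 1L)
  s_all <- 0:(ns - 1L)
  shift_map <- lapply(seq_len(nm), function(m) {
    d <- digits(s_all, m)
    ifelse(d < cap, s_all + (cap + 1L)^(m - 1L), s_all) + 1L
  })
  logf <- matrix(-Inf, nrow = L + 1L, ncol = ns)
  logf[1L, 1L] <- 0
  for (i in seq_len(L)) {
    contribs <- list(logf[i, ] + pp$lq0 + (if (em) pp$lbe_seq[i] else 0))
    for (m in seq_len(nm)) {
      km <- pp$kk[m]
      if (i >= km) {
        base <- logf[i - km + 1L, ] + pp$lq[m] +
          (if (em) pp$se[[m]][i - km + 1L] else 0)
        shifted <- rep(-Inf, ns)
        tgt <- shift_map[[m]]
        # accumulate with pooling (several sources can map to one target)
        for (s in which(is.finite(base))) {
          t <- tgt[s]
          shifted[t] <- .lse(c(shifted[t], base[s]))
        }
        contribs[[length(contribs) + 1L]] <- shifted
      }
    }
    logf[i + 1L, ] <- .lse_vecs(contribs)
  }
  logg <- logf[L + 1L, ]
  logtot <- .lse(logg)
  list(logg = logg, logtotal = logtot, prob = exp(logg - logtot),
       cap = cap, mode = mode, n_motifs = nm)
}

# phi^{sum_m min(c_m, c'_m)} matrix between joint states
#' @keywords internal
.phi_matrix_joint <- function(phi, cap, nm) {
  ns <- (cap + 1L)^nm
  s_all <- 0:(ns - 1L)
  tot <- matrix(0, ns, ns)
  for (m in seq_len(nm)) {
    d <- (s_all %/% (cap + 1L)^(m - 1L)) %% (cap + 1L)
    tot <- tot + outer(d, d, pmin)
  }
  phi^tot
}

#' Regulus similarity score of two sequences
#'
#' With at most `exact_max_motifs` motifs the score is computed exactly by
#' a joint dynamic program over per-motif site-count vectors (counts
#' pooled at `cap`); with more motifs a per-motif factorisation is used
#' (exact for a single motif; treats motif-count marginals as independent
#' across motifs). The result is symmetric in `(x, y)` and identically 0
#' when `phi = 1`.
#'
#' @param hmm a `regulus_hmm`.
#' @param x,y DNA strings.
#' @param cap per-motif site-count cap (default 8). A warning is issued
#'   when the pooled tail holds more than 1e-3 of the emission mass.
#' @param mode `"auto"` (default), `"exact"` or `"factorized"`.
#' @param exact_max_motifs largest motif set for which auto mode picks the
#'   exact joint DP (default 3).
#' @return a `regulus_score` list: llr, per_motif (factorized mode; NA for
#'   exact), mode.
#' @export
regulus_score <- function(hmm, x, y, cap = 8L,
                          mode = c("auto", "exact", "factorized"),
                          exact_max_motifs = 3L) {
  mode <- match.arg(mode)
  stopifnot(nchar(x) > 0L, nchar(y) > 0L)
  # canonical argument order makes the score exactly symmetric
  if (nchar(y) < nchar(x) || (nchar(y) == nchar(x) && y < x)) {
    tmp <- x; x <- y; y <- tmp
  }
  nm <- length(hmm$pwms)
  if (mode == "auto") {
    mode <- if (nm <= exact_max_motifs) "exact" else "factorized"
  }
  ppx <- .regulus_prep(hmm, dna_to_int(x))
  ppy <- .regulus_prep(hmm, dna_to_int(y))
  phi <- hmm$phi

  if (mode == "exact") {
    gx <- .joint_count_dist(hmm, ppx, cap, "emission")
    gy <- .joint_count_dist(hmm, ppy, cap, "emission")
    hx <- .joint_count_dist(hmm, ppx, cap, "path")
    hy <- .joint_count_dist(hmm, ppy, cap, "path")
    .check_tail(gx, cap, nm)
    .check_tail(gy, cap, nm)
    W <- .phi_matrix_joint(phi, cap, nm)
    e_em <- as.numeric(gx$prob %*% W %*% gy$prob)
    e_path <- as.numeric(hx$prob %*% W %*% hy$prob)
    llr <- log(e_em) - log(e_path)
    per <- rep(NA_real_, nm)
  } else {
    per <- .factorized_contributions(hmm, ppx, ppy, cap)
    llr <- sum(per)
  }
  structure(list(llr = llr, per_motif = per, mode = mode, cap = cap),
            class = "regulus_score")
}

# per-motif factorized contributions; precomputed x-side emission (gx),
# x-side path (hx) and y-side path (hy) distribution lists may be passed
# to amortise repeated scoring against the same sequence or length
#' @keywords internal
.factorized_contributions <- function(hmm, ppx, ppy, cap,
                                      gx_list = NULL, hx_list = NULL,
                                      hy_list = NULL) {
  nm <- length(hmm$pwms)
  phi <- hmm$phi
  same_len <- length(ppx$v) == length(ppy$v)
  W <- phi^outer(0:cap, 0:cap, pmin)
  per <- numeric(nm)
  for (m in seq_len(nm)) {
    gx <- if (is.null(gx_list)) .marginal_count_dist(hmm, ppx, m, cap,
                                                     "emission")
      else gx_list[[m]]
    gy <- .marginal_count_dist(hmm, ppy, m, cap, "emission")
    hx <- if (is.null(hx_list)) .marginal_count_dist(hmm, ppx, m, cap,
                                                     "path")
      else hx_list[[m]]
    hy <- if (!is.null(hy_list)) hy_list[[m]]
      else if (same_len) hx
      else .marginal_count_dist(hmm, ppy, m, cap, "path")
    if (gx$prob[cap + 1L] > 1e-3 || gy$prob[cap + 1L] > 1e-3) {
      warning("motif '", names(hmm$pwms)[m], "': pooled count-cap mass ",
              "exceeds 1e-3; consider raising cap")
    }
    e_em <- as.numeric(gx$prob %*% W %*% gy$prob)
    e_path <- as.numeric(hx$prob %*% W %*% hy$prob)
    per[m] <- log(e_em) - log(e_path)
  }
  names(per) <- names(hmm$pwms)
  per
}

#' @keywords internal
.check_tail <- function(g, cap, nm) {
  # mass on joint states where any motif count is pooled at cap
  s_all <- 0:((cap + 1L)^nm - 1L)
  at_cap <- rep(FALSE, length(s_all))
  for (m in seq_len(nm)) {
    at_cap <- at_cap | ((s_all %/% (cap + 1L)^(m - 1L)) %% (cap + 1L)) == cap
  }
  if (sum(g$prob[at_cap]) > 1e-3) {
    warning("pooled count-cap mass exceeds 1e-3; consider raising cap")
  }
}

#' @export
print.regulus_score <- function(x, ...) {
  cat(sprintf("<regulus_score> llr = %.6g (%s mode)\n", x$llr, x$mode))
  invisible(x)
}

#' Brute-force Regulus score (test oracle)
#'
#' Exhaustively enumerates every segmentation of both sequences into
#' sites and background bases and evaluates the likelihood ratio by the
#' literal model definition. Only feasible for short sequences and small
#' motif sets; exists to validate [regulus_score()].
#'
#' @param hmm a `regulus_hmm`.
#' @param x,y DNA strings (each at most `max_len` bases).
#' @param max_len enumeration bound (default 14).
#' @return the LLR (a number).
#' @export
regulus_brute_force <- function(hmm, x, y, max_len = 14L) {
  if (nchar(x) > max_len || nchar(y) > max_len) {
    stop("instance too large for brute-force enumeration", call. = FALSE)
  }
  enum <- function(s) {
    v <- dna_to_int(s)
    pp <- .regulus_prep(hmm, v)
    nm <- length(hmm$pwms)
    paths <- list()
    recurse <- function(i, lpr, lem, counts) {
      L <- length(v)
      if (i > L) {
        paths[[length(paths) + 1L]] <<- list(lpr = lpr, lem = lem,
                                             counts = counts)
        return(invisible())
      }
      recurse(i + 1L, lpr + pp$lq0, lem + pp$lbe_seq[i], counts)
      for (m in seq_len(nm)) {
        km <- pp$kk[m]
        if (i + km - 1L <= length(v)) {
          c2 <- counts
          c2[m] <- c2[m] + 1L
          recurse(i + km, lpr + pp$lq[m], lem + pp$se[[m]][i], c2)
        }
      }
    }
    recurse(1L, 0, 0, integer(length(hmm$pwms)))
    paths
  }
  px <- enum(x)
  py <- enum(y)
  phi <- hmm$phi
  num <- 0   # sum phi(T) Pr(T) Pr(S|T)
  zz <- 0    # sum phi(T) Pr(T)
  fx <- sum(vapply(px, function(p) exp(p$lpr + p$lem), 0))
  fy <- sum(vapply(py, function(p) exp(p$lpr + p$lem), 0))
  wx <- sum(vapply(px, function(p) exp(p$lpr), 0))
  wy <- sum(vapply(py, function(p) exp(p$lpr), 0))
  for (a in px) {
    for (b in py) {
      f <- phi^sum(pmin(a$counts, b$counts))
      pr <- exp(a$lpr + b$lpr)
      num <- num + f * pr * exp(a$lem + b$lem)
      zz <- zz + f * pr
    }
  }
  # length-conditioned likelihood ratio: homology (num / zz) over null
  # (fx * fy / (wx * wy))
  unname(log(num) - log(zz) - (log(fx) + log(fy) - log(wx) - log(wy)))
}

#' Map a CRM to candidate gene loci by Regulus similarity
#'
#' Scores the CRM against sliding windows of each gene locus (window width
#' = CRM length, step = half a window by default) and ranks genes by their
#' best window score.
#'
#' @param crm a single DNA string (the CRM).
#' @param loci named character vector: gene_id -> locus sequence.
#' @param hmm a `regulus_hmm`.
#' @param window window width in bp (default: CRM length).
#' @param step window step (default `window / 2`).
#' @param cap count cap passed to [regulus_score()].
#' @param mode scoring mode passed to [regulus_score()].
#' @return data.frame (gene_id, best_score, best_start, rank) sorted by
#'   rank (ties broken by gene order, flagged via the `ties` attribute);
#'   attribute `top2` holds the two best gene IDs.
#' @export
map_crm_to_loci <- function(crm, loci, hmm, window = nchar(crm),
                            step = max(1L, window %/% 2L), cap = 8L,
                            mode = "auto") {
  stopifnot(length(loci) >= 1L, !is.null(names(loci)))
  nm <- length(hmm$pwms)
  if (mode == "auto") mode <- if (nm <= 3L) "exact" else "factorized"
  fact <- mode == "factorized"
  if (fact) {
    # CRM-side distributions and per-length path distributions are
    # reused across all windows
    ppx <- .regulus_prep(hmm, dna_to_int(crm))
    gx_list <- lapply(seq_len(nm), function(m) {
      .marginal_count_dist(hmm, ppx, m, cap, "emission")
    })
    hx_list <- lapply(seq_len(nm), function(m) {
      .marginal_count_dist(hmm, ppx, m, cap, "path")
    })
    path_cache <- new.env(parent = emptyenv())
  }
  best <- numeric(length(loci))
  best_start <- integer(length(loci))
  for (i in seq_along(loci)) {
    locus <- loci[[i]]
    len <- nchar(locus)
    starts <- if (len <= window) 0L else
      unique(c(seq.int(0L, len - window, by = step), len - window))
    sc <- vapply(starts, function(s) {
      piece <- substr(locus, s + 1L, min(len, s + window))
      if (fact) {
        ppy <- .regulus_prep(hmm, dna_to_int(piece))
        key <- as.character(nchar(piece))
        hy_list <- if (!is.null(path_cache[[key]])) path_cache[[key]] else {
          hl <- if (nchar(piece) == nchar(crm)) hx_list else
            lapply(seq_len(nm), function(m) {
              .marginal_count_dist(hmm, ppy, m, cap, "path")
            })
          path_cache[[key]] <- hl
          hl
        }
        sum(.factorized_contributions(hmm, ppx, ppy, cap,
                                      gx_list = gx_list, hx_list = hx_list,
                                      hy_list = hy_list))
      } else {
        regulus_score(hmm, crm, piece, cap = cap, mode = mode)$llr
      }
    }, 0)
    best[i] <- max(sc)
    best_start[i] <- starts[which.max(sc)]
  }
  ord <- order(-best, seq_along(loci))
  out <- data.frame(gene_id = names(loci)[ord], best_score = best[ord],
                    best_start = best_start[ord],
                    rank = seq_along(loci), stringsAsFactors = FALSE)
  attr(out, "ties") <- anyDuplicated(best) > 0L
  attr(out, "top2") <- utils::head(out$gene_id, 2L)
  rownames(out) <- NULL
  out
}
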