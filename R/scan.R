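# Genome scanning, global/local ranking and candidate-CRM calling.
#
# Score profiles, ranked windows and candidates are BED-flavoured
# data.frames (0-based half-open). Masked windows (>10% N) never enter a
# profile.

# Fast per-contig window scores for the chain scorers: the top-order
# contribution is a rolling sum over a precomputed per-position
# log-likelihood-ratio array; the first `order` bases of each window are
# patched in from the lower-order tables. Agrees exactly with
# score_window() on each window.
#' @keywords internal
.chain_window_scores <- function(scorer, v, starts, width) {
  order <- scorer$positive$order
  dl <- lapply(seq_len(order + 1L), function(j) {
    scorer$positive$logcond[[j]] - scorer$negative$logcond[[j]]
  })
  L <- length(v)
  one_strand <- function(v, starts) {
    # delta over top-order words starting at each position (1-based)
    codes <- kmer_codes(v, order + 1L)
    delta <- dl[[order + 1L]][codes + 1L]
    delta[is.na(delta)] <- 0
    D <- c(0, cumsum(delta))
    n_top <- width - order               # top-order words per window
    sc <- D[starts + n_top + 1L] - D[starts + 1L]
    for (j in seq_len(min(order, width))) {   # head bases at orders 0..j-1
      cj <- kmer_codes(v, j)
      hv <- dl[[j]][cj[starts + 1L] + 1L]
      hv[is.na(hv)] <- 0
      sc <- sc + hv
    }
    sc
  }
  fwd <- one_strand(v, starts)
  vr <- revcomp_int(v)
  rc_starts <- L - starts - width
  rev <- one_strand(vr, rc_starts)
  (fwd + rev) / 2
}

#' @keywords internal
.pac_window_scores <- function(scorer, v, starts, width) {
  model <- scorer$positive
  k <- model$k
  codes <- kmer_codes(v, k)
  n_words <- width - k + 1L
  vapply(starts, function(s) {
    cd <- codes[(s + 1L):(s + n_words)]
    cd <- cd[!is.na(cd)]
    if (length(cd) == 0L) return(NA_real_)
    keys <- unique(model$canon[cd + 1L])
    mean(model$fval[keys + 1L])
  }, 0)
}

#' Scan a genome with a trained scorer
#'
#' Scores every unmasked sliding window of every contig. Deterministic:
#' re-running yields a bit-identical profile.
#'
#' @param scorer a `crm_scorer` from [train_scorer()].
#' @param genome named character vector of contig sequences.
#' @param width window width in bp (default 500).
#' @param step window step in bp (default 250).
#' @param max_n_frac masking threshold on the window N fraction
#'   (default 0.1).
#' @return a `score_profile`: data.frame with columns contig, start, end,
#'   score, and attribute `scorer_id`.
#' @export
scan_genome <- function(scorer, genome, width = 500L, step = 250L,
                        max_n_frac = 0.1) {
  stopifnot(inherits(scorer, "crm_scorer"), width >= scorer$k)
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    contig <- names(genome)[i]
    win <- iter_windows(genome[[i]], width = width, step = step,
                        contig = contig, max_n_frac = max_n_frac)
    win <- win[!win$masked, , drop = FALSE]
    if (nrow(win) == 0L) next
    v <- dna_to_int(genome[[i]])
    sc <- if (scorer$kind == "pacrc") {
      .pac_window_scores(scorer, v, win$start, width)
    } else {
      .chain_window_scores(scorer, v, win$start, width)
    }
    keep <- !is.na(sc)
    out[[i]] <- data.frame(contig = contig, start = win$start[keep],
                           end = win$end[keep], score = sc[keep],
                           stringsAsFactors = FALSE)
  }
  prof <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(prof)) {
    prof <- data.frame(contig = character(0), start = integer(0),
                       end = integer(0), score = numeric(0))
  }
  rownames(prof) <- NULL
  attr(prof, "scorer_id") <- scorer$scorer_id
  class(prof) <- c("score_profile", "data.frame")
  prof
}

#' Assign global ranks to a score profile
#'
#' Rank 1 is the highest score; ties are broken by (contig, start)
#' ascending so that ranking is a deterministic total order.
#'
#' @param profile a `score_profile`.
#' @return the profile with added columns `global_rank` and
#'   `global_fraction` (= rank / number of windows), sorted by rank.
#' @export
assign_global_ranks <- function(profile) {
  stopifnot(nrow(profile) > 0L)
  ord <- order(-profile$score, profile$contig, profile$start)
  ranked <- profile[ord, , drop = FALSE]
  ranked$global_rank <- seq_len(nrow(ranked))
  ranked$global_fraction <- ranked$global_rank / nrow(ranked)
  rownames(ranked) <- NULL
  attr(ranked, "scorer_id") <- attr(profile, "scorer_id")
  class(ranked) <- c("ranked_windows", "data.frame")
  ranked
}

# Greedy non-maximum suppression: walk windows by descending score
# (coordinate tie-break) and keep a window only if it does not overlap an
# already-kept one. One score peak spanning several overlapping windows
# thus occupies a single local-rank slot.
#' @keywords internal
.nms <- function(df) {
  ord <- order(-df$score, df$start)
  keep <- logical(nrow(df))
  kept_s <- numeric(0)
  kept_e <- numeric(0)
  for (i in ord) {
    if (!any(df$start[i] < kept_e & df$end[i] > kept_s)) {
      keep[i] <- TRUE
      kept_s <- c(kept_s, df$start[i])
      kept_e <- c(kept_e, df$end[i])
    }
  }
  df[keep, , drop = FALSE]
}

#' Local ranking of windows around a gene
#'
#' Considers all profile windows intersecting
#' `[gene.start - flank, gene.end + flank)` on the gene's contig, merges
#' overlapping windows by non-maximum suppression (best window of a peak
#' survives), and ranks the survivors by score.
#'
#' @param profile a `score_profile` (or ranked windows).
#' @param gene one-row data.frame with gene_id, contig, start, end.
#' @param flank flank size in bp (default 50000, i.e. a ~100-kb region).
#' @return data.frame of surviving windows with column `local_rank`
#'   (1 = best), sorted by rank; zero rows if the region has no windows.
#' @export
local_rank <- function(profile, gene, flank = 50000L) {
  stopifnot(nrow(gene) == 1L)
  lo <- max(0L, gene$start - flank)
  hi <- gene$end + flank
  sel <- profile$contig == gene$contig & profile$start < hi & profile$end > lo
  reg <- profile[sel, , drop = FALSE]
  if (nrow(reg) == 0L) {
    reg$local_rank <- integer(0)
    return(reg)
  }
  reg <- .nms(as.data.frame(reg))
  ord <- order(-reg$score, reg$start)
  reg <- reg[ord, , drop = FALSE]
  reg$local_rank <- seq_len(nrow(reg))
  rownames(reg) <- NULL
  reg
}

# edge-to-edge distance between half-open intervals; 0 when overlapping
#' @keywords internal
.interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s2 - e1, s1 - e2))
}

#' Call candidate CRMs
#'
#' A window is a candidate CRM when all four criteria hold:
#' \enumerate{
#'   \item the training-set/model combination is amenable (evaluation
#'     P value at or below the threshold -- an input flag here, computed by
#'     [evaluation_pvalue()]);
#'   \item the window lies within `gene_dist` of a gene of the expression
#'     gene set (edge-to-edge; 0 when overlapping);
#'   \item its global score fraction is at most `global_cut` (top 0.5\%);
#'   \item its local rank within `flank` of that gene is at most
#'     `local_cut`.
#' }
#'
#' @param ranked output of [assign_global_ranks()].
#' @param genes gene annotation data.frame (gene_id, contig, start, end).
#' @param expression_genes character vector of expression-gene-set IDs
#'   (already homology-mapped into the target genome's gene namespace).
#' @param amenable logical amenability flag for this dataset/model pair.
#' @param global_cut global rank fraction cutoff (default 0.005).
#' @param local_cut local rank cutoff (default 2).
#' @param gene_dist max window-gene distance in bp (default 20000).
#' @param flank local-rank flank in bp (default 50000).
#' @return data.frame of candidate windows with columns score, global_rank,
#'   global_fraction, local_rank, associated_gene, gene_distance, scorer.
#'   A window qualifying through several genes is reported once, with the
#'   nearest qualifying gene.
#' @export
call_candidate_crms <- function(ranked, genes, expression_genes,
                                amenable = TRUE, global_cut = 0.005,
                                local_cut = 2L, gene_dist = 20000L,
                                flank = 50000L) {
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      global_rank = integer(0), global_fraction = numeric(0),
                      local_rank = integer(0), associated_gene = character(0),
                      gene_distance = numeric(0), scorer = character(0))
  if (!amenable) return(empty)
  eg <- genes[genes$gene_id %in% expression_genes, , drop = FALSE]
  if (nrow(eg) == 0L) return(empty)
  rows <- list()
  for (gi in seq_len(nrow(eg))) {
    g <- eg[gi, , drop = FALSE]
    lr <- local_rank(ranked, g, flank = flank)
    if (nrow(lr) == 0L) next
    dist <- .interval_gap(lr$start, lr$end, g$start, g$end)
    ok <- dist <= gene_dist & lr$global_fraction <= global_cut &
      lr$local_rank <= local_cut
    if (any(ok)) {
      sub <- lr[ok, , drop = FALSE]
      sub$associated_gene <- g$gene_id
      sub$gene_distance <- dist[ok]
      rows[[length(rows) + 1L]] <- sub
    }
  }
  if (length(rows) == 0L) return(empty)
  cand <- do.call(rbind, rows)
  # one row per window: keep the nearest qualifying gene
  key <- paste(cand$contig, cand$start, sep = ":")
  cand <- cand[order(key, cand$gene_distance), , drop = FALSE]
  cand <- cand[!duplicated(paste(cand$contig, cand$start, sep = ":")), ,
               drop = FALSE]
  cand <- cand[order(cand$global_rank), , drop = FALSE]
  cand$scorer <- if (is.null(attr(ranked, "scorer_id"))) NA_character_ else
    attr(ranked, "scorer_id")
  rownames(cand) <- NULL
  cand
}

#' Write a score profile as BED5
#' @param profile a `score_profile` (optionally ranked).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_profile <- function(profile, path) {
  id <- attr(profile, "scorer_id")
  df <- data.frame(profile$contig, profile$start, profile$end,
                   if (is.null(id)) "." else id,
                   format(profile$score, digits = 8, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
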