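# The "evaluation P value": are the genes nearest to the top-scoring
# windows enriched in the homology-mapped expression gene set? This is the
# global, experiment-free assessment of a training-set/genome/model
# combination; combinations passing the threshold are called "amenable".

#' Map an expression gene set through a homology map
#'
#' One-to-many homology is expanded: every target gene homologous to any
#' source gene of the set is included.
#'
#' @param source_genes character vector of source-species gene IDs.
#' @param hmap homology map data.frame (columns source, target), see
#'   [read_homology_map()].
#' @return character vector of target-species gene IDs (possibly empty,
#'   with a warning).
#' @export
map_expression_gene_set <- function(source_genes, hmap) {
  out <- unique(hmap$target[hmap$source %in% source_genes])
  if (length(out) == 0L) {
    warning("expression gene set has no homologs in the target genome")
  }
  out
}

#' Nearest universe gene to a window
#'
#' @param window one-row data.frame (contig, start, end).
#' @param genes gene annotation data.frame.
#' @param universe character vector of universe gene IDs; genes outside the
#'   universe are ignored.
#' @return the gene_id minimising edge-to-edge distance (ties: smaller
#'   start), or `NA_character_` if the contig carries no universe gene.
#' @export
nearest_gene <- function(window, genes, universe = genes$gene_id) {
  g <- genes[genes$contig == window$contig & genes$gene_id %in% universe, ,
             drop = FALSE]
  if (nrow(g) == 0L) return(NA_character_)
  d <- .interval_gap(window$start, window$end, g$start, g$end)
  g$gene_id[order(d, g$start)][1L]
}

#' Upper-tail hypergeometric probability
#'
#' `Pr(X >= n)` when drawing `P_size` genes without replacement from a
#' universe of `U_size` genes of which `G_size` are successes. Computed
#' stably in log space via log-sum-exp over binomial coefficients.
#'
#' @param n observed overlap.
#' @param P_size number of genes drawn.
#' @param G_size number of successes in the universe.
#' @param U_size universe size.
#' @return probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(n, P_size, G_size, U_size) {
  if (n < 0 || n > min(P_size, G_size) || min(P_size, G_size) > U_size ||
      P_size > U_size || G_size > U_size) {
    stop("invalid hypergeometric bounds: n=", n, " P=", P_size,
         " G=", G_size, " U=", U_size, call. = FALSE)
  }
  if (n == 0) return(1)
  i <- n:min(P_size, G_size)
  lt <- lchoose(G_size, i) + lchoose(U_size - G_size, P_size - i) -
    lchoose(U_size, P_size)
  lt <- lt[is.finite(lt)]
  if (length(lt) == 0L) return(0)
  m <- max(lt)
  exp(m + log(sum(exp(lt - m))))
}

#' Evaluation P value of a ranked prediction profile
#'
#' Walks windows in global rank order, collecting each window's nearest
#' universe gene until `P_size` distinct genes are accumulated, then tests
#' the overlap of that gene set with the expression gene set `G` by an
#' upper-tail hypergeometric test against universe `U`.
#'
#' @param ranked output of [assign_global_ranks()] (sorted by rank).
#' @param genes gene annotation data.frame.
#' @param G character vector: the (homology-mapped) expression gene set.
#' @param U character vector: the gene universe; `G` must be a subset.
#' @param P_size number of distinct nearest genes to accumulate
#'   (default 200).
#' @param alpha amenability threshold on the P value (default 1e-5).
#' @return an `evaluation_result` list: n, P_size, G_size, U_size, p_value,
#'   amenable, genes (the accumulated set P).
#' @export
evaluation_pvalue <- function(ranked, genes, G, U, P_size = 200L,
                              alpha = 1e-5) {
  if (!all(G %in% U)) stop("expression gene set G must be a subset of U",
                           call. = FALSE)
  if (length(U) < P_size) {
    stop("universe smaller than P_size (", length(U), " < ", P_size, ")",
         call. = FALSE)
  }
  gu <- genes[genes$gene_id %in% U, , drop = FALSE]
  acc <- character(0)
  n_win <- nrow(ranked)
  i <- 1L
  while (length(acc) < P_size && i <= n_win) {
    w <- ranked[i, , drop = FALSE]
    ng <- nearest_gene(w, gu, universe = gu$gene_id)
    if (!is.na(ng) && !(ng %in% acc)) acc <- c(acc, ng)
    i <- i + 1L
  }
  if (length(acc) < P_size) {
    stop("only ", length(acc), " distinct nearest genes reachable; ",
         "P_size = ", P_size, " requested", call. = FALSE)
  }
  n <- sum(acc %in% G)
  p <- hypergeom_upper_tail(n, P_size, length(G), length(U))
  structure(list(n = n, P_size = as.integer(P_size), G_size = length(G),
                 U_size = length(U), p_value = p, amenable = p <= alpha,
                 genes = acc),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> n=%d |P|=%d |G|=%d |U|=%d p=%.3g %s\n",
              x$n, x$P_size, x$G_size, x$U_size, x$p_value,
              if (x$amenable) "amenable" else "not amenable"))
  invisible(x)
}

#' @keywords internal
.round_half_up <- function(x) floor(x + 0.5)

#' Confusion-matrix metrics
#'
#' Precision, recall, F1 (harmonic mean of precision and recall) and
#' specificity from a 2x2 confusion matrix, reported both raw (fractions)
#' and rounded half-up to integer percent. A ratio with a zero denominator
#' is reported as 0 and flagged.
#'
#' @param tp,fp,fn,tn non-negative integer cells.
#' @return list with elements precision, recall, f1, specificity (raw
#'   fractions), their `_pct` rounded integer-percent counterparts, and
#'   `undefined` (names of ratios with zero denominators).
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  undef <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      undef <<- c(undef, what)
      0
    } else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "f1")
  specificity <- safe_div(tn, tn + fp, "specificity")
  list(precision = precision, recall = recall, f1 = f1,
       specificity = specificity,
       precision_pct = .round_half_up(100 * precision),
       recall_pct = .round_half_up(100 * recall),
       f1_pct = .round_half_up(100 * f1),
       specificity_pct = .round_half_up(100 * specificity),
       undefined = undef)
}
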