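# PWM handling and binding-site annotation. Sites are annotated wherever
# the log-likelihood ratio of a k-bp window (PWM versus uniform
# background) exceeds half the LLR of the motif's optimal site; site
# strength is 10 * LLR / maxLLR, so the optimal site has strength 10.

#' Construct a PWM from a count matrix
#'
#' @param id motif identifier.
#' @param counts 4 x L numeric matrix (rows A, C, G, T; columns positions).
#' @param pseudocount added to every cell before normalisation
#'   (default 0.5).
#' @return an object of class `pwm`: list(id, mat, width, pseudocount);
#'   `mat` columns each sum to 1 and all entries are positive.
#' @export
make_pwm <- function(id, counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, all(counts >= 0))
  mat <- counts + pseudocount
  mat <- sweep(mat, 2L, colSums(mat), "/")
  rownames(mat) <- BASES
  structure(list(id = id, mat = mat, width = ncol(mat),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' Read PWMs from a count-matrix text file
#'
#' Format: a `>motif_id` header line followed by four whitespace-separated
#' numeric rows giving per-position counts for A, C, G and T in that
#' order. Optional leading row labels (`A:` / `A |`) are tolerated.
#'
#' @param path path to the motif file.
#' @param pseudocount per-cell pseudocount (default 0.5).
#' @return named list of `pwm` objects.
#' @export
read_pwms <- function(path, pseudocount = 0.5) {
  if (!file.exists(path)) stop("PWM file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0L) stop("no PWM headers ('>') in ", path,
                                call. = FALSE)
  out <- list()
  for (h in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[h]])
    last <- if (h < length(heads)) heads[h + 1L] - 1L else length(lines)
    body <- lines[(heads[h] + 1L):last]
    if (length(body) < 4L) {
      stop("PWM '", id, "': expected 4 count rows", call. = FALSE)
    }
    rows <- lapply(body[1:4], function(ln) {
      ln <- sub("^[ACGTacgt]\\s*[:|]\\s*", "", ln)
      as.numeric(strsplit(ln, "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("PWM '", id, "': ragged count rows", call. = FALSE)
    }
    out[[id]] <- make_pwm(id, do.call(rbind, rows), pseudocount = pseudocount)
  }
  out
}

#' Write PWMs in the count-matrix text format
#' @param pwms named list of `pwm` objects (probabilities are written
#'   scaled by 100, which round-trips through [read_pwms()] up to the
#'   pseudocount).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id), con)
    for (r in 1:4) {
      writeLines(paste(format(p$mat[r, ] * 100, trim = TRUE), collapse = " "),
                 con)
    }
  }
  invisible(path)
}

# per-start LLR of a PWM on an integer-encoded sequence, forward
# orientation of the matrix; NA where the site overlaps an N
#' @keywords internal
.pwm_llr_ints <- function(mat, v) {
  k <- ncol(mat)
  n <- length(v) - k + 1L
  if (n < 1L) return(numeric(0))
  lr <- log(mat / 0.25)
  sc <- numeric(n)
  for (j in seq_len(k)) {
    sc <- sc + lr[cbind(v[j:(j + n - 1L)], j)]
  }
  sc
}

#' Per-position LLR profile of a PWM over a sequence
#'
#' LLR of each k-bp window against a uniform background:
#' `LLR(s) = sum_i log(PWM[i][s_i] / 0.25)`; both strands are scored.
#'
#' @param pwm a `pwm`.
#' @param seq DNA string with `nchar(seq) >= pwm$width`.
#' @return list with `fwd` and `rev` (per-start LLR vectors, NA over N)
#'   and `maxLLR` (LLR of the optimal site).
#' @export
site_llr_profile <- function(pwm, seq) {
  v <- dna_to_int(seq)
  stopifnot(length(v) >= pwm$width)
  mat_rc <- pwm$mat[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  list(fwd = .pwm_llr_ints(pwm$mat, v),
       rev = .pwm_llr_ints(mat_rc, v),
       maxLLR = sum(log(apply(pwm$mat, 2L, max) / 0.25)))
}

#' Annotate binding sites in a sequence
#'
#' Sites on either strand whose LLR strictly exceeds
#' `threshold_frac * maxLLR` of their motif. Site strength is
#' `10 * LLR / maxLLR` (the optimal site scores 10).
#'
#' @param pwms a `pwm` or list of `pwm`s.
#' @param seq DNA string.
#' @param threshold_frac fraction of maxLLR required (default 0.5).
#' @param extend extend the sequence context convention: annotation is on
#'   `seq` as given; callers wishing the 1-kb flanking convention extend
#'   the sequence before calling.
#' @return data.frame (motif_id, start, end, strand, llr, strength) sorted
#'   by start; 0-based half-open site intervals.
#' @export
annotate_sites <- function(pwms, seq, threshold_frac = 0.5) {
  stopifnot(threshold_frac > 0, threshold_frac <= 1)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  rows <- list()
  for (p in pwms) {
    if (nchar(seq) < p$width) next
    prof <- site_llr_profile(p, seq)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") prof$fwd else prof$rev
      hit <- which(!is.na(sc) & sc > threshold_frac * prof$maxLLR)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif_id = p$id, start = hit - 1L, end = hit - 1L + p$width,
          strand = strand, llr = sc[hit],
          strength = 10 * sc[hit] / prof$maxLLR,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(motif_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      llr = numeric(0), strength = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif_id, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write site annotations as BED6
#'
#' name = motif_id, score = round(strength * 100).
#' @param sites output of [annotate_sites()].
#' @param contig contig name for column 1.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, contig, path) {
  df <- data.frame(contig, sites$start, sites$end, sites$motif_id,
                   as.integer(.round_half_up(sites$strength * 100)),
                   sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Motif-composition cosine similarity (MoCS)
#'
#' Casts each sequence as a vector of per-motif annotated-site counts and
#' returns the cosine of the two vectors (0 if either vector is all
#' zero). Provided as the simple count-vector baseline that Regulus is
#' designed to improve upon.
#'
#' @param x,y DNA strings.
#' @param pwms list of `pwm`s.
#' @param threshold_frac site-annotation threshold (default 0.5).
#' @return similarity in `[0, 1]`.
#' @export
mocs_similarity <- function(x, y, pwms, threshold_frac = 0.5) {
  stopifnot(length(pwms) >= 1L)
  count_vec <- function(s) {
    ann <- annotate_sites(pwms, s, threshold_frac = threshold_frac)
    vapply(pwms, function(p) sum(ann$motif_id == p$id), 0)
  }
  vx <- count_vec(x)
  vy <- count_vec(y)
  nx <- sqrt(sum(vx^2))
  ny <- sqrt(sum(vy^2))
  if (nx == 0 || ny == 0) return(0)
  sum(vx * vy) / (nx * ny)
}
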