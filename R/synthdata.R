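# Fully synthetic, seed-reproducible benchmark inputs. The generator
# emulates the structure the prediction pipeline assumes -- CRMs of
# related function share motif composition and sit near the genes they
# regulate -- on an i.i.d. background genome. It makes no attempt to
# mimic real insect genome composition (repeats, isochores, orthology);
# what passing tests on it show is that the machinery is correct, not
# that real genomes behave this way.

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
#' @keywords internal
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic PWMs (demo motif set)
#'
#' A deterministic set of synthetic transcription-factor motifs built
#' around fixed consensus words: at every position the consensus base has
#' probability `dominance` and the others share the remainder. These are
#' stand-ins constructed for testing and simulation; no real motif
#' matrices ship with the package.
#'
#' @param n number of motifs (up to 8).
#' @param dominance consensus-base probability per position (default
#'   0.95).
#' @return named list of `pwm` objects, IDs `synthM1..synthMn`.
#' @export
synthetic_pwms <- function(n = 5L, dominance = 0.95) {
  consensus <- c("ACGGAAGT", "TGCATCAG", "GATTACGA", "CCGTTAGC",
                 "TTGACGCA", "AGCTGGTA", "CATGCGTT", "GTAACCTG")
  stopifnot(n >= 1L, n <= length(consensus))
  out <- list()
  for (i in seq_len(n)) {
    v <- dna_to_int(consensus[i])
    counts <- matrix((1 - dominance) / 3, nrow = 4L, ncol = length(v))
    counts[cbind(v, seq_along(v))] <- dominance
    id <- paste0("synthM", i)
    # counts already sum to 1 per column; pseudocount 0 keeps them exact
    out[[id]] <- make_pwm(id, counts * 100, pseudocount = 0)
  }
  out
}

#' Generate an i.i.d. background sequence
#'
#' @param length sequence length in bp.
#' @param base_freqs probabilities for A, C, G, T (must sum to 1).
#' @param seed optional seed; when given, the caller's RNG state is left
#'   untouched.
#' @return a DNA string.
#' @export
generate_background <- function(length, base_freqs = rep(0.25, 4),
                                seed = NULL) {
  stopifnot(abs(sum(base_freqs) - 1) < 1e-9, length >= 0)
  .with_seed(seed, {
    if (length == 0) return("")
    paste(sample(BASES, length, replace = TRUE, prob = base_freqs),
          collapse = "")
  })
}

# sample one site sequence from a PWM (or its consensus)
#' @keywords internal
.sample_site <- function(pwm, consensus_only = FALSE) {
  b <- if (consensus_only) {
    apply(pwm$mat, 2L, which.max)
  } else {
    vapply(seq_len(pwm$width),
           function(j) sample.int(4L, 1L, prob = pwm$mat[, j]), 0L)
  }
  paste(BASES[b], collapse = "")
}

#' Implant motif sites into a sequence
#'
#' Places `n_sites` sites (motifs drawn round-robin from `pwms`, sequences
#' sampled from the PWM unless `consensus_only`) at random non-overlapping
#' positions and random strands.
#'
#' @param seq DNA string to implant into.
#' @param pwms named list of `pwm`s.
#' @param n_sites number of sites.
#' @param seed optional seed.
#' @param consensus_only implant consensus sequences only (default FALSE).
#' @param max_tries placement attempts before giving up (default 1000).
#' @return list(seq = modified string, truth = data.frame(motif_id, start,
#'   end, strand) with pairwise-disjoint 0-based half-open intervals).
#' @export
implant_sites <- function(seq, pwms, n_sites, seed = NULL,
                          consensus_only = FALSE, max_tries = 1000L) {
  if (n_sites == 0L) {
    return(list(seq = seq, truth = data.frame(
      motif_id = character(0), start = integer(0), end = integer(0),
      strand = character(0))))
  }
  stopifnot(n_sites * max(vapply(pwms, function(p) p$width, 0L)) <=
              nchar(seq))
  .with_seed(seed, {
    L <- nchar(seq)
    placed_s <- integer(0)
    placed_e <- integer(0)
    rows <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      p <- pwms[[((i - 1L) %% length(pwms)) + 1L]]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- sample.int(L - p$width + 1L, 1L) - 1L
        if (!any(s < placed_e & s + p$width > placed_s)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place site ", i, " without overlap after ",
                    max_tries, " tries", call. = FALSE)
      strand <- sample(c("+", "-"), 1L)
      site <- .sample_site(p, consensus_only)
      if (strand == "-") site <- revcomp(site)
      substr(seq, s + 1L, s + p$width) <- site
      placed_s <- c(placed_s, s)
      placed_e <- c(placed_e, s + p$width)
      rows[[i]] <- data.frame(motif_id = p$id, start = s, end = s + p$width,
                              strand = strand, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(seq = seq, truth = truth)
  })
}

#' Benchmark specification
#'
#' The defaults define the package's standard desk-scale benchmark: a 1-Mb
#' single-contig genome carrying 20 planted CRMs (500 bp, 14 implanted
#' sites each) near 10 flagged genes out of 80, with 50 training CRMs
#' drawn from the same implantation process and an i.i.d. background set.
#'
#' @param seed RNG seed (default 42).
#' @param genome_length genome size in bp (default 1e6).
#' @param n_planted_crms number of planted CRMs (default 20).
#' @param crm_length CRM length in bp (default 500).
#' @param sites_per_crm implanted sites per CRM (default 14).
#' @param pwms motif set (default [synthetic_pwms()] with 5 motifs).
#' @param base_freqs background base frequencies (default uniform).
#' @param n_genes number of genes (default 80).
#' @param gene_length gene body length (default 2000).
#' @param flagged_every every `flagged_every`-th gene carries the
#'   expression flag (default 8, i.e. 10 well-separated flagged genes).
#' @param n_training number of training CRMs (default 50).
#' @param n_background,background_length background set geometry
#'   (default 100 x 1000 bp).
#' @return a `benchmark_spec` list.
#' @export
benchmark_spec <- function(seed = 42L, genome_length = 1e6L,
                           n_planted_crms = 20L, crm_length = 500L,
                           sites_per_crm = 14L, pwms = synthetic_pwms(5L),
                           base_freqs = rep(0.25, 4), n_genes = 80L,
                           gene_length = 2000L, flagged_every = 8L,
                           n_training = 50L, n_background = 100L,
                           background_length = 1000L) {
  stopifnot(genome_length > 0, n_planted_crms > 0, crm_length > 0,
            sites_per_crm >= 0, n_genes > 0)
  structure(as.list(environment()), class = "benchmark_spec")
}

#' Build the synthetic benchmark bundle
#'
#' Generates mutually consistent files: genome.fa, genes.bed,
#' crm_truth.bed, training_crms.fa, background.fa, expr_set.txt,
#' homology.tsv. Planted CRMs and training CRMs come from the same
#' site-implantation process; every planted CRM lies within 20 kb of a
#' flagged (expression-set) gene, and flagged genes are spaced far apart
#' so each 100-kb local-rank neighbourhood contains only its own gene's
#' CRMs. Byte-identical output for identical spec.
#'
#' @param spec a [benchmark_spec()].
#' @param dir output directory (created if needed); `NULL` to skip
#'   writing files.
#' @return (invisibly) list with the in-memory objects: genome, genes,
#'   truth, training_crms, background, expr_source_genes, homology,
#'   flagged_genes, spec, and `files` when `dir` was given.
#' @export
build_benchmark <- function(spec = benchmark_spec(), dir = NULL) {
  stopifnot(inherits(spec, "benchmark_spec"))
  gene_span <- spec$genome_length / spec$n_genes
  if (gene_span < spec$gene_length + 2L * (spec$crm_length + 4000L)) {
    stop("genome too small for the requested gene/CRM layout", call. = FALSE)
  }
  .with_seed(spec$seed, {
    # gene bodies, evenly spaced
    centers <- round((seq_len(spec$n_genes) - 0.5) * gene_span)
    gstart <- as.integer(centers - spec$gene_length %/% 2L)
    genes <- data.frame(gene_id = sprintf("tgt_g%02d", seq_len(spec$n_genes)),
                        contig = "chr1", start = gstart,
                        end = gstart + spec$gene_length,
                        stringsAsFactors = FALSE)
    flagged_idx <- seq.int(spec$flagged_every %/% 2L, spec$n_genes,
                           by = spec$flagged_every)
    flagged_idx <- utils::head(flagged_idx, max(1L, spec$n_genes %/%
                                                  spec$flagged_every))
    flagged <- genes$gene_id[flagged_idx]

    genome <- generate_background(spec$genome_length, spec$base_freqs)

    make_crm <- function() {
      bg <- generate_background(spec$crm_length, spec$base_freqs)
      implant_sites(bg, spec$pwms, spec$sites_per_crm)$seq
    }

    # planted CRMs: round-robin over flagged genes, alternating sides,
    # 0.5-4 kb from the gene edge so the flagged gene is the nearest gene
    truth <- vector("list", spec$n_planted_crms)
    occupied_s <- genes$start[flagged_idx]
    occupied_e <- genes$end[flagged_idx]
    for (j in seq_len(spec$n_planted_crms)) {
      gi <- flagged_idx[((j - 1L) %% length(flagged_idx)) + 1L]
      side <- if (((j - 1L) %/% length(flagged_idx)) %% 2L == 0L) "right"
        else "left"
      repeat {
        off <- sample(500:4000, 1L)
        s <- if (side == "right") genes$end[gi] + off
          else genes$start[gi] - off - spec$crm_length
        e <- s + spec$crm_length
        if (s >= 0L && e <= spec$genome_length &&
            !any(s < occupied_e & e > occupied_s)) break
      }
      occupied_s <- c(occupied_s, s)
      occupied_e <- c(occupied_e, e)
      crm_seq <- make_crm()
      substr(genome, s + 1L, e) <- crm_seq
      truth[[j]] <- data.frame(crm_id = sprintf("crm%02d", j), contig = "chr1",
                               start = s, end = e,
                               gene_id = genes$gene_id[gi],
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL

    training <- vapply(seq_len(spec$n_training), function(i) make_crm(), "")
    names(training) <- sprintf("train_crm%02d", seq_len(spec$n_training))
    background <- vapply(seq_len(spec$n_background), function(i) {
      generate_background(spec$background_length, spec$base_freqs)
    }, "")
    names(background) <- sprintf("bg%03d", seq_len(spec$n_background))

    homology <- data.frame(
      source = sprintf("src_g%02d", seq_len(spec$n_genes)),
      target = genes$gene_id, stringsAsFactors = FALSE)
    expr_source <- homology$source[match(flagged, homology$target)]

    out <- list(genome = c(chr1 = genome), genes = genes, truth = truth,
                training_crms = training, background = background,
                expr_source_genes = expr_source, homology = homology,
                flagged_genes = flagged, spec = spec)

    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      f <- list(
        genome = file.path(dir, "genome.fa"),
        genes = file.path(dir, "genes.bed"),
        truth = file.path(dir, "crm_truth.bed"),
        training = file.path(dir, "training_crms.fa"),
        background = file.path(dir, "background.fa"),
        expr = file.path(dir, "expr_set.txt"),
        homology = file.path(dir, "homology.tsv"))
      write_fasta(out$genome, f$genome)
      write_gene_annotations(genes, f$genes)
      utils::write.table(truth[, c("contig", "start", "end", "crm_id",
                                   "gene_id")],
                         f$truth, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      write_fasta(training, f$training)
      write_fasta(background, f$background)
      writeLines(expr_source, f$expr)
      utils::write.table(homology, f$homology, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      out$files <- f
    }
    invisible(out)
  })
}

#' Synthetic locus-mapping case for Regulus
#'
#' One query CRM with implanted sites; `n_loci` gene loci of which
#' exactly one (gene `correct_gene`) carries an embedded homolog: an
#' independently generated segment with the same motif-site composition.
#' The remaining loci are pure background.
#'
#' @param seed RNG seed.
#' @param n_loci number of loci (default 10).
#' @param locus_length locus length in bp (default 1500).
#' @param crm_length CRM length in bp (default 400).
#' @param n_sites implanted sites in the CRM and in the homolog
#'   (default 6).
#' @param pwms motif set (default [synthetic_pwms()] with 5 motifs).
#' @param base_freqs background base frequencies.
#' @return list(crm, loci (named character vector), correct_gene).
#' @export
generate_regulus_case <- function(seed, n_loci = 10L, locus_length = 1500L,
                                  crm_length = 400L, n_sites = 6L,
                                  pwms = synthetic_pwms(5L),
                                  base_freqs = rep(0.25, 4)) {
  .with_seed(seed, {
    crm <- implant_sites(generate_background(crm_length, base_freqs),
                         pwms, n_sites)$seq
    loci <- vapply(seq_len(n_loci), function(i) {
      generate_background(locus_length, base_freqs)
    }, "")
    names(loci) <- sprintf("gene%02d", seq_len(n_loci))
    correct <- sample(names(loci), 1L)
    homolog <- implant_sites(generate_background(crm_length, base_freqs),
                             pwms, n_sites)$seq
    pos <- sample.int(locus_length - crm_length + 1L, 1L) - 1L
    s <- loci[[correct]]
    substr(s, pos + 1L, pos + crm_length) <- homolog
    loci[[correct]] <- s
    list(crm = crm, loci = loci, correct_gene = correct)
  })
}
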