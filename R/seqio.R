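#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

# ASCII lookup: A/a -> 1, C/c -> 2, G/g -> 3, T/t -> 4, everything else NA.
# Soft-masked (lowercase) bases are deliberately treated as ordinary bases.
.base_lookup <- local({
  lk <- rep(NA_integer_, 127L)
  lk[utf8ToInt("A")] <- 1L; lk[utf8ToInt("a")] <- 1L
  lk[utf8ToInt("C")] <- 2L; lk[utf8ToInt("c")] <- 2L
  lk[utf8ToInt("G")] <- 3L; lk[utf8ToInt("g")] <- 3L
  lk[utf8ToInt("T")] <- 4L; lk[utf8ToInt("t")] <- 4L
  lk
})

#' Encode a DNA string as integers
#'
#' Maps A/C/G/T (any case) to 1..4 and N (or any other IUPAC ambiguity
#' character) to `NA`. This integer encoding underlies all k-mer machinery.
#'
#' @param x a single DNA string.
#' @return integer vector of the same length as `nchar(x)`.
#' @keywords internal
dna_to_int <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  iv <- utf8ToInt(x)
  if (length(iv) == 0L) return(integer(0))
  out <- .base_lookup[iv]
  out
}

#' @keywords internal
int_to_dna <- function(v) {
  if (length(v) == 0L) return("")
  ch <- c(BASES, "N")[ifelse(is.na(v), 5L, v)]
  paste(ch, collapse = "")
}

# reverse complement of an integer-encoded sequence (NA stays NA)
#' @keywords internal
revcomp_int <- function(v) rev(5L - v)

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string over A/C/G/T/N.
#' @return the reverse-complemented string (uppercase).
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) int_to_dna(revcomp_int(dna_to_int(toupper(x))))

.normalize_seq <- function(s, id) {
  s <- toupper(s)
  bad <- grepl("[^ACGTN]", s)
  if (bad) {
    stop("sequence '", id, "' contains characters outside A/C/G/T/N",
         call. = FALSE)
  }
  s
}

#' Read a FASTA file
#'
#' Sequences are normalized to uppercase; only A/C/G/T/N are accepted.
#' Record order is preserved and duplicate IDs are an error.
#'
#' @param path path to a (multi-)FASTA file, wrapped or unwrapped.
#' @return a named character vector of sequences (names are record IDs),
#'   possibly empty. This is the `SequenceRecord` list used throughout.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  if (length(ss) == 0L) return(structure(character(0), names = character(0)))
  # first whitespace-delimited token is the ID, as is conventional
  ids <- vapply(strsplit(ids, "[ \t]"), `[[`, "", 1L)
  if (any(ids == "")) stop("empty FASTA record ID in ", path, call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA ID '", dup[[1L]], "' in ", path, call. = FALSE)
  }
  seqs <- as.character(ss)
  seqs <- mapply(.normalize_seq, seqs, ids, USE.NAMES = FALSE)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Enumerate sliding windows over a sequence
#'
#' Windows are `[i*step, i*step + width)` in 0-based half-open coordinates
#' for every `i` such that the window fits within the sequence. Windows in
#' which more than `max_n_frac` of bases are N are flagged `masked`; masked
#' windows are excluded from scoring and ranking downstream.
#'
#' @param seq a single DNA string (one genome contig).
#' @param width window width in bp (default 500).
#' @param step window step in bp (default 250).
#' @param contig contig name used in the output intervals.
#' @param max_n_frac maximum tolerated fraction of N per window (default 0.1).
#' @return data.frame with columns contig, start, end, masked. Zero rows when
#'   the sequence is shorter than `width`.
#' @export
iter_windows <- function(seq, width = 500L, step = 250L, contig = "seq",
                         max_n_frac = 0.1) {
  stopifnot(width >= 1L, step >= 1L)
  len <- nchar(seq)
  if (len < width) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), masked = logical(0)))
  }
  starts <- seq.int(0L, len - width, by = step)
  v <- dna_to_int(seq)
  ncum <- c(0L, cumsum(as.integer(is.na(v))))
  nfrac <- (ncum[starts + width + 1L] - ncum[starts + 1L]) / width
  data.frame(contig = contig, start = starts, end = starts + width,
             masked = nfrac > max_n_frac, stringsAsFactors = FALSE)
}

#' Read gene annotations from a BED4+ file
#'
#' Coordinates are 0-based half-open, as in BED. At least four columns
#' (contig, start, end, name) are required; a gene identifier is mandatory.
#'
#' @param path path to the BED file.
#' @return data.frame with columns gene_id, contig, start, end.
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 4L)) {
    stop("line ", which(ncol < 4L)[1L],
         ": gene identifier required (BED4+, got fewer than 4 columns)",
         call. = FALSE)
  }
  contig <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  gene_id <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("line ", bad[1L], ": non-numeric BED coordinates", call. = FALSE)
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    stop("line ", bad[1L], ": invalid interval (start >= end or start < 0)",
         call. = FALSE)
  }
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id '", dup[[1L]], "' in ", path, call. = FALSE)
  }
  data.frame(gene_id = gene_id, contig = contig, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Write gene-style annotations as BED4
#' @param genes data.frame with gene_id, contig, start, end.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(genes, path) {
  df <- data.frame(genes$contig, genes$start, genes$end, genes$gene_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column homology map (TSV)
#'
#' Column 1 is the source-species gene ID, column 2 the target-species gene
#' ID. Many-to-many pairs are allowed. A header line is detected (and
#' skipped) when the first line contains no pair seen again, conventionally
#' "source<TAB>target".
#'
#' @param path path to the TSV file.
#' @return data.frame with columns source, target.
#' @export
read_homology_map <- function(path) {
  if (!file.exists(path)) stop("homology map not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("source", "target"),
                          colClasses = "character")
  if (nrow(df) > 0L && identical(tolower(unlist(df[1L, ])),
                                 c("source", "target"))) {
    df <- df[-1L, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read a gene set (one gene ID per line)
#' @param path path to the plain-text file.
#' @return character vector of unique gene IDs.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path, call. = FALSE)
  ids <- readLines(path)
  ids <- trimws(ids)
  unique(ids[nzchar(ids)])
}
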