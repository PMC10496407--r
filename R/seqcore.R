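# Elementary sequence machinery: homopolymer compression, edit-distance
# alignment, Phred conversion, column consensus, FASTA/FASTQ plumbing.

DNA_BASES <- c("A", "C", "G", "T")

#' Sanitize a DNA sequence
#'
#' Uppercases and maps every character outside `{A,C,G,T}` to `N`.
#'
#' @param x character vector of sequences.
#' @return character vector over the alphabet `{A,C,G,T,N}`.
#' @export
dna_sanitize <- function(x) {
  x <- toupper(as.character(x))
  gsub("[^ACGT]", "N", x)
}

#' Random DNA sequence
#'
#' @param n length in bases.
#' @return a single sequence of `n` i.i.d. uniform bases.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Homopolymer compression with a coordinate map
#'
#' Collapses every maximal run of an identical base to a single base and
#' records, per compressed position, the original-coordinate run it came from
#' (0-based, half-open). The map is the single source of truth for lifting
#' compressed coordinates back to the original sequence.
#'
#' @param seq a single sequence (character scalar).
#' @return an object of class `hpc_map`: list with `compressed` (string),
#'   `start` and `end` (integer vectors, one run per compressed position) and
#'   `original_length`.
#' @export
hpc_compress <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  r <- cpp_hpc(seq)
  structure(list(compressed = r$compressed, start = r$start, end = r$end,
                 original_length = nchar(seq)),
            class = "hpc_map")
}

#' Expand a homopolymer-compressed sequence back to the original
#'
#' @param map an `hpc_map` from [hpc_compress()].
#' @return the original sequence.
#' @export
hpc_expand <- function(map) {
  stopifnot(inherits(map, "hpc_map"))
  if (nchar(map$compressed) == 0L) return("")
  bases <- strsplit(map$compressed, "", fixed = TRUE)[[1]]
  paste(rep(bases, map$end - map$start), collapse = "")
}

#' Lift a compressed coordinate to original coordinates
#'
#' @param map an `hpc_map`.
#' @param pos 0-based compressed position(s).
#' @param side `"start"` maps to the first original base of the run,
#'   `"end"` to one past its last base.
#' @return 0-based original coordinate(s).
#' @export
hpc_lift <- function(map, pos, side = c("start", "end")) {
  side <- match.arg(side)
  if (side == "start") map$start[pos + 1L] else map$end[pos]
}

#' Edit-distance (Levenshtein) alignment
#'
#' Unit-cost alignment of `query` against `target`. `"global"` aligns both
#' sequences end to end; `"semiglobal"` anchors the query at the target start
#' and leaves the target tail free; `"infix"` leaves both target ends free, so
#' the query may match anywhere inside the target. The band is doubled until
#' the distance is provably optimal (distance < band) or `max_band` is hit.
#'
#' @param query,target character scalars (non-empty).
#' @param mode alignment mode.
#' @param band initial band half-width (`NULL` = automatic).
#' @param max_band band cap; results with `edit_distance >= max_band` may be
#'   upper bounds (flagged via `exact = FALSE`).
#' @return object of class `sd_alignment`: `edit_distance`, `identity`
#'   (1 - edits / alignment length), `query_span`, `target_span` (0-based,
#'   half-open), `cigar` (data.frame of ops `=`, `X`, `I`, `D` and lengths),
#'   `alignment_length`, `mode`, `exact`.
#' @export
edit_align <- function(query, target, mode = c("global", "semiglobal", "infix"),
                       band = NULL, max_band = 4096L) {
  mode <- match.arg(mode)
  stopifnot(is.character(query), is.character(target),
            length(query) == 1L, length(target) == 1L)
  m <- nchar(query); n <- nchar(target)
  if (m == 0L || n == 0L) stop("edit_align requires non-empty sequences")
  free_ts <- mode == "infix"
  free_te <- mode != "global"
  B <- if (is.null(band)) 16L else as.integer(band)
  repeat {
    d_lo <- -B
    d_hi <- max(n - m, 0L) + B
    if ((m + 1) * (d_hi - d_lo + 1) > 6e8) stop("sequences too long for exact alignment at this band")
    r <- cpp_align(query, target, d_lo, d_hi, free_ts, free_te, FALSE,
                   TRUE, FALSE)
    if (!is.na(r$dist) && (r$dist < B || B >= max_band)) break
    if (B >= max_band) break
    B <- min(max_band, B * 4L)
  }
  if (is.na(r$dist)) stop("alignment failed (band exhausted)")
  ops <- c("=", "X", "I", "D")[r$cig_op + 1L]
  identity <- if (r$alnlen > 0) 1 - r$dist / r$alnlen else 1
  structure(list(edit_distance = r$dist,
                 identity = identity,
                 query_span = c(0L, r$q_end),
                 target_span = c(r$t_start, r$t_end),
                 cigar = data.frame(op = ops, len = r$cig_len),
                 alignment_length = r$alnlen,
                 mode = mode,
                 exact = r$dist < B),
            class = "sd_alignment")
}

#' @export
print.sd_alignment <- function(x, ...) {
  cat(sprintf("<%s alignment> edits=%d identity=%.4f q[%d,%d) t[%d,%d)\n",
              x$mode, x$edit_distance, x$identity,
              x$query_span[1], x$query_span[2],
              x$target_span[1], x$target_span[2]))
  invisible(x)
}

#' PAF-like record of an alignment
#'
#' One tab-friendly row per alignment: query/target names and lengths, spans,
#' edit distance and identity.
#'
#' @param aln an `sd_alignment`.
#' @param qname,tname sequence names.
#' @param qlen,tlen sequence lengths.
#' @return one-row data.frame.
#' @export
alignment_record <- function(aln, qname, tname, qlen, tlen) {
  data.frame(query = qname, qlen = qlen,
             qstart = aln$query_span[1], qend = aln$query_span[2],
             target = tname, tlen = tlen,
             tstart = aln$target_span[1], tend = aln$target_span[2],
             edit_distance = aln$edit_distance,
             identity = aln$identity)
}

#' Phred score of an alignment identity
#'
#' Converts an identity fraction to a Phred quality score
#' `Q = -10 log10(1 - identity)`, i.e. the identity is read as one minus the
#' per-base error probability `p = 10^(-Q/10)`. Perfect identity is capped.
#'
#' @param identity fraction(s) in `[0, 1]`.
#' @param cap score returned for identity 1 (default 60, the conventional
#'   FASTQ ceiling).
#' @return numeric vector of Phred scores.
#' @export
phred_from_identity <- function(identity, cap = 60) {
  if (any(!is.finite(identity)) || any(identity < 0) || any(identity > 1)) {
    stop("identity must lie in [0, 1]")
  }
  q <- ifelse(identity >= 1, cap, -10 * log10(1 - identity))
  pmin(q, cap)
}

#' Column-wise consensus of gapped rows
#'
#' Takes equal-length rows over `{A,C,G,T,N,-}` and returns, per column, the
#' most frequent non-gap symbol (`N` counts as missing). All-gap columns are
#' dropped. Ties break to the lexicographically smallest base.
#'
#' @param rows character vector of aligned rows (equal lengths).
#' @return consensus sequence.
#' @export
column_consensus <- function(rows) {
  if (length(rows) < 1L) stop("need at least one row")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("rows must have equal length")
  if (w == 0L) return("")
  mat <- matrix(unlist(strsplit(rows, "", fixed = TRUE)),
                nrow = length(rows), byrow = TRUE)
  out <- apply(mat, 2, function(col) {
    col <- col[col %in% DNA_BASES]
    if (length(col) == 0L) return(NA_character_)
    tab <- table(factor(col, levels = DNA_BASES))
    DNA_BASES[which.max(tab)]  # which.max returns first max: lexicographic
  })
  paste(out[!is.na(out)], collapse = "")
}

# --- FASTA / FASTQ -----------------------------------------------------------

#' Read sequences from FASTA or FASTQ
#'
#' @param path file path (gz-transparent).
#' @param format `"fasta"` or `"fastq"`; guessed from the extension by default.
#' @return named character vector of sequences.
#' @export
read_seqs <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path (`.gz` triggers compression).
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(dna_sanitize(seqs))
  names(x) <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs)) else names(seqs)
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences as FASTQ with a uniform placeholder quality
#'
#' @param seqs named character vector.
#' @param path output path (`.gz` triggers compression).
#' @param qual_char quality character applied to every base.
#' @export
write_fastq <- function(seqs, path, qual_char = "I") {
  ids <- if (is.null(names(seqs))) paste0("read", seq_along(seqs)) else names(seqs)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  q <- vapply(nchar(seqs), function(n) strrep(qual_char, n), "")
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", q), con)
  invisible(path)
}

#' Write 0-based half-open intervals as BED
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `name`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  write.table(df[, c("chrom", "start", "end", "name")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
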