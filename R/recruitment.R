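# Mapping phase: an in-memory minimizer index over the read set and
# chained-minimizer recruitment of reads similar to the anchor.

#' Build a minimizer index over a read set
#'
#' Canonical-k-mer minimizers (k <= 15, window `w`) of every read are stored
#' in a keyed table for exact lookup on both strands. The index is built once
#' per read set; queries never mutate it.
#'
#' @param reads named character vector of read sequences, or a data.frame with
#'   columns `id` and `seq` (e.g. from [sample_reads()]).
#' @param k k-mer size (11..15).
#' @param w minimizer window (>= 1).
#' @return an `sd_index`: list with `k`, `w`, `tab` (keyed data.table of
#'   minimizer hits), `ids`, `seqs`, `lens`.
#' @export
build_read_index <- function(reads, k = 15L, w = 10L) {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$id)
  if (length(reads) == 0L) stop("empty read set")
  if (k < 11L || k > 15L) stop("k must be in 11..15")
  if (w < 1L) stop("w must be >= 1")
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reads <- reads[order(names(reads))]  # input-order invariance
  mins <- lapply(reads, cpp_minimizers, k = as.integer(k), w = as.integer(w))
  nper <- vapply(mins, function(m) length(m$pos), 0L)
  tab <- data.table::data.table(
    hash = unlist(lapply(mins, `[[`, "hash"), use.names = FALSE),
    read = rep(seq_along(reads), nper),
    pos = unlist(lapply(mins, `[[`, "pos"), use.names = FALSE),
    strand = unlist(lapply(mins, `[[`, "strand"), use.names = FALSE))
  data.table::setkey(tab, hash)
  structure(list(k = as.integer(k), w = as.integer(w), tab = tab,
                 ids = names(reads), seqs = unname(reads),
                 rc = unname(revcomp_dna(reads)),
                 lens = unname(nchar(reads))),
            class = "sd_index")
}

#' @export
print.sd_index <- function(x, ...) {
  cat(sprintf("<sd_index> %d reads, k=%d w=%d, %d minimizers\n",
              length(x$ids), x$k, x$w, nrow(x$tab)))
  invisible(x)
}

#' Recruit reads containing a region similar to the anchor
#'
#' Looks the anchor's minimizers up in the index, groups hits per read and
#' relative strand, keeps hits consistent with the dominant alignment diagonal
#' and filters on the chained extent covered on the anchor: reads are retained
#' when the chain spans at least `min_cov_frac` of the anchor length (default:
#' half the anchor). Hit coordinates are reported in the read orientation that
#' matches the anchor.
#'
#' @param index `sd_index` from [build_read_index()].
#' @param anchor anchor sequence (length >= k).
#' @param min_cov_frac minimum fraction of the anchor length the chain must
#'   span.
#' @param min_hits minimum chained minimizer hits.
#' @param diag_tol tolerance around the median alignment diagonal
#'   (default `max(100, 0.25 * anchor length)`).
#' @return data.frame sorted by read id: `read_id`, `strand` (+1 read as
#'   stored, -1 reverse complement), `a_lo`, `a_hi` (anchor span, 0-based
#'   half-open), `r_lo`, `r_hi` (span on the oriented read), `span`, `n_hits`,
#'   `read_len`.
#' @export
recruit <- function(index, anchor, min_cov_frac = 0.5, min_hits = 3L,
                    diag_tol = NULL) {
  stopifnot(inherits(index, "sd_index"))
  La <- nchar(anchor)
  if (La < index$k) stop("anchor shorter than the index k-mer size")
  if (is.null(diag_tol)) diag_tol <- max(100, 0.25 * La)
  qm <- cpp_minimizers(anchor, index$k, index$w)
  if (length(qm$pos) == 0L) return(empty_hits())
  q <- data.table::data.table(hash = qm$hash, apos = qm$pos, astr = qm$strand)
  data.table::setkey(q, hash)
  m <- index$tab[q, nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(m) == 0L) return(empty_hits())
  k <- index$k
  rlen <- index$lens[m$read]
  rel <- m$strand * m$astr
  rp <- ifelse(rel > 0L, m$pos, rlen - m$pos - k)
  dt <- data.table::data.table(read = m$read, rel = rel, apos = m$apos,
                               rp = rp)
  chains <- dt[, {
    d <- rp - apos
    keep <- abs(d - stats::median(d)) <= diag_tol
    if (!any(keep)) keep[which.min(abs(d - stats::median(d)))] <- TRUE
    list(n_hits = sum(keep),
         a_lo = min(apos[keep]), a_hi = max(apos[keep]) + k,
         r_lo = min(rp[keep]), r_hi = max(rp[keep]) + k)
  }, by = list(read, rel)]
  chains[, "span" := chains$a_hi - chains$a_lo]
  chains <- chains[chains$span >= min_cov_frac * La & chains$n_hits >= min_hits, ]
  if (nrow(chains) == 0L) return(empty_hits())
  # one orientation per read: keep the chain with more hits (tie: forward)
  data.table::setorderv(chains, c("read", "n_hits", "rel"),
                        order = c(1L, -1L, -1L))
  chains <- chains[!duplicated(chains$read), ]
  out <- data.frame(read_id = index$ids[chains$read],
                    strand = chains$rel,
                    a_lo = chains$a_lo, a_hi = chains$a_hi,
                    r_lo = chains$r_lo, r_hi = chains$r_hi,
                    span = chains$span, n_hits = chains$n_hits,
                    read_len = index$lens[chains$read])
  out[order(out$read_id), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(read_id = character(0), strand = integer(0), a_lo = integer(0),
             a_hi = integer(0), r_lo = integer(0), r_hi = integer(0),
             span = integer(0), n_hits = integer(0), read_len = integer(0))
}

# oriented read sequences for a set of recruitment hits (reverse complements
# are precomputed at index build time)
oriented_reads <- function(index, hits) {
  ix <- match(hits$read_id, index$ids)
  seqs <- index$seqs[ix]
  neg <- hits$strand < 0L
  if (any(neg)) seqs[neg] <- index$rc[ix[neg]]
  setNames(seqs, hits$read_id)
}
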