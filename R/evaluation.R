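# Benchmark/validation layer: assign assembled contigs to truth SD units,
# compute resolution rates and Phred-scaled alignment quality.

#' Minimizer-seeded alignment of a query against a target
#'
#' Matches minimizers between the two sequences (both orientations), keeps the
#' orientation with more hits, filters hits around the dominant alignment
#' diagonal, and computes a banded global alignment of the chained regions.
#' Coverage is the chained query span divided by the query length — the
#' equivalent of the query coverage of a mapper's alignment record.
#'
#' @param query,target sequences.
#' @param k,w minimizer parameters.
#' @param max_band band cap for the chained-region alignment.
#' @param q_cap Phred cap for perfect identity.
#' @param align compute the banded alignment of the chained region; with
#'   `FALSE` only the chain-based coverage is returned (fast screening).
#' @return list: `coverage`, `identity`, `q`, `edit_distance`, `strand`,
#'   `query_span`, `target_span`, `n_hits`, `exact`.
#' @export
chained_alignment <- function(query, target, k = 15L, w = 10L,
                              max_band = 2048L, q_cap = 60, align = TRUE) {
  no_hit <- list(coverage = 0, identity = 0, q = 0,
                 edit_distance = NA_integer_, strand = NA_integer_,
                 query_span = c(0L, 0L), target_span = c(0L, 0L),
                 n_hits = 0L, exact = TRUE)
  if (nchar(query) < k || nchar(target) < k) return(no_hit)
  qm <- cpp_minimizers(query, k, w)
  tm <- cpp_minimizers(target, k, w)
  if (length(qm$pos) == 0L || length(tm$pos) == 0L) return(no_hit)
  tdt <- data.table::data.table(hash = tm$hash, tpos = tm$pos, tstr = tm$strand)
  data.table::setkey(tdt, hash)
  qdt <- data.table::data.table(hash = qm$hash, qpos = qm$pos, qstr = qm$strand)
  m <- tdt[qdt, nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(m) == 0L) return(no_hit)
  rel <- m$qstr * m$tstr
  use_rev <- sum(rel < 0) > sum(rel > 0)
  m <- m[rel == (if (use_rev) -1L else 1L), ]
  if (nrow(m) == 0L) return(no_hit)
  qlen <- nchar(query)
  q2 <- if (use_rev) revcomp_dna(query) else query
  qpos <- if (use_rev) qlen - m$qpos - k else m$qpos
  d <- m$tpos - qpos
  keep <- abs(d - stats::median(d)) <= max(200, 0.1 * qlen)
  if (sum(keep) < 2L) return(no_hit)
  q_lo <- min(qpos[keep]); q_hi <- max(qpos[keep]) + k
  t_lo <- min(m$tpos[keep]); t_hi <- max(m$tpos[keep]) + k
  spread <- diff(range(d[keep]))
  if (!align) {
    return(list(coverage = (q_hi - q_lo) / qlen, identity = NA_real_,
                q = NA_real_, edit_distance = NA_integer_,
                strand = if (use_rev) -1L else 1L,
                query_span = c(q_lo, q_hi), target_span = c(t_lo, t_hi),
                n_hits = sum(keep), exact = FALSE))
  }
  qs <- substr(q2, q_lo + 1L, q_hi)
  ts <- substr(target, t_lo + 1L, t_hi)
  B <- max(64L, spread + 48L)
  repeat {
    mm <- nchar(qs); nn <- nchar(ts)
    r <- cpp_align(qs, ts, -B, max(nn - mm, 0L) + B, FALSE, FALSE, FALSE,
                   TRUE, FALSE)
    if (!is.na(r$dist) && (r$dist < B || B >= max_band)) break
    if (B >= max_band) break
    B <- min(max_band, B * 4L)
  }
  if (is.na(r$dist)) return(no_hit)
  identity <- if (r$alnlen > 0) 1 - r$dist / r$alnlen else 1
  list(coverage = (q_hi - q_lo) / qlen,
       identity = identity,
       q = phred_from_identity(max(0, min(1, identity)), cap = q_cap),
       edit_distance = r$dist,
       strand = if (use_rev) -1L else 1L,
       query_span = c(q_lo, q_hi),
       target_span = c(t_lo, t_hi),
       n_hits = sum(keep),
       exact = isTRUE(r$dist < B))
}

#' Assign assembled contigs to truth SD units
#'
#' For every contig the best alignment against each truth unit is computed;
#' a contig is assigned to a unit when (i) the alignment covers at least
#' `min_coverage` of the contig length and (ii) the alignment Phred score is
#' the highest among all units. Ties break by lower edit distance, then unit
#' order, and are flagged ambiguous. A truth unit is resolved when at least
#' one contig is assigned to it.
#'
#' @param contigs named character vector of assembled contigs.
#' @param units named character vector of truth unit sequences.
#' @param min_coverage contig coverage threshold (default 0.95).
#' @param q_cap Phred cap.
#' @return `list(assignments, resolved)`: per-contig data.frame (`contig`,
#'   `unit`, `coverage`, `identity`, `q`, `edit_distance`, `ambiguous`; `unit`
#'   is `NA` for unassigned contigs) and a logical vector over units.
#' @export
assign_contigs <- function(contigs, units, min_coverage = 0.95, q_cap = 60) {
  stopifnot(length(contigs) >= 1L, length(units) >= 1L)
  cn <- names(contigs) %||% paste0("contig", seq_along(contigs))
  un <- names(units) %||% paste0("unit", seq_along(units))
  rows <- lapply(seq_along(contigs), function(i) {
    alns <- lapply(units, function(u) {
      scr <- chained_alignment(contigs[[i]], u, q_cap = q_cap, align = FALSE)
      if (scr$coverage < min_coverage) return(scr)
      chained_alignment(contigs[[i]], u, q_cap = q_cap)
    })
    cov <- vapply(alns, `[[`, 0, "coverage")
    qv <- vapply(alns, `[[`, 0, "q")
    ed <- vapply(alns, function(a) as.double(a$edit_distance %||% NA), 0)
    ok <- which(cov >= min_coverage)
    if (length(ok) == 0L) {
      return(data.frame(contig = cn[i], unit = NA_character_, coverage = max(cov),
                        identity = NA_real_, q = NA_real_,
                        edit_distance = NA_real_, ambiguous = FALSE))
    }
    ord <- ok[order(-qv[ok], ed[ok], ok)]
    best <- ord[1L]
    amb <- length(ord) > 1L && qv[ord[2L]] == qv[best] &&
      !is.na(ed[ord[2L]]) && !is.na(ed[best]) && ed[ord[2L]] == ed[best]
    data.frame(contig = cn[i], unit = un[best], coverage = cov[best],
               identity = alns[[best]]$identity, q = qv[best],
               edit_distance = ed[best], ambiguous = amb)
  })
  assignments <- do.call(rbind, rows)
  resolved <- setNames(un %in% assignments$unit, un)
  list(assignments = assignments, resolved = resolved)
}

#' BAC-style resolution of a reference clone by a contig
#'
#' A clone counts as resolved when the best alignment covers at least
#' `min_coverage` (default 99.5%) of the clone length; the quality is the
#' Phred score of that alignment's identity.
#'
#' @param contig assembled contig.
#' @param clone reference clone sequence.
#' @param min_coverage clone coverage threshold.
#' @param q_cap Phred cap.
#' @return `list(resolved, q, coverage, identity)`.
#' @export
bac_style_resolution <- function(contig, clone, min_coverage = 0.995,
                                 q_cap = 60) {
  stopifnot(nchar(contig) > 0, nchar(clone) > 0)
  a <- chained_alignment(clone, contig, q_cap = q_cap)
  list(resolved = a$coverage >= min_coverage, q = a$q,
       coverage = a$coverage, identity = a$identity)
}

#' Summarize contig-to-unit assignments per scenario
#'
#' @param assignments data.frame from [assign_contigs()] (optionally with a
#'   `scenario` column).
#' @param n_units number of truth units (leaves) per scenario; either a single
#'   value or a named vector by scenario.
#' @return data.frame per scenario: `n_units`, `n_resolved`, `resolved_pct`,
#'   `q_median`, `q_min` (Q statistics over assigned contigs; `NA` when
#'   nothing was assigned).
#' @export
summarize_assignments <- function(assignments, n_units) {
  if (is.null(assignments$scenario)) assignments$scenario <- "all"
  scen <- if (length(n_units) > 1L && !is.null(names(n_units)))
    names(n_units) else unique(assignments$scenario)
  rows <- lapply(scen, function(s) {
    a <- assignments[assignments$scenario == s, , drop = FALSE]
    nu <- if (length(n_units) > 1L) n_units[[s]] else n_units
    res <- unique(a$unit[!is.na(a$unit)])
    qs <- a$q[!is.na(a$unit)]
    data.frame(scenario = s, n_units = nu, n_resolved = length(res),
               resolved_pct = 100 * length(res) / nu,
               q_median = if (length(qs)) median(qs) else NA_real_,
               q_min = if (length(qs)) min(qs) else NA_real_)
  })
  do.call(rbind, rows)
}
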