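# Assembling + extending phases and the outer iteration driver: truncate the
# selected cluster's reads around the anchor window, build a consensus contig,
# relocate the anchor in it and extend the growing assembly.

#' Truncate reads to their anchor alignment plus a flank
#'
#' Clips each read to its aligned interval extended by at most `flank` bases
#' on each side (read coordinates), ensuring even coverage and a bounded
#' assembly window.
#'
#' @param reads character vector of (oriented) read sequences.
#' @param aln_start,aln_end 0-based half-open anchor-alignment interval on
#'   each read.
#' @param flank maximum retained bases beyond the alignment on each side.
#' @return character vector of truncated reads; attribute `offsets` gives the
#'   0-based position of each truncated read's start within the original read.
#' @export
truncate_reads <- function(reads, aln_start, aln_end, flank) {
  stopifnot(length(reads) == length(aln_start),
            length(reads) == length(aln_end), flank >= 0)
  lens <- nchar(reads)
  from <- pmax(0L, aln_start - flank)
  to <- pmin(lens, aln_end + flank)
  out <- substr(reads, from + 1L, to)
  attr(out, "offsets") <- from
  out
}

assembly_error <- function(msg) {
  stop(structure(class = c("sdweaver_assembly_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Assemble a read cluster into a consensus contig
#'
#' Cluster reads are already positioned by their anchor alignment, so a full
#' overlap-layout-consensus assembler is unnecessary: a backbone is spliced
#' from the positioned reads (greedy farthest-reaching extension over
#' overlapping reads) and then polished by repeated rounds of banded
#' realignment and per-column majority voting over bases, deletions and
#' inserted segments.
#'
#' @param reads character vector of truncated reads.
#' @param starts 0-based layout offset of each read in window coordinates.
#' @param min_reads minimum cluster size (default 5); fewer reads signal an
#'   assembly failure.
#' @param min_overlap minimum backbone overlap between spliced reads (bp).
#' @param band polishing band half-width.
#' @param rounds maximum polishing rounds.
#' @param max_div per-read divergence cap during polishing.
#' @return `list(contig, n_reads, rounds)`; signals a classed condition
#'   (`sdweaver_assembly_error`) when the cluster is too small or the layout
#'   is discontiguous (which would yield zero or multiple contigs).
#' @export
assemble_cluster <- function(reads, starts, min_reads = 5L, min_overlap = 200L,
                             band = 150L, rounds = 4L, max_div = 0.55) {
  stopifnot(length(reads) == length(starts))
  if (length(reads) < min_reads) {
    assembly_error(sprintf("cluster of %d reads is below min_reads = %d",
                           length(reads), min_reads))
  }
  ord <- order(starts, -nchar(reads))
  reads <- reads[ord]; starts <- starts[ord]
  ends <- starts + nchar(reads)
  # greedy backbone: always splice the read reaching farthest while
  # overlapping the current backbone end
  base <- starts[1L]
  tmpl <- reads[1L]
  cur_end <- ends[1L]
  repeat {
    cand <- which(starts <= cur_end - min_overlap & ends > cur_end)
    if (length(cand) == 0L) break
    i <- cand[which.max(ends[cand])]
    tmpl <- paste0(substr(tmpl, 1L, starts[i] - base), reads[i])
    cur_end <- ends[i]
  }
  if (any(starts > cur_end - 1L)) {
    assembly_error("discontiguous read layout: assembly would split into multiple contigs")
  }
  p <- cpp_polish(tmpl, reads, as.integer(starts - base), as.integer(band),
                  as.integer(rounds), max_div)
  list(contig = p$seq, n_reads = length(reads), rounds = p$rounds)
}

#' Create an anchor state
#'
#' @param anchor initial anchor sequence.
#' @return an `anchor_state`: the current anchor, the growing assembly (which
#'   always ends with the current anchor), the iteration counter, the
#'   previously selected read ids and the per-iteration history.
#' @export
new_anchor_state <- function(anchor) {
  anchor <- dna_sanitize(anchor)
  structure(list(anchor = anchor, assembled = anchor, iteration = 0L,
                 selected_reads = character(0), history = list()),
            class = "anchor_state")
}

#' @export
print.anchor_state <- function(x, ...) {
  cat(sprintf("<anchor_state> iteration %d, assembled %d bp, anchor %d bp\n",
              x$iteration, nchar(x$assembled), nchar(x$anchor)))
  invisible(x)
}

#' Extend the anchor with the novel suffix of a contig
#'
#' Locates the current anchor inside the contig by infix (free-end-gap)
#' alignment. The anchor-covered suffix of the growing assembly is replaced by
#' the freshly polished contig slice and the contig suffix beyond the anchor,
#' capped at `step_cap` bases, is appended. The new anchor is the last
#' `anchor_len` bases of the updated assembly.
#'
#' @param state `anchor_state`.
#' @param contig assembled cluster consensus.
#' @param step_cap maximum extension per iteration (bp).
#' @param anchor_len length of the new anchor (bp).
#' @param min_identity minimum anchor-in-contig identity; below it the
#'   iteration has lost track of its locus.
#' @return `list(state, status, extension)` with status one of `"extended"`,
#'   `"terminated_no_extension"`, `"terminated_lost_track"`.
#' @export
extend_anchor <- function(state, contig, step_cap, anchor_len,
                          min_identity = 0.9) {
  stopifnot(inherits(state, "anchor_state"), nchar(contig) > 0)
  a <- edit_align(state$anchor, contig, mode = "infix",
                  band = max(64L, ceiling(0.25 * nchar(state$anchor))))
  if (a$identity < min_identity) {
    return(list(state = state, status = "terminated_lost_track",
                extension = 0L))
  }
  suffix_len <- nchar(contig) - a$target_span[2L]
  ext <- min(suffix_len, step_cap)
  old_len <- nchar(state$assembled)
  new_assembled <- paste0(
    substr(state$assembled, 1L, old_len - nchar(state$anchor)),
    substr(contig, a$target_span[1L] + 1L, a$target_span[2L] + ext))
  if (ext <= 0L || nchar(new_assembled) <= old_len) {
    return(list(state = state, status = "terminated_no_extension",
                extension = 0L))
  }
  state$assembled <- new_assembled
  alen <- min(anchor_len, nchar(new_assembled))
  state$anchor <- substr(new_assembled, nchar(new_assembled) - alen + 1L,
                         nchar(new_assembled))
  state$iteration <- state$iteration + 1L
  list(state = state, status = "extended",
       extension = nchar(new_assembled) - old_len)
}

derive_seed <- function(seed, iteration, block) {
  as.integer((as.double(seed %||% 0L) * 48271 + iteration * 7919 +
                block * 104729) %% 2147483647)
}

#' Targeted iterative assembly from an anchor
#'
#' The outer driver: each iteration recruits reads similar to the current
#' anchor from the minimizer index, piles the anchor-spanning reads on the
#' homopolymer-compressed anchor, calls cis-morphisms, partitions the reads
#' into clusters, selects the cluster continuing the previous iteration,
#' assembles it into a consensus contig and extends the anchor, until a
#' termination condition is met.
#'
#' @param reads read set (named character vector or data.frame with
#'   `id`/`seq`), ignored when `index` is given.
#' @param anchor initial anchor sequence.
#' @param config an [run_config()] object.
#' @param index optional prebuilt [build_read_index()] (reused across runs).
#' @param diagnostics_dir optional directory for per-iteration cis-morphism
#'   and cluster-assignment tables.
#' @param verbose print a one-line summary per iteration.
#' @return `list(contig, assembled, state, history, status)`. `contig` is the
#'   final assembly with the once-polished tail of the last iteration trimmed;
#'   `assembled` is untrimmed. `history` has one row per iteration.
#' @export
sd_assemble <- function(reads, anchor, config = run_config(), index = NULL,
                        diagnostics_dir = NULL, verbose = FALSE) {
  cfg <- config
  if (is.null(index)) index <- build_read_index(reads, cfg$k, cfg$w)
  anchor <- dna_sanitize(anchor)
  La0 <- nchar(anchor)
  if (La0 < index$k) stop("initial anchor shorter than the index k-mer size")
  anchor_len <- cfg$anchor_len %||% La0
  flank <- cfg$flank %||% round(cfg$read_mean / 2)
  step_cap <- cfg$step_cap %||% round(cfg$read_mean / 2)
  trim_tail <- cfg$trim_tail %||% step_cap
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (!is.null(diagnostics_dir)) {
    dir.create(diagnostics_dir, recursive = TRUE, showWarnings = FALSE)
  }

  state <- new_anchor_state(anchor)
  prev <- NULL
  cov_fs <- cfg$coverage_fullspan
  hist <- list()
  sel_hist <- list()
  status <- "terminated_max_iters"
  iter <- 0L

  repeat {
    iter <- iter + 1L
    if (iter > cfg$max_iters) { status <- "terminated_max_iters"; break }
    if (!is.null(cfg$max_length) && nchar(state$assembled) >= cfg$max_length) {
      status <- "terminated_max_iters"; break
    }
    La <- nchar(state$anchor)
    hits <- recruit(index, state$anchor, cfg$min_cov_frac)
    if (nrow(hits) == 0L) {
      if (iter == 1L) {
        stop("no reads recruited by the initial anchor: check that the ",
             "anchor lies within the sequenced region and that k/w match ",
             "the read error rate")
      }
      status <- "terminated_no_reads"; break
    }
    # candidate spanning reads: chain ends are fuzzy on error-prone reads, so
    # only require the read to have room for the anchor beyond its chain; the
    # pileup alignment is the actual full-span arbiter
    fs <- hits[hits$r_lo >= 0.7 * hits$a_lo &
                 (hits$read_len - hits$r_hi) >= 0.7 * (La - hits$a_hi), ,
               drop = FALSE]
    if (nrow(fs) < cfg$min_reads) { status <- "terminated_no_reads"; break }

    orient <- oriented_reads(index, fs)
    r0 <- pmax(0L, fs$r_lo - ceiling(1.12 * fs$a_lo) - 80L)
    r1 <- pmin(fs$read_len, fs$r_hi + ceiling(1.12 * (La - fs$a_hi)) + 80L)
    segs <- setNames(substr(orient, r0 + 1L, r1), fs$read_id)
    pu <- build_pileup(state$anchor, segs, band = cfg$pileup_band,
                       max_div = cfg$pileup_max_div, require_flanked = TRUE)
    pu <- prune_pileup(pu)
    if (pu$n_reads < cfg$min_reads) { status <- "terminated_no_reads"; break }
    if (is.null(cov_fs)) {
      # expected anchor-spanning reads per copy; the iteration-1 anchor is
      # unique, so its observed count caps the estimate from below
      mu <- cfg$read_mean - La
      theo <- cfg$coverage / cfg$read_mean *
        (mu * stats::pnorm(mu / max(cfg$read_sd, 1)) +
           cfg$read_sd * stats::dnorm(mu / max(cfg$read_sd, 1)))
      # the observed count flags persistent recruitment losses, but a local
      # sampling dip at the start window must not poison every threshold
      cov_fs <- min(theo, max(pu$n_reads, 0.7 * theo))
    }

    N <- pu$n_reads
    if (!is.null(cfg$min_f2)) {
      cis <- call_cismorphisms(pu, cfg$min_f2, cfg$max_sites)
      cis$z <- Inf
    } else {
      cis <- call_loci_z(pu, cov_fs, cfg$error_rate, cfg$max_sites)
    }
    min_f2 <- if (nrow(cis)) min(cis$f2) else NA_real_

    if (nrow(cis) == 0L) {
      clusters <- list(list(ids = pu$read_ids, consensus = integer(0)))
      memb <- rep(1L, N)
      assign_all <- rep(1L, N)
    } else {
      geno <- read_genotypes(pu, cis)
      memb <- similarity_graph(geno, cfg$max_dist, cfg$min_shared)
      clusters <- list()
      assign_all <- integer(N)
      id_lists <- list()
      for (b in sort(unique(memb))) {
        rows <- which(memb == b)
        subs <- refine_block(pu, rows, cov_fs, cfg, iter, b)
        for (rws in subs) {
          id_lists[[length(id_lists) + 1L]] <- pu$read_ids[rws]
        }
      }
      id_lists <- attach_small_clusters(id_lists, geno, cfg$min_reads)
      for (ids in id_lists) {
        rws <- match(ids, pu$read_ids)
        clusters[[length(clusters) + 1L]] <-
          list(ids = ids,
               consensus = genotype_consensus(geno[rws, , drop = FALSE]))
        assign_all[rws] <- length(clusters)
      }
    }

    # the anchor is the previous window's own consensus, so its genotype is
    # a valid continuity signal whenever read overlap with the previous
    # selection is uninformative (first iteration, or starved overlap)
    sel <- select_cluster(clusters, prev_reads = prev,
                          anchor_geno = anchor_genotype(pu, cis))
    if (sel$status == "lost_track") { status <- "terminated_lost_track"; break }
    cl_ids <- clusters[[sel$index]]$ids
    # phase-carrier refinement: when the chosen cluster is larger than one
    # copy's worth of reads (a copy that failed to separate rides inside a
    # mixed cluster), trim it to the reads whose genotypes agree with the
    # reads carried over from the previous selection
    if (!is.null(prev) && nrow(cis) > 0L &&
        length(cl_ids) > 1.4 * cov_fs) {
      carriers <- intersect(intersect(prev, cl_ids), rownames(geno))
      if (length(carriers) >= cfg$min_reads) {
        tg <- genotype_consensus(geno[carriers, , drop = FALSE])
        gm <- geno[cl_ids, , drop = FALSE]
        dd <- vapply(seq_len(nrow(gm)), function(i) {
          ok <- gm[i, ] >= 0 & tg >= 0
          if (sum(ok) < 3L) return(0)  # too little evidence: keep the read
          sum(gm[i, ok] != tg[ok]) / sum(ok)
        }, 0)
        refined <- cl_ids[dd <= 0.3]
        if (length(refined) >= cfg$min_reads) cl_ids <- refined
      }
    }
    # purity-first sub-refinement: re-partition the selected cluster with the
    # size floor relaxed to min_reads but the full per-cluster penalty, so a
    # lingering sibling copy (too small to pass the global floor) can still
    # be split away; the phase-carrying sub-cluster is kept and consensus
    # depth is later restored by partial reads
    if (!is.null(prev) && nrow(cis) > 0L &&
        length(cl_ids) >= 2 * cfg$min_reads) {
      rows_sel <- match(cl_ids, pu$read_ids)
      subs <- refine_block(pu, rows_sel, cov_fs, cfg, iter,
                           block = 9973L,
                           floor_cov = max(cfg$min_reads, 0.5 * cov_fs),
                           penalty = 0.5 * cov_fs)
      if (length(subs) > 1L) {
        sub_ids <- lapply(subs, function(r) pu$read_ids[r])
        ref <- if (!is.null(prev)) prev else cl_ids
        ov2 <- vapply(sub_ids, function(x) length(intersect(x, ref)), 0L)
        sizes2 <- vapply(sub_ids, length, 0L)
        bestsub <- order(-ov2, -sizes2)[1L]
        if (sizes2[bestsub] >= cfg$min_reads) cl_ids <- sub_ids[[bestsub]]
      }
    }
    # continuity guard: the anchor is the consensus of the copy being walked,
    # so the selected cluster's consensus must agree with the anchor genotype
    # at the called loci; strong disagreement means the selection switched to
    # a different copy, and extending would weld two copies into a mosaic
    d_anchor <- NA_real_
    if (nrow(cis) > 0L && iter > 1L) {
      ag <- anchor_genotype(pu, cis)
      sc2 <- genotype_consensus(geno[match(cl_ids, pu$read_ids), ,
                                     drop = FALSE])
      okg <- ag >= 0L & sc2 >= 0L
      if (sum(okg) >= 5L) {
        d_anchor <- sum(ag[okg] != sc2[okg]) / sum(okg)
        if (d_anchor > 0.30) { status <- "terminated_lost_track"; break }
      }
    }
    prev <- cl_ids
    sel_hist[[iter]] <- cl_ids

    if (!is.null(diagnostics_dir)) {
      write_cis_table(cis, file.path(diagnostics_dir,
                                     sprintf("iter%03d_cismorphisms.tsv", iter)))
      write_cluster_assignments(pu$read_ids, memb, assign_all,
                                pu$read_ids %in% cl_ids,
                                file.path(diagnostics_dir,
                                          sprintf("iter%03d_clusters.tsv", iter)))
    }

    if (length(cl_ids) < cfg$min_reads) {
      status <- "terminated_no_extension"; break
    }

    ix <- match(cl_ids, pu$read_ids)
    fs_ix <- match(cl_ids, fs$read_id)
    r_as <- r0[fs_ix] + pu$r_as[ix]
    r_ae <- r0[fs_ix] + pu$r_ae[ix]
    full <- orient[cl_ids]
    lens <- nchar(full)
    offs <- rep(0L, length(cl_ids))

    # augment the consensus read set with partial reads of the same copy:
    # clustering requires anchor-spanning reads, but reads covering only part
    # of the window still carry genotypes over the loci they reach and add
    # consensus depth (and tail support) once assigned to the selected copy
    hp <- hits[!(hits$read_id %in% pu$read_ids) & hits$span >= 900L, ,
               drop = FALSE]
    if (nrow(hp) > 34L) hp <- hp[order(-hp$span), ][seq_len(34L), ]
    if (nrow(hp) > 0L) {
      sel_cons <- clusters[[sel$index]]$consensus
      other_cons <- lapply(clusters[-sel$index], `[[`, "consensus")
      op <- oriented_reads(index, hp)
      p0 <- pmax(0L, hp$r_lo - 150L)
      p1 <- pmin(hp$read_len, hp$r_hi + 150L)
      for (i in seq_len(nrow(hp))) {
        pc <- partial_calls(pu$hpc_map, substr(op[i], p0[i] + 1L, p1[i]),
                            hp$a_lo[i], hp$a_hi[i],
                            max_div = cfg$pileup_max_div)
        if (is.null(pc)) next
        if (nrow(cis) > 0L) {
          gp <- pc$calls[cis$pos]
          okl <- gp >= 0L & sel_cons >= 0L
          if (sum(okl) < 3L) next
          d_sel <- sum(gp[okl] != sel_cons[okl]) / sum(okl)
          if (d_sel > 0.25) next
          d_oth <- suppressWarnings(min(vapply(other_cons, function(cc) {
            ok2 <- gp >= 0L & cc >= 0L
            if (sum(ok2) < 3L) return(Inf)
            sum(gp[ok2] != cc[ok2]) / sum(ok2)
          }, 0)))
          if (is.finite(d_oth) && d_oth <= d_sel) next
        }
        ras_abs <- p0[i] + pc$r_as
        rae_abs <- p0[i] + pc$r_ae
        full <- c(full, op[i])
        lens <- c(lens, hp$read_len[i])
        r_as <- c(r_as, ras_abs)
        r_ae <- c(r_ae, rae_abs)
        offs <- c(offs, pu$hpc_map$start[pc$col_range[1L]])
      }
    }
    if (length(full) > 52L) {  # consensus gains saturate; cap the work
      keep64 <- seq_len(52L)
      full <- full[keep64]; lens <- lens[keep64]
      r_as <- r_as[keep64]; r_ae <- r_ae[keep64]; offs <- offs[keep64]
    }
    polish_reads <- substr(full, r_as + 1L, pmin(lens, r_ae + flank))
    La_end <- nchar(state$anchor)
    reaches_end <- offs + (r_ae - r_as) >= La_end - 60L
    tails <- ifelse(reaches_end, pmin(lens - r_ae, flank), 0L)
    want <- pmin(tails, step_cap + 400L)
    ord_want <- order(-want, seq_along(want))
    pick <- ord_want[1L]
    # past a duplication boundary the cluster's read tails can split into
    # incompatible camps (each copy exits into its own flanking sequence);
    # seed the template with the medoid tail so the majority camp polishes
    # coherently instead of smearing votes over a minority template
    cand <- ord_want[seq_len(min(10L, length(ord_want)))]
    cand <- cand[want[cand] >= 300L]

    if (length(cand) >= 3L) {
      tl <- substr(full[cand], r_ae[cand] + 1L,
                   r_ae[cand] + pmin(600L, want[cand]))
      nd <- length(cand)
      dm <- matrix(0, nd, nd)
      for (i in seq_len(nd - 1L)) for (j in seq((i + 1L), nd)) {
        a <- cpp_align(tl[i], tl[j], -120L,
                       max(nchar(tl[j]) - nchar(tl[i]), 0L) + 120L,
                       FALSE, TRUE, TRUE, TRUE, FALSE)
        d <- if (is.na(a$dist) || a$alnlen < 50L) 1 else a$dist / a$alnlen
        dm[i, j] <- dm[j, i] <- d
      }
      pick <- cand[which.min(apply(dm, 1L, median))]
    }
    template <- paste0(state$anchor,
                       substr(full[pick], r_ae[pick] + 1L,
                              r_ae[pick] + want[pick]))
    pol <- cpp_polish(template, polish_reads, as.integer(offs),
                      as.integer(cfg$polish_band),
                      as.integer(cfg$polish_rounds), 0.55)

    res <- extend_anchor(state, pol$seq, step_cap, anchor_len)
    hist[[iter]] <- data.frame(
      iteration = iter, recruited = nrow(hits), fullspan = N,
      n_cis = nrow(cis), n_blocks = length(unique(memb)),
      n_clusters = length(clusters), selected = length(cl_ids),
      min_f2 = min_f2, d_anchor = d_anchor, extension = res$extension,
      assembled_len = nchar(res$state$assembled), status = res$status)
    if (verbose) {
      message(sprintf(
        "iter %d: recruited %d, full-span %d, cis %d, blocks %d, clusters %d, selected %d, ext %d bp",
        iter, nrow(hits), N, nrow(cis), length(unique(memb)),
        length(clusters), length(cl_ids), res$extension))
    }
    state <- res$state
    if (res$status != "extended") { status <- res$status; break }
  }

  assembled <- state$assembled
  trim <- max(0L, min(trim_tail, nchar(assembled) - La0))
  contig <- substr(assembled, 1L, nchar(assembled) - trim)
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(iteration = integer(0))
  state$history <- history
  mean_danchor <- if (nrow(history) && "d_anchor" %in% names(history))
    mean(history$d_anchor, na.rm = TRUE) else NA_real_
  list(contig = contig, assembled = assembled, state = state,
       history = history, status = status, selected_reads = sel_hist,
       mean_danchor = mean_danchor)
}

#' Bidirectional targeted assembly
#'
#' Runs the driver once on the anchor and once on its reverse complement, then
#' stitches the two assemblies at the shared anchor.
#'
#' @inheritParams sd_assemble
#' @return as [sd_assemble()], plus `forward` and `reverse` run results.
#' @export
sd_assemble_bidirectional <- function(reads, anchor, config = run_config(),
                                      index = NULL, verbose = FALSE) {
  if (is.null(index)) index <- build_read_index(reads, config$k, config$w)
  fwd <- sd_assemble(reads, anchor, config, index = index, verbose = verbose)
  rev <- sd_assemble(reads, revcomp_dna(anchor), config, index = index,
                     verbose = verbose)
  left <- revcomp_dna(rev$contig)  # ends with the anchor region
  a <- edit_align(dna_sanitize(anchor), left, mode = "infix")
  merged <- paste0(substr(left, 1L, a$target_span[1L]), fwd$contig)
  list(contig = merged, forward = fwd, reverse = rev,
       status = c(forward = fwd$status, reverse = rev$status))
}
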