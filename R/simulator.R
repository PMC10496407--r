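# Simulator of collapsed segmental duplications: SD units evolve by per-base
# substitution along a tree topology, are laid out on a contig with unique
# random flanks, and error-prone long reads are sampled with truth labels.

#' Tree topology for SD evolution
#'
#' Builds the tree along which SD units descend from a root sequence.
#' `flat` is a star (all leaves children of the root), `bifurcating` a
#' balanced binary tree (sizes split as evenly as possible), `cascading` a
#' caterpillar, and `random` a random binary tree grown by repeatedly
#' splitting a uniformly chosen leaf.
#'
#' @param kind topology type.
#' @param n_leaves number of SD copies (>= 1).
#' @param newick optional explicit newick string overriding `kind`.
#' @return an [ape::read.tree()] `phylo` object with tips `L1..Ln`.
#' @export
topology_tree <- function(kind = c("flat", "bifurcating", "cascading", "random"),
                          n_leaves, newick = NULL) {
  if (!is.null(newick)) return(ape::read.tree(text = newick))
  kind <- match.arg(kind)
  stopifnot(n_leaves >= 1)
  labs <- paste0("L", seq_len(n_leaves))
  nwk <- if (n_leaves == 1L) {
    sprintf("(%s);", labs[1])
  } else if (kind == "flat") {
    sprintf("(%s);", paste(labs, collapse = ","))
  } else if (kind == "bifurcating") {
    balanced <- function(x) {
      if (length(x) == 1L) return(x)
      h <- ceiling(length(x) / 2)
      sprintf("(%s,%s)", balanced(x[seq_len(h)]), balanced(x[-seq_len(h)]))
    }
    paste0(balanced(labs), ";")
  } else if (kind == "cascading") {
    cat_tree <- function(x) {
      if (length(x) == 2L) return(sprintf("(%s,%s)", x[1], x[2]))
      sprintf("(%s,%s)", x[1], cat_tree(x[-1]))
    }
    paste0(cat_tree(labs), ";")
  } else {  # random rooted binary tree on the R RNG stream
    tr <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
    tr$tip.label <- labs
    return(tr)
  }
  ape::read.tree(text = nwk)
}

# substitute each base independently with probability `rate`
mutate_bases <- function(seq, rate) {
  n <- nchar(seq)
  if (n == 0L || rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(runif(n) < rate)
  if (length(idx)) {
    cur <- match(v[idx], DNA_BASES)
    cur[is.na(cur)] <- sample.int(4L, sum(is.na(cur)), replace = TRUE)
    off <- sample.int(3L, length(idx), replace = TRUE)
    v[idx] <- DNA_BASES[((cur - 1L + off) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

#' Evolve SD units along a tree
#'
#' Assigns `root_unit` to the tree root and generates each child by copying
#' its parent and substituting every base independently with probability
#' `mutation_rate` (to a uniformly chosen different base). Leaf sequences are
#' the simulated SD copies.
#'
#' @param root_unit root sequence (non-empty).
#' @param tree `phylo` tree from [topology_tree()].
#' @param mutation_rate per-base substitution probability per edge, in
#'   `[0, 0.5)`.
#' @return an `sd_truth` object: `tree`, `mutation_rate`, `root_unit`, `units`
#'   (named by leaf label). Complete it with [build_collapsed_contig()].
#' @export
evolve_units <- function(root_unit, tree, mutation_rate) {
  if (!is.character(root_unit) || nchar(root_unit) == 0L) {
    stop("root unit must be a non-empty sequence")
  }
  if (mutation_rate < 0 || mutation_rate >= 0.5) {
    stop("mutation_rate must lie in [0, 0.5)")
  }
  root_unit <- dna_sanitize(root_unit)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("character", ntip + tree$Nnode)
  seqs[root] <- root_unit
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  if (ntip == 1L && nrow(edges) == 0L) {
    seqs[1L] <- mutate_bases(root_unit, mutation_rate)
  } else {
    for (e in seq_len(nrow(edges))) {
      seqs[edges[e, 2L]] <- mutate_bases(seqs[edges[e, 1L]], mutation_rate)
    }
  }
  units <- setNames(seqs[seq_len(ntip)], tree$tip.label)
  structure(list(tree = tree, mutation_rate = mutation_rate,
                 root_unit = root_unit, units = units,
                 contig = NULL, unit_intervals = NULL, flanks = NULL,
                 flank_len = NULL, spacer_len = NULL),
            class = "sd_truth")
}

#' @export
print.sd_truth <- function(x, ...) {
  cat(sprintf("<sd_truth> %d units of ~%d bp, rate %.4g%s\n",
              length(x$units), nchar(x$units[[1]]), x$mutation_rate,
              if (is.null(x$contig)) "" else
                sprintf(", contig %d bp", nchar(x$contig))))
  invisible(x)
}

all_kmers <- function(seqs, k) {
  out <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  })
  unique(unlist(out, use.names = FALSE))
}

#' Lay the SD units out on a collapsed contig with unique random flanks
#'
#' The contig is the concatenation `F0 + U1 + S1 + U2 + ... + Un + Fn`:
#' outer flanks `F0`/`Fn` of `flank_len` bases and optional inter-unit spacers
#' `S1..S(n-1)` of `spacer_len` bases, all i.i.d. uniform random sequence.
#' Every flank/spacer is checked to share no 21-mer with any leaf unit
#' (regenerated on collision), so the sequence preceding each unit is unique
#' and can seed an unambiguous initial anchor.
#'
#' @param truth `sd_truth` from [evolve_units()].
#' @param flank_len outer flank length in bp (> 0).
#' @param spacer_len inter-unit spacer length in bp (default 0: units are
#'   adjacent; per-leaf anchoring then exists only for the first unit).
#' @param kmer_check k-mer size for the uniqueness check.
#' @param max_tries regeneration attempts per flank.
#' @return the completed `sd_truth` with `contig`, `unit_intervals` and
#'   `flanks` (0-based half-open coordinates).
#' @export
build_collapsed_contig <- function(truth, flank_len, spacer_len = 0L,
                                   kmer_check = 21L, max_tries = 25L) {
  stopifnot(inherits(truth, "sd_truth"), flank_len > 0, spacer_len >= 0)
  units <- truth$units
  n <- length(units)
  unit_kmers <- all_kmers(units, kmer_check)
  gen_flank <- function(len) {
    if (len == 0L) return("")
    for (i in seq_len(max_tries)) {
      f <- random_dna(len)
      fk <- all_kmers(f, kmer_check)
      if (!any(fk %in% unit_kmers)) return(f)
    }
    stop("could not generate a flank free of unit k-mers")
  }
  flank_names <- paste0("F", 0:n)
  flank_lens <- c(flank_len, rep(spacer_len, max(0L, n - 1L)), flank_len)
  flanks <- setNames(vapply(flank_lens, gen_flank, ""), flank_names)
  pieces <- character(2L * n + 1L)
  pieces[seq(1L, 2L * n + 1L, by = 2L)] <- flanks
  pieces[seq(2L, 2L * n, by = 2L)] <- units
  contig <- paste(pieces, collapse = "")
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  starts <- ends - lens
  is_unit <- seq_along(pieces) %% 2L == 0L
  truth$contig <- contig
  truth$unit_intervals <- data.frame(leaf = names(units),
                                     start = starts[is_unit],
                                     end = ends[is_unit])
  truth$flanks <- data.frame(name = flank_names,
                             start = starts[!is_unit],
                             end = ends[!is_unit])
  truth$flank_len <- flank_len
  truth$spacer_len <- spacer_len
  truth
}

#' Initial anchor for a leaf: suffix of its preceding unique flank
#'
#' @param truth completed `sd_truth`.
#' @param leaf leaf label (e.g. `"L3"`).
#' @param anchor_len anchor length in bp.
#' @return anchor sequence.
#' @export
anchor_for_leaf <- function(truth, leaf, anchor_len) {
  stopifnot(!is.null(truth$contig))
  i <- match(leaf, truth$unit_intervals$leaf)
  if (is.na(i)) stop("unknown leaf: ", leaf)
  fl <- truth$flanks[i, ]
  if (fl$end - fl$start < anchor_len) {
    stop(sprintf("flank %s preceding %s is shorter than anchor_len (%d < %d); ",
                 fl$name, leaf, fl$end - fl$start, anchor_len),
         "use spacer_len >= anchor_len for per-leaf anchors")
  }
  substr(truth$contig, fl$end - anchor_len + 1L, fl$end)
}

#' Truth units with their unique flanking context
#'
#' Returns, per leaf, the contig slice from the start of its preceding flank
#' to the end of its following flank. These flanked units are the reference
#' sequences a per-leaf targeted assembly is expected to reconstruct.
#'
#' @param truth completed `sd_truth`.
#' @return named character vector, one flanked unit per leaf.
#' @export
flanked_units <- function(truth) {
  stopifnot(!is.null(truth$contig))
  n <- nrow(truth$unit_intervals)
  out <- vapply(seq_len(n), function(i) {
    substr(truth$contig, truth$flanks$start[i] + 1L, truth$flanks$end[i + 1L])
  }, "")
  setNames(out, truth$unit_intervals$leaf)
}

#' Sample error-prone long reads from a contig
#'
#' Read starts are uniform over the contig; lengths are
#' `Normal(mean_len, sd_len)` truncated to `[200, contig length]`; each read
#' is reverse-complemented with probability `rc_prob`; sequencing errors are
#' applied independently per base at `error_rate`, split across
#' substitution/insertion/deletion by `error_mix`. Sampling stops once the
#' total sampled bases reach `coverage` times the contig length. Each read
#' carries the truth label of the SD unit containing its midpoint (`"flank"`
#' otherwise).
#'
#' @param x completed `sd_truth`, or a plain contig sequence.
#' @param coverage target fold coverage (> 0).
#' @param mean_len,sd_len read length distribution (bp); `mean_len >= 200`.
#' @param error_rate per-base error probability, `< 0.5`.
#' @param error_mix length-3 vector of substitution/insertion/deletion
#'   proportions of the total error rate.
#' @param rc_prob probability a read is reported on the reverse strand.
#' @return data.frame: `id`, `seq`, `start`, `end` (0-based half-open origin),
#'   `strand`, `truth_leaf`, `n_errors`.
#' @export
sample_reads <- function(x, coverage, mean_len = 18000, sd_len = 3000,
                         error_rate = 0.15,
                         error_mix = c(sub = 0.6, ins = 0.25, del = 0.15),
                         rc_prob = 0.5) {
  contig <- if (inherits(x, "sd_truth")) x$contig else x
  intervals <- if (inherits(x, "sd_truth")) x$unit_intervals else NULL
  stopifnot(is.character(contig), nchar(contig) > 0)
  if (coverage <= 0) stop("coverage must be positive")
  if (mean_len < 200) stop("mean_len must be >= 200")
  if (error_rate >= 0.5) stop("error_rate must be < 0.5")
  L <- nchar(contig)
  target <- coverage * L
  total <- 0
  chunks <- list()
  while (total < target) {
    nb <- max(8L, ceiling((target - total) / mean_len))
    lens <- round(rnorm(nb, mean_len, sd_len))
    for (i in 1:60) {  # truncate by rejection, then clamp
      bad <- lens < 200 | lens > L
      if (!any(bad)) break
      lens[bad] <- round(rnorm(sum(bad), mean_len, sd_len))
    }
    lens <- pmin(pmax(lens, 200), L)
    starts <- floor(runif(nb, 0, L - lens + 1))
    raw <- substring(contig, starts + 1, starts + lens)
    strand <- ifelse(runif(nb) < rc_prob, "-", "+")
    raw[strand == "-"] <- revcomp_dna(raw[strand == "-"])
    mut <- lapply(raw, cpp_mutate_read, rate = error_rate,
                  p_sub = error_mix[[1]], p_ins = error_mix[[2]],
                  p_del = error_mix[[3]])
    chunks[[length(chunks) + 1L]] <- data.frame(
      seq = vapply(mut, `[[`, "", "seq"),
      start = starts, end = starts + lens, strand = strand,
      n_errors = vapply(mut, `[[`, 0L, "n_ops"))
    total <- total + sum(lens)
  }
  reads <- do.call(rbind, chunks)
  mid <- floor((reads$start + reads$end) / 2)
  if (!is.null(intervals)) {
    idx <- findInterval(mid, intervals$start)
    leaf <- ifelse(idx >= 1 & mid < intervals$end[pmax(idx, 1L)],
                   intervals$leaf[pmax(idx, 1L)], "flank")
  } else {
    leaf <- NA_character_
  }
  reads$truth_leaf <- leaf
  reads$id <- sprintf("r%06d", seq_len(nrow(reads)))
  rownames(reads) <- NULL
  reads[, c("id", "seq", "start", "end", "strand", "truth_leaf", "n_errors")]
}

#' The ten-scenario benchmark suite
#'
#' Generates the evolutionary scenarios used for benchmarking: flat topologies
#' with 2, 4 and 8 leaves; three bifurcating trees (balanced with 8 leaves,
#' an asymmetric 8-leaf shape, balanced with 12 leaves); cascading with 4 and
#' 8 leaves; and two random trees with 10 leaves. Every unit is preceded by a
#' unique random flank (`spacer_len = flank_len`) so each leaf has its own
#' initial anchor. The per-edge mutation rate is `1 - identity`.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param unit_len SD unit length (bp).
#' @param flank_len unique flank/spacer length (bp).
#' @param identity target SD sequence identity per edge (e.g. 0.995).
#' @param coverage per-copy fold coverage of the sampled reads.
#' @param error_rate per-base read error rate.
#' @param read_mean,read_sd read length distribution (bp).
#' @param scenarios optional character vector selecting a subset by name.
#' @return named list of scenarios, each `list(name, truth, reads)`.
#' @export
benchmark_suite <- function(seed, unit_len = 20000, flank_len = 8000,
                            identity = 0.995, coverage = 40,
                            error_rate = 0.15, read_mean = 5000,
                            read_sd = 1000, scenarios = NULL) {
  defs <- list(
    flat2 = list(kind = "flat", n = 2),
    flat4 = list(kind = "flat", n = 4),
    flat8 = list(kind = "flat", n = 8),
    bifurcating8a = list(kind = "bifurcating", n = 8),
    bifurcating8b = list(newick = "(((L1,L2),(L3,L4)),((L5,(L6,L7)),L8));", n = 8),
    bifurcating12 = list(kind = "bifurcating", n = 12),
    cascading4 = list(kind = "cascading", n = 4),
    cascading8 = list(kind = "cascading", n = 8),
    random10a = list(kind = "random", n = 10),
    random10b = list(kind = "random", n = 10))
  if (!is.null(scenarios)) defs <- defs[scenarios]
  rate <- 1 - identity
  set.seed(as.integer(seed))
  out <- vector("list", length(defs))
  names(out) <- names(defs)
  for (nm in names(defs)) {
    d <- defs[[nm]]
    tree <- if (!is.null(d$newick)) topology_tree(newick = d$newick)
            else topology_tree(d$kind, d$n)
    root <- random_dna(unit_len)
    truth <- evolve_units(root, tree, rate)
    truth <- build_collapsed_contig(truth, flank_len, spacer_len = flank_len)
    reads <- sample_reads(truth, coverage = coverage, mean_len = read_mean,
                          sd_len = read_sd, error_rate = error_rate)
    out[[nm]] <- list(name = nm, truth = truth, reads = reads)
  }
  out
}

#' Write a truth set to disk
#'
#' Units as FASTA, collapsed contig as FASTA, unit intervals as BED.
#'
#' @param truth completed `sd_truth`.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(truth$units, file.path(dir, "units.fa"))
  write_fasta(setNames(truth$contig, "collapsed_contig"),
              file.path(dir, "contig.fa"))
  write_bed(data.frame(chrom = "collapsed_contig",
                       start = truth$unit_intervals$start,
                       end = truth$unit_intervals$end,
                       name = truth$unit_intervals$leaf),
            file.path(dir, "units.bed"))
  invisible(dir)
}

#' Write simulated reads (FASTQ) and their truth origins (BED)
#'
#' @param reads data.frame from [sample_reads()].
#' @param dir output directory.
#' @param format `"fastq"` or `"fasta"`.
#' @export
write_reads <- function(reads, dir, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- setNames(reads$seq, reads$id)
  if (format == "fastq") write_fastq(seqs, file.path(dir, "reads.fastq"))
  else write_fasta(seqs, file.path(dir, "reads.fasta"))
  write_bed(data.frame(chrom = "collapsed_contig", start = reads$start,
                       end = reads$end,
                       name = paste0(reads$id, ":", reads$truth_leaf)),
            file.path(dir, "read_origins.bed"))
  invisible(dir)
}
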