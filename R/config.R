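# Run configuration and the end-to-end benchmark driver.

#' Run configuration
#'
#' All tunables of the assembler with their defaults. Unknown keys are
#' rejected. `NULL` values mean "derive at run time": `min_f2` adapts to the
#' observed stack depth, `flank`/`step_cap` default to half the mean read
#' length, `anchor_len` to the initial anchor length, `trim_tail` to
#' `step_cap`, `coverage_fullspan` to the full-span read count of the first
#' (unique-anchor) iteration, and `pileup_band` scales with the anchor.
#'
#' @param k,w minimizer index parameters.
#' @param min_cov_frac recruitment filter: minimum chained anchor coverage as
#'   a fraction of the anchor length.
#' @param min_f2 cis-morphism second-base frequency threshold (`NULL` =
#'   adaptive).
#' @param max_sites maximum retained cis-morphism loci.
#' @param max_dist similarity-graph normalized Hamming threshold.
#' @param min_shared minimum shared loci per similarity edge.
#' @param min_frac cluster-size floor as a fraction of the per-copy full-span
#'   coverage.
#' @param n_sim random clustering simulations per block.
#' @param flank read truncation flank (bp).
#' @param step_cap maximum anchor extension per iteration (bp).
#' @param min_reads minimum cluster size for assembly.
#' @param max_iters iteration cap.
#' @param q_cap Phred cap for perfect identity.
#' @param seed integer seed; all randomness flows from it.
#' @param anchor_len sliding anchor length (bp).
#' @param coverage sequencing fold coverage per SD copy.
#' @param error_rate per-base read error rate the data were generated with.
#' @param read_mean,read_sd read length distribution (bp).
#' @param polish_rounds,polish_band consensus polishing controls.
#' @param pileup_band pileup alignment band (`NULL` = automatic).
#' @param pileup_max_div maximum HPC divergence for a read to enter the pileup.
#' @param max_length stop once the assembly reaches this length (bp; `NULL` =
#'   no cap).
#' @param trim_tail bases trimmed from the final assembly tail (`NULL` =
#'   `step_cap`).
#' @param coverage_fullspan expected anchor-spanning reads per SD copy
#'   (`NULL` = estimated at iteration 1).
#' @param ... rejected; guards against misspelled keys.
#' @return an `sd_config` list.
#' @export
run_config <- function(k = 15L, w = 10L, min_cov_frac = 0.5, min_f2 = NULL,
                       max_sites = 200L, max_dist = 0.4, min_shared = 3L,
                       min_frac = 0.8, n_sim = 100L, flank = NULL,
                       step_cap = NULL, min_reads = 5L, max_iters = 500L,
                       q_cap = 60, seed = NULL, anchor_len = NULL,
                       coverage = 40, error_rate = 0.15, read_mean = 18000,
                       read_sd = 3000, polish_rounds = 3L, polish_band = 110L,
                       pileup_band = NULL, pileup_max_div = 0.32,
                       max_length = NULL,
                       trim_tail = NULL, coverage_fullspan = NULL, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  }
  stopifnot(k >= 11, k <= 15, w >= 1, min_cov_frac >= 0, min_cov_frac <= 1,
            max_sites >= 1, max_dist >= 0, max_dist <= 1, min_shared >= 1,
            min_frac > 0, min_frac <= 1, n_sim >= 1, min_reads >= 1,
            max_iters >= 1, q_cap > 0, coverage > 0, error_rate >= 0,
            error_rate < 0.5, read_mean >= 200, read_sd >= 0,
            polish_rounds >= 1, polish_band >= 16)
  if (!is.null(min_f2) && (min_f2 <= 0 || min_f2 >= 1)) {
    stop("min_f2 must lie in (0, 1)")
  }
  structure(list(k = as.integer(k), w = as.integer(w),
                 min_cov_frac = min_cov_frac, min_f2 = min_f2,
                 max_sites = as.integer(max_sites), max_dist = max_dist,
                 min_shared = as.integer(min_shared), min_frac = min_frac,
                 n_sim = as.integer(n_sim), flank = flank,
                 step_cap = step_cap, min_reads = as.integer(min_reads),
                 max_iters = as.integer(max_iters), q_cap = q_cap,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 anchor_len = anchor_len, coverage = coverage,
                 error_rate = error_rate, read_mean = read_mean,
                 read_sd = read_sd, polish_rounds = as.integer(polish_rounds),
                 polish_band = as.integer(polish_band),
                 pileup_band = pileup_band, pileup_max_div = pileup_max_div,
                 max_length = max_length,
                 trim_tail = trim_tail, coverage_fullspan = coverage_fullspan),
            class = "sd_config")
}

#' @export
print.sd_config <- function(x, ...) {
  cat("<sd_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(x[[nm]])) "(auto)" else format(x[[nm]])))
  }
  invisible(x)
}

#' Write a configuration to a YAML file
#'
#' @param config an `sd_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sd_config"))
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' Unknown keys are rejected; values are validated by [run_config()].
#'
#' @param path YAML file path.
#' @return an `sd_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Benchmark preset parameters
#'
#' `desk` is the default benchmark scale (20 kb units, 8 kb unique flanks,
#' 5 kb +/- 1 kb reads, coverage 40x, error 15%, SD identity 99.5%).
#' `paper_scale` mirrors the original experiment scale (0.5 Mb flanked units,
#' 18 kb +/- 3 kb reads) and is slow; it is provided for completeness.
#'
#' @param preset preset name.
#' @return named list of simulation/assembly parameters.
#' @export
benchmark_preset <- function(preset = c("desk", "paper_scale")) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    list(unit_len = 20000L, flank_len = 8000L, identity = 0.995,
         coverage = 40, error_rate = 0.15, read_mean = 5000, read_sd = 1000,
         anchor_len = 2000L, step_cap = 1900L, flank = 2400L)
  } else {
    list(unit_len = 450000L, flank_len = 25000L, identity = 0.995,
         coverage = 40, error_rate = 0.15, read_mean = 18000, read_sd = 3000,
         anchor_len = 4000L, step_cap = 3600L, flank = 5500L)
  }
}

#' Run the full simulation -> assembly -> evaluation benchmark
#'
#' Generates the ten-scenario suite with [benchmark_suite()], runs the
#' targeted assembler once per leaf from that leaf's unique flank anchor,
#' assigns the contigs to the flanked truth units (>= 95% contig coverage,
#' maximum-Q rule) and summarizes resolution and Phred quality per scenario.
#'
#' @param seed integer seed driving every stage.
#' @param preset `"desk"` (default) or `"paper_scale"`; individual values can
#'   be overridden via `...`.
#' @param scenarios optional subset of scenario names.
#' @param n_sim clustering simulations per block.
#' @param out_dir optional output directory for the summary/assignment TSVs,
#'   contig FASTA and the resolved configuration.
#' @param verbose print progress.
#' @param ... overrides for [benchmark_preset()] values.
#' @return list: `summary` (per scenario), `assignments` (per contig),
#'   `contigs`, `runs` (per-run status and history).
#' @export
sd_benchmark <- function(seed, preset = "desk", scenarios = NULL,
                         n_sim = 52L, out_dir = NULL, verbose = FALSE, ...) {
  pp <- utils::modifyList(benchmark_preset(preset), list(...))
  suite <- benchmark_suite(seed, unit_len = pp$unit_len,
                           flank_len = pp$flank_len, identity = pp$identity,
                           coverage = pp$coverage, error_rate = pp$error_rate,
                           read_mean = pp$read_mean, read_sd = pp$read_sd,
                           scenarios = scenarios)
  all_assign <- list()
  all_contigs <- character(0)
  runs <- list()
  n_units <- integer(0)
  for (sc in suite) {
    if (verbose) message("scenario ", sc$name)
    index <- build_read_index(sc$reads, k = 15L, w = 10L)
    leaves <- sc$truth$unit_intervals$leaf
    n_units[sc$name] <- length(leaves)
    contigs <- character(0)
    for (li in seq_along(leaves)) {
      leaf <- leaves[li]
      anchor <- anchor_for_leaf(sc$truth, leaf, pp$anchor_len)
      cfg <- run_config(seed = derive_seed(seed, match(sc$name, names(suite)),
                                           li),
                        anchor_len = pp$anchor_len, coverage = pp$coverage,
                        error_rate = pp$error_rate, read_mean = pp$read_mean,
                        read_sd = pp$read_sd, n_sim = n_sim,
                        step_cap = pp$step_cap, flank = pp$flank,
                        max_length = pp$anchor_len + pp$unit_len +
                          min(2200L, round(0.6 * pp$flank_len)))
      run <- sd_assemble(NULL, anchor, cfg, index = index)
      nm <- paste0(sc$name, ".", leaf)
      # a run that never walked past its starting window produced no
      # assembly; its anchor-sized stub must not enter the assignment
      ok <- nchar(run$contig) > pp$anchor_len + 2 * pp$step_cap
      if (ok) contigs[nm] <- run$contig
      runs[[nm]] <- list(status = run$status, history = run$history,
                         assembled = ok)
      if (verbose) {
        message(sprintf("  %s: %d bp, %s", nm, nchar(run$contig), run$status))
      }
    }
    if (length(contigs)) {
      asg <- assign_contigs(contigs, flanked_units(sc$truth))
      asg$assignments$scenario <- sc$name
      all_assign[[sc$name]] <- asg$assignments
      all_contigs <- c(all_contigs, contigs)
    } else {
      all_assign[[sc$name]] <- data.frame(
        contig = character(0), unit = character(0), coverage = numeric(0),
        identity = numeric(0), q = numeric(0), edit_distance = numeric(0),
        ambiguous = logical(0), scenario = character(0))
    }
  }
  assignments <- do.call(rbind, all_assign)
  rownames(assignments) <- NULL
  summary <- summarize_assignments(assignments, n_units)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(assignments, file.path(out_dir, "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_fasta(all_contigs, file.path(out_dir, "contigs.fa"))
    write_config(run_config(seed = as.integer(seed), n_sim = n_sim,
                            coverage = pp$coverage,
                            error_rate = pp$error_rate,
                            read_mean = pp$read_mean, read_sd = pp$read_sd,
                            anchor_len = pp$anchor_len),
                 file.path(out_dir, "config.yaml"))
  }
  list(summary = summary, assignments = assignments, contigs = all_contigs,
       runs = runs)
}
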