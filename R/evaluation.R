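call_positions <- function(calls) {
  # position of a call with a TSD interval = interval midpoint
  (calls$start + calls$end) / 2
}

#' Score a call set against simulated truth
#'
#' A call is a true positive iff its position (midpoint of its TSD
#' interval) lies within `tolerance_bp` of a truth position on the same
#' chromosome; a truth record is recalled iff at least one call matches
#' it. Sensitivity is the fraction of truth records recalled;
#' specificity the fraction of calls that are true positives. Each true
#' positive call is matched to its nearest truth record (ties broken
#' toward the lower coordinate) and TSD recall is the fraction of true
#' positive calls whose `tsd_seq` string-equals the matched truth
#' `tsd_seq`.
#'
#' @param calls Call `data.frame` (`chrom`, `start`, `end`, `tsd_seq`,
#'   ...), normally the `confident` component of a `te_calls` object.
#' @param truth Truth `data.frame` from [plant_insertions()].
#' @param tolerance_bp Matching tolerance (bp). Default 100.
#' @return A `te_eval` object: list with `n_truth`, `n_calls`,
#'   `n_true_positive_calls`, `n_recalled_truth`, `sensitivity`,
#'   `specificity`, `tsd_recall` (NA when there are no TP calls).
#' @export
evaluate_calls <- function(calls, truth, tolerance_bp = 100) {
  if (nrow(calls) > 0) {
    unknown <- setdiff(unique(calls$chrom), unique(truth$chrom))
    if (nrow(truth) > 0 && length(unknown) > 0)
      stop("calls on chromosome(s) absent from truth: ",
           paste(unknown, collapse = ", "))
  }
  n_truth <- nrow(truth)
  n_calls <- nrow(calls)
  recalled <- rep(FALSE, n_truth)
  tp <- rep(FALSE, n_calls)
  tsd_ok <- rep(NA, n_calls)
  if (n_calls > 0 && n_truth > 0) {
    cp <- call_positions(calls)
    for (i in seq_len(n_calls)) {
      sel <- which(truth$chrom == calls$chrom[i])
      if (length(sel) == 0) next
      d <- abs(truth$position[sel] - cp[i])
      within <- d <= tolerance_bp
      if (!any(within)) next
      tp[i] <- TRUE
      recalled[sel[within]] <- TRUE
      # matched truth: nearest, ties toward lower coordinate
      cand <- sel[within]
      cand <- cand[order(d[within], truth$position[cand])]
      tsd_ok[i] <- !is.na(calls$tsd_seq[i]) &&
        calls$tsd_seq[i] == truth$tsd_seq[cand[1]]
    }
  }
  n_tp <- sum(tp)
  res <- list(n_truth = n_truth, n_calls = n_calls,
              n_true_positive_calls = n_tp,
              n_recalled_truth = sum(recalled),
              sensitivity = if (n_truth > 0) sum(recalled) / n_truth else NA_real_,
              specificity = if (n_calls > 0) n_tp / n_calls else NA_real_,
              tsd_recall = if (n_tp > 0) sum(tsd_ok[tp]) / n_tp else NA_real_)
  class(res) <- "te_eval"
  res
}

#' @export
print.te_eval <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("Evaluation vs %d truth insertions, %d calls:\n",
              x$n_truth, x$n_calls))
  cat(sprintf("  sensitivity %s  specificity %s  TSD recall %s\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$tsd_recall)))
  invisible(x)
}

#' Run the full plant/simulate/call/evaluate benchmark sweep
#'
#' For each (coverage, replicate) combination: plant insertions into the
#' reference, simulate reads, run the calling pipeline, and score the
#' confident calls against truth. Replicates differ in the planted
#' insertion set and the read sample.
#'
#' @param genome Reference [te_genome()].
#' @param library A [te_library()].
#' @param n_insertions Planted insertions per replicate.
#' @param coverages Numeric vector of sequence depths.
#' @param replicates Number of replicates per coverage.
#' @param seed Base seed; replicate r uses `seed + 1000 * r`.
#' @param error_rate Per-base substitution probability.
#' @param cfg A [te_config()].
#' @param quiet Suppress per-stage progress messages. Default TRUE.
#' @return A `data.frame` with one row per (coverage, replicate):
#'   `coverage`, `replicate`, `n_calls`, `sensitivity`, `specificity`,
#'   `tsd_recall`, plus attribute `"summary"` holding per-coverage mean
#'   and standard deviation of each metric.
#' @export
benchmark_sweep <- function(genome, library, n_insertions = 200,
                            coverages = c(3, 10), replicates = 3, seed = 1,
                            error_rate = 0.01, cfg = te_config(),
                            quiet = TRUE) {
  rows <- list()
  for (r in seq_len(replicates)) {
    rseed <- as.integer(seed + 1000 * r)
    pl <- plant_insertions(genome, library, n = n_insertions, seed = rseed,
                           min_dist = 2 * cfg$window_bp)
    for (cov in coverages) {
      run <- function() {
        pairs <- simulate_reads(pl$genome,
                                read_sim_params(coverage = cov,
                                                error_rate = error_rate,
                                                seed = rseed + 1L))
        calls <- call_te_insertions(pairs, library, genome, cfg)
        evaluate_calls(calls$confident, pl$truth, cfg$match_tolerance_bp)
      }
      ev <- tryCatch(
        if (quiet) suppressMessages(run()) else run(),
        error = function(e)
          stop(sprintf("benchmark (coverage %g, replicate %d): %s",
                       cov, r, conditionMessage(e)), call. = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        coverage = cov, replicate = r, n_calls = ev$n_calls,
        sensitivity = ev$sensitivity, specificity = ev$specificity,
        tsd_recall = ev$tsd_recall)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$coverage, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  agg <- do.call(rbind, lapply(split(out, out$coverage), function(d)
    data.frame(coverage = d$coverage[1],
               mean_sensitivity = mean(d$sensitivity),
               sd_sensitivity = stats::sd(d$sensitivity),
               mean_specificity = mean(d$specificity, na.rm = TRUE),
               sd_specificity = stats::sd(d$specificity),
               mean_tsd_recall = mean(d$tsd_recall, na.rm = TRUE),
               sd_tsd_recall = stats::sd(d$tsd_recall))))
  rownames(agg) <- NULL
  attr(out, "summary") <- agg
  out
}
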