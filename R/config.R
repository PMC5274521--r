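#' Pipeline run configuration
#'
#' Bundles the tunable thresholds of the insertion-calling pipeline. The
#' defaults mirror the standard parameterisation of junction-read TE
#' detection: a read must share at least `len_cut_match` aligned bases
#' (with at most `mismatch` substitutions) with a TE consensus to count as
#' informative, and a trimmed genomic flank must retain at least
#' `len_cut_trim` bases to be mappable.
#'
#' @param len_cut_match Minimum aligned length (bp) between a read and a TE
#'   consensus for a repeat hit. Default 10.
#' @param len_cut_trim Minimum genomic flank length (bp) retained after
#'   trimming the TE portion from a junction read. Default 10.
#' @param mismatch Maximum substitutions tolerated in a repeat hit and in a
#'   reference placement. Default 2.
#' @param window_bp Window width (bp) used to chain mapped reads into
#'   insertion clusters. Default 2000.
#' @param mapq_min Minimum mapping quality a candidate's best junction read
#'   must reach to survive cleaning. Default 29.
#' @param min_cluster_junctions Minimum total junction reads (left + right)
#'   a candidate needs when other candidates in the same cluster survive
#'   cleaning. Default 3.
#' @param annot_proximity_bp Distance (bp) to an annotated reference TE
#'   within which junction-only candidates are removed. Default 10.
#' @param match_tolerance_bp Positional tolerance (bp) used by the
#'   evaluation module when matching calls to truth. Default 100.
#' @param terminus_tol Tolerance (bp) for a repeat hit to count as reaching
#'   a consensus terminus; absorbs sequencing errors at the extreme
#'   junction base. Default 3.
#' @param tsd_slack Maximum distance (bp) between junction breakpoints
#'   grouped into one subcluster; exceeds the longest expected TSD while
#'   separating independent nearby insertions. Default 25.
#' @param seed_len Seed k-mer length of the repeat matcher. Default 7.
#' @param junction_control_len Number of trimmed-off bases adjacent to the
#'   flank compared against the reference in the false-junction control.
#'   Default 30.
#' @param junction_control_frac Mismatch fraction below which the trimmed
#'   portion is judged to continue the reference (the read is contiguous
#'   genomic sequence and the junction is false). Default 0.4.
#' @param supporting_block_score Minimum score (matches minus mismatches)
#'   an internal repeat hit needs to bar its mate from SUPPORTING
#'   promotion. Chance-level short matches against a multi-family library
#'   stay below this; genuine partial TE content exceeds it. Default 20.
#'
#' @return An object of class `te_config` (a validated list).
#' @examples
#' cfg <- te_config(mismatch = 1)
#' cfg$len_cut_match
#' @export
te_config <- function(len_cut_match = 10, len_cut_trim = 10, mismatch = 2,
                      window_bp = 2000, mapq_min = 29,
                      min_cluster_junctions = 3, annot_proximity_bp = 10,
                      match_tolerance_bp = 100, terminus_tol = 3,
                      tsd_slack = 25, seed_len = 7,
                      junction_control_len = 30,
                      junction_control_frac = 0.4,
                      supporting_block_score = 20) {
  cfg <- list(len_cut_match = as.integer(len_cut_match),
              len_cut_trim = as.integer(len_cut_trim),
              mismatch = as.integer(mismatch),
              window_bp = as.integer(window_bp),
              mapq_min = as.integer(mapq_min),
              min_cluster_junctions = as.integer(min_cluster_junctions),
              annot_proximity_bp = as.integer(annot_proximity_bp),
              match_tolerance_bp = as.integer(match_tolerance_bp),
              terminus_tol = as.integer(terminus_tol),
              tsd_slack = as.integer(tsd_slack),
              seed_len = as.integer(seed_len),
              junction_control_len = as.integer(junction_control_len),
              junction_control_frac = as.numeric(junction_control_frac),
              supporting_block_score = as.integer(supporting_block_score))
  num <- vapply(cfg, function(x) x[[1]], numeric(1))
  if (any(is.na(num)) || any(num < 0))
    stop("all te_config values must be non-negative numbers")
  class(cfg) <- "te_config"
  cfg
}

#' @export
print.te_config <- function(x, ...) {
  cat("TE caller configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
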