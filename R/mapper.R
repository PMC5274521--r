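#' Align fragments end-to-end to the reference genome
#'
#' Places each fragment (junction flank, full read or supporting read) on
#' the reference, either strand, allowing at most `max_mismatch`
#' substitutions over the full fragment length (no indels, no clipping:
#' flanks were already trimmed to pure genomic sequence). For every
#' fragment all qualifying placements are found; the best one is reported
#' with `mapq = 60` when it is unique at the minimal mismatch count and
#' `mapq = 0` when two or more co-optimal placements exist. Fragments
#' with no placement are dropped.
#'
#' @param fragments A `data.frame` with a `seq` column and any number of
#'   carry-through columns (`category`, `te_side`, `te_at`, `family`,
#'   `pair`, `mate`, ...), or a plain character vector of sequences.
#' @param genome A [te_genome()].
#' @param max_mismatch Maximum substitutions per placement. Default 2.
#' @return A `data.frame` with one row per placed fragment: the
#'   carry-through columns plus `chrom`, `start0`, `end0` (0-based
#'   half-open), `strand`, `mapq`, `mismatches`, `n_best`.
#' @examples
#' g <- te_genome(c(chr1 = strrep("ACGTTGCA", 50)))
#' align_to_reference(substr(g$seq, 11, 40), g)
#' @export
align_to_reference <- function(fragments, genome, max_mismatch = 2) {
  stopifnot(inherits(genome, "te_genome"))
  if (length(genome$seq) == 0) stop("empty reference")
  if (is.character(fragments))
    fragments <- data.frame(seq = fragments, stringsAsFactors = FALSE)
  if (nrow(fragments) == 0) {
    return(cbind(fragments[0, setdiff(names(fragments), "seq"), drop = FALSE],
                 data.frame(chrom = character(), start0 = integer(),
                            end0 = integer(), strand = character(),
                            mapq = integer(), mismatches = integer(),
                            n_best = integer())))
  }
  al <- cpp_align_end_to_end(toupper(fragments$seq), unname(genome$seq),
                             as.integer(max_mismatch))
  out <- fragments[al$fragment, setdiff(names(fragments), "seq"), drop = FALSE]
  out$chrom <- names(genome$seq)[al$chrom_id]
  out$start0 <- al$start0
  out$end0 <- al$end0
  out$strand <- al$strand
  out$mapq <- al$mapq
  out$mismatches <- al$mismatches
  out$n_best <- al$n_best
  rownames(out) <- NULL
  out
}

#' Sort alignments by chromosome, then start
#'
#' Stable: alignments tied on `(chrom, start0)` keep their input order.
#'
#' @param alignments An alignment `data.frame` (see
#'   [align_to_reference()]).
#' @return The sorted `data.frame`.
#' @export
sort_alignments <- function(alignments) {
  o <- order(alignments$chrom, alignments$start0, method = "radix")
  out <- alignments[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ingest coordinate-sorted alignments from a SAM file
#'
#' Adapter seam for running an external aligner instead of the internal
#' end-to-end mapper. Read categories, TE sides and families are
#' recovered from structured QNAME suffixes written by the repeat-matcher
#' stage (`<id>:<J|F|S>:<5P|3P|NA>:<family>`); MAPQ is taken as-is and
#' only ever compared against `mapq_min` downstream.
#'
#' @param path Path to a SAM file (header lines ignored).
#' @return An alignment `data.frame` compatible with the caller stage.
#' @export
read_sam_alignments <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0) {
    return(data.frame(pair = character(), category = character(),
                      te_side = character(), family = character(),
                      chrom = character(), start0 = integer(),
                      end0 = integer(), strand = character(),
                      mapq = integer(), stringsAsFactors = FALSE))
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  qn <- vapply(f, `[[`, "", 1)
  flag <- as.integer(vapply(f, `[[`, "", 2))
  parts <- strsplit(qn, ":", fixed = TRUE)
  bad <- lengths(parts) < 4
  if (any(bad)) stop("QNAME without category suffix: ", qn[which(bad)[1]])
  cat_code <- vapply(parts, `[[`, "", 2)
  category <- c(J = "JUNCTION", F = "FULL_TE", S = "SUPPORTING")[cat_code]
  if (anyNA(category)) stop("unknown category code in QNAME")
  te_side <- vapply(parts, `[[`, "", 3)
  te_side <- ifelse(te_side == "5P", "TE_5PRIME",
                    ifelse(te_side == "3P", "TE_3PRIME", NA_character_))
  seqlen <- nchar(vapply(f, `[[`, "", 10))
  data.frame(pair = vapply(parts, `[[`, "", 1),
             category = unname(category),
             te_side = te_side,
             family = vapply(parts, `[[`, "", 4),
             chrom = vapply(f, `[[`, "", 3),
             start0 = as.integer(vapply(f, `[[`, "", 4)) - 1L,
             end0 = as.integer(vapply(f, `[[`, "", 4)) - 1L + seqlen,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mapq = as.integer(vapply(f, `[[`, "", 5)),
             stringsAsFactors = FALSE)
}
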