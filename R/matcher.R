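#' Find TE-library matches in a set of reads
#'
#' Runs the internal seed-and-extend ungapped matcher between each read
#' (either strand) and every consensus in the library. A hit is a maximal
#' ungapped local alignment with aligned length >= `cfg$len_cut_match`,
#' at most `cfg$mismatch` substitutions, and containing at least one exact
#' `cfg$seed_len`-mer (the seed requirement mirrors tile-based repeat
#' search engines). Overlapping hits to the same family are reduced to the
#' highest-scoring one; hits to distinct families are all retained.
#'
#' @param reads Character vector of read sequences.
#' @param library A [te_library()].
#' @param cfg A [te_config()].
#' @return A `data.frame` of hits: `read` (index into `reads`), `family`,
#'   `read_start0`/`read_end0` and `te_start0`/`te_end0` (0-based
#'   half-open), `strand` (`+` read matches consensus, `-` read matches
#'   its reverse complement), `mismatches`, `score` (matches minus
#'   mismatches).
#' @examples
#' lib <- te_library("F", strrep("ACGGT", 80), 3)
#' read <- paste0(substr(lib$consensus, 361, 400), strrep("T", 60))
#' find_repeat_hits(read, lib, te_config())
#' @export
find_repeat_hits <- function(reads, library, cfg = te_config()) {
  stopifnot(inherits(library, "te_library"))
  if (nrow(library) == 0) stop("empty TE library")
  if (any(nchar(reads) < cfg$len_cut_match))
    stop("reads must be at least len_cut_match bases long")
  h <- cpp_find_repeat_hits(toupper(reads), library$consensus,
                            cfg$len_cut_match, cfg$mismatch, cfg$seed_len)
  h$family <- library$name[h$te]
  h$te <- NULL
  h[, c("read", "family", "read_start0", "read_end0", "te_start0",
        "te_end0", "strand", "mismatches", "score")]
}

#' Pick the winning TE family among a mate's repeat hits
#'
#' Deterministic rule for reads matching several families: highest score,
#' then fewest mismatches, then lexicographic family name.
#'
#' @param hits A non-empty hit `data.frame` (see [find_repeat_hits()]) for
#'   one mate.
#' @return The winning family name (length-1 character).
#' @export
assign_family <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) stop("assign_family: empty hit list")
  o <- order(-hits$score, hits$mismatches, hits$family, method = "radix")
  hits$family[o[1]]
}

# classification categories shared across modules
TE_CATEGORIES <- c("JUNCTION", "FULL_TE", "SUPPORTING", "UNINFORMATIVE")

# decide the category of one mate from its merged hits; returns a list
# mirroring the C++ bulk classifier (R reference implementation)
classify_mate_r <- function(seq, hits, library, cfg) {
  len <- nchar(seq)
  out <- list(category = "UNINFORMATIVE", family = NA_character_,
              blocked = FALSE, fragments = NULL)
  if (is.null(hits) || nrow(hits) == 0) return(out)
  tlen <- stats::setNames(nchar(library$consensus), library$name)
  reachS <- hits$te_start0 <= cfg$terminus_tol
  reachE <- tlen[hits$family] - hits$te_end0 <= cfg$terminus_tol
  out$blocked <- any(!reachS & !reachE & hits$score >= cfg$supporting_block_score)
  fam <- assign_family(hits)
  out$family <- fam
  fh <- hits[hits$family == fam, , drop = FALSE]
  o <- order(-fh$score, fh$mismatches, fh$read_start0, fh$te_start0,
             fh$strand, method = "radix")
  fh <- fh[o, , drop = FALSE]
  full <- fh$read_start0 < cfg$len_cut_trim &
    (len - fh$read_end0) < cfg$len_cut_trim
  if (any(full)) {
    out$category <- "FULL_TE"
    return(out)
  }
  for (i in seq_len(nrow(fh))) {
    h <- fh[i, ]
    rS <- h$te_start0 <= cfg$terminus_tol
    rE <- tlen[h$family] - h$te_end0 <= cfg$terminus_tol
    leftAdj <- if (h$strand == "+") rS else rE
    rightAdj <- if (h$strand == "+") rE else rS
    # project the trim point to the consensus terminus (a hit may stop a
    # few bases short of it when an error sits at the extreme junction base)
    gL <- unname(if (h$strand == "+") h$te_start0 else
      tlen[h$family] - h$te_end0)
    gR <- unname(if (h$strand == "+") tlen[h$family] - h$te_end0 else
      h$te_start0)
    lf <- if (leftAdj) h$read_start0 - gL else h$read_start0
    rf <- if (rightAdj) len - h$read_end0 - gR else len - h$read_end0
    qualL <- leftAdj && lf >= cfg$len_cut_trim
    qualR <- rightAdj && rf >= cfg$len_cut_trim
    emitL <- qualL && (rf < cfg$len_cut_trim || qualR)
    emitR <- qualR && (lf < cfg$len_cut_trim || qualL)
    if (!emitL && !emitR) next
    frs <- list()
    if (emitL)
      frs[[length(frs) + 1]] <- data.frame(
        flank_start0 = 0L, flank_end0 = h$read_start0 - gL,
        portion_start0 = h$read_start0 - gL,
        portion_end0 = min(len, h$read_start0 - gL + cfg$junction_control_len),
        te_side = if (h$strand == "+") "TE_5PRIME" else "TE_3PRIME",
        te_at = "R", stringsAsFactors = FALSE)
    if (emitR)
      frs[[length(frs) + 1]] <- data.frame(
        flank_start0 = h$read_end0 + gR, flank_end0 = len,
        portion_start0 = max(0L, h$read_end0 + gR - cfg$junction_control_len),
        portion_end0 = h$read_end0 + gR,
        te_side = if (h$strand == "+") "TE_3PRIME" else "TE_5PRIME",
        te_at = "L", stringsAsFactors = FALSE)
    out$category <- "JUNCTION"
    out$fragments <- do.call(rbind, frs)
    rownames(out$fragments) <- NULL
    return(out)
  }
  out
}

#' Classify one read pair into junction / full-TE / supporting categories
#'
#' Reference implementation of the per-pair classification rule:
#' \itemize{
#'   \item a hit covering essentially the whole mate (unmatched overhang
#'     shorter than `len_cut_trim` at both ends) makes it `FULL_TE`;
#'   \item a hit reaching a consensus terminus (within `terminus_tol`)
#'     with a read-side flank of at least `len_cut_trim` on exactly one
#'     side makes it `JUNCTION`, and the flank is retained with its
#'     `te_side`; a hit spanning an entire short consensus with long
#'     flanks on both sides yields two junction fragments;
#'   \item a mate with no hits whose partner is informative becomes
#'     `SUPPORTING`; a hit internal to the consensus blocks this
#'     promotion;
#'   \item everything else is `UNINFORMATIVE`.
#' }
#'
#' @param pair A one-row `data.frame` with `seq1` and `seq2` (see
#'   [read_fastq_pair()]).
#' @param hits1,hits2 Hit `data.frame`s for the two mates, as produced by
#'   [find_repeat_hits()] with the same `cfg`.
#' @param library A [te_library()].
#' @param cfg A [te_config()].
#' @return A list of two classified-read records (`mate1`, `mate2`), each
#'   with `category`, `te_family`, and for junction mates a `fragments`
#'   `data.frame` (flank interval, trimmed-portion interval, `te_side`,
#'   `te_at`) plus `flank_seq`.
#' @export
classify_pair <- function(pair, hits1, hits2, library, cfg = te_config()) {
  c1 <- classify_mate_r(pair$seq1, hits1, library, cfg)
  c2 <- classify_mate_r(pair$seq2, hits2, library, cfg)
  if (c1$category == "UNINFORMATIVE" && !c1$blocked &&
      c2$category %in% c("JUNCTION", "FULL_TE")) {
    c1$category <- "SUPPORTING"; c1$family <- c2$family
  }
  if (c2$category == "UNINFORMATIVE" && !c2$blocked &&
      c1$category %in% c("JUNCTION", "FULL_TE")) {
    c2$category <- "SUPPORTING"; c2$family <- c1$family
  }
  add_flank <- function(cl, seq) {
    if (!is.null(cl$fragments))
      cl$flank_seq <- substring(seq, cl$fragments$flank_start0 + 1,
                                cl$fragments$flank_end0)
    cl
  }
  list(mate1 = add_flank(c1, pair$seq1), mate2 = add_flank(c2, pair$seq2))
}

#' Classify many read pairs at once
#'
#' Bulk (compiled) version of [classify_pair()]: hits are computed
#' internally with the same matcher and every pair is classified in one
#' pass.
#'
#' @param pairs A `data.frame` of read pairs (`read_id`, `seq1`, `seq2`).
#' @param library A [te_library()].
#' @param cfg A [te_config()].
#' @return A list with `categories` (a `data.frame`: `pair`, `category1`,
#'   `category2`, `family1`, `family2`) and `fragments` (one row per
#'   junction fragment: `pair`, `mate`, `family`, flank and trimmed
#'   portion intervals, `te_side`, `te_at`).
#' @export
classify_read_pairs <- function(pairs, library, cfg = te_config()) {
  stopifnot(inherits(library, "te_library"))
  if (nrow(library) == 0) stop("empty TE library")
  rank <- match(library$name, sort(library$name))
  res <- cpp_classify_pairs(toupper(pairs$seq1), toupper(pairs$seq2),
                            library$consensus, rank,
                            cfg$len_cut_match, cfg$len_cut_trim, cfg$mismatch,
                            cfg$seed_len, cfg$terminus_tol,
                            cfg$junction_control_len,
                            cfg$supporting_block_score)
  cats <- data.frame(pair = seq_len(nrow(pairs)),
                     category1 = TE_CATEGORIES[res$category1],
                     category2 = TE_CATEGORIES[res$category2],
                     family1 = library$name[res$family1],
                     family2 = library$name[res$family2],
                     stringsAsFactors = FALSE)
  fr <- res$fragments
  fr$family <- library$name[fr$family_id]
  fr$family_id <- NULL
  list(categories = cats, fragments = fr)
}
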