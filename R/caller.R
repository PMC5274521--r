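revcomp_chr <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

hamming_frac <- function(a, b) {
  # per-element mismatch fraction of equal-length strings
  mapply(function(x, y) {
    rx <- charToRaw(x); ry <- charToRaw(y)
    sum(rx != ry) / length(rx)
  }, a, b, USE.NAMES = FALSE)
}

# genomic side of the TE relative to a mapped junction flank:
# TRUE when the TE lies genomically to the right of the flank (the flank is
# upstream => a LEFT junction)
te_is_genomic_right <- function(te_at, strand) {
  (te_at == "R") == (strand == "+")
}

#' Chain sorted alignments into insertion clusters
#'
#' Alignments whose starts are within `cfg$window_bp` of the previous
#' alignment on the same chromosome join the running cluster; a larger gap
#' starts a new one. Clusters containing no junction alignment are
#' discarded.
#'
#' @param alignments A coordinate-sorted alignment `data.frame` (see
#'   [sort_alignments()]) with a `category` column.
#' @param cfg A [te_config()].
#' @return The junction-bearing subset of `alignments` with an integer
#'   `cluster` column appended.
#' @export
build_clusters <- function(alignments, cfg = te_config()) {
  if (nrow(alignments) == 0) {
    alignments$cluster <- integer(0)
    return(alignments)
  }
  new_chrom <- c(TRUE, alignments$chrom[-1] != alignments$chrom[-nrow(alignments)])
  gap <- c(0L, diff(alignments$start0))
  alignments$cluster <- cumsum(new_chrom | gap > cfg$window_bp)
  keep <- unique(alignments$cluster[alignments$category == "JUNCTION"])
  out <- alignments[alignments$cluster %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refine one insertion cluster into breakpoint subclusters
#'
#' Junction alignments are oriented into left junctions (flank genomically
#' upstream of the TE) and right junctions; a left junction's putative
#' breakpoint is its rightmost aligned base, a right junction's its
#' leftmost. Breakpoints within `cfg$tsd_slack` of each other (single
#' linkage) sharing one TE family form a subcluster; supporting reads of
#' the same family are attached to the nearest subcluster within
#' `cfg$window_bp` and assigned a side by position.
#'
#' @param cluster One cluster's alignments (single chromosome).
#' @param cfg A [te_config()].
#' @return A list of subcluster records (chrom, family, breakpoints,
#'   per-side junction/support counts, best junction mapq, strand votes).
#' @export
refine_subclusters <- function(cluster, cfg = te_config()) {
  jn <- cluster[cluster$category == "JUNCTION", , drop = FALSE]
  if (nrow(jn) == 0) return(list())
  right_te <- te_is_genomic_right(jn$te_at, jn$strand)
  jn$side <- ifelse(right_te, "LEFT", "RIGHT")
  jn$breakpoint0 <- ifelse(right_te, jn$end0 - 1L, jn$start0)
  sup <- cluster[cluster$category == "SUPPORTING", , drop = FALSE]
  subs <- list()
  for (fam in unique(jn$family)) {
    jf <- jn[jn$family == fam, , drop = FALSE]
    jf <- jf[order(jf$breakpoint0), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(jf$breakpoint0) > cfg$tsd_slack))
    for (g in unique(grp)) {
      jg <- jf[grp == g, , drop = FALSE]
      lj <- jg[jg$side == "LEFT", , drop = FALSE]
      rj <- jg[jg$side == "RIGHT", , drop = FALSE]
      vote <- ifelse((jg$side == "LEFT") == (jg$te_side == "TE_5PRIME"), "+", "-")
      subs[[length(subs) + 1]] <- list(
        chrom = jg$chrom[1], family = fam,
        breakpoint_left = if (nrow(lj)) max(lj$breakpoint0) else NA_integer_,
        breakpoint_right = if (nrow(rj)) min(rj$breakpoint0) else NA_integer_,
        left_junction = nrow(lj), right_junction = nrow(rj),
        left_support = 0L, right_support = 0L,
        max_junction_mapq = max(jg$mapq),
        center = (min(jg$breakpoint0) + max(jg$breakpoint0)) / 2,
        te_sides = unique(jg$te_side), votes = unique(vote))
    }
  }
  if (nrow(sup) > 0 && length(subs) > 0) {
    centers <- vapply(subs, `[[`, numeric(1), "center")
    fams <- vapply(subs, `[[`, character(1), "family")
    mid <- (sup$start0 + sup$end0 - 1) / 2
    for (i in seq_len(nrow(sup))) {
      ok <- which(fams == sup$family[i])
      if (length(ok) == 0) next
      d <- abs(centers[ok] - mid[i])
      j <- ok[which.min(d)]
      if (min(d) > cfg$window_bp) next
      if (mid[i] < centers[j])
        subs[[j]]$left_support <- subs[[j]]$left_support + 1L
      else
        subs[[j]]$right_support <- subs[[j]]$right_support + 1L
    }
  }
  subs
}

#' Call a candidate insertion from one subcluster
#'
#' When junctions from both genomic sides exist and their flank alignments
#' overlap (right-flank start not past left-flank end) the overlap is the
#' TSD: its interval is reported 1-based inclusive and its sequence is
#' taken from the reference (never from reads). With both sides but no
#' overlap, or one side only, a single-base position is reported and
#' `tsd_seq` is `NA`.
#'
#' @param sub One subcluster record from [refine_subclusters()].
#' @param genome A [te_genome()].
#' @param cfg A [te_config()].
#' @return A one-row candidate `data.frame`.
#' @export
call_insertion <- function(sub, genome, cfg = te_config()) {
  bl <- sub$breakpoint_left
  br <- sub$breakpoint_right
  tsd <- NA_character_
  if (!is.na(bl) && !is.na(br)) {
    if (br <= bl) {
      start <- br + 1L           # 1-based inclusive TSD interval
      end <- bl + 1L
      tsd <- substring(genome$seq[[sub$chrom]], start, end)
    } else {
      start <- end <- bl + 1L    # breakpoint between the flanks
    }
  } else if (!is.na(bl)) {
    start <- end <- bl + 1L
  } else {
    start <- end <- br + 1L
  }
  strand <- NA_character_
  if (all(c("TE_5PRIME", "TE_3PRIME") %in% sub$te_sides) &&
      length(sub$votes) == 1)
    strand <- sub$votes
  confident <- (sub$left_junction >= 1 &&
                  sub$right_junction + sub$right_support >= 1) ||
    (sub$right_junction >= 1 && sub$left_junction + sub$left_support >= 1)
  data.frame(chrom = sub$chrom, start = as.integer(start),
             end = as.integer(end), family = sub$family, strand = strand,
             tsd_seq = tsd,
             left_junction = sub$left_junction,
             right_junction = sub$right_junction,
             left_support = sub$left_support,
             right_support = sub$right_support,
             max_junction_mapq = sub$max_junction_mapq,
             confidence = if (confident) "CONFIDENT" else "RAW_ONLY",
             stringsAsFactors = FALSE)
}

#' Apply the three cleaning filters and split confident from raw calls
#'
#' Cleaning removes candidates that are (i) only supported by low-quality
#' junction reads (best junction mapq below `cfg$mapq_min`); (iii)
#' supported by junction reads only and within `cfg$annot_proximity_bp`
#' of an annotated reference TE; and (ii) supported by fewer than
#' `cfg$min_cluster_junctions` junction reads in total while another
#' candidate in the same cluster survives (i) and (iii). The raw output
#' keeps every candidate; the confident output keeps survivors whose
#' evidence covers both ends of the insertion.
#'
#' @param candidates Candidate `data.frame` with a `cluster` column.
#' @param annotation Optional reference repeat annotation
#'   (`chrom`, `start`, `end`, `family`).
#' @param cfg A [te_config()].
#' @return `list(confident = ..., raw = ...)`.
#' @export
apply_filters <- function(candidates, annotation = NULL, cfg = te_config()) {
  raw <- candidates
  if (nrow(candidates) == 0)
    return(list(confident = candidates, raw = raw))
  pass_i <- candidates$max_junction_mapq >= cfg$mapq_min
  pass_iii <- rep(TRUE, nrow(candidates))
  if (!is.null(annotation) && nrow(annotation) > 0) {
    junction_only <- candidates$left_support + candidates$right_support == 0
    for (k in which(junction_only)) {
      ann <- annotation[annotation$chrom == candidates$chrom[k], , drop = FALSE]
      if (nrow(ann) == 0) next
      gap <- pmax(ann$start - candidates$end[k], candidates$start[k] - ann$end)
      if (any(gap <= cfg$annot_proximity_bp)) pass_iii[k] <- FALSE
    }
  }
  surv13 <- pass_i & pass_iii
  pass_ii <- rep(TRUE, nrow(candidates))
  nj <- candidates$left_junction + candidates$right_junction
  for (cl in unique(candidates$cluster)) {
    idx <- which(candidates$cluster == cl)
    weak <- idx[nj[idx] < cfg$min_cluster_junctions]
    for (k in weak) if (any(surv13[setdiff(idx, k)])) pass_ii[k] <- FALSE
  }
  keep <- surv13 & pass_ii & candidates$confidence == "CONFIDENT"
  conf <- candidates[keep, , drop = FALSE]
  rownames(conf) <- NULL
  list(confident = conf, raw = raw)
}

# compare the trimmed-off portion of each junction read with the reference
# immediately adjacent to its flank alignment; a low mismatch fraction means
# the read continues the reference (a false junction).  Returns a logical
# keep vector.
junction_control_keep <- function(jaln, genome, cfg) {
  n <- nrow(jaln)
  if (n == 0) return(logical(0))
  keep <- rep(TRUE, n)
  oriented <- ifelse(jaln$strand == "+", jaln$portion_seq,
                     revcomp_chr(jaln$portion_seq))
  adj_right <- te_is_genomic_right(jaln$te_at, jaln$strand)
  plen <- nchar(oriented)
  clen <- nchar(genome$seq)[jaln$chrom]
  avail <- ifelse(adj_right, pmin(plen, clen - jaln$end0), pmin(plen, jaln$start0))
  for (i in seq_len(n)) {
    if (avail[i] < 5) next  # too little context to judge
    if (adj_right[i]) {
      p <- substring(oriented[i], 1, avail[i])
      r <- substring(genome$seq[[jaln$chrom[i]]], jaln$end0[i] + 1,
                     jaln$end0[i] + avail[i])
    } else {
      p <- substring(oriented[i], plen[i] - avail[i] + 1, plen[i])
      r <- substring(genome$seq[[jaln$chrom[i]]], jaln$start0[i] - avail[i] + 1,
                     jaln$start0[i])
    }
    if (hamming_frac(p, r) < cfg$junction_control_frac) keep[i] <- FALSE
  }
  keep
}

#' Call non-reference TE insertions from paired-end reads
#'
#' Runs the full junction-read pipeline: read classification against the
#' TE library, flank trimming, end-to-end mapping of junction flanks,
#' full-TE reads and supporting mates, a false-junction control against
#' the untrimmed read, window clustering, breakpoint subcluster
#' refinement, TSD calling and the three cleaning filters.
#'
#' @param pairs Read pairs (`data.frame` with `read_id`, `seq1`, `seq2`),
#'   e.g. from [read_fastq_pair()] or [simulate_reads()].
#' @param library A [te_library()].
#' @param genome A [te_genome()]; its `annotation` (if any) drives
#'   cleaning rule (iii).
#' @param cfg A [te_config()].
#' @return A `te_calls` object: list with `confident` and `raw` call
#'   `data.frame`s, a `summary` (read category counts, calls per family)
#'   and the `config` used.
#' @examples
#' \donttest{
#' lib <- te_library("toy", paste(sample(c("A","C","G","T"), 600,
#'                                       replace = TRUE), collapse = ""), 3)
#' }
#' @export
call_te_insertions <- function(pairs, library, genome, cfg = te_config()) {
  stopifnot(inherits(library, "te_library"), inherits(genome, "te_genome"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] done at %.1fs", what, proc.time()[["elapsed"]] - t0))
    res
  }
  cls <- stage("classify", classify_read_pairs(pairs, library, cfg))
  cats <- cls$categories
  fr <- cls$fragments

  frag_tab <- stage("collect-fragments", {
    tabs <- list()
    if (nrow(fr) > 0) {
      mate_seq <- ifelse(fr$mate == 1, pairs$seq1[fr$pair], pairs$seq2[fr$pair])
      tabs$junction <- data.frame(
        seq = substring(mate_seq, fr$flank_start0 + 1, fr$flank_end0),
        portion_seq = substring(mate_seq, fr$portion_start0 + 1, fr$portion_end0),
        category = "JUNCTION", family = fr$family, te_side = fr$te_side,
        te_at = fr$te_at, pair = fr$pair, mate = fr$mate,
        stringsAsFactors = FALSE)
    }
    for (m in 1:2) {
      cat_m <- cats[[paste0("category", m)]]
      fam_m <- cats[[paste0("family", m)]]
      for (categ in c("FULL_TE", "SUPPORTING")) {
        sel <- which(cat_m == categ)
        if (length(sel) == 0) next
        tabs[[paste0(categ, m)]] <- data.frame(
          seq = if (m == 1) pairs$seq1[sel] else pairs$seq2[sel],
          portion_seq = NA_character_, category = categ,
          family = fam_m[sel], te_side = NA_character_,
          te_at = NA_character_, pair = sel, mate = m,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, tabs)
  })
  if (is.null(frag_tab)) frag_tab <- data.frame(
    seq = character(), portion_seq = character(), category = character(),
    family = character(), te_side = character(), te_at = character(),
    pair = integer(), mate = integer(), stringsAsFactors = FALSE)

  aln <- stage("map", align_to_reference(frag_tab, genome, cfg$mismatch))

  aln <- stage("junction-control", {
    isj <- aln$category == "JUNCTION"
    keepj <- junction_control_keep(aln[isj, , drop = FALSE], genome, cfg)
    failed <- aln[isj, , drop = FALSE][!keepj, c("pair", "mate")]
    out <- rbind(aln[isj, , drop = FALSE][keepj, , drop = FALSE],
                 aln[!isj, , drop = FALSE])
    if (nrow(failed) > 0) {
      # a junction mate whose every control-checked fragment failed is
      # contiguous genomic sequence; its partner loses SUPPORTING status
      failed_key <- unique(paste(failed$pair, failed$mate))
      passed_key <- unique(paste(out$pair[out$category == "JUNCTION"],
                                 out$mate[out$category == "JUNCTION"]))
      demoted <- setdiff(failed_key, passed_key)
      if (length(demoted) > 0) {
        sup <- out$category == "SUPPORTING"
        partner_key <- paste(out$pair, 3L - out$mate)
        out <- out[!(sup & partner_key %in% demoted), , drop = FALSE]
      }
    }
    out
  })

  aln <- sort_alignments(aln)
  clustered <- stage("cluster", build_clusters(aln, cfg))
  candidates <- stage("call", {
    cand <- list()
    for (cdf in split(clustered, clustered$cluster)) {
      subs <- refine_subclusters(cdf, cfg)
      for (s in subs) {
        row <- call_insertion(s, genome, cfg)
        row$cluster <- cdf$cluster[1]
        cand[[length(cand) + 1]] <- row
      }
    }
    if (length(cand) > 0) do.call(rbind, cand) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 family = character(), strand = character(),
                 tsd_seq = character(), left_junction = integer(),
                 right_junction = integer(), left_support = integer(),
                 right_support = integer(), max_junction_mapq = integer(),
                 confidence = character(), cluster = integer(),
                 stringsAsFactors = FALSE)
  })
  flt <- stage("filter", apply_filters(candidates, genome$annotation, cfg))
  summary <- list(
    n_pairs = nrow(pairs),
    reads_per_category = table(factor(c(cats$category1, cats$category2),
                                      levels = TE_CATEGORIES)),
    calls_per_family = table(flt$confident$family),
    n_confident = nrow(flt$confident),
    n_raw = nrow(flt$raw))
  structure(list(confident = flt$confident, raw = flt$raw,
                 summary = summary, config = cfg),
            class = "te_calls")
}

#' @export
print.te_calls <- function(x, ...) {
  cat(sprintf("TE insertion calls: %d confident / %d raw candidates\n",
              x$summary$n_confident, x$summary$n_raw))
  if (x$summary$n_confident > 0) {
    cat("Confident calls per family:\n")
    print(x$summary$calls_per_family)
  }
  invisible(x)
}

#' @export
summary.te_calls <- function(object, ...) {
  cat(sprintf("Input: %d read pairs\n", object$summary$n_pairs))
  cat("Read categories (both mates):\n")
  print(object$summary$reads_per_category)
  print(object)
  if (object$summary$n_confident > 0) {
    with_tsd <- sum(!is.na(object$confident$tsd_seq))
    cat(sprintf("TSD called for %d/%d confident insertions\n",
                with_tsd, object$summary$n_confident))
  }
  invisible(object)
}

#' Write a call set to the standard output files
#'
#' Writes `ALL.all_nonref_insert.gff` (confident calls) and
#' `ALL.all_nonref_insert.raw.gff` (all candidates) plus a JSON run
#' summary into `dir`.
#'
#' @param calls A `te_calls` object.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_te_calls <- function(calls, dir) {
  stopifnot(inherits(calls, "te_calls"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "ALL.all_nonref_insert.gff")
  f2 <- file.path(dir, "ALL.all_nonref_insert.raw.gff")
  f3 <- file.path(dir, "run_summary.json")
  write_insertions_gff3(calls$confident, f1)
  write_insertions_gff3(calls$raw, f2)
  s <- calls$summary
  jsonlite::write_json(list(
    n_pairs = s$n_pairs,
    reads_per_category = as.list(s$reads_per_category),
    calls_per_family = as.list(s$calls_per_family),
    n_confident = s$n_confident, n_raw = s$n_raw),
    f3, auto_unbox = TRUE)
  invisible(c(f1, f2, f3))
}
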