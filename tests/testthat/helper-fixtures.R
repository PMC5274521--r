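# shared fixtures and independent oracles, built in code

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp1 <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

small_library <- function(seed = 11, lens = c(400, 250, 600),
                          tsd = c(3, 5, 9)) {
  set.seed(seed)
  te_library(paste0("fam", seq_along(lens)),
             vapply(lens, function(l) rand_dna(l), character(1)), tsd)
}

# ---- brute-force repeat-hit oracle -----------------------------------------
# Exhaustively enumerates every maximal ungapped local alignment between the
# read (either strand) and each consensus with length >= len_cut_match and
# mismatches <= max_mismatch, then keeps those containing an exact run of at
# least seed_len bases (the matcher's documented detectability criterion),
# and finally reduces overlapping same-family hits to the highest scorer.
oracle_repeat_hits <- function(read, library, cfg) {
  wins <- list()
  for (strand in c("+", "-")) {
    r <- if (strand == "+") read else revcomp1(read)
    rl <- nchar(r)
    rv <- strsplit(r, "")[[1]]
    for (ti in seq_len(nrow(library))) {
      tv <- strsplit(library$consensus[ti], "")[[1]]
      tl <- length(tv)
      for (diag in (-(tl - 1)):(rl - 1)) {
        # overlap of read[i] vs te[i - diag]
        i0 <- max(0, diag)
        i1 <- min(rl - 1, tl - 1 + diag)
        if (i1 - i0 + 1 < cfg$len_cut_match) next
        seg_r <- rv[(i0:i1) + 1]
        seg_t <- tv[(i0:i1) - diag + 1]
        mmv <- which(seg_r != seg_t) - 1L   # 0-based within segment
        lg <- i1 - i0 + 1
        p <- c(-1L, mmv, lg)
        k <- length(mmv)
        for (i in 0:k) {
          s <- p[i + 1] + 1L
          e <- if (i + cfg$mismatch + 1 <= k) p[i + cfg$mismatch + 2] else lg
          if (e - s < cfg$len_cut_match) next
          inc <- mmv[mmv >= s & mmv < e]
          # longest exact run inside the window
          runs <- diff(c(s - 1L, inc, e)) - 1L
          if (max(runs) < cfg$seed_len) next
          rs_o <- i0 + s; re_o <- i0 + e
          ts <- rs_o - diag; tee <- re_o - diag
          rs <- if (strand == "-") rl - re_o else rs_o
          re <- if (strand == "-") rl - rs_o else re_o
          wins[[length(wins) + 1]] <- data.frame(
            family = library$name[ti], read_start0 = rs, read_end0 = re,
            te_start0 = ts, te_end0 = tee, strand = strand,
            mismatches = length(inc),
            score = (e - s) - 2L * length(inc), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(wins) == 0)
    return(data.frame(family = character(), read_start0 = integer(),
                      read_end0 = integer(), te_start0 = integer(),
                      te_end0 = integer(), strand = character(),
                      mismatches = integer(), score = integer(),
                      stringsAsFactors = FALSE))
  w <- unique(do.call(rbind, wins))
  o <- order(-w$score, w$mismatches, w$read_start0, w$te_start0, w$strand,
             method = "radix")
  w <- w[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(w))
  for (i in seq_len(nrow(w))) {
    if (!keep[i]) next
    if (i == 1) next
    prev <- which(keep[seq_len(i - 1)])
    ov <- w$family[prev] == w$family[i] &
      w$read_start0[prev] < w$read_end0[i] &
      w$read_start0[i] < w$read_end0[prev]
    if (any(ov)) keep[i] <- FALSE
  }
  w <- w[keep, , drop = FALSE]
  rownames(w) <- NULL
  w
}

canon_hits <- function(h) {
  h <- h[, c("family", "read_start0", "read_end0", "te_start0", "te_end0",
             "strand", "mismatches", "score")]
  h <- h[order(h$family, h$read_start0, h$te_start0, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# ---- brute-force end-to-end placement oracle -------------------------------
oracle_align <- function(frag, genome, max_mismatch = 2) {
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") frag else revcomp1(frag)
    qr <- charToRaw(q)
    L <- length(qr)
    for (ch in names(genome$seq)) {
      gr <- charToRaw(genome$seq[[ch]])
      if (length(gr) < L) next
      for (g in 0:(length(gr) - L)) {
        mm <- sum(gr[(g + 1):(g + L)] != qr)
        if (mm <= max_mismatch)
          out[[length(out) + 1]] <- data.frame(
            chrom = ch, start0 = g, end0 = g + L, strand = strand,
            mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# ---- cached desk-scale benchmark used by the acceptance tests --------------
.bench_cache <- new.env(parent = emptyenv())

acceptance_benchmark <- function() {
  if (!is.null(.bench_cache$res)) return(.bench_cache$res)
  lib <- te_fixture_library()
  gen <- random_genome(c(chr1 = 2e6), seed = 424242)
  rows <- list()
  for (r in 1:3) {
    pl <- plant_insertions(gen, lib, n = 200, seed = 9000L + r)
    for (cov in c(3, 10, 20)) {
      pairs <- simulate_reads(pl$genome,
                              read_sim_params(coverage = cov,
                                              error_rate = 0.01,
                                              seed = 9100L + r))
      calls <- suppressMessages(call_te_insertions(pairs, lib, gen))
      ev <- evaluate_calls(calls$confident, pl$truth)
      rows[[length(rows) + 1]] <- data.frame(
        coverage = cov, replicate = r,
        n_calls = ev$n_calls, sensitivity = ev$sensitivity,
        specificity = ev$specificity, tsd_recall = ev$tsd_recall)
      if (is.null(.bench_cache$example))
        .bench_cache$example <- list(calls = calls, truth = pl$truth,
                                     genome = gen)
    }
  }
  .bench_cache$res <- do.call(rbind, rows)
  .bench_cache$res
}

acceptance_example <- function() {
  acceptance_benchmark()
  .bench_cache$example
}
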