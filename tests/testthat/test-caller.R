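cfg <- te_config()

mk_aln <- function(chrom, start0, len = 60, category = "JUNCTION",
                   family = "fam1", te_at = "R", strand = "+", mapq = 60,
                   te_side = "TE_5PRIME") {
  data.frame(chrom = chrom, start0 = start0, end0 = start0 + len,
             strand = strand, mapq = mapq, category = category,
             family = family, te_side = te_side, te_at = te_at,
             stringsAsFactors = FALSE)
}

test_that("window chaining groups nearby starts and splits distant ones", {
  a <- sort_alignments(rbind(mk_aln("chr1", 1000), mk_aln("chr1", 1100)))
  expect_equal(unique(build_clusters(a, cfg)$cluster), 1)
  b <- sort_alignments(rbind(mk_aln("chr1", 1000), mk_aln("chr1", 4000)))
  expect_equal(unique(build_clusters(b, cfg)$cluster), c(1, 2))
  # supporting-only region yields no cluster
  s <- sort_alignments(mk_aln("chr1", 1000, category = "SUPPORTING"))
  expect_equal(nrow(build_clusters(s, cfg)), 0)
})

test_that("subcluster refinement counts sides and attaches support", {
  rows <- list()
  for (i in 1:5) rows[[length(rows) + 1]] <-
    mk_aln("chr1", 940 + i, len = 60, te_at = "R")   # left: breakpoints ~1000
  for (i in 1:4) rows[[length(rows) + 1]] <-
    mk_aln("chr1", 998 + i, len = 60, te_at = "L", te_side = "TE_3PRIME")
  rows[[length(rows) + 1]] <- mk_aln("chr1", 400, category = "SUPPORTING")
  rows[[length(rows) + 1]] <- mk_aln("chr1", 1500, category = "SUPPORTING")
  cl <- build_clusters(sort_alignments(do.call(rbind, rows)), cfg)
  subs <- refine_subclusters(cl, cfg)
  expect_length(subs, 1)
  expect_equal(subs[[1]]$left_junction, 5)
  expect_equal(subs[[1]]$right_junction, 4)
  expect_equal(subs[[1]]$left_support, 1)
  expect_equal(subs[[1]]$right_support, 1)
})

test_that("a single junction read forms a one-sided subcluster", {
  cl <- build_clusters(sort_alignments(mk_aln("chr1", 500)), cfg)
  subs <- refine_subclusters(cl, cfg)
  expect_length(subs, 1)
  expect_equal(subs[[1]]$left_junction + subs[[1]]$right_junction, 1)
})

test_that("overlapping flanks define the TSD from the reference", {
  gen <- random_genome(c(chr1 = 5000), seed = 19)
  # left junctions end at 0-based 1002 inclusive; right junctions start at 1000
  rows <- rbind(mk_aln("chr1", 943, len = 60, te_at = "R"),
                mk_aln("chr1", 1000, len = 60, te_at = "L",
                       te_side = "TE_3PRIME"))
  cl <- build_clusters(sort_alignments(rows), cfg)
  subs <- refine_subclusters(cl, cfg)
  ins <- call_insertion(subs[[1]], gen, cfg)
  expect_equal(ins$start, 1001)
  expect_equal(ins$end, 1003)
  expect_equal(ins$tsd_seq, substring(gen$seq[["chr1"]], 1001, 1003))
  expect_equal(ins$strand, "+")
  expect_equal(ins$confidence, "CONFIDENT")
})

test_that("one junction plus opposite-side support is confident without TSD", {
  gen <- random_genome(c(chr1 = 5000), seed = 20)
  rows <- rbind(mk_aln("chr1", 943, len = 60, te_at = "R"),
                mk_aln("chr1", 1400, category = "SUPPORTING"))
  cl <- build_clusters(sort_alignments(rows), cfg)
  subs <- refine_subclusters(cl, cfg)
  ins <- call_insertion(subs[[1]], gen, cfg)
  expect_equal(ins$confidence, "CONFIDENT")
  expect_true(is.na(ins$tsd_seq))
  # but a lone junction read stays raw-only
  lone <- refine_subclusters(build_clusters(sort_alignments(
    mk_aln("chr1", 943, len = 60)), cfg), cfg)
  expect_equal(call_insertion(lone[[1]], gen, cfg)$confidence, "RAW_ONLY")
})

test_that("cleaning rules drop low-mapq, weak-in-window and annotated hits", {
  cand <- function(start, nj, mapq = 60, support = 1L, cluster = 1L,
                   conf = "CONFIDENT") {
    data.frame(chrom = "chr1", start = start, end = start, family = "fam1",
               strand = NA_character_, tsd_seq = NA_character_,
               left_junction = nj, right_junction = 0L, left_support = 0L,
               right_support = support, max_junction_mapq = mapq,
               confidence = conf, cluster = cluster, stringsAsFactors = FALSE)
  }
  # rule i
  r <- apply_filters(cand(100, 5L, mapq = 20), NULL, cfg)
  expect_equal(nrow(r$confident), 0)
  expect_equal(nrow(r$raw), 1)
  # rule ii: A (6 junctions) and B (2 junctions) share a window
  ab <- rbind(cand(100, 6L), cand(900, 2L))
  r2 <- apply_filters(ab, NULL, cfg)
  expect_equal(r2$confident$start, 100)
  # B alone in its window survives
  r2b <- apply_filters(cand(900, 2L), NULL, cfg)
  expect_equal(nrow(r2b$confident), 1)
  # rule iii: junction-only candidate 5 bp from an annotated repeat
  ann <- data.frame(chrom = "chr1", start = 110, end = 200, family = "old")
  r3 <- apply_filters(cand(105, 5L, support = 0L), ann, cfg)
  expect_equal(nrow(r3$confident), 0)
  # with supporting evidence it survives the same annotation
  r3b <- apply_filters(cand(105, 5L, support = 2L), ann, cfg)
  expect_equal(nrow(r3b$confident), 1)
})

test_that("zero reads produce header-only GFF3 outputs", {
  lib <- small_library()
  gen <- random_genome(c(chr1 = 20000), seed = 22)
  pairs <- data.frame(read_id = character(), seq1 = character(),
                      qual1 = character(), seq2 = character(),
                      qual2 = character(), stringsAsFactors = FALSE)
  calls <- suppressMessages(call_te_insertions(pairs, lib, gen, cfg))
  expect_equal(nrow(calls$confident), 0)
  d <- tempfile()
  write_te_calls(calls, d)
  expect_identical(readLines(file.path(d, "ALL.all_nonref_insert.gff")),
                   "##gff-version 3")
  expect_identical(readLines(file.path(d, "ALL.all_nonref_insert.raw.gff")),
                   "##gff-version 3")
})

test_that("two insertions in one window resolve into distinct subclusters", {
  lib <- te_library(c("shortA", "shortB"),
                    c(rand_dna(350, seed = 23), rand_dna(300, seed = 24)),
                    c(3, 5))
  gen <- random_genome(c(chr1 = 60000), seed = 25)
  # plant two insertions ~900 bp apart by direct splicing
  p1 <- 30000L; p2 <- 30900L
  g <- gen$seq[["chr1"]]
  mut <- paste0(substring(g, 1, p1),
                substring(g, p1 + 1, p1 + 3), lib$consensus[1],
                substring(g, p1 + 1, p2),
                substring(g, p2 + 1, p2 + 5), lib$consensus[2],
                substring(g, p2 + 1, nchar(g)))
  pairs <- simulate_reads(te_genome(c(chr1 = mut)),
                          read_sim_params(coverage = 20, error_rate = 0,
                                          seed = 26))
  calls <- suppressMessages(call_te_insertions(pairs, lib, gen, cfg))
  expect_equal(nrow(calls$confident), 2)
  expect_setequal(calls$confident$family, c("shortA", "shortB"))
  cc <- calls$confident[order(calls$confident$start), ]
  expect_lt(abs(cc$start[1] - p1), 10)
  expect_lt(abs(cc$start[2] - p2), 10)
  # both subclusters came from a shared cluster window
  expect_equal(length(unique(cc$cluster)), 1)
})

test_that("end-to-end: planted insertions are recovered with exact TSDs", {
  lib <- small_library(seed = 27)
  gen <- random_genome(c(chr1 = 250000), seed = 28)
  bm <- simulate_te_benchmark(gen, lib, n_insertions = 12, coverage = 20,
                              seed = 29, error_rate = 0)
  calls <- suppressMessages(call_te_insertions(bm$pairs, lib, gen, cfg))
  ev <- evaluate_calls(calls$confident, bm$truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$tsd_recall, 1)
  # every reported TSD equals the reference substring at its interval
  for (i in seq_len(nrow(calls$raw))) {
    if (is.na(calls$raw$tsd_seq[i])) next
    expect_equal(calls$raw$tsd_seq[i],
                 substring(gen$seq[[calls$raw$chrom[i]]], calls$raw$start[i],
                           calls$raw$end[i]))
  }
  # confident is a subset of raw (as record sets)
  key <- function(d) paste(d$chrom, d$start, d$end, d$family)
  expect_true(all(key(calls$confident) %in% key(calls$raw)))
})

test_that("the caller is byte-deterministic for fixed reads and config", {
  lib <- small_library(seed = 33)
  gen <- random_genome(c(chr1 = 80000), seed = 34)
  bm <- simulate_te_benchmark(gen, lib, n_insertions = 4, coverage = 10,
                              seed = 35)
  c1 <- suppressMessages(call_te_insertions(bm$pairs, lib, gen, cfg))
  c2 <- suppressMessages(call_te_insertions(bm$pairs, lib, gen, cfg))
  d1 <- tempfile(); d2 <- tempfile()
  write_te_calls(c1, d1); write_te_calls(c2, d2)
  expect_identical(readLines(file.path(d1, "ALL.all_nonref_insert.gff")),
                   readLines(file.path(d2, "ALL.all_nonref_insert.gff")))
  expect_identical(readLines(file.path(d1, "ALL.all_nonref_insert.raw.gff")),
                   readLines(file.path(d2, "ALL.all_nonref_insert.raw.gff")))
})
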