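cfg <- te_config()

test_that("an exact terminal substring yields the expected single hit", {
  lib <- small_library()
  L <- nchar(lib$consensus[1])
  read <- paste0(substring(lib$consensus[1], L - 39, L), rand_dna(60, seed = 2))
  h <- find_repeat_hits(read, lib, cfg)
  top <- h[h$score == max(h$score), ]
  expect_equal(nrow(top), 1)
  expect_equal(top$family, "fam1")
  expect_equal(top$read_start0, 0)
  expect_equal(top$read_end0, 40)
  expect_equal(top$te_start0, L - 40)
  expect_equal(top$te_end0, L)
  expect_equal(top$strand, "+")
  expect_equal(top$mismatches, 0)
})

test_that("a read with no shared stretch produces no hits", {
  lib <- te_library("homo", strrep("A", 500), 3)
  read <- strrep("CT", 50)
  expect_equal(nrow(find_repeat_hits(read, lib, cfg)), 0)
  expect_error(find_repeat_hits(read, lib[0, ], cfg), "empty")
})

test_that("family assignment is deterministic under ties", {
  h <- data.frame(family = c("F1", "F2"), score = c(38L, 20L),
                  mismatches = c(0L, 0L))
  expect_equal(assign_family(h), "F1")
  h2 <- data.frame(family = c("beta", "alpha"), score = c(10L, 10L),
                   mismatches = c(1L, 1L))
  expect_equal(assign_family(h2), "alpha")
  expect_equal(assign_family(h[1, ]), "F1")
  expect_error(assign_family(h[0, ]), "empty")
})

test_that("matcher equals the exhaustive oracle on random and seeded reads", {
  lib <- small_library(seed = 31, lens = c(300, 200), tsd = c(3, 5))
  set.seed(77)
  reads <- character(0)
  for (i in 1:25) reads <- c(reads, rand_dna(100))
  # seeded reads that contain genuine TE fragments at assorted offsets
  for (i in 1:15) {
    ti <- sample(1:2, 1)
    tl <- nchar(lib$consensus[ti])
    w <- sample(12:60, 1)
    ts <- sample(tl - w + 1, 1)
    piece <- substring(lib$consensus[ti], ts, ts + w - 1)
    if (runif(1) < 0.5) piece <- revcomp1(piece)
    # sprinkle up to 2 substitutions
    nmm <- sample(0:2, 1)
    if (nmm > 0) {
      at <- sample(w, nmm)
      pv <- strsplit(piece, "")[[1]]
      pv[at] <- sample(c("A", "C", "G", "T"), nmm, replace = TRUE)
      piece <- paste(pv, collapse = "")
    }
    pre <- rand_dna(sample(0:40, 1))
    reads <- c(reads, paste0(pre, piece, rand_dna(100 - nchar(pre) - w)))
  }
  got <- find_repeat_hits(reads, lib, cfg)
  for (i in seq_along(reads)) {
    expect_equal(canon_hits(got[got$read == i, , drop = FALSE]),
                 canon_hits(oracle_repeat_hits(reads[i], lib, cfg)),
                 info = paste("read", i))
  }
})

test_that("a full-TE mate keeps its genomic partner as supporting", {
  lib <- small_library()
  inside <- substring(lib$consensus[3], 101, 200)
  genomic <- rand_dna(100, seed = 41)
  pair <- data.frame(seq1 = inside, seq2 = genomic)
  h1 <- find_repeat_hits(inside, lib, cfg)
  h2 <- find_repeat_hits(genomic, lib, cfg)
  cl <- classify_pair(pair, h1, h2, lib, cfg)
  expect_equal(cl$mate1$category, "FULL_TE")
  expect_equal(cl$mate1$family, "fam3")
  expect_equal(cl$mate2$category, "SUPPORTING")
  expect_equal(cl$mate2$family, "fam3")
})

test_that("junction mates are trimmed to their genomic flank", {
  lib <- small_library()
  L1 <- nchar(lib$consensus[1])
  flank <- rand_dna(65, seed = 13)
  read <- paste0(substring(lib$consensus[1], L1 - 34, L1), flank)
  pair <- data.frame(seq1 = read, seq2 = rand_dna(100, seed = 14))
  cl <- classify_pair(pair, find_repeat_hits(read, lib, cfg),
                      find_repeat_hits(pair$seq2, lib, cfg), lib, cfg)
  expect_equal(cl$mate1$category, "JUNCTION")
  expect_equal(cl$mate1$flank_seq, flank)
  expect_equal(cl$mate1$fragments$te_side, "TE_3PRIME")
  # trimming conservation: the flank is a verbatim substring of the mate
  expect_true(grepl(cl$mate1$flank_seq, read, fixed = TRUE))
})

test_that("a flank shorter than len_cut_trim yields no junction fragment", {
  lib <- small_library()
  read <- paste0(substring(lib$consensus[1], 1, 92), rand_dna(8, seed = 15))
  # TE 5' start is at the read start: flank would be on the right, 8 bp < 10
  cl <- classify_pair(data.frame(seq1 = read, seq2 = rand_dna(100, seed = 16)),
                      find_repeat_hits(read, lib, cfg), NULL, lib, cfg)
  expect_false(cl$mate1$category == "JUNCTION")
})

test_that("a read spanning a short consensus yields two junction fragments", {
  short_lib <- te_library("tiny", rand_dna(40, seed = 99), 3)
  read <- paste0(rand_dna(30, seed = 100), short_lib$consensus,
                 rand_dna(30, seed = 101))
  cl <- classify_pair(data.frame(seq1 = read, seq2 = rand_dna(100, seed = 17)),
                      find_repeat_hits(read, short_lib, cfg), NULL,
                      short_lib, cfg)
  expect_equal(cl$mate1$category, "JUNCTION")
  expect_equal(nrow(cl$mate1$fragments), 2)
  expect_setequal(cl$mate1$fragments$te_side, c("TE_5PRIME", "TE_3PRIME"))
})

test_that("substantial internal TE content blocks supporting promotion", {
  lib <- small_library()
  # 40 bp from the middle of fam1 embedded in genomic sequence
  piece <- substring(lib$consensus[1], 150, 189)
  withTE <- paste0(rand_dna(30, seed = 51), piece, rand_dna(30, seed = 52))
  full <- substring(lib$consensus[3], 1, 100)
  cl <- classify_pair(data.frame(seq1 = full, seq2 = withTE),
                      find_repeat_hits(full, lib, cfg),
                      find_repeat_hits(withTE, lib, cfg), lib, cfg)
  expect_equal(cl$mate1$category, "FULL_TE")
  expect_equal(cl$mate2$category, "UNINFORMATIVE")
})

test_that("bulk classification agrees with the per-pair reference", {
  lib <- small_library(seed = 61)
  set.seed(62)
  n <- 60
  mk_read <- function() {
    kind <- sample(c("genomic", "junction", "full", "partial"), 1)
    if (kind == "genomic") return(rand_dna(100))
    ti <- sample(nrow(lib), 1)
    tl <- nchar(lib$consensus[ti])
    if (kind == "full") {
      s <- sample(tl - 99, 1)
      return(substring(lib$consensus[ti], s, s + 99))
    }
    if (kind == "junction") {
      w <- sample(15:85, 1)
      if (runif(1) < 0.5)
        return(paste0(substring(lib$consensus[ti], tl - w + 1, tl),
                      rand_dna(100 - w)))
      return(paste0(rand_dna(100 - w), substring(lib$consensus[ti], 1, w)))
    }
    w <- sample(15:60, 1)
    s <- sample(seq(2, tl - w), 1)
    p <- rand_dna(sample(0:(100 - w), 1))
    paste0(p, substring(lib$consensus[ti], s, s + w - 1),
           rand_dna(100 - nchar(p) - w))
  }
  pairs <- data.frame(seq1 = replicate(n, mk_read()),
                      seq2 = replicate(n, mk_read()),
                      stringsAsFactors = FALSE)
  bulk <- classify_read_pairs(pairs, lib, cfg)
  for (i in seq_len(n)) {
    ref <- classify_pair(pairs[i, ], find_repeat_hits(pairs$seq1[i], lib, cfg),
                         find_repeat_hits(pairs$seq2[i], lib, cfg), lib, cfg)
    expect_equal(bulk$categories$category1[i], ref$mate1$category,
                 info = paste("pair", i, "mate1"))
    expect_equal(bulk$categories$category2[i], ref$mate2$category,
                 info = paste("pair", i, "mate2"))
    bf <- bulk$fragments[bulk$fragments$pair == i, , drop = FALSE]
    nref <- sum(!is.null(ref$mate1$fragments) && nrow(ref$mate1$fragments),
                !is.null(ref$mate2$fragments) && nrow(ref$mate2$fragments))
    for (m in 1:2) {
      rf <- if (m == 1) ref$mate1$fragments else ref$mate2$fragments
      bfm <- bf[bf$mate == m, c("flank_start0", "flank_end0", "te_side",
                                "te_at"), drop = FALSE]
      rownames(bfm) <- NULL
      if (is.null(rf)) {
        expect_equal(nrow(bfm), 0, info = paste("pair", i, "mate", m))
      } else {
        expect_equal(bfm, rf[, c("flank_start0", "flank_end0", "te_side",
                                 "te_at")], info = paste("pair", i, "mate", m))
      }
    }
  }
})

test_that("category partition and determinism hold over random pairs", {
  lib <- small_library(seed = 71)
  set.seed(72)
  pairs <- data.frame(seq1 = replicate(40, rand_dna(100)),
                      seq2 = replicate(40, rand_dna(100)),
                      stringsAsFactors = FALSE)
  a <- classify_read_pairs(pairs, lib, cfg)
  b <- classify_read_pairs(pairs, lib, cfg)
  expect_identical(a, b)
  expect_true(all(a$categories$category1 %in%
                    c("JUNCTION", "FULL_TE", "SUPPORTING", "UNINFORMATIVE")))
  # SUPPORTING requires an informative partner
  sup1 <- a$categories$category1 == "SUPPORTING"
  expect_true(all(a$categories$category2[sup1] %in% c("JUNCTION", "FULL_TE")))
  sup2 <- a$categories$category2 == "SUPPORTING"
  expect_true(all(a$categories$category1[sup2] %in% c("JUNCTION", "FULL_TE")))
})
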