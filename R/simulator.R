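#' Generate a random reference genome
#'
#' Uniform random ACGT sequence; a low-repeat stand-in for euchromatic
#' chromosome sequence in the simulation benchmark.
#'
#' @param lengths Named integer vector of chromosome lengths.
#' @param seed Integer seed.
#' @return A [te_genome()].
#' @export
random_genome <- function(lengths = c(chr1 = 2e6), seed = 1) {
  set.seed(seed)
  seqs <- vapply(lengths, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  te_genome(seqs)
}

#' Plant random TE insertions with TSDs into a genome
#'
#' Draws `n` insertion sites across the genome (uniformly, proportional to
#' chromosome length) with a minimum pairwise distance of
#' `2 * window_bp` so that truth sites stay unambiguous under the
#' evaluation tolerance. At each site the TSD motif — the `tsd_len`
#' reference bases immediately following the site — is duplicated and a
#' random family's consensus (random strand) is inserted between the two
#' copies.
#'
#' @param genome A [te_genome()].
#' @param library A [te_library()].
#' @param n Number of insertions. Default 200.
#' @param seed Integer seed.
#' @param min_dist Minimum pairwise distance between sites (bp).
#' @param margin Minimum distance of a site from either chromosome end.
#' @return A list: `genome` (the mutated [te_genome()]) and `truth`
#'   (a `data.frame`: `chrom`, `position` — the 1-based base after which
#'   the element was inserted, in original reference coordinates —
#'   `family`, `strand`, `tsd_seq`), sorted by position.
#' @export
plant_insertions <- function(genome, library, n = 200, seed = 1,
                             min_dist = 2 * 2000, margin = 1000) {
  stopifnot(inherits(genome, "te_genome"), inherits(library, "te_library"),
            n >= 1)
  set.seed(seed)
  clen <- nchar(genome$seq)
  chrom_of_site <- sample(names(clen), n, replace = TRUE,
                          prob = clen / sum(clen))
  counts <- table(factor(chrom_of_site, levels = names(clen)))
  truth <- list()
  mutated <- genome$seq
  for (ch in names(clen)) {
    m <- as.integer(counts[[ch]])
    if (m == 0) next
    avail <- clen[[ch]] - 2 * margin - (m - 1) * min_dist
    if (avail <= 0)
      stop("genome too short for ", m, " sites with min distance ", min_dist,
           " on ", ch)
    u <- sort(stats::runif(m, 0, avail))
    pos <- as.integer(floor(u)) + margin + (seq_len(m) - 1L) * min_dist
    fam_idx <- sample.int(nrow(library), m, replace = TRUE)
    strand <- sample(c("+", "-"), m, replace = TRUE)
    tsd_len <- library$tsd_len[fam_idx]
    motif <- substring(genome$seq[[ch]], pos + 1, pos + tsd_len)
    te_seq <- library$consensus[fam_idx]
    te_seq[strand == "-"] <- revcomp_chr(te_seq[strand == "-"])
    # splice motif+TE after each site (original motif copy stays in place)
    pieces <- character(2 * m + 1)
    prev <- 0L
    for (i in seq_len(m)) {
      pieces[2 * i - 1] <- substring(genome$seq[[ch]], prev + 1, pos[i])
      pieces[2 * i] <- paste0(motif[i], te_seq[i])
      prev <- pos[i]
    }
    pieces[2 * m + 1] <- substring(genome$seq[[ch]], prev + 1, clen[[ch]])
    mutated[[ch]] <- paste(pieces, collapse = "")
    truth[[ch]] <- data.frame(chrom = ch, position = pos,
                              family = library$name[fam_idx],
                              strand = strand, tsd_seq = motif,
                              stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$chrom, truth$position), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = te_genome(mutated), truth = truth)
}

#' Read-simulation parameters
#'
#' @param read_len Read length (bp). Default 100.
#' @param coverage Mean sequence depth (fold).
#' @param insert_mean Mean fragment (insert) length. Default 500.
#' @param insert_sd Fragment length standard deviation. Default 100.
#' @param error_rate Per-base substitution probability. Default 0.01.
#' @param seed Integer seed.
#' @return A validated list of class `read_sim_params`.
#' @export
read_sim_params <- function(read_len = 100, coverage = 10, insert_mean = 500,
                            insert_sd = 100, error_rate = 0.01, seed = 1) {
  stopifnot(read_len <= insert_mean, coverage > 0, error_rate >= 0,
            error_rate <= 1)
  structure(list(read_len = as.integer(read_len), coverage = coverage,
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.numeric(insert_sd),
                 error_rate = as.numeric(error_rate),
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  widths <- nchar(seqs)
  big <- paste(seqs, collapse = "")
  raw <- charToRaw(big)
  total <- length(raw)
  n_err <- stats::rbinom(1, total, error_rate)
  if (n_err == 0) return(seqs)
  at <- sample.int(total, n_err)
  # substitute with one of the three other bases, uniformly
  bases <- charToRaw("ACGT")
  cur <- raw[at]
  pick <- sample.int(3, n_err, replace = TRUE)
  new <- raw[at]
  for (b in seq_along(bases)) {
    sel <- cur == bases[b]
    if (any(sel)) {
      others <- bases[-b]
      new[sel] <- others[pick[sel]]
    }
  }
  raw[at] <- new
  ends <- cumsum(widths)
  substring(rawToChar(raw), c(1, ends[-length(ends)] + 1), ends)
}

#' Simulate paired-end reads from a genome
#'
#' Draws `N = ceiling(coverage * genome_length / (2 * read_len))`
#' fragments: starts uniform over the genome (chromosome picked
#' proportional to length), lengths normal
#' `(insert_mean, insert_sd)` truncated to
#' `[read_len, 2 * insert_mean]`. Mate 1 is the fragment's 5' `read_len`
#' bases; mate 2 the reverse complement of its 3' `read_len` bases.
#' Substitution errors are applied per base with probability
#' `error_rate`; qualities are constant Q30. Fully seeded and
#' deterministic.
#'
#' @param genome A [te_genome()].
#' @param params A [read_sim_params()].
#' @return A `data.frame` of pairs: `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @export
simulate_reads <- function(genome, params) {
  stopifnot(inherits(genome, "te_genome"), inherits(params, "read_sim_params"))
  set.seed(params$seed)
  clen <- nchar(genome$seq)
  glen <- sum(clen)
  rl <- params$read_len
  n <- as.integer(ceiling(params$coverage * glen / (2 * rl)))
  chrom <- sample(names(clen), n, replace = TRUE, prob = clen / sum(clen))
  flen <- pmin(pmax(as.integer(round(
    stats::rnorm(n, params$insert_mean, params$insert_sd))), rl),
    2L * params$insert_mean)
  flen <- pmin(flen, clen[chrom])  # degenerate tiny chromosomes
  start1 <- floor(stats::runif(n) * (clen[chrom] - flen + 1)) + 1  # 1-based
  m1 <- substring(genome$seq[chrom], start1, start1 + rl - 1)
  m2 <- revcomp_chr(substring(genome$seq[chrom], start1 + flen - rl,
                              start1 + flen - 1))
  m1 <- apply_substitutions(m1, params$error_rate)
  m2 <- apply_substitutions(m2, params$error_rate)
  qual <- strrep("?", rl)  # Phred+33 Q30
  data.frame(read_id = sprintf("sim_%07d", seq_len(n)),
             seq1 = m1, qual1 = qual, seq2 = m2, qual2 = qual,
             stringsAsFactors = FALSE)
}

#' Build a complete simulated benchmark dataset
#'
#' Convenience wrapper: plant insertions, then simulate reads from the
#' mutated genome.
#'
#' @param genome A reference [te_genome()].
#' @param library A [te_library()].
#' @param n_insertions Number of planted insertions.
#' @param coverage Sequence depth for the reads.
#' @param seed Integer seed (drives both planting and read simulation).
#' @param error_rate Per-base substitution probability.
#' @param window_bp Cluster window (controls minimum site spacing).
#' @return A list: `genome` (mutated), `truth`, `pairs`, `reference`
#'   (the unmodified input genome).
#' @export
simulate_te_benchmark <- function(genome, library, n_insertions = 200,
                                  coverage = 10, seed = 1, error_rate = 0.01,
                                  window_bp = 2000) {
  pl <- plant_insertions(genome, library, n = n_insertions, seed = seed,
                         min_dist = 2 * window_bp)
  pairs <- simulate_reads(pl$genome,
                          read_sim_params(coverage = coverage,
                                          error_rate = error_rate,
                                          seed = seed + 1L))
  list(genome = pl$genome, truth = pl$truth, pairs = pairs, reference = genome)
}

#' Write simulated truth records to GFF3
#'
#' @param truth Truth `data.frame` from [plant_insertions()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_gff3 <- function(truth, path) {
  rec <- data.frame(chrom = truth$chrom, start = truth$position,
                    end = truth$position, family = truth$family,
                    strand = truth$strand, tsd_seq = truth$tsd_seq,
                    stringsAsFactors = FALSE)
  write_insertions_gff3(rec, path, type = "TE_insertion_truth")
}

#' Read simulated truth records from GFF3
#'
#' Inverse of [write_truth_gff3()].
#'
#' @param path Path to a truth GFF3 file.
#' @return A truth `data.frame` (`chrom`, `position`, `family`, `strand`,
#'   `tsd_seq`).
#' @export
read_truth_gff3 <- function(path) {
  df <- read_insertions_gff3(path)
  if (nrow(df) == 0)
    return(data.frame(chrom = character(), position = integer(),
                      family = character(), strand = character(),
                      tsd_seq = character(), stringsAsFactors = FALSE))
  data.frame(chrom = df$chrom, position = df$start, family = df$family,
             strand = df$strand, tsd_seq = df$tsd_seq,
             stringsAsFactors = FALSE)
}
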