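#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and any character outside the A/C/G/T/N
#' alphabet is mapped to N. Lowercase (soft-masked) bases are uppercased;
#' masking information is discarded.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate record names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- nm
  seqs
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

strip_mate_suffix <- function(ids) {
  out <- sub("(/[12]$)|( [12]($|(:.*$)))", "", ids)
  bad <- grepl("/[12]", out)
  if (any(bad))
    stop("unrecognized mate naming for read id: ", out[which(bad)[1]])
  out
}

#' Read a pair of synchronized FASTQ files
#'
#' Mate identifiers must be equal after stripping `/1`, `/2` or
#' Casava-style ` 1`, ` 2` suffixes; anything else is an error rather
#' than a guess.
#'
#' @param path1,path2 Paths to the two mate FASTQ files.
#' @return A `data.frame` with columns `read_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`, one row per pair, in file order.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("desynchronized FASTQ pair: ", length(r1), " vs ", length(r2), " records")
  id1 <- strip_mate_suffix(names(r1))
  id2 <- strip_mate_suffix(names(r2))
  mism <- which(id1 != id2)
  if (length(mism) > 0)
    stop("desynchronized FASTQ pair at record ", mism[1], ": '",
         id1[mism[1]], "' vs '", id2[mism[1]], "'")
  data.frame(read_id = id1,
             seq1 = as.character(r1),
             qual1 = as.character(S4Vectors::mcols(r1)$qualities),
             seq2 = as.character(r2),
             qual2 = as.character(S4Vectors::mcols(r2)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write paired reads to two FASTQ files
#'
#' Mate identifiers are written with `/1` and `/2` suffixes.
#'
#' @param pairs A `data.frame` as returned by [read_fastq_pair()] or
#'   [simulate_reads()].
#' @param path1,path2 Output paths for the two mates.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pair <- function(pairs, path1, path2) {
  for (m in 1:2) {
    ss <- Biostrings::DNAStringSet(pairs[[paste0("seq", m)]])
    names(ss) <- paste0(pairs$read_id, "/", m)
    qq <- Biostrings::BStringSet(pairs[[paste0("qual", m)]])
    Biostrings::writeXStringSet(ss, if (m == 1) path1 else path2,
                                format = "fastq", qualities = qq)
  }
  invisible(c(path1, path2))
}

#' Load a reference genome from FASTA
#'
#' @param path Path to a genome FASTA file.
#' @param annotation Optional `data.frame` of annotated reference repeats
#'   with columns `chrom`, `start`, `end` (1-based inclusive), `family`.
#' @return A `te_genome` object: list with `seq` (named character vector)
#'   and `annotation`.
#' @export
read_genome_fasta <- function(path, annotation = NULL) {
  te_genome(read_fasta(path), annotation)
}

#' Construct a reference genome object
#'
#' @param seq Named character vector, one element per chromosome.
#' @param annotation Optional repeat annotation `data.frame`
#'   (`chrom`, `start`, `end`, `family`; 1-based inclusive).
#' @return A `te_genome` object.
#' @export
te_genome <- function(seq, annotation = NULL) {
  if (length(seq) == 0 || any(!nzchar(seq))) stop("genome sequences must be non-empty")
  if (is.null(names(seq)) || anyDuplicated(names(seq)))
    stop("chromosome names must be present and unique")
  if (!is.null(annotation)) {
    stopifnot(all(c("chrom", "start", "end", "family") %in% names(annotation)))
    len <- nchar(seq)[annotation$chrom]
    if (any(is.na(len)) || any(annotation$start < 1) ||
        any(annotation$end > len) || any(annotation$start > annotation$end))
      stop("annotation intervals out of chromosome bounds")
  }
  structure(list(seq = seq, annotation = annotation), class = "te_genome")
}

#' @export
print.te_genome <- function(x, ...) {
  cat(sprintf("Reference genome: %d chromosome(s), %s bp total\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ",")))
  if (!is.null(x$annotation))
    cat(sprintf("  with %d annotated repeat(s)\n", nrow(x$annotation)))
  invisible(x)
}

# ---- GFF3 ----

#' Write insertion records to GFF3
#'
#' Works for both calls and simulated truth records. Coordinates in the
#' file are 1-based inclusive; attributes carry the TE family, per-side
#' junction/supporting read counts and the TSD sequence (`"NA"` when
#' uncalled). Reading the file back with [read_insertions_gff3()]
#' reproduces the records.
#'
#' @param records A `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `family`, `strand` and optionally `tsd_seq`,
#'   `left_junction`, `right_junction`, `left_support`, `right_support`.
#' @param path Output path.
#' @param source Value of the GFF3 source column.
#' @param type Value of the GFF3 type column.
#' @return The path, invisibly.
#' @export
write_insertions_gff3 <- function(records, path,
                                  source = "junctionTE",
                                  type = "transposable_element_insertion_site") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  n <- nrow(records)
  if (is.null(n) || n == 0) return(invisible(path))
  strand <- as.character(records$strand)
  strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "."
  attr_cols <- intersect(c("tsd_seq", "left_junction", "right_junction",
                           "left_support", "right_support"), names(records))
  ids <- sprintf("%s.%d", type, seq_len(n))
  attrs <- sprintf("ID=%s;TE=%s", ids, records$family)
  for (ac in attr_cols) {
    v <- records[[ac]]
    v <- ifelse(is.na(v), "NA", as.character(v))
    attrs <- paste0(attrs, ";", ac, "=", v)
  }
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   records$chrom, source, type,
                   as.integer(records$start), as.integer(records$end),
                   strand, attrs)
  writeLines(lines, con)
  invisible(path)
}

#' Read insertion records from GFF3
#'
#' Inverse of [write_insertions_gff3()].
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `family` plus any extra attributes present
#'   (`tsd_seq`, read counts ...). Zero rows for a header-only file.
#' @export
read_insertions_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- NA_character_
  mc <- S4Vectors::mcols(gr)
  if ("TE" %in% colnames(mc)) df$family <- as.character(mc$TE)
  for (ac in c("tsd_seq", "position")) {
    if (ac %in% colnames(mc)) {
      v <- as.character(mc[[ac]])
      v[v == "NA"] <- NA_character_
      df[[ac]] <- v
    }
  }
  for (ac in c("left_junction", "right_junction", "left_support", "right_support")) {
    if (ac %in% colnames(mc)) df[[ac]] <- as.integer(as.character(mc[[ac]]))
  }
  if ("position" %in% names(df)) df$position <- as.integer(df$position)
  df
}
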