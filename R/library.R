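#' Construct a TE consensus library
#'
#' A TE library holds one consensus sequence per family together with the
#' expected target site duplication (TSD) length of that family
#' (0 means "no TSD expected").
#'
#' @param name Character vector of unique family names.
#' @param consensus Character vector of consensus sequences (ACGTN).
#' @param tsd_len Integer vector of expected TSD lengths (bp).
#' @return A `te_library` object (a `data.frame` with columns `name`,
#'   `consensus`, `tsd_len`).
#' @examples
#' lib <- te_library("toyTE", strrep("ACGT", 100), 3)
#' @export
te_library <- function(name, consensus, tsd_len) {
  name <- as.character(name)
  consensus <- toupper(as.character(consensus))
  tsd_len <- as.integer(tsd_len)
  if (length(name) == 0) stop("empty TE library")
  if (anyDuplicated(name)) stop("TE family names must be unique")
  if (any(nchar(consensus) < 1)) stop("consensus sequences must be non-empty")
  if (any(is.na(tsd_len)) || any(tsd_len < 0)) stop("tsd_len must be >= 0")
  if (any(grepl("[^ACGTN]", consensus))) stop("consensus alphabet is ACGTN")
  structure(data.frame(name = name, consensus = consensus, tsd_len = tsd_len,
                       stringsAsFactors = FALSE),
            class = c("te_library", "data.frame"))
}

#' @export
print.te_library <- function(x, ...) {
  cat(sprintf("TE library: %d families, %s bp total\n",
              nrow(x), format(sum(nchar(x$consensus)), big.mark = ",")))
  print(data.frame(name = x$name, length = nchar(x$consensus),
                   tsd_len = x$tsd_len))
  invisible(x)
}

#' Read a TE library from FASTA
#'
#' Expected TSD lengths are taken from a `tsd=<int>` token in each record
#' description line; records without one default to `default_tsd`.
#'
#' @param path Path to a FASTA file of TE consensi.
#' @param default_tsd TSD length used for records without a `tsd=` token.
#' @return A `te_library` object.
#' @export
read_te_library <- function(path, default_tsd = 0) {
  if (!file.exists(path)) stop("TE library file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty TE library file: ", path)
  full <- names(ss)
  nm <- sub("\\s.*$", "", full)
  if (anyDuplicated(nm)) stop("duplicate TE family names in ", path)
  tsd <- rep(as.integer(default_tsd), length(ss))
  has <- grepl("tsd=\\d+", full)
  tsd[has] <- as.integer(sub(".*tsd=(\\d+).*", "\\1", full[has]))
  seqs <- gsub("[^ACGTN]", "N", toupper(as.character(ss)))
  te_library(nm, seqs, tsd)
}

#' The bundled 14-family synthetic rice-like TE library
#'
#' A synthetic stand-in for the fourteen TE families commonly profiled in
#' rice resequencing studies (seven DNA transposons and seven LTR
#' retrotransposons). Family names are real; the consensus sequences are
#' seeded random sequences (lengths 300-8000 bp) because published
#' consensi are not redistributable here, with family TSD lengths drawn
#' from the biologically typical range (2-9 bp).
#'
#' @return A `te_library` with 14 families.
#' @export
te_fixture_library <- function() {
  path <- system.file("extdata", "te_library.fa", package = "junctionTE",
                      mustWork = TRUE)
  read_te_library(path)
}
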