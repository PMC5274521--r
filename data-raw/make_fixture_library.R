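# Builds inst/extdata/te_library.fa: a synthetic 14-family TE library.
# Family names follow the set commonly profiled in rice resequencing
# (7 DNA transposons, 7 LTR retrotransposons); sequences are seeded random
# ACGT (published consensi are not redistributable here).  TSD lengths:
# Tourist-like MITEs 3 bp, hAT-like elements 9 bp, Mutator-like 9 bp,
# CACTA-like 2-3 bp, LTR retrotransposons 5 bp.
set.seed(20160901)
fam <- c(mPing = 430L, nDart = 300L, Gaijin = 350L, spmlike = 500L,
         Truncator = 450L, mGing = 380L, nDarz = 320L,
         Bajie = 4500L, Dasheng = 5500L, Retro1 = 4000L, RIRE2 = 8000L,
         RIRE3 = 7000L, Copia2 = 5000L, karma = 6500L)
tsd <- c(mPing = 3L, nDart = 9L, Gaijin = 3L, spmlike = 2L, Truncator = 9L,
         mGing = 3L, nDarz = 9L,
         Bajie = 5L, Dasheng = 5L, Retro1 = 5L, RIRE2 = 5L, RIRE3 = 5L,
         Copia2 = 5L, karma = 5L)
out <- file.path("inst", "extdata", "te_library.fa")
dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
con <- file(out, "wt")
for (nm in names(fam)) {
  s <- paste(sample(c("A", "C", "G", "T"), fam[[nm]], replace = TRUE),
             collapse = "")
  writeLines(sprintf(">%s tsd=%d synthetic", nm, tsd[[nm]]), con)
  writeLines(substring(s, seq(1, nchar(s), 70), pmin(seq(1, nchar(s), 70) + 69,
                                                     nchar(s))), con)
}
close(con)
cat("wrote", out, "\n")
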