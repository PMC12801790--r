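## Shared fixtures, built in code. The toy-genome cache persists across test
## files within one session so the (seconds-scale) genome build runs once.

.fixtureCache <- new.env(parent = emptyenv())

cachedToyGenome <- function(key = "default", cfg = simulationConfig(),
                            seed = 101L) {
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- buildToyGenome(cfg, seed = seed)
  .fixtureCache[[key]]
}

## a small deterministic reference written/read through FASTA
writeTempFasta <- function(seqs) {
  ref <- Biostrings::DNAStringSet(seqs)
  p <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(ref, p)
  p
}

## SampleFragments from explicit 0-based half-open intervals, via the BED
## reader (so fixtures exercise the I/O path)
fragmentsFromBed <- function(df, reference, seqinfo, sampleId = "toy") {
  p <- tempfile(fileext = ".bed")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  readFragmentsBed(p, reference, seqinfo, sampleId = sampleId)
}

seqinfoFor <- function(seqs) {
  GenomeInfoDb::Seqinfo(names(seqs), vapply(seqs, nchar, integer(1)))
}

revcompStr <- function(s) {
  m <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(m[strsplit(s, "")[[1L]]]), collapse = "")
}
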