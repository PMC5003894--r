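toyMatrixPath <- function() {
  system.file("extdata", "toy_matrix.tsv", package = "introscan",
              mustWork = TRUE)
}

table2Counts <- function() {
  read.delim(system.file("extdata", "table2_genetic_events.tsv",
                         package = "introscan", mustWork = TRUE),
             row.names = 1)
}

table3Counts <- function() {
  read.delim(system.file("extdata", "table3_msap_events.tsv",
                         package = "introscan", mustWork = TRUE),
             row.names = 1)
}

## small simulation settings used by property tests
smallParams <- function(seed, ...) {
  simulationParams(nShared = 30, nRecurrentSpecific = 25,
                   nDonorSpecific = 20, nReferenceSpecific = 10,
                   nIls = 4, nMsapInformative = 20, nMsapShared = 5,
                   seed = seed, ...)
}

## a fully random valid band matrix (independent of the generator's
## structured model): random parents too, so all origin categories occur
randomBandSet <- function(seed, nGenetic = 40, nMsap = 10, nIl = 4) {
  set.seed(seed)
  samples <- c("P1", "P2", "REF", paste0("L", seq_len(nIl)))
  roles <- c("RECURRENT_PARENT", "DONOR_PARENT", "REFERENCE",
             rep("IL", nIl))
  ns <- length(samples)
  H <- matrix(rbinom(nGenetic * ns, 1L, 0.5), nGenetic, ns,
              dimnames = list(NULL, samples))
  MH <- matrix(rbinom(nMsap * ns, 1L, 0.6), nMsap, ns,
               dimnames = list(NULL, samples))
  MM <- matrix(rbinom(nMsap * ns, 1L, 0.6), nMsap, ns,
               dimnames = list(NULL, samples))
  bs <- BandSet(H = rbind(H, MH), M = rbind(H, MM),
                markerSystem = c(rep(c("AFLP", "SSR"),
                                     length.out = nGenetic),
                                 rep("MSAP", nMsap)),
                primerCombo = c(rep("E01-M01", nGenetic),
                                rep("ETTC+HMTCC", nMsap)),
                bandLabel = c(sprintf("g%03d", seq_len(nGenetic)),
                              sprintf("%dbp", 100 + seq_len(nMsap))),
                sampleId = samples, role = roles)
  bs[order(rownames(bs), method = "radix"), ]
}

bandSetsIdentical <- function(a, b) {
  identical(SummarizedExperiment::assay(a, "H"),
            SummarizedExperiment::assay(b, "H")) &&
    identical(SummarizedExperiment::assay(a, "M"),
              SummarizedExperiment::assay(b, "M")) &&
    identical(as.data.frame(SummarizedExperiment::rowData(a)),
              as.data.frame(SummarizedExperiment::rowData(b))) &&
    identical(as.data.frame(SummarizedExperiment::colData(a)),
              as.data.frame(SummarizedExperiment::colData(b)))
}

writeTempMatrix <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trole\tmarker_system\tprimer_combo\tband_label\tchannel\tpresence",
               lines), f)
  f
}
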