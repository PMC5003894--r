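#' BandSet: presence/absence band matrices over samples and loci
#'
#' A \code{BandSet} stores scored dominant-marker fingerprints (SSR, AFLP,
#' MSAP) as a \linkS4class{SummarizedExperiment} with loci as rows and
#' samples as columns. Two binary assays, \code{"H"} and \code{"M"}, hold the
#' two digestion channels of MSAP loci (EcoRI+HpaII and EcoRI+MspI lanes);
#' for single-channel SSR/AFLP loci the two assays are constrained to be
#' identical and represent the single presence call.
#'
#' Row metadata carries \code{marker_system}, \code{primer_combo} and
#' \code{band_label}; row names are the canonical locus identifier
#' \code{"{marker_system}:{primer_combo}:{band_label}"}. Co-migration between
#' samples is equality of this identifier. Column metadata carries the sample
#' \code{role}: exactly one \code{RECURRENT_PARENT}, exactly one
#' \code{DONOR_PARENT}, at most one \code{REFERENCE} (a natural allotetraploid
#' used to flag convergent bands), and any number of \code{IL} (introgression
#' line) samples.
#'
#' Size-labelled AFLP/MSAP bands (labels such as \code{"214bp"}) must exceed
#' 100 bp, the conventional scoring cutoff for clear reproducible fragments;
#' named SSR markers are exempt.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#' @aliases BandSet
#' @seealso \code{\link{readBandMatrix}}, \code{\link{classifyLoci}},
#'   \code{\link{summarizeMsap}}
#' @importFrom methods setClass validObject new is
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @exportClass BandSet
setClass("BandSet", contains = "SummarizedExperiment")

validBandSet <- function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("H", "M") %in% an))
    return("assays 'H' and 'M' are required")
  H <- SummarizedExperiment::assay(object, "H")
  M <- SummarizedExperiment::assay(object, "M")
  if (anyNA(H) || anyNA(M))
    msg <- c(msg, "presence values must not be missing")
  if (!all(H %in% c(0L, 1L)) || !all(M %in% c(0L, 1L)))
    msg <- c(msg, "presence values must be 0 or 1")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("marker_system", "primer_combo", "band_label")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain", paste(need, collapse = ", ")))
  if (!all(rd$marker_system %in% MARKER_SYSTEMS))
    msg <- c(msg, "marker_system must be one of SSR, AFLP, MSAP")
  if (any(!nzchar(rd$band_label)))
    msg <- c(msg, "band_label must be non-empty")
  ids <- canonicalLocusId(rd$marker_system, rd$primer_combo, rd$band_label)
  if (is.null(rownames(object)) || !identical(rownames(object), ids))
    msg <- c(msg, "rownames must equal marker_system:primer_combo:band_label")
  if (anyDuplicated(ids))
    msg <- c(msg, paste("duplicated locus_id:",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  single <- rd$marker_system != "MSAP"
  if (any(single) && !identical(H[single, , drop = FALSE],
                                M[single, , drop = FALSE]))
    msg <- c(msg, "SSR/AFLP loci must have identical H and M channels")
  sz <- parseBandSize(rd$band_label)
  bad <- !is.na(sz) & sz <= 100 & rd$marker_system %in% c("AFLP", "MSAP")
  if (any(bad))
    msg <- c(msg, paste("size-labelled AFLP/MSAP bands must exceed 100 bp:",
                        paste(ids[bad], collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!"role" %in% colnames(cd))
    return("colData must contain a 'role' column")
  if (!all(cd$role %in% SAMPLE_ROLES))
    msg <- c(msg, "role must be one of RECURRENT_PARENT, DONOR_PARENT, REFERENCE, IL")
  if (ncol(object) > 0L) {
    if (sum(cd$role == "RECURRENT_PARENT") != 1L)
      msg <- c(msg, "exactly one RECURRENT_PARENT sample is required")
    if (sum(cd$role == "DONOR_PARENT") != 1L)
      msg <- c(msg, "exactly one DONOR_PARENT sample is required")
  }
  if (sum(cd$role == "REFERENCE") > 1L)
    msg <- c(msg, "at most one REFERENCE sample is allowed")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  bad_chr <- grepl("[\t\n\r]", c(rd$primer_combo, rd$band_label, colnames(object)))
  if (any(bad_chr))
    msg <- c(msg, "labels must not contain tab or newline characters")
  if (length(msg)) msg else TRUE
}

setValidity("BandSet", validBandSet)

#' Construct a BandSet
#'
#' @param H integer/binary matrix, loci x samples: EcoRI+HpaII channel for
#'   MSAP loci, the single presence call for SSR/AFLP loci.
#' @param M like \code{H} for the EcoRI+MspI channel; defaults to \code{H}
#'   (correct for single-channel loci).
#' @param markerSystem character vector per locus: "SSR", "AFLP" or "MSAP".
#' @param primerCombo character vector per locus, e.g. "E45-M57".
#' @param bandLabel character vector per locus: a marker name (SSR) or a band
#'   size label such as "214bp" (AFLP/MSAP).
#' @param sampleId character vector of sample names; defaults to
#'   \code{colnames(H)}.
#' @param role character vector per sample (see \linkS4class{BandSet}).
#' @return a validated \code{BandSet}.
#' @export
#' @examples
#' H <- matrix(1L, 2, 3, dimnames = list(NULL, c("Korso", "G1_1", "IL1")))
#' bs <- BandSet(H, markerSystem = c("SSR", "AFLP"),
#'               primerCombo = c("p1", "E45-M57"),
#'               bandLabel = c("BrID10227", "214bp"),
#'               role = c("RECURRENT_PARENT", "DONOR_PARENT", "IL"))
#' bs
BandSet <- function(H, M = H, markerSystem, primerCombo, bandLabel,
                    sampleId = colnames(H), role) {
  H <- as.matrix(H); storage.mode(H) <- "integer"
  M <- as.matrix(M); storage.mode(M) <- "integer"
  ids <- canonicalLocusId(markerSystem, primerCombo, bandLabel)
  dimnames(H) <- dimnames(M) <- list(ids, sampleId)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(H = H, M = M),
    rowData = S4Vectors::DataFrame(marker_system = markerSystem,
                                   primer_combo = primerCombo,
                                   band_label = bandLabel,
                                   row.names = ids),
    colData = S4Vectors::DataFrame(role = role, row.names = sampleId))
  out <- methods::new("BandSet", se)
  methods::validObject(out)
  out
}
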