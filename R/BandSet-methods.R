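#' @describeIn BandSet-accessors marker system ("SSR"/"AFLP"/"MSAP") per locus.
#' @export
setGeneric("markerSystem", function(x) standardGeneric("markerSystem"))
#' @describeIn BandSet-accessors primer combination per locus.
#' @export
setGeneric("primerCombo", function(x) standardGeneric("primerCombo"))
#' @describeIn BandSet-accessors band label per locus.
#' @export
setGeneric("bandLabel", function(x) standardGeneric("bandLabel"))
#' @describeIn BandSet-accessors canonical locus identifier per locus.
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))
#' @describeIn BandSet-accessors sample role per sample, named by sample id.
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))
#' @describeIn BandSet-accessors presence matrix of one digestion channel.
#' @export
setGeneric("channelPresence",
           function(x, channel = c("H", "M")) standardGeneric("channelPresence"))

#' Accessors for BandSet objects
#'
#' @param x a \linkS4class{BandSet}.
#' @param channel which MSAP digestion channel to return ("H" = EcoRI+HpaII,
#'   "M" = EcoRI+MspI). For SSR/AFLP loci both channels hold the single
#'   presence call.
#' @return vectors per locus or sample, or a binary loci x samples matrix.
#' @name BandSet-accessors
NULL

#' @rdname BandSet-accessors
#' @export
setMethod("markerSystem", "BandSet", function(x)
  SummarizedExperiment::rowData(x)$marker_system)

#' @rdname BandSet-accessors
#' @export
setMethod("primerCombo", "BandSet", function(x)
  SummarizedExperiment::rowData(x)$primer_combo)

#' @rdname BandSet-accessors
#' @export
setMethod("bandLabel", "BandSet", function(x)
  SummarizedExperiment::rowData(x)$band_label)

#' @rdname BandSet-accessors
#' @export
setMethod("locusId", "BandSet", function(x) rownames(x))

#' @rdname BandSet-accessors
#' @export
setMethod("sampleRoles", "BandSet", function(x) {
  r <- SummarizedExperiment::colData(x)$role
  names(r) <- colnames(x)
  r
})

#' @rdname BandSet-accessors
#' @export
setMethod("channelPresence", "BandSet", function(x, channel = c("H", "M")) {
  channel <- match.arg(channel)
  SummarizedExperiment::assay(x, channel)
})

## sample ids by role (internal)
sampleByRole <- function(x, role) {
  colnames(x)[sampleRoles(x) == role]
}
recurrentParent <- function(x) sampleByRole(x, "RECURRENT_PARENT")
donorParent <- function(x) sampleByRole(x, "DONOR_PARENT")
referenceSample <- function(x) {
  s <- sampleByRole(x, "REFERENCE")
  if (length(s)) s else NA_character_
}
ilSamples <- function(x) sampleByRole(x, "IL")

#' Subset a BandSet to genetic (SSR/AFLP) or MSAP loci
#'
#' @param x a \linkS4class{BandSet}.
#' @return a \code{BandSet} with only the requested locus class.
#' @export
geneticLoci <- function(x) x[markerSystem(x) != "MSAP", ]

#' @rdname geneticLoci
#' @export
msapLoci <- function(x) x[markerSystem(x) == "MSAP", ]

setMethod("show", "BandSet", function(object) {
  sys <- table(factor(markerSystem(object), levels = MARKER_SYSTEMS))
  rol <- table(factor(sampleRoles(object), levels = SAMPLE_ROLES))
  cat("BandSet:", nrow(object), "loci x", ncol(object), "samples\n")
  cat("  loci:   ", paste(sprintf("%s=%d", names(sys), sys), collapse = ", "),
      "\n")
  cat("  samples:", paste(sprintf("%s=%d", names(rol), rol), collapse = ", "),
      "\n")
  ils <- ilSamples(object)
  if (length(ils))
    cat("  ILs:    ", paste(utils::head(ils, 8), collapse = ", "),
        if (length(ils) > 8) "..." else "", "\n")
})
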