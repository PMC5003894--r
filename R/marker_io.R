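#' Read a band matrix from long-format TSV
#'
#' Reads scored fingerprints from a tab-separated file with header columns
#' \code{sample_id}, \code{role}, \code{marker_system}, \code{primer_combo},
#' \code{band_label}, \code{channel}, \code{presence}. \code{channel} is
#' empty for SSR/AFLP rows and \code{"H"} (EcoRI+HpaII) or \code{"M"}
#' (EcoRI+MspI) for MSAP rows; \code{presence} is 0/1. The long format is
#' canonical because MSAP loci carry two presence calls per cell.
#'
#' Validation is order-independent: the returned object is in canonical order
#' (loci sorted by locus id, samples by role then id), so any permutation of
#' input rows yields an identical \code{BandSet}. Duplicate rows with
#' identical presence are collapsed; duplicates that disagree are an error
#' naming the cell.
#'
#' @param path path to a UTF-8 TSV file.
#' @param strict logical; when \code{TRUE} (default) any incomplete locus
#'   (missing cells, an MSAP locus with a missing channel) or an AFLP/MSAP
#'   band whose size label is <= 100 bp is a hard error. When \code{FALSE}
#'   offending loci are dropped with a message.
#' @return a validated \linkS4class{BandSet}.
#' @export
#' @seealso \code{\link{writeBandMatrix}}
readBandMatrix <- function(path, strict = TRUE) {
  if (!file.exists(path))
    stop("input file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("sample_id", "role", "marker_system", "primer_combo",
            "band_label", "channel", "presence")
  if (!all(need %in% colnames(df)))
    stop("missing required columns: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  n <- nrow(df)
  line <- seq_len(n) + 1L  # file line numbers; line 1 is the header

  bad <- !(df$presence %in% c("0", "1"))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("non-binary presence value '", df$presence[i], "' at line ", line[i])
  }
  bad <- !(df$marker_system %in% MARKER_SYSTEMS)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("unknown marker_system '", df$marker_system[i], "' at line ", line[i])
  }
  bad <- !(df$role %in% SAMPLE_ROLES)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("missing or unknown role '", df$role[i], "' at line ", line[i])
  }
  msap <- df$marker_system == "MSAP"
  bad <- msap & !(df$channel %in% c("H", "M"))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("MSAP rows need channel 'H' or 'M'; got '", df$channel[i],
         "' at line ", line[i])
  }
  bad <- !msap & nzchar(df$channel)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("channel must be empty for ", df$marker_system[which(bad)[1L]],
         " rows; got '", df$channel[i], "' at line ", line[i])
  }

  roles <- tapply(df$role, df$sample_id, unique, simplify = FALSE)
  multi <- vapply(roles, length, 1L) > 1L
  if (any(multi))
    stop("conflicting role declarations for sample ",
         names(roles)[multi][1L])
  roles <- vapply(roles, identity, character(1))

  df$locus_id <- canonicalLocusId(df$marker_system, df$primer_combo,
                                  df$band_label)
  key <- paste(df$sample_id, df$locus_id, df$channel, sep = "\r")
  pres <- tapply(df$presence, key, unique, simplify = FALSE)
  conflict <- vapply(pres, length, 1L) > 1L
  if (any(conflict)) {
    parts <- strsplit(names(pres)[conflict][1L], "\r", fixed = TRUE)[[1L]]
    stop("conflicting duplicate rows for sample '", parts[1L], "', locus '",
         parts[2L], "'",
         if (length(parts) > 2L && nzchar(parts[3L]))
           paste0(", channel '", parts[3L], "'") else "")
  }

  ## canonical ordering
  loci <- unique(df[, c("locus_id", "marker_system", "primer_combo",
                        "band_label")])
  loci <- loci[order(loci$locus_id, method = "radix"), , drop = FALSE]
  samp_ids <- names(roles)
  role_rank <- match(roles, SAMPLE_ROLES)
  ord <- order(role_rank, samp_ids, method = "radix")
  samp_ids <- samp_ids[ord]

  H <- M <- matrix(NA_integer_, nrow(loci), length(samp_ids),
                   dimnames = list(loci$locus_id, samp_ids))
  ri <- match(df$locus_id, loci$locus_id)
  ci <- match(df$sample_id, samp_ids)
  p <- as.integer(df$presence)
  isH <- df$channel == "H" | !nzchar(df$channel)
  isM <- df$channel == "M" | !nzchar(df$channel)
  H[cbind(ri[isH], ci[isH])] <- p[isH]
  M[cbind(ri[isM], ci[isM])] <- p[isM]

  drop <- rep(FALSE, nrow(loci))
  incomplete <- rowSums(is.na(H)) + rowSums(is.na(M)) > 0L
  if (any(incomplete)) {
    who <- loci$locus_id[incomplete]
    if (strict)
      stop("incomplete locus (missing cells or MSAP channel): ",
           paste(utils::head(who, 5), collapse = ", "))
    message("dropping ", sum(incomplete), " incomplete locus/loci: ",
            paste(utils::head(who, 5), collapse = ", "))
    drop <- drop | incomplete
  }
  sz <- parseBandSize(loci$band_label)
  small <- !is.na(sz) & sz <= 100 & loci$marker_system %in% c("AFLP", "MSAP")
  if (any(small)) {
    who <- loci$locus_id[small]
    if (strict)
      stop("AFLP/MSAP bands must be larger than 100 bp: ",
           paste(utils::head(who, 5), collapse = ", "))
    message("dropping ", sum(small), " band(s) at or below the 100 bp ",
            "scoring cutoff: ", paste(utils::head(who, 5), collapse = ", "))
    drop <- drop | small
  }
  keep <- !drop
  BandSet(H = H[keep, , drop = FALSE], M = M[keep, , drop = FALSE],
          markerSystem = loci$marker_system[keep],
          primerCombo = loci$primer_combo[keep],
          bandLabel = loci$band_label[keep],
          sampleId = samp_ids, role = unname(roles[samp_ids]))
}

#' Write a band matrix to long-format TSV
#'
#' Emits the canonical long format read by \code{\link{readBandMatrix}}:
#' one row per (sample, locus) for SSR/AFLP and two rows (channels H and M)
#' per (sample, locus) for MSAP. \code{readBandMatrix(writeBandMatrix(x))}
#' reproduces \code{x} exactly.
#'
#' @param x a \linkS4class{BandSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBandMatrix <- function(x, path) {
  stopifnot(methods::is(x, "BandSet"))
  H <- channelPresence(x, "H")
  M <- channelPresence(x, "M")
  roles <- sampleRoles(x)
  ns <- ncol(x)
  blocks <- lapply(seq_len(nrow(x)), function(i) {
    if (markerSystem(x)[i] == "MSAP") {
      data.frame(sample_id = rep(colnames(x), each = 2L),
                 role = rep(unname(roles), each = 2L),
                 marker_system = "MSAP",
                 primer_combo = primerCombo(x)[i],
                 band_label = bandLabel(x)[i],
                 channel = rep(c("H", "M"), ns),
                 presence = as.vector(rbind(H[i, ], M[i, ])),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = colnames(x),
                 role = unname(roles),
                 marker_system = markerSystem(x)[i],
                 primer_combo = primerCombo(x)[i],
                 band_label = bandLabel(x)[i],
                 channel = "",
                 presence = H[i, ],
                 stringsAsFactors = FALSE)
    }
  })
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(sample_id = character(), role = character(),
               marker_system = character(), primer_combo = character(),
               band_label = character(), channel = character(),
               presence = integer(), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
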