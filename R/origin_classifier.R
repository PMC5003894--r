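#' Classify SSR/AFLP loci by parental origin
#'
#' Every single-channel (SSR/AFLP) locus falls in exactly one cell of the
#' 2x2 parental presence table:
#' \itemize{
#'   \item \code{SHARED_PARENTAL} — band co-migrates in both parents;
#'   \item \code{RECURRENT_SPECIFIC} — present in the recurrent parent only
#'     (the informative loci for loss calling);
#'   \item \code{DONOR_SPECIFIC} — present in the donor parent only (the
#'     informative loci for introgression calling);
#'   \item \code{ABSENT_IN_PARENTS} — absent from both parents.
#' }
#' Orthogonally, \code{reference_comigrating} flags loci with a band in the
#' REFERENCE sample (the natural allotetraploid); it is \code{NA} for every
#' locus when no reference sample is present, in which case
#' reference-dependent quantities downstream are reported as not assessable
#' rather than zero.
#'
#' @param x a \linkS4class{BandSet} with both parents; MSAP loci are ignored.
#' @return a \link[S4Vectors]{DataFrame} with one row per SSR/AFLP locus
#'   (columns \code{marker_system}, \code{category},
#'   \code{reference_comigrating}) whose \code{metadata()} carries the
#'   informative-locus denominators; see \code{\link{originDenominators}}.
#' @export
#' @examples
#' sim <- generateBandSet(simulationParams(seed = 7, nIls = 2))
#' org <- classifyLoci(sim$bandSet)
#' table(org$category)
#' originDenominators(org)
classifyLoci <- function(x) {
  stopifnot(methods::is(x, "BandSet"))
  g <- geneticLoci(x)
  if (nrow(g) == 0L)
    stop("no SSR/AFLP loci in the matrix")
  P <- channelPresence(g, "H")
  rec <- P[, recurrentParent(g)]
  don <- P[, donorParent(g)]
  category <- factor(ifelse(rec == 1L,
                            ifelse(don == 1L, "SHARED_PARENTAL",
                                   "RECURRENT_SPECIFIC"),
                            ifelse(don == 1L, "DONOR_SPECIFIC",
                                   "ABSENT_IN_PARENTS")),
                     levels = ORIGIN_CATEGORIES)
  ref <- referenceSample(g)
  refflag <- if (is.na(ref)) rep(NA, nrow(g)) else P[, ref] == 1L
  out <- S4Vectors::DataFrame(marker_system = markerSystem(g),
                              category = category,
                              reference_comigrating = refflag,
                              row.names = rownames(g))
  tab <- table(category)
  n_shared <- unname(tab["SHARED_PARENTAL"])
  n_rec <- unname(tab["RECURRENT_SPECIFIC"])
  n_don <- unname(tab["DONOR_SPECIFIC"])
  n_abs <- unname(tab["ABSENT_IN_PARENTS"])
  d_ref <- if (is.na(ref)) NA_integer_ else
    sum(category == "ABSENT_IN_PARENTS" & refflag)
  S4Vectors::metadata(out)$denominators <- list(
    n_donor_specific = as.integer(n_don),
    n_recurrent_specific = as.integer(n_rec),
    n_reference_specific = as.integer(d_ref),
    n_shared = as.integer(n_shared),
    n_absent_in_parents = as.integer(n_abs),
    n_total_distinct_parental = as.integer(n_shared + n_rec + n_don),
    n_polymorphic = as.integer(n_rec + n_don))
  out
}

#' Informative-locus denominators of a locus-origin table
#'
#' @param origins the \code{DataFrame} returned by \code{\link{classifyLoci}}.
#' @return a named list: \code{n_donor_specific} (introgression denominator),
#'   \code{n_recurrent_specific} (loss denominator),
#'   \code{n_reference_specific} (reference-co-migrating bands absent from
#'   both parents; \code{NA} without a reference sample), \code{n_shared},
#'   \code{n_absent_in_parents}, \code{n_total_distinct_parental} and
#'   \code{n_polymorphic}.
#' @export
originDenominators <- function(origins) {
  d <- S4Vectors::metadata(origins)$denominators
  if (is.null(d))
    stop("no denominators found; pass the result of classifyLoci()")
  d
}

#' Call per-IL genetic events
#'
#' For each introgression line (IL), counts and lists:
#' \itemize{
#'   \item introgressed bands — donor-specific loci present in the IL;
#'   \item lost bands — recurrent-parent-specific loci absent from the IL;
#'   \item novel bands — loci present in the IL but absent from BOTH parents,
#'     regardless of reference status (novel and reference-co-migrating
#'     tallies may overlap);
#'   \item reference-specific bands — reference-co-migrating,
#'     parent-absent loci present in the IL (NA without a reference sample).
#' }
#' Shared parental loci are uninformative for event calling and only enter a
#' diagnostics column (\code{n_shared_absent}, shared bands unexpectedly
#' missing from the IL).
#'
#' @param x the \linkS4class{BandSet} the origins were computed from.
#' @param origins result of \code{\link{classifyLoci}(x)}.
#' @return a \link[S4Vectors]{DataFrame} with one row per IL and columns
#'   \code{n_introgressed}, \code{n_lost}, \code{n_novel}, \code{n_reference},
#'   \code{n_shared_absent}; \code{metadata()$loci} holds the per-IL locus
#'   id lists and \code{metadata()$denominators} is carried over.
#' @export
callEvents <- function(x, origins) {
  stopifnot(methods::is(x, "BandSet"))
  g <- geneticLoci(x)
  if (!identical(rownames(g), rownames(origins)))
    stop("origins do not match the SSR/AFLP loci of the matrix")
  ils <- ilSamples(g)
  if (!length(ils))
    stop("at least one IL sample is required for event calling")
  P <- channelPresence(g, "H")
  cat_ <- origins$category
  refflag <- origins$reference_comigrating
  has_ref <- !all(is.na(refflag))
  per_il <- lapply(ils, function(il) {
    pres <- P[, il] == 1L
    list(introgressed = rownames(g)[cat_ == "DONOR_SPECIFIC" & pres],
         lost = rownames(g)[cat_ == "RECURRENT_SPECIFIC" & !pres],
         novel = rownames(g)[cat_ == "ABSENT_IN_PARENTS" & pres],
         reference = if (has_ref)
           rownames(g)[cat_ == "ABSENT_IN_PARENTS" & refflag %in% TRUE & pres]
         else NULL,
         shared_absent = rownames(g)[cat_ == "SHARED_PARENTAL" & !pres])
  })
  names(per_il) <- ils
  cnt <- function(field) unname(vapply(per_il, function(e)
    length(e[[field]]), 1L))
  out <- S4Vectors::DataFrame(
    n_introgressed = cnt("introgressed"),
    n_lost = cnt("lost"),
    n_novel = cnt("novel"),
    n_reference = if (has_ref) cnt("reference")
    else rep(NA_integer_, length(ils)),
    n_shared_absent = cnt("shared_absent"),
    row.names = ils)
  S4Vectors::metadata(out)$loci <- per_il
  S4Vectors::metadata(out)$denominators <- originDenominators(origins)
  out
}

## resolve denominators for summarizeGenetic: either carried in events/origins
## metadata or supplied explicitly
resolveDenominators <- function(events, origins, denominators) {
  if (!is.null(denominators)) {
    stopifnot(all(c("donor", "recurrent") %in% names(denominators)))
    if (is.null(denominators$reference))
      denominators$reference <- NA_integer_
    return(denominators)
  }
  d <- if (!is.null(origins)) originDenominators(origins)
  else S4Vectors::metadata(events)$denominators
  if (is.null(d))
    stop("supply `origins` or explicit `denominators`")
  list(donor = d$n_donor_specific, recurrent = d$n_recurrent_specific,
       reference = d$n_reference_specific)
}

#' Summarize genetic events across ILs
#'
#' Produces the publication-style aggregate of an event table: per-IL counts,
#' column means (1 decimal place, halves rounded away from zero) and overall
#' frequencies. Frequencies are computed from the unrounded column sums as
#' \eqn{100 \cdot \sum_i k_i / (N_{IL} \cdot D)} and then rounded, where the
#' denominator D is the number of informative loci for that event class:
#' donor-specific for introgression, recurrent-specific for loss,
#' reference-specific for reference-co-migrating bands. No denominator for
#' novel bands exists a priori; the default uses the recurrent-specific count
#' (\code{novelDenominator = "recurrent"}), which reproduces published usage;
#' \code{"reference"} or a custom \code{novelN} may be chosen instead.
#'
#' @param events a per-IL event table: the result of \code{\link{callEvents}}
#'   or any data.frame with columns \code{n_introgressed}, \code{n_lost},
#'   \code{n_novel}, \code{n_reference} (row names = IL ids).
#' @param origins optional \code{\link{classifyLoci}} result supplying
#'   denominators.
#' @param denominators optional explicit list with elements \code{donor},
#'   \code{recurrent} and (optionally) \code{reference}; overrides
#'   \code{origins}.
#' @param novelDenominator \code{"recurrent"} (default) or \code{"reference"}.
#' @param novelN optional custom integer denominator for the novel-band
#'   frequency; overrides \code{novelDenominator}.
#' @return an object of class \code{genetic_summary}: a list with
#'   \code{per_il} (counts data.frame), \code{totals}, \code{average}
#'   (1 dp), \code{frequency_pct} (1 dp percent; \code{NA} when a denominator
#'   is missing or zero), \code{denominators} and \code{n_il}.
#' @export
summarizeGenetic <- function(events, origins = NULL, denominators = NULL,
                             novelDenominator = c("recurrent", "reference"),
                             novelN = NULL) {
  novelDenominator <- match.arg(novelDenominator)
  dd <- resolveDenominators(events, origins, denominators)
  ev <- as.data.frame(events)
  cols <- c("n_introgressed", "n_lost", "n_novel", "n_reference")
  if (!all(cols %in% colnames(ev)))
    stop("events must contain columns ", paste(cols, collapse = ", "))
  ev <- ev[, cols]
  n_il <- nrow(ev)
  if (n_il < 1L) stop("at least one IL is required")
  d_novel <- if (!is.null(novelN)) novelN
  else if (novelDenominator == "recurrent") dd$recurrent else dd$reference
  D <- c(n_introgressed = dd$donor, n_lost = dd$recurrent,
         n_novel = d_novel, n_reference = dd$reference)
  totals <- vapply(ev, function(v) sum(as.numeric(v)), 0)
  average <- roundHalfUp(totals / n_il, 1L)
  freq <- rep(NA_real_, length(cols))
  names(freq) <- cols
  for (k in cols) {
    if (is.na(D[[k]]) || is.na(totals[[k]])) {
      warning("frequency for ", k, " is not assessable ",
              "(missing denominator or counts)", call. = FALSE)
    } else if (D[[k]] == 0) {
      warning("zero denominator for ", k, "; frequency omitted",
              call. = FALSE)
    } else {
      freq[[k]] <- roundHalfUp(100 * totals[[k]] / (n_il * D[[k]]), 1L)
    }
  }
  structure(list(per_il = ev, totals = totals, average = average,
                 frequency_pct = freq, denominators = as.list(D),
                 n_il = n_il),
            class = "genetic_summary")
}

#' @export
print.genetic_summary <- function(x, ...) {
  tab <- x$per_il
  tab[] <- lapply(tab, function(v) formatC(v, format = "d"))
  tab <- rbind(tab,
               Average = fmt1(x$average),
               `Frequency (%)` = fmt1(x$frequency_pct))
  cat("Genetic event summary over", x$n_il, "ILs\n")
  cat("(denominators: donor-specific =", x$denominators$n_introgressed,
      "| recurrent-specific =", x$denominators$n_lost,
      "| novel =", x$denominators$n_novel,
      "| reference-specific =", x$denominators$n_reference, ")\n")
  print(tab)
  invisible(x)
}

#' Parental locus accounting
#'
#' Totals of distinct parental loci: the union of bands present in either
#' parent, the shared (co-migrating) fraction, and the polymorphic fraction
#' with its percentage at 1 decimal place.
#'
#' @param origins result of \code{\link{classifyLoci}}.
#' @return a list with \code{n_total} (loci present in at least one parent),
#'   \code{n_shared}, \code{n_polymorphic} and \code{pct_polymorphic}.
#' @export
parentalAccounting <- function(origins) {
  d <- originDenominators(origins)
  parentalAccountingFromTotals(
    nRecurrent = d$n_shared + d$n_recurrent_specific,
    nDonor = d$n_shared + d$n_donor_specific,
    nShared = d$n_shared)
}

#' @rdname parentalAccounting
#' @param nRecurrent number of bands in the recurrent parent's profile.
#' @param nDonor number of bands in the donor parent's profile.
#' @param nShared number of bands co-migrating in both parents.
#' @export
parentalAccountingFromTotals <- function(nRecurrent, nDonor, nShared) {
  stopifnot(nShared <= nRecurrent, nShared <= nDonor)
  n_total <- nRecurrent + nDonor - nShared
  n_poly <- n_total - nShared
  list(n_total = n_total,
       n_shared = nShared,
       n_polymorphic = n_poly,
       pct_polymorphic = if (n_total > 0)
         roundHalfUp(100 * n_poly / n_total, 1L) else NA_real_)
}
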