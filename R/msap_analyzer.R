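#' Methylation state from a dual-digest band pattern
#'
#' MSAP scores each fragment in two lanes: EcoRI+HpaII (H) and EcoRI+MspI
#' (M). The isoschizomers HpaII and MspI cut CCGG sites differently depending
#' on cytosine methylation, so the presence pattern classifies the site:
#' \itemize{
#'   \item \code{A} = (H=1, M=1): band in both digests — non-methylated site
#'     (or methylation confined to a single strand);
#'   \item \code{B} = (H=1, M=0): band in HpaII only — hemi-methylated
#'     (half-methylation) site;
#'   \item \code{C} = (H=0, M=1): band in MspI only — fully methylated
#'     (internal-cytosine) site;
#'   \item \code{D} = (H=0, M=0): no band in either digest (not named in the
#'     classical three-type scheme; either methylation of both cytosines
#'     beyond either enzyme's tolerance, or loss of the site).
#' }
#'
#' @param h,m binary vectors: band presence in the HpaII and MspI lanes.
#' @return character vector of states \code{"A"/"B"/"C"/"D"}.
#' @export
#' @examples
#' bandState(c(1, 1, 0, 0), c(1, 0, 1, 0))  # "A" "B" "C" "D"
bandState <- function(h, m) {
  stopifnot(length(h) == length(m), all(h %in% c(0, 1)), all(m %in% c(0, 1)))
  c("D", "C", "B", "A")[as.integer(h) * 2L + as.integer(m) + 1L]
}

#' Compare methylation states between recurrent parent and IL
#'
#' States are ordered by methylation level A < B < C; an IL state above the
#' parent's is a hypermethylation event, below it a hypomethylation event,
#' equal states are no event. The all-absent state D confounds heavy
#' methylation with sequence loss, so under the default
#' \code{dPolicy = "uninformative"} any comparison involving D is
#' \code{UNINFORMATIVE}; \code{dPolicy = "top_level"} instead treats D as the
#' most-methylated level (A < B < C < D), as parts of the MSAP literature do.
#'
#' @param parent,il character vectors of states ("A"/"B"/"C"/"D"),
#'   recycled to a common length.
#' @param dPolicy how to treat state D (see above).
#' @return character vector over \code{HYPER}, \code{HYPO}, \code{NONE},
#'   \code{UNINFORMATIVE}.
#' @export
#' @examples
#' compareStates("A", "C")                         # HYPER
#' compareStates("C", "A")                         # HYPO
#' compareStates("B", "D")                         # UNINFORMATIVE
#' compareStates("B", "D", dPolicy = "top_level")  # HYPER
compareStates <- function(parent, il,
                          dPolicy = c("uninformative", "top_level")) {
  dPolicy <- match.arg(dPolicy)
  stopifnot(all(parent %in% METHYLATION_STATES),
            all(il %in% METHYLATION_STATES))
  n <- max(length(parent), length(il))
  parent <- rep_len(parent, n)
  il <- rep_len(il, n)
  lv <- c(A = 0, B = 1, C = 2, D = if (dPolicy == "top_level") 3 else NA)
  lp <- lv[parent]
  li <- lv[il]
  out <- rep("UNINFORMATIVE", n)
  ok <- !is.na(lp) & !is.na(li)
  out[ok & li > lp] <- "HYPER"
  out[ok & li < lp] <- "HYPO"
  out[ok & li == lp] <- "NONE"
  out
}

## parent/IL MSAP states for the informative loci of a BandSet (internal)
msapStates <- function(x) {
  m <- msapLoci(x)
  if (nrow(m) == 0L)
    stop("no MSAP loci in the matrix")
  H <- channelPresence(m, "H")
  M <- channelPresence(m, "M")
  rec <- recurrentParent(m)
  don <- donorParent(m)
  ## informative = banded in the recurrent parent (either lane), absent from
  ## the donor parent in both lanes
  informative <- (H[, rec] + M[, rec] >= 1L) & (H[, don] + M[, don] == 0L)
  ils <- ilSamples(m)
  if (!length(ils))
    stop("at least one IL sample is required")
  il_states <- matrix(vapply(ils, function(s) bandState(H[, s], M[, s]),
                             character(nrow(m))),
                      nrow = nrow(m), dimnames = list(rownames(m), ils))
  list(locus_id = rownames(m),
       informative = informative,
       parent_state = bandState(H[, rec], M[, rec]),
       il_states = il_states,
       ils = ils)
}

#' Summarize MSAP methylation changes across ILs
#'
#' Classifies each MSAP locus into a methylation state per sample
#' (\code{\link{bandState}}), compares each IL with the recurrent parent at
#' the informative loci (banded in the recurrent parent, absent from the
#' donor — the loci where a change is attributable to the IL rather than to
#' donor chromatin), and tabulates hyper-/hypomethylation events.
#'
#' Frequencies divide by the informative-locus count \code{D_msap} (or an
#' explicit \code{denominator} override for replicating published tables):
#' per-IL frequency = 100 k / D, overall frequency = 100 (column sum) /
#' (N_IL D), all at 1 decimal place, halves away from zero. The total-change
#' percentage is the sum of the two rounded overall frequencies, matching how
#' such tables are typically totalled.
#'
#' @param x a \linkS4class{BandSet} containing MSAP loci and both parents.
#' @param dPolicy passed to \code{\link{compareStates}}.
#' @param denominator optional explicit frequency denominator.
#' @return an object of class \code{msap_summary}: list with \code{per_il}
#'   (counts, per-IL percent frequencies, and n_none/n_uninformative so each
#'   row sums to D_msap), \code{average}, \code{frequency_pct} (overall hyper
#'   and hypo percent), \code{total_change_pct}, \code{d_msap}, \code{n_il},
#'   \code{d_policy}.
#' @export
summarizeMsap <- function(x, dPolicy = c("uninformative", "top_level"),
                          denominator = NULL) {
  dPolicy <- match.arg(dPolicy)
  st <- msapStates(x)
  keep <- st$informative
  d_msap <- sum(keep)
  if (d_msap == 0L)
    stop("no informative MSAP loci (recurrent-parent-banded, donor-absent)")
  parent <- st$parent_state[keep]
  counts <- t(vapply(st$ils, function(s) {
    ev <- compareStates(parent, st$il_states[keep, s], dPolicy = dPolicy)
    c(n_hyper = sum(ev == "HYPER"), n_hypo = sum(ev == "HYPO"),
      n_none = sum(ev == "NONE"),
      n_uninformative = sum(ev == "UNINFORMATIVE"))
  }, numeric(4)))
  msapSummaryFromCounts(hyper = counts[, "n_hyper"],
                        hypo = counts[, "n_hypo"],
                        dMsap = if (is.null(denominator)) d_msap
                        else denominator,
                        sampleId = st$ils,
                        none = counts[, "n_none"],
                        uninformative = counts[, "n_uninformative"],
                        dPolicy = dPolicy)
}

#' @rdname summarizeMsap
#' @param hyper,hypo integer vectors of per-IL hyper-/hypomethylation event
#'   counts (for building the summary from pre-tabulated counts).
#' @param dMsap the informative-locus denominator.
#' @param sampleId optional IL names.
#' @param none,uninformative optional per-IL counts of the remaining loci.
#' @export
msapSummaryFromCounts <- function(hyper, hypo, dMsap, sampleId = NULL,
                                  none = NA_integer_,
                                  uninformative = NA_integer_,
                                  dPolicy = NA_character_) {
  stopifnot(length(hyper) == length(hypo), dMsap > 0)
  n_il <- length(hyper)
  if (is.null(sampleId)) sampleId <- paste0("IL", seq_len(n_il))
  per_il <- data.frame(
    n_hyper = as.integer(hyper),
    freq_hyper_pct = roundHalfUp(100 * hyper / dMsap, 1L),
    n_hypo = as.integer(hypo),
    freq_hypo_pct = roundHalfUp(100 * hypo / dMsap, 1L),
    n_none = as.integer(rep_len(none, n_il)),
    n_uninformative = as.integer(rep_len(uninformative, n_il)),
    row.names = sampleId)
  freq <- c(hyper = roundHalfUp(100 * sum(hyper) / (n_il * dMsap), 1L),
            hypo = roundHalfUp(100 * sum(hypo) / (n_il * dMsap), 1L))
  structure(list(per_il = per_il,
                 average = c(hyper = roundHalfUp(sum(hyper) / n_il, 1L),
                             hypo = roundHalfUp(sum(hypo) / n_il, 1L)),
                 frequency_pct = freq,
                 total_change_pct = unname(freq["hyper"] + freq["hypo"]),
                 d_msap = dMsap, n_il = n_il, d_policy = dPolicy),
            class = "msap_summary")
}

#' @export
print.msap_summary <- function(x, ...) {
  cat("MSAP methylation-change summary over", x$n_il, "ILs",
      "(informative loci D =", paste0(x$d_msap, ")"), "\n")
  tab <- x$per_il[, c("n_hyper", "freq_hyper_pct", "n_hypo", "freq_hypo_pct")]
  tab$freq_hyper_pct <- fmt1(tab$freq_hyper_pct)
  tab$freq_hypo_pct <- fmt1(tab$freq_hypo_pct)
  tab <- rbind(tab, Average = c(fmt1(x$average["hyper"]),
                                fmt1(x$frequency_pct["hyper"]),
                                fmt1(x$average["hypo"]),
                                fmt1(x$frequency_pct["hypo"])))
  print(tab)
  cat("Total methylation change:", fmt1(x$total_change_pct), "%\n")
  invisible(x)
}
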