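#' Parameters for the synthetic fingerprint generator
#'
#' Defines the study conditions emulated by \code{\link{generateBandSet}}:
#' a recurrent parent, a donor parent, an allotetraploid reference and a set
#' of introgression lines scored over dominant SSR/AFLP-style loci and
#' dual-channel MSAP loci. Defaults are the observed structure of a typical
#' asymmetric-somatic-hybridization marker screen: 1117 bands co-migrating in
#' both parents, 376 recurrent-parent-specific, 306 donor-specific and 226
#' reference-specific loci; 12 ILs; per-locus Bernoulli event rates 0.075
#' (introgression of a donor band), 0.051 (loss of a recurrent band), 0.014
#' (novel bands, expressed per recurrent-specific locus), 0.155 (presence of
#' a reference-specific band); and an MSAP block of 290 informative loci with
#' hyper-/hypomethylation transition probabilities 0.124 / 0.048.
#'
#' @param nShared,nRecurrentSpecific,nDonorSpecific,nReferenceSpecific
#'   genetic locus counts by parental origin.
#' @param nIls number of introgression lines.
#' @param pIntrogress probability a donor-specific band is present in an IL.
#' @param pLoss probability a recurrent-specific band is lost in an IL.
#' @param pNovel expected novel bands per IL per recurrent-specific locus
#'   (novel bands are brand-new loci absent from both parents).
#' @param pReferencePresent probability a reference-specific band appears in
#'   an IL.
#' @param nMsapInformative number of MSAP loci banded in the recurrent parent
#'   and absent from the donor (the event denominator).
#' @param nMsapShared number of additional MSAP loci banded in both parents
#'   (excluded from event denominators; ILs inherit the parental state).
#' @param msapParentStateProbs distribution of the recurrent parent's state
#'   over A (unmethylated), B (hemi-methylated), C (fully methylated) at
#'   informative loci.
#' @param pHyper,pHypo per-locus probabilities that an IL moves one
#'   methylation level up / down from the parental state (a locus already at
#'   the boundary cannot move further and stays unchanged).
#' @param pNovelInReference fraction of novel bands that also co-migrate with
#'   the reference, mimicking overlapping novel/reference tallies.
#' @param msapTwoStep when \code{TRUE}, an upward move from state A goes to B
#'   or C with equal probability instead of always one step.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return a validated list of class \code{simulation_params}.
#' @export
simulationParams <- function(nShared = 1117L,
                             nRecurrentSpecific = 376L,
                             nDonorSpecific = 306L,
                             nReferenceSpecific = 226L,
                             nIls = 12L,
                             pIntrogress = 0.075,
                             pLoss = 0.051,
                             pNovel = 0.014,
                             pReferencePresent = 0.155,
                             nMsapInformative = 290L,
                             nMsapShared = 111L,
                             msapParentStateProbs = c(A = 0.50, B = 0.30,
                                                      C = 0.20),
                             pHyper = 0.124,
                             pHypo = 0.048,
                             pNovelInReference = 0,
                             msapTwoStep = FALSE,
                             seed = 1L) {
  p <- list(nShared = as.integer(nShared),
            nRecurrentSpecific = as.integer(nRecurrentSpecific),
            nDonorSpecific = as.integer(nDonorSpecific),
            nReferenceSpecific = as.integer(nReferenceSpecific),
            nIls = as.integer(nIls),
            pIntrogress = pIntrogress, pLoss = pLoss, pNovel = pNovel,
            pReferencePresent = pReferencePresent,
            nMsapInformative = as.integer(nMsapInformative),
            nMsapShared = as.integer(nMsapShared),
            msapParentStateProbs = msapParentStateProbs,
            pHyper = pHyper, pHypo = pHypo,
            pNovelInReference = pNovelInReference,
            msapTwoStep = isTRUE(msapTwoStep),
            seed = as.integer(seed))
  counts <- unlist(p[c("nShared", "nRecurrentSpecific", "nDonorSpecific",
                       "nReferenceSpecific", "nIls", "nMsapInformative",
                       "nMsapShared")])
  if (any(counts < 0L)) stop("locus and sample counts must be >= 0")
  probs <- unlist(p[c("pIntrogress", "pLoss", "pNovel", "pReferencePresent",
                      "pHyper", "pHypo", "pNovelInReference")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (p$pHyper + p$pHypo > 1) stop("pHyper + pHypo must be <= 1")
  sp <- p$msapParentStateProbs
  if (!all(c("A", "B", "C") %in% names(sp)) || any(sp < 0) || sum(sp) <= 0)
    stop("msapParentStateProbs must be non-negative and named A, B, C")
  p$msapParentStateProbs <- sp[c("A", "B", "C")] / sum(sp)
  structure(p, class = "simulation_params")
}

## one-step methylation transitions (internal)
moveUp <- function(state, twoStep) {
  vapply(state, function(s) switch(s,
    A = if (twoStep) sample(c("B", "C"), 1L) else "B",
    B = "C", C = "C", D = "D"), character(1), USE.NAMES = FALSE)
}
moveDown <- function(state) {
  c(A = "A", B = "A", C = "B", D = "D")[state]
}

#' Generate a synthetic band matrix with ground truth
#'
#' Simulates parent, reference and IL fingerprints under the model described
#' in \code{\link{simulationParams}}. Parents are noise-free fixed profiles;
#' only ILs carry stochastic events, drawn independently per (IL, locus) as
#' Bernoulli trials. Novel bands are created as brand-new loci absent from
#' all parents (and, unless \code{pNovelInReference > 0}, from the
#' reference). MSAP IL states move at most one methylation level per event.
#'
#' @param params a \code{\link{simulationParams}} object.
#' @return a list with \code{bandSet} (a canonical-order
#'   \linkS4class{BandSet} that validates under strict I/O) and \code{truth}
#'   (class \code{simulation_truth}): the parameters, per-genetic-locus
#'   category labels, per-IL event locus lists, MSAP parental states and the
#'   realized per-(locus, IL) MSAP event matrix.
#' @export
#' @examples
#' sim <- generateBandSet(simulationParams(nIls = 3, seed = 42))
#' sim$bandSet
#' lengths(sim$truth$genetic[["IL001"]])
generateBandSet <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  nIl <- params$nIls
  ils <- sprintf("IL%03d", seq_len(nIl))
  samples <- c("recurrent", "donor", "reference", ils)
  roles <- c("RECURRENT_PARENT", "DONOR_PARENT", "REFERENCE",
             rep("IL", nIl))

  ## genetic (single-channel) loci
  lab <- function(prefix, n) if (n > 0L) sprintf("%s%05d", prefix, seq_len(n))
    else character()
  shared <- lab("S", params$nShared)
  recsp <- lab("R", params$nRecurrentSpecific)
  donsp <- lab("D", params$nDonorSpecific)
  refsp <- lab("C", params$nReferenceSpecific)
  base_labels <- c(shared, recsp, donsp, refsp)
  nb <- length(base_labels)
  P <- matrix(0L, nb, length(samples),
              dimnames = list(base_labels, samples))
  is_shared <- base_labels %in% shared
  is_rec <- base_labels %in% recsp
  is_don <- base_labels %in% donsp
  is_ref <- base_labels %in% refsp
  P[is_shared | is_rec, "recurrent"] <- 1L
  P[is_shared | is_don, "donor"] <- 1L
  P[is_ref, "reference"] <- 1L

  truth_genetic <- vector("list", nIl)
  names(truth_genetic) <- ils
  novel_per_il <- vector("list", nIl)
  for (i in seq_len(nIl)) {
    il <- ils[i]
    P[is_shared, il] <- 1L
    kept <- stats::rbinom(sum(is_rec), 1L, 1 - params$pLoss)
    P[is_rec, il] <- kept
    intro <- stats::rbinom(sum(is_don), 1L, params$pIntrogress)
    P[is_don, il] <- intro
    refp <- stats::rbinom(sum(is_ref), 1L, params$pReferencePresent)
    P[is_ref, il] <- refp
    k_novel <- stats::rbinom(1L, sum(is_rec), params$pNovel)
    novel_per_il[[i]] <- k_novel
    truth_genetic[[il]] <- list(
      introgressed = canonicalLocusId("AFLP", "SIM", donsp[intro == 1L]),
      lost = canonicalLocusId("AFLP", "SIM", recsp[kept == 0L]),
      reference_present = canonicalLocusId("AFLP", "SIM",
                                           refsp[refp == 1L]))
  }
  ## novel loci: brand-new bands, each private to one IL
  n_novel <- sum(unlist(novel_per_il))
  novel_labels <- lab("N", n_novel)
  if (n_novel > 0L) {
    NV <- matrix(0L, n_novel, length(samples),
                 dimnames = list(novel_labels, samples))
    owner <- rep(seq_len(nIl), times = unlist(novel_per_il))
    NV[cbind(seq_len(n_novel), 3L + owner)] <- 1L
    NV[, "reference"] <- stats::rbinom(n_novel, 1L,
                                       params$pNovelInReference)
    P <- rbind(P, NV)
    for (i in seq_len(nIl))
      truth_genetic[[ils[i]]]$novel <-
        canonicalLocusId("AFLP", "SIM", novel_labels[owner == i])
  } else {
    for (i in seq_len(nIl)) truth_genetic[[ils[i]]]$novel <- character()
  }
  g_labels <- rownames(P)
  g_category <- c(rep("SHARED_PARENTAL", length(shared)),
                  rep("RECURRENT_SPECIFIC", length(recsp)),
                  rep("DONOR_SPECIFIC", length(donsp)),
                  rep("REFERENCE_SPECIFIC", length(refsp)),
                  rep("NOVEL", n_novel))
  names(g_category) <- canonicalLocusId("AFLP", "SIM", g_labels)

  ## MSAP loci
  n_mi <- params$nMsapInformative
  n_ms <- params$nMsapShared
  m_labels <- c(lab("MI", n_mi), lab("MS", n_ms))
  nm <- length(m_labels)
  stateH <- c(A = 1L, B = 1L, C = 0L, D = 0L)
  stateM <- c(A = 1L, B = 0L, C = 1L, D = 0L)
  MH <- MM <- matrix(0L, nm, length(samples),
                     dimnames = list(m_labels, samples))
  msap_events <- NULL
  parent_states <- character()
  if (nm > 0L) {
    sp <- params$msapParentStateProbs
    parent_states <- sample(names(sp), nm, replace = TRUE, prob = sp)
    names(parent_states) <- canonicalLocusId("MSAP", "SIM", m_labels)
    MH[, "recurrent"] <- stateH[parent_states]
    MM[, "recurrent"] <- stateM[parent_states]
    if (n_ms > 0L) {  # shared MSAP bands: donor carries the same state
      sh <- seq.int(n_mi + 1L, nm)
      MH[sh, "donor"] <- MH[sh, "recurrent"]
      MM[sh, "donor"] <- MM[sh, "recurrent"]
    }
    msap_events <- matrix(
      "NONE", n_mi, nIl,
      dimnames = list(canonicalLocusId("MSAP", "SIM",
                                       m_labels[seq_len(n_mi)]), ils))
    for (i in seq_len(nIl)) {
      il <- ils[i]
      st <- parent_states
      if (n_mi > 0L) {
        u <- stats::runif(n_mi)
        up <- u < params$pHyper
        down <- !up & u < params$pHyper + params$pHypo
        st[seq_len(n_mi)][up] <-
          moveUp(parent_states[seq_len(n_mi)][up], params$msapTwoStep)
        st[seq_len(n_mi)][down] <-
          moveDown(parent_states[seq_len(n_mi)][down])
        msap_events[, i] <- compareStates(parent_states[seq_len(n_mi)],
                                          st[seq_len(n_mi)])
      }
      MH[, il] <- stateH[st]
      MM[, il] <- stateM[st]
    }
  }

  ## assemble in canonical order (genetic labels sort before none; loci are
  ## already label-sorted within marker system, and AFLP: < MSAP:)
  H <- rbind(P, MH)
  M <- rbind(P, MM)
  bs <- BandSet(H = H, M = M,
                markerSystem = c(rep("AFLP", nrow(P)), rep("MSAP", nm)),
                primerCombo = "SIM",
                bandLabel = c(g_labels, m_labels),
                sampleId = samples, role = roles)
  ord <- order(rownames(bs), method = "radix")
  bs <- bs[ord, ]
  truth <- structure(list(params = params,
                          locus_category = g_category,
                          genetic = truth_genetic,
                          msap_parent_states = parent_states,
                          msap_events = msap_events),
                     class = "simulation_truth")
  list(bandSet = bs, truth = truth)
}

#' Estimate generating rates from a band matrix
#'
#' Recovers the per-locus event rates of the generative model from any band
#' matrix with declared roles, with normal-approximation binomial confidence
#' intervals (clipped to [0, 1]). The genetic point estimates are the
#' pipeline's unrounded overall frequencies: events divided by exposure
#' (number of ILs x informative-locus denominator). Two refinements make the
#' estimators consistent for the generating rates: novel bands that
#' co-migrate with the reference are excluded from the novel-rate numerator
#' (they are driven by the reference-presence rate), and the MSAP rates are
#' computed per opportunity — a locus whose parental state is already at the
#' top (C) cannot gain methylation, so the hypermethylation exposure counts
#' only parental states A/B, and the hypomethylation exposure only B/C.
#'
#' @param x a \linkS4class{BandSet} with roles declared.
#' @param conf confidence level (default 0.95).
#' @return a data.frame with columns \code{rate}, \code{estimate},
#'   \code{lower}, \code{upper}, \code{events}, \code{exposure}.
#' @export
recoverRates <- function(x, conf = 0.95) {
  origins <- classifyLoci(x)
  events <- callEvents(x, origins)
  d <- originDenominators(origins)
  nIl <- nrow(events)
  loci <- S4Vectors::metadata(events)$loci
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- list()
  addRow <- function(rate, k, n) {
    if (is.na(n) || n == 0) {
      rows[[rate]] <<- data.frame(rate = rate, estimate = NA_real_,
                                  lower = 0, upper = 1, events = k,
                                  exposure = n)
      return(invisible())
    }
    p <- k / n
    se <- sqrt(p * (1 - p) / n)
    rows[[rate]] <<- data.frame(rate = rate, estimate = p,
                                lower = max(0, p - z * se),
                                upper = min(1, p + z * se),
                                events = k, exposure = n)
  }
  addRow("p_introgress", sum(events$n_introgressed),
         nIl * d$n_donor_specific)
  addRow("p_loss", sum(events$n_lost), nIl * d$n_recurrent_specific)
  ref_ids <- rownames(origins)[origins$category == "ABSENT_IN_PARENTS" &
                                 origins$reference_comigrating %in% TRUE]
  k_novel <- sum(vapply(loci, function(e)
    length(setdiff(e$novel, ref_ids)), 1L))
  addRow("p_novel", k_novel, nIl * d$n_recurrent_specific)
  if (!is.na(d$n_reference_specific))
    addRow("p_reference_present", sum(events$n_reference),
           nIl * d$n_reference_specific)
  if (any(markerSystem(x) == "MSAP")) {
    st <- msapStates(x)
    parent <- st$parent_state[st$informative]
    ilst <- st$il_states[st$informative, , drop = FALSE]
    ev <- apply(ilst, 2L, function(s) compareStates(parent, s))
    addRow("p_hyper", sum(ev == "HYPER"),
           nIl * sum(parent %in% c("A", "B")))
    addRow("p_hypo", sum(ev == "HYPO"),
           nIl * sum(parent %in% c("B", "C")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
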