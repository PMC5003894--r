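test_that("loci are classified by the 2x2 parental presence table", {
  x <- readBandMatrix(toyMatrixPath())
  org <- classifyLoci(x)
  expect_equal(unname(org["SSR:Ol10:BrID10227", "category"]),
               factor("DONOR_SPECIFIC", levels = levels(org$category)))
  expect_equal(as.character(org["SSR:Ol11:BrID10205", "category"]),
               "RECURRENT_SPECIFIC")
  expect_equal(as.character(org["AFLP:E45-M57:150bp", "category"]),
               "SHARED_PARENTAL")
  expect_equal(as.character(org["SSR:Na15:cnu-m052a", "category"]),
               "ABSENT_IN_PARENTS")
  expect_true(org["SSR:Na15:cnu-m052a", "reference_comigrating"])
  d <- originDenominators(org)
  expect_equal(d$n_donor_specific, 3L)
  expect_equal(d$n_recurrent_specific, 4L)
  expect_equal(d$n_reference_specific, 2L)
  expect_equal(d$n_shared, 3L)
  # partition + accounting identities
  expect_equal(d$n_shared + d$n_recurrent_specific + d$n_donor_specific +
                 d$n_absent_in_parents, sum(markerSystem(x) != "MSAP"))
  expect_equal(d$n_total_distinct_parental,
               d$n_shared + d$n_recurrent_specific + d$n_donor_specific)
  expect_equal(d$n_polymorphic, d$n_total_distinct_parental - d$n_shared)
})

test_that("MSAP loci are excluded and MSAP-only matrices are rejected", {
  x <- readBandMatrix(toyMatrixPath())
  org <- classifyLoci(x)
  expect_false(any(grepl("^MSAP:", rownames(org))))
  expect_error(classifyLoci(msapLoci(x)), "no SSR/AFLP loci")
})

test_that("per-IL events match the toy fixture's construction", {
  x <- readBandMatrix(toyMatrixPath())
  org <- classifyLoci(x)
  ev <- callEvents(x, org)
  li <- S4Vectors::metadata(ev)$loci
  # IL11 carries exactly the three donor-specific SSR bands
  expect_setequal(li$IL11$introgressed,
                  c("SSR:Ol10:BrID10227", "SSR:Na12:nia-m037a",
                    "SSR:At3:At3g55005a"))
  expect_equal(ev["IL11", "n_introgressed"], 3L)
  # counts equal list lengths
  for (il in rownames(ev)) {
    expect_equal(ev[il, "n_introgressed"], length(li[[il]]$introgressed))
    expect_equal(ev[il, "n_lost"], length(li[[il]]$lost))
    expect_equal(ev[il, "n_novel"], length(li[[il]]$novel))
  }
  # novel and reference-co-migrating tallies may overlap (IL11's cnu-m052a)
  expect_true("SSR:Na15:cnu-m052a" %in% li$IL11$novel)
  expect_true("SSR:Na15:cnu-m052a" %in% li$IL11$reference)
  # introgression and loss lists draw from disjoint categories
  expect_length(intersect(li$IL11$introgressed, li$IL11$lost), 0L)
})

test_that("an IL identical to the recurrent parent has all-zero events", {
  sim <- generateBandSet(smallParams(seed = 5, pIntrogress = 0, pLoss = 0,
                                     pNovel = 0, pReferencePresent = 0))
  org <- classifyLoci(sim$bandSet)
  ev <- callEvents(sim$bandSet, org)
  expect_true(all(ev$n_introgressed == 0L))
  expect_true(all(ev$n_lost == 0L))
  expect_true(all(ev$n_novel == 0L))
  expect_true(all(ev$n_reference == 0L))
})

test_that("event counts equal a brute-force per-locus re-count on random matrices", {
  for (s in c(2, 7, 13)) {
    x <- randomBandSet(s, nGenetic = 80, nMsap = 10, nIl = 4)
    org <- classifyLoci(x)
    ev <- callEvents(x, org)
    bf <- bruteForceGeneticCounts(x)
    expect_equal(as.data.frame(ev)[, colnames(bf)], bf)
    acc <- parentalAccounting(org)
    bfa <- bruteForceParentalAccounting(x)
    expect_equal(acc$n_total, bfa$n_total)
    expect_equal(acc$n_shared, bfa$n_shared)
    expect_equal(acc$n_polymorphic, bfa$n_polymorphic)
  }
})

test_that("adding one donor-specific presence raises only that IL's introgression count by one", {
  x <- randomBandSet(21, nGenetic = 60, nMsap = 0, nIl = 3)
  org <- classifyLoci(x)
  ev0 <- callEvents(x, org)
  don_abs <- rownames(org)[org$category == "DONOR_SPECIFIC"]
  H <- SummarizedExperiment::assay(x, "H")
  target <- don_abs[H[don_abs, "L2"] == 0][1]
  expect_false(is.na(target))
  SummarizedExperiment::assay(x, "H")[target, "L2"] <- 1L
  SummarizedExperiment::assay(x, "M")[target, "L2"] <- 1L
  ev1 <- callEvents(x, classifyLoci(x))
  expect_equal(ev1["L2", "n_introgressed"], ev0["L2", "n_introgressed"] + 1L)
  others <- setdiff(rownames(ev0), "L2")
  expect_equal(as.data.frame(ev1)[others, ], as.data.frame(ev0)[others, ])
})

test_that("summary means and frequencies follow the stated arithmetic", {
  # hand-computed small case: 2 ILs, donor denominator 20, recurrent 10
  ev <- data.frame(n_introgressed = c(3L, 4L), n_lost = c(1L, 2L),
                   n_novel = c(0L, 1L), n_reference = c(2L, 0L),
                   row.names = c("a", "b"))
  gs <- summarizeGenetic(ev, denominators = list(donor = 20, recurrent = 10,
                                                 reference = 8))
  expect_equal(unname(gs$average),
               c(3.5, 1.5, 0.5, 1.0))
  expect_equal(unname(gs$frequency_pct["n_introgressed"]),
               17.5)                       # 100*7/(2*20)
  expect_equal(unname(gs$frequency_pct["n_lost"]), 15.0)    # 100*3/20
  expect_equal(unname(gs$frequency_pct["n_novel"]), 5.0)    # 100*1/20
  expect_equal(unname(gs$frequency_pct["n_reference"]), 12.5)
  # single IL with no events
  ev0 <- data.frame(n_introgressed = 0L, n_lost = 0L, n_novel = 0L,
                    n_reference = 0L)
  gs0 <- summarizeGenetic(ev0, denominators = list(donor = 5, recurrent = 5,
                                                   reference = 5))
  expect_true(all(gs0$average == 0))
  expect_true(all(gs0$frequency_pct == 0))
  # zero or missing denominators warn and yield NA, never divide by zero
  expect_warning(
    gsz <- summarizeGenetic(ev, denominators = list(donor = 20,
                                                    recurrent = 10,
                                                    reference = 0)),
    "zero denominator")
  expect_true(is.na(gsz$frequency_pct["n_reference"]))
})

test_that("frequencies lie in [0, 100] even at extreme rates", {
  sim <- generateBandSet(smallParams(seed = 17, pIntrogress = 1, pLoss = 1,
                                     pReferencePresent = 1))
  org <- classifyLoci(sim$bandSet)
  gs <- summarizeGenetic(callEvents(sim$bandSet, org), org)
  f <- gs$frequency_pct[!is.na(gs$frequency_pct)]
  expect_true(all(f >= 0 & f <= 100))
  expect_equal(unname(gs$frequency_pct["n_introgressed"]), 100)
})

test_that("rounding is half-away-from-zero at one decimal", {
  expect_equal(roundHalfUp(19.25), 19.3)   # bankers' rounding would give 19.2
  expect_equal(roundHalfUp(231 / 12), 19.3)
  expect_equal(roundHalfUp(-0.05), -0.1)
  expect_equal(roundHalfUp(2.04), 2.0)
  expect_equal(roundHalfUp(424 / 12), 35.3)
})

test_that("parental accounting handles identical parents", {
  acc <- parentalAccountingFromTotals(100, 100, 100)
  expect_equal(acc$n_total, 100)
  expect_equal(acc$n_polymorphic, 0)
  expect_equal(acc$pct_polymorphic, 0)
})

test_that("reference-dependent results are flagged not assessable without a reference sample", {
  sim <- generateBandSet(smallParams(seed = 9))
  x <- sim$bandSet[, sampleRoles(sim$bandSet) != "REFERENCE"]
  org <- classifyLoci(x)
  expect_true(all(is.na(org$reference_comigrating)))
  expect_true(is.na(originDenominators(org)$n_reference_specific))
  ev <- callEvents(x, org)
  expect_true(all(is.na(ev$n_reference)))
  expect_warning(gs <- summarizeGenetic(ev, org), "not assessable")
  expect_true(is.na(gs$frequency_pct["n_reference"]))
})
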