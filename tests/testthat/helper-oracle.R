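## Independent brute-force oracles: naive loops over every (IL, locus) pair,
## deliberately avoiding the vectorized code paths under test.

bruteForceGeneticCounts <- function(x) {
  g <- geneticLoci(x)
  P <- channelPresence(g, "H")
  roles <- sampleRoles(g)
  rec <- names(roles)[roles == "RECURRENT_PARENT"]
  don <- names(roles)[roles == "DONOR_PARENT"]
  ref <- names(roles)[roles == "REFERENCE"]
  ils <- names(roles)[roles == "IL"]
  out <- data.frame(n_introgressed = integer(length(ils)),
                    n_lost = integer(length(ils)),
                    n_novel = integer(length(ils)),
                    n_reference = integer(length(ils)),
                    row.names = ils)
  for (il in ils) {
    for (i in seq_len(nrow(g))) {
      r <- P[i, rec]; d <- P[i, don]; p <- P[i, il]
      if (r == 0 && d == 1 && p == 1)
        out[il, "n_introgressed"] <- out[il, "n_introgressed"] + 1L
      if (r == 1 && d == 0 && p == 0)
        out[il, "n_lost"] <- out[il, "n_lost"] + 1L
      if (r == 0 && d == 0 && p == 1)
        out[il, "n_novel"] <- out[il, "n_novel"] + 1L
      if (length(ref) && r == 0 && d == 0 && P[i, ref] == 1 && p == 1)
        out[il, "n_reference"] <- out[il, "n_reference"] + 1L
    }
  }
  out
}

bruteForceParentalAccounting <- function(x) {
  g <- geneticLoci(x)
  P <- channelPresence(g, "H")
  roles <- sampleRoles(g)
  inRec <- rownames(g)[P[, names(roles)[roles == "RECURRENT_PARENT"]] == 1]
  inDon <- rownames(g)[P[, names(roles)[roles == "DONOR_PARENT"]] == 1]
  list(n_total = length(union(inRec, inDon)),
       n_shared = length(intersect(inRec, inDon)),
       n_polymorphic = length(union(inRec, inDon)) -
         length(intersect(inRec, inDon)))
}

## hand-built 16-pair transition truth tables, frozen independently of
## compareStates(): rows are parent state, columns IL state
truthTableUninformative <- matrix(c(
  # IL:    A          B        C        D
  "NONE",  "HYPER", "HYPER", "UNINFORMATIVE",   # parent A
  "HYPO",  "NONE",  "HYPER", "UNINFORMATIVE",   # parent B
  "HYPO",  "HYPO",  "NONE",  "UNINFORMATIVE",   # parent C
  "UNINFORMATIVE", "UNINFORMATIVE", "UNINFORMATIVE", "UNINFORMATIVE"),
  nrow = 4, byrow = TRUE, dimnames = list(c("A", "B", "C", "D"),
                                          c("A", "B", "C", "D")))

truthTableTopLevel <- matrix(c(
  "NONE",  "HYPER", "HYPER", "HYPER",
  "HYPO",  "NONE",  "HYPER", "HYPER",
  "HYPO",  "HYPO",  "NONE",  "HYPER",
  "HYPO",  "HYPO",  "HYPO",  "NONE"),
  nrow = 4, byrow = TRUE, dimnames = list(c("A", "B", "C", "D"),
                                          c("A", "B", "C", "D")))
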