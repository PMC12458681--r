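hotspotInputs <- function(name, chain1 = "A", chain2 = "B") {
  sel <- fixtureSelection(name, chain1, chain2)
  list(summaries = summarizePairs(findContacts(sel)),
       burials = residueBurial(sel))
}

test_that("windows respect the length bounds and cover the contact region", {
  h <- hotspotInputs("helix_pair")
  w <- rankWindows(h$summaries, h$burials, "A")
  expect_true(all(w$length >= 4 & w$length <= 16))
  expect_true(all(w$endRes - w$startRes + 1 == w$length))
  # the top window contains every contact-bearing residue position possible
  contactRes <- unique(h$summaries$resno1)
  top <- w[1, ]
  expect_gte(top$nContacts, max(w$nContacts))
})

test_that("top-1 score equals the brute-force window maximum", {
  for (fx in list(c("helix_pair", "A", "B"), c("nucleic_protein", "B", "A"))) {
    m <- fixtureModel(fx[1])
    sel <- resolveSelection(m, regionSelection(fx[2]), regionSelection(fx[3]))
    sm <- summarizePairs(findContacts(sel))
    b <- residueBurial(sel)
    w <- rankWindows(sm, b, fx[2])
    # oracle: per-residue totals, then exhaustive window enumeration
    res <- b[b$chain == fx[2], ]
    res <- res[order(res$resno), ]
    tot <- sm$nPolar + sm$nNonpolar + sm$nOther + sm$nUntyped
    per <- vapply(res$resno, function(r) {
      sum(tot[sm$chain1 == fx[2] & sm$resno1 == r]) +
        sum(tot[sm$chain2 == fx[2] & sm$resno2 == r])
    }, numeric(1))
    best <- 0
    for (s in seq_along(per)) for (e in seq_along(per)) {
      len <- e - s + 1
      if (len >= 4 && len <= 16) best <- max(best, sum(per[s:e]))
    }
    expect_equal(w$nContacts[1], best)
  }
})

test_that("scores sum per-residue contacts with burial as tie-break", {
  sm <- data.frame(chain1 = "A", resname1 = "ALA", resno1 = c(10L, 11L, 30L),
                   icode1 = "", chain2 = "B", resname2 = "ALA",
                   resno2 = 1L, icode2 = "",
                   nPolar = c(2L, 1L, 3L), nNonpolar = c(0L, 1L, 0L),
                   nOther = 0L, nUntyped = 0L, minDistance = 3.0,
                   stringsAsFactors = FALSE)
  burials <- data.frame(selection = 1L, chain = "A", resname = "ALA",
                        resno = 1:40, icode = "", polymerClass = "protein",
                        sasaFree = 100, sasaComplex = 100, delta = 0,
                        bin = c(rep(0L, 9), 5L, 3L, rep(0L, 29)),
                        stringsAsFactors = FALSE)
  w <- rankWindows(sm, burials, "A")
  # residues 10+11 carry 4 contacts, residue 30 carries 3; a single window
  # cannot span both (21 residues > 16), so the 10-11 cluster wins
  expect_equal(w$nContacts[1], 4L)
  expect_true(w$startRes[1] <= 10 && w$endRes[1] >= 11 && w$endRes[1] < 30)
})

test_that("tie-breaks prefer buried, then N-terminal, then shorter windows", {
  sm <- data.frame(chain1 = "A", resname1 = "ALA", resno1 = c(5L, 25L),
                   icode1 = "", chain2 = "B", resname2 = "ALA", resno2 = 1L,
                   icode2 = "", nPolar = 2L, nNonpolar = 0L, nOther = 0L,
                   nUntyped = 0L, minDistance = 3.0, stringsAsFactors = FALSE)
  burials <- data.frame(selection = 1L, chain = "A", resname = "ALA",
                        resno = 1:30, icode = "", polymerClass = "protein",
                        sasaFree = 100, sasaComplex = 100, delta = 0,
                        bin = c(rep(0L, 24), 4L, rep(0L, 5)),
                        stringsAsFactors = FALSE)
  w <- rankWindows(sm, burials, "A")
  # both isolated contact residues give equal-contact windows; the one
  # containing buried residue 25 wins on nBuried
  expect_equal(w$nContacts[1], 2L)
  expect_true(25 >= w$startRes[1] && 25 <= w$endRes[1])
  # among equal (contacts, buried) windows the N-terminal shortest leads
  same <- w[w$nContacts == 2 & w$nBuried == w$nBuried[1], ]
  expect_equal(same$startRes[1], min(same$startRes))
})

test_that("chains shorter than the minimum window give no windows", {
  sm <- summarizePairs(findContacts(fixtureSelection("two_atoms")))
  b <- residueBurial(fixtureSelection("two_atoms"))
  expect_equal(nrow(rankWindows(sm, b, "A")), 0)
})

test_that("greedy non-overlap selection keeps disjoint top windows", {
  w <- data.frame(chain = "A", startRes = c(10L, 12L, 30L, 28L, 50L),
                  endRes = c(20L, 18L, 40L, 33L, 60L), length = 10L,
                  nContacts = c(9L, 8L, 7L, 6L, 5L), nBuried = 0L,
                  stringsAsFactors = FALSE)
  kept <- selectNonoverlapping(w, 2)
  expect_equal(kept$startRes, c(10L, 30L))
  expect_equal(nrow(selectNonoverlapping(w, 0)), 0)
  all5 <- selectNonoverlapping(w, 5)
  expect_equal(all5$startRes, c(10L, 30L, 50L))  # overlaps dropped
  # disjointness always holds
  for (i in seq_len(nrow(all5))) for (j in seq_len(nrow(all5))) {
    if (i >= j) next
    expect_true(all5$startRes[i] > all5$endRes[j] ||
                  all5$startRes[j] > all5$endRes[i])
  }
})

test_that("ranking is deterministic across reruns", {
  h <- hotspotInputs("nucleic_protein")
  w1 <- rankWindows(h$summaries, h$burials, "A")
  w2 <- rankWindows(h$summaries, h$burials, "A")
  expect_identical(w1, w2)
})
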