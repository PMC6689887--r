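test_that("purification records with identical sides are rejected as NO_CHANGE", {
  r <- parse_reaction_line("[CH3:1][OH:2]>>[CH3:1][OH:2] purif1")
  out <- standardize_reaction(r)
  expect_identical(out$status, "rejected")
  expect_identical(out$reason, "NO_CHANGE")
  # the equality test ignores map numbers and atom order
  r2 <- parse_reaction_line("OCC>>CCO purif2")
  expect_identical(standardize_reaction(r2)$reason, "NO_CHANGE")
})

test_that("the product size cap rejects at 41 heavy atoms and passes at 40", {
  chain <- function(n) paste(rep("C", n), collapse = "")
  # a transforming reaction: alcohol -> alkane (the O drops off)
  r41 <- parse_reaction_line(paste0("[OH:1][CH2:2]", chain(40), ">>[CH3:2]", chain(40), " big41"))
  expect_identical(standardize_reaction(r41)$reason, "PRODUCT_TOO_LARGE")
  r40 <- parse_reaction_line(paste0("[OH:1][CH2:2]", chain(39), ">>[CH3:2]", chain(39), " big40"))
  expect_identical(standardize_reaction(r40)$status, "accepted")
})

test_that("multi-fragment products are rejected; the single-product form passes", {
  multi <- parse_reaction_line(
    "[CH3:1][C:2](=[O:3])[O:4][CH3:5]>>[CH3:1][C:2](=[O:3])[OH:4].CO est1")
  expect_identical(standardize_reaction(multi)$reason, "MULTI_PRODUCT")
  single <- parse_reaction_line(
    "[CH3:1][C:2](=[O:3])[O:4][CH3:5]>>[CH3:1][C:2](=[O:3])[OH:4] est2")
  expect_identical(standardize_reaction(single)$status, "accepted")
})

test_that("unmapped spectator fragments are removed with a fix code", {
  r <- parse_reaction_line(
    "[CH3:1][C:2](=[O:3])[O:4][CH3:5].Cc1ccccc1>>[CH3:1][C:2](=[O:3])[OH:4] spec1")
  out <- standardize_reaction(r)
  expect_identical(out$status, "accepted")
  expect_true("NONPARTICIPATING_REMOVED" %in% out$fixes)
  expect_identical(length(side_fragments(out$reaction$reactants)), 1L)
  # oracle: the surviving fragment is exactly the one holding mapped atoms
  expect_true(all(out$reaction$reactants$atoms$map[1:5] > 0))
})

test_that("standardization is idempotent on accepted reactions", {
  rxns <- utils::head(small_rxns(), 30)
  for (r in rxns) {
    o1 <- standardize_reaction(r)
    expect_identical(o1$status, "accepted", label = r$reaction_id)
    o2 <- standardize_reaction(o1$reaction)
    expect_identical(o2$status, "accepted")
    expect_identical(o2$fixes, character(0), label = paste("refix", r$reaction_id))
    expect_identical(write_reaction_line(o2$reaction)$text,
                     write_reaction_line(o1$reaction)$text)
  }
})

test_that("every accepted reaction has one product fragment within the size cap", {
  res <- standardize_reactions(small_rxns())
  for (r in res$accepted) {
    expect_identical(length(side_fragments(r$products)), 1L)
    expect_lte(nrow(r$products$atoms), 40)
  }
})

test_that("record accounting is conserved across accept/reject and reasons", {
  corp <- generate_corpus(per_family = 10, seed = 13, inject_defects = 0.2)
  res <- standardize_reactions(lapply(corp$lines, parse_reaction_line))
  rep <- res$report
  expect_identical(rep$accepted + rep$rejected, rep$input)
  reason_cols <- c("MULTI_PRODUCT", "NO_CHANGE", "BAD_MAPPING",
                   "PRODUCT_TOO_LARGE", "BAD_NAME", "EMPTY_AFTER_CLEANUP")
  expect_identical(sum(unlist(rep[reason_cols])), rep$rejected)
})

test_that("injected defects are rejected with the expected reason or repaired", {
  corp <- generate_corpus(per_family = 10, seed = 17, inject_defects = 0.25)
  man <- corp$manifest
  res <- standardize_reactions(lapply(corp$lines, parse_reaction_line))
  for (i in seq_len(nrow(man))) {
    o <- res$outcomes[[i]]
    if (is.na(man$defect[i])) {
      expect_identical(o$status, "accepted", label = man$reaction_id[i])
    } else if (man$expected[i] == "accepted_with_fix") {
      expect_identical(o$status, "accepted", label = man$reaction_id[i])
      expect_true(length(o$fixes) > 0)
    } else {
      expect_identical(o$status, "rejected", label = man$reaction_id[i])
      expect_identical(o$reason, man$expected[i], label = man$reaction_id[i])
    }
  }
})

test_that("a malformed reaction name is rejected", {
  r <- parse_reaction_line("[CH3:1][OH:2]>>[CH3:1][Cl:2] bad-name!")
  expect_identical(standardize_reaction(r)$reason, "BAD_NAME")
})

test_that("duplicate-map repair finds the unique element-keyed bijection", {
  r <- parse_reaction_line("[OH:1][CH3:1]>>[O:1]=[CH2:1] dup1")
  fixed <- repair_duplicate_maps(r)
  expect_false(is.null(fixed))
  # O and C are each unique by element: maps must pair O<->O and C<->C
  lm <- fixed$reactants$atoms
  rm <- fixed$products$atoms
  expect_identical(lm$map[lm$symbol == "O"], rm$map[rm$symbol == "O"])
  expect_identical(lm$map[lm$symbol == "C"], rm$map[rm$symbol == "C"])
  expect_false(any(duplicated(lm$map[lm$map > 0])))
  # brute-force oracle: over all element-preserving bijections of this
  # 2-atom skeleton there is exactly one (O->O, C->C)
  expect_identical(sum(lm$symbol == "O"), 1L)
  expect_identical(sum(lm$symbol == "C"), 1L)
})

test_that("duplicate-map repair fails loudly on symmetric substrates", {
  # two indistinguishable terminal CH3 groups: no unique bijection
  r <- parse_reaction_line("[CH3:1]C(=O)[CH3:1]>>[CH3:1]C(O)[CH3:1] dup2")
  expect_null(repair_duplicate_maps(r))
  expect_identical(standardize_reaction(r)$reason, "BAD_MAPPING")
})
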