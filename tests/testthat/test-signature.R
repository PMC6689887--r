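test_that("atom typing separates chemically distinct environments", {
  # all six benzene carbons share one label
  expect_identical(length(unique(assign_atom_types(parse_smiles("c1ccccc1")))), 1L)
  # carbonyl O vs ester O of methyl acetate differ (U and C differ)
  m <- parse_smiles("CC(=O)OC")
  lab <- assign_atom_types(m)
  os <- which(m$atoms$symbol == "O")
  expect_identical(length(unique(lab[os])), 2L)
  sp <- atom_type_spec()
  dec <- decode_atom_type(lab[os], sp)
  expect_setequal(dec$U, c(1L, 0L))
  expect_setequal(dec$C, c(1L, 2L))
  # element-only spec partitions acetic acid into exactly C and O classes
  expect_identical(length(unique(assign_atom_types(parse_smiles("CC(=O)O"),
                                                   atom_type_spec("Z")))), 2L)
})

test_that("labels are injective over property tuples and decode losslessly", {
  mols <- lapply(c("CC(=O)OC", "O=[N+]([O-])c1ccc(C)cc1", "C1CCNC1",
                   "N#Cc1ccc(F)cc1", "c1ccc2[nH]ccc2c1"), parse_smiles)
  sp <- atom_type_spec(c("Z", "A", "C", "O", "R", "S", "U", "PI", "H"))
  for (m in mols) {
    lab <- assign_atom_types(m, sp)
    dec <- decode_atom_type(lab, sp)
    # same label <=> same decoded tuple
    key <- do.call(paste, dec)
    expect_identical(as.integer(factor(key, unique(key))),
                     as.integer(factor(lab, unique(lab))))
    # round trip through decode/re-encode
    pm <- synthon:::atom_property_matrix(m)
    expect_equal(dec$Z, as.integer(pm[, "Z"]), ignore_attr = TRUE)
    expect_equal(dec$O, as.integer(pm[, "O"]) - 8L, ignore_attr = TRUE)
  }
})

test_that("the hemiaminal ring-closure core is atoms 1-5, with 2 and 3 ring-only", {
  rxn <- parse_reaction_line(example_ring_closure_reaction())
  core <- find_changing_atoms(rxn)
  maps_of <- function(mol, idx) sort(mol$atoms$map[idx])
  expect_identical(maps_of(rxn$reactants, core$left), 1:5)
  expect_identical(maps_of(rxn$products, core$right), 1:5)
  # disabling ring properties removes exactly the two chain carbons
  core2 <- find_changing_atoms(rxn, atom_type_spec("ZACOU"))
  expect_identical(maps_of(rxn$reactants, core2$left), c(1L, 4L, 5L))
})

test_that("an identity reaction has an empty core and cannot be signed", {
  rxn <- parse_reaction_line("[CH3:1][OH:2]>>[CH3:1][OH:2] ident1")
  core <- find_changing_atoms(rxn)
  expect_length(core$left, 0)
  expect_length(core$right, 0)
  expect_error(reaction_signature(rxn), "empty core")
})

test_that("the ester-hydrolysis product core is the single hydroxyl oxygen", {
  rxn <- parse_reaction_line(
    "[CH3:1][C:2](=[O:3])[O:4][CH3:5]>>[CH3:1][C:2](=[O:3])[OH:4] esterfig")
  core <- find_changing_atoms(rxn)
  expect_identical(rxn$products$atoms$map[core$right], 4L)
  expect_identical(rxn$products$atoms$symbol[core$right], "O")
})

test_that("core expansion is breadth-first, fragment-local and saturating", {
  tol <- parse_smiles("Cc1ccccc1")
  ipso <- which(tol$atoms$aromatic & synthon:::heavy_degree(tol) == 3)
  # radius 0 is the core itself
  expect_identical(expand_core(tol, ipso, 0), ipso)
  # brute-force oracle: all atoms within distance r by igraph shortest paths
  g <- synthon:::mol_igraph(tol)
  d <- igraph::distances(g, v = ipso)
  for (r in 0:3) {
    expect_identical(expand_core(tol, ipso, r), sort(which(d[1, ] <= r)),
                     label = paste("radius", r))
  }
  expect_identical(length(expand_core(tol, ipso, 1)), 4L)   # ipso + 2 ring C + CH3
  # radius >= diameter covers the fragment
  expect_identical(expand_core(tol, ipso, 10), seq_len(7))
  # monotone containment in radius
  corp <- utils::head(small_rxns(), 10)
  for (rxn in corp) {
    core <- find_changing_atoms(rxn)
    prev <- integer()
    for (r in 0:3) {
      cur <- expand_core(rxn$reactants, core$left, r)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("signatures are byte-identical under random atom permutations", {
  set.seed(23)
  lines <- small_corpus()$lines[seq(1, 120, by = 7)]
  for (ln in lines) {
    r <- parse_reaction_line(ln)
    base <- reaction_signature(r, radius_max = 2)$text
    for (k in 1:3) {
      parts <- strsplit(ln, " ")[[1]]
      sides <- strsplit(parts[1], ">>")[[1]]
      shuf <- paste0(shuffle_smiles(sides[1]), ">>", shuffle_smiles(sides[2]), " ", parts[2])
      r2 <- parse_reaction_line(shuf)
      expect_identical(reaction_signature(r2, radius_max = 2)$text, base,
                       label = paste("perm", k, parts[2]))
    }
  }
})

test_that("agents never affect signatures", {
  r1 <- parse_reaction_line("[CH3:1][Cl:2].[NH2:3]C>>[CH3:1][NH:3]C ag1")
  r2 <- parse_reaction_line("[CH3:1][Cl:2].[NH2:3]C>CO.c1ccccc1>[CH3:1][NH:3]C ag1")
  expect_identical(reaction_signature(r1, radius_max = 2)$text,
                   reaction_signature(r2, radius_max = 2)$text)
})

test_that("signature classes refine with radius and coarsen when properties drop", {
  st <- signed_table("small")
  sigs <- st$sigs
  # refinement: same radius-(k+1) signature implies same radius-k signature
  wide <- tidyr::pivot_wider(sigs, names_from = "radius", values_from = "signature",
                             names_prefix = "r")
  for (k in 0:1) {
    grp <- split(wide[[paste0("r", k)]], wide[[paste0("r", k + 1)]])
    for (g in grp) expect_identical(length(unique(g)), 1L)
  }
  # unique-signature counts are non-decreasing in radius
  counts <- vapply(0:2, function(r)
    length(unique(sigs$signature[sigs$radius == r])), integer(1))
  expect_true(all(diff(counts) >= 0))
  # dropping a property can only merge classes: grouping under ZACORSU
  # refines grouping under ZAC
  coarse <- sign_reactions(st$rxns, atom_type_spec("ZAC"), radius_max = 0)
  full0 <- sigs[sigs$radius == 0, ]
  merged <- dplyr::inner_join(full0, coarse, by = "reaction_id",
                              suffix = c("_full", "_coarse"))
  grp <- split(merged$signature_coarse, merged$signature_full)
  for (g in grp) expect_identical(length(unique(g)), 1L)
})

test_that("signature text equality agrees with a labeled-isomorphism oracle", {
  st <- signed_table("small")
  rxns <- st$rxns
  sigs0 <- st$sigs[st$sigs$radius == 1, ]
  ids <- vapply(rxns, `[[`, character(1), "reaction_id")
  set.seed(31)
  same_cluster <- split(seq_along(rxns), sigs0$signature[match(ids, sigs0$reaction_id)])
  # within-cluster pairs must be isomorphic; cross-cluster pairs must not be
  big <- Filter(function(x) length(x) >= 2, same_cluster)
  for (cl in utils::head(big, 4)) {
    pr <- sample(cl, 2)
    expect_true(sig_isomorphic_oracle(rxns[[pr[1]]], rxns[[pr[2]]], radius = 1))
  }
  reps <- vapply(utils::head(big, 4), `[[`, integer(1), 1)
  if (length(reps) >= 2) {
    for (k in 2:length(reps)) {
      expect_false(sig_isomorphic_oracle(rxns[[reps[1]]], rxns[[reps[k]]], radius = 1))
    }
  }
})
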