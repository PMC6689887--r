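#' Synthetic reaction corpora with known family structure
#'
#' [generate_corpus()] builds deterministic, atom-mapped, single-product
#' forward reactions from six common reaction families — ester hydrolysis,
#' amide coupling from an acid chloride (Schotten-Baumann), amide coupling
#' from a carboxylic acid, N-alkylation of a cyclic secondary amine with a
#' benzylic bromide, nitro reduction, and nucleophilic aromatic substitution
#' (SnAr) — each decorated with randomized peripheral substituents drawn
#' from a fixed small alphabet. Within a family every member shares the
#' radius-0 signature under the default atom-type spec; decorations split
#' the families at larger radii. The accompanying manifest records the
#' ground truth (family, product, synthons, injected defects, chained
#' pairs), fully determining the corpus byte-for-byte.
#'
#' @name fixtures
NULL

FX_FAMILIES <- c("ester_hydrolysis", "amide_from_acid_chloride",
                 "amide_from_acid", "n_alkylation", "nitro_reduction", "snar")

## substituent alphabet: small, core-clean groups only (no OH/NH2/acyl that
## could collide with a query motif)
FX_SUBS <- c("", "F", "Cl", "C", "OC", "C#N", "CC")

## para/meta/ortho-substituted phenyl attached at its first ring atom;
## ring-closure digit d keeps nested rings distinct
fx_aryl <- function(s2, s3, s4, d = 1) {
  tok <- function(s) if (s == "") "c" else paste0("c(", s, ")")
  paste0("c", d, tok(s2), tok(s3), tok(s4), "cc", d)
}

fx_aryl_grid <- function(d = 1) {
  g <- expand.grid(s2 = FX_SUBS, s3 = FX_SUBS, s4 = FX_SUBS,
                   stringsAsFactors = FALSE)
  vapply(seq_len(nrow(g)), function(i) fx_aryl(g$s2[i], g$s3[i], g$s4[i], d),
         character(1))
}

## --- small graph-surgery helpers (independent of the template engine) ----

fx_map_all <- function(mol) {
  mol$atoms$map <- seq_len(n_atoms(mol))
  mol
}

fx_next_map <- function(mol) max(mol$atoms$map) + 1L

fx_add_atom <- function(mol, symbol, bond_to, order = 1, charge = 0L, map = 0L,
                        aromatic = FALSE) {
  mol$atoms <- dplyr::bind_rows(mol$atoms, tibble::tibble(
    symbol = symbol, charge = as.integer(charge), aromatic = aromatic,
    hcount = 0L, map = as.integer(map), frag = mol$atoms$frag[bond_to]))
  mol$bonds <- dplyr::bind_rows(mol$bonds, tibble::tibble(
    a1 = bond_to, a2 = nrow(mol$atoms), order = order))
  recompute_hcount(mol, c(bond_to, nrow(mol$atoms)))
}

fx_break_bond <- function(mol, i, j) {
  be <- bond_between(mol, i, j)
  stopifnot(length(be) == 1)
  mol$bonds <- mol$bonds[-be, ]
  mol$atoms$frag <- renumber_frags(mol$atoms, mol$bonds)
  recompute_hcount(mol, c(i, j))
}

## --- family constructors: product built first and fully mapped, then the
## reactant side derived by family-specific surgery (this is the ground
## truth the template engine is tested against, so it shares no code with
## apply_template) ---------------------------------------------------------

fx_build <- function(family, params) {
  switch(family,
    ester_hydrolysis = {
      prod <- fx_map_all(parse_smiles(paste0("OC(=O)", params$acyl)))
      stopifnot(prod$atoms$symbol[1] == "O")
      ester <- fx_add_atom(prod, "C", bond_to = 1L, map = fx_next_map(prod))
      list(product = prod, reactants = ester)
    },
    amide_from_acid_chloride = {
      prod <- fx_map_all(parse_smiles(paste0("O=C(", params$acyl, ")", params$amine)))
      cN <- fx_find_amide(prod)
      rs <- fx_break_bond(prod, cN$c, cN$n)
      rs <- fx_add_atom(rs, "Cl", bond_to = cN$c, map = fx_next_map(rs))
      list(product = prod, reactants = rs)
    },
    amide_from_acid = {
      prod <- fx_map_all(parse_smiles(paste0("O=C(", params$acyl, ")", params$amine)))
      cN <- fx_find_amide(prod)
      rs <- fx_break_bond(prod, cN$c, cN$n)
      rs <- fx_add_atom(rs, "O", bond_to = cN$c, map = fx_next_map(rs))
      list(product = prod, reactants = rs)
    },
    n_alkylation = {
      prod <- fx_map_all(parse_smiles(paste0("C(", params$amine, ")", params$aryl)))
      stopifnot(prod$atoms$symbol[1] == "C", prod$atoms$symbol[2] == "N")
      rs <- fx_break_bond(prod, 1L, 2L)
      rs <- fx_add_atom(rs, "Br", bond_to = 1L, map = fx_next_map(rs))
      list(product = prod, reactants = rs)
    },
    nitro_reduction = {
      prod <- fx_map_all(parse_smiles(paste0("N", params$aryl)))
      stopifnot(prod$atoms$symbol[1] == "N")
      rs <- prod
      rs$atoms$charge[1] <- 1L
      rs <- fx_add_atom(rs, "O", bond_to = 1L, charge = -1L, map = fx_next_map(rs))
      rs <- fx_add_atom(rs, "O", bond_to = 1L, order = 2, map = fx_next_map(rs))
      rs <- recompute_hcount(rs, 1L)
      list(product = prod, reactants = rs)
    },
    snar = {
      prod <- fx_map_all(parse_smiles(paste0("N(", params$tail, ")", params$aryl)))
      stopifnot(prod$atoms$symbol[1] == "N")
      adjN <- adjacency(prod)[[1]]
      cipso <- adjN[prod$atoms$aromatic[adjN]][1]
      rs <- fx_break_bond(prod, 1L, cipso)
      rs <- fx_add_atom(rs, "F", bond_to = cipso, map = fx_next_map(rs))
      list(product = prod, reactants = rs)
    },
    stop("unknown family: ", family, call. = FALSE)
  )
}

## locate the (single) amide C-N pair of a constructed amide product
fx_find_amide <- function(mol) {
  adj <- adjacency(mol)
  for (i in seq_len(n_atoms(mol))) {
    if (mol$atoms$symbol[i] != "C" || mol$atoms$aromatic[i]) next
    nb <- adj[[i]]
    has_o2 <- any(vapply(nb, function(j) mol$atoms$symbol[j] == "O" &&
                           mol$bonds$order[bond_between(mol, i, j)] == 2, logical(1)))
    nn <- nb[vapply(nb, function(j) mol$atoms$symbol[j] == "N" &&
                      !mol$atoms$aromatic[j], logical(1))]
    if (has_o2 && length(nn) == 1) return(list(c = i, n = nn))
  }
  stop("no amide motif found", call. = FALSE)
}

## parameter grids per family (sampled without replacement)
fx_param_grid <- function(family) {
  aryl1 <- fx_aryl_grid(1)
  aryl2 <- fx_aryl_grid(2)
  amines <- c(paste0("N", fx_aryl_grid(2)[1:49]),       # anilines
              paste0("NC", fx_aryl_grid(2)[1:25]),      # benzylamines
              "NCC", "NCCC")
  switch(family,
    ester_hydrolysis = tibble::tibble(acyl = c(aryl1, "CC", "CCC", "C(C)C", "CCCC")),
    amide_from_acid_chloride = ,
    amide_from_acid = tidyr::expand_grid(acyl = aryl1[1:60], amine = amines),
    n_alkylation = tidyr::expand_grid(
      amine = c("N1CCCCC1", "N1CCOCC1", "N1CCN(C)CC1"), aryl = aryl2),
    nitro_reduction = tibble::tibble(aryl = aryl1),
    snar = tidyr::expand_grid(tail = c("C", "CC", "CCC", "Cc1ccccc1"),
                              aryl = aryl2),
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' Generate a decorated, atom-mapped synthetic reaction corpus
#'
#' @param families Character vector of family names (default: all six).
#' @param per_family Members per family.
#' @param seed Integer seed; the corpus is a pure function of the arguments.
#' @param inject_defects Fraction of lines to corrupt (0 disables). Defect
#'   modes cycle through duplicate atom maps, an unmapped spectator
#'   fragment, a second product fragment, and an oversized (>40 heavy
#'   atoms) product — one mode per standardizer rule.
#' @param n_chained Number of chained pairs: an amide-coupling member whose
#'   amine reactant is the product of a nitro-reduction member, so the
#'   amine synthon can itself be deconstructed (multi-step route tests).
#' @return A list with `lines` (character vector of reaction lines) and
#'   `manifest` (tibble: reaction_id, family, line, product and synthon
#'   canonical SMILES, defect mode, expected standardizer outcome, chained
#'   child id; plus the seed as an attribute).
#' @export
generate_corpus <- function(families = FX_FAMILIES, per_family = 100, seed = 1,
                            inject_defects = 0, n_chained = 0) {
  stopifnot(all(families %in% FX_FAMILIES), per_family >= 1,
            inject_defects >= 0, inject_defects <= 1)
  set.seed(seed)
  ## nitro products must exist before the amide families when chaining
  fam_order <- intersect(c("nitro_reduction", setdiff(FX_FAMILIES, "nitro_reduction")),
                         families)
  rows <- list()
  counter <- 0L
  nitro_products <- character()

  for (fam in fam_order) {
    grid <- fx_param_grid(fam)
    if (nrow(grid) < per_family) {
      stop("family ", fam, " supports at most ", nrow(grid),
           " distinct members", call. = FALSE)
    }
    pick <- grid[sample(nrow(grid), per_family), , drop = FALSE]
    if (fam == "amide_from_acid_chloride" && n_chained > 0) {
      k <- min(n_chained, per_family, length(nitro_products))
      pick$amine[seq_len(k)] <- nitro_products[seq_len(k)]
      chained_parent <- c(rep(TRUE, k), rep(FALSE, per_family - k))
    } else {
      chained_parent <- rep(FALSE, per_family)
    }
    for (i in seq_len(per_family)) {
      counter <- counter + 1L
      id <- sprintf("rx%04d", counter)
      built <- fx_build(fam, as.list(pick[i, ]))
      rxn <- mapped_reaction(reactants = built$reactants, agents = empty_molecule(),
                             products = built$product, reaction_id = id)
      if (fam == "nitro_reduction") {
        nitro_products <- c(nitro_products, paste0("N", pick$aryl[i]))
      }
      rows[[counter]] <- list(
        id = id, family = fam, rxn = rxn,
        product = canonical_smiles_of_mol(built$product),
        synthons = sort(vapply(side_fragments(built$reactants),
                               canonical_smiles_of_mol, character(1))),
        chained = chained_parent[i]
      )
    }
  }

  ## chained pairs: amide member i uses the product of nitro member i
  chained_child <- rep(NA_character_, length(rows))
  fams <- vapply(rows, `[[`, character(1), "family")
  nit_idx <- which(fams == "nitro_reduction")
  for (j in which(vapply(rows, `[[`, logical(1), "chained"))) {
    k <- match(j, which(vapply(rows, `[[`, logical(1), "chained")))
    chained_child[j] <- rows[[nit_idx[k]]]$id
  }

  ## defect injection
  defect <- rep(NA_character_, length(rows))
  expected <- rep(NA_character_, length(rows))
  if (inject_defects > 0) {
    modes <- c("duplicate_maps", "spectator", "multi_product", "oversized")
    n_def <- max(1L, round(inject_defects * length(rows)))
    hit <- sort(sample(length(rows), n_def))
    for (m in seq_along(hit)) {
      j <- hit[m]
      mode <- modes[(m - 1) %% length(modes) + 1]
      rows[[j]]$rxn <- fx_corrupt(rows[[j]]$rxn, mode)
      defect[j] <- mode
      expected[j] <- switch(mode,
        duplicate_maps = "BAD_MAPPING", spectator = "accepted_with_fix",
        multi_product = "MULTI_PRODUCT", oversized = "PRODUCT_TOO_LARGE")
    }
  }

  lines <- vapply(rows, function(r) write_reaction_line(r$rxn)$text, character(1))
  if (anyDuplicated(lines)) stop("generated duplicate reaction lines", call. = FALSE)
  manifest <- tibble::tibble(
    reaction_id = vapply(rows, `[[`, character(1), "id"),
    family = fams,
    line = lines,
    product = vapply(rows, `[[`, character(1), "product"),
    synthons = lapply(rows, `[[`, "synthons"),
    defect = defect,
    expected = expected,
    chained_child = chained_child
  )
  attr(manifest, "seed") <- seed
  list(lines = lines, manifest = manifest)
}

canonical_smiles_of_mol <- function(mol) write_smiles(mol, write_maps = FALSE)

fx_corrupt <- function(rxn, mode) {
  switch(mode,
    duplicate_maps = {
      rxn$reactants$atoms$map[2] <- rxn$reactants$atoms$map[1]
      rxn$duplicate_maps <- TRUE
      rxn
    },
    spectator = {
      spec <- parse_smiles("c1ccccc1")
      rxn$reactants <- combine_mols(rxn$reactants, spec)
      rxn
    },
    multi_product = {
      extra <- parse_smiles("CO")
      rxn$products <- combine_mols(rxn$products, extra)
      rxn
    },
    oversized = {
      built <- fx_build("ester_hydrolysis", list(acyl = strrep("C", 43)))
      mapped_reaction(reactants = built$reactants, agents = empty_molecule(),
                      products = built$product, reaction_id = rxn$reaction_id)
    },
    stop("unknown defect mode: ", mode, call. = FALSE)
  )
}

#' Generate a building-block collection for a corpus
#'
#' Includes the stated fraction of the manifest's true synthons (sampled
#' deterministically) plus structurally distinct decoys; every fifth
#' included entry is written as a hydrochloride salt to exercise salt
#' stripping. Decoy canonical keys never collide with true synthons.
#'
#' @param manifest The manifest from [generate_corpus()].
#' @param fraction Fraction of true synthons to include (0..1).
#' @param seed Integer seed.
#' @return A tibble with columns `smiles` and `id`.
#' @export
generate_building_blocks <- function(manifest, fraction = 1, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(seed)
  truth <- sort(unique(unlist(manifest$synthons[is.na(manifest$defect)])))
  n_in <- floor(fraction * length(truth))
  include <- sort(sample(truth, n_in))
  decoys <- c(paste0("I", fx_aryl_grid(1)[seq(1, 343, by = 12)]),
              "CCCCCCCC", "C1CCCCC1C", "OCC(C)CO")
  decoys <- decoys[!vapply(decoys, function(s) canonical_smiles(s) %in% truth,
                           logical(1))]
  smiles <- c(include, decoys)
  salted <- seq_along(smiles) %% 5 == 0 & seq_along(smiles) <= length(include)
  smiles[salted] <- paste0(smiles[salted], ".Cl")
  tibble::tibble(smiles = smiles,
                 id = sprintf("BB%04d", seq_along(smiles)))
}

#' Worked example: an intramolecular hemiaminal ring closure
#'
#' A heterocycle-forming reaction (3-aminopropanal closing to azetidin-2-ol)
#' whose reaction core under the default atom-type spec is exactly the five
#' mapped atoms 1-5: the amine nitrogen (connectivity changes), the two
#' chain carbons 2 and 3 (only their ring membership changes), the carbonyl
#' carbon 4 (connectivity and unsaturation change) and the oxygen 5
#' (unsaturation changes). With the ring properties R and S disabled, atoms
#' 2 and 3 drop out of the core.
#'
#' @return The reaction line (character).
#' @export
example_ring_closure_reaction <- function() {
  "[NH2:1][CH2:2][CH2:3][CH:4]=[O:5]>>[OH:5][CH:4]1[CH2:3][CH2:2][NH:1]1 ringclose1"
}

#' A Gleevec-class kinase-inhibitor target
#'
#' Imatinib's public structure: it contains an amide bond (amenable to both
#' acid-chloride and acid amide-coupling disconnections), a benzylic
#' CH2-piperazine motif (N-alkylation) and an anilino-pyrimidine linkage
#' (SnAr), so a repository trained on those families proposes all four
#' disconnection types.
#'
#' @return A SMILES string.
#' @export
imatinib_target <- function() {
  "Cc1ccc(NC(=O)c2ccc(CN3CCN(C)CC3)cc2)cc1Nc1nccc(-c2cccnc2)n1"
}
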