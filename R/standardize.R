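#' Standardizer configuration
#'
#' Controls the reaction-cleanup pipeline. Each rule can be toggled off
#' individually; all default on. The product size cap defaults to 40 heavy
#' atoms.
#'
#' @param max_product_heavy_atoms Reject reactions whose (single) product
#'   exceeds this heavy-atom count.
#' @param reject_multi_fragment_product Reject forward reactions with more
#'   than one product fragment (after duplicate-fragment removal).
#' @param reject_no_change Reject records with no structural change between
#'   the two sides (e.g. purifications).
#' @param strip_and_remap_on_duplicate_maps Attempt
#'   [repair_duplicate_maps()] when a side carries duplicate map numbers;
#'   when off (or when repair fails) such reactions are rejected.
#' @param remove_nonparticipating_fragments Remove fragments with no mapped
#'   atoms or no changing atoms.
#' @param handle_appearing_disappearing_atoms Record appearing and
#'   disappearing atoms as annotations on the outcome.
#' @param consistent_kekule Normalize aromaticity so both sides of a
#'   preserved ring carry identical bond orders (Kekule-written rings are
#'   perceived and flagged aromatic).
#' @param remove_duplicate_fragments Remove structurally identical duplicate
#'   fragments within a side.
#' @param require_alnum_name Reject reactions whose id is not one continuous
#'   alphanumeric token (internal whitespace having been replaced by `_`).
#' @param spec The [atom_type_spec()] used for the participation and change
#'   tests.
#' @return A `standardizer_config` object.
#' @export
standardizer_config <- function(max_product_heavy_atoms = 40,
                                reject_multi_fragment_product = TRUE,
                                reject_no_change = TRUE,
                                strip_and_remap_on_duplicate_maps = TRUE,
                                remove_nonparticipating_fragments = TRUE,
                                handle_appearing_disappearing_atoms = TRUE,
                                consistent_kekule = TRUE,
                                remove_duplicate_fragments = TRUE,
                                require_alnum_name = TRUE,
                                spec = atom_type_spec()) {
  stopifnot(max_product_heavy_atoms >= 1)
  structure(as.list(environment()), class = "standardizer_config")
}

REJECT_REASONS <- c("MULTI_PRODUCT", "NO_CHANGE", "BAD_MAPPING",
                    "PRODUCT_TOO_LARGE", "BAD_NAME", "EMPTY_AFTER_CLEANUP")

outcome <- function(status, reaction = NULL, reason = NULL, fixes = character(),
                    annotations = list()) {
  structure(list(status = status, reaction = reaction, reason = reason,
                 fixes = fixes, annotations = annotations),
            class = "standardize_outcome")
}

#' @export
print.standardize_outcome <- function(x, ...) {
  cat("<standardize_outcome> ", x$status,
      if (!is.null(x$reason)) paste0(" (", x$reason, ")"),
      if (length(x$fixes)) paste0(" fixes: ", paste(x$fixes, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

#' Standardize a mapped reaction
#'
#' Applies the cleanup pipeline: (1) reject multi-fragment products (after
#' duplicate removal); (2) reject records with no structural change; (3)
#' repair or reject duplicate atom maps; (4) remove non-participating
#' fragments; (5) record appearing/disappearing atoms; (6) normalize
#' aromatic/Kekule form; (7) remove duplicate fragments; (8) reject
#' oversized products; (9) reject malformed reaction names. Rules execute
#' in this order: cheap structural rejections first, the mapping repair
#' before removals so the repair sees full context.
#'
#' @param rxn A `mapped_reaction`.
#' @param cfg A [standardizer_config()].
#' @return A `standardize_outcome`; when accepted it carries the
#'   standardized reaction and the list of applied fix codes.
#' @export
standardize_reaction <- function(rxn, cfg = standardizer_config()) {
  fixes <- character()
  ann <- list()

  ## (1) multi-fragment product (after duplicate-fragment removal)
  prods <- side_fragments(rxn$products)
  if (cfg$remove_duplicate_fragments && length(prods) > 1) {
    dd <- dedup_fragments(prods)
    if (dd$removed > 0) {
      prods <- dd$frags
      rxn$products <- Reduce(combine_mols, prods)
      fixes <- c(fixes, "DUPLICATE_FRAGMENT_REMOVED")
    }
  }
  if (cfg$reject_multi_fragment_product && length(prods) > 1) {
    return(outcome("rejected", reason = "MULTI_PRODUCT"))
  }
  if (length(prods) == 0 || n_fragments(rxn$reactants) == 0) {
    return(outcome("rejected", reason = "EMPTY_AFTER_CLEANUP"))
  }

  ## (2) no structural change between the sides, e.g. purification records
  if (cfg$reject_no_change && identical_sides(rxn$reactants, rxn$products)) {
    return(outcome("rejected", reason = "NO_CHANGE"))
  }

  ## (3) duplicate atom maps
  if (rxn$duplicate_maps ||
      side_has_duplicate_maps(rxn$reactants) || side_has_duplicate_maps(rxn$products)) {
    if (!cfg$strip_and_remap_on_duplicate_maps) {
      return(outcome("rejected", reason = "BAD_MAPPING"))
    }
    rep <- repair_duplicate_maps(rxn)
    if (is.null(rep)) return(outcome("rejected", reason = "BAD_MAPPING"))
    rxn <- rep
    fixes <- c(fixes, "REMAPPED")
  }

  ## (6, early half) normalize aromaticity before any canonical comparison
  if (cfg$consistent_kekule) {
    before <- c(write_smiles(rxn$reactants), write_smiles(rxn$products))
    rxn$reactants <- perceive_aromaticity(rxn$reactants)
    rxn$products <- perceive_aromaticity(rxn$products)
    if (n_atoms(rxn$agents) > 0) rxn$agents <- perceive_aromaticity(rxn$agents)
    if (!identical(before, c(write_smiles(rxn$reactants), write_smiles(rxn$products)))) {
      fixes <- c(fixes, "AROMATIC_NORMALIZED")
    }
  }

  ## (4) remove non-participating fragments (no mapped atoms, or no atoms
  ## whose type changes)
  if (cfg$remove_nonparticipating_fragments) {
    core <- find_changing_atoms(rxn, cfg$spec)
    res <- drop_nonparticipating(rxn$reactants, core$left)
    if (res$removed > 0) {
      rxn$reactants <- res$mol
      fixes <- c(fixes, "NONPARTICIPATING_REMOVED")
    }
    if (n_fragments(rxn$reactants) == 0) {
      return(outcome("rejected", reason = "EMPTY_AFTER_CLEANUP"))
    }
  }

  ## (7) duplicate fragments on the reactant side
  if (cfg$remove_duplicate_fragments) {
    rfr <- side_fragments(rxn$reactants)
    if (length(rfr) > 1) {
      dd <- dedup_fragments(rfr)
      if (dd$removed > 0) {
        rxn$reactants <- Reduce(combine_mols, dd$frags)
        fixes <- c(fixes, "DUPLICATE_FRAGMENT_REMOVED")
      }
    }
  }

  ## (5) appearing / disappearing atoms (relative to the forward direction:
  ## disappearing = reactant-side atoms without product counterpart)
  core <- find_changing_atoms(rxn, cfg$spec)
  if (cfg$handle_appearing_disappearing_atoms) {
    ann$disappearing_atoms <- core$unpaired_left
    ann$appearing_atoms <- core$unpaired_right
  }

  ## re-test structural change after cleanup: an empty core means nothing
  ## actually transforms
  if (cfg$reject_no_change && length(core$left) == 0 && length(core$right) == 0) {
    return(outcome("rejected", reason = "NO_CHANGE"))
  }

  ## (8) product size cap
  if (n_atoms(rxn$products) > cfg$max_product_heavy_atoms) {
    return(outcome("rejected", reason = "PRODUCT_TOO_LARGE"))
  }

  ## (9) reaction name must be one continuous alphanumeric token
  if (cfg$require_alnum_name) {
    id <- gsub("\\s+", "_", rxn$reaction_id)
    if (!grepl("^[A-Za-z0-9_]+$", id)) {
      return(outcome("rejected", reason = "BAD_NAME"))
    }
    rxn$reaction_id <- id
  }

  outcome("accepted", reaction = rxn, fixes = fixes, annotations = ann)
}

## multiset equality of canonical fragment SMILES (maps ignored)
identical_sides <- function(a, b) {
  ka <- sort(vapply(side_fragments(a), canonical_smiles, character(1)))
  kb <- sort(vapply(side_fragments(b), canonical_smiles, character(1)))
  identical(ka, kb)
}

## duplicate-fragment removal: a fragment is dropped when another fragment
## has the identical canonical SMILES *including* map numbers (true textual
## duplicates), or when it is unmapped and structurally identical to an
## earlier fragment. Mapped non-identical copies are kept: their maps pair
## with distinct product atoms.
dedup_fragments <- function(frags) {
  key_mapped <- vapply(frags, function(f) write_smiles(f, write_maps = TRUE), character(1))
  key_struct <- vapply(frags, function(f) write_smiles(f, write_maps = FALSE), character(1))
  unmapped <- vapply(frags, function(f) all(f$atoms$map == 0), logical(1))
  keep <- logical(length(frags))
  seen_mapped <- character(); seen_struct <- character()
  for (k in seq_along(frags)) {
    dup <- key_mapped[k] %in% seen_mapped ||
      (unmapped[k] && key_struct[k] %in% seen_struct)
    keep[k] <- !dup
    if (!dup) {
      seen_mapped <- c(seen_mapped, key_mapped[k])
      seen_struct <- c(seen_struct, key_struct[k])
    }
  }
  list(frags = frags[keep], removed = sum(!keep))
}

## remove reactant-side fragments with no mapped atoms or with no changing
## atoms; returns the reduced molecule and the number of removed fragments
drop_nonparticipating <- function(mol, changing) {
  if (n_atoms(mol) == 0) return(list(mol = mol, removed = 0L))
  frag_of <- mol$atoms$frag
  keep_frags <- vapply(sort(unique(frag_of)), function(f) {
    idx <- which(frag_of == f)
    any(mol$atoms$map[idx] > 0) && any(idx %in% changing)
  }, logical(1))
  frags_keep <- sort(unique(frag_of))[keep_frags]
  removed <- sum(!keep_frags)
  if (removed == 0) return(list(mol = mol, removed = 0L))
  list(mol = keep_atoms(mol, which(frag_of %in% frags_keep)), removed = removed)
}

#' Repair duplicate atom maps by stripping and minimally re-mapping
#'
#' All maps are stripped, then a bijection between reactant- and
#' product-side atoms is sought greedily: atoms are keyed by (element,
#' degree, sorted attached-element multiset), and a key pairing is accepted
#' only when it is unique on both sides. If any product heavy atom remains
#' unmatched the repair fails (returns `NULL`) — the re-mapper is
#' deliberately minimal and fails loudly rather than guessing.
#'
#' @param rxn A `mapped_reaction` with duplicate maps.
#' @return The re-mapped `mapped_reaction`, or `NULL` on failure.
#' @export
repair_duplicate_maps <- function(rxn) {
  lmol <- rxn$reactants
  rmol <- rxn$products
  lmol$atoms$map <- 0L
  rmol$atoms$map <- 0L
  keyfun <- function(mol) {
    adj <- adjacency(mol)
    vapply(seq_len(n_atoms(mol)), function(i) {
      paste(mol$atoms$symbol[i], length(adj[[i]]),
            paste(sort(mol$atoms$symbol[adj[[i]]]), collapse = ","))
    }, character(1))
  }
  kl <- keyfun(lmol)
  kr <- keyfun(rmol)
  nextmap <- 1L
  for (key in unique(kr)) {
    il <- which(kl == key)
    ir <- which(kr == key)
    if (length(il) == 1 && length(ir) == 1) {
      lmol$atoms$map[il] <- nextmap
      rmol$atoms$map[ir] <- nextmap
      nextmap <- nextmap + 1L
    }
  }
  if (any(rmol$atoms$map == 0)) return(NULL)
  out <- rxn
  out$reactants <- lmol
  out$products <- rmol
  out$duplicate_maps <- FALSE
  out
}

#' Standardize a batch of reactions with accounting
#'
#' @param rxns List of `mapped_reaction` objects.
#' @param cfg A [standardizer_config()].
#' @return A list with `accepted` (list of standardized reactions),
#'   `outcomes` (list of all outcomes, in input order) and `report` (tibble
#'   of per-reason rejection counts plus accepted/input totals).
#' @export
standardize_reactions <- function(rxns, cfg = standardizer_config()) {
  outcomes <- lapply(rxns, standardize_reaction, cfg = cfg)
  status <- vapply(outcomes, `[[`, character(1), "status")
  reasons <- vapply(outcomes, function(o) o$reason %||% NA_character_, character(1))
  rep <- tibble::tibble(reason = REJECT_REASONS,
                        count = vapply(REJECT_REASONS, function(r)
                          sum(reasons == r, na.rm = TRUE), integer(1)))
  list(
    accepted = lapply(outcomes[status == "accepted"], `[[`, "reaction"),
    outcomes = outcomes,
    report = tibble::tibble(
      input = length(rxns),
      accepted = sum(status == "accepted"),
      rejected = sum(status == "rejected")
    ) |> dplyr::bind_cols(tidyr::pivot_wider(rep, names_from = "reason",
                                             values_from = "count"))
  )
}
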