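#' Detect changing atoms (the reaction core)
#'
#' An atom is part of the reaction core when its enabled-property tuple
#' differs between its two map-paired occurrences, or when it has no mapped
#' counterpart on the other side (appearing/disappearing atoms, and all
#' unmapped atoms). Agents never contribute core atoms.
#'
#' @param rxn A `mapped_reaction` (standardized; valid mapping).
#' @param spec An [atom_type_spec()].
#' @return A `core_assignment`: list with `left` / `right` integer vectors of
#'   changing-atom indices (into the reactant / product side molecules),
#'   `pairs` (tibble of map, left, right indices), and `unpaired_left` /
#'   `unpaired_right`.
#' @export
find_changing_atoms <- function(rxn, spec = atom_type_spec()) {
  lmol <- rxn$reactants
  rmol <- rxn$products
  lab_l <- assign_atom_types(lmol, spec)
  lab_r <- assign_atom_types(rmol, spec)
  lmap <- lmol$atoms$map
  rmap <- rmol$atoms$map
  pos_l <- which(lmap > 0)
  pos_r <- which(rmap > 0)
  common <- intersect(lmap[pos_l], rmap[pos_r])
  li <- pos_l[match(common, lmap[pos_l])]
  ri <- pos_r[match(common, rmap[pos_r])]
  changed_pair <- lab_l[li] != lab_r[ri]
  unpaired_left <- setdiff(seq_len(n_atoms(lmol)), li)
  unpaired_right <- setdiff(seq_len(n_atoms(rmol)), ri)
  structure(list(
    left = sort(c(li[changed_pair], unpaired_left)),
    right = sort(c(ri[changed_pair], unpaired_right)),
    pairs = tibble::tibble(map = common, left = li, right = ri,
                           changed = changed_pair),
    unpaired_left = unpaired_left,
    unpaired_right = unpaired_right
  ), class = "core_assignment")
}

#' Expand a reaction core by a bond radius
#'
#' Breadth-first expansion over bonds: all atoms at graph distance at most
#' `radius` from any core atom. Expansion is fragment-local by construction
#' (bonds never cross fragments).
#'
#' @param mol A `mapped_molecule`.
#' @param core Integer vector of core atom indices (may be empty).
#' @param radius Non-negative integer.
#' @return Sorted integer vector of atom indices.
#' @export
expand_core <- function(mol, core, radius) {
  stopifnot(radius >= 0)
  if (length(core) == 0 || radius == 0) return(sort(unique(core)))
  adj <- adjacency(mol)
  seen <- unique(core)
  frontier <- seen
  for (r in seq_len(radius)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' Compute the per-radius canonical signature of a reaction
#'
#' For each radius 0..`radius_max` the radius-expanded core of each side is
#' extracted as an induced subgraph, each fragment is serialized as a
#' canonical labeled string (atom tokens `sym{label}` with the atom-type
#' label computed in the full molecule), fragments within a side are joined
#' in lexicographic order with `.`, and the two sides with `>>`. The text is
#' invariant to input atom ordering. Agents are ignored.
#'
#' @param rxn A standardized `mapped_reaction` with a non-empty core.
#' @param spec An [atom_type_spec()].
#' @param radius_max Largest radius to compute (default 2).
#' @param core Optional precomputed [find_changing_atoms()] result.
#' @return A `reaction_signature`: list with `text` (character vector named
#'   by radius), `atom_sets` (per radius, list of `left`/`right` index
#'   vectors), `spec` and `radius_max`.
#' @export
reaction_signature <- function(rxn, spec = atom_type_spec(), radius_max = 2,
                               core = NULL) {
  if (is.null(core)) core <- find_changing_atoms(rxn, spec)
  if (length(core$left) == 0 && length(core$right) == 0) {
    stop("reaction ", rxn$reaction_id, " has an empty core (no changing atoms)",
         call. = FALSE)
  }
  lab_l <- assign_atom_types(rxn$reactants, spec)
  lab_r <- assign_atom_types(rxn$products, spec)
  text <- character(radius_max + 1)
  atom_sets <- vector("list", radius_max + 1)
  for (r in 0:radius_max) {
    lset <- expand_core(rxn$reactants, core$left, r)
    rset <- expand_core(rxn$products, core$right, r)
    text[r + 1] <- paste0(side_signature_text(rxn$reactants, lset, lab_l),
                          ">>",
                          side_signature_text(rxn$products, rset, lab_r))
    atom_sets[[r + 1]] <- list(left = lset, right = rset)
  }
  names(text) <- as.character(0:radius_max)
  names(atom_sets) <- as.character(0:radius_max)
  structure(list(text = text, atom_sets = atom_sets, spec = spec,
                 radius_max = radius_max),
            class = "reaction_signature")
}

side_signature_text <- function(mol, atom_set, labels) {
  if (length(atom_set) == 0) return("")
  sub <- keep_atoms(mol, atom_set)
  sublab <- labels[sort(atom_set)]
  ranks <- canonical_ranks(sub, as.character(sublab))
  token_fn <- function(i) {
    sym <- sub$atoms$symbol[i]
    if (sub$atoms$aromatic[i] && sym %in% c("B", "C", "N", "O", "P", "S")) sym <- tolower(sym)
    paste0(sym, "{", format(sublab[i], scientific = FALSE), "}")
  }
  pieces <- vapply(side_fragments_idx(sub), function(idx) {
    emit_fragment(sub, idx, ranks, write_maps = FALSE, atom_token_fn = token_fn)
  }, character(1))
  paste(sort(pieces), collapse = ".")
}

#' Signatures for a batch of reactions, as a tidy table
#'
#' @param rxns A list of standardized `mapped_reaction` objects.
#' @param spec An [atom_type_spec()].
#' @param radius_max Largest radius.
#' @return A tibble with columns `reaction_id`, `radius`, `signature`.
#' @export
sign_reactions <- function(rxns, spec = atom_type_spec(), radius_max = 2) {
  purrr::map_dfr(rxns, function(rxn) {
    sig <- reaction_signature(rxn, spec, radius_max)
    tibble::tibble(reaction_id = rxn$reaction_id,
                   radius = 0:radius_max,
                   signature = unname(sig$text))
  })
}
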