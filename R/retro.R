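#' Compile a reverse-reaction template into a substructure query
#'
#' The query graph is the radius-expanded core of the template's retro-input
#' side (the original product), closed under incidence to edited bonds:
#' atoms whose bonds are broken, formed or change order — and the anchor
#' atoms of added atoms — are included even when their own property tuple
#' does not change, since without them the transformation is not
#' well-defined on a matched target. Each query atom is constrained to its
#' full enabled-property tuple (the atom-type label computed in the template
#' molecule); each query bond to its order.
#'
#' @param template A `mapped_reaction` in reversed (retro) orientation:
#'   reactant side = the original product, product side = the synthons.
#' @param radius Expansion radius (matching the repository's).
#' @param spec The [atom_type_spec()] (matching the repository's).
#' @return An `rrt_query` object carrying the query graph, the mapped edit
#'   script, and the template sides.
#' @export
compile_query <- function(template, radius = 0, spec = atom_type_spec()) {
  left <- template$reactants
  right <- template$products
  core <- find_changing_atoms(template, spec)
  if (length(core$left) == 0 && length(core$right) == 0) {
    stop("template ", template$reaction_id, " has an empty core", call. = FALSE)
  }
  l2r <- rep(NA_integer_, n_atoms(left))
  l2r[core$pairs$left] <- core$pairs$right
  r2l <- rep(NA_integer_, n_atoms(right))
  r2l[core$pairs$right] <- core$pairs$left

  lb <- left$bonds
  rb <- right$bonds

  ## bond edits between paired atoms
  broken <- list(); formed <- list(); reorder <- list()
  for (k in seq_len(nrow(lb))) {
    i <- lb$a1[k]; j <- lb$a2[k]
    ri <- l2r[i]; rj <- l2r[j]
    if (is.na(ri) || is.na(rj)) next      # bond to a deleted atom: goes with it
    be <- bond_between(right, ri, rj)
    if (length(be) == 0) {
      broken[[length(broken) + 1]] <- c(i, j)
    } else if (right$bonds$order[be] != lb$order[k]) {
      reorder[[length(reorder) + 1]] <- list(i = i, j = j, order = right$bonds$order[be])
    }
  }
  for (k in seq_len(nrow(rb))) {
    ri <- rb$a1[k]; rj <- rb$a2[k]
    i <- r2l[ri]; j <- r2l[rj]
    if (is.na(i) || is.na(j)) next        # involves an added atom: handled below
    if (length(bond_between(left, i, j)) == 0) {
      formed[[length(formed) + 1]] <- list(i = i, j = j, order = rb$order[k])
    }
  }

  added <- core$unpaired_right            # synthon-side atoms to create
  deleted <- core$unpaired_left           # retro-input atoms to remove
  ## anchors: paired left atoms bonded (on the right side) to an added atom
  anchors <- integer()
  for (k in seq_len(nrow(rb))) {
    ri <- rb$a1[k]; rj <- rb$a2[k]
    if (ri %in% added && !rj %in% added && !is.na(r2l[rj])) anchors <- c(anchors, r2l[rj])
    if (rj %in% added && !ri %in% added && !is.na(r2l[ri])) anchors <- c(anchors, r2l[ri])
  }

  ## paired atoms whose charge or aromatic flag changes
  prop_updates <- list()
  for (k in seq_len(nrow(core$pairs))) {
    i <- core$pairs$left[k]; ri <- core$pairs$right[k]
    if (left$atoms$charge[i] != right$atoms$charge[ri] ||
        left$atoms$aromatic[i] != right$atoms$aromatic[ri]) {
      prop_updates[[length(prop_updates) + 1]] <-
        list(i = i, charge = right$atoms$charge[ri],
             aromatic = right$atoms$aromatic[ri])
    }
  }

  edit_atoms <- unique(c(
    unlist(broken), vapply(formed, function(e) c(e$i, e$j), numeric(2)),
    vapply(reorder, function(e) c(e$i, e$j), numeric(2)),
    anchors, deleted,
    vapply(prop_updates, function(e) e$i, numeric(1))
  ))
  qatoms <- sort(unique(c(expand_core(left, core$left, radius), edit_atoms)))

  labels <- assign_atom_types(left, spec)
  qpos <- match(seq_len(n_atoms(left)), qatoms)   # left idx -> query position
  keepb <- lb$a1 %in% qatoms & lb$a2 %in% qatoms
  qbonds <- tibble::tibble(q1 = qpos[lb$a1[keepb]], q2 = qpos[lb$a2[keepb]],
                           order = lb$order[keepb])

  structure(list(
    atoms = tibble::tibble(left_idx = qatoms, label = labels[qatoms]),
    bonds = qbonds,
    left = left, right = right, l2r = l2r, r2l = r2l,
    edits = list(broken = broken, formed = formed, reorder = reorder,
                 added = added, deleted = deleted, anchors = anchors,
                 prop_updates = prop_updates),
    radius = radius, spec = spec,
    reaction_id = template$reaction_id,
    provenance = template$provenance
  ), class = "rrt_query")
}

#' @export
print.rrt_query <- function(x, ...) {
  cat("<rrt_query> ", nrow(x$atoms), " query atoms, ", nrow(x$bonds),
      " bonds, radius ", x$radius, " (template ", x$reaction_id, ")\n", sep = "")
  invisible(x)
}

#' Find all embeddings of a compiled query in a molecule
#'
#' Backtracking subgraph matching: a query atom matches a target atom with
#' the identical atom-type label (all enabled properties equal); every query
#' bond must map onto a target bond of the same order.
#'
#' @param query An `rrt_query`.
#' @param mol Target `mapped_molecule`.
#' @param labels Optional precomputed target labels ([assign_atom_types()]).
#' @return A list of embeddings; each is an integer vector of target atom
#'   indices, one per query atom (in query-atom order).
#' @export
match_query <- function(query, mol, labels = NULL) {
  if (is.null(labels)) labels <- assign_atom_types(mol, query$spec)
  nq <- nrow(query$atoms)
  qlab <- query$atoms$label
  cands <- lapply(qlab, function(l) which(labels == l))
  if (any(vapply(cands, length, integer(1)) == 0)) return(list())

  ## adjacency of the query graph, with bond orders
  qadj <- vector("list", nq)
  for (k in seq_len(nrow(query$bonds))) {
    q1 <- query$bonds$q1[k]; q2 <- query$bonds$q2[k]; o <- query$bonds$order[k]
    qadj[[q1]] <- rbind(qadj[[q1]], c(q2, o))
    qadj[[q2]] <- rbind(qadj[[q2]], c(q1, o))
  }
  ## visit order: most-constrained first, then prefer atoms adjacent to
  ## already-ordered ones so adjacency prunes early
  ord <- integer(0)
  remaining <- order(vapply(cands, length, integer(1)))
  while (length(ord) < nq) {
    nbr <- setdiff(unlist(lapply(ord, function(q)
      if (!is.null(qadj[[q]])) qadj[[q]][, 1])), ord)
    nxt <- if (length(nbr) > 0) nbr[1] else setdiff(remaining, ord)[1]
    ord <- c(ord, nxt)
  }

  tadj_order <- function(i, j) {
    be <- bond_between(mol, i, j)
    if (length(be) == 0) NA_real_ else mol$bonds$order[be]
  }

  results <- list()
  emb <- integer(nq)
  assign_next <- function(step) {
    if (step > nq) {
      results[[length(results) + 1]] <<- emb
      return(invisible())
    }
    q <- ord[step]
    for (t in cands[[q]]) {
      if (t %in% emb[ord[seq_len(step - 1)]]) next
      ok <- TRUE
      if (!is.null(qadj[[q]])) {
        for (r in seq_len(nrow(qadj[[q]]))) {
          q2 <- qadj[[q]][r, 1]
          if (!q2 %in% ord[seq_len(step - 1)]) next
          if (!identical(tadj_order(t, emb[q2]), qadj[[q]][r, 2])) { ok <- FALSE; break }
        }
      }
      if (ok) {
        emb[q] <<- t
        assign_next(step + 1)
        emb[q] <<- 0L
      }
    }
  }
  assign_next(1)
  results
}

#' Apply a reverse-reaction template to a matched target
#'
#' Performs the template's mapped edit script on the embedded atoms: breaks
#' and forms bonds, updates bond orders and atom charges, removes atoms
#' without a synthon-side counterpart, and grafts on the appearing atoms.
#' Unembedded target atoms are carried through unchanged. The result is
#' split into fragments (the synthons) and each is valence-checked.
#'
#' @param target Target `mapped_molecule`.
#' @param query An `rrt_query`.
#' @param embedding One embedding from [match_query()].
#' @return A list of synthon `mapped_molecule`s, or `NULL` when the edit
#'   produces a valence-invalid intermediate (that embedding is skipped).
#' @export
apply_template <- function(target, query, embedding) {
  tg <- target
  tg$atoms$map <- 0L
  emb_of <- function(left_idx) embedding[match(left_idx, query$atoms$left_idx)]
  touched <- integer()

  for (e in query$edits$prop_updates) {
    t <- emb_of(e$i)
    tg$atoms$charge[t] <- e$charge
    tg$atoms$aromatic[t] <- e$aromatic
    touched <- c(touched, t)
  }
  for (pr in query$edits$broken) {
    ti <- emb_of(pr[1]); tj <- emb_of(pr[2])
    be <- bond_between(tg, ti, tj)
    tg$bonds <- tg$bonds[-be, ]
    touched <- c(touched, ti, tj)
  }
  for (e in query$edits$reorder) {
    ti <- emb_of(e$i); tj <- emb_of(e$j)
    be <- bond_between(tg, ti, tj)
    tg$bonds$order[be] <- e$order
    touched <- c(touched, ti, tj)
  }
  for (e in query$edits$formed) {
    ti <- emb_of(e$i); tj <- emb_of(e$j)
    tg$bonds <- dplyr::bind_rows(tg$bonds,
                                 tibble::tibble(a1 = ti, a2 = tj, order = e$order))
    touched <- c(touched, ti, tj)
  }

  ## graft appearing atoms (synthon-side atoms with no target counterpart)
  right <- query$right
  new_of <- rep(NA_integer_, n_atoms(right))
  for (ra in query$edits$added) {
    tg$atoms <- dplyr::bind_rows(tg$atoms, tibble::tibble(
      symbol = right$atoms$symbol[ra], charge = right$atoms$charge[ra],
      aromatic = right$atoms$aromatic[ra], hcount = right$atoms$hcount[ra],
      map = 0L, frag = 1L))
    new_of[ra] <- nrow(tg$atoms)
    touched <- c(touched, new_of[ra])
  }
  if (length(query$edits$added) > 0) {
    for (k in seq_len(nrow(right$bonds))) {
      ri <- right$bonds$a1[k]; rj <- right$bonds$a2[k]
      ai <- ri %in% query$edits$added; aj <- rj %in% query$edits$added
      if (!ai && !aj) next
      ti <- if (ai) new_of[ri] else emb_of(query$r2l[ri])
      tj <- if (aj) new_of[rj] else emb_of(query$r2l[rj])
      if (is.na(ti) || is.na(tj)) next
      tg$bonds <- dplyr::bind_rows(tg$bonds,
                                   tibble::tibble(a1 = ti, a2 = tj,
                                                  order = right$bonds$order[k]))
      touched <- c(touched, ti, tj)
    }
  }

  ## remove atoms with no synthon-side counterpart; surviving neighbours
  ## need their hydrogen counts refreshed
  del <- vapply(query$edits$deleted, emb_of, integer(1))
  if (length(del) > 0) {
    nb <- c(tg$bonds$a2[tg$bonds$a1 %in% del], tg$bonds$a1[tg$bonds$a2 %in% del])
    touched <- c(touched, setdiff(nb, del))
  }
  keep <- setdiff(seq_len(nrow(tg$atoms)), del)
  newpos <- integer(nrow(tg$atoms))
  newpos[keep] <- seq_along(keep)
  tg <- keep_atoms(tg, keep)
  touched <- newpos[setdiff(unique(touched), del)]
  touched <- touched[touched > 0]

  tryCatch({
    tg <- recompute_hcount(tg, touched)
    side_fragments(tg)
  }, synthon_valence_error = function(e) NULL)
}

## deduplicated synthon multiset key for a route
synthon_key <- function(synthons) {
  paste(sort(vapply(synthons, canonical_smiles, character(1))), collapse = "+")
}
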