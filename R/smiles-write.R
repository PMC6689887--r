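#' Write a mapped molecule as SMILES
#'
#' By default emits a canonical form: atoms are ordered by a canonical graph
#' labeling (BLISS on the vertex-colored, bond-order-annotated graph), the
#' traversal starts from the first-ranked atom of each fragment, neighbours
#' are visited in rank order, and fragments are sorted lexicographically.
#' The output therefore depends only on the molecular graph, never on input
#' atom order. Map numbers are written when `write_maps = TRUE` but never
#' influence the canonical order.
#'
#' @param mol A `mapped_molecule`.
#' @param canonical Use canonical atom ordering (default) or input order.
#' @param write_maps Write atom-map numbers on mapped atoms.
#' @param ranks Optional explicit integer rank per atom, overriding the
#'   canonical ranks (used to emit randomized-but-valid atom orders).
#' @return A single SMILES string; fragments joined with ".".
#' @export
write_smiles <- function(mol, canonical = TRUE, write_maps = TRUE, ranks = NULL) {
  if (n_atoms(mol) == 0) return("")
  if (is.null(ranks)) {
    ranks <- if (canonical) canonical_ranks(mol, default_color_key(mol)) else seq_len(n_atoms(mol))
  }
  frags <- side_fragments_idx(mol)
  pieces <- vapply(frags, function(idx) {
    emit_fragment(mol, idx, ranks, write_maps)
  }, character(1))
  if (canonical) pieces <- sort(pieces)
  paste(pieces, collapse = ".")
}

## list of atom index vectors, one per fragment
side_fragments_idx <- function(mol) {
  split(seq_len(n_atoms(mol)), mol$atoms$frag)
}

emit_fragment <- function(mol, idx, ranks, write_maps, atom_token_fn = NULL) {
  adj <- adjacency(mol)
  deg <- heavy_degree(mol)
  bos <- bond_order_sum(mol)
  n <- n_atoms(mol)

  ## ring-closure bonds: spanning-tree traversal in rank order, extra edges
  ## become numbered closures
  visited <- rep(FALSE, n)

  at <- mol$atoms
  atom_token <- if (!is.null(atom_token_fn)) atom_token_fn else function(i) {
    sym <- at$symbol[i]; chg <- at$charge[i]; aro <- at$aromatic[i]
    hc <- at$hcount[i]; mapn <- at$map[i]
    wm <- write_maps && mapn > 0
    implied <- implied_hcount(sym, chg, aro, deg[i], bos[i])
    need <- chg != 0 || wm || !(sym %in% ORGANIC_SUBSET) || hc != implied
    out_sym <- if (aro && sym %in% c("B", "C", "N", "O", "P", "S")) tolower(sym) else sym
    if (!need) return(out_sym)
    h <- if (hc == 0) "" else if (hc == 1) "H" else paste0("H", hc)
    ch <- if (chg == 0) "" else if (chg == 1) "+" else if (chg == -1) "-" else
      sprintf("%+d", chg)
    mp <- if (wm) paste0(":", mapn) else ""
    paste0("[", out_sym, h, ch, mp, "]")
  }

  bond_token <- function(i, j, ord) {
    if (ord == 2) return("=")
    if (ord == 3) return("#")
    if (ord == 1.5) return("")           # aromatic, implicit between aromatic atoms
    if (mol$atoms$aromatic[i] && mol$atoms$aromatic[j]) return("-")
    ""
  }

  start <- idx[which.min(ranks[idx])]
  ## first pass: find tree/closure structure
  tree_parent <- rep(NA_integer_, n)
  closures <- list()
  seen_edge <- character(0)
  visited[start] <- TRUE
  dfs <- function(i) {
    nbrs <- adj[[i]][order(ranks[adj[[i]]])]
    for (j in nbrs) {
      ek <- paste(min(i, j), max(i, j))
      if (ek %in% seen_edge) next
      seen_edge <<- c(seen_edge, ek)
      if (!visited[j]) {
        visited[j] <<- TRUE
        tree_parent[j] <<- i
        dfs(j)
      } else {
        closures[[length(closures) + 1]] <<- c(i, j)
      }
    }
  }
  dfs(start)

  ## assign closure digits
  cl_digit <- integer(length(closures))
  if (length(closures)) cl_digit <- seq_along(closures)
  digit_str <- function(d) if (d < 10) as.character(d) else paste0("%", d)

  closure_at <- function(i) {
    out <- character(0)
    for (k in seq_along(closures)) {
      pr <- closures[[k]]
      if (pr[1] == i || pr[2] == i) {
        other <- if (pr[1] == i) pr[2] else pr[1]
        be <- bond_between(mol, i, other)
        bt <- bond_token(i, other, mol$bonds$order[be])
        ## write the bond symbol on the first mention only
        first_mention <- !(k %in% written_closures)
        if (first_mention) {
          written_closures <<- c(written_closures, k)
          out <- c(out, paste0(bt, digit_str(cl_digit[k])))
        } else {
          out <- c(out, digit_str(cl_digit[k]))
        }
      }
    }
    paste(out, collapse = "")
  }
  written_closures <- integer(0)

  ## children in the spanning tree, rank-ordered
  children <- function(i) {
    ch <- which(tree_parent == i)
    ch[order(ranks[ch])]
  }

  emit <- function(i) {
    s <- paste0(atom_token(i), closure_at(i))
    ch <- children(i)
    if (length(ch) == 0) return(s)
    parts <- character(0)
    for (k in seq_along(ch)) {
      j <- ch[k]
      be <- bond_between(mol, i, j)
      bt <- bond_token(i, j, mol$bonds$order[be])
      sub <- paste0(bt, emit(j))
      parts <- c(parts, if (k < length(ch)) paste0("(", sub, ")") else sub)
    }
    paste0(s, paste(parts, collapse = ""))
  }
  emit(start)
}

#' Canonical SMILES key of a molecule (maps stripped)
#'
#' The structural identity key used for duplicate detection, the no-change
#' test and building-block lookup.
#'
#' @param mol A `mapped_molecule` (or SMILES string, which is parsed).
#' @return Canonical SMILES without atom maps.
#' @export
canonical_smiles <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  write_smiles(mol, canonical = TRUE, write_maps = FALSE)
}

#' Rewrite a SMILES with a random atom order
#'
#' Emits the same molecular graph starting from a random atom with randomized
#' neighbour visit order. Used to exercise canonicality: the canonical SMILES
#' and signatures of the rewritten form must be byte-identical to the
#' original's.
#'
#' @param smiles A SMILES string.
#' @return A SMILES string describing the same molecule in a shuffled order.
#' @export
shuffle_smiles <- function(smiles) {
  mol <- parse_smiles(smiles)
  ranks <- sample(n_atoms(mol))
  write_smiles(mol, canonical = FALSE, write_maps = TRUE, ranks = ranks)
}
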