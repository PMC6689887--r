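#' Mapped molecule objects
#'
#' A `mapped_molecule` is a light molecular graph: an atom table and a bond
#' table. Atoms carry element symbol, formal charge, aromatic flag, hydrogen
#' count, atom-map number (0 = unmapped) and a fragment id; bonds carry the
#' two atom indices and a bond order (1, 2, 3, or 1.5 for aromatic). A single
#' object may hold several disconnected fragments (one side of a reaction is
#' stored as one multi-fragment molecule).
#'
#' @param atoms A data frame with columns `symbol`, `charge`, `aromatic`,
#'   `hcount`, `map`, `frag`.
#' @param bonds A data frame with columns `a1`, `a2`, `order`.
#' @return A `mapped_molecule` object.
#' @export
mapped_molecule <- function(atoms, bonds) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  stopifnot(all(c("symbol", "charge", "aromatic", "hcount", "map", "frag") %in% names(atoms)),
            all(c("a1", "a2", "order") %in% names(bonds)))
  mol <- structure(list(atoms = atoms, bonds = bonds), class = "mapped_molecule")
  validate_molecule(mol)
  mol
}

validate_molecule <- function(mol) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  if (nrow(b) > 0) {
    if (any(b$a1 == b$a2) || any(b$a1 < 1 | b$a1 > n | b$a2 < 1 | b$a2 > n)) {
      stop("bond references a missing or identical atom", call. = FALSE)
    }
  }
  pos <- mol$atoms$map[mol$atoms$map > 0]
  if (anyDuplicated(pos)) {
    attr(mol, "duplicate_maps") <- TRUE
  }
  invisible(mol)
}

#' @export
print.mapped_molecule <- function(x, ...) {
  cat("<mapped_molecule> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds, ",
      dplyr::n_distinct(x$atoms$frag), " fragment(s)\n", sep = "")
  cat("  ", write_smiles(x), "\n", sep = "")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

n_fragments <- function(mol) if (nrow(mol$atoms) == 0) 0L else dplyr::n_distinct(mol$atoms$frag)

empty_molecule <- function() {
  mapped_molecule(
    tibble::tibble(symbol = character(), charge = integer(), aromatic = logical(),
                   hcount = integer(), map = integer(), frag = integer()),
    tibble::tibble(a1 = integer(), a2 = integer(), order = numeric())
  )
}

#' Split a multi-fragment molecule into single-fragment molecules
#'
#' @param mol A `mapped_molecule`.
#' @return A list of single-fragment `mapped_molecule` objects, in fragment
#'   id order.
#' @export
side_fragments <- function(mol) {
  if (n_atoms(mol) == 0) return(list())
  lapply(sort(unique(mol$atoms$frag)), function(f) keep_atoms(mol, which(mol$atoms$frag == f)))
}

## Retain only the given atom indices (renumbering bonds accordingly).
keep_atoms <- function(mol, idx) {
  idx <- sort(idx)
  newpos <- integer(n_atoms(mol))
  newpos[idx] <- seq_along(idx)
  atoms <- mol$atoms[idx, , drop = FALSE]
  keep <- mol$bonds$a1 %in% idx & mol$bonds$a2 %in% idx
  bonds <- mol$bonds[keep, , drop = FALSE]
  bonds$a1 <- newpos[bonds$a1]
  bonds$a2 <- newpos[bonds$a2]
  atoms$frag <- renumber_frags(atoms, bonds)
  mapped_molecule(atoms, bonds)
}

## Fragment membership from connectivity (1-based, ordered by lowest atom).
renumber_frags <- function(atoms, bonds) {
  n <- nrow(atoms)
  if (n == 0) return(integer())
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      ra <- find(bonds$a1[k]); rb <- find(bonds$a2[k])
      if (ra != rb) comp[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

combine_mols <- function(a, b) {
  if (n_atoms(a) == 0) return(b)
  if (n_atoms(b) == 0) return(a)
  off <- n_atoms(a)
  foff <- max(a$atoms$frag)
  bt <- b$atoms
  bt$frag <- bt$frag + foff
  bb <- b$bonds
  bb$a1 <- bb$a1 + off
  bb$a2 <- bb$a2 + off
  mapped_molecule(dplyr::bind_rows(a$atoms, bt), dplyr::bind_rows(a$bonds, bb))
}

## Adjacency list: for each atom, integer vector of neighbours.
adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  adj
}

heavy_degree <- function(mol) {
  n <- n_atoms(mol)
  d <- integer(n)
  if (nrow(mol$bonds) > 0) {
    t1 <- tabulate(mol$bonds$a1, n)
    t2 <- tabulate(mol$bonds$a2, n)
    d <- t1 + t2
  }
  d
}

bond_between <- function(mol, i, j) {
  which((mol$bonds$a1 == i & mol$bonds$a2 == j) | (mol$bonds$a1 == j & mol$bonds$a2 == i))
}

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

ATOMIC_NUMBERS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Fe = 26, Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35,
  Pd = 46, Ag = 47, Sn = 50, I = 53, Pt = 78, Au = 79, Hg = 80
)

atomic_number <- function(symbol) {
  z <- ATOMIC_NUMBERS[symbol]
  if (anyNA(z)) {
    stop("unsupported element symbol: ", paste(symbol[is.na(z)], collapse = ", "), call. = FALSE)
  }
  unname(z)
}

## Allowed valences for an element at a given formal charge. Cations of
## N/O/P/S gain a bond, anions lose one; C/B lose one either way.
allowed_valences <- function(symbol, charge) {
  base <- switch(symbol,
    B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
    F = 1, Cl = c(1, 3), Br = 1, I = c(1, 3),
    NULL
  )
  if (is.null(base)) return(0L)  # no implicit hydrogens for other elements
  if (charge == 0) return(base)
  if (symbol %in% c("N", "O", "P", "S")) return(pmax(base + charge, 0))
  pmax(base - abs(charge), 0)
}

## Sum of bond orders around each atom, aromatic bonds counting 1 each
## (the aromatic correction is handled separately via needs-double logic).
bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    o <- if (b$order[k] == 1.5) 1 else b$order[k]
    s[b$a1[k]] <- s[b$a1[k]] + o
    s[b$a2[k]] <- s[b$a2[k]] + o
  }
  s
}

## Implicit hydrogen count an atom would receive from valence rules alone.
## Aromatic atoms follow the reading convention for lowercase SMILES atoms:
## one valence unit is reserved for the delocalized double bond on carbon
## (and on two-connected nitrogen); aromatic O/S and three-connected N
## contribute a lone pair instead.
implied_hcount <- function(symbol, charge, aromatic, degree, bosum) {
  if (aromatic) {
    vals <- allowed_valences(symbol, charge)
    if (identical(vals, 0L)) return(0L)
    nd <- 0L
    if (symbol %in% c("C", "B")) nd <- 1L
    if (symbol %in% c("N", "P") && degree == 2 && charge == 0) nd <- 1L
    extra <- bosum - degree   # non-aromatic multiple bonds raise the sum
    h <- min(vals) - degree - nd - extra
    return(as.integer(max(0, h)))
  }
  vals <- allowed_valences(symbol, charge)
  ok <- vals[vals >= bosum]
  if (length(ok) == 0) return(0L)
  as.integer(min(ok) - bosum)
}

## Recompute the hydrogen count of the given atoms from valence rules.
## Returns the molecule, or signals class "synthon_valence_error" when an
## atom exceeds every allowed valence (used to veto template applications).
recompute_hcount <- function(mol, idx = seq_len(n_atoms(mol))) {
  deg <- heavy_degree(mol)
  bos <- bond_order_sum(mol)
  for (i in idx) {
    a <- mol$atoms[i, ]
    if (!a$aromatic) {
      vals <- allowed_valences(a$symbol, a$charge)
      if (!identical(vals, 0L) && length(vals[vals >= bos[i]]) == 0) {
        stop(structure(class = c("synthon_valence_error", "error", "condition"),
                       list(message = sprintf("valence violation at atom %d (%s, bond order sum %g)",
                                              i, a$symbol, bos[i]),
                            call = NULL)))
      }
    }
    mol$atoms$hcount[i] <- implied_hcount(a$symbol, a$charge, a$aromatic, deg[i], bos[i])
  }
  mol
}

#' Heavy atom count of a molecule
#'
#' @param mol A `mapped_molecule`.
#' @return Integer number of non-hydrogen atoms.
#' @export
heavy_atom_count <- function(mol) n_atoms(mol)
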