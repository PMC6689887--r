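#' Atom-type specifications
#'
#' An atom-type spec selects which atomic properties participate in atom
#' typing, core detection and signature labels. Available properties:
#'
#' * `Z` atomic number
#' * `A` aromaticity (0/1)
#' * `C` number of connections (heavy-atom degree)
#' * `O` formal charge
#' * `R` ring bond count (ring bonds incident to the atom)
#' * `S` smallest ring size through the atom (0 if acyclic)
#' * `U` unsaturation: count of non-aromatic multiple bonds on the atom
#'   (aromaticity is carried entirely by `A`)
#' * `PI` pi-electron count: one per double-bond order unit plus one for an
#'   aromatic atom
#' * `H` hydrogen count
#'
#' The default spec is `Z,A,C,O,R,S,U`. Each enabled property is encoded as
#' a bounded non-negative integer and packed positionally (mixed-radix) into
#' one numeric label per atom; distinct enabled-property tuples always give
#' distinct labels, and labels are decodable with [decode_atom_type()].
#' Disabled properties occupy a zero slot, so disabling a property can only
#' merge label classes, never split them.
#'
#' @param properties Character vector of property codes, or a compact string
#'   such as `"ZACORSU"` (`P` stands for `PI` in compact form).
#' @return An `atom_type_spec` object.
#' @export
atom_type_spec <- function(properties = c("Z", "A", "C", "O", "R", "S", "U")) {
  if (length(properties) == 1 && nchar(properties) > 1 && !properties %in% ATS_PROPS) {
    chars <- strsplit(properties, "")[[1]]
    properties <- vapply(chars, function(ch) if (ch == "P") "PI" else ch, character(1))
  }
  properties <- unique(toupper(properties))
  bad <- setdiff(properties, ATS_PROPS)
  if (length(bad)) stop("unknown atom properties: ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(properties) == 0) stop("at least one atom property is required", call. = FALSE)
  structure(list(properties = properties), class = "atom_type_spec")
}

ATS_PROPS <- c("Z", "A", "C", "O", "R", "S", "U", "PI", "H")
## per-property radix; the product (2^44) stays well inside exact double range
ATS_BASE <- c(Z = 128, A = 2, C = 16, O = 32, R = 16, S = 64, U = 16, PI = 16, H = 16)

#' @export
print.atom_type_spec <- function(x, ...) {
  cat("<atom_type_spec> ", paste(x$properties, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' @export
format.atom_type_spec <- function(x, ...) {
  paste(vapply(x$properties, function(p) if (p == "PI") "P" else p, character(1)),
        collapse = "")
}

## raw per-atom property matrix (all nine properties, unencoded)
atom_property_matrix <- function(mol) {
  n <- n_atoms(mol)
  deg <- heavy_degree(mol)
  rbc <- ring_bond_count(mol)
  srs <- smallest_ring_size(mol)
  u <- integer(n); pi_e <- integer(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (b$order[k] %in% c(2, 3)) {
      u[b$a1[k]] <- u[b$a1[k]] + 1L
      u[b$a2[k]] <- u[b$a2[k]] + 1L
      pi_e[b$a1[k]] <- pi_e[b$a1[k]] + as.integer(b$order[k] - 1)
      pi_e[b$a2[k]] <- pi_e[b$a2[k]] + as.integer(b$order[k] - 1)
    }
  }
  pi_e <- pi_e + as.integer(mol$atoms$aromatic)
  cbind(
    Z = atomic_number(mol$atoms$symbol),
    A = as.integer(mol$atoms$aromatic),
    C = pmin(deg, 15L),
    O = pmin(pmax(mol$atoms$charge + 8L, 0L), 31L),
    R = pmin(rbc, 15L),
    S = pmin(srs, 63L),
    U = pmin(u, 15L),
    PI = pmin(pi_e, 15L),
    H = pmin(mol$atoms$hcount, 15L)
  )
}

#' Assign atom-type labels to every atom of a molecule
#'
#' @param mol A `mapped_molecule` (rings and aromaticity as stored).
#' @param spec An [atom_type_spec()].
#' @return Numeric vector of one injectively packed label per atom.
#' @export
assign_atom_types <- function(mol, spec = atom_type_spec()) {
  pm <- atom_property_matrix(mol)
  mult <- 1
  lab <- numeric(nrow(pm))
  for (p in ATS_PROPS) {
    if (p %in% spec$properties) lab <- lab + pm[, p] * mult
    mult <- mult * ATS_BASE[[p]]
  }
  lab
}

#' Decode an atom-type label back to its property tuple
#'
#' @param label Numeric label(s) produced by [assign_atom_types()].
#' @param spec The `atom_type_spec` used to produce them.
#' @return A tibble with one row per label and one column per enabled
#'   property (charge decoded back to its signed value).
#' @export
decode_atom_type <- function(label, spec = atom_type_spec()) {
  out <- tibble::tibble(.rows = length(label))
  rem <- label
  for (p in ATS_PROPS) {
    v <- rem %% ATS_BASE[[p]]
    rem <- (rem - v) / ATS_BASE[[p]]
    if (p %in% spec$properties) {
      out[[p]] <- if (p == "O") as.integer(v) - 8L else as.integer(v)
    }
  }
  out
}
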