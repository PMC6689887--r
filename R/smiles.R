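#' Parse a SMILES string into a mapped molecule
#'
#' Reads the common organic subset plus bracket atoms with formal charge,
#' explicit hydrogen counts and atom-map numbers (`[NH3+:4]`). Aromaticity
#' is taken as written (lowercase atoms / `:` bonds); Kekule-written rings
#' are normalized later by [perceive_aromaticity()]. Stereo markers
#' (`/`, `\`, `@`) and isotopes are accepted and ignored. Dots separate
#' fragments of one multi-fragment molecule.
#'
#' @param smiles A single SMILES string.
#' @return A `mapped_molecule`.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  s <- trimws(smiles)
  if (!nzchar(s)) stop("cannot parse empty SMILES", call. = FALSE)
  toks <- tokenize_smiles(s)

  symbol <- character(); charge <- integer(); aromatic <- logical()
  hexp <- integer()      # explicit bracket H count, NA when implicit
  amap <- integer(); frag <- integer()
  b_a1 <- integer(); b_a2 <- integer(); b_ord <- numeric()

  prev <- NA_integer_
  pending <- NA_real_    # bond order queued by a bond symbol
  stack <- integer()
  rings <- list()        # closure digit -> list(atom, order)
  fragno <- 1L

  add_bond <- function(i, j, ord) {
    if (is.na(ord)) {
      ord <- if (aromatic[i] && aromatic[j]) 1.5 else 1
    }
    b_a1 <<- c(b_a1, i); b_a2 <<- c(b_a2, j); b_ord <<- c(b_ord, ord)
  }

  for (tok in toks) {
    if (tok == "(") {
      if (is.na(prev)) stop("branch start with no preceding atom in ", smiles, call. = FALSE)
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0) stop("unbalanced ')' in ", smiles, call. = FALSE)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prev <- NA_integer_
      pending <- NA_real_
      fragno <- fragno + 1L
    } else if (tok %in% c("-", "/", "\\")) {
      pending <- 1
    } else if (tok == "=") {
      pending <- 2
    } else if (tok == "#") {
      pending <- 3
    } else if (tok == ":") {
      pending <- 1.5
    } else if (grepl("^%?[0-9]+$", tok)) {
      key <- sub("^%", "", tok)
      if (is.na(prev)) stop("ring closure with no preceding atom in ", smiles, call. = FALSE)
      if (!is.null(rings[[key]])) {
        opener <- rings[[key]]
        ord <- pending
        if (is.na(ord)) ord <- opener$order
        add_bond(opener$atom, prev, ord)
        rings[[key]] <- NULL
      } else {
        rings[[key]] <- list(atom = prev, order = pending)
      }
      pending <- NA_real_
    } else {
      at <- parse_atom_token(tok, smiles)
      symbol <- c(symbol, at$symbol); charge <- c(charge, at$charge)
      aromatic <- c(aromatic, at$aromatic); hexp <- c(hexp, at$hcount)
      amap <- c(amap, at$map); frag <- c(frag, fragno)
      this <- length(symbol)
      if (!is.na(prev)) add_bond(prev, this, pending)
      prev <- this
      pending <- NA_real_
    }
  }
  if (length(stack) > 0) stop("unbalanced '(' in ", smiles, call. = FALSE)
  if (length(rings) > 0 && any(!vapply(rings, is.null, logical(1)))) {
    stop("unclosed ring bond in ", smiles, call. = FALSE)
  }
  if (length(symbol) == 0) stop("no atoms in SMILES ", smiles, call. = FALSE)

  atoms <- tibble::tibble(symbol = symbol, charge = charge, aromatic = aromatic,
                          hcount = 0L, map = amap, frag = frag)
  bonds <- tibble::tibble(a1 = b_a1, a2 = b_a2, order = b_ord)
  atoms$frag <- renumber_frags(atoms, bonds)
  mol <- mapped_molecule(atoms, bonds)

  deg <- heavy_degree(mol)
  bos <- bond_order_sum(mol)
  h <- integer(n_atoms(mol))
  for (i in seq_len(n_atoms(mol))) {
    h[i] <- if (!is.na(hexp[i])) hexp[i] else {
      implied_hcount(symbol[i], charge[i], aromatic[i], deg[i], bos[i])
    }
  }
  mol$atoms$hcount <- h
  ## an implicit bond between aromatic atoms of two different rings
  ## (biphenyl written without "-") is a single bond, not an aromatic one
  if (any(mol$bonds$order == 1.5)) {
    rb <- ring_bonds(mol)
    mol$bonds$order[mol$bonds$order == 1.5 & !rb] <- 1
  }
  mol
}

TOKEN_RE <- "\\[[^\\]]*\\]|Cl|Br|[BCNOPSFI]|[bcnops]|%[0-9]{2}|[0-9]|[-=#:/\\\\]|[().]"

tokenize_smiles <- function(s) {
  m <- gregexpr(TOKEN_RE, s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(s)) {
    covered <- rep(FALSE, nchar(s))
    for (k in seq_along(toks)) covered[m[k]:(m[k] + nchar(toks[k]) - 1)] <- TRUE
    bad <- substr(s, which(!covered)[1], which(!covered)[1])
    stop("unrecognized SMILES character '", bad, "' in ", s, call. = FALSE)
  }
  toks
}

ATOM_BRACKET_RE <- "^\\[([0-9]+)?([A-Z][a-z]?|[bcnops]|\\*)(@{1,2})?(H[0-9]*)?((?:\\+{1,}|-{1,})[0-9]*)?(?::([0-9]+))?\\]$"

parse_atom_token <- function(tok, context) {
  if (!startsWith(tok, "[")) {
    sym <- tok
    aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
    if (aromatic) sym <- toupper(sym)
    return(list(symbol = sym, charge = 0L, aromatic = aromatic,
                hcount = NA_integer_, map = 0L))
  }
  m <- regmatches(tok, regexec(ATOM_BRACKET_RE, tok, perl = TRUE))[[1]]
  if (length(m) == 0) stop("unparseable atom token '", tok, "' in ", context, call. = FALSE)
  sym <- m[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  if (aromatic) sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  hpart <- m[5]
  hc <- if (!nzchar(hpart)) 0L else if (hpart == "H") 1L else as.integer(sub("H", "", hpart))
  cpart <- m[6]
  chg <- 0L
  if (nzchar(cpart)) {
    sign <- if (startsWith(cpart, "+")) 1L else -1L
    digits <- gsub("[+-]", "", cpart)
    chg <- if (nzchar(digits)) sign * as.integer(digits) else sign * nchar(cpart)
  }
  mp <- if (nzchar(m[7] %||% "")) as.integer(m[7]) else 0L
  list(symbol = sym, charge = chg, aromatic = aromatic, hcount = hc, map = mp)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
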