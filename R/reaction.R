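#' Mapped reaction objects
#'
#' A `mapped_reaction` holds three reaction sides (reactants, agents,
#' products), each stored as one possibly multi-fragment [mapped_molecule()],
#' plus a reaction id and free-text provenance. Atom-map numbers tie atoms
#' across the reactant and product sides; agents (species above/below the
#' arrow) never participate in core detection.
#'
#' @param reactants,agents,products `mapped_molecule` objects (agents may be
#'   empty).
#' @param reaction_id Unique reaction identifier (non-empty string).
#' @param provenance Free-text origin record, e.g. `"US03931153_nan_64"`.
#' @return A `mapped_reaction` object.
#' @export
mapped_reaction <- function(reactants, agents, products, reaction_id,
                            provenance = reaction_id) {
  stopifnot(inherits(reactants, "mapped_molecule"),
            inherits(products, "mapped_molecule"),
            is.character(reaction_id), nzchar(reaction_id))
  if (is.null(agents)) agents <- empty_molecule()
  rxn <- structure(
    list(reactants = reactants, agents = agents, products = products,
         reaction_id = reaction_id, provenance = provenance,
         duplicate_maps = side_has_duplicate_maps(reactants) ||
           side_has_duplicate_maps(products)),
    class = "mapped_reaction"
  )
  rxn
}

side_has_duplicate_maps <- function(mol) {
  pos <- mol$atoms$map[mol$atoms$map > 0]
  anyDuplicated(pos) > 0
}

#' @export
print.mapped_reaction <- function(x, ...) {
  cat("<mapped_reaction> ", x$reaction_id, "\n  ", sep = "")
  cat(write_reaction_line(x)$text, "\n")
  if (x$duplicate_maps) cat("  [flag] duplicate atom maps within a side\n")
  invisible(x)
}

#' Parse one reaction line into a mapped reaction
#'
#' A reaction line is `reactants>agents>products<whitespace>ID`. Fragments
#' within a side are separated by `.` (standard dialect) or `+` (the
#' alternate dialect used by template files); the separator is auto-detected
#' unless forced. Duplicate map numbers within a side are flagged on the
#' returned object, never silently repaired (the standardizer decides their
#' fate).
#'
#' @param line One reaction line (reaction SMILES, whitespace, id).
#' @param dialect `"auto"` (default), `"dot"` or `"plus"`.
#' @return A `mapped_reaction`.
#' @export
parse_reaction_line <- function(line, dialect = c("auto", "dot", "plus")) {
  dialect <- match.arg(dialect)
  line <- trimws(line)
  parts <- strsplit(line, "\\s+")[[1]]
  if (length(parts) < 2) {
    stop("reaction line is missing an ID token: ", line, call. = FALSE)
  }
  rxn_smiles <- parts[1]
  id <- paste(parts[-1], collapse = "_")
  sides <- split_outside_brackets(rxn_smiles, ">")
  if (length(sides) == 2) sides <- c(sides[1], "", sides[2])
  if (length(sides) != 3) {
    stop("reaction SMILES must have 2 or 3 '>'-separated sides: ", rxn_smiles,
         call. = FALSE)
  }
  if (dialect == "auto") {
    ## a bare "+" outside brackets only ever occurs as the alternate
    ## fragment separator (charges are always bracketed)
    dialect <- if (any(vapply(sides, function(s)
      length(split_outside_brackets(s, "+")) > 1, logical(1)))) "plus" else "dot"
  }
  sep <- if (dialect == "plus") "+" else "."
  parse_side <- function(s, what) {
    if (!nzchar(s)) return(empty_molecule())
    frags <- split_outside_brackets(s, sep)
    frags <- frags[nzchar(frags)]
    if (length(frags) == 0) stop("empty ", what, " side in ", rxn_smiles, call. = FALSE)
    mols <- lapply(frags, function(f) {
      tryCatch(parse_smiles(f), error = function(e) {
        stop("unparseable ", what, " fragment '", f, "' in reaction ", id,
             ": ", conditionMessage(e), call. = FALSE)
      })
    })
    Reduce(combine_mols, mols)
  }
  if (!nzchar(sides[1]) && !nzchar(sides[3])) {
    stop("reaction has no reactant or product fragments: ", line, call. = FALSE)
  }
  mapped_reaction(
    reactants = parse_side(sides[1], "reactant"),
    agents = parse_side(sides[2], "agent"),
    products = parse_side(sides[3], "product"),
    reaction_id = id
  )
}

## split on a separator character, ignoring occurrences inside [...]
split_outside_brackets <- function(s, sep) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  cut <- logical(length(chars))
  for (i in seq_along(chars)) {
    if (chars[i] == "[") depth <- depth + 1L
    else if (chars[i] == "]") depth <- depth - 1L
    else if (chars[i] == sep && depth == 0L) cut[i] <- TRUE
  }
  if (!any(cut)) return(s)
  idx <- c(0L, which(cut), length(chars) + 1L)
  vapply(seq_len(length(idx) - 1), function(k) {
    lo <- idx[k] + 1L; hi <- idx[k + 1] - 1L
    if (hi < lo) "" else paste(chars[lo:hi], collapse = "")
  }, character(1))
}

#' Reverse a mapped reaction
#'
#' Exchanges the reactant and product sides; agents stay in place; map
#' numbers and the reaction id are untouched. Pure structural swap, its own
#' inverse.
#'
#' @param rxn A `mapped_reaction`.
#' @return The reversed `mapped_reaction`.
#' @export
reverse_reaction <- function(rxn) {
  out <- rxn
  out$reactants <- rxn$products
  out$products <- rxn$reactants
  out
}

#' Write a mapped reaction as a reaction line
#'
#' Canonical output: fragments within a side are sorted by their canonical
#' SMILES, so writing is a fixed point (write-parse-write is byte-identical).
#'
#' @param rxn A `mapped_reaction`.
#' @param dialect `"dot"` or `"plus"` intra-side fragment separator.
#' @return A list with `text` (the full line), `smiles`, `dialect` and
#'   `reaction_id`.
#' @export
write_reaction_line <- function(rxn, dialect = c("dot", "plus")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "plus") "+" else "."
  side_text <- function(mol) {
    frags <- side_fragments(mol)
    if (length(frags) == 0) return("")
    paste(sort(vapply(frags, write_smiles, character(1))), collapse = sep)
  }
  smiles <- paste0(side_text(rxn$reactants), ">", side_text(rxn$agents), ">",
                   side_text(rxn$products))
  list(text = paste(smiles, rxn$reaction_id), smiles = smiles,
       dialect = dialect, reaction_id = rxn$reaction_id)
}

#' Read a reaction SMILES file into a list of mapped reactions
#'
#' One reaction per line, `reactants>agents>products<whitespace>ID`; blank
#' lines and `#` comments are skipped.
#'
#' @param path File path.
#' @param dialect Passed to [parse_reaction_line()].
#' @return A list of `mapped_reaction` objects.
#' @export
read_reaction_file <- function(path, dialect = "auto") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(lines, parse_reaction_line, dialect = dialect)
}

#' Read a SMILES + ID file (targets, building blocks)
#'
#' @param path File path; each line is `SMILES<whitespace>ID`.
#' @return A tibble with columns `smiles` and `id`.
#' @export
read_molecule_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(trimws(lines), "\\s+")
  tibble::tibble(
    smiles = vapply(parts, `[[`, character(1), 1),
    id = vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_, character(1))
  )
}

total_atom_count <- function(rxn) {
  n_atoms(rxn$reactants) + n_atoms(rxn$products)
}
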