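#' Build a building-block availability index
#'
#' Keys are canonical SMILES after salt stripping (largest fragment by heavy
#' atom count; ties broken by canonical SMILES order). Multiple collection
#' entries sharing one structure are aggregated.
#'
#' @param blocks A tibble with columns `smiles` and `id` (as from
#'   [read_molecule_file()]), or a path to a SMILES + ID file.
#' @return A `bb_index` object (environment-backed hash of key -> ids).
#' @export
building_block_index <- function(blocks) {
  if (is.character(blocks) && length(blocks) == 1) blocks <- read_molecule_file(blocks)
  idx <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(blocks))) {
    key <- tryCatch(strip_salt_key(blocks$smiles[k]), error = function(e) NA_character_)
    if (is.na(key)) next
    idx[[key]] <- c(idx[[key]], blocks$id[k])
  }
  structure(list(index = idx, n = nrow(blocks)), class = "bb_index")
}

strip_salt_key <- function(smiles) {
  mol <- parse_smiles(smiles)
  frags <- side_fragments(mol)
  if (length(frags) > 1) {
    sizes <- vapply(frags, n_atoms, integer(1))
    keys <- vapply(frags, canonical_smiles, character(1))
    frags <- frags[order(-sizes, keys)]
  }
  canonical_smiles(frags[[1]])
}

#' @export
print.bb_index <- function(x, ...) {
  cat("<bb_index> ", length(ls(x$index)), " distinct structures from ",
      x$n, " entries\n", sep = "")
  invisible(x)
}

#' Look up synthons in a building-block collection
#'
#' Exact canonical-structure match; an absent key simply means unavailable.
#'
#' @param synthons Character vector of SMILES (or list of molecules).
#' @param bb A [building_block_index()].
#' @return A tibble with columns `synthon` (canonical SMILES), `available`,
#'   and `bb_ids` (list column of matching collection ids).
#' @export
lookup_building_blocks <- function(synthons, bb) {
  if (is.list(synthons)) synthons <- vapply(synthons, canonical_smiles, character(1))
  keys <- unname(vapply(synthons, canonical_smiles, character(1)))
  ids <- lapply(keys, function(k) bb$index[[k]] %||% character())
  tibble::tibble(synthon = keys,
                 available = unname(lengths(ids) > 0),
                 bb_ids = ids)
}

#' Compile every template of a repository into queries
#'
#' @param repo An `rrt_repository`.
#' @return A list of `rrt_query` objects, one per retained cluster, each
#'   annotated with the cluster's signature and support.
#' @export
compile_repository <- function(repo) {
  cl <- repo$clusters
  lapply(seq_len(nrow(cl)), function(i) {
    tmpl <- parse_reaction_line(paste(cl$template[i], cl$template_provenance[i]),
                                dialect = "plus")
    tmpl$provenance <- cl$template_provenance[i]
    q <- compile_query(tmpl, radius = repo$radius, spec = repo$spec)
    q$signature <- cl$signature[i]
    q$support <- cl$support[i]
    q
  })
}

#' Design retrosynthetic routes for target molecules
#'
#' Each repository template is matched against each target; successful
#' embeddings are applied to deconstruct the target into synthons (failures
#' to match are simply discarded). Routes are deduplicated by (template
#' signature, canonical synthon multiset), optionally annotated with
#' building-block availability, and — when `max_depth > 1` — unavailable
#' synthons are recursively treated as new hypothesis structures. Routes
#' are ordered by depth, then descending support, then signature, and
#' truncated to `max_routes` per target.
#'
#' @param targets A tibble with columns `smiles` and `id` (or a character
#'   vector of SMILES, or a path to a SMILES + ID file).
#' @param repo An `rrt_repository` (or path to a saved one).
#' @param bb Optional [building_block_index()]; availability flags are only
#'   set when it is supplied.
#' @param max_depth Maximum recursion depth (default 1: single-step routes).
#' @param max_routes Per-target cap on reported routes.
#' @return A tibble with one row per disconnection: `target_id`, `depth`,
#'   `parent` (the synthon expanded by a recursive step, `NA` at depth 1),
#'   `target` (canonical SMILES of the structure deconstructed at this
#'   step), `signature`, `support`, `provenance`, `synthons`
#'   (`+`-joined canonical SMILES), `synthon_list`, `available` and
#'   `bb_ids` (list columns; `available` is `NA` without a lookup
#'   collection). Unparseable targets are collected in the `errors`
#'   attribute and do not stop the batch.
#' @export
design_routes <- function(targets, repo, bb = NULL, max_depth = 1,
                          max_routes = 100) {
  stopifnot(max_depth >= 1)
  if (is.character(repo) && length(repo) == 1) repo <- load_repository(repo)
  if (is.character(targets)) {
    targets <- if (length(targets) == 1 && file.exists(targets)) {
      read_molecule_file(targets)
    } else {
      tibble::tibble(smiles = targets,
                     id = paste0("target", seq_along(targets)))
    }
  }
  queries <- compile_repository(repo)
  errors <- tibble::tibble(target_id = character(), error = character())
  rows <- list()

  one_level <- function(mol, labels) {
    out <- list()
    for (q in queries) {
      embs <- match_query(q, mol, labels)
      seen <- character()
      for (e in embs) {
        syn <- apply_template(mol, q, e)
        if (is.null(syn)) next
        key <- synthon_key(syn)
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1]] <- list(query = q, synthons = syn, key = key)
      }
    }
    out
  }

  descend <- function(target_id, mol, depth, parent) {
    labels <- assign_atom_types(mol, repo$spec)
    for (hit in one_level(mol, labels)) {
      syn_smiles <- sort(vapply(hit$synthons, canonical_smiles, character(1)))
      avail <- if (!is.null(bb)) lookup_building_blocks(syn_smiles, bb) else NULL
      rows[[length(rows) + 1]] <<- tibble::tibble(
        target_id = target_id, depth = depth, parent = parent,
        target = canonical_smiles(mol),
        signature = hit$query$signature %||% NA_character_,
        support = hit$query$support %||% NA_integer_,
        provenance = hit$query$provenance,
        synthons = hit$key,
        synthon_list = list(syn_smiles),
        available = list(if (is.null(avail)) rep(NA, length(syn_smiles)) else avail$available),
        bb_ids = list(if (is.null(avail)) vector("list", length(syn_smiles)) else avail$bb_ids)
      )
      if (depth < max_depth) {
        unav <- if (is.null(avail)) rep(TRUE, length(syn_smiles)) else !avail$available
        for (s in syn_smiles[unav]) {
          descend(target_id, parse_smiles(s), depth + 1, s)
        }
      }
    }
  }

  for (k in seq_len(nrow(targets))) {
    mol <- tryCatch(parse_smiles(targets$smiles[k]), error = function(e) e)
    if (inherits(mol, "error")) {
      errors <- dplyr::bind_rows(errors, tibble::tibble(
        target_id = targets$id[k], error = conditionMessage(mol)))
      next
    }
    n0 <- length(rows)
    descend(targets$id[k], mol, 1L, NA_character_)
    if (length(rows) > n0) {
      tgt_rows <- dplyr::bind_rows(rows[(n0 + 1):length(rows)]) |>
        dplyr::arrange(.data$depth, dplyr::desc(.data$support), .data$signature) |>
        utils::head(max_routes)
      rows <- c(rows[seq_len(n0)], list(tgt_rows))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    target_id = character(), depth = integer(), parent = character(),
    target = character(), signature = character(), support = integer(),
    provenance = character(), synthons = character(), synthon_list = list(),
    available = list(), bb_ids = list())
  attr(out, "errors") <- errors
  out
}
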