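#' Cluster reactions by signature identity
#'
#' Exact partition of reactions by signature text at one radius; string
#' equality is the grouping operation.
#'
#' @param signatures A tibble with columns `reaction_id`, `radius`,
#'   `signature` (as from [sign_reactions()]).
#' @param radius The radius to cluster at.
#' @return A tibble with one row per cluster: `signature`, `support`,
#'   `members` (list column of reaction ids), sorted by descending support
#'   then signature text.
#' @export
cluster_by_signature <- function(signatures, radius) {
  sub <- dplyr::filter(signatures, .data$radius == !!radius)
  if (nrow(sub) == 0) {
    return(tibble::tibble(signature = character(), support = integer(),
                          members = list()))
  }
  sub |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(support = dplyr::n(),
                     members = list(sort(.data$reaction_id)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$support), .data$signature)
}

#' Filter clusters by minimum support
#'
#' @param clusters A cluster tibble from [cluster_by_signature()].
#' @param min_support Keep clusters with at least this many members.
#' @return The filtered tibble, sorted by descending support then signature.
#' @export
filter_by_support <- function(clusters, min_support = 1) {
  stopifnot(min_support >= 1)
  clusters |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::arrange(dplyr::desc(.data$support), .data$signature)
}

#' Select the representative template of a cluster
#'
#' The member with the fewest total heavy atoms; ties broken by
#' lexicographically smallest reaction id. Which member is chosen does not
#' affect the transformation rule (all members share the signature); small
#' templates are preferred for clarity.
#'
#' @param members A list of `mapped_reaction` objects (one cluster).
#' @return The selected `mapped_reaction`.
#' @export
select_template <- function(members) {
  stopifnot(length(members) >= 1)
  sizes <- vapply(members, total_atom_count, numeric(1))
  ids <- vapply(members, `[[`, character(1), "reaction_id")
  members[[order(sizes, ids)[1]]]
}

#' Cumulative coverage curve of a cluster set
#'
#' With clusters sorted by descending support, point k gives the fraction of
#' all member reactions covered by the k most-supported signatures. The
#' curve is non-decreasing and ends at 1.
#'
#' @param clusters A cluster tibble (any order; re-sorted internally).
#' @return A tibble with columns `n_signatures` and `fraction_covered`,
#'   of class `coverage_curve`.
#' @export
coverage_curve <- function(clusters) {
  cl <- dplyr::arrange(clusters, dplyr::desc(.data$support), .data$signature)
  out <- tibble::tibble(
    n_signatures = seq_len(nrow(cl)),
    fraction_covered = cumsum(cl$support) / sum(cl$support)
  )
  class(out) <- c("coverage_curve", class(out))
  out
}

#' Plot a coverage curve
#'
#' @param object A `coverage_curve` (or a list of them, named by series).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_signatures,
                                       y = .data$fraction_covered)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Number of reaction signatures",
                  y = "Fraction of reaction examples covered") +
    ggplot2::ylim(0, 1)
}

#' Train a reverse-reaction-template repository
#'
#' Runs the full training pipeline: standardize the forward reactions,
#' reverse them, re-standardize (with the forward-only rejections disabled,
#' since the reversed "product" side is the original multi-fragment
#' reactant side), compute signatures at the requested radius, cluster by
#' signature identity, filter by support, and select one representative
#' template per cluster. Deterministic: shuffled input order yields a
#' byte-identical repository.
#'
#' @param reactions A list of `mapped_reaction` objects (forward,
#'   atom-mapped), or a path to a reaction SMILES file.
#' @param radius Signature radius for clustering.
#' @param min_support Minimum cluster support to retain.
#' @param spec The [atom_type_spec()] used throughout.
#' @param cfg Standardizer configuration for the forward pass.
#' @return An `rrt_repository`: list with `spec`, `radius`, `min_support`,
#'   `clusters` (tibble: signature, support, template, template_provenance,
#'   members), and `counts` (pipeline stage accounting).
#' @export
build_repository <- function(reactions, radius = 0, min_support = 1,
                             spec = atom_type_spec(),
                             cfg = standardizer_config(spec = spec)) {
  if (is.character(reactions)) reactions <- read_reaction_file(reactions)
  n_input <- length(reactions)

  pass1 <- standardize_reactions(reactions, cfg)
  reversed <- lapply(pass1$accepted, reverse_reaction)

  cfg2 <- cfg
  cfg2$reject_multi_fragment_product <- FALSE
  cfg2$reject_no_change <- FALSE
  cfg2$max_product_heavy_atoms <- Inf
  pass2 <- standardize_reactions(reversed, cfg2)
  rxns <- pass2$accepted

  sigs <- sign_reactions(rxns, spec, radius_max = radius)
  clusters <- cluster_by_signature(sigs, radius)
  retained <- filter_by_support(clusters, min_support)

  by_id <- stats::setNames(rxns, vapply(rxns, `[[`, character(1), "reaction_id"))
  templ <- lapply(retained$members, function(ids) select_template(by_id[ids]))
  retained$template <- vapply(templ, function(t)
    write_reaction_line(t, dialect = "plus")$smiles, character(1))
  retained$template_provenance <- vapply(templ, `[[`, character(1), "provenance")

  counts <- tibble::tibble(
    input = n_input,
    rejected_forward = pass1$report$rejected,
    rejected_reversed = pass2$report$rejected,
    signed = length(rxns),
    clusters = nrow(clusters),
    retained_clusters = nrow(retained)
  )
  structure(list(spec = spec, radius = as.integer(radius),
                 min_support = as.integer(min_support),
                 clusters = retained, counts = counts,
                 reject_report = pass1$report),
            class = "rrt_repository")
}

#' @export
print.rrt_repository <- function(x, ...) {
  cat("<rrt_repository> radius ", x$radius, ", atom types ",
      format(x$spec), ", min support ", x$min_support, "\n", sep = "")
  cat("  ", nrow(x$clusters), " template(s) from ", x$counts$signed,
      " signed reactions (", x$counts$input, " input)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a template repository into its cluster table
#'
#' @param x An `rrt_repository`.
#' @param ... Unused.
#' @return A tibble: one row per retained cluster with signature, support,
#'   template reaction SMILES (plus dialect), provenance and member ids.
#' @export
tidy.rrt_repository <- function(x, ...) {
  dplyr::mutate(x$clusters, radius = x$radius, .before = 1)
}

#' One-row summary of a template repository
#'
#' @param x An `rrt_repository`.
#' @param ... Unused.
#' @return A one-row tibble of the pipeline stage counts.
#' @export
glance.rrt_repository <- function(x, ...) {
  dplyr::mutate(x$counts, radius = x$radius, min_support = x$min_support,
                atom_types = format(x$spec))
}

#' Save a template repository to a TSV file with a JSON header
#'
#' Line-oriented, diff-able format: `#%` header lines carry a JSON block
#' with the atom-type spec, radius, support threshold and stage counts,
#' followed by one TSV row per cluster.
#'
#' @param repo An `rrt_repository`.
#' @param path Output file path.
#' @param members Write the member-id list column (can be disabled for
#'   large corpora).
#' @return `path`, invisibly.
#' @export
save_repository <- function(repo, path, members = TRUE) {
  hdr <- jsonlite::toJSON(list(
    format = "rrt_repository",
    atom_types = format(repo$spec),
    radius = repo$radius,
    min_support = repo$min_support,
    counts = as.list(repo$counts)
  ), auto_unbox = TRUE)
  cl <- repo$clusters
  rows <- vapply(seq_len(nrow(cl)), function(i) {
    paste(cl$signature[i], cl$support[i], cl$template[i],
          cl$template_provenance[i],
          if (members) paste(cl$members[[i]], collapse = ",") else "",
          sep = "\t")
  }, character(1))
  writeLines(c(paste0("#% ", hdr),
               "#signature\tsupport\ttemplate\tprovenance\tmembers",
               rows), path)
  invisible(path)
}

#' Load a template repository saved by [save_repository()]
#'
#' @param path File path.
#' @return An `rrt_repository`.
#' @export
load_repository <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_line <- grep("^#% ", lines, value = TRUE)[1]
  if (is.na(hdr_line)) stop("not a repository file (missing '#%' header): ", path,
                            call. = FALSE)
  hdr <- jsonlite::fromJSON(sub("^#% ", "", hdr_line))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) > 0) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    clusters <- tibble::tibble(
      signature = vapply(parts, `[[`, character(1), 1),
      support = as.integer(vapply(parts, `[[`, character(1), 2)),
      members = lapply(parts, function(p)
        if (length(p) >= 5 && nzchar(p[[5]])) strsplit(p[[5]], ",")[[1]] else character()),
      template = vapply(parts, `[[`, character(1), 3),
      template_provenance = vapply(parts, `[[`, character(1), 4)
    )
  } else {
    clusters <- tibble::tibble(signature = character(), support = integer(),
                               members = list(), template = character(),
                               template_provenance = character())
  }
  counts <- tibble::as_tibble(lapply(hdr$counts, as.integer))
  structure(list(spec = atom_type_spec(hdr$atom_types),
                 radius = as.integer(hdr$radius),
                 min_support = as.integer(hdr$min_support), clusters = clusters,
                 counts = counts, reject_report = NULL),
            class = "rrt_repository")
}
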