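# Shared fixture objects, built once per test run and memoised. The small
# corpus (6 x 20) backs the unit tests; the full study corpus (6 x 100) is
# built only by the acceptance tests.
.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- force(expr)
  .fx_cache[[key]]
}

small_corpus <- function() fx_memo("small_corpus",
  generate_corpus(per_family = 20, seed = 7, n_chained = 5))

small_rxns <- function() fx_memo("small_rxns",
  lapply(small_corpus()$lines, parse_reaction_line))

small_repo <- function(radius = 0) fx_memo(paste0("small_repo_", radius),
  build_repository(small_rxns(), radius = radius, min_support = 1))

study_corpus <- function() fx_memo("study_corpus",
  generate_corpus(per_family = 100, seed = 1, n_chained = 10))

study_rxns <- function() fx_memo("study_rxns",
  lapply(study_corpus()$lines, parse_reaction_line))

study_repo <- function(radius = 0, min_support = 10)
  fx_memo(paste0("study_repo_", radius, "_", min_support),
          build_repository(study_rxns(), radius = radius, min_support = min_support))

# signature table at radii 0..2 for the standardized + reversed reactions
signed_table <- function(rxns_key = "small") {
  fx_memo(paste0("signed_", rxns_key), {
    rxns <- if (rxns_key == "small") small_rxns() else study_rxns()
    p1 <- standardize_reactions(rxns)
    rev <- lapply(p1$accepted, reverse_reaction)
    cfg2 <- standardizer_config(reject_multi_fragment_product = FALSE,
                                reject_no_change = FALSE,
                                max_product_heavy_atoms = Inf)
    p2 <- standardize_reactions(rev, cfg2)
    list(rxns = p2$accepted, sigs = sign_reactions(p2$accepted, radius_max = 2))
  })
}

# independent isomorphism oracle for signature equality: the two reactions'
# expanded-core subgraphs on both sides are isomorphic as labeled graphs
# (igraph VF2 with atom-type vertex colors and bond-order edge colors)
sig_isomorphic_oracle <- function(rxn1, rxn2, radius, spec = atom_type_spec()) {
  side_graph <- function(rxn, side) {
    mol <- rxn[[side]]
    core <- find_changing_atoms(rxn, spec)
    cset <- expand_core(mol, if (side == "reactants") core$left else core$right, radius)
    lab <- assign_atom_types(mol, spec)[cset]
    sub <- synthon:::keep_atoms(mol, cset)
    g <- igraph::make_empty_graph(n = length(cset), directed = FALSE)
    if (nrow(sub$bonds) > 0) g <- igraph::add_edges(g, rbind(sub$bonds$a1, sub$bonds$a2))
    list(g = g, lab = lab, orders = sub$bonds$order)
  }
  iso_side <- function(a, b) {
    if (length(a$lab) != length(b$lab)) return(FALSE)
    if (!identical(sort(a$lab), sort(b$lab))) return(FALSE)
    ca <- match(a$lab, sort(unique(c(a$lab, b$lab))))
    cb <- match(b$lab, sort(unique(c(a$lab, b$lab))))
    ea <- match(a$orders, c(1, 2, 3, 1.5))
    eb <- match(b$orders, c(1, 2, 3, 1.5))
    igraph::graph.isomorphic.vf2(a$g, b$g,
                                 vertex.color1 = ca, vertex.color2 = cb,
                                 edge.color1 = ea, edge.color2 = eb)$iso
  }
  iso_side(side_graph(rxn1, "reactants"), side_graph(rxn2, "reactants")) &&
    iso_side(side_graph(rxn1, "products"), side_graph(rxn2, "products"))
}
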