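## Ring perception and canonical atom ordering, built on igraph.

mol_igraph <- function(mol) {
  n <- n_atoms(mol)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  }
  g
}

## TRUE for each bond that lies in at least one cycle (i.e. is not a bridge).
ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(0))
  g <- mol_igraph(mol)
  br <- igraph::bridges(g)
  res <- rep(TRUE, nb)
  res[as.integer(br)] <- FALSE
  res
}

## Number of ring bonds incident to each atom.
ring_bond_count <- function(mol) {
  n <- n_atoms(mol)
  rb <- ring_bonds(mol)
  cnt <- integer(n)
  if (any(rb)) {
    b <- mol$bonds[rb, ]
    cnt <- tabulate(b$a1, n) + tabulate(b$a2, n)
  }
  cnt
}

## Size of the smallest ring through each atom (0 for acyclic atoms).
## The smallest cycle through an atom is min over its incident ring bonds
## (u,v) of d(u,v) in the graph without that bond, plus one.
smallest_ring_size <- function(mol) {
  n <- n_atoms(mol)
  out <- integer(n)
  rb <- ring_bonds(mol)
  if (!any(rb)) return(out)
  g <- mol_igraph(mol)
  ring_edge_ids <- which(rb)
  cyc <- rep(Inf, n)
  for (e in ring_edge_ids) {
    u <- mol$bonds$a1[e]; v <- mol$bonds$a2[e]
    g2 <- igraph::delete_edges(g, e)
    d <- igraph::distances(g2, v = u, to = v)[1, 1]
    if (is.finite(d)) {
      len <- d + 1
      if (len < cyc[u]) cyc[u] <- len
      if (len < cyc[v]) cyc[v] <- len
    }
  }
  ## atoms whose incident edges are all shared with larger rings still sit in
  ## the smallest cycle through them; the per-edge pass above covers both ends
  ## of every ring bond, which reaches every ring atom.
  out[is.finite(cyc)] <- as.integer(cyc[is.finite(cyc)])
  out
}

## Normalize aromaticity:
##  - demote "aromatic" bonds that are not in a ring to single bonds
##    (implicit bonds between aromatic atoms of different rings);
##  - perceive simple Kekule-written aromatic rings (benzene-like 6-rings
##    with alternating double bonds; 5-rings with two double bonds and one
##    lone-pair heteroatom) and flag their atoms/bonds aromatic.
## Fused polycyclic Kekule input is out of scope for perception and is
## documented as such; aromatic-form input passes through unchanged.
perceive_aromaticity <- function(mol) {
  if (nrow(mol$bonds) == 0) return(mol)
  rb <- ring_bonds(mol)
  demote <- mol$bonds$order == 1.5 & !rb
  mol$bonds$order[demote] <- 1

  ## candidate Kekule rings: cycles of non-aromatic ring bonds
  cand_edges <- which(rb & mol$bonds$order != 1.5)
  if (length(cand_edges) == 0) return(mol)
  g <- mol_igraph(mol)
  seen <- character()
  for (e in cand_edges) {
    u <- mol$bonds$a1[e]; v <- mol$bonds$a2[e]
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v)$vpath[[1]])
    if (length(sp) == 0) next
    ring <- as.integer(sp)
    if (length(ring) < 5 || length(ring) > 6) next
    key <- paste(sort(ring), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    mol <- try_aromatize_ring(mol, ring)
  }
  mol
}

try_aromatize_ring <- function(mol, ring) {
  k <- length(ring)
  eid <- integer(k)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    be <- bond_between(mol, ring[i], ring[j])
    if (length(be) != 1) return(mol)
    eid[i] <- be
  }
  ords <- mol$bonds$order[eid]
  if (any(ords == 1.5)) return(mol)
  dbl <- ords == 2
  deg <- heavy_degree(mol)
  if (k == 6) {
    ## benzene-like: three alternating double bonds, all atoms C or N
    ok <- sum(dbl) == 3 && all(dbl == rep(dbl[1:2], 3)) && dbl[1] != dbl[2] &&
      all(mol$atoms$symbol[ring] %in% c("C", "N"))
  } else {
    ## five-ring: two doubles; the one atom with no ring double bond must be
    ## a lone-pair heteroatom (N with an H or a third substituent, O, S)
    in_dbl <- logical(k)
    for (i in seq_len(k)) {
      j <- if (i == 1) k else i - 1L
      in_dbl[i] <- dbl[i] || dbl[j]
    }
    lp <- ring[!in_dbl]
    ok <- sum(dbl) == 2 && length(lp) == 1 &&
      (mol$atoms$symbol[lp] %in% c("O", "S") ||
         (mol$atoms$symbol[lp] == "N" && (mol$atoms$hcount[lp] > 0 || deg[lp] == 3)))
  }
  if (!ok) return(mol)
  ## no exocyclic double bonds allowed on ring atoms
  for (a in ring) {
    inc <- which(mol$bonds$a1 == a | mol$bonds$a2 == a)
    ext <- setdiff(inc, eid)
    if (any(mol$bonds$order[ext] > 1 & mol$bonds$order[ext] != 1.5)) return(mol)
  }
  mol$atoms$aromatic[ring] <- TRUE
  mol$bonds$order[eid] <- 1.5
  ## carbons pick up the aromatic H convention; lone-pair heteroatoms keep
  ## their stored hydrogen count (pyrrole-type NH)
  recompute_hcount(mol, ring[mol$atoms$symbol[ring] == "C"])
}

## Canonical atom order via BLISS canonical labeling on a vertex-colored
## graph. Bond orders are encoded by subdividing each bond with a dummy
## vertex colored by the order, so the canonical form respects them.
## `color_key` is any character vector (one entry per atom); equal keys =
## exchangeable atoms. Returns an integer rank per atom (1 = start atom).
canonical_ranks <- function(mol, color_key) {
  n <- n_atoms(mol)
  if (n == 1) return(1L)
  nb <- nrow(mol$bonds)
  acol <- match(color_key, sort(unique(color_key)))
  ncol <- max(acol)
  bcode <- match(mol$bonds$order, c(1, 2, 3, 1.5))
  edges <- integer(0)
  if (nb > 0) {
    mid <- n + seq_len(nb)
    edges <- as.vector(rbind(mol$bonds$a1, mid, mid, mol$bonds$a2))
  }
  g <- igraph::make_empty_graph(n = n + nb, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  colors <- c(acol, if (nb > 0) ncol + bcode else integer(0))
  lab <- igraph::canonical_permutation(g, colors = colors)$labeling
  rank(lab[seq_len(n)])
}

## Default canonicalization key: everything structural except map numbers.
default_color_key <- function(mol) {
  paste(mol$atoms$symbol, mol$atoms$charge, mol$atoms$aromatic, mol$atoms$hcount)
}
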