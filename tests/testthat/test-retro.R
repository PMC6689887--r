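test_that("every compiled query matches its own template's retro input", {
  repo <- small_repo(0)
  for (q in compile_repository(repo)) {
    embs <- match_query(q, q$left)
    expect_gte(length(embs), 1)
  }
})

test_that("an amide query matches acetanilide but not ethyl acetate", {
  repo <- small_repo(0)
  queries <- compile_repository(repo)
  is_sb <- vapply(queries, function(q) grepl("Cl", q$signature), logical(1))
  q <- queries[[which(is_sb)[1]]]
  expect_gte(length(match_query(q, parse_smiles("CC(=O)Nc1ccccc1"))), 1)
  expect_length(match_query(q, parse_smiles("CCOC(C)=O")), 0)
})

test_that("the Schotten-Baumann template splits acetanilide into acid chloride and aniline", {
  repo <- small_repo(0)
  queries <- compile_repository(repo)
  q <- queries[[which(vapply(queries, function(q) grepl("Cl", q$signature),
                             logical(1)))[1]]]
  target <- parse_smiles("CC(=O)Nc1ccccc1")
  embs <- match_query(q, target)
  expect_identical(length(embs), 1L)
  syn <- apply_template(target, q, embs[[1]])
  got <- sort(vapply(syn, canonical_smiles, character(1)))
  expect_identical(got, sort(c(canonical_smiles("CC(=O)Cl"),
                               canonical_smiles("Nc1ccccc1"))))
})

test_that("template application round-trips every cluster member", {
  repo <- small_repo(0)
  man <- small_corpus()$manifest
  queries <- compile_repository(repo)
  for (i in seq_len(nrow(man))) {
    mol <- parse_smiles(man$product[i])
    truth <- paste(man$synthons[[i]], collapse = "+")
    keys <- character()
    for (q in queries) {
      for (e in match_query(q, mol)) {
        syn <- apply_template(mol, q, e)
        if (!is.null(syn)) keys <- c(keys, synthon:::synthon_key(syn))
      }
    }
    expect_true(truth %in% keys, label = paste("round trip", man$reaction_id[i]))
  }
})

test_that("symmetry-equivalent embeddings deduplicate; distinct ones persist", {
  repo <- small_repo(0)
  # two equivalent amide bonds -> one synthon multiset after deduplication
  sym <- design_routes("CC(=O)Nc1ccc(NC(C)=O)cc1", repo)
  sb <- sym[grepl("Cl", sym$signature), ]
  expect_identical(nrow(sb), 1L)
  # two inequivalent amide bonds -> two distinct disconnections
  asym <- design_routes("CC(=O)Nc1ccc(NC(=O)CC)cc1", repo)
  sb2 <- asym[grepl("Cl", asym$signature), ]
  expect_identical(nrow(sb2), 2L)
  expect_identical(length(unique(sb2$synthons)), 2L)
})

test_that("raising the radius never widens the matched molecule set", {
  repo2 <- small_repo(2)
  man <- small_corpus()$manifest
  mols <- lapply(man$product[seq(1, nrow(man), by = 4)], parse_smiles)
  for (cl_i in seq_len(min(6, nrow(repo2$clusters)))) {
    tmpl <- parse_reaction_line(paste(repo2$clusters$template[cl_i], "t"),
                                dialect = "plus")
    q0 <- compile_query(tmpl, radius = 0, spec = repo2$spec)
    q2 <- compile_query(tmpl, radius = 2, spec = repo2$spec)
    m0 <- vapply(mols, function(m) length(match_query(q0, m)) > 0, logical(1))
    m2 <- vapply(mols, function(m) length(match_query(q2, m)) > 0, logical(1))
    expect_true(all(which(m2) %in% which(m0)))
  }
})

test_that("building-block lookup is exact, salt-stripped and silent on misses", {
  bb <- building_block_index(tibble::tibble(
    smiles = c("CC(=O)Cl", "Nc1ccccc1.Cl", "CCO"),
    id = c("BB1", "BB2", "BB3")))
  hit <- lookup_building_blocks(c("CC(=O)Cl", "Nc1ccccc1", "CCCCCC"), bb)
  expect_identical(hit$available, c(TRUE, TRUE, FALSE))
  expect_identical(hit$bb_ids[[1]], "BB1")
  expect_identical(hit$bb_ids[[2]], "BB2")   # found despite the HCl salt
  expect_identical(hit$bb_ids[[3]], character(0))
  # empty collection: everything unavailable
  empty <- building_block_index(tibble::tibble(smiles = character(), id = character()))
  expect_false(any(lookup_building_blocks("CC(=O)Cl", empty)$available))
})

test_that("an empty repository yields an empty route list", {
  repo <- build_repository(utils::head(small_rxns(), 10), radius = 0,
                           min_support = 99)
  routes <- design_routes("CC(=O)Nc1ccccc1", repo)
  expect_identical(nrow(routes), 0L)
})

test_that("unparseable targets become error records without stopping the batch", {
  repo <- small_repo(0)
  routes <- design_routes(tibble::tibble(smiles = c("C(C", "CC(=O)Nc1ccccc1"),
                                         id = c("badtarget", "goodtarget")),
                          repo)
  errs <- attr(routes, "errors")
  expect_identical(errs$target_id, "badtarget")
  expect_true(all(routes$target_id == "goodtarget"))
  expect_gte(nrow(routes), 1)
})

test_that("route lists are deterministic and ordered by depth, support, signature", {
  repo <- small_repo(0)
  man <- small_corpus()$manifest
  bb <- building_block_index(generate_building_blocks(man, fraction = 0, seed = 2))
  tg <- tibble::tibble(smiles = man$product[c(30, 61)], id = c("t1", "t2"))
  r1 <- design_routes(tg, repo, bb = bb, max_depth = 2)
  r2 <- design_routes(tg, repo, bb = bb, max_depth = 2)
  expect_identical(r1$synthons, r2$synthons)
  for (id in unique(r1$target_id)) {
    sub <- r1[r1$target_id == id, ]
    expect_true(!is.unsorted(sub$depth))
    for (d in unique(sub$depth)) {
      dd <- sub[sub$depth == d, ]
      expect_true(!is.unsorted(-dd$support))
    }
  }
})

test_that("chained pairs resolve into two-step routes with correct depths", {
  man <- small_corpus()$manifest
  repo <- small_repo(0)
  ch <- man[!is.na(man$chained_child), ]
  expect_gte(nrow(ch), 1)
  bb <- building_block_index(generate_building_blocks(man, fraction = 0, seed = 3))
  routes <- design_routes(tibble::tibble(smiles = ch$product[1], id = "chain"),
                          repo, bb = bb, max_depth = 2)
  expect_setequal(unique(routes$depth), c(1L, 2L))
  # the depth-2 step deconstructs the aniline synthon back to a nitroarene
  child <- man[man$reaction_id == ch$chained_child[1], ]
  aniline <- child$product
  d2 <- routes[routes$depth == 2 & routes$parent == aniline, ]
  expect_gte(nrow(d2), 1)
  expect_true(child$synthons[[1]] %in% unlist(d2$synthon_list))
})

test_that("design coverage never grows with support threshold or radius", {
  man <- small_corpus()$manifest
  targets <- tibble::tibble(smiles = c(man$product[seq(1, 120, by = 6)],
                                       imatinib_target()),
                            id = paste0("t", 1:21))
  covered <- function(repo) {
    r <- design_routes(targets, repo)
    length(unique(r$target_id))
  }
  repo0 <- small_repo(0)
  # raising the support threshold can only drop templates
  repo_hi <- repo0
  repo_hi$clusters <- filter_by_support(repo0$clusters, 21)
  c_lo <- covered(repo0)
  c_hi <- covered(repo_hi)
  expect_lte(c_hi, c_lo)
  expect_identical(c_hi, 0L)     # all six supports are 20
  # raising the radius can only narrow queries
  c_r2 <- covered(small_repo(2))
  expect_lte(c_r2, c_lo)
  expect_gt(c_lo, 0L)
})

test_that("every route carries provenance resolving to a corpus reaction", {
  repo <- small_repo(0)
  man <- small_corpus()$manifest
  routes <- design_routes(man$product[5], repo)
  expect_gte(nrow(routes), 1)
  expect_true(all(routes$provenance %in% man$reaction_id))
})
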