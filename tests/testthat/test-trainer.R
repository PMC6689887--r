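test_that("clustering partitions the corpus into its six known families", {
  st <- signed_table("small")
  cl0 <- cluster_by_signature(st$sigs, radius = 0)
  expect_identical(nrow(cl0), 6L)
  expect_identical(sort(cl0$support), rep(20L, 6))
  expect_identical(sum(cl0$support), length(st$rxns))
  # single reaction input
  one <- cluster_by_signature(st$sigs[st$sigs$reaction_id == st$sigs$reaction_id[1], ], 0)
  expect_identical(nrow(one), 1L)
  expect_identical(one$support, 1L)
  # radius 2 gives at least as many clusters
  cl2 <- cluster_by_signature(st$sigs, radius = 2)
  expect_gte(nrow(cl2), nrow(cl0))
  expect_identical(sum(cl2$support), length(st$rxns))
})

test_that("support filtering is nested across thresholds", {
  st <- signed_table("small")
  cl <- cluster_by_signature(st$sigs, radius = 2)
  expect_identical(filter_by_support(cl, 1)$signature, cl$signature)
  expect_identical(nrow(filter_by_support(cl, 1000)), 0L)
  prev <- NULL
  for (ms in c(1, 2, 5, 10)) {
    cur <- filter_by_support(cl, ms)$signature
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("template selection prefers the smallest member, ties by id", {
  mk <- function(line) parse_reaction_line(line)
  small <- mk("[CH3:1][OH:2]>>[CH3:1][Cl:2] rxB")
  big <- mk("[CH3:1][C:3]([CH3:4])([CH3:5])[OH:2]>>[CH3:1][C:3]([CH3:4])([CH3:5])[Cl:2] rxC")
  expect_identical(select_template(list(big, small))$reaction_id, "rxB")
  tieA <- mk("[CH3:1][OH:2]>>[CH3:1][Cl:2] rxA")
  expect_identical(select_template(list(small, tieA))$reaction_id, "rxA")
  expect_identical(select_template(list(big))$reaction_id, "rxC")
})

test_that("coverage curves are correct, monotone and radius-ordered", {
  cl <- tibble::tibble(signature = c("a", "b", "c"), support = c(50L, 30L, 20L))
  cv <- coverage_curve(cl)
  expect_equal(cv$fraction_covered, c(0.5, 0.8, 1.0))
  # equal supports give a straight line
  cve <- coverage_curve(tibble::tibble(signature = letters[1:4], support = rep(5L, 4)))
  expect_equal(cve$fraction_covered, (1:4) / 4)
  # on the fixture corpus the radius-0 curve dominates the radius-2 curve
  st <- signed_table("small")
  cv0 <- coverage_curve(cluster_by_signature(st$sigs, 0))
  cv2 <- coverage_curve(cluster_by_signature(st$sigs, 2))
  shared <- seq_len(min(nrow(cv0), nrow(cv2)))
  expect_true(all(cv0$fraction_covered[shared] >= cv2$fraction_covered[shared] - 1e-12))
  expect_true(all(diff(cv0$fraction_covered) >= 0))
  expect_equal(cv0$fraction_covered[nrow(cv0)], 1.0)
  p <- autoplot(cv0)
  expect_s3_class(p, "ggplot")
})

test_that("repository training conserves stage counts and is deterministic", {
  repo <- small_repo(0)
  g <- glance(repo)
  expect_identical(g$input, 120L)
  expect_identical(g$input - g$rejected_forward - g$rejected_reversed, g$signed)
  expect_identical(g$clusters, 6L)
  expect_identical(g$retained_clusters, 6L)
  # shuffled input order yields a byte-identical repository file
  set.seed(5)
  shuffled <- sample(small_rxns())
  repo2 <- build_repository(shuffled, radius = 0, min_support = 1)
  f1 <- tempfile(); f2 <- tempfile()
  save_repository(repo, f1)
  save_repository(repo2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a min_support above every family size gives a valid empty repository", {
  repo <- build_repository(utils::head(small_rxns(), 30), radius = 0,
                           min_support = 1000)
  expect_identical(nrow(tidy(repo)), 0L)
  f <- tempfile()
  save_repository(repo, f)
  expect_identical(nrow(tidy(load_repository(f))), 0L)
})

test_that("repository serialization round-trips losslessly", {
  repo <- small_repo(0)
  f <- tempfile()
  save_repository(repo, f)
  back <- load_repository(f)
  expect_identical(back$radius, repo$radius)
  expect_identical(format(back$spec), format(repo$spec))
  expect_identical(back$clusters$signature, repo$clusters$signature)
  expect_identical(back$clusters$support, repo$clusters$support)
  expect_identical(back$clusters$template, repo$clusters$template)
  expect_identical(back$clusters$members, repo$clusters$members)
  # and the loaded repository designs identical routes
  r1 <- design_routes(imatinib_target(), repo)
  r2 <- design_routes(imatinib_target(), back)
  expect_identical(r1$synthons, r2$synthons)
})
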