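test_that("mpd and mntd match hand-enumerated values", {
  dm <- pairwise_distances(tree4())
  expect_equal(mpd(c("A", "B"), dm), 2)
  expect_equal(mpd(c("A", "B", "C", "D"), dm), 10 / 3)  # (2+4+4+4+4+2)/6
  expect_equal(mntd(c("A", "B", "C", "D"), dm), 2)      # nearest neighbour each
  expect_equal(mntd(c("A", "C"), dm), 4)
  expect_equal(mpd(c("A", "C"), dm), mntd(c("A", "C"), dm))  # pairs coincide
  expect_error(mpd("A", dm), "at least 2")
  expect_error(mntd(c("A", "Z"), dm), "not in distance matrix")

  # star tree: all pairwise distances equal c
  star <- parse_newick("(A:3,B:3,C:3,D:3);")
  dstar <- pairwise_distances(star)
  expect_equal(mpd(c("A", "B", "C"), dstar), 6)
  expect_equal(mntd(c("A", "B", "C"), dstar), 6)
})

test_that("metrics are order-invariant and mntd <= mpd", {
  set.seed(5)
  tr <- simulate_bd_tree(20, seed = 5)
  dm <- pairwise_distances(tr)
  for (i in 1:25) {
    comm <- sample(rownames(dm), sample(3:10, 1))
    expect_equal(mpd(comm, dm), mpd(rev(comm), dm))
    expect_equal(mntd(comm, dm), mntd(sample(comm), dm))
    expect_lte(mntd(comm, dm), mpd(comm, dm))
  }
})

test_that("observed metrics agree with picante", {
  tr <- simulate_bd_tree(24, seed = 9)
  dm <- pairwise_distances(tr)
  set.seed(1)
  comms <- lapply(1:8, function(i) sample(rownames(dm), sample(3:12, 1)))
  samp <- t(vapply(comms, function(s) as.integer(rownames(dm) %in% s),
                   integer(nrow(dm))))
  colnames(samp) <- rownames(dm)
  expect_equal(vapply(comms, mpd, numeric(1), dm = dm),
               unname(picante::mpd(samp, dm)), tolerance = 1e-12)
  expect_equal(vapply(comms, mntd, numeric(1), dm = dm),
               unname(picante::mntd(samp, dm)), tolerance = 1e-12)
})

test_that("exhaustive nulls enumerate every subset once", {
  dm <- pairwise_distances(tree4())
  null <- null_distribution(2, rownames(dm), dm, "mpd", mode = "exhaustive")
  expect_equal(sort(null), c(2, 2, 4, 4, 4, 4))  # all 6 richness-2 subsets
  expect_error(null_distribution(5, rownames(dm), dm, "mpd"), "exceeds pool")
  expect_error(
    null_distribution(3, rownames(dm), dm, "mpd", mode = "exhaustive",
                      exhaustive_threshold = 2),
    "infeasible"
  )
})

test_that("sampled nulls are reproducible and degenerate at full richness", {
  tr <- simulate_bd_tree(10, seed = 3)
  dm <- pairwise_distances(tr)
  a <- null_distribution(4, rownames(dm), dm, "mntd", n_rand = 50, seed = 7)
  b <- null_distribution(4, rownames(dm), dm, "mntd", n_rand = 50, seed = 7)
  expect_identical(a, b)
  # richness = pool size: all draws identical
  full <- null_distribution(10, rownames(dm), dm, "mpd", n_rand = 20, seed = 1)
  expect_equal(stats::sd(full), 0)
})

test_that("sampled null moments converge to the exhaustive values", {
  tr <- simulate_bd_tree(12, seed = 13)
  dm <- pairwise_distances(tr)
  pool <- rownames(dm)
  for (metric in c("mpd", "mntd")) {
    exact <- null_distribution(4, pool, dm, metric, mode = "exhaustive")
    sampled <- null_distribution(4, pool, dm, metric, n_rand = 999, seed = 17)
    mc_se <- stats::sd(exact) / sqrt(999)
    expect_lt(abs(mean(sampled) - mean(exact)), 3 * mc_se)
  }
})

test_that("ses standardizes against the null and flags degeneracy", {
  null <- c(2, 2, 4, 4, 4, 4)
  s <- ses(2, null)
  expect_equal(s$null_mean, 10 / 3)
  expect_equal(s$null_sd, sqrt(16 / 15))
  expect_equal(round(s$ses, 4), -1.2910)
  expect_equal(ses(mean(null), null)$ses, 0)
  sdg <- ses(3, rep(5, 10))
  expect_true(sdg$degenerate)
  expect_true(is.na(sdg$ses))
  expect_error(ses(1, numeric(0)), "empty")
})

test_that("ses_table computes per-community SES with derived seeds", {
  t4 <- tree4()
  m <- data.frame(
    study_id = "s1",
    community_id = rep(c("sister", "spread"), each = 2),
    species = c("A", "B", "A", "C"),
    growth_form = "woody", stringsAsFactors = FALSE
  )
  ct <- make_community_table(m)
  # richness 2 communities need a relaxed read; exhaustive nulls on T4
  res <- ses_table(ct, t4, mode = "exhaustive")
  expect_equal(round(res$ses_mpd[res$community_id == "sister"], 4), -1.2910)
  expect_equal(round(res$ses_mpd[res$community_id == "spread"], 4), 0.6455)

  # whole pool community: degenerate null
  m2 <- data.frame(study_id = "s1", community_id = "all",
                   species = c("A", "B", "C", "D"), growth_form = "woody")
  res2 <- ses_table(make_community_table(m2), t4, mode = "exhaustive")
  expect_true(res2$degenerate)

  # reruns identical; community order irrelevant
  resA <- ses_table(ct, t4, n_rand = 99, seed = 5)
  resB <- ses_table(make_community_table(m[c(3, 4, 1, 2), ]), t4,
                    n_rand = 99, seed = 5)
  expect_equal(resA[order(resA$community_id), ],
               resB[order(resB$community_id), ],
               ignore_attr = TRUE)

  expect_error(ses_table(make_community_table(
    data.frame(study_id = "s1", community_id = "c", species = c("A", "B", "Z"),
               growth_form = "woody")), t4), "absent from tree: Z")
})

test_that("single-clade communities are clustered, cross-clade ones overdispersed", {
  tr <- parse_newick("(((a1:1,a2:1):1,(a3:1,a4:1):1):2,((b1:1,b2:1):1,(b3:1,b4:1):1):2);")
  dm <- pairwise_distances(tr)
  pool <- rownames(dm)
  clus <- ses(mpd(c("a1", "a2", "a3", "a4"), dm),
              null_distribution(4, pool, dm, "mpd", mode = "exhaustive"))
  spread <- ses(mpd(c("a1", "a3", "b1", "b3"), dm),
                null_distribution(4, pool, dm, "mpd", mode = "exhaustive"))
  expect_lt(clus$ses, 0)
  expect_gt(spread$ses, 0)
})
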