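# Correlation scores, hypergeometric overlap, fold enrichment, BH
# adjustment, candidate ranking, and over-representation analysis.

test_that("correlation score matches hand-computed centered cosine", {
  a <- setNames(c(1, 0, 0), c("n1", "n2", "n3"))
  b <- setNames(c(0, 1, 0), c("n1", "n2", "n3"))
  expect_equal(correlation_score(a, b), -0.5, tolerance = 1e-12)
  expect_equal(correlation_score(a, a), 1, tolerance = 1e-12)

  # symmetry, bounds and joint-permutation invariance on random vectors
  set.seed(1)
  for (i in 1:20) {
    x <- setNames(runif(10), paste0("n", 1:10))
    y <- setNames(runif(10), paste0("n", 1:10))
    s <- correlation_score(x, y)
    expect_equal(s, correlation_score(y, x), tolerance = 1e-12)
    expect_true(s >= -1 && s <= 1)
    perm <- sample(10)
    expect_equal(correlation_score(x[perm], y[perm]), s,
                 tolerance = 1e-12)
    # positive affine transform preserves a perfect score
    z <- setNames(2 * x + 3, names(x))
    expect_equal(correlation_score(x, z), 1, tolerance = 1e-12)
  }

  expect_error(correlation_score(setNames(rep(0.5, 2), c("a", "b")),
                                 setNames(c(0.3, 0.7), c("a", "b"))),
               "zero-variance")
  expect_error(correlation_score(a, b[c(2, 1, 3)]), "node index")
})

test_that("hypergeometric overlap matches hand-enumerated draws", {
  expect_equal(hypergeometric_overlap(5, 5, 5, 10), 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(2, 3, 3, 6), 0.5, tolerance = 1e-12)
  expect_identical(hypergeometric_overlap(0, 5, 5, 10), 1)
  expect_error(hypergeometric_overlap(6, 5, 5, 10), "impossible")
  expect_error(hypergeometric_overlap(1, 11, 5, 10), "M_total")
})

test_that("hypergeometric overlap matches exhaustive enumeration for all
           small configurations", {
  got <- numeric(0); want <- numeric(0)
  for (M in 2:25) {
    for (N in 1:M) {
      for (n in 1:M) {
        for (k in 0:min(n, N)) {
          got <- c(got, hypergeometric_overlap(k, n, N, M))
          want <- c(want, enum_hypergeom_upper(k, n, N, M))
        }
      }
    }
  }
  expect_gt(length(got), 1000L)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("fold enrichment follows (k/n) * rho and truncates for
           display", {
  expect_equal(fold_enrichment(5, 50, background_ratio = 113.8), 11.38,
               tolerance = 1e-12)
  expect_identical(fold_enrichment(0, 50, background_ratio = 113.8), 0)
  expect_equal(trunc_decimals(fold_enrichment(6, 50,
                                              background_ratio = 113.8),
                              2), 13.65)
  expect_equal(fold_enrichment(3, 10, N = 5, M_total = 100), 6)
  expect_error(fold_enrichment(1, 0, background_ratio = 1), "n must")
  expect_error(fold_enrichment(1, 10, background_ratio = 0), "ratio")
  expect_error(fold_enrichment(1, 10), "supply")
})

test_that("a single calibrated background ratio reproduces every printed
           enrichment cell", {
  rho <- 11.38 * 50 / 5  # calibrated from the reference row
  cells <- list(list(k = 5, n = 50, printed = 11.38, digits = 2),
                list(k = 2, n = 11, printed = 20.69, digits = 2),
                list(k = 6, n = 50, printed = 13.65, digits = 2),
                list(k = 4, n = 50, printed = 9.104, digits = 3),
                list(k = 4, n = 25, printed = 18.20, digits = 2),
                list(k = 6, n = 50, printed = 13.65, digits = 2),
                list(k = 3, n = 50, printed = 6.82, digits = 2),
                list(k = 7, n = 48, printed = 16.59, digits = 2),
                list(k = 8, n = 50, printed = 18.20, digits = 2),
                list(k = 8, n = 50, printed = 18.20, digits = 2))
  for (cell in cells) {
    got <- trunc_decimals(fold_enrichment(cell$k, cell$n,
                                          background_ratio = rho),
                          cell$digits)
    expect_equal(got, cell$printed, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand-rolled step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04),
               tolerance = 1e-12)
  expect_identical(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 4)), rep(0.05, 4))
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))
    expect_equal(bh_adjust(p), bh_by_hand(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("candidate ranking orders by score with id tie-break and is
           deterministic", {
  idx <- paste0("n", 1:6)
  dis <- structure(list(entity = "DIS01",
                        p = setNames(c(0.4, 0.3, 0.1, 0.1, 0.05, 0.05),
                                     idx),
                        iterations = 1L, converged = TRUE),
                   class = "diffusion_profile")
  mk <- function(id, v) structure(list(entity = id, p = setNames(v, idx),
                                       iterations = 1L, converged = TRUE),
                                  class = "diffusion_profile")
  profiles <- list(H2 = mk("H2", c(0.39, 0.31, 0.1, 0.1, 0.05, 0.05)),
                   H1 = mk("H1", c(0.39, 0.31, 0.1, 0.1, 0.05, 0.05)),
                   H3 = mk("H3", c(0.05, 0.05, 0.1, 0.1, 0.3, 0.4)))
  targets <- list(H1 = c("n1", "n2"), H2 = c("n1", "n2"), H3 = "n5")
  tab <- rank_candidates(profiles, dis, targets,
                         disease_proteins = c("n1", "n2"),
                         background = idx, exclude = character(0))
  expect_s3_class(tab, "ranked_candidates")
  # identical profiles tie; id breaks the tie
  expect_identical(tab$entity[1:2], c("H1", "H2"))
  expect_identical(tab$entity[3], "H3")
  expect_true(all(tab$score >= -1 & tab$score <= 1))
  expect_identical(tab,
                   rank_candidates(profiles, dis, targets,
                                   disease_proteins = c("n1", "n2"),
                                   background = idx,
                                   exclude = character(0)))
  # overlap columns agree with direct set arithmetic
  expect_identical(tab$k[tab$entity == "H1"], 2L)
  expect_identical(tab$n[tab$entity == "H3"], 1L)

  empty <- rank_candidates(list(), dis, list(), "n1", idx)
  expect_identical(nrow(empty), 0L)
})

test_that("over-representation analysis produces coherent statistics", {
  bg <- paste0("G", 1:40)
  targets <- paste0("G", 1:10)
  lib <- list(identical_term = paste0("G", 1:10),
              disjoint_term = paste0("G", 21:30),
              half_term = paste0("G", 6:15))
  res <- over_representation(targets, lib, bg)
  # the identical term dominates: minimal p, maximal odds ratio
  expect_identical(res$term[1], "identical_term")
  expect_true(res$p_value[1] < min(res$p_value[-1]))
  expect_true(res$odds_ratio[1] >= max(res$odds_ratio[-1]))
  # a disjoint term gives k = 0, p = 1, combined score 0
  dis <- res[res$term == "disjoint_term", ]
  expect_identical(dis$overlap, 0L)
  expect_identical(dis$p_value, 1)
  expect_identical(dis$combined_score, 0)
  # odds ratio equals direct 2x2 arithmetic for the half-overlap term
  half <- res[res$term == "half_term", ]
  a <- 5; b <- 5; c2 <- 5; d <- 25
  expect_equal(half$odds_ratio, (a * d) / (b * c2), tolerance = 1e-12)
  # z-score matches the hypergeometric-null moments
  k <- 5; n <- 10; K <- 10; M <- 40
  mu <- n * K / M
  v <- n * (K / M) * ((M - K) / M) * ((M - n) / (M - 1))
  expect_equal(half$z, (k - mu) / sqrt(v), tolerance = 1e-12)
  expect_equal(half$combined_score, -log(half$p_value) * half$z,
               tolerance = 1e-12)

  expect_error(over_representation(targets, lib, character(0)),
               "empty background")
  expect_error(over_representation("NOT_IN_BG", lib, bg), "outside")
})

test_that("GMT reader parses terms and rejects malformed lines", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("term1\tdesc one\tG1\tG2\tG3",
               "term2\tdesc two\tG2\tG4"), path)
  lib <- read_gmt(path)
  expect_identical(names(lib), c("term1", "term2"))
  expect_identical(lib$term2, c("G2", "G4"))
  expect_identical(unname(attr(lib, "descriptions")["term1"]), "desc one")

  bad <- tempfile(fileext = ".gmt")
  writeLines("only_term\tdesc", bad)
  expect_error(read_gmt(bad), "line 1")
})
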