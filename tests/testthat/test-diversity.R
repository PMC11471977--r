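# Incidence matrices, Jaccard/UPGMA, accumulation, jackknife, Poisson GLM.

test_that("incidence matrix collapses duplicates and derives Q1/Q2/S_obs", {
  recs <- make_records(rep(NA_character_, 6),
                       accepted = c("a", "a", "b", "c", "b", "b"),
                       year = c(2000, 2000, 2000, 2000, 2001, 2001))
  x <- build_incidence(recs, "year")
  expect_equal(x$m, 2)
  expect_equal(x$S_obs, 3)
  expect_equal(unname(x$m_i[c("a", "b", "c")]), c(1, 2, 1))
  expect_equal(x$Q1, 2)
  expect_equal(x$Q2, 1)
  expect_equal(nrow(tidy(x)), 4)

  single <- build_incidence(recs[recs$year == 2000, ], "year")
  expect_equal(single$S_obs, 3)
  expect_equal(single$Q1, 3)
  expect_equal(single$Q2, 0)
})

test_that("richness and endemism per unit follow the exact-code rule", {
  tax <- tiny_taxonomy()
  recs <- make_records(
    rep(NA_character_, 3),
    accepted = c("Boana boans", "Rhinella marina", "Boana boans"),
    year = c(2000, 2000, 2001))
  x <- build_incidence(recs, "year")
  div <- richness_endemism(x, tax)
  # Boana boans is {AM} (endemic); Rhinella marina {AM, CE} is not
  expect_equal(div$richness, c(2, 1))
  expect_equal(div$endemic_count, c(1, 1))
  expect_true(all(div$endemic_count <= div$richness))
})

test_that("Jaccard similarity matches set arithmetic and an independent oracle", {
  m <- rbind(u1 = c(TRUE, TRUE, TRUE, FALSE),
             u2 = c(FALSE, TRUE, TRUE, TRUE),
             u3 = c(TRUE, TRUE, TRUE, FALSE))
  colnames(m) <- letters[1:4]
  x <- new_incidence_matrix(m)
  j <- jaccard_similarity(x)
  expect_equal(j["u1", "u2"], 0.5)   # {a,b,c} vs {b,c,d}: 2 shared / 4 union
  expect_equal(j["u1", "u3"], 1.0)
  expect_true(isSymmetric(j))
  expect_equal(unname(diag(j)), rep(1, 3))
  withr::local_seed(9)
  y <- random_incidence(8, 30)
  got <- jaccard_similarity(y)
  want <- 1 - as.matrix(vegan::vegdist(y$presence * 1, method = "jaccard"))
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("disjoint compositions give 0 and empty pairs give 1 with a warning", {
  m <- rbind(u1 = c(TRUE, FALSE), u2 = c(FALSE, TRUE), u3 = c(FALSE, FALSE),
             u4 = c(FALSE, FALSE))
  colnames(m) <- c("a", "b")
  expect_warning(j <- jaccard_similarity(new_incidence_matrix(m)), "empty")
  expect_equal(j["u1", "u2"], 0)
  expect_equal(j["u3", "u4"], 1)
})

test_that("UPGMA reproduces the hand-computed 3-leaf dendrogram and cut", {
  sim <- matrix(c(1, 0.8, 0.4,
                  0.8, 1, 0.2,
                  0.4, 0.2, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # distances: d(A,B)=0.2, d(A,C)=0.6, d(B,C)=0.8
  hc <- upgma_cluster(sim)
  expect_equal(hc$height, c(0.2, 0.7))       # (A,B)@0.2 then (AB,C)@(0.6+0.8)/2
  expect_true(all(diff(hc$height) >= 0))
  groups <- cut_dendrogram(hc, min_similarity = 0.40)
  g <- stats::setNames(groups$group, groups$unit)
  expect_equal(g[["A"]], g[["B"]])
  expect_false(g[["A"]] == g[["C"]])
})

test_that("identical units cluster into a single group at any threshold", {
  m <- matrix(TRUE, 4, 3, dimnames = list(paste0("u", 1:4), letters[1:3]))
  hc <- upgma_cluster(jaccard_similarity(new_incidence_matrix(m)))
  expect_equal(max(cut_dendrogram(hc, 0.99)$group), 1)
})

test_that("exact accumulation matches hand arithmetic and vegan, ending at S_obs", {
  m <- rbind(u1 = c(TRUE, TRUE), u2 = c(TRUE, FALSE))
  colnames(m) <- c("both", "one")
  x <- new_incidence_matrix(m)
  curve <- accumulation_curve(x, method = "exact")
  expect_equal(curve$richness, c(1.5, 2))    # 1 + (1 - C(1,1)/C(2,1)) = 1.5
  withr::local_seed(21)
  y <- random_incidence(12, 40)
  exact <- accumulation_curve(y, method = "exact")
  expect_true(all(diff(exact$richness) >= -1e-12))
  expect_equal(exact$richness[y$m], y$S_obs)
  sa <- vegan::specaccum(y$presence * 1, method = "exact")
  expect_equal(exact$richness, unname(sa$richness), tolerance = 1e-10)
})

test_that("permutation accumulation converges on the exact expectation", {
  withr::local_seed(33)
  x <- random_incidence(10, 20)
  exact <- accumulation_curve(x, method = "exact")
  perm <- accumulation_curve(x, method = "permutation", n_perm = 500, seed = 99)
  # Monte-Carlo 3 sigma on the mean of 500 permutations, per t
  sds <- vapply(seq_len(x$m), function(t) {
    max(stats::sd(perm$richness), 1e-6)
  }, numeric(1))
  expect_true(all(abs(perm$richness - exact$richness) <=
                    pmax(3 * sds / sqrt(500), 0.5)))
  expect_equal(perm$richness[x$m], x$S_obs)
  expect_error(accumulation_curve(x, method = "permutation", n_perm = 0, seed = 1),
               "n_perm")
  expect_error(accumulation_curve(x, method = "permutation"), "seed")
})

test_that("jackknife estimators follow the closed formulas and vegan agrees", {
  # S_obs=10, Q1=3, Q2=2, m=5 -> 10 + 3*7/5 - 2*9/20 = 13.3
  m <- matrix(FALSE, 5, 10, dimnames = list(paste0("u", 1:5), paste0("s", 1:10)))
  for (s in 1:5) m[1:5, s] <- TRUE          # 5 widespread species
  m[1, 6] <- TRUE; m[2, 7] <- TRUE; m[3, 8] <- TRUE       # Q1 = 3
  m[1:2, 9] <- TRUE; m[3:4, 10] <- TRUE                   # Q2 = 2
  x <- new_incidence_matrix(m)
  expect_equal(c(x$S_obs, x$Q1, x$Q2), c(10, 3, 2))
  est <- jackknife2(x)
  expect_equal(est$jack2, 13.3)
  expect_equal(est$jack1, 10 + 3 * 4 / 5)
  expect_error(jackknife2(new_incidence_matrix(m[1, , drop = FALSE])), "m < 2")
  withr::local_seed(55)
  for (i in 1:5) {
    y <- random_incidence(sample(4:12, 1), sample(15:40, 1))
    pool <- vegan::specpool(y$presence * 1)
    est <- jackknife2(y)
    expect_equal(est$jack2, pool$jack2, tolerance = 1e-10)
    expect_equal(est$jack1, pool$jack1, tolerance = 1e-10)
  }
})

test_that("a complete census drives the jackknife back to observed richness", {
  m <- matrix(TRUE, 20, 15, dimnames = list(paste0("u", 1:20), paste0("s", 1:15)))
  est <- jackknife2(new_incidence_matrix(m))
  expect_equal(est$jack2, est$S_obs)
  expect_equal(glance(est)$completeness_pct, 100)
})

test_that("Poisson GLM: intercept-only MLE, slope recovery, likelihood optimum", {
  df0 <- data.frame(richness = c(1, 2, 3), area_km2 = c(100, 100, 100))
  # constant covariate: slope is aliased, intercept alone carries log-mean 2
  fit0 <- poisson_glm(df0)
  expect_equal(unname(stats::coef(fit0$fit)[1]), log(2), tolerance = 1e-8)

  withr::local_seed(77)
  n <- 500
  area <- exp(stats::runif(n, 6, 12))
  mu <- exp(0.8 + 0.5 * log(area))
  df <- data.frame(richness = stats::rpois(n, mu), area_km2 = area)
  fit <- poisson_glm(df)
  co <- tidy(fit)
  slope <- co[co$term == "log_area", ]
  expect_lt(abs(slope$estimate - 0.5), 3 * slope$std_error)
  expect_gt(slope$z, 10)

  # brute-force likelihood grid around the IRLS optimum finds nothing better
  loglik <- function(b0, b1, x, y) sum(y * (b0 + b1 * x) - exp(b0 + b1 * x))
  x <- log(df$area_km2); y <- df$richness
  b <- stats::coef(fit$fit)
  grid <- expand.grid(b0 = b[1] + seq(-0.05, 0.05, length.out = 41),
                      b1 = b[2] + seq(-0.005, 0.005, length.out = 41))
  best_grid <- max(mapply(loglik, grid$b0, grid$b1,
                          MoreArgs = list(x = x, y = y)))
  expect_gte(loglik(b[1], b[2], x, y) + 1e-6, best_grid)
})

test_that("near-constant data gives a small slope z", {
  withr::local_seed(78)
  df <- data.frame(richness = stats::rpois(200, 20),
                   area_km2 = exp(stats::runif(200, 6, 12)))
  co <- tidy(poisson_glm(df))
  expect_lt(abs(co$z[co$term == "log_area"]), 3)
})

test_that("newick export encodes the UPGMA topology", {
  sim <- matrix(c(1, 0.8, 0.4, 0.8, 1, 0.2, 0.4, 0.2, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgma_cluster(sim)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, path)
  txt <- readLines(path)
  expect_match(txt, "^\\(.*A.*B.*C.*;$|^\\(.*C.*\\(.*A.*B.*\\).*;$")
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  # ultrametric: root-to-tip distance equals half the final merge height
  depths <- ape::node.depth.edgelength(tree)[1:3]
  expect_equal(unname(depths), rep(0.35, 3), tolerance = 1e-6)
})
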