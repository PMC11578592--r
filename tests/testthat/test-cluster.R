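test_that("cluster masses match hand enumeration on tiny grids", {
  adj <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2)   # the two electrodes touch
  map <- rbind(c(3, 3, 0), c(0, 0, 0))
  cl <- clusters_and_mass(map, threshold = 2, adj)
  expect_equal(length(cl$mass), 1)
  expect_equal(cl$mass, 6)
  expect_equal(sum(cl$id > 0), 2)
  # everything below threshold
  expect_equal(length(clusters_and_mass(map, 4, adj)$mass), 0)
  # adjacent nodes of opposite sign split into two clusters
  map2 <- rbind(c(3, -3, 0), c(0, 0, 0))
  cl2 <- clusters_and_mass(map2, 2, adj)
  expect_equal(sort(cl2$mass), c(-3, 3))
  expect_equal(length(cl2$mass), 2)
  # spatial adjacency joins electrodes at the same sample
  map3 <- rbind(c(3, 0, 0), c(2.5, 0, 0))
  cl3 <- clusters_and_mass(map3, 2, adj)
  expect_equal(cl3$mass, 5.5)
  # without the edge they stay separate
  cl4 <- clusters_and_mass(map3, 2, matrix(FALSE, 2, 2))
  expect_equal(sort(cl4$mass), c(2.5, 3))
})

test_that("automatic electrode adjacency hits the target degree", {
  pos <- vigoureeg:::default_layout()[, c("x", "y")]
  adj <- electrode_adjacency(as.matrix(pos))
  expect_true(isSymmetric(unclass(adj * 1)))
  expect_true(all(!diag(adj)))
  expect_gte(stats::median(rowSums(adj)), 6)
})

test_that("within-cell permutation preserves cells and is uniform", {
  d <- data.frame(participant = rep(c("P1", "P2"), each = 6),
                  incentive = rep(c(0, 50), 6),
                  distractor = rep(c(0, 0, 1, 1), 3),
                  thp = 0)
  f <- interaction(d[, c("participant", "incentive", "distractor", "thp")],
                   drop = TRUE)
  set.seed(1)
  for (r in 1:20) {
    idx <- permute_within_cells(d)
    expect_true(all(f[idx] == f))          # cells invariant
    expect_setequal(idx, seq_len(nrow(d)))
  }
  # singleton cells stay put
  d1 <- d[1:4, ]; d1$distractor <- 0:3    # every cell size 1
  expect_equal(permute_within_cells(d1), 1:4)
  # a 3-trial cell visits its 6 orderings uniformly
  d3 <- data.frame(participant = "P1", incentive = 0, distractor = 0,
                   thp = 0)[rep(1, 3), ]
  set.seed(2)
  draws <- replicate(3000, paste(permute_within_cells(d3), collapse = ""))
  tab <- table(draws)
  expect_equal(length(tab), 6)
  expect_true(all(abs(tab / 3000 - 1 / 6) < 3 * sqrt((1 / 6) * (5 / 6) / 3000)))
})

test_that("p-values use add-one smoothing and the max-mass rule", {
  p <- permutation_pvalues(mass = c(50, -1), null_max = rep(2, 2500))
  expect_equal(p$p[1], 1 / 2501)
  expect_equal(p$p[2], 1)
  expect_true(p$significant[1])
  expect_false(p$significant[2])
})

test_that("null t-maps from the two-stage engine are central t", {
  set.seed(41)
  P <- 12
  d <- expand.grid(rep = 1:10, incentive = c(0, 50), distractor = c(0, 1),
                   participant = sprintf("P%02d", 1:P))
  d$thp <- rep(c(0, 1), length.out = nrow(d))
  d$trial_id <- sprintf("t%04d", seq_len(nrow(d)))
  d$beh <- rnorm(nrow(d))
  ne <- 4; ns <- 30
  ep <- epoch_set(array(rnorm(nrow(d) * ne * ns), c(nrow(d), ne, ns)),
                  paste0("E", 1:ne), cbind(1:ne, 0), 256,
                  seq(0, by = 4, length.out = ns), trial_ids = d$trial_id)
  sm <- observed_stat_map(ep, d, "beh")
  expect_equal(dim(sm$t), c(ne, ns))
  expect_equal(sm$df, P - 1)
  ks <- stats::ks.test(as.numeric(sm$t), stats::pt, df = sm$df)
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted single-node association tops the stat map", {
  hits <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    P <- 10
    d <- expand.grid(rep = 1:12, incentive = c(0, 50), distractor = c(0, 1),
                     participant = sprintf("P%02d", 1:P))
    d$thp <- rep(c(0, 1), length.out = nrow(d))
    d$trial_id <- sprintf("t%04d", seq_len(nrow(d)))
    ne <- 4; ns <- 12
    v <- array(rnorm(nrow(d) * ne * ns), c(nrow(d), ne, ns))
    d$beh <- rnorm(nrow(d)) + 0.8 * v[, 2, 5]   # node (2, 5) carries signal
    ep <- epoch_set(v, paste0("E", 1:ne), cbind(1:ne, 0), 256,
                    seq(0, by = 4, length.out = ns), trial_ids = d$trial_id)
    sm <- observed_stat_map(ep, d, "beh")
    if (which.max(abs(sm$t)) == (5 - 1) * ne + 2) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("difference-mode maps vanish for identical conditions", {
  set.seed(43)
  d <- data.frame(participant = rep(sprintf("P%d", 1:4), each = 8),
                  incentive = rep(c(0, 50), 16))
  d$trial_id <- sprintf("t%03d", 1:32)
  v <- array(0, c(32, 2, 10))
  base <- matrix(rnorm(4 * 10), 4)     # same mean wave in both conditions
  for (i in 1:32) v[i, , ] <- rep(base[(i - 1) %/% 8 + 1, ], each = 2)
  ep <- epoch_set(v, c("Cz", "Fz"), cbind(1:2, 0), 256,
                  seq(0, by = 4, length.out = 10), trial_ids = d$trial_id)
  sm <- observed_stat_map(ep, d, mode = "difference", factor = "incentive")
  expect_true(all(abs(sm$t) < 1e-8))
})

test_that("Monte-Carlo p matches the exhaustive permutation p on a toy", {
  # 2 participants x 3 trials, one electrode x 4 samples: 36 permutations
  set.seed(44)
  d <- data.frame(participant = rep(c("Pa", "Pb"), each = 3),
                  incentive = 0, distractor = 0, thp = 0)
  d$trial_id <- sprintf("t%d", 1:6)
  d$beh <- c(1.2, -0.5, 0.1, 0.8, -1.1, 0.4)
  v <- array(rnorm(6 * 1 * 4), c(6, 1, 4))
  v[, 1, 2] <- v[, 1, 2] + 1.5 * d$beh
  ep <- epoch_set(v, "Cz", cbind(0, 0), 256, seq(0, by = 4, length.out = 4),
                  trial_ids = d$trial_id)
  thr <- 1.5
  adj <- matrix(FALSE, 1, 1)

  # exhaustive oracle, written against the same statistic definition
  y <- zscore(d$beh)
  design <- matrix(1, 6, 1, dimnames = list(NULL, "(Intercept)"))
  ctx <- vigoureeg:::ols2_context(y, design, d$participant)
  tmap_of <- function(idx) {
    V <- matrix(ep$voltages[idx, 1, ], nrow = 6)
    matrix(vigoureeg:::ols2_tmap(V, ctx), 1)
  }
  obs <- tmap_of(1:6)
  ocl <- clusters_and_mass(obs, thr, adj)
  perms <- vigoureeg:::all_within_cell_permutations(d$participant)
  expect_equal(length(perms), 36)
  null_max <- vapply(perms, function(idx) {
    cl <- clusters_and_mass(tmap_of(idx), thr, adj)
    if (length(cl$mass)) max(abs(cl$mass)) else 0
  }, numeric(1))
  exact_p <- vapply(ocl$mass, function(m) mean(null_max >= abs(m)),
                    numeric(1))

  mc <- cluster_permutation_test(ep, d, "beh", n_perm = 3000,
                                 threshold = thr, adjacency = adj,
                                 seed = 9)
  expect_equal(mc$clusters$mass, ocl$mass, tolerance = 1e-10)
  # MC p converges to the exact p (within 3 binomial SEs + smoothing)
  for (k in seq_along(exact_p)) {
    se <- sqrt(exact_p[k] * (1 - exact_p[k]) / 3000)
    expect_lt(abs(mc$clusters$p[k] - exact_p[k]), 3 * se + 1 / 3000)
  }
})

test_that("density cluster test finds a planted dip and respects the null", {
  set.seed(45)
  P <- 12; nb <- 61
  grid <- seq(-60, 60, by = 2)
  # null: no structure
  curves0 <- matrix(rnorm(P * nb, 0, 0.01), P)
  r0 <- density_cluster_test(curves0, n_perm = 300, seed = 3)
  expect_true(all(!r0$clusters$significant))
  # planted dip at -30 deg in every participant
  dip <- -0.05 * exp(-(grid - (-30))^2 / 50)
  curves1 <- matrix(rep(dip, each = P), P) + matrix(rnorm(P * nb, 0, 0.01), P)
  r1 <- density_cluster_test(curves1, n_perm = 300, seed = 4)
  sig <- r1$clusters[r1$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  expect_lt(min(sig$mass), 0)
  in_cluster <- which(r1$id[1, ] > 0)
  expect_true(which.min(abs(grid - (-30))) %in% in_cluster)
  # sign-flipping all curves negates every cluster mass
  r2 <- density_cluster_test(-curves1, n_perm = 50, seed = 4)
  expect_equal(sort(r2$clusters$mass), sort(-r1$clusters$mass),
               tolerance = 1e-10)
  expect_error(density_cluster_test(curves1[1, , drop = FALSE]),
               "at least 2")
})

test_that("the lmm and two-stage engines agree on a small grid", {
  set.seed(46)
  d <- expand.grid(rep = 1:15, incentive = c(0, 50), distractor = c(0, 1),
                   participant = sprintf("P%02d", 1:8))
  d$thp <- rep(c(0, 1), length.out = nrow(d))
  d$trial_id <- sprintf("t%04d", seq_len(nrow(d)))
  ne <- 2; ns <- 6
  v <- array(rnorm(nrow(d) * ne * ns), c(nrow(d), ne, ns))
  d$beh <- rnorm(nrow(d)) + 0.4 * v[, 1, 3]
  ep <- epoch_set(v, c("Cz", "Fz"), cbind(1:2, 0), 256,
                  seq(0, by = 4, length.out = ns), trial_ids = d$trial_id)
  s1 <- observed_stat_map(ep, d, "beh", engine = "ols2")
  s2 <- observed_stat_map(ep, d, "beh", engine = "lmm")
  # both engines agree on where the signal is and its sign
  expect_equal(which.max(abs(s1$t)), which.max(abs(s2$t)))
  expect_gt(stats::cor(as.numeric(s1$t), as.numeric(s2$t)), 0.9)
})
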