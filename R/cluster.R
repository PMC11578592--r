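## Cluster-mass permutation inference over electrode x time grids and
## angle-density curves.

#' Spatial adjacency between electrodes
#'
#' Electrodes are neighbours when their layout distance is below a
#' threshold. If `threshold` is NULL the smallest threshold giving a
#' median degree of at least `target_degree` is chosen.
#'
#' @param positions channels x 2 layout coordinates.
#' @param threshold distance threshold, or NULL for automatic.
#' @param target_degree desired median neighbour count (automatic mode).
#' @return symmetric logical matrix without self-edges; attribute
#'   `threshold` records the distance used.
#' @export
electrode_adjacency <- function(positions, threshold = NULL,
                                target_degree = 6) {
  d <- as.matrix(stats::dist(positions))
  if (is.null(threshold)) {
    cand <- sort(unique(round(d[upper.tri(d)], 10)))
    for (th in cand) {
      deg <- rowSums(d <= th + 1e-12) - 1
      if (stats::median(deg) >= min(target_degree, nrow(d) - 1)) {
        threshold <- th + 1e-12
        break
      }
    }
    if (is.null(threshold)) threshold <- max(d)
  }
  adj <- d <= threshold
  diag(adj) <- FALSE
  attr(adj, "threshold") <- threshold
  adj
}

#' Connected supra-threshold clusters and their masses
#'
#' Nodes of an electrodes x samples statistic map exceeding `threshold`
#' in absolute value, sharing a sign, and connected in the graph
#' (spatial neighbours at the same sample; same electrode at consecutive
#' samples) form clusters; mass is the sum of the statistic over the
#' cluster.
#'
#' @param stat_map electrodes x samples numeric matrix.
#' @param threshold cluster-forming threshold (> 0) on |t|.
#' @param adjacency electrode adjacency matrix (ignored for single-row
#'   maps, which use chain adjacency over samples).
#' @return list: `id` (integer matrix, 0 = background), `mass` (signed
#'   masses by cluster), `sign`.
#' @export
clusters_and_mass <- function(stat_map, threshold, adjacency = NULL) {
  stopifnot(threshold > 0)
  stat_map <- as.matrix(stat_map)
  ne <- nrow(stat_map); ns <- ncol(stat_map)
  if (is.null(adjacency)) adjacency <- matrix(FALSE, ne, ne)
  supra <- which(abs(stat_map) > threshold & is.finite(stat_map))
  id <- matrix(0L, ne, ns)
  if (!length(supra)) {
    return(list(id = id, mass = numeric(0), sign = integer(0)))
  }
  sgn <- matrix(0L, ne, ns)
  sgn[supra] <- ifelse(stat_map[supra] > 0, 1L, -1L)
  nb_e <- lapply(seq_len(ne), function(e) which(adjacency[e, ]))
  cl <- 0L
  mass <- numeric(0)
  csign <- integer(0)
  for (v in supra) {
    if (id[v] != 0L) next
    cl <- cl + 1L
    s0 <- sgn[v]
    queue <- v
    id[v] <- cl
    msum <- 0
    while (length(queue)) {
      node <- queue[[1]]
      queue <- queue[-1]
      msum <- msum + stat_map[node]
      e <- (node - 1L) %% ne + 1L
      s <- (node - 1L) %/% ne + 1L
      cand <- integer(0)
      if (s > 1L) cand <- c(cand, node - ne)
      if (s < ns) cand <- c(cand, node + ne)
      if (length(nb_e[[e]])) cand <- c(cand, (s - 1L) * ne + nb_e[[e]])
      for (w in cand) {
        if (sgn[w] == s0 && id[w] == 0L) {
          id[w] <- cl
          queue <- c(queue, w)
        }
      }
    }
    mass <- c(mass, msum)
    csign <- c(csign, s0)
  }
  list(id = id, mass = mass, sign = csign)
}

## per-participant two-stage regression context: residualizers for the
## factorial design and the behaviour residuals, computed once so that
## permutation refits only touch the voltage matrix
ols2_context <- function(y, design, participant) {
  g <- factor(participant, levels = unique(participant))
  n <- length(y)
  blocks <- lapply(levels(g), function(p) {
    sel <- which(g == p)
    X <- design[sel, , drop = FALSE]
    X <- X[, c(TRUE, apply(X[, -1, drop = FALSE], 2, stats::sd) > 0),
           drop = FALSE]
    list(sel = sel, Q = qr.Q(qr(X)))
  })
  ncolq <- sum(vapply(blocks, function(b) ncol(b$Q), 0L))
  Qblk <- matrix(0, n, ncolq)       # block-diagonal orthonormal projector
  off <- 0L
  for (b in blocks) {
    Qblk[b$sel, off + seq_len(ncol(b$Q))] <- b$Q
    off <- off + ncol(b$Q)
  }
  rb <- as.numeric(y - Qblk %*% crossprod(Qblk, y))
  list(Qblk = Qblk, rb = rb, g = g, P = nlevels(g))
}

## t-map (vector over nodes) for a trials x nodes voltage matrix
ols2_tmap <- function(V, ctx) {
  P <- ctx$P
  Rv <- V - ctx$Qblk %*% crossprod(ctx$Qblk, V)
  num <- rowsum(Rv * ctx$rb, ctx$g, reorder = FALSE)
  den <- rowsum(Rv^2, ctx$g, reorder = FALSE)
  den[den == 0] <- NA
  slopes <- num / den
  mu <- colMeans(slopes)
  ssq <- colSums(slopes^2) - P * mu^2
  tv <- mu / sqrt(pmax(ssq / (P - 1), 0) / P)
  tv[!is.finite(tv)] <- 0
  tv
}

stat_map_ols2 <- function(V, y, design, participant) {
  ctx <- ols2_context(y, design, participant)
  list(t = ols2_tmap(V, ctx), df = ctx$P - 1)
}

## factorial design for the covariate adjustment; factors that are
## constant in the analysed trials (degenerate toys) drop to an
## intercept-only design instead of erroring
regression_design <- function(d, factors) {
  keep <- factors[vapply(factors, function(f)
    length(unique(d[[f]])) > 1, TRUE)]
  if (!length(keep)) {
    return(matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)")))
  }
  zscore_design(d, keep)
}

## node-wise mixed-model t of the voltage term (reference engine)
stat_map_lmm <- function(V, y, design, participant) {
  nno <- ncol(V)
  tv <- numeric(nno)
  nonconv <- 0L
  for (j in seq_len(nno)) {
    X <- cbind(design, voltage = V[, j])
    f <- tryCatch(fit_ranint_ml(y, X, participant), error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      nonconv <- nonconv + 1L
      tv[j] <- 0
    } else {
      tv[j] <- f$t[["voltage"]]
    }
  }
  if (nonconv) warning(sprintf("%d node fits did not converge (t set to 0)",
                               nonconv))
  list(t = tv, df = length(y) - ncol(design) - 1)
}

#' Observed statistic map over electrodes x time
#'
#' Mode `"regression"`: per node, the t-statistic for the voltage term
#' in a regression of the behavioural variable on voltage plus the
#' factorial design, either via the two-stage per-participant engine
#' (`"ols2"`, default: per-participant OLS slopes, across-participant
#' t) or the node-wise mixed model (`"lmm"`). Mode `"difference"`: per
#' node, a paired t across participants on condition difference waves.
#'
#' @param epochs an [epoch_set()].
#' @param data trial table (must cover the epochs' trial ids).
#' @param behaviour behavioural outcome column (regression mode).
#' @param mode `"regression"` or `"difference"`.
#' @param factor factor column (difference mode).
#' @param factors factorial design columns (regression mode).
#' @param engine `"ols2"` or `"lmm"`.
#' @return list: `t` (electrodes x samples matrix), `df`, `mode`.
#' @export
observed_stat_map <- function(epochs, data, behaviour = NULL,
                              mode = c("regression", "difference"),
                              factor = NULL,
                              factors = c("incentive", "distractor", "thp"),
                              engine = c("ols2", "lmm")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  ne <- length(epochs$channels)
  ns <- length(epochs$times)
  if (mode == "difference") {
    dw <- difference_waves(epochs, data, factor)
    P <- dim(dw$diff)[1]
    mu <- apply(dw$diff, c(2, 3), mean)
    sdv <- apply(dw$diff, c(2, 3), stats::sd)
    tmap <- mu / (sdv / sqrt(P))
    tmap[!is.finite(tmap)] <- 0
    return(list(t = tmap, df = P - 1, mode = mode))
  }
  m <- match(epochs$trial_ids, data$trial_id)
  if (anyNA(m)) stop("epochs contain trials absent from the table")
  d <- data[m, , drop = FALSE]
  ok <- stats::complete.cases(d[, c(behaviour, factors, "participant")])
  d <- d[ok, , drop = FALSE]
  V <- matrix(epochs$voltages[ok, , , drop = FALSE], nrow = sum(ok))
  y <- zscore(as.numeric(d[[behaviour]]))
  design <- regression_design(d, factors)
  res <- switch(engine,
                ols2 = stat_map_ols2(V, y, design, d$participant),
                lmm = stat_map_lmm(V, y, design, d$participant))
  list(t = matrix(res$t, ne, ns), df = res$df, mode = mode)
}

#' Permute trial-to-voltage assignment within design cells
#'
#' Returns an index vector `idx` such that trial i is assigned the
#' voltages of trial `idx[i]`; the permutation acts independently within
#' every participant x incentive x distractor x drug cell, leaving the
#' behavioural table untouched. Cells of size 1 are left unpermuted.
#'
#' @param data trial table.
#' @param cells columns defining the cells.
#' @return integer permutation of `seq_len(nrow(data))`.
#' @export
permute_within_cells <- function(data,
                                 cells = c("participant", "incentive",
                                           "distractor", "thp")) {
  f <- interaction(data[, cells], drop = TRUE)
  idx <- seq_len(nrow(data))
  for (lev in levels(f)) {
    sel <- which(f == lev)
    if (length(sel) > 1) idx[sel] <- sel[sample.int(length(sel))]
  }
  idx
}

#' Family-wise p-values from a max-cluster-mass null
#'
#' `p = (1 + #\{null max |mass| >= |observed mass|\}) / (n_perm + 1)`
#' (add-one smoothing; two-tailed through the absolute mass).
#'
#' @param mass observed signed cluster masses.
#' @param null_max permutation null of the maximum absolute mass.
#' @param fwer family-wise error rate.
#' @return data.frame `cluster`, `mass`, `p`, `significant`.
#' @export
permutation_pvalues <- function(mass, null_max, fwer = 0.05) {
  n_perm <- length(null_max)
  p <- vapply(mass, function(m)
    (1 + sum(null_max >= abs(m))) / (n_perm + 1), numeric(1))
  data.frame(cluster = seq_along(mass), mass = mass, p = p,
             significant = p <= fwer)
}

#' Cluster-mass permutation test of behaviour on voltage
#'
#' Builds the observed t-map, forms supra-threshold clusters, then
#' constructs the max-cluster-mass null by shuffling voltages across
#' trials within each participant x condition cell (regression mode) or
#' by sign-flipping participant difference waves (difference mode).
#' Permutations are seeded counter-style (`seed + i`), so results are
#' reproducible and order-independent.
#'
#' @inheritParams observed_stat_map
#' @param n_perm number of permutations.
#' @param threshold cluster-forming |t| threshold; NULL uses the
#'   two-tailed 5% t critical value for the engine's df.
#' @param fwer family-wise error rate.
#' @param adjacency electrode adjacency; NULL builds it from the layout.
#' @param seed base seed.
#' @return list of class `ClusterResult`: observed `t` map, `threshold`,
#'   cluster `id` matrix, `clusters` table with p-values, `null_max`,
#'   `n_perm`, `seed`.
#' @export
cluster_permutation_test <- function(epochs, data, behaviour = NULL,
                                     mode = c("regression", "difference"),
                                     factor = NULL,
                                     factors = c("incentive", "distractor",
                                                 "thp"),
                                     engine = c("ols2", "lmm"),
                                     n_perm = 2500, threshold = NULL,
                                     fwer = 0.05, adjacency = NULL,
                                     seed = 1) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  stopifnot(n_perm >= 1)
  if (mode == "regression") {
    data <- data[data$trial_id %in% epochs$trial_ids, , drop = FALSE]
    epochs <- subset_epochs(epochs, data$trial_id)
    ok <- stats::complete.cases(data[, c(behaviour, factors, "participant")])
    data <- data[ok, , drop = FALSE]
    epochs <- subset_epochs(epochs, data$trial_id)
  }
  ne <- length(epochs$channels)
  ns <- length(epochs$times)
  fast_ols2 <- mode == "regression" && engine == "ols2"
  if (fast_ols2) {
    V <- matrix(epochs$voltages, nrow = nrow(data))
    y <- zscore(as.numeric(data[[behaviour]]))
    design <- regression_design(data, factors)
    ctx <- ols2_context(y, design, data$participant)
    obs <- list(t = matrix(ols2_tmap(V, ctx), ne, ns), df = ctx$P - 1,
                mode = mode)
  } else {
    obs <- observed_stat_map(epochs, data, behaviour, mode, factor, factors,
                             engine)
  }
  if (is.null(threshold)) threshold <- stats::qt(0.975, obs$df)
  if (is.null(adjacency) && !is.null(epochs$positions))
    adjacency <- electrode_adjacency(epochs$positions)
  ocl <- clusters_and_mass(obs$t, threshold, adjacency)

  if (mode == "regression") {
    cell_idx <- split(seq_len(nrow(data)),
                      interaction(data[, c("participant", factors)],
                                  drop = TRUE))
    shuffle_cells <- function() {
      idx <- seq_len(nrow(data))
      for (sel in cell_idx) {
        if (length(sel) > 1) idx[sel] <- sel[sample.int(length(sel))]
      }
      idx
    }
  }
  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed((seed + i) %% 2147483629L)
    if (fast_ols2) {
      idx <- shuffle_cells()
      pm <- list(t = matrix(ols2_tmap(V[idx, , drop = FALSE], ctx), ne, ns))
    } else if (mode == "regression") {
      idx <- permute_within_cells(data)
      perm_epochs <- epochs
      perm_epochs$voltages <- epochs$voltages[idx, , , drop = FALSE]
      pm <- observed_stat_map(perm_epochs, data, behaviour, mode, factor,
                              factors, engine)
    } else {
      dw <- difference_waves(epochs, data, factor)
      flips <- sample(c(-1, 1), dim(dw$diff)[1], replace = TRUE)
      flipped <- dw$diff * flips
      P <- dim(flipped)[1]
      mu <- apply(flipped, c(2, 3), mean)
      sdv <- apply(flipped, c(2, 3), stats::sd)
      tmap <- mu / (sdv / sqrt(P))
      tmap[!is.finite(tmap)] <- 0
      pm <- list(t = tmap)
    }
    pcl <- clusters_and_mass(pm$t, threshold, adjacency)
    null_max[i] <- if (length(pcl$mass)) max(abs(pcl$mass)) else 0
  }
  clusters <- permutation_pvalues(ocl$mass, null_max, fwer)
  structure(list(t = obs$t, df = obs$df, threshold = threshold,
                 id = ocl$id, clusters = clusters, null_max = null_max,
                 n_perm = n_perm, fwer = fwer, seed = seed, mode = mode,
                 engine = engine),
            class = "ClusterResult")
}

#' @method print ClusterResult
#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("Cluster-mass permutation test (%s, %d permutations, |t| > %.2f)\n",
              x$mode, x$n_perm, x$threshold))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  else cat("no supra-threshold clusters\n")
  invisible(x)
}

#' One-dimensional cluster test on per-participant difference curves
#'
#' Bins are chain-adjacent nodes; the observed statistic is the
#' one-sample t across participants per bin, and the null is built by
#' participant-level sign flips of the difference curves.
#'
#' @param curves participants x bins matrix of difference curves.
#' @param n_perm permutations.
#' @param threshold cluster-forming |t| threshold; NULL uses the 5%
#'   two-tailed critical value at df = participants - 1.
#' @param fwer family-wise error rate.
#' @param seed base seed.
#' @return `ClusterResult` (the `t` map is 1 x bins).
#' @export
density_cluster_test <- function(curves, n_perm = 2500, threshold = NULL,
                                 fwer = 0.05, seed = 1) {
  curves <- as.matrix(curves)
  P <- nrow(curves)
  if (P < 2) stop("at least 2 participants are required")
  if (is.null(threshold)) threshold <- stats::qt(0.975, P - 1)
  tfun <- function(m) {
    tv <- colMeans(m) / (apply(m, 2, stats::sd) / sqrt(nrow(m)))
    tv[!is.finite(tv)] <- 0
    matrix(tv, nrow = 1)
  }
  obs <- tfun(curves)
  ocl <- clusters_and_mass(obs, threshold, NULL)
  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed((seed + i) %% 2147483629L)
    flips <- sample(c(-1, 1), P, replace = TRUE)
    pcl <- clusters_and_mass(tfun(curves * flips), threshold, NULL)
    null_max[i] <- if (length(pcl$mass)) max(abs(pcl$mass)) else 0
  }
  clusters <- permutation_pvalues(ocl$mass, null_max, fwer)
  structure(list(t = obs, df = P - 1, threshold = threshold, id = ocl$id,
                 clusters = clusters, null_max = null_max, n_perm = n_perm,
                 fwer = fwer, seed = seed, mode = "density",
                 engine = "signflip"),
            class = "ClusterResult")
}

## all permutations of 1..n (test/oracle utility)
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

## cartesian product of within-cell permutations (exact-oracle utility;
## feasible only for tiny cells)
all_within_cell_permutations <- function(cell) {
  f <- factor(cell)
  sets <- lapply(levels(f), function(lev) {
    sel <- which(f == lev)
    lapply(perms_of(length(sel)), function(p) sel[p])
  })
  combos <- list(integer(0))
  for (s in sets) {
    combos <- unlist(lapply(combos, function(cmb)
      lapply(s, function(x) c(cmb, x))), recursive = FALSE)
  }
  ord <- order(unlist(lapply(levels(f), function(lev) which(f == lev))))
  lapply(combos, function(cmb) cmb[ord])
}
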