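## Multivariate catch-composition analyses: Hellinger transformation,
## principal component analysis with variance proportions and per-boat
## centroids/hulls, one-factor redundancy analysis with a permutation
## F-test, and a lag-1 autocorrelation check between consecutive netting
## walls.

as_species_matrix <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stopf("species matrix must be numeric")
  m
}

#' Hellinger transformation
#'
#' `h_ij = sqrt(y_ij / rowsum_i)`: the square root of row-normalised
#' abundances, which makes Euclidean-based ordination appropriate for
#' species data.  All-zero rows map to all-zero rows.
#'
#' @param x samples x species matrix (or data frame) of nonnegative
#'   abundances or biomasses.
#' @return transformed matrix; every non-zero row has unit Euclidean norm.
#' @export
hellinger <- function(x) {
  m <- as_species_matrix(x)
  if (any(m < 0)) stopf("species matrix must be nonnegative")
  rs <- rowSums(m)
  rs[rs == 0] <- 1  # all-zero rows stay all-zero
  sqrt(m / rs)
}

#' Principal component analysis of a species matrix
#'
#' Column-centered singular value decomposition: eigenvalues are squared
#' singular values divided by `n - 1` (sample variance normalisation) and
#' scores live in sample space.  For reproducible score files the axis sign
#' is fixed so that the largest-magnitude loading of each axis is positive.
#'
#' @param x samples x species matrix.
#' @param center center columns (default `TRUE`).
#' @return list of class `species_pca`: `scores`, `loadings`,
#'   `eigenvalues` (nonincreasing), `proportion_explained` (sums to 1).
#' @export
species_pca <- function(x, center = TRUE) {
  m <- as_species_matrix(x)
  if (nrow(m) < 2L) stopf("at least 2 rows are required")
  p <- stats::prcomp(m, center = center, scale. = FALSE)
  for (k in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, k]))
    if (p$rotation[i, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  eig <- p$sdev^2
  structure(list(scores = p$x, loadings = p$rotation, eigenvalues = eig,
                 proportion_explained = if (sum(eig) > 0) eig / sum(eig)
                                        else eig),
            class = "species_pca")
}

#' @export
print.species_pca <- function(x, ...) {
  k <- min(2L, length(x$eigenvalues))
  cat(sprintf("PCA of %d samples: first %d axes explain %s of the variance\n",
              nrow(x$scores), k,
              paste(sprintf("%.1f%%", 100 * x$proportion_explained[1:k]),
                    collapse = " + ")))
  invisible(x)
}

#' Group centroids and convex hulls in ordination space
#'
#' Per-group (typically per-boat) mean scores and convex-hull vertices on
#' the first two ordination axes, as used to judge whether sampled boats
#' are representative of a fleet.
#'
#' @param result a [species_pca()] result or a score matrix.
#' @param groups group label per sample (row).
#' @return list with `centroids` (data frame `group`, `axis1`, `axis2`) and
#'   `hulls` (named list of vertex matrices, in hull order).
#' @export
boat_summary <- function(result, groups) {
  scores <- if (inherits(result, "species_pca")) result$scores else
    as.matrix(result)
  if (nrow(scores) != length(groups))
    stopf("every sample must be mapped to a group")
  if (anyNA(groups)) stopf("every sample must be mapped to a group")
  g <- factor(as.character(groups))
  if (any(table(g) == 0L)) stopf("empty group")
  s2 <- scores[, 1:2, drop = FALSE]
  cent <- stats::aggregate(s2, by = list(group = g), FUN = mean)
  names(cent) <- c("group", "axis1", "axis2")
  hulls <- lapply(levels(g), function(lv) {
    pts <- s2[g == lv, , drop = FALSE]
    pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  })
  names(hulls) <- levels(g)
  list(centroids = cent, hulls = hulls)
}

## Constrained (between-group) and residual sums of squares of a
## column-centered matrix for a one-factor design; the permutation loop
## reuses this on relabelled rows.
rda_ss <- function(Yc, g) {
  tot <- sum(Yc^2)
  sums <- rowsum(Yc, g)
  fit <- sum(sums^2 / as.numeric(table(g)))
  c(fit = fit, res = tot - fit, tot = tot)
}

#' One-factor redundancy analysis
#'
#' Variance of the column-centered response projected onto the indicator
#' space of a single factor (equivalently, the between-group variance),
#' with `F = (constrained/df1) / (residual/df2)`, `df1 = levels - 1`,
#' `df2 = n - levels`.  The response is typically a Hellinger-transformed
#' species matrix.
#'
#' @param Y samples x species matrix.
#' @param groups factor level per sample (>= 2 levels present).
#' @return list of class `gear_rda`: `constrained_variance`,
#'   `residual_variance`, `total_variance` (sum of the first two), `df1`,
#'   `df2`, `statistic`.
#' @export
gear_rda <- function(Y, groups) {
  m <- as_species_matrix(Y)
  g <- factor(as.character(groups))
  if (nrow(m) != length(g)) stopf("one group label per row is required")
  if (nlevels(g) < 2L) stopf("at least 2 factor levels are required")
  n <- nrow(m)
  df1 <- nlevels(g) - 1L
  df2 <- n - nlevels(g)
  if (df2 < 1L) stopf("no residual degrees of freedom")
  Yc <- scale(m, center = TRUE, scale = FALSE)
  ss <- rda_ss(Yc, g)
  structure(list(constrained_variance = ss[["fit"]] / (n - 1),
                 residual_variance = ss[["res"]] / (n - 1),
                 total_variance = ss[["tot"]] / (n - 1),
                 df1 = df1, df2 = df2,
                 statistic = (ss[["fit"]] / df1) / (ss[["res"]] / df2)),
            class = "gear_rda")
}

#' @export
print.gear_rda <- function(x, ...) {
  cat(sprintf("RDA: variance explained %.4g, residual %.4g; F = %.4g (df = %d,%d)\n",
              x$constrained_variance, x$residual_variance, x$statistic,
              x$df1, x$df2))
  invisible(x)
}

#' Permutation F-test for the redundancy analysis
#'
#' Rows are relabelled by free permutation of the factor (the design that
#' deliberately ignores net-level structure) or, for sensitivity, by
#' permutation within blocks.  The p-value uses the add-one rule
#' `p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1)`.
#'
#' @param Y samples x species matrix.
#' @param groups factor level per sample.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed for reproducibility.
#' @param blocks optional blocking vector; labels are then permuted within
#'   each block only.
#' @return list of class `rda_perm`: the observed `gear_rda` plus `p_perm`,
#'   `n_perm`, `seed`.
#' @export
rda_permutation_test <- function(Y, groups, n_perm = 1000, seed = NULL,
                                 blocks = NULL) {
  if (n_perm < 99) stopf("at least 99 permutations are required")
  m <- as_species_matrix(Y)
  g <- factor(as.character(groups))
  obs <- gear_rda(m, g)
  Yc <- scale(m, center = TRUE, scale = FALSE)
  if (sum(Yc^2) == 0) {
    warnf("response has zero total variance; permutation test degenerate")
    return(structure(c(unclass(obs), list(p_perm = 1, n_perm = n_perm,
                                          seed = seed)),
                     class = "rda_perm"))
  }
  if (!is.null(seed)) set.seed(seed)
  df1 <- obs$df1
  df2 <- obs$df2
  n <- nrow(m)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    gp <- if (is.null(blocks)) g[sample.int(n)] else {
      idx <- seq_len(n)
      for (b in unique(blocks)) {
        sel <- which(blocks == b)
        idx[sel] <- sel[sample.int(length(sel))]
      }
      g[idx]
    }
    ss <- rda_ss(Yc, gp)
    Fp <- (ss[["fit"]] / df1) / (ss[["res"]] / df2)
    if (Fp >= obs$statistic) hits <- hits + 1L
  }
  structure(c(unclass(obs), list(p_perm = (1 + hits) / (n_perm + 1),
                                 n_perm = n_perm, seed = seed)),
            class = "rda_perm")
}

#' @export
print.rda_perm <- function(x, ...) {
  cat(sprintf("RDA permutation test: F = %.4g, p = %.4g (%d permutations)\n",
              x$statistic, x$p_perm, x$n_perm))
  invisible(x)
}

#' Lag-1 autocorrelation between consecutive netting walls
#'
#' Tests whether consecutive walls of a net are statistically dependent:
#' the statistic is the pooled Pearson correlation between consecutive-wall
#' value pairs within nets (nets with at least 3 walls contribute); the
#' null distribution permutes wall order independently within each net and
#' the p-value uses the add-one rule on the absolute statistic
#' (two-sided).
#'
#' @param values per-wall response values.
#' @param net net identifier per wall.
#' @param index wall position within net (defaults to input order).
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list of class `lag1_test`: `statistic`, `p_value`, `n_pairs`,
#'   `n_perm`.  A degenerate (constant) series yields `NA` statistic and
#'   `p = 1` with a warning.
#' @export
lag1_autocorrelation_test <- function(values, net, index = NULL,
                                      n_perm = 999, seed = NULL) {
  if (is.null(index)) index <- stats::ave(seq_along(values), net,
                                          FUN = seq_along)
  nets <- split(data.frame(v = values, i = index), net)
  nets <- lapply(nets, function(d) d$v[order(d$i)])
  nets <- nets[lengths(nets) >= 3L]
  if (length(nets) == 0L)
    stopf("no net with at least 3 walls")
  pairs_of <- function(series) {
    a <- unlist(lapply(series, function(v) v[-length(v)]))
    b <- unlist(lapply(series, function(v) v[-1]))
    cbind(a, b)
  }
  pool_cor <- function(series) {
    pr <- pairs_of(series)
    if (stats::sd(pr[, 1]) == 0 || stats::sd(pr[, 2]) == 0) NA_real_
    else stats::cor(pr[, 1], pr[, 2])
  }
  obs <- pool_cor(nets)
  n_pairs <- sum(lengths(nets) - 1L)
  if (is.na(obs)) {
    warnf("constant series: autocorrelation statistic undefined")
    return(structure(list(statistic = NA_real_, p_value = 1,
                          n_pairs = n_pairs, n_perm = n_perm),
                     class = "lag1_test"))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- lapply(nets, function(v) v[sample.int(length(v))])
    r <- pool_cor(perm)
    if (!is.na(r) && abs(r) >= abs(obs)) hits <- hits + 1L
  }
  structure(list(statistic = obs, p_value = (1 + hits) / (n_perm + 1),
                 n_pairs = n_pairs, n_perm = n_perm), class = "lag1_test")
}

#' @export
print.lag1_test <- function(x, ...) {
  cat(sprintf("Lag-1 wall autocorrelation: r = %.3f over %d pairs, p = %.4g\n",
              x$statistic, x$n_pairs, x$p_value))
  invisible(x)
}

#' Wall-by-species discard matrix
#'
#' Builds the samples x species biomass matrix for ordination from
#' processed catch items (discards attributable to a wall).
#'
#' @param walls wall table.
#' @param items processed items (see [process_items()]).
#' @return numeric matrix with one row per wall (including empty walls) and
#'   one column per discarded species.
#' @export
wall_species_matrix <- function(walls, items) {
  items <- items[items$fate == "DISCARD" & items$wall_id != NET_LEVEL, ,
                 drop = FALSE]
  species <- sort(unique(items$species))
  m <- matrix(0, nrow = nrow(walls), ncol = length(species),
              dimnames = list(walls$wall_id, species))
  if (nrow(items) > 0L) {
    s <- tapply(items$weight_kg, list(items$wall_id, items$species), sum)
    s[is.na(s)] <- 0
    m[rownames(s), colnames(s)] <- s
  }
  m
}
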