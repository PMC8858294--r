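#' Exact Tukey halfspace depth of a point in a 2-D cloud
#'
#' The halfspace (Tukey) depth of a point is the minimum, over all closed
#' halfplanes whose boundary passes through the point, of the number of cloud
#' points contained in the halfplane. The minimum is always attained by a
#' halfplane whose boundary passes through a cloud point, so the exact value
#' is found by enumerating the directions normal to point-to-point segments
#' (O(n^2), exact for n up to a few thousand). Points coincident with the
#' query point lie in every closed halfplane and always count. Degenerate
#' (collinear) clouds are handled by the same enumeration.
#'
#' @param point Numeric length-2, the query point.
#' @param cloud Two-column numeric matrix or data frame of cloud points
#'   (n >= 3).
#' @return Integer depth (count of cloud points; divide by `nrow(cloud)` for
#'   the fractional depth).
#' @export
halfspace_depth <- function(point, cloud) {
  cloud <- as.matrix(cloud)
  stopifnot(length(point) == 2L, ncol(cloud) == 2L, nrow(cloud) >= 3L)
  z <- sweep(cloud, 2, as.numeric(point))
  r <- sqrt(rowSums(z^2))
  scale <- max(r, 1)
  on_point <- r < 1e-12 * scale
  n0 <- sum(on_point)
  z <- z[!on_point, , drop = FALSE]
  if (nrow(z) == 0) return(as.integer(n0))
  theta <- atan2(z[, 2], z[, 1])
  # The count of a closed halfplane with normal direction phi is piecewise
  # constant in phi, changing only at the critical angles theta_j +/- pi/2.
  # Evaluating at every critical angle and at every arc midpoint between
  # consecutive critical angles therefore covers all attainable counts.
  crit <- sort(unique(c(theta + pi / 2, theta - pi / 2) %% (2 * pi)))
  mids <- (crit + diff(c(crit, crit[1] + 2 * pi)) / 2)
  cand <- c(crit, mids)
  tol <- 1e-12 * scale
  counts <- vapply(cand, function(phi) {
    u <- c(cos(phi), sin(phi))
    sum(z %*% u >= -tol)
  }, numeric(1))
  as.integer(min(counts) + n0)
}

# --- Tukey depth contours (exact, 2-D) -------------------------------------

# Sutherland-Hodgman clip of a convex polygon by the halfplane {z: u.z <= c0}.
clip_halfplane <- function(poly, u, c0) {
  n <- nrow(poly)
  out <- NULL
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1 else i + 1, ]
    da <- sum(u * a) - c0
    db <- sum(u * b) - c0
    if (da <= 1e-12) out <- rbind(out, a)
    if ((da < -1e-12 && db > 1e-12) || (da > 1e-12 && db < -1e-12)) {
      t <- da / (da - db)
      out <- rbind(out, a + t * (b - a))
    }
  }
  out
}

# Exact depth region {z in R^2: depth(z) >= k} as a convex polygon (or NULL
# when empty). The region is the intersection, over all directions normal to
# point pairs, of the halfplanes bounded by the k-th largest projection.
tukey_region <- function(pts, k) {
  n <- nrow(pts)
  dirs <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- pts[j, ] - pts[i, ]
      if (sum(v^2) < 1e-20) next
      u <- c(-v[2], v[1]) / sqrt(sum(v^2))
      dirs <- rbind(dirs, u, -u)
    }
  }
  if (is.null(dirs)) return(NULL)
  m <- max(abs(pts)) * 10 + 10
  poly <- rbind(c(-m, -m), c(m, -m), c(m, m), c(-m, m))
  for (r in seq_len(nrow(dirs))) {
    u <- dirs[r, ]
    proj <- sort(pts %*% u, decreasing = TRUE)
    poly <- clip_halfplane(poly, u, proj[k] + 1e-12)
    if (is.null(poly) || nrow(poly) < 3) return(NULL)
  }
  poly
}

polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# distance from `centre` to the boundary of convex polygon `H` along
# direction angle `phi` (0 when the ray never crosses, e.g. degenerate H)
radial_extent <- function(H, centre, phi) {
  u <- c(cos(phi), sin(phi))
  m <- nrow(H)
  rmax <- 0
  for (i in seq_len(m)) {
    a <- H[i, ] - centre
    b <- H[if (i == m) 1 else i + 1, ] - centre
    mm <- cbind(u, a - b)
    if (abs(det(mm)) < 1e-14) next
    s <- tryCatch(solve(mm, a), error = function(e) c(-1, -1))
    if (s[2] >= -1e-9 && s[2] <= 1 + 1e-9 && s[1] > 0) rmax <- max(rmax, s[1])
  }
  rmax
}

#' Bagplot outlier identification
#'
#' A bivariate analogue of the boxplot built on Tukey halfspace depth. The
#' *bag* is the depth region holding half of the points, obtained by radial
#' interpolation between the two consecutive exact depth contours whose
#' point counts bracket `n/2`, about the Tukey median (the centroid of the
#' deepest contour). The *fence* is the bag inflated by `fence_factor` about
#' the Tukey median; points beyond the fence are flagged as outliers.
#'
#' @param data Data frame of paired observations.
#' @param x,y Column names (strings) of the two coordinates.
#' @param labels Optional column name holding point labels.
#' @param fence_factor Inflation factor of the bag (default 3, the usual
#'   bagplot convention).
#' @param standardize Compute depth on z-scored coordinates (default FALSE).
#'   Recommended whenever the two axes have incomparable scales.
#' @return A list of class `bagplot_result` with elements `points` (a tibble
#'   with `label`, `x`, `y`, `depth`, `in_bag`, `outlier`), `bag_hull` and
#'   `fence_hull` (coordinate tibbles on the original scale), `outliers`
#'   (label vector), `fence_factor`.
#' @export
bagplot_outliers <- function(data, x, y, labels = NULL, fence_factor = 3,
                             standardize = FALSE) {
  xv <- pull_col(data, x)
  yv <- pull_col(data, y)
  lab <- if (!is.null(labels)) as.character(data[[labels]]) else
    as.character(seq_along(xv))
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]; lab <- lab[keep]
  n <- length(xv)
  if (n < 5) stop("bagplot requires at least 5 complete pairs", call. = FALSE)
  sx <- if (standardize) stats::sd(xv) else 1
  sy <- if (standardize) stats::sd(yv) else 1
  mx <- if (standardize) mean(xv) else 0
  my <- if (standardize) mean(yv) else 0
  pts <- cbind((xv - mx) / sx, (yv - my) / sy)
  depth <- vapply(seq_len(n),
                  function(i) halfspace_depth(pts[i, ], pts), integer(1))

  # Tukey median: centroid of the deepest non-empty depth contour
  deepest <- NULL
  kk <- max(depth)
  while (is.null(deepest) && kk >= 1) {
    deepest <- tukey_region(pts, kk)
    kk <- kk - 1
  }
  if (is.null(deepest)) {
    stop("bagplot undefined for degenerate (collinear) data", call. = FALSE)
  }
  centre <- polygon_centroid(deepest)

  # bracket n/2 between consecutive depth contours and interpolate radially
  cnt <- vapply(seq_len(max(depth)), function(k) sum(depth >= k), integer(1))
  k_out <- max(which(cnt >= n / 2))
  r_out_poly <- tukey_region(pts, k_out)
  r_in_poly <- if (k_out + 1 <= max(depth)) tukey_region(pts, k_out + 1)
  if (is.null(r_in_poly)) {
    r_in_poly <- r_out_poly
    n_in <- cnt[k_out]
  } else {
    n_in <- cnt[k_out + 1]
  }
  lambda <- if (cnt[k_out] == n_in) 0 else (n / 2 - n_in) / (cnt[k_out] - n_in)
  bag_radius <- function(phi) {
    (1 - lambda) * radial_extent(r_in_poly, centre, phi) +
      lambda * radial_extent(r_out_poly, centre, phi)
  }

  rad <- sqrt(rowSums(sweep(pts, 2, centre)^2))
  ang <- atan2(pts[, 2] - centre[2], pts[, 1] - centre[1])
  r_bag_at <- vapply(ang, bag_radius, numeric(1))
  in_bag <- rad <= r_bag_at + 1e-9
  outlier <- rad > fence_factor * r_bag_at + 1e-9

  phis <- seq(0, 2 * pi, length.out = 73)[-73]
  r_phi <- vapply(phis, bag_radius, numeric(1))
  unscale <- function(m) tibble::tibble(x = m[, 1] * sx + mx,
                                        y = m[, 2] * sy + my)
  bag_poly <- sweep(cbind(cos(phis), sin(phis)) * r_phi, 2, centre, FUN = "+")
  fence_poly <- sweep(cbind(cos(phis), sin(phis)) * (fence_factor * r_phi),
                      2, centre, FUN = "+")
  structure(
    list(
      points = tibble::tibble(label = lab, x = xv, y = yv,
                              depth = depth, in_bag = in_bag,
                              outlier = outlier),
      bag_hull = unscale(bag_poly),
      fence_hull = unscale(fence_poly),
      outliers = lab[outlier],
      fence_factor = fence_factor,
      standardized = standardize
    ),
    class = "bagplot_result"
  )
}

#' @export
print.bagplot_result <- function(x, ...) {
  cat("<bagplot_result> n =", nrow(x$points),
      "| fence factor", x$fence_factor,
      if (x$standardized) "| standardized axes" else "", "\n")
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  } else cat("  no outliers\n")
  invisible(x)
}

#' @export
autoplot.bagplot_result <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(data = object$fence_hull, fill = NA,
                          colour = "grey70", linetype = 2) +
    ggplot2::geom_polygon(data = object$bag_hull, fill = "grey85",
                          colour = "grey50", alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red")) +
    ggplot2::theme_minimal()
}

#' Spearman rank correlation with small-sample p-values
#'
#' Rank correlation with midrank ties. The p-value is computed from the exact
#' permutation distribution for small samples without ties (via
#' [stats::cor.test()]'s exact method) and from the asymptotic t
#' approximation otherwise; `p_method` selects the behaviour.
#'
#' @param data Data frame of paired observations; rows with a missing value
#'   in either column are dropped.
#' @param x,y Column names (strings).
#' @param labels Optional label column name.
#' @param p_method `"exact"` (exact permutation null, used for n <= 10 when
#'   there are no ties; falls back to asymptotic with a message otherwise)
#'   or `"asymptotic"`.
#' @param exclude Optional character vector of labels to drop before the
#'   analysis (e.g. bagplot outliers).
#' @return A list of class `correlation_result` with `rho`, `p_value`,
#'   `n_used`, `excluded`, `p_method_used`.
#' @export
spearman_cor <- function(data, x, y, labels = NULL,
                         p_method = c("exact", "asymptotic"),
                         exclude = NULL) {
  p_method <- match.arg(p_method)
  xv <- pull_col(data, x)
  yv <- pull_col(data, y)
  lab <- if (!is.null(labels)) as.character(data[[labels]]) else
    as.character(seq_along(xv))
  keep <- is.finite(xv) & is.finite(yv) & !(lab %in% exclude)
  xv <- xv[keep]; yv <- yv[keep]; lab <- lab[keep]
  n <- length(xv)
  if (n < 4) stop("need at least 4 complete pairs after exclusions",
                  call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("constant x or y: Spearman correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rank(xv), rank(yv))
  has_ties <- anyDuplicated(xv) > 0 || anyDuplicated(yv) > 0
  use_exact <- p_method == "exact" && n <= 10 && !has_ties
  if (p_method == "exact" && !use_exact) {
    message("exact permutation p unavailable (ties or n > 10); ",
            "using asymptotic approximation")
  }
  p <- suppressWarnings(
    stats::cor.test(xv, yv, method = "spearman", exact = use_exact)$p.value
  )
  structure(
    list(rho = rho, p_value = p, n_used = n,
         excluded = exclude %||% character(0),
         p_method_used = if (use_exact) "exact" else "asymptotic",
         labels = lab),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.3f, p = %.4g (%s), n = %d\n",
              x$rho, x$p_value, x$p_method_used, x$n_used))
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value, n_used = x$n_used,
                 p_method = x$p_method_used,
                 excluded = paste(x$excluded, collapse = ";"))
}

#' Ordinary least squares with a pointwise confidence band
#'
#' @param data Data frame; rows with missing values dropped.
#' @param x,y Column names (strings).
#' @param confidence Confidence level (default 0.95).
#' @param through_origin Constrain the intercept to zero.
#' @param n_grid Number of grid points for the band.
#' @return A list of class `linear_fit` with `slope`, `intercept` (0 when
#'   through the origin), their standard errors, the underlying `lm`, and
#'   `band` (tibble `x`, `fit`, `lower`, `upper`).
#' @export
linear_fit_ci <- function(data, x, y, confidence = 0.95,
                          through_origin = FALSE, n_grid = 100) {
  xv <- pull_col(data, x)
  yv <- pull_col(data, y)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(xv) == 0) stop("rank-deficient fit: x is constant",
                               call. = FALSE)
  df <- data.frame(x = xv, y = yv)
  fit <- if (through_origin) stats::lm(y ~ x + 0, data = df)
  else stats::lm(y ~ x, data = df)
  grid <- data.frame(x = seq(min(xv), max(xv), length.out = n_grid))
  band <- stats::predict(fit, newdata = grid, interval = "confidence",
                         level = confidence)
  cf <- summary(fit)$coefficients
  structure(
    list(slope = cf["x", "Estimate"], slope_se = cf["x", "Std. Error"],
         intercept = if (through_origin) 0 else cf["(Intercept)", "Estimate"],
         intercept_se = if (through_origin) 0
         else cf["(Intercept)", "Std. Error"],
         confidence = confidence, lm = fit,
         band = tibble::tibble(x = grid$x, fit = band[, "fit"],
                               lower = band[, "lwr"], upper = band[, "upr"]),
         data = tibble::as_tibble(df)),
    class = "linear_fit"
  )
}

#' @export
tidy.linear_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(x$intercept_se, x$slope_se))
}

#' @export
glance.linear_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 confidence = x$confidence, n = nrow(x$data))
}

#' @export
autoplot.linear_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(data = object$band,
                         ggplot2::aes(x = .data$x, y = .data$fit,
                                      ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(data = object$band,
                       ggplot2::aes(x = .data$x, y = .data$fit)) +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}

#' Principal component analysis with a deterministic sign convention
#'
#' Centred (and by default scaled) PCA of the complete cases, wrapping
#' [stats::prcomp()]. Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible across
#' platforms.
#'
#' @param data Data frame; only numeric columns are used and only complete
#'   cases are kept.
#' @param scale Scale columns to unit variance (default TRUE).
#' @param n_components Number of components to return (default all).
#' @return A list of class `pca_result` with `scores`, `loadings` (tibbles)
#'   and `variance_explained` (fractions).
#' @export
pca_scores <- function(data, scale = TRUE, n_components = NULL) {
  num <- data[vapply(data, is.numeric, logical(1))]
  cc <- stats::complete.cases(num)
  num <- num[cc, , drop = FALSE]
  n_components <- n_components %||% min(dim(num))
  if (nrow(num) < n_components) {
    stop("fewer complete observations than requested components",
         call. = FALSE)
  }
  pc <- stats::prcomp(num, center = TRUE, scale. = scale)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  structure(
    list(
      scores = tibble::as_tibble(as.data.frame(sco)),
      loadings = tibble::as_tibble(as.data.frame(rot), rownames = "variable"),
      variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
      n_used = nrow(num)
    ),
    class = "pca_result"
  )
}

#' Correlation analysis with bagplot outlier exclusion
#'
#' The full robust-correlation workflow used for the thermodynamics/activity
#' comparisons: flag bivariate outliers with a bagplot (on standardized
#' coordinates by default, since binding constants and activities live on
#' different scales), exclude them, then compute the Spearman rank
#' correlation and an ordinary least-squares fit with a confidence band on
#' the retained points.
#'
#' @param data Data frame of paired observations.
#' @param x,y Column names (strings).
#' @param labels Optional label column name.
#' @param fence_factor,standardize Passed to [bagplot_outliers()].
#' @param p_method Passed to [spearman_cor()].
#' @param bagplot Set to FALSE to skip outlier exclusion.
#' @return A list of class `robust_correlation` with elements `bagplot`
#'   (`NULL` when skipped), `correlation` ([spearman_cor()] result) and
#'   `linear_fit` ([linear_fit_ci()] result).
#' @export
correlate_robust <- function(data, x, y, labels = NULL, fence_factor = 3,
                             standardize = TRUE,
                             p_method = c("exact", "asymptotic"),
                             bagplot = TRUE) {
  xv <- pull_col(data, x)
  yv <- pull_col(data, y)
  keep <- is.finite(xv) & is.finite(yv)
  cc <- data[keep, , drop = FALSE]
  bp <- NULL
  excluded <- character(0)
  if (bagplot) {
    bp <- bagplot_outliers(cc, x, y, labels = labels,
                           fence_factor = fence_factor,
                           standardize = standardize)
    excluded <- bp$outliers
  }
  cor_res <- spearman_cor(cc, x, y, labels = labels, p_method = p_method,
                          exclude = excluded)
  lab <- if (!is.null(labels)) as.character(cc[[labels]]) else
    as.character(seq_len(nrow(cc)))
  lf <- linear_fit_ci(cc[!(lab %in% excluded), , drop = FALSE], x, y)
  structure(list(bagplot = bp, correlation = cor_res, linear_fit = lf),
            class = "robust_correlation")
}

#' @export
print.robust_correlation <- function(x, ...) {
  print(x$correlation)
  cat(sprintf("  linear fit: slope %.4g +/- %.2g\n",
              x$linear_fit$slope, x$linear_fit$slope_se))
  invisible(x)
}
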