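# Great-circle geometry, spatial thinning and the autocorrelation screens
# used to draw spatially independent locality subsets.

EARTH_RADIUS_KM <- 6371

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(lon < -180 | lon >= 180) || any(lat < -90 | lat > 90))
    stop("coordinates out of range: lon must be in [-180, 180), lat in [-90, 90]",
         call. = FALSE)
  invisible(NULL)
}

#' Great-circle (haversine) distance in kilometres
#'
#' Distance between two points on a sphere of radius 6,371 km, the radius
#' conventionally used for reef-locality distances.
#'
#' @param a,b Numeric vectors `c(lon, lat)` in degrees, or two-column
#'   matrices of such points (recycled row-wise).
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(c(0, 0), c(0, 90))  # quarter circumference, ~10,007.5 km
#' @export
haversine_km <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  check_lonlat(a[, 1], a[, 2])
  check_lonlat(b[, 1], b[, 2])
  drop(geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM))
}

# Full pairwise haversine distance matrix (km) for a two-column lon/lat matrix.
pairwise_km <- function(lonlat) {
  lonlat <- as.matrix(lonlat)
  n <- nrow(lonlat)
  d <- matrix(0, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    ji <- (i + 1L):n
    d[i, ji] <- geosphere::distHaversine(lonlat[i, , drop = FALSE],
                                         lonlat[ji, , drop = FALSE],
                                         r = EARTH_RADIUS_KM)
  }
  d + t(d)
}

#' Greedy spatial thinning by a minimum-distance rule
#'
#' Visits localities in a seeded random order, retaining each one only if it
#' lies strictly more than `threshold_km` from every locality already
#' retained. This is the subset sampler used to control spatial
#' autocorrelation before model fitting.
#'
#' @param localities Data frame with `lon` and `lat` columns (and optionally
#'   `id`), or a two-column lon/lat matrix.
#' @param threshold_km Minimum separation in kilometres (> 0).
#' @param seed Integer seed governing the visiting order.
#' @return An object of class `reef_subset`: a list with `indices` (rows
#'   retained, in inclusion order), `ids`, `min_pairwise_km`, `threshold_km`
#'   and `seed`.
#' @export
thin_by_distance <- function(localities, threshold_km, seed = 1L) {
  assert_number(threshold_km, "threshold_km", lower = 1e-9)
  lonlat <- extract_lonlat(localities)
  n <- nrow(lonlat)
  if (n == 0L) stop("no localities to thin", call. = FALSE)
  ord <- with_seed(seed, sample.int(n))
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L) { keep <- i; next }
    d <- geosphere::distHaversine(lonlat[i, , drop = FALSE],
                                  lonlat[keep, , drop = FALSE],
                                  r = EARTH_RADIUS_KM)
    if (all(d > threshold_km)) keep <- c(keep, i)
  }
  ids <- if (is.data.frame(localities) && !is.null(localities$id))
    localities$id[keep] else keep
  min_d <- if (length(keep) > 1L) min(pairwise_km(lonlat[keep, , drop = FALSE])[
    upper.tri(diag(length(keep)))]) else Inf
  structure(list(indices = keep, ids = ids, min_pairwise_km = min_d,
                 threshold_km = threshold_km, seed = seed,
                 independence_p = NA_real_, accepted = NA),
            class = "reef_subset")
}

#' @export
print.reef_subset <- function(x, ...) {
  cat("Spatially thinned subset:", length(x$indices), "localities\n")
  cat("  min pairwise distance:", format(x$min_pairwise_km, digits = 5),
      "km (threshold", x$threshold_km, "km)\n")
  if (!is.na(x$independence_p))
    cat("  independence test p =", format(x$independence_p, digits = 4),
        if (isTRUE(x$accepted)) "(accepted)" else "(rejected)", "\n")
  invisible(x)
}

extract_lonlat <- function(localities) {
  if (is.data.frame(localities)) {
    if (!all(c("lon", "lat") %in% names(localities)))
      stop("`localities` must have lon and lat columns", call. = FALSE)
    m <- as.matrix(localities[, c("lon", "lat")])
  } else m <- as.matrix(localities)
  check_lonlat(m[, 1], m[, 2])
  m
}

#' Distance-band neighbour graph
#'
#' Binary symmetric adjacency in which two localities are neighbours when
#' their haversine distance is at most `band_km`. The default band for
#' join-count screening is twice the thinning threshold, so every retained
#' point can still have neighbours at the thinned scale.
#'
#' @param localities Data frame with lon/lat or a lon/lat matrix.
#' @param band_km Neighbourhood radius in kilometres.
#' @return A binary n-by-n adjacency matrix with zero diagonal.
#' @export
distance_band_graph <- function(localities, band_km) {
  assert_number(band_km, "band_km", lower = 1e-9)
  d <- pairwise_km(extract_lonlat(localities))
  w <- (d <= band_km) * 1
  diag(w) <- 0
  w
}

#' Inverse-distance spatial weights
#'
#' @param localities Data frame with lon/lat or a lon/lat matrix.
#' @return Symmetric matrix of 1/d_km weights with zero diagonal. Coincident
#'   points (zero distance) are an error; deduplicate first.
#' @export
inverse_distance_weights <- function(localities) {
  d <- pairwise_km(extract_lonlat(localities))
  off <- d[upper.tri(d)]
  if (any(off == 0))
    stop("coincident localities: thin at a small distance before weighting",
         call. = FALSE)
  w <- 1 / d
  diag(w) <- 0
  w
}

# Falling factorial n (n-1) ... (n-k+1).
ffact <- function(n, k) prod(n - seq_len(k) + 1)

#' Join-count test of spatial randomness for categorical labels
#'
#' Counts same-class and cross-class neighbour joins on a binary adjacency
#' graph and compares them with their expectation under random relabelling
#' without replacement (non-free sampling: the class counts are held fixed
#' and positions permuted). Same-class z-scores and two-sided normal
#' p-values follow the classical randomisation moments; they can be
#' cross-checked against a label-permutation null with `n_perm`.
#'
#' @param labels Factor or vector of class labels, one per graph node.
#' @param graph Binary symmetric adjacency matrix (e.g. from
#'   [distance_band_graph()]).
#' @param n_perm If > 0, also compute permutation p-values from this many
#'   random relabellings.
#' @param seed Seed for the permutation null.
#' @return An object of class `join_count_result`: a data frame of class
#'   pairs with observed/expected counts, variances, z and p, plus
#'   `degenerate` flag and `n_joins_total`.
#' @export
join_count_test <- function(labels, graph, n_perm = 0L, seed = 1L) {
  labels <- as.factor(labels)
  w <- as.matrix(graph)
  n <- length(labels)
  if (nrow(w) != n || ncol(w) != n)
    stop("graph dimension does not match labels", call. = FALSE)
  w <- (w != 0) * 1
  diag(w) <- 0
  w <- pmax(w, t(w))  # enforce symmetry

  classes <- levels(labels)
  counts <- table(labels)
  S0 <- sum(w)
  deg <- rowSums(w)
  S1 <- 2 * S0          # binary symmetric weights
  S2 <- 4 * sum(deg^2)
  degenerate <- length(classes) < 2L || S0 == 0

  ind <- lapply(classes, function(cl) as.numeric(labels == cl))
  names(ind) <- classes

  join_count <- function(zi, zj) sum(w * outer(zi, zj)) / 2

  rows <- list()
  for (a in seq_along(classes)) {
    za <- ind[[a]]; na <- counts[[a]]
    obs <- join_count(za, za)
    e <- S0 / 2 * ffact(na, 2) / ffact(n, 2)
    ej2 <- (S1 * ffact(na, 2) / ffact(n, 2) +
            (S2 - 2 * S1) * ffact(na, 3) / ffact(n, 3) +
            (S0^2 + S1 - S2) * ffact(na, 4) / ffact(n, 4)) / 4
    v <- max(ej2 - e^2, 0)
    rows[[length(rows) + 1L]] <- data.frame(
      class_a = classes[a], class_b = classes[a], same_class = TRUE,
      observed = obs, expected = e, variance = v)
  }
  if (length(classes) > 1L) {
    for (a in seq_len(length(classes) - 1L)) for (b in (a + 1L):length(classes)) {
      za <- ind[[a]]; zb <- ind[[b]]
      na <- counts[[a]]; nb <- counts[[b]]
      obs <- sum(w * outer(za, zb)) / 2 + sum(w * outer(zb, za)) / 2
      e <- S0 * na * nb / ffact(n, 2)
      ej2 <- (2 * S1 * na * nb / ffact(n, 2) +
              (S2 - 2 * S1) * na * nb * (na + nb - 2) / ffact(n, 3) +
              4 * (S0^2 + S1 - S2) * ffact(na, 2) * ffact(nb, 2) / ffact(n, 4)) / 4
      v <- max(ej2 - e^2, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        class_a = classes[a], class_b = classes[b], same_class = FALSE,
        observed = obs, expected = e, variance = v)
    }
  }
  res <- do.call(rbind, rows)
  res$z <- ifelse(res$variance > 0, (res$observed - res$expected) / sqrt(res$variance), NA_real_)
  res$p <- ifelse(is.na(res$z), NA_real_, 2 * pnorm(-abs(res$z)))

  if (n_perm > 0L && !degenerate) {
    perm_obs <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        lp <- sample(labels)
        indp <- lapply(classes, function(cl) as.numeric(lp == cl))
        out <- numeric(nrow(res))
        k <- 0L
        for (a in seq_along(classes)) {
          k <- k + 1L
          out[k] <- join_count(indp[[a]], indp[[a]])
        }
        if (length(classes) > 1L)
          for (a in seq_len(length(classes) - 1L)) for (b in (a + 1L):length(classes)) {
            k <- k + 1L
            out[k] <- sum(w * outer(indp[[a]], indp[[b]])) / 2 +
                      sum(w * outer(indp[[b]], indp[[a]])) / 2
          }
        out
      }, numeric(nrow(res)))
    })
    perm_obs <- matrix(perm_obs, nrow = nrow(res))
    res$p_perm <- vapply(seq_len(nrow(res)), function(i) {
      dev <- abs(perm_obs[i, ] - res$expected[i])
      (sum(dev >= abs(res$observed[i] - res$expected[i])) + 1) / (n_perm + 1)
    }, numeric(1))
    # mid-p: half-weight on permutations exactly as deviant as observed --
    # the discreteness-corrected analogue of the continuous normal p
    res$p_perm_mid <- vapply(seq_len(nrow(res)), function(i) {
      obs_dev <- abs(res$observed[i] - res$expected[i])
      dev <- abs(perm_obs[i, ] - res$expected[i])
      (sum(dev > obs_dev) + 0.5 * sum(dev == obs_dev)) / n_perm
    }, numeric(1))
  }

  structure(list(table = res, degenerate = degenerate,
                 n_joins_total = S0 / 2, class_counts = as.vector(counts),
                 classes = classes),
            class = "join_count_result")
}

#' @export
print.join_count_result <- function(x, ...) {
  cat("Join-count test (non-free sampling),", x$n_joins_total, "joins total\n")
  if (x$degenerate) cat("  [degenerate: fewer than two classes or no edges]\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# Screening p-value of a join-count result. With two classes the total
# same-class join count is S0/2 minus the cross-class count, so its
# randomisation p equals the cross-class one -- a single calibrated test.
# With more classes, fall back on the smallest same-class p (conservative
# screen, anti-conservative as a test). NA when degenerate.
join_count_p <- function(jc) {
  if (jc$degenerate) return(NA_real_)
  if (length(jc$classes) == 2L) return(jc$table$p[!jc$table$same_class][1])
  p <- jc$table$p[jc$table$same_class]
  if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE)
}

#' Moran's I with randomisation or permutation inference
#'
#' Computes Moran's I for a continuous variable under a spatial weights
#' matrix, with the expectation and variance of the randomisation
#' (permutation) null in closed form, and optionally an explicit
#' label-permutation p-value.
#'
#' @param values Numeric vector (length >= 3, non-constant).
#' @param weights Spatial weights matrix (binary adjacency or
#'   inverse-distance); the diagonal is ignored.
#' @param n_perm If > 0, also compute a permutation p-value.
#' @param seed Seed for the permutation null.
#' @return An object of class `moran_result` with `I`, `expected`,
#'   `variance`, `z`, `p` (two-sided normal) and optionally `p_perm`.
#' @export
morans_i <- function(values, weights, n_perm = 0L, seed = 1L) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3L) stop("Moran's I needs at least 3 observations", call. = FALSE)
  if (sd(x) == 0) stop("Moran's I undefined for constant values", call. = FALSE)
  w <- as.matrix(weights)
  diag(w) <- 0
  if (sum(w) == 0) stop("weights matrix has no non-zero entries", call. = FALSE)

  S0 <- sum(w)
  S1 <- sum((w + t(w))^2) / 2
  S2 <- sum((rowSums(w) + colSums(w))^2)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  b2 <- (sum(z^4) / n) / m2^2

  I_of <- function(zz) (n / S0) * sum(w * outer(zz, zz)) / sum(zz^2)
  I <- I_of(z)
  EI <- -1 / (n - 1)
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
          ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zstat <- (I - EI) / sqrt(varI)
  p <- 2 * pnorm(-abs(zstat))

  p_perm <- NULL
  if (n_perm > 0L) {
    Ip <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(i) I_of(sample(z)), numeric(1)))
    p_perm <- (sum(abs(Ip - EI) >= abs(I - EI)) + 1) / (n_perm + 1)
  }
  structure(list(I = I, expected = EI, variance = varI, z = zstat, p = p,
                 p_perm = p_perm, n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E = %.4f, sd = %.4f), z = %.3f, p = %.4g\n",
              x$I, x$expected, sqrt(x$variance), x$z, x$p))
  if (!is.null(x$p_perm)) cat(sprintf("  permutation p = %.4g\n", x$p_perm))
  invisible(x)
}

#' Draw a spatially independent locality subset
#'
#' Repeats the greedy thinning with fresh random orders until the retained
#' labels pass the requested independence screen (join-count for a binary
#' status, Moran's I for a continuous response) at `alpha`, i.e. until the
#' test is non-significant. Subsets failing the screen are discarded and the
#' sampler retries, mirroring a replicate-until-valid design.
#'
#' @param localities Data frame with lon/lat (and optionally `id`).
#' @param labels Binary/categorical labels (join_count) or numeric values
#'   (morans_i), one per locality.
#' @param threshold_km Thinning distance.
#' @param test `"join_count"` or `"morans_i"`.
#' @param alpha Significance level of the screen (default 0.05).
#' @param max_tries Maximum attempts before failing.
#' @param seed Integer seed; attempt k uses a seed derived from it.
#' @param band_km Neighbour band for the join-count graph; defaults to twice
#'   the thinning threshold.
#' @return A `reef_subset` with `independence_p`, `accepted = TRUE` and
#'   `attempts` filled in.
#' @export
sample_independent_subset <- function(localities, labels, threshold_km,
                                      test = c("join_count", "morans_i"),
                                      alpha = 0.05, max_tries = 100L, seed = 1L,
                                      band_km = 2 * threshold_km) {
  test <- match.arg(test)
  if (max_tries < 1L)
    stop(sprintf("no valid subset: max_tries = %d exhausted before any attempt (alpha = %g)",
                 max_tries, alpha), call. = FALSE)
  if (length(labels) != nrow(localities))
    stop("labels must match localities", call. = FALSE)
  for (k in seq_len(max_tries)) {
    sub <- thin_by_distance(localities, threshold_km,
                            seed = derive_seed(seed, paste0("thin", k)))
    idx <- sub$indices
    lab <- labels[idx]
    p <- NA_real_
    if (test == "join_count") {
      if (length(unique(lab)) >= 2L) {
        g <- distance_band_graph(localities[idx, , drop = FALSE], band_km)
        if (sum(g) > 0) p <- join_count_p(join_count_test(lab, g))
      }
    } else {
      if (length(idx) >= 3L && sd(as.numeric(lab)) > 0) {
        w <- inverse_distance_weights(localities[idx, , drop = FALSE])
        p <- morans_i(as.numeric(lab), w)$p
      }
    }
    accepted <- is.na(p) || p > alpha
    if (accepted) {
      sub$independence_p <- p
      sub$accepted <- TRUE
      sub$attempts <- k
      sub$test <- test
      return(sub)
    }
  }
  stop(sprintf("no subset passed the %s screen at alpha = %g within %d tries",
               test, alpha, max_tries), call. = FALSE)
}
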