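# Shared fixtures and independent oracles, built in code at test time.

# Reduced BRT settings keeping tree-count selection meaningful but fast.
fast_brt <- function(loss = "bernoulli", ...) {
  brt_config(learning_rate = 0.05, bag_fraction = 0.5, tree_complexity = 3,
             tree_range = c(50, 300), tree_step = 10, n_folds = 3,
             loss = loss, ...)
}

# A hand-assembled reef grid for unit tests that need exact control over
# alert histories and DHW series.
toy_grid <- function(lon, lat, restored,
                     alerts_l1 = NULL, alerts_l2 = NULL, dhw = NULL) {
  n <- length(lon)
  ay <- 1986:2021; dy <- 2015:2100
  zero <- function(nc) matrix(0L, n, nc)
  a1 <- alerts_l1 %||% zero(length(ay))
  a2 <- alerts_l2 %||% zero(length(ay))
  dh <- dhw %||% zero(length(dy))
  dimnames(a1) <- dimnames(a2) <- list(seq_len(n), ay)
  dimnames(dh) <- list(seq_len(n), dy)
  loc <- data.frame(id = seq_len(n), lon = lon, lat = lat,
                    restored = restored,
                    gravity = seq_len(n), remoteness = rev(seq_len(n)),
                    impact_mean = 1, impact_trend = 0, coral_richness = 10L)
  structure(list(localities = loc, alerts_l1 = a1, alerts_l2 = a2,
                 alert_years = ay, dhw = dh, dhw_years = dy,
                 config = sim_config()),
            class = "reef_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent spherical-law-of-cosines distance (km), for cross-checking
# the haversine implementation.
slc_km <- function(a, b) {
  to_rad <- pi / 180
  la1 <- a[2] * to_rad; la2 <- b[2] * to_rad
  dlon <- (b[1] - a[1]) * to_rad
  c <- sin(la1) * sin(la2) + cos(la1) * cos(la2) * cos(dlon)
  6371 * acos(pmin(pmax(c, -1), 1))
}

# Rook-adjacency lattice graph for join-count tests.
lattice_graph <- function(nr, nc) {
  xy <- expand.grid(x = seq_len(nc), y = seq_len(nr))
  d <- as.matrix(dist(xy))
  (d > 0 & d <= 1.001) * 1
}
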