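# Independent oracles and tiny fixture builders shared across tests.

# Brute-force flood fill component count: pixel-by-pixel stack walk,
# independent of the igraph-based labeling it checks.
flood_fill_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  n <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || seen[r, c]) next
    n <- n + 1L
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_along(dr)) {
        rr <- p[1] + dr[k]; cc <- p[2] + dc[k]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  n
}

# Quadrature of A * 2^(-t / th) (or a weighted sum of such terms).
quad_cumulated <- function(amplitudes, half_lives, upper = Inf) {
  stats::integrate(function(t) {
    v <- 0
    for (i in seq_along(amplitudes))
      v <- v + amplitudes[i] * 2^(-t / half_lives[i])
    v
  }, 0, upper, rel.tol = 1e-10)$value
}

# Deterministic small count matrix with a couple of separated blobs.
two_focus_fixture <- function() {
  m <- matrix(0, 6, 6)
  m[2:3, 2:3] <- 9
  m[5, 5:6] <- 7
  m
}

test_scan <- function(anterior, posterior = NULL, ...) {
  planar_scan(anterior, posterior, acquisition_duration_s = 100,
              time_post_admin_h = 24, ...)
}

lu_kin <- function() compartment_kinetics(preset = "lu177_dotatate")

# Small fast phantom for pipeline-level tests (not the default study
# phantom): same construction, quarter area.
small_phantom <- function(noise = "none", seed = 1) {
  rows <- matrix(1:80, 80, 40)
  cols <- matrix(1:40, 80, 40, byrow = TRUE)
  areas <- c(sum((rows - 22)^2 + (cols - 20)^2 <= 36),
             sum((rows - 55)^2 + (cols - 24)^2 <= 16))
  fr <- 0.6 * areas / sum(areas)
  phantom_spec(image_shape = c(80, 40),
               body_ellipse = list(center = c(40, 20),
                                   semi_axes = c(36, 15)),
               foci = list(
                 list(center = c(22, 20), radius_px = 6,
                      activity_fraction = fr[1]),
                 list(center = c(55, 24), radius_px = 4,
                      activity_fraction = fr[2])),
               A_total_MBq_at_scan = 500,
               sensitivity_cps_per_MBq = 5,
               acquisition_duration_s = 200,
               noise = noise, seed = seed)
}
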