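# Fixture builders and independent oracles shared across the suite.

# A clean hermaphrodite record set with valid defaults; any column can be
# overridden with a vector recycled to length n.
make_records <- function(n = 5, ...) {
  overrides <- list(...)
  base <- tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)),
    source_observation_id = sprintf("obs%03d", seq_len(n)),
    species = "inflata",
    latitude = seq(40, 45, length.out = n),
    longitude = seq(-80, -75, length.out = n),
    gps_accuracy = 10,
    observation_date = as.Date("2020-07-01") + seq_len(n),
    exsertion_score = "present",
    n_visible_flowers = 3L,
    n_exserted_flowers = 1L,
    flowers_present = TRUE,
    fruit_present = "yes",
    sex = "hermaphrodite",
    elevation = 100 + seq_len(n)
  )
  for (nm in names(overrides)) base[[nm]] <- rep_len(overrides[[nm]], n)
  base
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  readr::write_csv(records, path, progress = FALSE)
  path
}

# Records whose per-species score tallies equal the published raw counts.
make_published_count_records <- function() {
  counts <- list(
    cardinalis  = c(present = 283, possible = 49,  absent = 83,   unscorable = 85),
    inflata     = c(present = 453, possible = 318, absent = 1733, unscorable = 1388),
    kalmii      = c(present = 344, possible = 110, absent = 472,  unscorable = 227),
    siphilitica = c(present = 281, possible = 18,  absent = 84,   unscorable = 66),
    spicata     = c(present = 334, possible = 131, absent = 549,  unscorable = 243)
  )
  rows <- lapply(names(counts), function(sp) {
    cnt <- counts[[sp]]
    score <- rep(names(cnt), cnt)
    n <- length(score)
    make_records(n, species = sp, exsertion_score = score,
                 n_visible_flowers = ifelse(score == "unscorable", 0L, 3L),
                 n_exserted_flowers = ifelse(score == "present", 1L,
                                             ifelse(score == "possible", NA_integer_, 0L)),
                 flowers_present = score != "unscorable",
                 latitude = 40, longitude = -80)
  })
  do.call(rbind, rows)
}

filter_cols <- function(report) {
  setdiff(names(report), c("n_input", "n_retained"))
}

# O(n^3) hull-extremality oracle: a point is a hull vertex iff it is the
# endpoint of a directed edge with every other point strictly to one side.
brute_force_hull_vertices <- function(lon, lat) {
  pts <- unique(cbind(lon, lat))
  n <- nrow(pts)
  extremal <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- pts[j, 1] - pts[i, 1]; dy <- pts[j, 2] - pts[i, 2]
      cross <- dx * (pts[, 2] - pts[i, 2]) - dy * (pts[, 1] - pts[i, 1])
      others <- cross[-c(i, j)]
      if (all(others > 0) || all(others < 0)) {
        extremal[i] <- TRUE
        break
      }
    }
  }
  pts[extremal, , drop = FALSE]
}

# Brute-force boundary distance: 10 000 points sampled along each hull
# edge by spherical linear interpolation, minimum haversine distance.
brute_force_hull_distance <- function(lon, lat, model, n_samples = 10000) {
  v <- model$hull
  nv <- nrow(v)
  best <- Inf
  t <- seq(0, 1, length.out = n_samples)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    a <- lonlat_to_xyz(v[i, 1], v[i, 2])
    b <- lonlat_to_xyz(v[j, 1], v[j, 2])
    omega <- acos(min(max(sum(a * b), -1), 1))
    if (omega < 1e-15) next
    s <- outer(sin((1 - t) * omega), a) + outer(sin(t * omega), b)
    s <- s / sin(omega)
    slat <- asin(pmin(pmax(s[, 3], -1), 1)) * 180 / pi
    slon <- atan2(s[, 2], s[, 1]) * 180 / pi
    best <- min(best, great_circle_distance(lon, lat, slon, slat))
  }
  best
}

lonlat_to_xyz <- function(lon, lat) {
  lam <- lon * pi / 180; phi <- lat * pi / 180
  c(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

# Random non-degenerate point cloud in a continental-scale window.
random_cloud <- function(n, lon_range = c(-100, -60), lat_range = c(30, 50)) {
  tibble::tibble(longitude = stats::runif(n, lon_range[1], lon_range[2]),
                 latitude = stats::runif(n, lat_range[1], lat_range[2]))
}

# Derivative-free ML oracle: Nelder-Mead on the negative log-likelihood,
# restarted from its own solution to polish the simplex.
neldermead_glm <- function(y, X, family) {
  X1 <- cbind(1, X)
  nll <- if (family == "binomial") {
    function(b) {
      eta <- drop(X1 %*% b)
      -sum(y * eta - log1p(exp(eta)))
    }
  } else {
    function(b) {
      eta <- drop(X1 %*% b)
      -sum(y * eta - exp(eta))
    }
  }
  b <- rep(0, ncol(X1))
  for (k in 1:4) {
    b <- stats::optim(b, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))$par
  }
  b
}
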