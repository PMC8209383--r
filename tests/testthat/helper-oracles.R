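# Independent oracles used across the suite.

# Brute-force local fibrosis entropy by direct neighbor enumeration
# (independent of the vectorized array-shift implementation).
brute_fe <- function(labels, nx, ny, neighborhood = "moore",
                     fe_mode = "binary") {
  offs <- if (neighborhood == "moore")
    expand.grid(dx = -1:1, dy = -1:1)[-5, ]
  else
    data.frame(dx = c(1, -1, 0, 0), dy = c(0, 0, 1, -1))
  lab <- matrix(labels, nx, ny)
  fe <- numeric(nx * ny)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    ndiff <- 0L; ntot <- 0L
    for (k in seq_len(nrow(offs))) {
      xx <- x + offs$dx[k]; yy <- y + offs$dy[k]
      if (xx >= 1 && xx <= nx && yy >= 1 && yy <= ny) {
        ntot <- ntot + 1L
        if (lab[xx, yy] != lab[x, y]) ndiff <- ndiff + 1L
      }
    }
    p <- ndiff / ntot
    h <- 0
    if (fe_mode == "binary") {
      if (p > 0 && p < 1) h <- -(p * log(p) + (1 - p) * log(1 - p))
    } else if (p > 0) h <- -p * log(p)
    fe[(y - 1L) * nx + x] <- h
  }
  fe
}

# Winding number of a phase field around an arbitrary closed rectangular
# loop (counter-clockwise), by direct summation of wrapped differences.
brute_winding <- function(theta_mat, x0, y0, x1, y1) {
  wrap <- function(d) d - 2 * pi * ceiling((d - pi) / (2 * pi))
  path <- rbind(
    cbind(x0:x1, y0),                       # bottom, left-to-right
    cbind(x1, y0:y1),                       # right, up
    cbind(x1:x0, y1),                       # top, right-to-left
    cbind(x0, y1:y0))                       # left, down
  vals <- theta_mat[cbind(path[, 1], path[, 2])]
  sum(wrap(diff(c(vals, vals[1]))))
}

# Analytic vortex phase field: charge q at (x0, y0) on an nx x ny grid.
vortex_field <- function(nx, ny, x0, y0, q = 1) {
  x <- rep(seq_len(nx), times = ny)
  y <- rep(seq_len(ny), each = nx)
  q * atan2(y - y0, x - x0)
}

# Smooth random band-limited phase field (superposition of a few vortices
# plus low-frequency ripple) for detector-equivalence checks.
random_smooth_phase <- function(nx, ny, n_vortices = 2) {
  th <- matrix(0, nx, ny)
  for (k in seq_len(n_vortices)) {
    x0 <- runif(1, 3.2, nx - 2.2)
    y0 <- runif(1, 3.2, ny - 2.2)
    q <- sample(c(-1, 1), 1)
    th <- th + matrix(vortex_field(nx, ny, x0, y0, q), nx, ny)
  }
  x <- rep(seq_len(nx), times = ny) / nx
  y <- rep(seq_len(ny), each = nx) / ny
  th + matrix(0.4 * sin(2 * pi * x + runif(1, 0, 2 * pi)) *
              cos(2 * pi * y + runif(1, 0, 2 * pi)), nx, ny)
}

# Minimal hand-built voltage_recording for detector unit tests.
fake_recording <- function(vm, interval_ms = 2, nx = NULL, ny = NULL,
                           trigger_time_ms = 0) {
  n <- nrow(vm)
  if (is.null(nx)) { nx <- as.integer(sqrt(n)); ny <- nx }
  structure(list(
    vm = vm, time_ms = (seq_len(ncol(vm)) - 1) * interval_ms,
    first_activation_ms = rep(NA_real_, n),
    trigger_time_ms = trigger_time_ms, t_end_ms = ncol(vm) * interval_ms,
    geometry = make_sheet(nx, ny, 0.25),
    config = simulation_config(snapshot_interval_ms = interval_ms)),
    class = "voltage_recording")
}

# small standard objects reused by several files
tiny_sheet <- function(n = 40, dx = 0.25) make_sheet(n, n, dx)
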