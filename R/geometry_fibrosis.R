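# Synthetic tissue geometries and seeded fibrosis label maps.
#
# Node order is row-major with the x index varying fastest; node i (1-based)
# sits at column x = (i-1) %% nx + 1, row y = (i-1) %/% nx + 1. Fibrosis
# labels are 0 (normal myocyte) / 1 (fibrotic). Every generator hits the
# target fibrotic count round(amount * n_nodes) exactly and is fully
# determined by (pattern, amount, seed, params, geometry).

#' Regular 2D tissue sheet
#'
#' @param nx,ny node counts per axis (>= 3).
#' @param dx node spacing, mm.
#' @return object of class `tissue_geometry` with `kind = "sheet2d"`.
#' @export
#' @examples
#' g <- make_sheet(200, 200, 0.25)
#' g$n_nodes  # 40000
make_sheet <- function(nx, ny, dx = 0.25) {
  if (nx < 3 || ny < 3) stop("nx and ny must both be >= 3", call. = FALSE)
  if (dx <= 0) stop("dx must be > 0", call. = FALSE)
  structure(list(kind = "sheet2d", nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, n_nodes = as.integer(nx) * as.integer(ny),
                 boundary = "no-flux"),
            class = "tissue_geometry")
}

#' Regular 3D tissue slab
#'
#' Used by the fibrosis generators and the entropy module; the electrical
#' solver operates on 2D sheets.
#'
#' @param nx,ny,nz node counts per axis (>= 3).
#' @param dx node spacing, mm.
#' @return object of class `tissue_geometry` with `kind = "slab3d"`.
#' @export
make_slab <- function(nx, ny, nz, dx = 0.25) {
  if (nx < 3 || ny < 3 || nz < 3)
    stop("nx, ny and nz must all be >= 3", call. = FALSE)
  if (dx <= 0) stop("dx must be > 0", call. = FALSE)
  structure(list(kind = "slab3d", nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), dx = dx,
                 n_nodes = as.integer(nx) * as.integer(ny) * as.integer(nz),
                 boundary = "no-flux"),
            class = "tissue_geometry")
}

#' @export
print.tissue_geometry <- function(x, ...) {
  dims <- if (x$kind == "sheet2d") sprintf("%d x %d", x$nx, x$ny)
          else sprintf("%d x %d x %d", x$nx, x$ny, x$nz)
  cat(sprintf("Tissue geometry (%s): %s nodes, dx = %g mm\n",
              x$kind, dims, x$dx))
  invisible(x)
}

.geom_dims <- function(geometry) {
  if (geometry$kind == "sheet2d") c(geometry$nx, geometry$ny)
  else c(geometry$nx, geometry$ny, geometry$nz)
}

.check_amount <- function(amount, allow_large = FALSE) {
  if (!is.finite(amount) || amount < 0 || (amount > 0.5 && !allow_large) ||
      amount > 1)
    stop("fibrosis amount must lie in [0, 0.5] (the study range; pass ",
         "allow_large = TRUE for fractions up to 1)", call. = FALSE)
}

new_fibrosis_map <- function(labels, pattern, amount, seed, params,
                             geometry) {
  structure(list(labels = as.integer(labels), pattern = pattern,
                 amount = amount, seed = as.integer(seed), params = params,
                 geometry = geometry,
                 n_fibrotic = sum(labels != 0L)),
            class = "fibrosis_map")
}

#' @export
print.fibrosis_map <- function(x, ...) {
  cat(sprintf("Fibrosis map: %s, amount %.2f (%d / %d nodes), seed %d\n",
              x$pattern, x$amount, x$n_fibrotic, x$geometry$n_nodes,
              x$seed))
  invisible(x)
}

#' Diffuse fibrosis: uniformly scattered fibrotic nodes
#'
#' Exactly `round(amount * n_nodes)` nodes are labeled fibrotic, drawn by
#' uniform sampling without replacement under the given seed.
#'
#' @param geometry a [make_sheet()] or [make_slab()] geometry.
#' @param amount target fibrotic fraction in `[0, 0.5]`.
#' @param seed integer seed; same seed, same map.
#' @param allow_large permit fractions above the 0.5 study cap.
#' @return a `fibrosis_map`.
#' @export
generate_diffuse <- function(geometry, amount, seed, allow_large = FALSE) {
  .check_amount(amount, allow_large)
  n <- geometry$n_nodes
  k <- round(amount * n)
  labels <- integer(n)
  if (k > 0) {
    idx <- with_seed(seed, sample.int(n, k))
    labels[idx] <- 1L
  }
  new_fibrosis_map(labels, "diffuse", amount, seed, list(), geometry)
}

# rasterize one strand: nodes within `thickness`/2 of a segment from
# (x0, y0) at angle theta with given length (all in node units)
.strand_nodes <- function(nx, ny, x0, y0, theta, len, thickness) {
  step <- 0.4
  svec <- seq(0, len, by = step)
  cx <- x0 + cos(theta) * svec
  cy <- y0 + sin(theta) * svec
  half <- thickness / 2
  wvec <- seq(-half + 0.25, half - 0.25, by = 0.5)
  if (!length(wvec)) wvec <- 0
  px <- rep(cx, times = length(wvec)) +
    rep(wvec, each = length(cx)) * (-sin(theta))
  py <- rep(cy, times = length(wvec)) +
    rep(wvec, each = length(cx)) * cos(theta)
  ix <- round(px); iy <- round(py)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  unique((iy[ok] - 1L) * nx + ix[ok])
}

#' Patchy fibrosis: elongated, roughly parallel strands
#'
#' Fibrotic nodes are organized into elongated strands (default length at
#' least five times the thickness) with embedded non-fibrotic inclusions
#' controlled by `gap_fill` < 1, emulating string-like fibrosis that
#' separates myocyte bundles over extended distances. Strands are added,
#' and the last strand trimmed, until the exact target count is reached.
#'
#' @inheritParams generate_diffuse
#' @param stripe_params list with elements `orientation_mean` (radians;
#'   `NULL` draws one per map, strands within a map are near-parallel),
#'   `orientation_jitter` (radians), `length_range` (nodes),
#'   `thickness` (nodes) and `gap_fill` (probability that a strand node is
#'   actually fibrotic; 1 gives solid strands).
#' @return a `fibrosis_map`.
#' @export
generate_patchy <- function(geometry, amount, seed,
                            stripe_params = list(), allow_large = FALSE) {
  .check_amount(amount, allow_large)
  if (geometry$kind != "sheet2d")
    stop("patchy generation is defined on 2D sheets", call. = FALSE)
  sp <- utils::modifyList(list(orientation_mean = NULL,
                               orientation_jitter = 0.15,
                               length_range = c(30, 60),
                               thickness = 2, gap_fill = 0.85),
                          stripe_params)
  if (sp$gap_fill <= 0 || sp$gap_fill > 1)
    stop("gap_fill must lie in (0, 1]", call. = FALSE)
  if (min(sp$length_range) < 5 * sp$thickness)
    stop("strand length must be at least 5 x thickness; adjust ",
         "length_range or thickness", call. = FALSE)
  nx <- geometry$nx; ny <- geometry$ny
  n <- geometry$n_nodes
  target <- round(amount * n)
  labels <- integer(n)
  if (target == 0)
    return(new_fibrosis_map(labels, "patchy", amount, seed, sp, geometry))

  with_seed(seed, {
    orient <- sp$orientation_mean %||% runif(1, 0, pi)
    count <- 0L
    tries <- 0L
    max_tries <- 200L * ceiling(target / (min(sp$length_range) *
                                          sp$thickness * sp$gap_fill))
    while (count < target) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("cannot reach amount ", amount, " with the given ",
             "stripe_params; increase gap_fill, length or thickness",
             call. = FALSE)
      x0 <- runif(1, 1, nx); y0 <- runif(1, 1, ny)
      th <- orient + runif(1, -sp$orientation_jitter, sp$orientation_jitter)
      len <- runif(1, sp$length_range[1], sp$length_range[2])
      nodes <- .strand_nodes(nx, ny, x0, y0, th, len, sp$thickness)
      if (sp$gap_fill < 1)
        nodes <- nodes[runif(length(nodes)) < sp$gap_fill]
      nodes <- nodes[labels[nodes] == 0L]
      if (!length(nodes)) next
      excess <- count + length(nodes) - target
      if (excess > 0)  # trim the final strand to hit the count exactly
        nodes <- nodes[seq_len(length(nodes) - excess)]
      labels[nodes] <- 1L
      count <- count + length(nodes)
    }
  })
  new_fibrosis_map(labels, "patchy", amount, seed, sp, geometry)
}

#' Compact fibrosis: dense scar-like clusters
#'
#' Fibrotic nodes form exactly `n_clusters` connected components
#' (4-neighbor adjacency), each grown as a filled, hole-free elliptical
#' region around a seeded center; clusters are re-seeded if they would
#' touch. Component sizes are near-equal and sum exactly to
#' `round(amount * n_nodes)`.
#'
#' @inheritParams generate_diffuse
#' @param n_clusters number of scar regions (>= 1).
#' @param max_retries re-seeding attempts before giving up.
#' @return a `fibrosis_map`.
#' @export
generate_compact <- function(geometry, amount, seed, n_clusters = 3,
                             max_retries = 200, allow_large = FALSE) {
  .check_amount(amount, allow_large)
  if (n_clusters < 1) stop("n_clusters must be >= 1", call. = FALSE)
  if (geometry$kind != "sheet2d")
    stop("compact generation is defined on 2D sheets", call. = FALSE)
  nx <- geometry$nx; ny <- geometry$ny
  n <- geometry$n_nodes
  target <- round(amount * n)
  labels <- integer(n)
  params <- list(n_clusters = n_clusters)
  if (target == 0)
    return(new_fibrosis_map(labels, "compact", amount, seed, params,
                            geometry))
  if (target < n_clusters)
    stop("amount too small for ", n_clusters, " clusters", call. = FALSE)

  sizes <- rep(target %/% n_clusters, n_clusters)
  extra <- target - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

  xs <- rep(seq_len(nx), times = ny)
  ys <- rep(seq_len(ny), each = nx)

  with_seed(seed, {
    for (ci in seq_len(n_clusters)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        cx <- runif(1, 1, nx); cy <- runif(1, 1, ny)
        phi <- runif(1, 0, pi)
        asp <- runif(1, 1, 2)
        u <- (xs - cx) * cos(phi) + (ys - cy) * sin(phi)
        v <- -(xs - cx) * sin(phi) + (ys - cy) * cos(phi)
        score <- (u / asp)^2 + (v * asp)^2
        ord <- order(score, seq_len(n))  # deterministic tie-break
        cand <- ord[seq_len(sizes[ci])]
        # reject if the cluster would touch an existing one (would merge)
        if (any(labels[cand] != 0L)) next
        touch <- .touches_existing(cand, labels, nx, ny)
        if (touch) next
        if (!.is_connected(cand, nx, ny)) next
        labels[cand] <- 1L
        placed <- TRUE
        break
      }
      if (!placed) {
        # random placement leaves too little room (dense amounts): fall
        # back to one ellipse per band of the longer axis, sized to keep
        # a >= 1.5-node gap between bands so clusters never touch
        labels[] <- 0L
        labels <- .compact_band_layout(nx, ny, sizes, xs, ys)
        placed <- TRUE
        break
      }
    }
  })
  new_fibrosis_map(labels, "compact", amount, seed, params, geometry)
}

# Fallback layout for dense compact maps: one axis-aligned elliptical
# cluster per band of the longer axis. The across-band semi-axis is capped
# at (band width - 4)/2, guaranteeing >= 1.5 nodes of clearance between
# bands, so the clusters can never touch. Seeded jitter keeps replicates
# distinct; consumes the caller's with_seed() stream.
.compact_band_layout <- function(nx, ny, sizes, xs, ys) {
  n <- nx * ny
  k <- length(sizes)
  labels <- integer(n)
  along_x <- nx >= ny          # bands split the longer axis
  wb <- (if (along_x) nx else ny) / k          # band width
  Lb <- if (along_x) ny else nx                # band length
  for (ci in seq_len(k)) {
    s <- sizes[ci]
    b_hi <- (wb - 4) / 2                       # across-band semi-axis cap
    b_lo <- s / (pi * max((Lb - 6) / 2, 1))    # keep the long axis inside
    if (b_hi < b_lo || b_hi <= 0)
      stop("cannot fit ", k, " disjoint compact clusters of total size ",
           sum(sizes), " on this sheet; reduce n_clusters or amount",
           call. = FALSE)
    b <- runif(1, min(b_lo * 1.02, b_hi), b_hi)
    a <- s / (pi * b)
    cw <- (ci - 0.5) * wb + runif(1, -1, 1)    # center across bands
    cl <- Lb / 2 + runif(1, -max((Lb - 2 * a - 4) / 2, 0),
                         max((Lb - 2 * a - 4) / 2, 0))
    u <- if (along_x) xs - cw else ys - cw
    v <- if (along_x) ys - cl else xs - cl
    score <- (u / b)^2 + (v / a)^2
    ord <- order(score, seq_len(n))
    labels[ord[seq_len(s)]] <- 1L
  }
  labels
}

# would any candidate node be 4-adjacent to an already fibrotic node?
.touches_existing <- function(cand, labels, nx, ny) {
  if (!any(labels != 0L)) return(FALSE)
  x <- (cand - 1L) %% nx + 1L
  y <- (cand - 1L) %/% nx + 1L
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    xx <- x + d[1]; yy <- y + d[2]
    ok <- xx >= 1L & xx <= nx & yy >= 1L & yy <= ny
    if (any(labels[(yy[ok] - 1L) * nx + xx[ok]] != 0L)) return(TRUE)
  }
  FALSE
}

# BFS connectivity of a node set under 4-neighbor adjacency
.is_connected <- function(nodes, nx, ny) {
  if (length(nodes) <= 1L) return(TRUE)
  inset <- logical(nx * ny)
  inset[nodes] <- TRUE
  seen <- logical(nx * ny)
  queue <- nodes[1]
  seen[queue] <- TRUE
  nfound <- 1L
  while (length(queue)) {
    i <- queue
    queue <- integer(0)
    x <- (i - 1L) %% nx + 1L
    y <- (i - 1L) %/% nx + 1L
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      xx <- x + d[1]; yy <- y + d[2]
      ok <- xx >= 1L & xx <= nx & yy >= 1L & yy <= ny
      nb <- (yy[ok] - 1L) * nx + xx[ok]
      nb <- nb[inset[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        nfound <- nfound + length(nb)
        queue <- c(queue, nb)
      }
    }
  }
  nfound == length(nodes)
}

# connected components of the fibrotic set; returns a list of node vectors
fibrotic_components <- function(map, adjacency = c("von_neumann", "moore")) {
  adjacency <- match.arg(adjacency)
  g <- map$geometry
  nx <- g$nx; ny <- g$ny
  inset <- map$labels != 0L
  comp <- integer(length(inset))
  ncomp <- 0L
  offsets <- if (adjacency == "von_neumann")
    list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  else
    list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
         c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  todo <- which(inset)
  for (start in todo) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue)) {
      i <- queue
      queue <- integer(0)
      x <- (i - 1L) %% nx + 1L
      y <- (i - 1L) %/% nx + 1L
      for (d in offsets) {
        xx <- x + d[1]; yy <- y + d[2]
        ok <- xx >= 1L & xx <= nx & yy >= 1L & yy <= ny
        nb <- (yy[ok] - 1L) * nx + xx[ok]
        nb <- nb[inset[nb] & comp[nb] == 0L]
        if (length(nb)) {
          comp[nb] <- ncomp
          queue <- c(queue, nb)
        }
      }
    }
  }
  split(which(comp != 0L), comp[comp != 0L])
}

# principal-axis elongation (sd ratio) of each fibrotic component
component_elongation <- function(map, adjacency = "von_neumann") {
  comps <- fibrotic_components(map, adjacency)
  nx <- map$geometry$nx
  vapply(comps, function(nodes) {
    if (length(nodes) < 3) return(Inf)
    x <- (nodes - 1L) %% nx
    y <- (nodes - 1L) %/% nx
    ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE,
                only.values = TRUE)$values
    if (ev[2] < 1e-9) return(Inf)  # perfectly collinear set
    sqrt(ev[1] / ev[2])
  }, numeric(1))
}

#' Generate a full ensemble of fibrosis maps
#'
#' One map per (pattern, amount, replicate) cell with seeds derived
#' deterministically from `base_seed`. The defaults reproduce the study
#' grid: 3 patterns x 5 amounts (10-50%) x 5 replicates = 75 maps.
#'
#' @param geometry a `tissue_geometry`.
#' @param patterns subset of `c("diffuse", "patchy", "compact")`.
#' @param amounts fibrotic fractions.
#' @param n_replicates replicates per (pattern, amount) cell.
#' @param base_seed integer; fully determines all per-map seeds.
#' @param ... extra arguments passed to the individual generators.
#' @return object of class `fibrosis_ensemble`: list with `maps` (list of
#'   `fibrosis_map`) and `manifest` (data.frame with columns id, pattern,
#'   amount, replicate, seed, n_fibrotic).
#' @export
generate_ensemble <- function(geometry,
                              patterns = c("diffuse", "patchy", "compact"),
                              amounts = seq(0.1, 0.5, by = 0.1),
                              n_replicates = 5, base_seed = 1L, ...) {
  patterns <- match.arg(patterns, several.ok = TRUE)
  if (!length(patterns) || !length(amounts) || n_replicates < 1)
    stop("need at least one pattern, amount and replicate", call. = FALSE)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      amount = amounts, pattern = patterns,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("pattern", "amount", "replicate")]
  seeds <- (as.integer(base_seed) %% 1000000L) * 2003L + seq_len(nrow(grid))
  maps <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid$pattern[i]
    maps[[i]] <- switch(p,
      diffuse = generate_diffuse(geometry, grid$amount[i], seeds[i], ...),
      patchy  = generate_patchy(geometry, grid$amount[i], seeds[i], ...),
      compact = generate_compact(geometry, grid$amount[i], seeds[i], ...))
  }
  manifest <- data.frame(
    id = sprintf("%s_a%02d_r%d", grid$pattern, round(grid$amount * 100),
                 grid$replicate),
    pattern = grid$pattern, amount = grid$amount,
    replicate = grid$replicate, seed = seeds,
    n_fibrotic = vapply(maps, function(m) m$n_fibrotic, integer(1)),
    stringsAsFactors = FALSE)
  structure(list(maps = maps, manifest = manifest, base_seed = base_seed),
            class = "fibrosis_ensemble")
}

#' Write a fibrosis map (labels + metadata) as plain text
#'
#' @param map a `fibrosis_map`.
#' @param path output file; labels as one row per node with header
#'   comments carrying pattern/amount/seed metadata.
#' @export
write_fibrosis_map <- function(map, path) {
  g <- map$geometry
  hdr <- c(sprintf("# pattern: %s", map$pattern),
           sprintf("# amount: %g", map$amount),
           sprintf("# seed: %d", map$seed),
           sprintf("# dims: %s", paste(.geom_dims(g), collapse = " ")),
           sprintf("# dx_mm: %g", g$dx))
  writeLines(c(hdr, as.character(map$labels)), path)
  invisible(path)
}
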