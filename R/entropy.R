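# Fibrosis entropy: local Shannon entropy of the neighbor-disagreement
# fraction of a binary fibrosis label map, and its tissue mean (MFE).

.neighbor_offsets <- function(ndim, neighborhood) {
  if (neighborhood == "von_neumann") {
    offs <- lapply(seq_len(ndim), function(a) {
      o1 <- rep(0L, ndim); o1[a] <- 1L
      o2 <- rep(0L, ndim); o2[a] <- -1L
      list(o1, o2)
    })
    do.call(c, offs)
  } else {
    g <- do.call(expand.grid, rep(list(-1L:1L), ndim))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
    lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
  }
}

# shift an array by an integer offset, padding with NA outside the domain
.shift_array <- function(arr, off) {
  d <- dim(arr)
  out <- array(NA_integer_, d)
  src <- dst <- vector("list", length(d))
  for (a in seq_along(d)) {
    o <- off[a]
    if (o >= 0) {
      if (o >= d[a]) return(out)
      src[[a]] <- seq_len(d[a] - o)
      dst[[a]] <- seq_len(d[a] - o) + o
    } else {
      if (-o >= d[a]) return(out)
      src[[a]] <- seq_len(d[a] + o) - o
      dst[[a]] <- seq_len(d[a] + o)
    }
  }
  out2 <- do.call(`[`, c(list(arr), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(out2)))
}

binary_entropy <- function(p) {
  e <- numeric(length(p))
  ok <- p > 0 & p < 1
  e[ok] <- -(p[ok] * log(p[ok]) + (1 - p[ok]) * log(1 - p[ok]))
  e
}

#' Local fibrosis entropy and its tissue mean
#'
#' For each node i, `P_i` is the fraction of its neighbors whose fibrosis
#' label differs from node i's; boundary nodes use only their existing
#' neighbors. The default local entropy is the full binary Shannon
#' entropy `-[P ln P + (1-P) ln(1-P)]` (nats, bounded by `ln 2`), with
#' the convention `0 * ln 0 = 0`; `fe_mode = "one_term"` gives the
#' literal one-sided form `-P ln P`. The mean fibrosis entropy (MFE) is
#' the arithmetic mean over all nodes.
#'
#' Both modes are invariant under a global label flip because `P_i`
#' counts disagreement with node i, not fibrosis per se.
#'
#' @param map a `fibrosis_map`.
#' @param geometry geometry the map lives on (defaults to the map's own).
#' @param neighborhood `"moore"` (8 neighbors in 2D, 26 in 3D; default)
#'   or `"von_neumann"` (4 / 6).
#' @param fe_mode `"binary"` (default) or `"one_term"`.
#' @return object of class `entropy_result`: `local_fe` (per-node vector,
#'   nats), `mfe`, `p` (disagreement fractions), plus the mode tags.
#' @export
#' @examples
#' g <- make_sheet(50, 50)
#' m <- generate_diffuse(g, 0.3, seed = 1)
#' local_fe(m)$mfe
local_fe <- function(map, geometry = map$geometry,
                     neighborhood = c("moore", "von_neumann"),
                     fe_mode = c("binary", "one_term")) {
  neighborhood <- match.arg(neighborhood)
  fe_mode <- match.arg(fe_mode)
  dims <- .geom_dims(geometry)
  if (length(map$labels) != prod(dims))
    stop("fibrosis map size does not match geometry", call. = FALSE)
  arr <- array(map$labels, dims)
  offs <- .neighbor_offsets(length(dims), neighborhood)
  ndiff <- array(0L, dims)
  ntot <- array(0L, dims)
  for (off in offs) {
    sh <- .shift_array(arr, off)
    have <- !is.na(sh)
    ntot <- ntot + have
    ndiff <- ndiff + (have & sh != arr)
  }
  p <- as.numeric(ndiff) / as.numeric(ntot)
  fe <- if (fe_mode == "binary") binary_entropy(p)
        else ifelse(p > 0, -p * log(p), 0)
  structure(list(local_fe = fe, mfe = mean(fe), p = p,
                 neighborhood = neighborhood, fe_mode = fe_mode),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("Fibrosis entropy (%s neighborhood, %s mode): MFE = %.4f nats\n",
              x$neighborhood, x$fe_mode, x$mfe))
  invisible(x)
}

#' Per-map MFE table for an ensemble of fibrosis maps
#'
#' @param ensemble a [generate_ensemble()] result.
#' @inheritParams local_fe
#' @return data.frame with columns pattern, amount, replicate, mfe,
#'   neighborhood, fe_mode.
#' @export
entropy_table <- function(ensemble, neighborhood = "moore",
                          fe_mode = "binary") {
  man <- ensemble$manifest
  mfe <- vapply(ensemble$maps, function(m)
    local_fe(m, neighborhood = neighborhood, fe_mode = fe_mode)$mfe,
    numeric(1))
  data.frame(pattern = man$pattern, amount = man$amount,
             replicate = man$replicate, mfe = mfe,
             neighborhood = neighborhood, fe_mode = fe_mode,
             stringsAsFactors = FALSE)
}

#' Group-mean fibrosis entropy by (pattern, amount)
#'
#' Averages per-map MFE over replicates within each (pattern, amount)
#' cell, mirroring the study's averaging of its five replicate
#' distributions.
#'
#' @param results data.frame with columns pattern, amount, replicate and
#'   mfe (for example from [entropy_table()]).
#' @return long-format data.frame: pattern, amount, n, mfe_mean, mfe_sd.
#' @export
mean_fe_by_group <- function(results) {
  req <- c("pattern", "amount", "mfe")
  if (!all(req %in% names(results)) || nrow(results) == 0)
    stop("results must be a non-empty data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(mfe ~ pattern + amount, data = results,
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = stats::sd(v)))
  out <- data.frame(pattern = agg$pattern, amount = agg$amount,
                    n = agg$mfe[, "n"], mfe_mean = agg$mfe[, "mean"],
                    mfe_sd = agg$mfe[, "sd"], stringsAsFactors = FALSE)
  out[order(out$pattern, out$amount), ]
}
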