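# Independent brute-force oracles and toy-image builders used across tests.

# Queue-based breadth-first flood labeling; deliberately naive and independent
# of the package's graph-based implementation.
bfs_label <- function(mask, connectivity = 8) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (s in shifts) {
        r <- p[1] + s[1]; cc <- p[2] + s[2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- cur
          queue[[length(queue) + 1]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# Brute-force gap extraction: BFS-label the sub-threshold pixels 4-connected,
# drop every component containing a pixel on the dLGN contour.
bfs_gap <- function(dlgn_mask, sub_mask) {
  lab <- bfs_label(sub_mask & dlgn_mask, connectivity = 4)
  contour <- dlgn_mask & !(shift_and(dlgn_mask))
  bad <- unique(lab[contour & lab > 0])
  keep <- lab > 0 & !(lab %in% bad)
  keep
}

shift_and <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- function(dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- mask[rs[okr], cs[okc]]
    out
  }
  pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
}

# Exhaustive DM-VL sweep oracle: enumerates every 1-px offset, projects pixel
# centres explicitly, span = outermost intersections + 1 px footprint.
oracle_dmvl <- function(dlgn_mask, patch_mask, d, v) {
  u <- (v - d) / sqrt(sum((v - d)^2))
  nv <- c(-u[2], u[1])
  px_d <- which(dlgn_mask, arr.ind = TRUE)
  px_p <- which(patch_mask, arr.ind = TRUE)
  off_d <- round((px_d[, 1] - d[1]) * nv[1] + (px_d[, 2] - d[2]) * nv[2])
  off_p <- round((px_p[, 1] - d[1]) * nv[1] + (px_p[, 2] - d[2]) * nv[2])
  t_d <- (px_d[, 1] - d[1]) * u[1] + (px_d[, 2] - d[2]) * u[2]
  t_p <- (px_p[, 1] - d[1]) * u[1] + (px_p[, 2] - d[2]) * u[2]
  best <- c(q = -Inf, dpv = -Inf, off = Inf)
  for (o in sort(unique(off_p))) {
    tp <- t_p[off_p == o]
    td <- t_d[off_d == o]
    q <- max(tp) - min(tp) + 1
    dpv <- if (length(td)) max(td) - min(td) + 1 else 0
    better <- q > best["q"] ||
      (q == best["q"] && (dpv > best["dpv"] ||
                            (dpv == best["dpv"] && abs(o) < abs(best["off"]))))
    if (better) best <- c(q = q, dpv = dpv, off = o)
  }
  list(Q1Q2 = unname(best["q"]), DpVp = unname(best["dpv"]),
       norm = 100 * unname(best["q"] / best["dpv"]))
}

# Rectangle toy section: dLGN mask spanning rows/cols ranges, D/V on the base
# (bottom edge unless stated), outer boundary = top edge.
toy_rect_section <- function(nrow_img = 120, ncol_img = 240,
                             rows = 11:110, cols = 21:220,
                             intensity = NULL) {
  mask <- matrix(FALSE, nrow_img, ncol_img)
  mask[rows, cols] <- TRUE
  if (is.null(intensity)) intensity <- matrix(0, nrow_img, ncol_img)
  lm <- list(
    dm_tip = c(max(rows), min(cols)),
    vl_tip = c(max(rows), max(cols)),
    outer_arc = cbind(min(rows), seq(min(cols), max(cols))))
  section_image(intensity, mask, lm)
}

patchset_from_mask <- function(mask) extract_patches(mask, min_size = 0L)

# Rotate a logical mask by `deg` about the image centre into a square canvas,
# nearest-neighbour inverse mapping; returns the mask plus the forward affine
# for transforming landmark coordinates.
make_rotation <- function(dim_in, deg, dim_out = NULL) {
  th <- deg * pi / 180
  if (is.null(dim_out)) {
    n <- ceiling(sqrt(sum(dim_in^2))) + 4
    dim_out <- c(n, n)
  }
  cin <- (dim_in + 1) / 2; cout <- (dim_out + 1) / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  list(
    fwd = function(p) as.numeric(R %*% (p - cin) + cout),
    mask = function(mask) {
      nr <- dim_out[1]; nc <- dim_out[2]
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      src <- t(R) %*% rbind(as.vector(rows) - cout[1], as.vector(cols) - cout[2])
      sr <- round(src[1, ] + cin[1]); sc <- round(src[2, ] + cin[2])
      ok <- sr >= 1 & sr <= dim_in[1] & sc >= 1 & sc <= dim_in[2]
      out <- matrix(FALSE, nr, nc)
      out[cbind(as.vector(rows)[ok], as.vector(cols)[ok])] <-
        mask[cbind(sr[ok], sc[ok])]
      out
    })
}

# Shared noiseless phantom fixtures, rendered once per test run.
phantom_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    cache[[name]] <- switch(
      name,
      ipsi = make_series(phantom_spec(patch_fraction = 0.2)),
      contra = make_series(phantom_spec(gap_fraction = 0.15)),
      stop("unknown fixture ", name))
    cache[[name]]
  }
})
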