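#' Label connected components of a binary pixel mask
#'
#' Assigns an integer label to every `TRUE` pixel such that two pixels share a
#' label exactly when they are connected under the requested pixel adjacency.
#' Foreground (labelled signal) is conventionally traversed with 8-connectivity
#' and background (sub-threshold regions) with 4-connectivity, the standard
#' complementary pairing of digital topology that avoids paradoxes at diagonal
#' contacts.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity Integer, `4` or `8`.
#' @return Integer matrix of the same shape: `0` outside the mask, component
#'   labels `1, 2, ...` inside (labelled in first-pixel column-major order).
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- m[2, 2] <- TRUE
#' label_components(m, 8)[1, 1] == label_components(m, 8)[2, 2]  # diagonal join
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  mask <- mask_as_logical(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)

  # Map full-matrix linear indices to 1..n_fg vertex ids
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)

  shifts <- list(c(1L, 0L), c(0L, 1L))                      # S, E
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))  # SE, SW

  r0 <- ((idx - 1L) %% nr) + 1L
  c0 <- ((idx - 1L) %/% nr) + 1L
  edges <- vector("list", length(shifts))
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1L]; dc <- shifts[[k]][2L]
    r1 <- r0 + dr; c1 <- c0 + dc
    ok <- r1 >= 1L & r1 <= nr & c1 >= 1L & c1 <= nc
    nb <- (c1[ok] - 1L) * nr + r1[ok]
    hit <- mask[nb]
    edges[[k]] <- cbind(vid[idx[ok][hit]], vid[nb[hit]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  # Relabel in order of first appearance (column-major) for determinism
  first <- match(unique(memb), memb)
  ord <- order(first)
  relab <- integer(max(memb)); relab[unique(memb)[ord]] <- seq_along(ord)
  lab[idx] <- relab[memb]
  lab
}

#' Contour pixels of a region mask
#'
#' A contour pixel is a mask pixel with at least one 4-neighbour outside the
#' mask (image borders count as outside).
#'
#' @param mask Logical matrix.
#' @return Logical matrix marking contour pixels.
#' @export
mask_contour <- function(mask) {
  mask <- mask_as_logical(mask)
  pad <- function(dr, dc) {
    out <- matrix(FALSE, nrow(mask), ncol(mask))
    rs <- seq_len(nrow(mask)) + dr
    cs <- seq_len(ncol(mask)) + dc
    okr <- rs >= 1 & rs <= nrow(mask)
    okc <- cs >= 1 & cs <= ncol(mask)
    out[okr, okc] <- mask[rs[okr], cs[okc]]
    out
  }
  inner <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  mask & !inner
}

#' Erode a mask by n 4-connected steps
#'
#' Used to test how deep a region penetrates from the mask contour.
#' @param mask Logical matrix.
#' @param n Number of erosion passes.
#' @return Logical matrix.
#' @keywords internal
erode_mask <- function(mask, n) {
  mask <- mask_as_logical(mask)
  for (i in seq_len(n)) mask <- mask & !mask_contour(mask)
  mask
}

mask_as_logical <- function(mask) {
  if (!is.logical(mask)) mask <- mask != 0
  mask
}
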