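#' Label connected components of a binary mask
#'
#' 8-connected component labeling (the convention of the MATLAB-style
#' boundary tracer this pipeline mirrors). Labels are assigned in
#' column-major raster order of each component's first pixel, so labeling
#' is deterministic.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(out)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    d <- offs[[k]]
    r2 <- r + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[j]
    edges[[k]] <- cbind(pos[idx[ok][keep]], pos[j[keep]])
  }
  e <- do.call(rbind, edges)
  memb <- if (is.null(e) || nrow(e) == 0L) {
    seq_along(idx)
  } else {
    g <- igraph::make_graph(t(e), n = length(idx), directed = FALSE)
    igraph::components(g)$membership
  }
  # relabel so component ids follow first occurrence in raster order
  u <- unique(memb)  # order of first appearance == raster order of idx
  relab <- integer(max(memb))
  relab[u] <- seq_along(u)
  out[idx] <- relab[memb]
  out
}
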