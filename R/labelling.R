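#' Label connected components of a 3-D binary mask
#'
#' Foreground voxels are joined into components under the chosen
#' neighbourhood (6 = faces, 18 = faces + edges, 26 = faces + edges +
#' corners). Components are found on the voxel adjacency graph via
#' `igraph`; labels are assigned in order of the smallest linear voxel
#' index of each component, so labelling is deterministic.
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array of the same shape: 0 background, 1..k component
#'   labels.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  d <- dim(mask)
  lab <- array(0L, dim = d)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)

  # half-neighbourhood offsets (the mirror pairs are implied)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  off <- off[keep, , drop = FALSE]
  # one of each +/- pair suffices for an undirected graph
  first_pos <- apply(off, 1L, function(o) o[match(TRUE, o != 0)] > 0)
  off <- off[first_pos, , drop = FALSE]

  pos <- integer(prod(d))          # linear index -> node id (0 = background)
  pos[idx] <- seq_len(n)
  ind <- arrayInd(idx, d)

  edges <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    nb <- sweep(ind, 2L, off[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nlin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    hit <- pos[nlin] > 0L
    if (!any(hit)) next
    edges[[r]] <- cbind(which(ok)[hit], pos[nlin[hit]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(el) && nrow(el) > 0L)
    g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)$membership
  # relabel by first (smallest linear index) appearance
  relab <- integer(max(comp))
  relab[unique(comp)] <- seq_along(unique(comp))
  lab[idx] <- relab[comp]
  lab
}
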