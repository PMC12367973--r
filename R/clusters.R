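# Connected-component labelling on sparse voxel sets.
#
# The permutation engine only ever needs components of the (small)
# supra-threshold set, so labelling works on a vector of linear array
# indices rather than the full volume: neighbours are found with match()
# on precomputed offsets and merged with a union-find.

.neighbour_offsets <- function(connectivity = 26L) {
  e <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  e <- e[rowSums(abs(e)) > 0L, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6"  = rowSums(abs(e)) == 1L,
                 "18" = rowSums(abs(e)) <= 2L,
                 "26" = rep(TRUE, nrow(e)),
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  e <- e[keep, , drop = FALSE]
  # half-space of offsets: each unordered neighbour pair visited once
  lex <- e[, 1] + 3 * e[, 2] + 9 * e[, 3]
  e[lex > 0, , drop = FALSE]
}

# idx: 1-based linear indices of active voxels (any order, no duplicates)
# returns integer component labels (1..K) aligned with idx
.label_components <- function(idx, dims, connectivity = 26L) {
  k <- length(idx)
  if (k == 0L) return(integer(0))
  off <- .neighbour_offsets(connectivity)
  co <- arrayInd(idx, dims)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sx <- dims[1L]; sxy <- dims[1L] * dims[2L]
  for (o in seq_len(nrow(off))) {
    nx <- co[, 1L] + off[o, 1L]
    ny <- co[, 2L] + off[o, 2L]
    nz <- co[, 3L] + off[o, 3L]
    inb <- nx >= 1L & nx <= dims[1L] & ny >= 1L & ny <= dims[2L] &
      nz >= 1L & nz <= dims[3L]
    if (!any(inb)) next
    nlin <- (nz[inb] - 1L) * sxy + (ny[inb] - 1L) * sx + nx[inb]
    j <- match(nlin, idx)
    from <- which(inb)[!is.na(j)]
    to <- j[!is.na(j)]
    for (m in seq_along(from)) {
      ra <- find(from[m]); rb <- find(to[m])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  match(roots, unique(roots))
}

# largest component statistic of a supra-threshold set; stat is "size"
# (extent in voxels) or "mass" (sum of |t| over members)
.max_cluster_stat <- function(idx, dims, connectivity, stat = "size",
                              tvals = NULL) {
  if (!length(idx)) return(0)
  lab <- .label_components(idx, dims, connectivity)
  if (stat == "size") max(tabulate(lab))
  else max(vapply(split(abs(tvals), lab), sum, numeric(1)))
}

#' Form candidate clusters from a statistical map
#'
#' Thresholds the eligible voxels of a t map at the critical value
#' corresponding to the cluster-forming p (two-sided, applied per sign)
#' and labels connected components under the configured neighbourhood.
#'
#' @param tmap numeric 3-D array of t statistics (`NA` outside eligible
#'   voxels is fine).
#' @param eligible logical 3-D array of voxels passing the minimum-group
#'   rule.
#' @param grid the [common_grid()] the arrays live on.
#' @param t_threshold positive critical t value.
#' @param sign `"positive"` (t > threshold) or `"negative"`
#'   (t < -threshold).
#' @param connectivity 6, 18 or 26 neighbourhood.
#' @return A list with `table` (data frame: `cluster`, `sign`, `size`,
#'   `mass`, `peak_t`, `x`, `y`, `z`) sorted by decreasing size, and
#'   `voxels` (list of linear index vectors, aligned with the table rows).
#' @export
form_clusters <- function(tmap, eligible, grid, t_threshold,
                          sign = c("positive", "negative"),
                          connectivity = 26L) {
  sign <- match.arg(sign)
  if (t_threshold <= 0) stop("'t_threshold' must be positive", call. = FALSE)
  ok <- eligible & is.finite(tmap)
  supra <- if (sign == "positive") ok & tmap > t_threshold
           else ok & tmap < -t_threshold
  idx <- which(supra)
  if (!length(idx))
    return(list(table = data.frame(cluster = integer(), sign = character(),
                                   size = integer(), mass = numeric(),
                                   peak_t = numeric(), x = numeric(),
                                   y = numeric(), z = numeric(),
                                   stringsAsFactors = FALSE),
                voxels = list()))
  lab <- .label_components(idx, dim(tmap), connectivity)
  groups <- split(seq_along(idx), lab)
  ord <- order(-lengths(groups))
  groups <- groups[ord]
  rows <- lapply(seq_along(groups), function(g) {
    members <- idx[groups[[g]]]
    mm <- voxel_to_mm(grid, arrayInd(members, dim(tmap)))
    tv <- tmap[members]
    data.frame(cluster = g, sign = sign, size = length(members),
               mass = sum(abs(tv)), peak_t = tv[which.max(abs(tv))],
               x = mean(mm[, 1]), y = mean(mm[, 2]), z = mean(mm[, 3]),
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows),
       voxels = lapply(groups, function(g) idx[g]))
}
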