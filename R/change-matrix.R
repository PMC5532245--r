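#' Land-cover change matrix between two epochs
#'
#' Cross-tabulates the classified area of two co-registered SEEA grids:
#' `flows[i, j]` is the area (km2) that was class `i` at the opening epoch
#' and class `j` at the closing epoch. Row sums therefore reproduce the
#' opening per-class areas and column sums the closing areas, and the grand
#' total is the classified territory (conserved across epochs).
#'
#' CORINE-style change layers suppress changed patches below a minimum
#' mapping unit (5 ha for the 2000-2012 layers). `min_mapping_unit`
#' emulates that filter: 4-connected patches of cells undergoing the same
#' class-to-class transition whose total area falls below the threshold are
#' treated as unchanged (folded back onto the matrix diagonal). The default
#' 0 disables filtering.
#'
#' @param grid_t0,grid_t1 `land_cover_grid`s in SEEA nomenclature with
#'   identical shape, cell size and nodata mask.
#' @param min_mapping_unit Minimum changed-patch area in km2 (0.05 = 5 ha).
#' @return A `change_matrix` object: a 14 x 14 numeric matrix of km2 with
#'   dimnames `"1"`..`"14"` and attributes `epoch_pair` and `cell_area_km2`.
#' @examples
#' g0 <- land_cover_grid(matrix(c(2L, 2L, 6L, 6L), 2, 2), 1, "2000")
#' g1 <- land_cover_grid(matrix(c(1L, 2L, 6L, 6L), 2, 2), 1, "2006")
#' change_matrix(g0, g1)["2", "1"]
#' @export
change_matrix <- function(grid_t0, grid_t1, min_mapping_unit = 0) {
  check_grid_pair(grid_t0, grid_t1)
  if (min_mapping_unit < 0) stop("`min_mapping_unit` must be >= 0")
  a <- grid_t0$codes
  b <- grid_t1$codes
  if (min_mapping_unit > 0) {
    fold <- small_change_patches(a, b,
                                 max_cells = min_mapping_unit /
                                   grid_t0$cell_area_km2)
    b[fold] <- a[fold]
  }
  keep <- a != 0L
  counts <- table(factor(a[keep], levels = 1:14),
                  factor(b[keep], levels = 1:14))
  flows <- unclass(counts) * grid_t0$cell_area_km2
  dimnames(flows) <- list(from = as.character(1:14), to = as.character(1:14))
  structure(flows, class = c("change_matrix", "matrix", "array"),
            epoch_pair = c(grid_t0$epoch, grid_t1$epoch),
            cell_area_km2 = grid_t0$cell_area_km2)
}

# Identify changed cells belonging to 4-connected patches of the same
# (from, to) transition with strictly fewer cells than `max_cells`.
# Returns a logical matrix marking cells to fold back to "unchanged".
# BFS labelling over the changed-cell set; grids here are modest
# (hundreds of cells a side) so plain R with an explicit queue suffices.
small_change_patches <- function(a, b, max_cells) {
  nr <- nrow(a); nc <- ncol(a)
  changed <- which(a != b & a != 0L)
  fold <- matrix(FALSE, nr, nc)
  if (!length(changed)) return(fold)
  seen <- logical(nr * nc)
  for (start in changed) {
    if (seen[start]) next
    key_from <- a[start]; key_to <- b[start]
    queue <- start; seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      cell <- queue[[1L]]; queue <- queue[-1L]
      comp <- c(comp, cell)
      r <- ((cell - 1L) %% nr) + 1L
      cc <- ((cell - 1L) %/% nr) + 1L
      nb <- c(if (r > 1L) cell - 1L, if (r < nr) cell + 1L,
              if (cc > 1L) cell - nr, if (cc < nc) cell + nr)
      for (m in nb) {
        if (!seen[m] && a[m] == key_from && b[m] == key_to && a[m] != b[m]) {
          seen[m] <- TRUE
          queue <- c(queue, m)
        }
      }
    }
    if (length(comp) < max_cells) fold[comp] <- TRUE
  }
  fold
}

#' @export
print.change_matrix <- function(x, ...) {
  ep <- attr(x, "epoch_pair")
  cat(sprintf("<change_matrix> %s -> %s, %.6g km2 classified, %.6g km2 changed\n",
              if (nzchar(ep[1])) ep[1] else "t0",
              if (nzchar(ep[2])) ep[2] else "t1",
              sum(x), sum(x) - sum(diag(unclass(x)))))
  m <- unclass(x)
  nz <- rowSums(m) > 0 | colSums(m) > 0
  print(round(m[nz, nz, drop = FALSE], 6))
  invisible(x)
}

#' Row-normalised transition-probability estimate from two epochs
#'
#' Estimates the per-cell class-transition matrix that carried `grid_t0`
#' into `grid_t1`: the change matrix with each row divided by its sum.
#' Rows with no source cells are undefined and returned as `NA` (absent),
#' never zero-filled.
#'
#' @inheritParams change_matrix
#' @return A 14 x 14 matrix of estimated transition probabilities; rows
#'   with no source area are all-`NA`.
#' @seealso [advance_epoch()] for the generating process this inverts.
#' @export
recover_transitions <- function(grid_t0, grid_t1) {
  cm <- unclass(change_matrix(grid_t0, grid_t1, min_mapping_unit = 0))
  rs <- rowSums(cm)
  est <- cm / ifelse(rs > 0, rs, NA_real_)
  est[rs == 0, ] <- NA_real_
  est
}
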