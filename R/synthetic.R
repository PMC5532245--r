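#' Construct and validate a class-transition matrix
#'
#' A 14 x 14 per-cell transition matrix: row `i`, column `j` is the
#' probability that a cell of class `i` at one epoch is class `j` at the
#' next. Rows must be probability vectors.
#'
#' @param x A 14 x 14 non-negative matrix with rows summing to 1 (within
#'   1e-12).
#' @return A validated `transition_matrix`.
#' @export
transition_matrix <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(14L, 14L)))
    stop("a transition matrix must be 14 x 14")
  if (any(x < 0)) stop("transition probabilities must be non-negative")
  if (any(abs(rowSums(x) - 1) > 1e-12))
    stop("transition-matrix rows must sum to 1")
  dimnames(x) <- list(from = as.character(1:14), to = as.character(1:14))
  structure(x, class = c("transition_matrix", "matrix", "array"))
}

# identity transitions plus named off-diagonal flows, e.g.
# perturb_identity(`2->1` = 0.005)
perturb_identity <- function(...) {
  flows <- c(...)
  m <- diag(14)
  for (nm in names(flows)) {
    ij <- as.integer(strsplit(nm, "->", fixed = TRUE)[[1]])
    m[ij[1], ij[2]] <- m[ij[1], ij[2]] + flows[[nm]]
    m[ij[1], ij[1]] <- m[ij[1], ij[1]] - flows[[nm]]
  }
  transition_matrix(m)
}

#' Per-cover soil property distributions for the sample generator
#'
#' Parameters of the per-cover sampling distributions used by
#' [gen_soil_samples()]: SOC concentration is lognormal (non-negative and
#' right-skewed, as in survey data), pH is normal truncated to (3, 10)
#' and the peat flag is Bernoulli. The defaults are calibrated to the
#' qualitative pattern of European survey data -- tree-covered and
#' aquatic/flooded soils carry the highest SOC, cropped soils are
#' near-neutral in pH while woodland soils are acidic (around 4.5-5), and
#' peat is concentrated under aquatic/regularly flooded vegetation --
#' not to any published absolute totals.
#'
#' @return Data frame with one row per SEEA class and columns `code`,
#'   `soc_meanlog`, `soc_sdlog` (log g/kg), `ph_mean`, `ph_sd`,
#'   `peat_prob`.
#' @export
default_cover_params <- function() {
  med_soc <- c(20, 15, 12, 18, 30, 45, 60, 35, 60, 25, 10, 20, 30, 30)
  data.frame(
    code = 1:14,
    soc_meanlog = log(med_soc),
    soc_sdlog = rep(0.6, 14),
    ph_mean = c(6.8, 6.8, 7.0, 6.5, 5.8, 5.0, 6.5, 5.5,
                5.5, 6.5, 7.5, 6.0, 6.5, 7.5),
    ph_sd = rep(0.8, 14),
    peat_prob = c(0.01, 0.01, 0.01, 0.01, 0.04, 0.05, 0.01, 0.01,
                  0.25, 0.01, 0.01, 0.01, 0.01, 0.01)
  )
}

#' Define a synthetic land-cover and soil scenario
#'
#' A scenario bundles everything the generators need: grid shape and cell
#' size, the number of epochs and their labels, the initial class mixture
#' and patch scale, the per-epoch transition matrix, per-cover soil
#' distribution parameters and the number of soil samples. All generator
#' output is a pure function of (scenario, seed).
#'
#' @param nrow,ncol Grid shape (both >= 1).
#' @param cell_area_km2 Cell area in km2.
#' @param epochs Character vector of epoch labels (>= 1).
#' @param mixture Named numeric vector of initial class proportions
#'   (names = SEEA codes), summing to 1.
#' @param patchiness Expected patch diameter in cells (>= 1); 1 gives
#'   spatially independent cells.
#' @param transition A [transition_matrix()] applied per epoch step.
#' @param cover_params Per-cover distribution table as in
#'   [default_cover_params()].
#' @param n_samples Number of soil samples to draw.
#' @return A `scenario` object (list).
#' @export
scenario <- function(nrow, ncol, cell_area_km2 = 1, epochs = c("t0", "t1"),
                     mixture, patchiness = 1,
                     transition = transition_matrix(diag(14)),
                     cover_params = default_cover_params(),
                     n_samples = 500) {
  if (nrow < 1 || ncol < 1) stop("degenerate grid shape")
  if (abs(sum(mixture) - 1) > 1e-9)
    stop("mixture proportions must sum to 1")
  if (is.null(names(mixture)) || !all(names(mixture) %in% as.character(1:14)))
    stop("mixture must be named by SEEA codes")
  if (patchiness < 1) stop("`patchiness` must be >= 1")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cell_area_km2 = cell_area_km2, epochs = epochs,
                 mixture = mixture, patchiness = patchiness,
                 transition = transition_matrix(transition),
                 cover_params = cover_params,
                 n_samples = as.integer(n_samples)),
            class = "scenario")
}

#' A toy scenario shaped like the EU-25 study area
#'
#' Dominant herbaceous crops and tree cover with a small artificial class
#' growing at the crops' expense, woodland also gaining, over three
#' epochs labelled 2000/2006/2012 -- the qualitative change structure of
#' the European accounting period, at toy scale. Class proportions follow
#' the EU-25 opening shares; per-epoch transition probabilities are a few
#' per mille, matching the observed magnitude of net change (under 1% of
#' territory per class per period).
#'
#' @param nrow,ncol Grid shape (default 100 x 100 cells of 1 km2).
#' @param n_samples Number of soil samples (default 2000).
#' @return A `scenario`.
#' @export
eu25_toy_scenario <- function(nrow = 100, ncol = 100, n_samples = 2000) {
  mixture <- c(`1` = 0.028, `2` = 0.262, `3` = 0.025, `4` = 0.114,
               `5` = 0.107, `6` = 0.354, `8` = 0.040, `9` = 0.021,
               `10` = 0.005, `11` = 0.002, `13` = 0.042)
  tm <- perturb_identity(`2->1` = 0.005, `2->3` = 0.001, `2->6` = 0.001,
                         `4->1` = 0.002, `5->6` = 0.003, `8->6` = 0.004)
  scenario(nrow, ncol, cell_area_km2 = 1,
           epochs = c("2000", "2006", "2012"),
           mixture = mixture, patchiness = 4, transition = tm,
           n_samples = n_samples)
}

#' Generate the initial land-cover grid of a scenario
#'
#' Nuclei are placed uniformly at random (one per
#' `patchiness^2` cells in expectation), each draws a class from the
#' mixture, and patches grow from the nuclei by multi-source breadth-first
#' search until the grid is filled -- a cheap approximate-Voronoi tessellation
#' giving contiguous patches with expected diameter `patchiness`. With
#' `patchiness = 1` every cell is its own nucleus and cells are
#' independent draws from the mixture.
#'
#' @param scn A [scenario()].
#' @param seed Integer seed; identical (scenario, seed) gives a
#'   bit-identical grid.
#' @return A `land_cover_grid` (SEEA nomenclature) labelled with the
#'   scenario's first epoch.
#' @export
gen_initial_grid <- function(scn, seed = 1) {
  stopifnot(inherits(scn, "scenario"))
  with_local_seed(seed, {
    nr <- scn$nrow; nc <- scn$ncol
    ncells <- nr * nc
    m <- max(1L, min(ncells, as.integer(round(ncells / scn$patchiness^2))))
    cls <- as.integer(names(scn$mixture))
    nuclei <- if (m == ncells) seq_len(ncells) else sample.int(ncells, m)
    nucleus_class <- cls[sample.int(length(cls), m, replace = TRUE,
                                    prob = scn$mixture)]
    codes <- integer(ncells)
    codes[nuclei] <- nucleus_class
    if (m < ncells) {
      # multi-source BFS flood fill, FIFO over a preallocated ring
      queue <- integer(ncells)
      queue[seq_len(m)] <- sample(nuclei)   # random service order
      head <- 1L; tail <- m
      while (head <= tail) {
        cell <- queue[head]; head <- head + 1L
        r <- ((cell - 1L) %% nr) + 1L
        cc <- ((cell - 1L) %/% nr) + 1L
        for (nb in c(if (r > 1L) cell - 1L, if (r < nr) cell + 1L,
                     if (cc > 1L) cell - nr, if (cc < nc) cell + nr)) {
          if (codes[nb] == 0L) {
            codes[nb] <- codes[cell]
            tail <- tail + 1L
            queue[tail] <- nb
          }
        }
      }
    }
    land_cover_grid(matrix(codes, nr, nc), scn$cell_area_km2,
                    epoch = scn$epochs[1], nomenclature = "seea")
  })
}

#' Advance a land-cover grid by one epoch under a transition matrix
#'
#' Each classified cell's class is redrawn independently from its row of
#' the transition matrix; nodata cells are untouched.
#'
#' @param grid A SEEA-nomenclature `land_cover_grid`.
#' @param tm A [transition_matrix()].
#' @param seed Integer seed.
#' @param epoch Label for the advanced grid.
#' @return A `land_cover_grid`.
#' @export
advance_epoch <- function(grid, tm, seed = 1, epoch = "") {
  stopifnot(inherits(grid, "land_cover_grid"))
  if (grid$nomenclature != "seea") stop("grid must be in SEEA nomenclature")
  tm <- transition_matrix(tm)
  with_local_seed(seed, {
    orig <- grid$codes
    codes <- orig
    for (k in sort(unique(orig[orig != 0L]))) {
      idx <- which(orig == k)   # source classes, not already-redrawn ones
      codes[idx] <- sample.int(14L, length(idx), replace = TRUE,
                               prob = tm[k, ])
    }
    land_cover_grid(codes, grid$cell_area_km2, epoch, "seea")
  })
}

#' Draw LUCAS-like soil samples from a land-cover grid
#'
#' Samples `n` classified cells uniformly without replacement; each
#' sample's SOC is drawn lognormal, its pH truncated-normal on (3, 10)
#' and its peat flag Bernoulli, with the parameters of the cell's cover
#' class.
#'
#' @param grid A SEEA-nomenclature `land_cover_grid`.
#' @param n Number of samples (1 <= n <= number of classified cells).
#' @param params Per-cover distribution table as in
#'   [default_cover_params()].
#' @param seed Integer seed.
#' @return A `soil_samples` table.
#' @export
gen_soil_samples <- function(grid, n, params = default_cover_params(),
                             seed = 1) {
  stopifnot(inherits(grid, "land_cover_grid"))
  classified <- which(grid$codes != 0L)
  if (n < 1) stop("`n` must be >= 1")
  if (n > length(classified))
    stop("n = ", n, " exceeds the ", length(classified),
         " classified cells")
  with_local_seed(seed, {
    cells <- sort(sample(classified, n))
    nr <- nrow(grid$codes)
    cover <- grid$codes[cells]
    p <- params[match(cover, params$code), ]
    soc <- stats::rlnorm(n, p$soc_meanlog, p$soc_sdlog)
    ph <- rtruncnorm(n, p$ph_mean, p$ph_sd, 3, 10)
    peat <- stats::runif(n) < p$peat_prob
    soil_samples(data.frame(
      sample_id = seq_len(n),
      row = ((cells - 1L) %% nr) + 1L,
      col = ((cells - 1L) %/% nr) + 1L,
      cover = cover, soc_g_per_kg = soc, ph = ph, peat = peat))
  })
}

# inverse-CDF truncated normal draw (vectorized over mean/sd)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Simulate a full scenario: epoch grids and soil samples
#'
#' Runs [gen_initial_grid()], advances one epoch per additional label
#' with [advance_epoch()], and draws samples from the first epoch's grid
#' with [gen_soil_samples()]. Sub-seeds are derived deterministically
#' from `seed`.
#'
#' @param scn A [scenario()].
#' @param seed Integer seed.
#' @return List with `grids` (list of `land_cover_grid`, one per epoch)
#'   and `samples` (a `soil_samples` table).
#' @export
simulate_scenario <- function(scn, seed = 1) {
  stopifnot(inherits(scn, "scenario"))
  grids <- vector("list", length(scn$epochs))
  names(grids) <- scn$epochs
  grids[[1]] <- gen_initial_grid(scn, seed = seed)
  for (i in seq_along(scn$epochs)[-1]) {
    grids[[i]] <- advance_epoch(grids[[i - 1]], scn$transition,
                                seed = seed + 1000L * i,
                                epoch = scn$epochs[i])
  }
  samples <- gen_soil_samples(grids[[1]], scn$n_samples,
                              scn$cover_params, seed = seed + 77L)
  list(grids = grids, samples = samples)
}
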