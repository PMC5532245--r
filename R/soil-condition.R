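#' Soil condition class labels
#'
#' `soc_classes()` returns the four topsoil organic-carbon condition
#' classes (peat; organo-mineral, SOC > 12%; humus-mineral, 3-12%;
#' mineral, < 3%). `ph_classes()` returns the six pH classes with
#' breakpoints 4.5, 5, 6, 7 and 8.3 -- the end breakpoints carry physical
#' meaning (aluminium toxicity below pH 4.5; boron toxicity and sodium
#' dominance above 8.3), the interior ones are display divisions.
#'
#' @return Character vector of class labels, in order.
#' @export
soc_classes <- function() {
  c("peat", "organo_mineral", "humus_mineral", "mineral")
}

#' @rdname soc_classes
#' @export
ph_classes <- function() {
  c("<4.5", "4.5-5", "5-6", "6-7", "7-8.3", ">8.3")
}

#' Mask cells with high peat probability
#'
#' Peat is map-defined, not concentration-defined: a cell is treated as
#' peat when the mapped probability of finding peat strictly exceeds the
#' threshold (default 35%).
#'
#' @param prob_grid Numeric matrix of peat probabilities in \[0, 1\].
#' @param threshold Probability threshold (default 0.35); exceedance is
#'   strict.
#' @return Logical matrix of the same shape.
#' @examples
#' peat_mask(matrix(c(0.4, 0.35, 0, 0.9), 2, 2))
#' @export
peat_mask <- function(prob_grid, threshold = 0.35) {
  if (!is.numeric(prob_grid)) stop("`prob_grid` must be numeric")
  if (any(prob_grid < 0 | prob_grid > 1, na.rm = TRUE))
    stop("peat probabilities must lie in [0, 1]")
  prob_grid > threshold
}

#' Classify topsoil organic carbon concentration
#'
#' Samples flagged as peat (from the peat-probability mask) are classed
#' peat regardless of concentration. Otherwise SOC above 12% is
#' organo-mineral, 3-12% inclusive is humus-mineral and below 3% is
#' mineral. SOC is taken in g/kg at the interface (survey convention);
#' the percent thresholds correspond to 120 and 30 g/kg. Both thresholds
#' are strict on the outer side, so 120 g/kg and 30 g/kg are both
#' humus-mineral.
#'
#' @param soc_g_per_kg Organic carbon concentration in g/kg (>= 0);
#'   vectorized.
#' @param peat Logical peat flag, recycled against `soc_g_per_kg`.
#' @return Factor with levels `soc_classes()`.
#' @examples
#' classify_soc(c(150, 120, 30, 25), peat = FALSE)
#' classify_soc(25, peat = TRUE)
#' @export
classify_soc <- function(soc_g_per_kg, peat = FALSE) {
  if (any(is.na(soc_g_per_kg)) || any(soc_g_per_kg < 0))
    stop("`soc_g_per_kg` must be non-negative and non-missing")
  pct <- soc_g_per_kg / 10
  out <- ifelse(rep_len(peat, length(pct)), "peat",
                ifelse(pct > 12, "organo_mineral",
                       ifelse(pct >= 3, "humus_mineral", "mineral")))
  factor(out, levels = soc_classes())
}

#' Classify topsoil pH
#'
#' Bins are lower-inclusive -- `[min, 4.5)`, `[4.5, 5)`, `[5, 6)`,
#' `[6, 7)` -- except the top two: `>8.3` is strict, so `7-8.3` is the
#' closed interval `[7, 8.3]` and pH exactly 8.3 falls in it.
#'
#' @param ph pH values, strictly between 0 and 14; vectorized.
#' @return Factor with levels `ph_classes()`.
#' @examples
#' classify_ph(c(4.2, 4.5, 6.5, 8.3, 8.31))
#' @export
classify_ph <- function(ph) {
  if (any(is.na(ph)) || any(ph <= 0 | ph >= 14))
    stop("pH must lie strictly between 0 and 14")
  idx <- findInterval(ph, c(4.5, 5, 6, 7)) + 1L        # bins 1..5
  idx[ph > 8.3] <- 6L                                   # strict top bin
  factor(ph_classes()[idx], levels = ph_classes())
}

#' Construct and validate a soil sample table
#'
#' A LUCAS-style point-sample table: one row per surveyed topsoil sample
#' with its grid location, land cover, organic carbon concentration, pH
#' and peat flag.
#'
#' @param df Data frame with columns `sample_id` (unique), `row`, `col`
#'   (grid indices), `cover` (SEEA code 1-14), `soc_g_per_kg` (>= 0),
#'   `ph` (in (0, 14)) and `peat` (logical or 0/1).
#' @return A `soil_samples` data frame.
#' @export
soil_samples <- function(df) {
  need <- c("sample_id", "row", "col", "cover", "soc_g_per_kg", "ph", "peat")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id values")
  if (any(df$soc_g_per_kg < 0)) stop("soc_g_per_kg must be >= 0")
  if (any(df$ph <= 0 | df$ph >= 14))
    stop("ph must lie strictly between 0 and 14")
  if (!all(df$cover %in% 1:14)) stop("cover must be a SEEA code 1-14")
  df$peat <- as.logical(df$peat)
  structure(as.data.frame(df), class = c("soil_samples", "data.frame"))
}

#' Read or write a soil sample table as CSV
#'
#' The CSV carries columns `sample_id, row, col, cover, soc_g_per_kg, ph,
#' peat` with peat coded 0/1.
#'
#' @param path File path.
#' @return `read_soil_samples()` returns a `soil_samples` data frame.
#' @export
read_soil_samples <- function(path) {
  soil_samples(utils::read.csv(path, comment.char = "#"))
}

#' @rdname read_soil_samples
#' @param samples A `soil_samples` table.
#' @param comment Optional `#` comment line(s) before the header.
#' @export
write_soil_samples <- function(samples, path, comment = NULL) {
  df <- as.data.frame(samples)
  df$peat <- as.integer(df$peat)
  write_csv_commented(df, path, comment)
}

#' Cross-tabulate soil condition area by land cover
#'
#' Design-based area attribution: within each cover the samples are
#' treated as an equal-probability sample of that cover's area, so
#' `area(cover, class) = cover_area * n_class / n_cover`. Rows therefore
#' sum to the cover areas exactly.
#'
#' @param samples A `soil_samples` table (or coercible data frame).
#' @param cover_areas Named numeric vector of per-cover areas in
#'   hectares; every cover with positive area must have at least one
#'   sample.
#' @param classifier `"soc"` or `"ph"`.
#' @return A `condition_crosstab`: numeric matrix (covers x condition
#'   classes, ha) with attributes `classifier` and `basis = "state"`.
#' @examples
#' s <- soil_samples(data.frame(sample_id = 1:4, row = 1, col = 1:4,
#'                              cover = 2, soc_g_per_kg = c(10, 20, 50, 250),
#'                              ph = 6, peat = c(0, 0, 0, 1)))
#' condition_crosstab(s, c(`2` = 100), "soc")
#' @export
condition_crosstab <- function(samples, cover_areas,
                               classifier = c("soc", "ph")) {
  classifier <- match.arg(classifier)
  df <- as.data.frame(samples)
  covers <- names(cover_areas)[cover_areas > 0]
  no_samples <- setdiff(covers, as.character(df$cover))
  if (length(no_samples))
    stop("cover(s) with positive area but no samples: ",
         paste(no_samples, collapse = ", "))
  cond <- if (classifier == "soc")
    classify_soc(df$soc_g_per_kg, df$peat) else classify_ph(df$ph)
  counts <- table(factor(as.character(df$cover), levels = covers), cond)
  prop <- counts / rowSums(counts)
  tab <- unclass(prop) * as.numeric(cover_areas[covers])
  dimnames(tab) <- list(cover = covers, condition = colnames(counts))
  structure(tab, class = c("condition_crosstab", "matrix", "array"),
            classifier = classifier, basis = "state")
}

#' @export
print.condition_crosstab <- function(x, ...) {
  cat(sprintf("Soil condition cross-tab (%s, %s basis), area in ha\n",
              attr(x, "classifier"), attr(x, "basis")))
  print(round(unclass(x), 1))
  invisible(x)
}

#' Soil condition of land subject to land-cover change
#'
#' For every cell that changed class between the two epochs, the soil
#' condition class is taken from the nearest sample (Euclidean distance
#' in grid row/column coordinates; ties broken by lowest `sample_id`),
#' and the cell areas are aggregated by (origin class, destination class,
#' condition class). This nearest-sample attribution is a deliberate
#' simplification of a design-based change estimator; see the package
#' vignette.
#'
#' @param samples A `soil_samples` table with grid `row`/`col` indices.
#' @param grid_t0,grid_t1 SEEA-nomenclature grids as in
#'   [change_matrix()].
#' @param classifier `"soc"` or `"ph"`.
#' @return A `change_condition_crosstab`: data frame with columns `from`,
#'   `to`, `condition` and `area_ha`, one row per observed combination
#'   (empty when nothing changed).
#' @export
change_condition_crosstab <- function(samples, grid_t0, grid_t1,
                                      classifier = c("soc", "ph")) {
  classifier <- match.arg(classifier)
  check_grid_pair(grid_t0, grid_t1)
  df <- as.data.frame(samples)
  if (!nrow(df)) stop("at least one sample is required")
  cond_levels <- if (classifier == "soc") soc_classes() else ph_classes()
  cond <- if (classifier == "soc")
    classify_soc(df$soc_g_per_kg, df$peat) else classify_ph(df$ph)
  a <- grid_t0$codes; b <- grid_t1$codes
  changed <- which(a != b & a != 0L, arr.ind = TRUE)
  out <- data.frame(from = integer(0), to = integer(0),
                    condition = factor(character(0), levels = cond_levels),
                    area_ha = numeric(0))
  if (!nrow(changed)) return(new_change_crosstab(out, classifier))
  ord <- order(df$sample_id)   # tie-break: lowest sample_id wins
  d2 <- outer(changed[, "row"], df$row[ord], "-")^2 +
    outer(changed[, "col"], df$col[ord], "-")^2
  nearest <- ord[max.col(-d2, ties.method = "first")]
  cell_ha <- grid_t0$cell_area_km2 * 100
  key <- data.frame(from = a[changed], to = b[changed],
                    condition = cond[nearest])
  agg <- stats::aggregate(list(n = rep(1L, nrow(key))),
                          by = key, FUN = sum)
  agg$area_ha <- agg$n * cell_ha
  agg$n <- NULL
  new_change_crosstab(agg[order(agg$from, agg$to), ], classifier)
}

new_change_crosstab <- function(df, classifier) {
  rownames(df) <- NULL
  structure(df, class = c("change_condition_crosstab", "data.frame"),
            classifier = classifier, basis = "change")
}

#' Marginals of a change-condition cross-tab
#'
#' Aggregates the changed area by condition class and, separately, by
#' origin and destination cover -- the published change panels can be read
#' on either basis, so both marginals are provided.
#'
#' @param x A `change_condition_crosstab`.
#' @return List of three named vectors (ha): `condition`, `origin`,
#'   `destination`.
#' @export
change_crosstab_marginals <- function(x) {
  stopifnot(inherits(x, "change_condition_crosstab"))
  df <- as.data.frame(x)
  by_of <- function(f) {
    if (!nrow(df)) return(stats::setNames(numeric(0), character(0)))
    v <- tapply(df$area_ha, df[[f]], sum)
    v <- v[!is.na(v)]   # factor levels with no changed area are absent
    stats::setNames(as.numeric(v), names(v))
  }
  list(condition = by_of("condition"), origin = by_of("from"),
       destination = by_of("to"))
}

#' Write a condition cross-tab as CSV
#'
#' Covers as rows, condition classes as columns, area in hectares.
#'
#' @param x A `condition_crosstab` or `change_condition_crosstab`.
#' @param path Output path.
#' @param comment Optional `#` comment line(s) before the header.
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(x, path, comment = NULL) {
  if (inherits(x, "condition_crosstab")) {
    df <- data.frame(cover = rownames(x), unclass(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
  }
  write_csv_commented(df, path, comment)
}

#' @export
plot.condition_crosstab <- function(x, ...) {
  m <- t(unclass(x))
  graphics::barplot(m, legend.text = rownames(m),
                    xlab = "SEEA cover class", ylab = "Area (ha)",
                    main = sprintf("Soil condition by land cover (%s)",
                                   attr(x, "classifier")), ...)
  invisible(x)
}
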