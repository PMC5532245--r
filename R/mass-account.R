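#' Soil formation rate bounds
#'
#' Pedogenesis rates at national scale are highly uncertain, so the mass
#' account is run under lower- and upper-bound formation rates. The
#' defaults, 0.4 and 1.4 t per hectare, bracket published estimates of the
#' attainable soil production rate in European conditions; cosmogenic
#' 10Be work on granite-derived soils (about 0.15 mm of new soil per year,
#' roughly 1.6 t/ha at typical bulk density) supports the upper bound's
#' order of magnitude.
#'
#' @param low,high Formation rates in t ha-1 (per `years` multiplier of
#'   the account); `0 <= low <= high`.
#' @return A `formation_rates` object (list with `low` and `high`).
#' @export
formation_rates <- function(low = 0.4, high = 1.4) {
  if (!is.numeric(low) || !is.numeric(high) || is.na(low) || is.na(high))
    stop("formation rates must be numeric")
  if (low < 0 || low > high)
    stop("formation rates must satisfy 0 <= low <= high")
  structure(list(low = low, high = high), class = "formation_rates")
}

#' Per-class gross erosion rates and sediment delivery fraction
#'
#' Gross rill-and-sheet erosion rates by SEEA class (t ha-1), typically
#' from an external erosion model, together with the fraction of gross
#' eroded mass delivered to watercourses rather than redeposited on land
#' (a whole-territory sediment-delivery ratio). The packaged default rates
#' are the EU-25 per-class rates implied by the published account cells
#' (see [eu_mass_inputs()]); the default delivery fraction is 0.10.
#'
#' @param gross_rates Named numeric vector of gross erosion rates
#'   (t ha-1), names = SEEA codes.
#' @param delivery_fraction Fraction of gross erosion lost to
#'   watercourses, in \[0, 1\].
#' @return An `erosion_params` object.
#' @export
erosion_params <- function(gross_rates, delivery_fraction = 0.10) {
  if (any(is.na(gross_rates)) || any(gross_rates < 0))
    stop("gross erosion rates must be non-negative")
  if (is.null(names(gross_rates)))
    stop("`gross_rates` must be named by SEEA class code")
  if (delivery_fraction < 0 || delivery_fraction > 1)
    stop("`delivery_fraction` must lie in [0, 1]")
  structure(list(gross_rates = gross_rates,
                 delivery_fraction = delivery_fraction),
            class = "erosion_params")
}

#' Soil mass formed over an area
#'
#' @param area Area in hectares (>= 0).
#' @param rate Formation rate in t ha-1 (>= 0).
#' @return Mass in tonnes, full precision (rounding to integer tonnes
#'   happens only when an account is written).
#' @examples
#' formation_mass(110464899, 1.4)
#' @export
formation_mass <- function(area, rate) {
  if (any(area < 0, na.rm = TRUE)) stop("`area` must be >= 0")
  if (any(rate < 0, na.rm = TRUE)) stop("`rate` must be >= 0")
  area * rate
}

#' Partition gross eroded mass into redeposition and loss to watercourses
#'
#' Of the soil mobilised by rill-and-sheet erosion, only a fraction (the
#' sediment delivery ratio) reaches watercourses; the rest is redeposited
#' on land, where it is mass-neutral for the territory. The loss is
#' rounded to integer tonnes first and redeposition takes the remainder,
#' so the pair always sums exactly to the gross mass.
#'
#' @param gross Gross eroded mass in tonnes (>= 0).
#' @param delivery_fraction Fraction delivered to watercourses, in
#'   \[0, 1\].
#' @return Named numeric vector `c(redeposited = , lost = )`.
#' @examples
#' partition_erosion(294941314, 0.10)
#' @export
partition_erosion <- function(gross, delivery_fraction = 0.10) {
  if (any(gross < 0, na.rm = TRUE)) stop("`gross` must be >= 0")
  if (delivery_fraction < 0 || delivery_fraction > 1)
    stop("`delivery_fraction` must lie in [0, 1]")
  lost <- round_half_away(delivery_fraction * gross)
  c(redeposited = gross - lost, lost = lost)
}

#' Build the per-land-cover soil mass-balance account
#'
#' For each accounted class the account records, as additions to stock,
#' soil formation under the high and low rate bounds and the deposition of
#' eroded soil on land; and, as reductions, the redeposited eroded mass
#' and the mass lost to watercourses. Deposition equals redeposition by
#' construction (within-territory redistribution is mass-neutral), so the
#' closing stock change reduces algebraically to
#' `closing_high = formation_high - lost` (and likewise for the low
#' bound). Opening stocks and mass sealed under construction are unknown
#' and carried as explicit missing values, never zero. Classes outside
#' `accounted_seea_classes()` (artificial, mangrove, aquatic, snow, water)
#' carry no soil mass flows and are emitted with missing cells to
#' preserve the 14-class layout.
#'
#' @param areas Named numeric vector of per-class areas in hectares;
#'   must cover every accounted class.
#' @param rates A [formation_rates()] object.
#' @param erosion An [erosion_params()] object with a gross rate for every
#'   accounted class with nonzero area.
#' @param years Period multiplier applied to all rates (default 1: the
#'   account is expressed per rate-unit period; see the package vignette
#'   on the annual-versus-period ambiguity in the published table).
#' @return A `mass_account`: data frame with one row per SEEA class and
#'   columns `code`, `name`, `area_ha`, `formation_high`, `formation_low`,
#'   `deposition`, `redeposited`, `lost`, `sealed`,
#'   `total_additions_high`, `total_additions_low`, `total_reductions`,
#'   `closing_high`, `closing_low` (masses in tonnes, full precision).
#' @examples
#' inp <- eu_mass_inputs()
#' ma <- build_mass_account(inp$areas, erosion = inp$erosion)
#' subset(ma, code == 2, c(name, closing_high, closing_low))
#' @export
build_mass_account <- function(areas, rates = formation_rates(),
                               erosion, years = 1) {
  stopifnot(inherits(rates, "formation_rates"),
            inherits(erosion, "erosion_params"))
  if (years < 0) stop("`years` must be >= 0")
  acc <- accounted_seea_classes()
  missing_cls <- setdiff(acc, as.integer(names(areas)))
  if (length(missing_cls))
    stop("missing area for accounted class(es): ",
         paste(missing_cls, collapse = ", "))
  if (any(areas < 0, na.rm = TRUE)) stop("areas must be >= 0")

  n <- 14L
  area_ha <- f_hi <- f_lo <- gross <- rep(NA_real_, n)
  for (k in acc) {
    a <- areas[[as.character(k)]]
    area_ha[k] <- a
    f_hi[k] <- formation_mass(a, rates$high) * years
    f_lo[k] <- formation_mass(a, rates$low) * years
    gr <- erosion$gross_rates[[as.character(k)]]
    if (is.null(gr)) {
      if (a > 0) stop("no gross erosion rate for accounted class ", k)
      gr <- 0
    }
    gross[k] <- a * gr * years
  }
  part <- vapply(gross, function(g) {
    if (is.na(g)) c(redeposited = NA_real_, lost = NA_real_)
    else partition_erosion(g, erosion$delivery_fraction)
  }, numeric(2))
  redep <- part["redeposited", ]
  lost <- part["lost", ]

  acct <- data.frame(
    code = 1:14,
    name = seea_classes()$name,
    area_ha = area_ha,
    formation_high = f_hi,
    formation_low = f_lo,
    deposition = redep,          # deposition == redeposited, mass-neutral
    redeposited = redep,
    lost = lost,
    sealed = rep(NA_real_, n),   # unknown, serialized as empty
    total_additions_high = f_hi + redep,
    total_additions_low = f_lo + redep,
    total_reductions = redep + lost,
    closing_high = f_hi - lost,
    closing_low = f_lo - lost,
    stringsAsFactors = FALSE
  )
  structure(acct, class = c("mass_account", "data.frame"),
            rates = rates, delivery_fraction = erosion$delivery_fraction,
            years = years)
}

#' @export
print.mass_account <- function(x, ...) {
  r <- attr(x, "rates")
  cat(sprintf(
    "Soil mass account (formation %.3g-%.3g t/ha, delivery fraction %.3g)\n",
    r$low, r$high, attr(x, "delivery_fraction")))
  df <- as.data.frame(x)
  df <- df[!is.na(df$area_ha), ]
  df$name <- substr(df$name, 1, 28)
  show <- c("code", "name", "formation_high", "redeposited", "lost",
            "closing_high", "closing_low")
  df[show[-(1:2)]] <- lapply(df[show[-(1:2)]], round_half_away)
  print(df[, show], row.names = FALSE)
  invisible(x)
}

#' @export
summary.mass_account <- function(object, ...) {
  nb <- net_balance_summary(object)
  dep <- nb$code[nb$depleting]
  cat("Soil mass account summary\n")
  cat(sprintf("  accounted area: %.6g ha\n",
              sum(object$area_ha, na.rm = TRUE)))
  cat(sprintf("  formation (high bound): %.6g t; lost to watercourses: %.6g t\n",
              sum(object$formation_high, na.rm = TRUE),
              sum(object$lost, na.rm = TRUE)))
  if (length(dep))
    cat("  depleting even at the high formation bound:",
        paste(seea_classes()$name[dep], collapse = ", "), "\n")
  else cat("  no class depleting at the high formation bound\n")
  invisible(nb)
}

#' Net soil mass balance and depletion flags
#'
#' A class is flagged as depleting when its closing stock change is
#' negative even under the optimistic (high) formation bound, i.e. erosion
#' loss cannot be offset by formation.
#'
#' @param acct A `mass_account`.
#' @return Data frame with columns `code`, `name`, `net_high`
#'   (formation_high minus gross erosion, tonnes), `depleting` (logical).
#' @export
net_balance_summary <- function(acct) {
  stopifnot(inherits(acct, "mass_account"))
  df <- as.data.frame(acct)
  gross <- df$redeposited + df$lost
  data.frame(code = df$code, name = df$name,
             net_high = df$formation_high - gross,
             depleting = !is.na(df$closing_high) & df$closing_high < 0,
             stringsAsFactors = FALSE)
}

#' Convert a soil depth rate to a mass rate
#'
#' One millimetre of soil over one hectare is 10 cubic metres, so a
#' depth-formation rate converts to mass as
#' `depth_mm * 10 * bulk_density`.
#'
#' @param depth_rate_mm Soil formation rate in mm yr-1 (> 0).
#' @param bulk_density Soil bulk density in t m-3 (> 0).
#' @return Mass rate in t ha-1 yr-1.
#' @examples
#' depth_rate_to_mass_rate(1, 1.0)      # 10 t/ha by unit identity
#' depth_rate_to_mass_rate(0.15, 1.067) # ~1.6 t/ha
#' @export
depth_rate_to_mass_rate <- function(depth_rate_mm, bulk_density) {
  if (any(depth_rate_mm <= 0) || any(bulk_density <= 0))
    stop("depth rate and bulk density must be > 0")
  depth_rate_mm * 10 * bulk_density
}

#' Write a mass account as CSV in the published table layout
#'
#' Account lines are rows, the 14 SEEA classes are columns; masses are
#' rounded half-away-from-zero to integer tonnes at write time. Unknown
#' cells (opening stock, sealed mass, classes with no flows) are written
#' empty, never as 0. The lost column is rounded before redeposition takes
#' the integer remainder, so each class's written pair sums exactly to its
#' written gross erosion.
#'
#' @param acct A `mass_account`.
#' @param path Output path.
#' @param comment Optional `#` comment line(s) before the header.
#' @return `path`, invisibly.
#' @export
write_mass_account <- function(acct, path, comment = NULL) {
  stopifnot(inherits(acct, "mass_account"))
  df <- as.data.frame(acct)
  r <- attr(acct, "rates")
  gross_r <- round_half_away(df$redeposited + df$lost)
  lost_r <- round_half_away(df$lost)
  redep_r <- gross_r - lost_r
  lines <- list(
    "Opening stock of resources" = rep(NA_real_, 14),
    "Soil formation (high rate, t)" = round_half_away(df$formation_high),
    "Soil formation (low rate, t)" = round_half_away(df$formation_low),
    "Soil deposition from erosion (t)" = redep_r,
    "Upward reappraisals" = ifelse(is.na(df$area_ha), NA_real_, 0),
    "Total additions to stock (high)" =
      round_half_away(df$formation_high) + redep_r,
    "Extraction (construction) sealed" = rep(NA_real_, 14),
    "Soil eroded redeposited (t)" = redep_r,
    "Soil eroded lost to water courses (t)" = lost_r,
    "Downward reappraisals" = ifelse(is.na(df$area_ha), NA_real_, 0),
    "Total reductions in stock" = redep_r + lost_r,
    "Closing stock (high rate)" = round_half_away(df$closing_high),
    "Closing stock (low rate)" = round_half_away(df$closing_low)
  )
  names(lines)[2] <- sprintf("Soil formation (%.1f t/ha)", r$high)
  names(lines)[3] <- sprintf("Soil formation (%.1f t/ha)", r$low)
  names(lines)[12] <- sprintf("Closing stock (%.1f t/ha)", r$high)
  names(lines)[13] <- sprintf("Closing stock (%.1f t/ha)", r$low)
  tab <- t(vapply(lines, fmt_cell, character(14)))
  out <- data.frame(account_line = names(lines), tab,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("account_line", paste0("class_", 1:14))
  write_csv_commented(out, path, comment)
}
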