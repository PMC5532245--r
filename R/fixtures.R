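#' Published EU-25 extent-account inputs, 2000-2012
#'
#' Loads the packaged per-class opening areas, net area flows and printed
#' closing areas (km2) for the EU-25 2000-2012 accounting period, compiled
#' from CORINE-based change reporting aggregated to the 14 SEEA classes.
#' Mangrove and permanent snow/glaciers carry no published value and are
#' `NA`. A few printed closings differ by 1 km2 from `opening + net`
#' (rounding in the source table); the printed values are kept verbatim,
#' so validation against this table should use the internally consistent
#' classes.
#'
#' @return Data frame with columns `seea_code`, `opening_km2`, `net_km2`,
#'   `closing_km2` (14 rows).
#' @seealso [eu_extent_account()]
#' @export
eu_extent_inputs <- function() {
  utils::read.csv(system.file("extdata", "eu25_extent_2000_2012.csv",
                              package = "soilcapital"),
                  comment.char = "#")
}

#' The EU-25 2000-2012 extent account
#'
#' Assembles the extent account from the packaged opening areas and net
#' flows via the account identity (see [extent_account_from_net()]).
#'
#' @return An `extent_account`.
#' @examples
#' ea <- eu_extent_account()
#' ea[ea$code == 1, "closing"]  # 107482 km2
#' @export
eu_extent_account <- function() {
  inp <- eu_extent_inputs()
  extent_account_from_net(inp$opening_km2, inp$net_km2,
                          epoch_pair = c("2000", "2012"))
}

#' EU-25 mass-account inputs: accounted areas and gross erosion rates
#'
#' Loads the packaged per-class areas (ha) and gross rill-and-sheet
#' erosion rates (t ha-1) for the eight accounted classes of the EU-25
#' soil mass-balance account. These inputs are back-solved from the
#' published account cells: the area reproduces both printed formation
#' masses (0.4 and 1.4 t/ha) under half-away-from-zero rounding, and the
#' rate is the printed gross eroded mass divided by that area. They stand
#' in for the external erosion-model surfaces, which are inputs, not part
#' of this package.
#'
#' @return List with `areas` (named vector, ha), `erosion`
#'   (an [erosion_params()] with delivery fraction 0.10) and `table`
#'   (the raw data frame).
#' @examples
#' inp <- eu_mass_inputs()
#' round(inp$erosion$gross_rates, 2)
#' @export
eu_mass_inputs <- function() {
  d <- utils::read.csv(system.file("extdata", "eu25_mass_inputs.csv",
                                   package = "soilcapital"),
                       comment.char = "#")
  areas <- stats::setNames(d$area_ha, d$seea_code)
  list(areas = areas,
       erosion = erosion_params(
         stats::setNames(d$gross_rate_t_per_ha, d$seea_code),
         delivery_fraction = 0.10),
       table = d)
}

#' The EU-25 2000-2012 soil mass-balance account
#'
#' Builds the mass account from the packaged inputs with the default
#' formation bounds (0.4-1.4 t/ha) and delivery fraction 0.10.
#'
#' @return A `mass_account`.
#' @examples
#' ma <- eu_mass_account()
#' net_balance_summary(ma)
#' @export
eu_mass_account <- function() {
  inp <- eu_mass_inputs()
  build_mass_account(inp$areas, formation_rates(), inp$erosion)
}
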