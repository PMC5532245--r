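#' The 14 interim SEEA land-cover classes
#'
#' Returns the interim land-cover classification used by the SEEA Central
#' Framework for extent accounting: 14 classes with integer codes 1-14.
#' The `managed` column marks the classes treated as under direct economic
#' management when splitting expansion/regression into managed and natural
#' flows (artificial surfaces and the three cropped systems); `accounted`
#' marks the classes that carry soil mass flows in the mass account
#' (terrestrial vegetated or bare covers -- artificial, mangrove, aquatic,
#' snow and water classes carry none).
#'
#' @return A data frame with columns `code` (integer 1-14), `name`
#'   (character), `managed` (logical) and `accounted` (logical).
#' @examples
#' seea_classes()
#' @export
seea_classes <- function() {
  data.frame(
    code = 1:14,
    name = c(
      "Artificial surfaces",
      "Herbaceous crops",
      "Woody crops",
      "Multiple or layered crops",
      "Grassland",
      "Tree covered areas",
      "Mangrove",
      "Shrub covered areas",
      "Shrubs and/or herbaceous vegetation, aquatic or regularly flooded",
      "Sparsely natural vegetated areas",
      "Terrestrial barren land",
      "Permanent snow and glaciers",
      "Inland water bodies",
      "Coastal water bodies and intertidal areas"
    ),
    managed = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 10)),
    accounted = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                  FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' SEEA codes of classes under direct economic management
#'
#' Convenience accessor for the default `managed_classes` argument of
#' [build_extent_account()]: artificial surfaces (1), herbaceous crops (2),
#' woody crops (3) and multiple or layered crops (4).
#'
#' @return Integer vector of SEEA codes.
#' @export
managed_seea_classes <- function() {
  cls <- seea_classes()
  cls$code[cls$managed]
}

#' SEEA codes of classes carrying soil mass flows
#'
#' The eight classes accounted for in the soil mass-balance account:
#' herbaceous crops (2), woody crops (3), multiple or layered crops (4),
#' grassland (5), tree covered areas (6), shrub covered areas (8),
#' sparsely natural vegetated areas (10) and terrestrial barren land (11).
#'
#' @return Integer vector of SEEA codes.
#' @export
accounted_seea_classes <- function() {
  cls <- seea_classes()
  cls$code[cls$accounted]
}

#' Read a CORINE-to-SEEA class mapping
#'
#' A class mapping assigns every 3-digit CORINE land-cover code to one of
#' the 14 SEEA classes. The default mapping shipped with the package covers
#' the full 44-code CORINE nomenclature: 1xx to artificial surfaces, 21x to
#' herbaceous crops, 22x to woody crops, 24x to multiple/layered crops,
#' 231 and 321 to grassland, 31x and 324 to tree cover, 322-323 to shrub
#' cover, 41x to aquatic/regularly flooded vegetation, 333 to sparsely
#' vegetated, 331/332/334 to barren, 335 to snow and glaciers, 51x to
#' inland water and 42x/52x to coastal water. No CORINE class maps to
#' mangrove (class 7), which is absent from Europe.
#'
#' @param path Path to a two-column CSV (`corine_code`, `seea_code`).
#'   Defaults to the packaged mapping.
#' @return A `class_mapping` object: data frame with columns `corine_code`
#'   and `seea_code`.
#' @examples
#' m <- read_class_mapping()
#' subset(m, corine_code == 312)  # coniferous forest -> tree covered areas
#' @export
read_class_mapping <- function(path = system.file("extdata",
                                                  "corine_seea_mapping.csv",
                                                  package = "soilcapital")) {
  m <- utils::read.csv(path, comment.char = "#")
  class_mapping(m)
}

#' Construct and validate a class mapping
#'
#' @param entries Data frame with integer columns `corine_code` and
#'   `seea_code`.
#' @return A validated `class_mapping` object.
#' @export
class_mapping <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("corine_code", "seea_code") %in% names(entries)))
  entries$corine_code <- as.integer(entries$corine_code)
  entries$seea_code <- as.integer(entries$seea_code)
  if (anyDuplicated(entries$corine_code))
    stop("class mapping assigns some CORINE code more than once")
  if (!all(entries$seea_code %in% 1:14))
    stop("SEEA codes in mapping must be in 1..14")
  structure(entries, class = c("class_mapping", "data.frame"))
}
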