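#' Build a land-cover extent account from a change matrix
#'
#' Assembles the SEEA extent-account ledger for one accounting period:
#' per-class opening area, additions to stock (managed expansion, natural
#' expansion, upward reappraisals), reductions in stock (managed
#' regression, natural regression, downward reappraisals; all non-positive)
#' and the closing area given by the account identity
#' `closing = opening + total additions + total reductions`.
#'
#' In `"net"` mode each class records only its net flow (column sum minus
#' row sum of the change matrix): a positive net is an expansion, a
#' negative net a regression, so at most one of the two totals is nonzero
#' per class. In `"gross"` mode expansion is the total inflow (column sum
#' minus the diagonal) and regression the negated total outflow; net
#' aggregation can hide large compensating flows, which gross mode exposes.
#' Flows into or out of a class in `managed_classes` are recorded under the
#' managed heading, all others under the natural heading. Reappraisal rows
#' are part of the account layout but are always 0 here.
#'
#' Mangrove (class 7) does not occur in the CORINE nomenclature; when a
#' grid-derived account has no mangrove area the class is reported as
#' missing (`NA`), not as zero.
#'
#' @param cm A [change_matrix()].
#' @param opening_areas Optional named per-class opening areas (km2);
#'   defaults to the matrix row sums. Checked against the row sums.
#' @param managed_classes SEEA codes treated as under direct economic
#'   management; default artificial surfaces and the cropped systems
#'   (1, 2, 3, 4).
#' @param mode `"net"` (default, the published account layout) or
#'   `"gross"`.
#' @param tolerance Maximum absolute discrepancy (km2) allowed between
#'   `opening_areas` and the matrix row sums.
#' @return An `extent_account`: a data frame with one row per SEEA class
#'   and columns `code`, `name`, `opening`, `managed_expansion`,
#'   `natural_expansion`, `upward_reappraisal`, `total_additions`,
#'   `managed_regression`, `natural_regression`, `downward_reappraisal`,
#'   `total_reductions`, `closing` (all areas km2).
#' @examples
#' g0 <- land_cover_grid(matrix(c(2L, 2L, 6L, 6L), 2, 2), 1, "2000")
#' g1 <- land_cover_grid(matrix(c(1L, 2L, 6L, 6L), 2, 2), 1, "2006")
#' acct <- build_extent_account(change_matrix(g0, g1))
#' subset(acct, code %in% c(1, 2))
#' @export
build_extent_account <- function(cm, opening_areas = NULL,
                                 managed_classes = managed_seea_classes(),
                                 mode = c("net", "gross"),
                                 tolerance = 1e-6) {
  stopifnot(inherits(cm, "change_matrix"))
  mode <- match.arg(mode)
  m <- unclass(cm)
  row_tot <- rowSums(m)
  col_tot <- colSums(m)
  if (is.null(opening_areas)) {
    opening <- row_tot
  } else {
    opening <- as.numeric(opening_areas)[match(as.character(1:14),
                                               names(opening_areas))]
    resid <- opening - row_tot
    bad <- which(!is.na(resid) & abs(resid) > tolerance)
    if (length(bad))
      stop("opening areas inconsistent with change-matrix row sums; ",
           "per-class residuals (km2): ",
           paste(sprintf("class %d: %+g", bad, resid[bad]), collapse = ", "))
  }
  if (mode == "net") {
    net <- col_tot - row_tot
    expansion <- pmax(net, 0)
    regression <- pmin(net, 0)
  } else {
    expansion <- col_tot - diag(m)
    regression <- -(row_tot - diag(m))
  }
  managed <- 1:14 %in% managed_classes
  acct <- new_extent_account(
    opening = opening,
    managed_expansion = ifelse(managed, expansion, 0),
    natural_expansion = ifelse(managed, 0, expansion),
    managed_regression = ifelse(managed, regression, 0),
    natural_regression = ifelse(managed, 0, regression),
    epoch_pair = attr(cm, "epoch_pair"), mode = mode)
  # mangrove never appears in CORINE-derived grids: absent, not zero
  if (opening[7] == 0 && col_tot[7] == 0)
    acct[7, c("opening", "total_additions", "total_reductions",
              "closing")] <- NA_real_
  acct
}

#' Assemble an extent account from per-class net flows
#'
#' Builds the account ledger directly from opening areas and per-class net
#' area changes, without a change matrix. This is the entry point for
#' published account tables that report only net flows (which need not sum
#' exactly to zero across classes once rounded to km2); the identity
#' `closing = opening + additions + reductions` is applied per class.
#'
#' @param opening Named or positional numeric vector of 14 opening areas
#'   (km2); `NA` marks a class absent from the territory.
#' @param net Numeric vector of 14 net area changes (km2); positive =
#'   expansion, negative = regression, `NA` treated as 0 flow on an
#'   absent class.
#' @param managed_classes As in [build_extent_account()].
#' @param epoch_pair Character vector of two epoch labels.
#' @return An `extent_account`.
#' @export
extent_account_from_net <- function(opening, net,
                                    managed_classes = managed_seea_classes(),
                                    epoch_pair = c("", "")) {
  stopifnot(length(opening) == 14, length(net) == 14)
  opening <- as.numeric(opening)
  net <- ifelse(is.na(net), 0, as.numeric(net))
  managed <- 1:14 %in% managed_classes
  new_extent_account(
    opening = opening,
    managed_expansion = ifelse(managed, pmax(net, 0), 0),
    natural_expansion = ifelse(managed, 0, pmax(net, 0)),
    managed_regression = ifelse(managed, pmin(net, 0), 0),
    natural_regression = ifelse(managed, 0, pmin(net, 0)),
    epoch_pair = epoch_pair, mode = "net")
}

new_extent_account <- function(opening, managed_expansion, natural_expansion,
                               managed_regression, natural_regression,
                               upward_reappraisal = numeric(14),
                               downward_reappraisal = numeric(14),
                               epoch_pair = c("", ""), mode = "net") {
  total_additions <- managed_expansion + natural_expansion +
    upward_reappraisal
  total_reductions <- managed_regression + natural_regression +
    downward_reappraisal
  if (any(total_reductions > 0, na.rm = TRUE))
    stop("reductions in stock must be non-positive")
  acct <- data.frame(
    code = 1:14,
    name = seea_classes()$name,
    opening = opening,
    managed_expansion = managed_expansion,
    natural_expansion = natural_expansion,
    upward_reappraisal = upward_reappraisal,
    total_additions = total_additions,
    managed_regression = managed_regression,
    natural_regression = natural_regression,
    downward_reappraisal = downward_reappraisal,
    total_reductions = total_reductions,
    closing = opening + total_additions + total_reductions,
    stringsAsFactors = FALSE
  )
  structure(acct, class = c("extent_account", "data.frame"),
            epoch_pair = epoch_pair, mode = mode)
}

#' @export
print.extent_account <- function(x, digits = 0, ...) {
  ep <- attr(x, "epoch_pair") %||% c("", "")
  cat(sprintf("Land-cover extent account (%s mode), %s -> %s\n",
              attr(x, "mode") %||% "net",
              if (nzchar(ep[1])) ep[1] else "opening",
              if (nzchar(ep[2])) ep[2] else "closing"))
  df <- as.data.frame(x)
  df$name <- substr(df$name, 1, 28)
  num <- vapply(df, is.numeric, logical(1)); num["code"] <- FALSE
  df[num] <- lapply(df[num], round, digits)
  print(df[, c("code", "name", "opening", "total_additions",
               "total_reductions", "closing")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.extent_account <- function(object, ...) {
  df <- as.data.frame(object)
  net <- df$closing - df$opening
  cat("Extent account summary\n")
  cat(sprintf("  classified opening area: %.6g km2\n",
              sum(df$opening, na.rm = TRUE)))
  cat(sprintf("  gross additions: %.6g km2, gross reductions: %.6g km2\n",
              sum(df$total_additions, na.rm = TRUE),
              sum(df$total_reductions, na.rm = TRUE)))
  up <- which(!is.na(net) & net > 0); dn <- which(!is.na(net) & net < 0)
  if (length(up))
    cat("  expanding:", paste0(df$name[up], " (+", round(net[up]), ")",
                               collapse = ", "), "\n")
  if (length(dn))
    cat("  regressing:", paste0(df$name[dn], " (", round(net[dn]), ")",
                                collapse = ", "), "\n")
  invisible(data.frame(code = df$code, net_km2 = net))
}

#' Net land-cover change per class, absolute and relative
#'
#' @param acct An `extent_account`.
#' @param total_area Total classified territory (km2) used as the
#'   denominator of the percentage; must be positive.
#' @return Data frame with columns `code`, `name`, `net_km2`
#'   (closing minus opening, sign preserved) and `net_pct`
#'   (100 * net / total_area).
#' @examples
#' ea <- eu_extent_account()
#' net_change_summary(ea, total_area = sum(ea$opening, na.rm = TRUE))
#' @export
net_change_summary <- function(acct, total_area) {
  stopifnot(inherits(acct, "extent_account"))
  if (!is.numeric(total_area) || length(total_area) != 1 || total_area <= 0)
    stop("`total_area` must be a single positive number")
  df <- as.data.frame(acct)
  net <- df$closing - df$opening
  data.frame(code = df$code, name = df$name, net_km2 = net,
             net_pct = 100 * net / total_area, stringsAsFactors = FALSE)
}

#' Write an extent account as CSV in the published table layout
#'
#' Account lines are rows and the 14 SEEA classes are columns. Areas are
#' rounded half-away-from-zero to whole km2 at write time only; absent
#' classes (NA) are written as empty cells.
#'
#' @param acct An `extent_account`.
#' @param path Output path.
#' @param comment Optional `#` comment line(s) written before the header
#'   (provenance: version, config hash, seed).
#' @return `path`, invisibly.
#' @export
write_extent_account <- function(acct, path, comment = NULL) {
  stopifnot(inherits(acct, "extent_account"))
  rows <- c(opening = "Opening area (km2)",
            managed_expansion = "Managed expansion",
            natural_expansion = "Natural expansion",
            upward_reappraisal = "Upward reappraisals",
            total_additions = "Total additions to stock",
            managed_regression = "Managed regression",
            natural_regression = "Natural regression",
            downward_reappraisal = "Downward reappraisals",
            total_reductions = "Total reductions in stock",
            closing = "Closing area (km2)")
  df <- as.data.frame(acct)
  tab <- t(vapply(names(rows),
                  function(f) fmt_cell(round_half_away(df[[f]])),
                  character(14)))
  out <- data.frame(account_line = unname(rows), tab,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("account_line", paste0("class_", 1:14))
  write_csv_commented(out, path, comment)
}

#' @export
plot.extent_account <- function(x, ...) {
  df <- as.data.frame(x)
  net <- df$closing - df$opening
  keep <- !is.na(net)
  graphics::barplot(net[keep], names.arg = df$code[keep],
                    xlab = "SEEA class", ylab = "Net change (km2)",
                    main = "Net land-cover change", ...)
  invisible(x)
}
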