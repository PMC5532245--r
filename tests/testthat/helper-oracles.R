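# Independent brute-force oracles used by the property tests. These stay
# deliberately naive (explicit per-cell loops, closed forms) and share no
# code with the implementation they check.

# naive per-cell double-loop change tally
brute_change_matrix <- function(g0, g1) {
  m <- matrix(0, 14, 14)
  for (r in seq_len(nrow(g0$codes))) {
    for (cc in seq_len(ncol(g0$codes))) {
      i <- g0$codes[r, cc]; j <- g1$codes[r, cc]
      if (i != 0L) m[i, j] <- m[i, j] + g0$cell_area_km2
    }
  }
  m
}

# hand ledger from matrix marginals (net mode)
brute_net_ledger <- function(m, managed = c(1, 2, 3, 4)) {
  net <- colSums(m) - rowSums(m)
  data.frame(code = 1:14,
             opening = rowSums(m),
             managed_expansion = ifelse(1:14 %in% managed, pmax(net, 0), 0),
             natural_expansion = ifelse(1:14 %in% managed, 0, pmax(net, 0)),
             managed_regression = ifelse(1:14 %in% managed, pmin(net, 0), 0),
             natural_regression = ifelse(1:14 %in% managed, 0, pmin(net, 0)),
             closing = rowSums(m) + net)
}

# exhaustive nearest-sample assignment for changed cells
brute_nearest_condition <- function(samples, g0, g1, classifier) {
  df <- as.data.frame(samples)
  cond <- if (classifier == "soc") classify_soc(df$soc_g_per_kg, df$peat)
          else classify_ph(df$ph)
  out <- list()
  for (r in seq_len(nrow(g0$codes))) {
    for (cc in seq_len(ncol(g0$codes))) {
      i <- g0$codes[r, cc]; j <- g1$codes[r, cc]
      if (i == 0L || i == j) next
      d <- sqrt((df$row - r)^2 + (df$col - cc)^2)
      best <- which(d == min(d))
      best <- best[which.min(df$sample_id[best])]
      out[[length(out) + 1]] <- data.frame(
        from = i, to = j, condition = as.character(cond[best]),
        area_ha = g0$cell_area_km2 * 100)
    }
  }
  if (!length(out)) return(NULL)
  agg <- stats::aggregate(area_ha ~ from + to + condition,
                          do.call(rbind, out), sum)
  agg[order(agg$from, agg$to, agg$condition), ]
}

# random SEEA grid (no nodata unless asked)
random_seea_grid <- function(nr, nc, classes = 1:14, cell_area = 1,
                             epoch = "", p_nodata = 0) {
  codes <- matrix(sample(classes, nr * nc, replace = TRUE), nr, nc)
  if (p_nodata > 0)
    codes[stats::runif(nr * nc) < p_nodata] <- 0L
  land_cover_grid(codes, cell_area, epoch)
}

# closed-form per-cover condition-class probabilities implied by the
# generator's parametric distributions and the classification thresholds
expected_soc_probs <- function(p) {
  pk <- p$peat_prob
  po <- stats::plnorm(120, p$soc_meanlog, p$soc_sdlog, lower.tail = FALSE)
  pm <- stats::plnorm(30, p$soc_meanlog, p$soc_sdlog)
  c(peat = pk, organo_mineral = (1 - pk) * po,
    humus_mineral = (1 - pk) * (1 - po - pm), mineral = (1 - pk) * pm)
}

expected_ph_probs <- function(p) {
  z <- function(x) stats::pnorm(x, p$ph_mean, p$ph_sd)
  tot <- z(10) - z(3)
  br <- c(3, 4.5, 5, 6, 7, 8.3, 10)
  q <- diff(z(br)) / tot
  names(q) <- ph_classes()
  q
}
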