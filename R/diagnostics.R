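# Stoichiometric analysis: size-class N:P decomposition and its residual
# acclimation signal, the latitudinal coefficient of variation, paired
# P-storage estimation from culture tables, biomass-weighted trait
# histograms, and zonal profiles.

#' Size-class N:P decomposition
#'
#' `N:P_Size = f_S * M_S + (1 - f_S) * M_L`: the part of the bulk N:P
#' explained purely by the mix of the two size classes, using fixed global
#' mean class ratios. The residual `delta_NP = N:P - N:P_Size` quantifies
#' within-class physiological acclimation (including variable P storage).
#'
#' @param f_S small-class biomass fraction in `[0, 1]` (vectorized).
#' @param M_S,M_L global mean N:P of the small and large class, mol/mol.
#' @param total_NP optional local total N:P; when supplied, `delta_NP` is
#'   returned alongside.
#' @return if `total_NP` is NULL, the `NP_size` vector; otherwise a
#'   data.frame with `NP_size` and `delta_NP`.
#' @export
np_size <- function(f_S, M_S, M_L, total_NP = NULL) {
  if (any(!is.finite(f_S) | f_S < 0 | f_S > 1)) {
    stop("np_size: f_S must be within [0, 1]")
  }
  if (M_S <= 0 || M_L <= 0) stop("np_size: M_S and M_L must be positive")
  nps <- f_S * M_S + (1 - f_S) * M_L
  if (is.null(total_NP)) return(nps)
  data.frame(NP_size = nps, delta_NP = total_NP - nps)
}

#' Coefficient of variation of a latitudinal profile
#'
#' `CV = sigma / mean` with the population (n-denominator) standard
#' deviation, applied to the per-latitude mean values of a field.
#'
#' @param x numeric series (e.g. zonal means); must be nonempty with a
#'   positive mean.
#' @param na.rm drop missing values first.
#' @return the scalar CV.
#' @export
coefficient_of_variation <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[is.finite(x)]
  if (length(x) == 0L) stop("coefficient_of_variation: empty series")
  m <- mean(x)
  if (!is.finite(m) || m <= 0) {
    stop("coefficient_of_variation: mean must be positive")
  }
  sqrt(mean((x - m)^2)) / m
}

#' Phosphorus storage estimated from paired cultures
#'
#' Implements the paired-culture estimate of luxury P storage: for each
#' N-limited observation in a culture table, find the P-limited observation
#' of the same group with the closest growth rate (within `mu_tol`); the
#' storage estimate is `P:C(N-limited) - P:C(P-limited)`, floored at zero.
#' Under N limitation cells fill their P stores from the replete medium;
#' under P limitation they hold only structural P, so the difference
#' isolates the storage pool.
#'
#' @param table culture table with columns `group`, `mu`, `limitation`,
#'   `PC` (as produced by [run_culture_grid()] or
#'   [lab_compilation_reader()]).
#' @param mu_tol maximum growth-rate gap for an admissible pair, d^-1.
#' @return list with `pairs` (one row per N-limited observation with a
#'   match: group, mu of both members, estimate) and `summary` (per group:
#'   n, median and quartiles of the estimates); observations without an
#'   admissible pair are counted in `skipped` with a reason.
#' @export
p_storage_from_pairs <- function(table, mu_tol = 0.1) {
  need <- c("group", "mu", "limitation", "PC")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0L) {
    stop("p_storage_from_pairs: missing columns: ",
         paste(missing, collapse = ", "))
  }
  pairs <- list(); skipped <- list()
  for (g in unique(table$group)) {
    sub <- table[table$group == g, ]
    nlim <- sub[sub$limitation == "N", ]
    plim <- sub[sub$limitation == "P", ]
    if (nrow(nlim) == 0L || nrow(plim) == 0L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        group = g, n = nrow(sub),
        reason = "needs both N-limited and P-limited observations")
      next
    }
    for (r in seq_len(nrow(nlim))) {
      gap <- abs(plim$mu - nlim$mu[r])
      j <- which.min(gap)
      if (gap[j] > mu_tol) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          group = g, n = 1L,
          reason = sprintf("no P-limited partner within %.3g d^-1 of mu = %.3g",
                           mu_tol, nlim$mu[r]))
        next
      }
      pairs[[length(pairs) + 1L]] <- data.frame(
        group = g, mu_N = nlim$mu[r], mu_P = plim$mu[j],
        PC_N = nlim$PC[r], PC_P = plim$PC[j],
        storage = max(nlim$PC[r] - plim$PC[j], 0))
    }
  }
  pairs <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(group = character(), mu_N = numeric(), mu_P = numeric(),
               PC_N = numeric(), PC_P = numeric(), storage = numeric())
  summ <- do.call(rbind, lapply(split(pairs, pairs$group), function(d) {
    q <- stats::quantile(d$storage, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = d$group[1], n = nrow(d),
               q1 = q[1], median = q[2], q3 = q[3])
  }))
  if (is.null(summ)) summ <- data.frame(group = character(), n = integer(),
                                        q1 = numeric(), median = numeric(),
                                        q3 = numeric())
  rownames(summ) <- NULL
  list(pairs = pairs, summary = summ,
       skipped = if (length(skipped) > 0L) do.call(rbind, skipped) else
         data.frame(group = character(), n = integer(), reason = character()))
}

#' Biomass-weighted histogram of stoichiometric ratios
#'
#' Bins biomass by one or two trait ratios (e.g. N:C and P:C, or N:P with
#' bin width 1) and reports the weighted counts, the modal bin, and the
#' span of occupied bins. Total binned biomass equals total input biomass.
#'
#' @param weights biomass per observation (cell x class), any consistent
#'   unit.
#' @param x first ratio per observation.
#' @param y optional second ratio (2-D histogram when supplied).
#' @param breaks_x,breaks_y numeric break vectors, or a scalar bin width
#'   (breaks are then built to cover the data range).
#' @param occupancy_frac a bin is "occupied" when it carries at least this
#'   fraction of the total weight (default 1e-3, i.e. anything that would be
#'   visible in a log-shaded trait histogram).
#' @return list with `table` (data.frame: bin centers, weight), `mode`
#'   (center(s) of the heaviest bin), `occupied_range_x` (min/max centers of
#'   occupied bins along x) and `total_weight`.
#' @export
biomass_weighted_histogram <- function(weights, x, y = NULL,
                                       breaks_x = 1, breaks_y = NULL,
                                       occupancy_frac = 1e-3) {
  if (length(weights) != length(x) ||
      (!is.null(y) && length(y) != length(x))) {
    stop("biomass_weighted_histogram: misaligned input lengths")
  }
  keep <- is.finite(weights) & is.finite(x) & weights > 0 &
    (if (is.null(y)) TRUE else is.finite(y))
  weights <- weights[keep]; x <- x[keep]; if (!is.null(y)) y <- y[keep]
  mk_breaks <- function(v, br) {
    if (length(br) > 1L) return(br)
    lo <- floor(min(v) / br) * br
    hi <- ceiling(max(v) / br) * br
    seq(lo, hi + br / 2, by = br)
  }
  bx <- mk_breaks(x, breaks_x)
  ix <- cut(x, breaks = bx, include.lowest = TRUE, labels = FALSE)
  cx <- (bx[-length(bx)] + bx[-1]) / 2
  if (is.null(y)) {
    w <- tapply(weights, factor(ix, levels = seq_along(cx)), sum,
                default = 0)
    tab <- data.frame(x = cx, weight = as.numeric(w))
  } else {
    if (is.null(breaks_y)) breaks_y <- breaks_x
    by <- mk_breaks(y, breaks_y)
    iy <- cut(y, breaks = by, include.lowest = TRUE, labels = FALSE)
    cy <- (by[-length(by)] + by[-1]) / 2
    w <- tapply(weights,
                list(factor(ix, levels = seq_along(cx)),
                     factor(iy, levels = seq_along(cy))), sum, default = 0)
    tab <- expand.grid(x = cx, y = cy)
    tab$weight <- as.numeric(w)
  }
  total <- sum(weights)
  mode_row <- tab[which.max(tab$weight), , drop = FALSE]
  occ <- tab$weight >= occupancy_frac * total & tab$weight > 0
  occupied_range_x <- if (any(occ)) range(tab$x[occ]) else c(NA_real_, NA_real_)
  list(table = tab, mode = mode_row, occupied_range_x = occupied_range_x,
       total_weight = total)
}

#' Zonal profiles from a grid result
#'
#' Per-latitude means over the photic analysis depth (default top 260 m) of
#' N:C, P:C, N:P, the small-class fraction and dissolved nutrients.
#' Biomass-weighted by default (each cell's classes weighted by their
#' biomass); volume-weighted mode averages the bulk cell ratios with equal
#' weight per cell.
#'
#' @param result a `grid_result` from [run_grid()].
#' @param max_depth analysis depth, m.
#' @param weighting `"biomass"` or `"volume"`.
#' @return data.frame, one row per latitude: `lat`, `NC`, `PC`, `NP`,
#'   `f_S`, `NO3`, `PO4`, `Fe`, `biomass`; latitudes whose band is empty
#'   (no finite biomass) carry `NA` and are flagged in the `missing`
#'   attribute.
#' @export
zonal_profiles <- function(result, max_depth = 260, weighting = c("biomass", "volume")) {
  weighting <- match.arg(weighting)
  cells <- result$cells[result$cells$depth <= max_depth, ]
  out <- lapply(split(cells, cells$lat), function(d) {
    Bs <- d$B_small; Bl <- d$B_large
    totB <- sum(Bs + Bl, na.rm = TRUE)
    if (!is.finite(totB) || totB <= 0) {
      return(data.frame(lat = d$lat[1], NC = NA, PC = NA, NP = NA, f_S = NA,
                        NO3 = mean(d$NO3), PO4 = mean(d$PO4), Fe = mean(d$Fe),
                        biomass = 0))
    }
    if (weighting == "biomass") {
      N <- sum(Bs * d$Q_N_small + Bl * d$Q_N_large, na.rm = TRUE)
      P <- sum(Bs * d$Q_P_small + Bl * d$Q_P_large, na.rm = TRUE)
      C <- totB
    } else {
      nc_cell <- (Bs * d$Q_N_small + Bl * d$Q_N_large) / (Bs + Bl)
      pc_cell <- (Bs * d$Q_P_small + Bl * d$Q_P_large) / (Bs + Bl)
      N <- mean(nc_cell, na.rm = TRUE); P <- mean(pc_cell, na.rm = TRUE); C <- 1
    }
    data.frame(lat = d$lat[1], NC = N / C, PC = P / C, NP = N / P,
               f_S = sum(Bs) / totB,
               NO3 = mean(d$NO3), PO4 = mean(d$PO4), Fe = mean(d$Fe),
               biomass = totB)
  })
  prof <- do.call(rbind, out)
  rownames(prof) <- NULL
  prof <- prof[order(prof$lat), ]
  attr(prof, "missing") <- prof$lat[!is.finite(prof$NC)]
  prof
}

#' Population table from a grid result
#'
#' Flattens a `grid_result` into one row per (cell, class) with biomass,
#' stoichiometric ratios and an area weight (`cos(lat)`), the input for the
#' biomass-weighted histograms.
#'
#' @param result a `grid_result`.
#' @param max_depth analysis depth, m.
#' @return data.frame with `lat`, `depth`, `class`, `biomass` (area-weighted
#'   mmol C m^-3), `NC`, `PC`, `NP`.
#' @export
population_table <- function(result, max_depth = 260) {
  cells <- result$cells[result$cells$depth <= max_depth, ]
  w <- cos(cells$lat * pi / 180)
  mk <- function(cl) {
    B <- cells[[paste0("B_", cl)]]
    qn <- cells[[paste0("Q_N_", cl)]]
    qp <- cells[[paste0("Q_P_", cl)]]
    data.frame(lat = cells$lat, depth = cells$depth, class = cl,
               biomass = B * w, NC = qn, PC = qp, NP = qn / qp)
  }
  out <- rbind(mk("small"), mk("large"))
  out[is.finite(out$biomass) & out$biomass > 0, ]
}
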