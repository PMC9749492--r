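# Steady-state macromolecular allocation core.
#
# The model resolves coarse-grained macromolecular pools (photosynthetic,
# biosynthetic and constitutive protein; RNA; DNA; chlorophyll; thylakoid
# phospholipid; other C; and storage pools for C, N, P and Fe), each with a
# fixed elemental ratio. Under the pseudo-steady-state assumption each
# elemental quota is a quadratic function of growth rate whose coefficients
# depend on light through the chlorophyll demand, and the map is inverted in
# closed form to get the growth rate a given quota can support.

#' Chlorophyll-specific photosynthesis rate
#'
#' Saturating light response `v_I = v_I_max * (1 - exp(-A_I * I))` with
#' `A_I` the (positive) light-response coefficient.
#'
#' @param I light intensity, umol m^-2 s^-1 (scalar or vector, `>= 0`).
#' @param params an [alloc_params] object.
#' @return rate in mol C (mol C in Chl)^-1 d^-1, bounded by `v_I_max`.
#' @export
photosynthesis_rate <- function(I, params) {
  if (any(!is.finite(I) | I < 0)) stop("photosynthesis_rate: I must be >= 0")
  params$v_I_max * (1 - exp(-abs(params$A_I) * I))
}

#' Light-dependent chlorophyll coefficients
#'
#' `A_Chl = (1 + E)/v_I` (chlorophyll required per unit growth rate) and
#' `B_Chl = m/v_I` (maintenance chlorophyll), both diverging as light, and
#' hence `v_I`, goes to zero.
#'
#' @inheritParams photosynthesis_rate
#' @return list with `v_I`, `A_Chl` (d) and `B_Chl` (dimensionless);
#'   vectorized over `I`.
#' @export
light_coefficients <- function(I, params) {
  if (any(!is.finite(I) | I < 0)) stop("light_coefficients: I must be >= 0")
  if (any(I == 0)) {
    stop("light_coefficients: degenerate light I = 0 (infinite chlorophyll demand)",
         call. = FALSE)
  }
  v_I <- photosynthesis_rate(I, params)
  list(v_I = v_I, A_Chl = (1 + params$E) / v_I, B_Chl = params$m / v_I)
}

#' Quadratic quota coefficients
#'
#' Coefficients `(a, b, c)` of the structural quota `Q_i = a*mu^2 + b*mu + c`
#' for element `i` in N, P, C, at a given light intensity. `c` is the
#' structural quota at zero growth; every `a` carries the RNA coefficient
#' `A_RNA_P` as a factor (RNA scales with growth rate times protein).
#'
#' @param element one of `"N"`, `"P"`, `"C"`.
#' @inheritParams photosynthesis_rate
#' @return list with `element`, `a`, `b`, `c` (vectorized over `I`).
#' @export
quota_coefficients <- function(element, I, params) {
  element <- match.arg(element, c("N", "P", "C"))
  lc <- light_coefficients(I, params)
  .quota_coefficients_lc(element, lc, params)
}

# Internal: coefficients from precomputed light coefficients.
.quota_coefficients_lc <- function(element, lc, p) {
  A_Chl <- lc$A_Chl; B_Chl <- lc$B_Chl
  # protein C is A_Pho*(A_Chl*mu + B_Chl) + A_Bio*mu + Q_C_Pro_Other, so the
  # growth-proportional and constant protein parts recur in every element:
  pro_mu <- p$A_Pho * A_Chl + p$A_Bio
  pro_0 <- p$A_Pho * B_Chl + p$Q_C_Pro_Other
  if (element == "N") {
    a <- p$A_RNA_P * pro_mu * p$Y_RNA_NP
    b <- pro_mu * p$Y_Pro_NC + A_Chl * p$Y_Chl_NC + p$A_RNA_P * pro_0 * p$Y_RNA_NP
    c <- B_Chl * p$Y_Chl_NC + pro_0 * p$Y_Pro_NC +
      p$Q_P_min_RNA * p$Y_RNA_NP + p$Q_C_DNA * p$Y_DNA_NC
  } else if (element == "P") {
    a <- p$A_RNA_P * pro_mu
    b <- p$A_RNA_P * pro_0 + p$A_Pho_PChl * A_Chl
    c <- p$Q_P_min_RNA + p$Q_C_DNA * p$Y_DNA_PC + p$A_Pho_PChl * B_Chl +
      p$Q_P_Other
  } else {
    chl_cost <- 1 + p$A_Pho + p$A_Pho_PChl * p$Y_Plip_CP
    a <- p$A_RNA_P * pro_mu * p$Y_RNA_CP
    b <- A_Chl * chl_cost + p$A_Bio + p$A_RNA_P * pro_0 * p$Y_RNA_CP
    c <- chl_cost * B_Chl + p$Q_C_Pro_Other + p$Q_P_min_RNA * p$Y_RNA_CP +
      p$Q_C_DNA + p$Q_C_Other
  }
  list(element = element, a = a, b = b, c = c)
}

#' Growth rate supported by a single element
#'
#' Inverts the structural-quota relationship for one element, neglecting
#' storage: the nonnegative root of `a*mu^2 + b*mu + (c - Q_i) = 0` for N, P
#' and C (with `Q_C = 1`), or the linear inversion
#' `mu_Fe = (Q_Fe - A_Pho_Fe*B_Chl) / (A_Pho_Fe*A_Chl)` for Fe. Clamped at 0
#' when the quota is at or below the structural minimum `c_i` (the cell
#' cannot build structure, so it cannot grow).
#'
#' @param element one of `"N"`, `"P"`, `"C"`, `"Fe"`.
#' @param Q_i elemental quota (ignored for C, which is fixed at 1; pass
#'   `Q_i = 1` or leave the default).
#' @inheritParams photosynthesis_rate
#' @return growth rate, d^-1 (vectorized over `Q_i` / `I`).
#' @export
growth_if_limited <- function(element, Q_i = 1, I, params) {
  element <- match.arg(element, c("N", "P", "C", "Fe"))
  if (any(!is.finite(Q_i) | Q_i <= 0)) stop("growth_if_limited: Q_i must be > 0")
  lc <- light_coefficients(I, params)
  .growth_if_limited_lc(element, Q_i, lc, params)
}

.growth_if_limited_lc <- function(element, Q_i, lc, params) {
  if (element == "Fe") {
    mu <- (Q_i - params$A_Pho_Fe * lc$B_Chl) / (params$A_Pho_Fe * lc$A_Chl)
    return(pmax(mu, 0))
  }
  if (element == "C") Q_i <- rep(1, max(length(lc$A_Chl), length(Q_i)))
  qc <- .quota_coefficients_lc(element, lc, params)
  .solve_quota_quadratic(qc$a, qc$b, qc$c, Q_i)
}

# Nonnegative root of a*mu^2 + b*mu + c = Q, clamped at 0 for Q <= c, with a
# linear fallback when a == 0.
.solve_quota_quadratic <- function(a, b, c, Q) {
  n <- max(length(a), length(b), length(c), length(Q))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); Q <- rep_len(Q, n)
  mu <- numeric(n)
  feas <- Q > c
  quad <- feas & a > 0
  lin <- feas & a == 0
  if (any(quad)) {
    disc <- b[quad]^2 - 4 * a[quad] * (c[quad] - Q[quad])
    if (any(disc < 0)) {
      stop("growth_if_limited: negative discriminant with Q_i > c_i; ",
           "parameters are inconsistent")
    }
    mu[quad] <- (-b[quad] + sqrt(disc)) / (2 * a[quad])
  }
  if (any(lin)) mu[lin] <- (Q[lin] - c[lin]) / b[lin]
  mu
}

#' Liebig growth rate
#'
#' Evaluates the four single-element growth rates (each neglecting storage)
#' and applies Liebig's Law of the Minimum. Ties are broken by the fixed
#' priority order N, P, C, Fe.
#'
#' @param state a [cell_state].
#' @inheritParams photosynthesis_rate
#' @return list with `mu` (d^-1), `limiter` (element name) and `mu_i` (the
#'   four per-element rates).
#' @export
liebig_growth <- function(state, I, params) {
  lc <- light_coefficients(I, params)
  mu_i <- c(
    N = .growth_if_limited_lc("N", state$Q_N, lc, params),
    P = .growth_if_limited_lc("P", state$Q_P, lc, params),
    C = .growth_if_limited_lc("C", 1, lc, params),
    Fe = .growth_if_limited_lc("Fe", state$Q_Fe, lc, params))
  k <- which.min(mu_i)  # which.min returns the first minimum: N > P > C > Fe
  list(mu = unname(mu_i[k]), limiter = names(mu_i)[k], mu_i = mu_i)
}

#' Structural (non-storage) quota
#'
#' The element bound in functional macromolecules at growth rate `mu` and
#' light `I`: `a*mu^2 + b*mu + c` for N, P, C and
#' `A_Pho_Fe*(A_Chl*mu + B_Chl)` for Fe.
#'
#' @param element one of `"N"`, `"P"`, `"C"`, `"Fe"`.
#' @param mu growth rate, d^-1 (`>= 0`; vectorized).
#' @inheritParams photosynthesis_rate
#' @return quota, mol element (mol C)^-1.
#' @export
structural_quota <- function(element, mu, I, params) {
  element <- match.arg(element, c("N", "P", "C", "Fe"))
  if (any(!is.finite(mu) | mu < 0)) stop("structural_quota: mu must be >= 0")
  lc <- light_coefficients(I, params)
  .structural_quota_lc(element, mu, lc, params)
}

.structural_quota_lc <- function(element, mu, lc, params) {
  if (element == "Fe") {
    return(params$A_Pho_Fe * (lc$A_Chl * mu + lc$B_Chl))
  }
  qc <- .quota_coefficients_lc(element, lc, params)
  qc$a * mu^2 + qc$b * mu + qc$c
}

#' Storage partition of the current quotas
#'
#' For each element, storage is the total quota minus the structural quota at
#' the realized (Liebig) growth rate, floored at zero; the limiting element
#' has zero storage by construction. Carbon storage is computed last as the
#' residual `Q_C_Sto = 1 - Q_C_NonSto - Q_N_Sto * Y_Nsto_CN`; if the carbon
#' cost of N storage overfills the cell, `Q_C_Sto` is clamped at 0 and
#' `Q_N_Sto` shrunk so its carbon cost fits (reported via the `adjusted`
#' flag).
#'
#' @param state a [cell_state].
#' @param mu the Liebig growth rate for this state, d^-1.
#' @param limiter the limiting element reported by [liebig_growth()].
#' @inheritParams photosynthesis_rate
#' @return list with `N`, `P`, `C`, `Fe` storage quotas, `clamped` (logical:
#'   any negative intermediate floored) and `adjusted` (logical: N storage
#'   shrunk for carbon closure).
#' @export
storage_partition <- function(state, mu, limiter, I, params) {
  lc <- light_coefficients(I, params)
  .storage_partition_lc(state, mu, limiter, lc, params)
}

.storage_partition_lc <- function(state, mu, limiter, lc, params) {
  non_N <- .structural_quota_lc("N", mu, lc, params)
  non_P <- .structural_quota_lc("P", mu, lc, params)
  non_C <- .structural_quota_lc("C", mu, lc, params)
  non_Fe <- .structural_quota_lc("Fe", mu, lc, params)
  raw <- c(N = state$Q_N - non_N, P = state$Q_P - non_P, Fe = state$Q_Fe - non_Fe)
  clamped <- any(raw < -1e-12)
  sto <- pmax(raw, 0)
  if (limiter %in% names(sto)) sto[[limiter]] <- 0
  # Under C limitation N storage is also taken as small (its molecules are
  # carbon rich), so mu_C was solved dropping both C and N storage terms.
  if (limiter == "C") sto[["N"]] <- 0
  adjusted <- FALSE
  sto_C <- 1 - non_C - sto[["N"]] * params$Y_Nsto_CN
  if (limiter == "C") sto_C <- 0
  if (sto_C < 0) {
    # carbon closure must hold: shrink N storage so its carbon cost fits
    sto_C <- 0
    room <- max(1 - non_C, 0)
    sto[["N"]] <- min(sto[["N"]], room / params$Y_Nsto_CN)
    adjusted <- TRUE
  }
  list(N = unname(sto[["N"]]), P = unname(sto[["P"]]), C = sto_C,
       Fe = unname(sto[["Fe"]]), clamped = clamped, adjusted = adjusted)
}

#' Maximum quota
#'
#' For N the cap is dynamic: structural quota at `(mu, I)` plus the
#' prescribed maximum N-storage capacity. For P and Fe the caps are the
#' prescribed class constants (laboratory quotas saturate at values nearly
#' independent of growth rate). Carbon has no cap (it is the normalization).
#'
#' @param element one of `"N"`, `"P"`, `"Fe"`.
#' @param mu growth rate, d^-1.
#' @param I light intensity.
#' @param traits a [size_class_traits].
#' @return maximum quota, mol element (mol C)^-1.
#' @export
max_quota <- function(element, mu, I, traits) {
  element <- match.arg(element, c("N", "P", "Fe"))
  if (element == "N") {
    structural_quota("N", mu, I, traits$params) + traits$caps$Q_N_Sto_max
  } else if (element == "P") {
    rep_len(traits$caps$Q_P_max, max(length(mu), length(I)))
  } else {
    rep_len(traits$caps$Q_Fe_max, max(length(mu), length(I)))
  }
}

#' Excess quota above the storage cap
#'
#' `Q_i_Exc = max(Q_i - Q_i_max, 0)` for N, P and Fe. Where diagnosed
#' storage exceeds the storage capacity, storage is truncated to the cap and
#' the difference moved to the excess pool (which is later exuded).
#'
#' @param state a [cell_state].
#' @param mu the Liebig growth rate.
#' @param I light intensity.
#' @param traits a [size_class_traits].
#' @param storages optional storage list from [storage_partition()]; computed
#'   if missing (requires the `limiter`).
#' @param limiter limiting element (used only when `storages` is missing).
#' @return list with `excess` (named N/P/Fe), `storage` (truncated storage
#'   pools incl. C) and `max` (the caps used).
#' @export
excess_quota <- function(state, mu, I, traits, storages = NULL, limiter = NULL) {
  if (is.null(storages)) {
    if (is.null(limiter)) limiter <- liebig_growth(state, I, traits$params)$limiter
    storages <- storage_partition(state, mu, limiter, I, traits$params)
  }
  caps <- c(N = max_quota("N", mu, I, traits),
            P = max_quota("P", mu, I, traits),
            Fe = max_quota("Fe", mu, I, traits))
  q <- c(N = state$Q_N, P = state$Q_P, Fe = state$Q_Fe)
  exc <- pmax(q - caps, 0)
  sto <- storages
  for (el in c("N", "P", "Fe")) sto[[el]] <- max(sto[[el]] - exc[[el]], 0)
  list(excess = as.list(exc), storage = sto, max = as.list(caps))
}

#' Full macromolecular composition
#'
#' Builds every macromolecular pool from the growth rate, light and the
#' storage pools, and verifies the four elemental closure sums. Carbon
#' storage is taken as the residual that closes the carbon budget to 1
#' (`Q_C_Sto = 1 - Q_C_NonSto - Q_N_Sto * Y_Nsto_CN`); if the non-storage
#' pools plus the carbon cost of N storage already exceed 1 the cell is
#' over-full and an infeasibility error identifies the overflow.
#'
#' @param mu growth rate, d^-1 (`>= 0`).
#' @param I light intensity (`> 0`).
#' @param storages list with nonnegative `N`, `P`, `Fe` storage quotas.
#' @inheritParams photosynthesis_rate
#' @return object of class `macromolecular_composition`: named list of carbon
#'   pools (summing to 1), nitrogen, phosphorus and iron pools, and the
#'   elemental totals `Q_N`, `Q_P`, `Q_Fe`.
#' @export
macromolecular_composition <- function(mu, I, storages, params) {
  if (!is.finite(mu) || mu < 0) stop("macromolecular_composition: mu must be >= 0")
  sN <- storages$N %||% 0; sP <- storages$P %||% 0; sFe <- storages$Fe %||% 0
  if (any(c(sN, sP, sFe) < 0)) stop("macromolecular_composition: storages must be >= 0")
  lc <- light_coefficients(I, params)
  Q_C_Chl <- lc$A_Chl * mu + lc$B_Chl
  Q_C_Pro_Pho <- params$A_Pho * Q_C_Chl
  Q_C_Pro_Bio <- params$A_Bio * mu
  Q_C_Pro <- Q_C_Pro_Pho + Q_C_Pro_Bio + params$Q_C_Pro_Other
  Q_P_RNA <- params$A_RNA_P * mu * Q_C_Pro + params$Q_P_min_RNA
  Q_C_RNA <- Q_P_RNA * params$Y_RNA_CP
  Q_P_Thy <- params$A_Pho_PChl * Q_C_Chl
  Q_C_PlipThy <- Q_P_Thy * params$Y_Plip_CP
  Q_C_of_Nsto <- sN * params$Y_Nsto_CN
  non_sto_C <- Q_C_Pro + Q_C_RNA + params$Q_C_DNA + params$Q_C_Other +
    Q_C_PlipThy + Q_C_Chl
  Q_C_Csto <- 1 - non_sto_C - Q_C_of_Nsto
  if (Q_C_Csto < -1e-12) {
    stop(sprintf(paste0(
      "macromolecular_composition: carbon pools overflow the cell by %.3e ",
      "(non-storage C = %.4f, N-storage C = %.4f); infeasible (mu, I, storage)"),
      -Q_C_Csto, non_sto_C, Q_C_of_Nsto))
  }
  Q_C_Csto <- max(Q_C_Csto, 0)
  comp <- list(
    Q_C_Pro_Pho = Q_C_Pro_Pho, Q_C_Pro_Bio = Q_C_Pro_Bio,
    Q_C_Pro_Other = params$Q_C_Pro_Other, Q_C_Chl = Q_C_Chl,
    Q_C_RNA = Q_C_RNA, Q_C_DNA = params$Q_C_DNA, Q_C_Other = params$Q_C_Other,
    Q_C_PlipThy = Q_C_PlipThy, Q_C_Csto = Q_C_Csto, Q_C_of_Nsto = Q_C_of_Nsto,
    Q_N_Pro = Q_C_Pro * params$Y_Pro_NC,
    Q_N_RNA = Q_P_RNA * params$Y_RNA_NP,
    Q_N_DNA = params$Q_C_DNA * params$Y_DNA_NC,
    Q_N_Chl = Q_C_Chl * params$Y_Chl_NC,
    Q_N_Sto = sN,
    Q_P_RNA = Q_P_RNA,
    Q_P_DNA = params$Q_C_DNA * params$Y_DNA_PC,
    Q_P_Thy = Q_P_Thy,
    Q_P_Other = params$Q_P_Other,
    Q_P_Sto = sP,
    Q_Fe_Pho = params$A_Pho_Fe * Q_C_Chl,
    Q_Fe_Sto = sFe)
  comp$Q_N <- comp$Q_N_Pro + comp$Q_N_RNA + comp$Q_N_DNA + comp$Q_N_Chl + comp$Q_N_Sto
  comp$Q_P <- comp$Q_P_RNA + comp$Q_P_DNA + comp$Q_P_Thy + comp$Q_P_Other + comp$Q_P_Sto
  comp$Q_Fe <- comp$Q_Fe_Pho + comp$Q_Fe_Sto
  structure(comp, class = "macromolecular_composition")
}

#' @export
print.macromolecular_composition <- function(x, ...) {
  cpools <- unlist(x[grep("^Q_C_", names(x))])
  cat("<macromolecular_composition>\n")
  cat(sprintf("  C pools sum: %.10f  Q_N: %.5f  Q_P: %.5f  Q_Fe: %.3e\n",
              sum(cpools), x$Q_N, x$Q_P, x$Q_Fe))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
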