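# Two-size-class ecosystem driver: biomass, dissolved nutrients and a
# minimal detrital pool, in a closed box, a set of restoring boxes, or an
# idealized depth-latitude grid. All cells are stepped together with
# vectorized arithmetic; element bookkeeping is written so that every
# transfer is paired (uptake, exudation, mortality, remineralization) and
# closed configurations conserve N, P and Fe to machine precision.

#' Biomass tendency
#'
#' `dB/dt = (mu - m_l - m_q * B) * B`: growth minus linear mortality
#' (sinking and maintenance losses) minus an optional quadratic closure
#' representing implicit grazers (small by default, zero if `m_q = 0`).
#'
#' @param B biomass, mmol C m^-3 (`>= 0`).
#' @param mu realized growth rate, d^-1.
#' @param m_l linear mortality, d^-1.
#' @param m_q quadratic mortality, (mmol C m^-3)^-1 d^-1.
#' @return tendency, mmol C m^-3 d^-1.
#' @export
biomass_tendency <- function(B, mu, m_l, m_q = 0) {
  if (any(B < 0)) stop("biomass_tendency: B must be >= 0")
  (mu - m_l - m_q * B) * B
}

#' Light at depth
#'
#' Exponential attenuation `I(z) = I_surface * exp(-k * z)`.
#'
#' @param I_surface surface light, umol m^-2 s^-1.
#' @param z depth, m (`>= 0`).
#' @param k_attenuation attenuation coefficient, m^-1 (`> 0`).
#' @return light at depth `z`.
#' @export
light_at_depth <- function(I_surface, z, k_attenuation) {
  if (any(z < 0)) stop("light_at_depth: z must be >= 0")
  if (any(k_attenuation <= 0)) stop("light_at_depth: k must be > 0")
  I_surface * exp(-k_attenuation * z)
}

#' Initialize an ecosystem state
#'
#' @param n number of cells.
#' @param traits trait list from [read_traits()].
#' @param B0 initial biomass per class, mmol C m^-3.
#' @param dissolved named list/vector (N, P, Fe) of initial concentrations,
#'   recycled across cells; may be vectors of length `n`.
#' @param I light per cell (used to set feasible initial quotas).
#' @return object of class `eco_state`.
#' @export
eco_init <- function(n, traits, B0 = 0.05,
                     dissolved = list(N = 5, P = 0.3, Fe = 5e-4),
                     I = 100) {
  mk_class <- function(tr) {
    p <- tr$params
    Imid <- rep_len(pmax(I, 1), n)
    mu0 <- 0.3
    list(B = rep_len(B0, n),
         Q_N = structural_quota("N", mu0, Imid, p) * 1.05,
         Q_P = structural_quota("P", mu0, Imid, p) * 1.2,
         Q_Fe = structural_quota("Fe", mu0, Imid, p) * 1.2)
  }
  structure(list(
    n = n,
    classes = list(small = mk_class(traits$small), large = mk_class(traits$large)),
    dissolved = list(N = rep_len(dissolved$N, n), P = rep_len(dissolved$P, n),
                     Fe = rep_len(dissolved$Fe, n)),
    detritus = list(N = rep(0, n), P = rep(0, n), Fe = rep(0, n))),
    class = "eco_state")
}

#' Total element inventories of an ecosystem state
#'
#' Dissolved + sum over classes of biomass * quota + detritus, per cell.
#'
#' @param state an `eco_state`.
#' @return list with numeric vectors `N`, `P`, `Fe` (length `n`).
#' @export
eco_totals <- function(state) {
  tot <- list(N = state$dissolved$N + state$detritus$N,
              P = state$dissolved$P + state$detritus$P,
              Fe = state$dissolved$Fe + state$detritus$Fe)
  for (cl in state$classes) {
    tot$N <- tot$N + cl$B * cl$Q_N
    tot$P <- tot$P + cl$B * cl$Q_P
    tot$Fe <- tot$Fe + cl$B * cl$Q_Fe
  }
  tot
}

# Precompute per-class light-dependent quantities for fixed forcing light.
.precompute_class <- function(I, tr) {
  p <- tr$params
  lc <- light_coefficients(pmax(I, 1e-6), p)
  list(lc = lc,
       qcN = .quota_coefficients_lc("N", lc, p),
       qcP = .quota_coefficients_lc("P", lc, p),
       qcC = .quota_coefficients_lc("C", lc, p))
}

# Vectorized cell-model evaluation for one class over all cells.
# Returns mu, limiter code (1=N,2=P,3=C,4=Fe), excesses above caps.
.eval_cells <- function(cl, pre, tr) {
  p <- tr$params
  mu_N <- .solve_quota_quadratic(pre$qcN$a, pre$qcN$b, pre$qcN$c, cl$Q_N)
  mu_P <- .solve_quota_quadratic(pre$qcP$a, pre$qcP$b, pre$qcP$c, cl$Q_P)
  mu_C <- .solve_quota_quadratic(pre$qcC$a, pre$qcC$b, pre$qcC$c, 1)
  mu_Fe <- pmax((cl$Q_Fe - p$A_Pho_Fe * pre$lc$B_Chl) /
                  (p$A_Pho_Fe * pre$lc$A_Chl), 0)
  mu <- pmin(mu_N, mu_P, mu_C, mu_Fe)
  limiter <- ifelse(mu == mu_N, 1L,
                    ifelse(mu == mu_P, 2L, ifelse(mu == mu_C, 3L, 4L)))
  cap_N <- pre$qcN$a * mu^2 + pre$qcN$b * mu + pre$qcN$c + tr$caps$Q_N_Sto_max
  exc <- list(N = pmax(cl$Q_N - cap_N, 0),
              P = pmax(cl$Q_P - tr$caps$Q_P_max, 0),
              Fe = pmax(cl$Q_Fe - tr$caps$Q_Fe_max, 0))
  list(mu = mu, limiter = limiter, exc = exc)
}

#' One coupled ecosystem step
#'
#' Advances both classes' quotas and biomasses, the dissolved pools and the
#' detrital pools by `dt`. Quota updates are done on the element-conserving
#' tracers (biomass and biomass-times-quota), so the Droop dilution term
#' emerges from the bookkeeping and closed configurations conserve mass to
#' machine precision. Uptake is demand-limited so dissolved pools cannot go
#' negative; mortality uses exact exponential decay over the step.
#'
#' @param state an `eco_state`.
#' @param forcing list with `I` (per cell), optional `restore` (named list
#'   of target concentration vectors N/P/Fe), `tau_mix` (restoring
#'   timescale, d), and `remin` (detrital remineralization rate, d^-1;
#'   default 0.1).
#' @param traits trait list from [read_traits()].
#' @param dt time step, d.
#' @param precomp optional precomputed light coefficients (internal reuse).
#' @return updated `eco_state` with a `diagnostics` attribute (per class:
#'   `mu`, `limiter`).
#' @export
coupled_step <- function(state, forcing, traits, dt = 0.05, precomp = NULL) {
  n <- state$n
  remin <- forcing$remin %||% 0.1
  if (is.null(precomp)) {
    precomp <- list(small = .precompute_class(forcing$I, traits$small),
                    large = .precompute_class(forcing$I, traits$large))
  }
  elements <- c("N", "P", "Fe")
  # gross per-biomass uptake demand for both classes
  Vs <- list(); evals <- list()
  for (k in names(state$classes)) {
    tr <- traits[[k]]
    Vs[[k]] <- list(
      N = monod_uptake(state$dissolved$N, tr$uptake$V_max_N, tr$uptake$K_N),
      P = monod_uptake(state$dissolved$P, tr$uptake$V_max_P, tr$uptake$K_P),
      Fe = monod_uptake(state$dissolved$Fe, tr$uptake$V_max_Fe, tr$uptake$K_Fe))
    evals[[k]] <- .eval_cells(state$classes[[k]], precomp[[k]], tr)
  }
  # demand limitation: scale both classes' uptake so no pool is overdrawn
  scale <- list()
  for (el in elements) {
    demand <- rep(0, n)
    for (k in names(state$classes)) {
      demand <- demand + Vs[[k]][[el]] * state$classes[[k]]$B * dt
    }
    scale[[el]] <- ifelse(demand > 0,
                          pmin(1, 0.95 * state$dissolved[[el]] / pmax(demand, 1e-300)),
                          1)
  }
  diss_delta <- list(N = rep(0, n), P = rep(0, n), Fe = rep(0, n))
  det_delta <- list(N = rep(0, n), P = rep(0, n), Fe = rep(0, n))
  diag <- list()
  for (k in names(state$classes)) {
    tr <- traits[[k]]
    cl <- state$classes[[k]]
    ev <- evals[[k]]
    mort_frac <- 1 - exp(-(tr$m_l + tr$m_q * cl$B) * dt)
    M_C <- cl$B * mort_frac
    tau <- c(N = tr$uptake$tau_Exu_N, P = tr$uptake$tau_Exu_P,
             Fe = tr$uptake$tau_Exu_Fe)
    B_new <- cl$B + ev$mu * cl$B * dt - M_C
    for (el in elements) {
      q <- cl[[paste0("Q_", el)]]
      pool <- cl$B * q
      upt <- scale[[el]] * Vs[[k]][[el]] * cl$B * dt
      exu <- ev$exc[[el]] * min(dt / tau[[el]], 1) * cl$B
      mrt <- M_C * q
      pool_new <- pool + upt - exu - mrt
      diss_delta[[el]] <- diss_delta[[el]] - upt + exu
      det_delta[[el]] <- det_delta[[el]] + mrt
      cl[[paste0("Q_", el)]] <- ifelse(B_new > 0, pool_new / pmax(B_new, 1e-300),
                                       q)
    }
    cl$B <- pmax(B_new, 0)
    state$classes[[k]] <- cl
    diag[[k]] <- list(mu = ev$mu, limiter = ev$limiter)
  }
  for (el in elements) {
    rem <- remin * state$detritus[[el]] * dt
    state$dissolved[[el]] <- state$dissolved[[el]] + diss_delta[[el]] + rem
    state$detritus[[el]] <- state$detritus[[el]] + det_delta[[el]] - rem
    if (!is.null(forcing$restore)) {
      tau_mix <- forcing$tau_mix %||% 10
      relax <- 1 - exp(-dt / tau_mix)
      state$dissolved[[el]] <- state$dissolved[[el]] +
        (forcing$restore[[el]] - state$dissolved[[el]]) * relax
    }
  }
  attr(state, "diagnostics") <- diag
  state
}

#' Run a set of boxes to (quasi-)equilibrium
#'
#' Steps [coupled_step()] for `duration` days and averages the state over
#' the trailing `window` days. Non-equilibrated cells (mean biomass drift
#' between the two halves of the window above `equil_tol`) are flagged.
#'
#' @param state initial `eco_state`.
#' @param forcing forcing list (see [coupled_step()]).
#' @param traits trait list.
#' @param duration total integration, d.
#' @param dt step, d.
#' @param window trailing averaging window, d.
#' @param equil_tol relative drift threshold for the equilibrium flag.
#' @return list with `mean` (time-mean fields: per class `B`, biomass-
#'   weighted quotas, `mu`; dissolved means; `f_S`), `final` (final
#'   `eco_state`), `equilibrated` (logical per cell), `limiter` (per class,
#'   modal limiter code over the window).
#' @export
run_cells <- function(state, forcing, traits, duration = 540, dt = 0.05,
                      window = 180, equil_tol = 0.05) {
  n_steps <- ceiling(duration / dt)
  w_steps <- min(n_steps, ceiling(window / dt))
  half <- floor(w_steps / 2)
  precomp <- list(small = .precompute_class(forcing$I, traits$small),
                  large = .precompute_class(forcing$I, traits$large))
  acc <- list()
  for (k in names(state$classes)) {
    acc[[k]] <- list(B = 0, BQ_N = 0, BQ_P = 0, BQ_Fe = 0, Bmu = 0,
                     B_half1 = 0, B_half2 = 0,
                     lim_counts = matrix(0, nrow = state$n, ncol = 4))
  }
  diss_acc <- list(N = 0, P = 0, Fe = 0)
  for (s in seq_len(n_steps)) {
    state <- coupled_step(state, forcing, traits, dt, precomp)
    if (s > n_steps - w_steps) {
      dg <- attr(state, "diagnostics")
      for (k in names(state$classes)) {
        cl <- state$classes[[k]]
        acc[[k]]$B <- acc[[k]]$B + cl$B
        acc[[k]]$BQ_N <- acc[[k]]$BQ_N + cl$B * cl$Q_N
        acc[[k]]$BQ_P <- acc[[k]]$BQ_P + cl$B * cl$Q_P
        acc[[k]]$BQ_Fe <- acc[[k]]$BQ_Fe + cl$B * cl$Q_Fe
        acc[[k]]$Bmu <- acc[[k]]$Bmu + cl$B * dg[[k]]$mu
        idx <- cbind(seq_len(state$n), dg[[k]]$limiter)
        acc[[k]]$lim_counts[idx] <- acc[[k]]$lim_counts[idx] + 1
        if (s <= n_steps - half) acc[[k]]$B_half1 <- acc[[k]]$B_half1 + cl$B
        else acc[[k]]$B_half2 <- acc[[k]]$B_half2 + cl$B
      }
      for (el in c("N", "P", "Fe")) {
        diss_acc[[el]] <- diss_acc[[el]] + state$dissolved[[el]]
      }
    }
  }
  mean_out <- list(); equil <- rep(TRUE, state$n); limiter <- list()
  tot_B <- 0
  for (k in names(state$classes)) {
    a <- acc[[k]]
    Bm <- a$B / w_steps
    mean_out[[k]] <- list(
      B = Bm,
      Q_N = ifelse(a$B > 0, a$BQ_N / a$B, NA_real_),
      Q_P = ifelse(a$B > 0, a$BQ_P / a$B, NA_real_),
      Q_Fe = ifelse(a$B > 0, a$BQ_Fe / a$B, NA_real_),
      mu = ifelse(a$B > 0, a$Bmu / a$B, NA_real_))
    tot_B <- tot_B + Bm
    h1 <- a$B_half1 / (w_steps - half); h2 <- a$B_half2 / half
    drift <- abs(h2 - h1) / pmax(pmax(h1, h2), 1e-8)
    equil <- equil & (drift < equil_tol | pmax(h1, h2) < 1e-6)
    limiter[[k]] <- c("N", "P", "C", "Fe")[max.col(a$lim_counts,
                                                   ties.method = "first")]
  }
  mean_out$dissolved <- lapply(diss_acc, function(x) x / w_steps)
  mean_out$f_S <- ifelse(tot_B > 0, mean_out$small$B / tot_B, NA_real_)
  list(mean = mean_out, final = state, equilibrated = equil,
       limiter = limiter)
}

#' Run the idealized depth-latitude grid
#'
#' Builds one restoring box per (latitude, depth) cell from a
#' [make_meridional_grid()] scenario, integrates to quasi-equilibrium and
#' returns time-mean gridded fields. Deterministic given the scenario.
#'
#' @param scenario a `grid_scenario` from [make_meridional_grid()].
#' @param traits trait list from [read_traits()].
#' @param duration,dt,window see [run_cells()].
#' @return object of class `grid_result`: a long data.frame `cells` (one row
#'   per lat x depth with forcing, per-class means and dissolved means) plus
#'   attributes `lat`, `depth`, `equilibrated`.
#' @export
run_grid <- function(scenario, traits, duration = 540, dt = 0.05,
                     window = 180) {
  stopifnot(inherits(scenario, "grid_scenario"))
  n <- length(scenario$cells$lat)
  forcing <- list(I = scenario$cells$I,
                  restore = list(N = scenario$cells$target_N,
                                 P = scenario$cells$target_P,
                                 Fe = scenario$cells$target_Fe),
                  tau_mix = scenario$cells$tau_mix,
                  remin = scenario$remin)
  state <- eco_init(n, traits, B0 = 0.05,
                    dissolved = list(N = scenario$cells$target_N,
                                     P = scenario$cells$target_P,
                                     Fe = scenario$cells$target_Fe),
                    I = pmax(scenario$cells$I, 1))
  res <- run_cells(state, forcing, traits, duration, dt, window)
  cells <- data.frame(
    lat = scenario$cells$lat, depth = scenario$cells$depth,
    I = scenario$cells$I,
    B_small = res$mean$small$B, B_large = res$mean$large$B,
    Q_N_small = res$mean$small$Q_N, Q_P_small = res$mean$small$Q_P,
    Q_Fe_small = res$mean$small$Q_Fe, mu_small = res$mean$small$mu,
    Q_N_large = res$mean$large$Q_N, Q_P_large = res$mean$large$Q_P,
    Q_Fe_large = res$mean$large$Q_Fe, mu_large = res$mean$large$mu,
    limiter_small = res$limiter$small, limiter_large = res$limiter$large,
    NO3 = res$mean$dissolved$N, PO4 = res$mean$dissolved$P,
    Fe = res$mean$dissolved$Fe,
    f_S = res$mean$f_S,
    equilibrated = res$equilibrated)
  structure(list(cells = cells, lat = scenario$lat, depth = scenario$depth,
                 scenario = scenario),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result>", length(x$lat), "latitudes x", length(x$depth),
      "depths;", sum(!x$cells$equilibrated), "cells not equilibrated\n")
  invisible(x)
}
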