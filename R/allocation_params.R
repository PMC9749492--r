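#' @keywords internal
"_PACKAGE"

# Names of the cell-level allocation coefficients and macromolecular Y ratios.
.alloc_fields <- c(
  "A_RNA_P", "Q_P_min_RNA", "A_Pho", "A_Bio", "Q_C_Pro_Other", "Q_C_DNA",
  "Q_C_Other", "Q_P_Other", "A_Pho_PChl", "A_Pho_Fe", "E", "m",
  "v_I_max", "A_I",
  "Y_Pro_NC", "Y_RNA_NP", "Y_RNA_CP", "Y_DNA_NC", "Y_DNA_PC", "Y_Chl_NC",
  "Y_Plip_CP", "Y_Nsto_CN")

.uptake_fields <- c("V_max_N", "V_max_P", "V_max_Fe",
                    "K_N", "K_P", "K_Fe",
                    "tau_Exu_N", "tau_Exu_P", "tau_Exu_Fe")

.cap_fields <- c("Q_P_max", "Q_Fe_max", "Q_N_Sto_max")

#' Cellular allocation parameters
#'
#' Bundle of the allocation coefficients and the fixed macromolecular
#' elemental ratios that map growth rate and light to macromolecular and
#' elemental composition.  All quotas are per mole cellular carbon.
#'
#' The light-response coefficient `A_I` is stored as a positive magnitude and
#' applied as `v_I = v_I_max * (1 - exp(-A_I * I))`, so the chlorophyll-
#' specific photosynthesis rate is positive and saturating for all `I >= 0`.
#'
#' @param x named list or vector of parameter values; must contain every
#'   field listed in the package vignette (allocation coefficients plus Y
#'   ratios).
#' @return object of class `alloc_params` (a validated named list).
#' @export
alloc_params <- function(x) {
  x <- as.list(x)
  missing <- setdiff(.alloc_fields, names(x))
  if (length(missing) > 0L) {
    stop("alloc_params: missing fields: ", paste(missing, collapse = ", "))
  }
  p <- lapply(x[.alloc_fields], as.numeric)
  structure(p, class = "alloc_params")
}

#' Validate allocation parameters
#'
#' Checks strict positivity of all coefficients and ratios, and that
#' maintenance respiration is below the maximum chlorophyll-specific
#' photosynthesis rate (otherwise no positive growth is feasible at any
#' light level).
#'
#' @param params an [alloc_params] object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_alloc_params <- function(params) {
  stopifnot(inherits(params, "alloc_params"))
  vals <- unlist(params)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad) > 0L) {
    stop("alloc_params: non-finite or non-positive fields: ",
         paste(bad, collapse = ", "))
  }
  if (params$m >= params$v_I_max) {
    stop("alloc_params: maintenance respiration m must be < v_I_max")
  }
  invisible(params)
}

#' Size-class trait bundle
#'
#' Combines [alloc_params], Monod uptake kinetics, exudation timescales,
#' mortality, and the prescribed maximum quotas for one plankton size class.
#'
#' @param label class label, `"small"` or `"large"`.
#' @param values named list with every allocation, uptake, mortality and cap
#'   field (see `inst/extdata/traits.ini` for the documented set).
#' @return object of class `size_class_traits`.
#' @export
size_class_traits <- function(label, values) {
  label <- match.arg(label, c("small", "large"))
  values <- as.list(values)
  need <- c(.uptake_fields, .cap_fields, "m_l", "m_q")
  missing <- setdiff(need, names(values))
  if (length(missing) > 0L) {
    stop("size_class_traits(", label, "): missing fields: ",
         paste(missing, collapse = ", "))
  }
  tr <- structure(
    list(label = label,
         params = validate_alloc_params(alloc_params(values)),
         uptake = lapply(values[.uptake_fields], as.numeric),
         caps = lapply(values[.cap_fields], as.numeric),
         m_l = as.numeric(values$m_l),
         m_q = as.numeric(values$m_q)),
    class = "size_class_traits")
  up <- unlist(tr$uptake)
  if (any(!is.finite(up) | up <= 0)) stop("size_class_traits: uptake fields must be positive")
  cp <- unlist(tr$caps)
  if (any(!is.finite(cp) | cp <= 0)) stop("size_class_traits: quota caps must be positive")
  if (tr$m_l < 0 || tr$m_q < 0) stop("size_class_traits: mortality must be >= 0")
  tr
}

#' @export
print.size_class_traits <- function(x, ...) {
  cat("<size_class_traits> class:", x$label, "\n")
  cat("  v_I_max:", x$params$v_I_max, " V_max (N,P,Fe):",
      x$uptake$V_max_N, x$uptake$V_max_P, x$uptake$V_max_Fe, "\n")
  cat("  caps Q_P_max:", x$caps$Q_P_max, " Q_Fe_max:", x$caps$Q_Fe_max,
      " Q_N_Sto_max:", x$caps$Q_N_Sto_max, "\n")
  invisible(x)
}

# Parse a minimal INI file: `[section]` headers, `key = value` lines,
# `#` comments. Returns a named list of named numeric lists.
.parse_ini <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("trait file: key outside any [section]: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- suppressWarnings(as.numeric(trimws(paste(kv[-1], collapse = "="))))
      if (is.na(val)) stop("trait file: non-numeric value for key '", key, "'")
      out[[section]][[key]] <- val
    } else {
      stop("trait file: unparseable line: ", ln)
    }
  }
  out
}

#' Read size-class traits from a structured text file
#'
#' Reads an INI-style trait file (`[shared]`, `[small]`, `[large]` blocks of
#' `key = value` pairs; units documented in-file as comments), applies the
#' per-class overrides, validates all invariants, and enforces the imposed
#' trait ordering: the large class must have higher `V_max_i`, `K_i`,
#' `v_I_max` and `Q_P_max` than the small class (opportunist vs gleaner).
#'
#' @param path file path; default is the trait table shipped with the
#'   package.
#' @return named list with elements `small` and `large`, each a
#'   [size_class_traits].
#' @export
read_traits <- function(path = system.file("extdata", "traits.ini",
                                           package = "phytoalloc")) {
  ini <- .parse_ini(path)
  for (sec in c("shared", "small", "large")) {
    if (is.null(ini[[sec]])) stop("trait file must contain a [", sec, "] block")
  }
  build <- function(label) {
    vals <- utils::modifyList(ini$shared, ini[[label]])
    size_class_traits(label, vals)
  }
  traits <- list(small = build("small"), large = build("large"))
  for (f in c("V_max_N", "V_max_P", "V_max_Fe", "K_N", "K_P", "K_Fe")) {
    if (traits$large$uptake[[f]] <= traits$small$uptake[[f]]) {
      stop("trait ordering violated: large ", f, " must exceed small ", f)
    }
  }
  if (traits$large$params$v_I_max <= traits$small$params$v_I_max) {
    stop("trait ordering violated: large v_I_max must exceed small v_I_max")
  }
  if (traits$large$caps$Q_P_max <= traits$small$caps$Q_P_max) {
    stop("trait ordering violated: large Q_P_max must exceed small Q_P_max")
  }
  traits
}

#' Current cell state (elemental quotas)
#'
#' @param Q_N,Q_P,Q_Fe elemental quotas, mol element per mol cellular C; all
#'   strictly positive. `Q_C` is 1 by normalization.
#' @return object of class `cell_state`.
#' @export
cell_state <- function(Q_N, Q_P, Q_Fe) {
  q <- c(Q_N = as.numeric(Q_N), Q_P = as.numeric(Q_P), Q_Fe = as.numeric(Q_Fe))
  if (any(!is.finite(q) | q <= 0)) stop("cell_state: quotas must be positive and finite")
  structure(as.list(q), class = "cell_state")
}

#' Point environment
#'
#' @param I light intensity, umol photons m^-2 s^-1.
#' @param conc_N,conc_P,conc_Fe dissolved NO3, PO4 and Fe, mmol m^-3.
#' @return object of class `environment_point`.
#' @export
env_point <- function(I, conc_N, conc_P, conc_Fe) {
  v <- c(I = I, conc_N = conc_N, conc_P = conc_P, conc_Fe = conc_Fe)
  if (any(!is.finite(v) | v < 0)) stop("env_point: fields must be finite and >= 0")
  structure(as.list(v), class = "environment_point")
}
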