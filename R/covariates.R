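# Covariate handling: standardization, lag construction, missingness masks.

# Canonical order of the ten productivity-covariate terms on the logit scale:
# arrival mass, predation, SSTa (lag 0, 1), SAM (lag 0, 1), ENSO (lag 2, 3),
# interspecific competition, intraspecific auto-covariate.
PROD_TERMS <- c("A", "P", "S0", "S1", "M0", "M1", "E2", "E3", "D", "C")
SURV_TERMS <- c("P_shared", "P_fledgling", "SSTa_lag1")

#' Standardize a series to zero mean and unit variance
#'
#' Standardizes the observed entries of a (possibly partially missing) series
#' to mean 0 and sample standard deviation 1 (n - 1 denominator), and returns
#' the centring constants so that values imputed later, or fed back from the
#' latent process, can be placed on the same scale.  Missing entries are
#' propagated unchanged.
#'
#' @param x numeric vector, `NA` for missing.
#' @param mask logical vector of observed flags; defaults to `!is.na(x)`.
#' @return list with `values` (standardized vector, `NA` where missing),
#'   `center` and `scale` (mean and sd of the observed entries).
#' @examples
#' standardize_series(c(1, 2, 3))$values
#' @export
standardize_series <- function(x, mask = !is.na(x)) {
  stopifnot(length(mask) == length(x))
  obs <- x[mask]
  if (length(obs) < 2)
    stop_sspm("standardize_series: need at least 2 observed values, got ",
              length(obs))
  m <- mean(obs)
  s <- stats::sd(obs)
  if (!is.finite(s) || s == 0)
    stop_sspm("standardize_series: observed values have zero variance; ",
              "cannot standardize a degenerate series")
  out <- x
  out[mask] <- (obs - m) / s
  out[!mask] <- NA_real_
  list(values = out, center = m, scale = s)
}

#' Assemble a standardized covariate matrix with lag columns
#'
#' Takes raw annual covariate series and builds the design columns used by
#' the demographic model: predation index `P`, sea-surface temperature
#' anomalies at lag 0 and 1 (`S0`, `S1`), Southern Annular Mode at lag 0 and
#' 1 (`M0`, `M1`), ENSO at lags 2 and 3 (`E2`, `E3`), female arrival mass
#' `A`, and interspecific competition `D`.  Each base series is standardized
#' once on its observed entries, then shifted, so a lag-k column at year t
#' equals the lag-0 column at year t - k.  Rows before `years[1]` in `data`
#' serve only as lag lead-in.
#'
#' The intraspecific auto-covariate `C` (standardized breeding-female count)
#' is not a column here: it is computed from the latent state during
#' inference.
#'
#' @param data data.frame with columns `year`, `P`, `S`, `M`, `E`, `A`, `D`
#'   on their raw scales, `NA` for missing cells.  May include lead-in years.
#' @param years integer vector of study years to retain (default: all years
#'   for which the lag-3 column can be formed from `data`).
#' @return object of class `covariate_matrix`: a data.frame of standardized
#'   columns `year, P, S0, S1, M0, M1, E2, E3, A, D` with attributes `mask`
#'   (logical observed-flag matrix) and `scales` (per-series centring
#'   constants).
#' @export
covariate_matrix <- function(data, years = NULL) {
  need <- c("year", "P", "S", "M", "E", "A", "D")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_sspm("covariate_matrix: missing columns: ", paste(miss, collapse = ", "))
  data <- data[order(data$year), , drop = FALSE]
  if (any(diff(data$year) != 1))
    stop_sspm("covariate_matrix: years must be consecutive")
  if (is.null(years)) years <- data$year[data$year >= data$year[1] + 3]
  if (!all(years %in% data$year))
    stop_sspm("covariate_matrix: requested years not all present in data")

  # Each base series is standardized on its observed cells within the
  # window where its primary (shortest-lag) column is used, so that column
  # is exactly standardized over the study years and longer-lag columns
  # share the same scale (keeping the lag-shift identity).
  std_windowed <- function(series, lag0) {
    idx <- match(years - lag0, data$year)
    win <- rep(FALSE, length(series))
    win[idx[!is.na(idx)]] <- TRUE
    mask <- win & !is.na(series)
    z <- standardize_series(ifelse(win, series, NA), mask = mask)
    list(values = (series - z$center) / z$scale,
         center = z$center, scale = z$scale)
  }
  base_lag <- c(P = 0, S = 0, M = 0, E = 2, A = 0, D = 0)
  std <- lapply(names(base_lag), function(nm)
    std_windowed(data[[nm]], base_lag[[nm]]))
  names(std) <- names(base_lag)
  lagged <- function(series, k) {
    idx <- match(years - k, data$year)
    series[idx]
  }
  out <- data.frame(
    year = years,
    P  = lagged(std$P$values, 0),
    S0 = lagged(std$S$values, 0),
    S1 = lagged(std$S$values, 1),
    M0 = lagged(std$M$values, 0),
    M1 = lagged(std$M$values, 1),
    E2 = lagged(std$E$values, 2),
    E3 = lagged(std$E$values, 3),
    A  = lagged(std$A$values, 0),
    D  = lagged(std$D$values, 0)
  )
  mask <- !is.na(as.matrix(out[-1]))
  structure(out,
            mask = mask,
            scales = lapply(std, function(z) z[c("center", "scale")]),
            class = c("covariate_matrix", "data.frame"))
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat("Standardized covariate matrix:", nrow(x), "years (",
      x$year[1], "-", x$year[nrow(x)], ")\n", sep = "")
  nmiss <- colSums(!attr(x, "mask"))
  nmiss <- nmiss[nmiss > 0]
  if (length(nmiss))
    cat("Missing cells:",
        paste(names(nmiss), nmiss, sep = ":", collapse = ", "), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Retrieve the observed-flag matrix of a covariate_matrix.
covariate_mask <- function(cov) attr(cov, "mask")
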