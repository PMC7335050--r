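# Steady-state SPR affinity estimation with the threefold-saturation QC
# rule, and liposome dye-release quantification.

#' Read a steady-state isotherm CSV
#'
#' Expects columns `conc_nM` and `response_RU`; a `conc_uM` column is
#' accepted instead and converted to nM explicitly.
#'
#' @param path CSV file.
#' @return A `gm_isotherm` data frame.
#' @export
read_isotherm_csv <- function(path) {
  d <- read.csv(path)
  if ("conc_uM" %in% names(d) && !"conc_nM" %in% names(d)) {
    d$conc_nM <- d$conc_uM * 1000
  }
  if (!all(c("conc_nM", "response_RU") %in% names(d))) {
    stopf("%s must have columns conc_nM (or conc_uM) and response_RU", path)
  }
  structure(d[, c("conc_nM", "response_RU")],
            class = c("gm_isotherm", "data.frame"))
}

#' Fit a 1:1 steady-state (Langmuir) binding isotherm
#'
#' Least-squares fit of `R_eq(C) = rmax * C / (kd + C)` (no bulk-offset
#' term by default; responses are assumed blank-subtracted).  For any
#' candidate `kd` the conditionally linear `rmax` has a closed form, so the
#' fit profiles the residual sum of squares over a fixed log-spaced `kd`
#' grid and polishes the best start with 1-D optimisation — deterministic
#' given the data and robust to local minima.  Standard errors come from
#' the Gauss-Newton curvature at the optimum.  The saturation QC flag
#' requires the top analysed concentration to be at least threefold above
#' the fitted K_D.
#'
#' @param iso A `gm_isotherm` (columns `conc_nM`, `response_RU`) with at
#'   least 4 distinct positive concentrations.
#' @param offset Also fit an additive bulk-response offset.
#' @return A `gm_fit` list: `kd` (nM), `rmax` (RU), `se_kd`, `se_rmax`,
#'   `offset`, `residual_rms` (RU), `cmax_over_kd`, `saturation_ok`,
#'   `caveat` (character, `NA` when QC passes), `n`.
#' @export
fit_steady_state <- function(iso, offset = FALSE) {
  C <- iso$conc_nM
  R <- iso$response_RU
  if (any(C <= 0)) stopf("concentrations must be positive")
  if (length(unique(C)) < 4L) stopf("need >= 4 distinct concentrations")
  if (all(R == 0)) stopf("all responses are zero; nothing to fit")

  rss_at <- function(kd) {
    f <- C / (kd + C)
    if (offset) {
      fit <- stats::lm.fit(cbind(f, 1), R)
      cf <- fit$coefficients
      list(rss = sum(fit$residuals^2), rmax = cf[1L], b0 = cf[2L])
    } else {
      rmax <- sum(R * f) / sum(f * f)
      list(rss = sum((R - rmax * f)^2), rmax = rmax, b0 = 0)
    }
  }

  grid <- 10^seq(log10(min(C)) - 2, log10(max(C)) + 2, length.out = 121)
  rss <- vapply(grid, function(k) rss_at(k)$rss, numeric(1))
  kd_hat <- NA_real_
  for (idx in order(rss)) {
    lo <- grid[max(1L, idx - 1L)]
    hi <- grid[min(length(grid), idx + 1L)]
    opt <- optimize(function(lk) rss_at(10^lk)$rss, c(log10(lo), log10(hi)),
                    tol = 1e-10)
    cand <- 10^opt$minimum
    if (rss_at(cand)$rmax > 0) {
      kd_hat <- cand
      break
    }
  }
  if (is.na(kd_hat)) stopf("steady-state fit failed to converge")
  sol <- rss_at(kd_hat)
  rmax_hat <- unname(sol$rmax)

  # Gauss-Newton standard errors
  f <- C / (kd_hat + C)
  J <- cbind(rmax = f, kd = -rmax_hat * C / (kd_hat + C)^2)
  if (offset) J <- cbind(J, b0 = 1)
  p <- ncol(J)
  dof <- length(C) - p
  sigma2 <- if (dof > 0) sol$rss / dof else NA_real_
  covm <- tryCatch(sigma2 * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, p, p))
  cmax <- max(C)
  qc <- check_saturation(list(kd = kd_hat), cmax)
  structure(list(kd = kd_hat, rmax = rmax_hat,
                 se_kd = sqrt(covm[2L, 2L]), se_rmax = sqrt(covm[1L, 1L]),
                 offset = unname(sol$b0),
                 residual_rms = sqrt(sol$rss / length(C)),
                 cmax_over_kd = qc$ratio, saturation_ok = qc$ok,
                 caveat = qc$caveat, n = length(C)),
            class = "gm_fit")
}

#' Saturation quality control for steady-state affinity estimates
#'
#' A steady-state K_D is only trusted when the top analysed concentration
#' is at least threefold above it (inclusive at exactly 3); otherwise the
#' plateau is extrapolated and the estimate carries a caveat.
#'
#' @param fit A `gm_fit` (or any list with element `kd`).
#' @param cmax Highest analysed concentration (same units as `kd`).
#' @return List with `ratio` (`cmax / kd`), `ok` flag, and `caveat` text
#'   (`NA` when the check passes).
#' @export
check_saturation <- function(fit, cmax) {
  ratio <- cmax / fit$kd
  ok <- ratio >= 3
  caveat <- if (ok) NA_character_ else
    sprintf(paste("top concentration (%.4g) is less than threefold above",
                  "the fitted K_D (%.4g); the steady-state criterion is",
                  "not met and the estimate is approximate"),
            cmax, fit$kd)
  list(ratio = ratio, ok = ok, caveat = caveat)
}

#' Percent dye release from dequenching fluorescence
#'
#' `(F_sample - F_blank) / (F_Triton - F_blank) * 100`.  Values outside
#' `[0, 100]` are possible with noisy inputs and are flagged with a
#' warning, not clipped.  Invariant under common positive scaling or a
#' common offset of the three fluorescence values.
#'
#' @param f_sample,f_blank,f_triton Fluorescence values (AU), vectorised.
#' @return Release percent.
#' @export
release_percent <- function(f_sample, f_blank, f_triton) {
  if (any(f_triton == f_blank)) {
    stopf("f_triton equals f_blank; release percent undefined")
  }
  pct <- (f_sample - f_blank) / (f_triton - f_blank) * 100
  if (any(pct < 0 | pct > 100)) {
    warnf("release percent outside [0, 100] (noisy inputs); not clipped")
  }
  pct
}

#' Read a release-trace CSV
#'
#' Expects columns `time_s`, `F_sample`, `F_blank`, `F_triton`.
#'
#' @param path CSV file.
#' @return A `gm_release_trace` data frame.
#' @export
read_release_csv <- function(path) {
  d <- read.csv(path)
  need <- c("time_s", "F_sample", "F_blank", "F_triton")
  if (!all(need %in% names(d))) {
    stopf("%s must have columns: %s", path, paste(need, collapse = ", "))
  }
  structure(d[, need], class = c("gm_release_trace", "data.frame"))
}

#' Summarise release traces per condition
#'
#' Plateau fluorescence is the mean over the final `window` fraction of
#' each trace (default: last 10\% of points); [release_percent()] is
#' applied to the three plateaus, and replicates are summarised as mean and
#' sample SD (SD is `NA`, not 0, for a single replicate).
#'
#' @param traces A single `gm_release_trace`, a list of replicate traces,
#'   or a named list of such lists (one entry per condition).
#' @param window Final fraction of the time base to average, in (0, 1].
#' @return Data frame `condition`, `mean_percent`, `sd_percent`,
#'   `n_replicates`.
#' @export
summarize_release <- function(traces, window = 0.1) {
  if (!is.numeric(window) || window <= 0 || window > 1) {
    stopf("`window` must be in (0, 1]")
  }
  is_trace <- function(x) is.data.frame(x) && "F_sample" %in% names(x)
  if (is_trace(traces)) traces <- list(condition = list(traces))
  if (all(vapply(traces, is_trace, logical(1)))) {
    if (is.null(names(traces)) || any(!nzchar(names(traces)))) {
      traces <- list(condition = traces)  # replicates of one condition
    } else {
      traces <- lapply(traces, list)      # one trace per named condition
    }
  }
  plateau_pct <- function(tr) {
    n <- nrow(tr)
    k <- max(1L, ceiling(window * n))
    idx <- seq.int(n - k + 1L, n)
    release_percent(mean(tr$F_sample[idx]), mean(tr$F_blank[idx]),
                    mean(tr$F_triton[idx]))
  }
  out <- do.call(rbind, lapply(names(traces), function(nm) {
    pcts <- vapply(traces[[nm]], plateau_pct, numeric(1))
    data.frame(condition = nm, mean_percent = mean(pcts),
               sd_percent = if (length(pcts) > 1L) sd(pcts) else NA_real_,
               n_replicates = length(pcts))
  }))
  rownames(out) <- NULL
  out
}
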