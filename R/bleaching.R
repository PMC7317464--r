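#' Thermal threshold of a host--symbiont link
#'
#' Each association tolerates heat up to an absolute temperature threshold
#' built from the host's local climatology and the pair's physiology:
#' `W = T_MMM + T_delta * (tau_symbiont + tau_host) / 2`, where `T_MMM` is
#' the mean monthly maximum SST of the host's subregion, `T_delta` is the
#' upper thermal limit of the association above that baseline (3 degrees C
#' by default), and the two tolerances are averaged because either partner
#' may drive the breakdown of the symbiosis. Vectorized.
#'
#' @param t_mmm Host subregion baseline temperature, degrees C.
#' @param tau_host,tau_symbiont Node tolerances in \[0, 1\].
#' @param t_delta Upper thermal limit above `t_mmm`, degrees C.
#' @return Link threshold(s) `W` in degrees C.
#' @export
#' @examples
#' link_weight(28.68, 1, 1)    # most tolerant pair on the Great Barrier Reef
#' link_weight(30.38, 0.5, 0.7)
link_weight <- function(t_mmm, tau_host, tau_symbiont, t_delta = 3) {
  if (any(is.na(tau_host)) || any(tau_host < 0 | tau_host > 1) ||
      any(is.na(tau_symbiont)) || any(tau_symbiont < 0 | tau_symbiont > 1)) {
    abort("tolerances must lie in [0, 1]", class = "coralnet_domain_error")
  }
  t_mmm + t_delta * (tau_symbiont + tau_host) / 2
}

#' Link thresholds for every edge of a network
#'
#' @param net A realized `coral_network` (tolerances assigned).
#' @param t_delta Upper thermal limit, degrees C.
#' @return The edge tibble with `tau_host`, `tau_symbiont`, `t_mmm_c`, `w_c`.
#' @export
link_weights <- function(net, t_delta = 3) {
  if (!"tolerance" %in% names(net$hosts) || anyNA(net$hosts$tolerance) ||
      !"tolerance" %in% names(net$symbionts) || anyNA(net$symbionts$tolerance)) {
    abort("network tolerances are not (fully) assigned; call realize_tolerances()",
          class = "coralnet_configuration_error")
  }
  net$edges |>
    left_join(select(net$hosts, "host_id", "t_mmm_c", tau_host = "tolerance"),
              by = "host_id") |>
    left_join(select(net$symbionts, "symbiont_id", tau_symbiont = "tolerance"),
              by = "symbiont_id") |>
    mutate(w_c = link_weight(.data$t_mmm_c, .data$tau_host, .data$tau_symbiont,
                             t_delta))
}

# per-host bleaching temperature: the threshold of its last surviving link.
# A link breaks when T >= W (closed threshold); a host is bleached once it
# has no links left, so its bleaching temperature is max(W) over its links.
host_bleach_temperatures <- function(net, t_delta = 3) {
  lw <- link_weights(net, t_delta)
  net$hosts |>
    select("host_id", "family", "subregion") |>
    left_join(summarise(group_by(lw, .data$host_id), w_max = max(.data$w_c)),
              by = "host_id")
}

#' Simulate bleaching along a temperature ramp
#'
#' Sweeps absolute temperature upward; every link whose threshold `W` is
#' reached breaks (ties break simultaneously), and a host is bleached once
#' isolated. The sweep is event-driven: the bleached fraction can only
#' change at a host's final-link threshold, so the curve is returned as its
#' exact breakpoints.
#'
#' @param net A realized `coral_network`.
#' @param t_delta Upper thermal limit, degrees C.
#' @return A `bleaching_curve` tibble with `temperature_c` and
#'   `fraction_bleached` (the fraction of host nodes bleached once the ramp
#'   reaches that temperature), starting just below the first event at the
#'   initially-isolated fraction and ending at 1. Attribute `n_hosts`
#'   records the denominator.
#' @export
simulate_bleaching <- function(net, t_delta = 3) {
  n_hosts <- nrow(net$hosts)
  if (n_hosts == 0) {
    warn("network has no host nodes; returning an empty curve")
    out <- tibble(temperature_c = double(), fraction_bleached = double())
    return(structure(out, n_hosts = 0L,
                     class = c("bleaching_curve", class(out))))
  }
  bt <- host_bleach_temperatures(net, t_delta)
  isolated0 <- sum(is.na(bt$w_max))
  temps <- sort(unique(bt$w_max[!is.na(bt$w_max)]))
  frac <- (isolated0 + cumsum(tabulate(match(bt$w_max, temps),
                                       nbins = length(temps)))) / n_hosts
  out <- tibble(
    temperature_c = c(if (length(temps) > 0) temps[1] - 1e-6 else numeric(), temps),
    fraction_bleached = c(if (length(temps) > 0) isolated0 / n_hosts else numeric(),
                          frac))
  structure(out, n_hosts = n_hosts, class = c("bleaching_curve", class(out)))
}

#' Evaluate a bleaching curve at given temperatures
#'
#' Step-function (right-continuous) evaluation of the event curve.
#'
#' @param curve A `bleaching_curve`.
#' @param temperature_c Temperatures, degrees C.
#' @return Bleached fractions.
#' @export
bleach_fraction_at <- function(curve, temperature_c) {
  if (nrow(curve) == 0) return(rep(NA_real_, length(temperature_c)))
  idx <- findInterval(temperature_c, curve$temperature_c)
  ifelse(idx == 0, curve$fraction_bleached[1], curve$fraction_bleached[pmax(idx, 1)])
}

#' Resistance to temperature stress from a bleaching curve
#'
#' Resistance is the temperature rise that takes the network from 10% to
#' 90% of hosts bleached, normalized by the maximum possible excursion for
#' that range (`t_delta`): `R = (T_90 - T_10) / t_delta`. Crossing
#' temperatures are first-passage on the event step function (the first
#' breakpoint at which the fraction meets or exceeds the threshold) —
#' bleaching is a discrete per-host isolation event, so no interpolation is
#' used. Dimensionless; for a single-subregion network `R <= 1`.
#'
#' @param curve A `bleaching_curve`.
#' @param t_delta Upper thermal limit used in the simulation, degrees C.
#' @param lower,upper Bleached-fraction thresholds (default 0.1 and 0.9).
#' @return Resistance, a non-negative scalar.
#' @export
resistance_from_curve <- function(curve, t_delta = 3, lower = 0.1, upper = 0.9) {
  if (nrow(curve) == 0 || max(curve$fraction_bleached) < upper) {
    abort("bleaching curve never reaches the upper threshold; resistance undefined",
          class = "coralnet_metric_error")
  }
  t_lo <- curve$temperature_c[which(curve$fraction_bleached >= lower)[1]]
  t_hi <- curve$temperature_c[which(curve$fraction_bleached >= upper)[1]]
  (t_hi - t_lo) / t_delta
}

#' Resistance over an ensemble of bleaching simulations
#'
#' Runs the bleaching model `replicates` times. Each replicate redraws the
#' imputed node tolerances from the plan (measured tolerances are fixed),
#' optionally applies a null-network transform, simulates the ramp, and
#' computes resistance. Replicate substreams derive from `seed`, so runs
#' are reproducible and replicate `i` is unaffected by the others.
#'
#' @param net A `coral_network` carrying a tolerance plan
#'   (see [tolerance_plan()]).
#' @param replicates Number of simulations (default 100).
#' @param t_delta Upper thermal limit, degrees C.
#' @param seed Master seed for the ensemble; `NULL` uses the current RNG
#'   state.
#' @param null Optional null-network construction applied to each realized
#'   replicate: a function `net -> net`, or one of `"shuffled_tolerance"`,
#'   `"random_tolerance"`, `"rbdc"`, `"rbndc"`.
#' @param keep_curves Keep each replicate's curve (for ensemble plots).
#' @return A `resistance_result`: replicate values with mean and sd;
#'   replicates whose curve never reaches 90% are recorded as failures and
#'   excluded with a warning.
#' @export
resistance_ensemble <- function(net, replicates = 100, t_delta = 3, seed = NULL,
                                null = NULL, keep_curves = FALSE) {
  null_fun <- resolve_null(null)
  curves <- if (keep_curves) vector("list", replicates)
  values <- rep(NA_real_, replicates)
  for (i in seq_len(replicates)) {
    sub <- if (is.null(seed)) NULL else substream_seed(seed, "resistance", i)
    res <- with_substream(sub, {
      real <- realize_tolerances(net)
      if (!is.null(null_fun)) real <- null_fun(real)
      simulate_bleaching(real, t_delta)
    })
    if (keep_curves) curves[[i]] <- res
    values[i] <- tryCatch(resistance_from_curve(res, t_delta),
                          coralnet_metric_error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(values))
  if (n_failed > 0) {
    warn(paste0(n_failed, " replicate(s) had an undefined resistance and were excluded"))
  }
  ok <- values[!is.na(values)]
  structure(
    list(values = tibble(replicate = seq_len(replicates), resistance = values),
         mean = mean(ok), sd = if (length(ok) > 1) sd(ok) else 0,
         n_failed = n_failed, replicates = replicates, t_delta = t_delta,
         null = if (is.character(null)) null else if (is.null(null)) "natural" else "custom",
         curves = curves, seed = seed),
    class = "resistance_result")
}

#' @export
print.resistance_result <- function(x, ...) {
  cat("<resistance_result> ", x$null, " network, ", x$replicates,
      " replicates\n  R = ", format(round(x$mean, 3), nsmall = 3), " ± ",
      format(round(x$sd, 3), nsmall = 3), "\n", sep = "")
  if (x$n_failed > 0) cat("  (", x$n_failed, " failed replicates excluded)\n", sep = "")
  invisible(x)
}

#' @export
tidy.resistance_result <- function(x, ...) x$values

#' @export
glance.resistance_result <- function(x, ...) {
  tibble(network = x$null, mean = x$mean, sd = x$sd,
         replicates = x$replicates, n_failed = x$n_failed,
         t_delta = x$t_delta)
}

#' Average an ensemble of bleaching curves on a common grid
#'
#' @param result A `resistance_result` computed with `keep_curves = TRUE`.
#' @param step Temperature grid step, degrees C.
#' @param probs Lower/upper percentile band across replicates (defaults to
#'   the central 97%).
#' @return A tibble with `temperature_c`, `mean`, `lower`, `upper`.
#' @export
ensemble_curve <- function(result, step = 0.01, probs = c(0.015, 0.985)) {
  curves <- purrr::compact(result$curves)
  if (length(curves) == 0) {
    abort("no stored curves; rerun resistance_ensemble(keep_curves = TRUE)",
          class = "coralnet_configuration_error")
  }
  lo <- min(purrr::map_dbl(curves, ~ min(.x$temperature_c)))
  hi <- max(purrr::map_dbl(curves, ~ max(.x$temperature_c)))
  grid <- seq(lo - step, hi + step, by = step)
  mat <- vapply(curves, bleach_fraction_at, numeric(length(grid)),
                temperature_c = grid)
  tibble(temperature_c = grid,
         mean = rowMeans(mat),
         lower = apply(mat, 1, quantile, probs = probs[1]),
         upper = apply(mat, 1, quantile, probs = probs[2]))
}
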