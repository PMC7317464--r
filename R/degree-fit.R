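# Discrete heavy-tail model fits for degree sequences.
#
# Three candidate models on k = kmin, kmin+1, ...:
#   power law           p(k) ~ k^-alpha
#   truncated power law p(k) ~ k^-alpha * exp(-lambda k)
#   exponential         p(k) ~ exp(-lambda k)
# Normalizing constants are computed by direct summation over a finite
# support large enough that the tail mass is negligible for any lambda > 0
# and alpha > 1 actually reached by the optimizer.

tail_support <- function(degrees) max(10000L, 50L * max(degrees))

discrete_loglik <- function(degrees, kmin, logp_fun) {
  ks <- kmin:tail_support(degrees)
  logp <- logp_fun(ks)
  logz <- log(sum(exp(logp - max(logp)))) + max(logp)
  sum(logp_fun(degrees)) - length(degrees) * logz
}

fit_one_model <- function(degrees, kmin, model) {
  nll <- switch(model,
    power_law = function(par) {
      a <- par[1]
      if (a <= 1 || a > 20) return(1e10)
      -discrete_loglik(degrees, kmin, function(k) -a * log(k))
    },
    truncated_power_law = function(par) {
      a <- par[1]; l <- exp(par[2])
      if (a <= 0 || a > 20 || l > 10) return(1e10)
      -discrete_loglik(degrees, kmin, function(k) -a * log(k) - l * k)
    },
    exponential = function(par) {
      l <- exp(par[1])
      if (l > 10) return(1e10)
      -discrete_loglik(degrees, kmin, function(k) -l * k)
    })
  init <- switch(model,
    power_law = 2, truncated_power_law = c(1.5, log(0.05)),
    exponential = log(1 / max(mean(degrees), 1.5)))
  fit <- optim(init, nll, method = if (length(init) == 1) "Brent" else "Nelder-Mead",
               lower = if (length(init) == 1) switch(model, power_law = 1.0001, -15) else -Inf,
               upper = if (length(init) == 1) switch(model, power_law = 20, 3) else Inf)
  par <- switch(model,
    power_law = c(alpha = fit$par[1], lambda = NA_real_),
    truncated_power_law = c(alpha = fit$par[1], lambda = exp(fit$par[2])),
    exponential = c(alpha = NA_real_, lambda = exp(fit$par[1])))
  k <- length(init)
  tibble(model = model, alpha = par[["alpha"]], lambda = par[["lambda"]],
         n_par = k, loglik = -fit$value, aic = 2 * k + 2 * fit$value)
}

#' Fit candidate degree-distribution models
#'
#' Fits discrete power-law, truncated power-law (power law with exponential
#' cutoff), and exponential models to a degree sequence by maximum
#' likelihood, and ranks them by AIC. Sparse association networks of this
#' kind typically show a truncated power law: many specialist nodes and a
#' few generalist hubs. The fit is descriptive; nothing downstream depends
#' on it.
#'
#' @param degrees Integer degree sequence (a vector, or the tibble returned
#'   by [degree_sequence()]); zero-degree nodes are dropped.
#' @param kmin Smallest degree included in the fit (default 1).
#'
#' @return A `degree_fit` object: tibble of per-model parameters, log
#'   likelihood and AIC, with attributes `preferred` (model name) and
#'   `failed` (TRUE for degenerate sequences).
#' @export
fit_degree_distribution <- function(degrees, kmin = 1L) {
  if (is.data.frame(degrees)) degrees <- degrees$degree
  degrees <- as.integer(degrees[degrees >= kmin])
  failed <- length(degrees) < 10 || length(unique(degrees)) < 3
  if (failed) {
    out <- tibble(model = character(), alpha = double(), lambda = double(),
                  n_par = integer(), loglik = double(), aic = double())
    return(structure(out, preferred = NA_character_, failed = TRUE,
                     n = length(degrees), kmin = kmin, class = c("degree_fit", class(out))))
  }
  out <- bind_rows(lapply(c("power_law", "truncated_power_law", "exponential"),
                          function(m) fit_one_model(degrees, kmin, m))) |>
    arrange(.data$aic)
  structure(out, preferred = out$model[1], failed = FALSE,
            n = length(degrees), kmin = kmin, class = c("degree_fit", class(out)))
}

#' @export
print.degree_fit <- function(x, ...) {
  if (attr(x, "failed")) {
    cat("<degree_fit> fit failed (degenerate or too-short degree sequence)\n")
    return(invisible(x))
  }
  cat("<degree_fit> n =", attr(x, "n"), " preferred:", attr(x, "preferred"), "\n")
  print(as_tibble(x))
  invisible(x)
}

#' @export
tidy.degree_fit <- function(x, ...) as_tibble(x)

#' @export
glance.degree_fit <- function(x, ...) {
  tibble(preferred = attr(x, "preferred"), failed = attr(x, "failed"),
         n = attr(x, "n"), kmin = attr(x, "kmin"))
}

#' Sample degrees from a discrete truncated power law
#'
#' @param n Number of draws.
#' @param alpha Power-law exponent.
#' @param cutoff Exponential cutoff scale kappa; p(k) ~ k^-alpha exp(-k/kappa).
#' @param kmin,kmax Support bounds.
#' @return Integer vector of degrees.
#' @export
rtrunc_power_law <- function(n, alpha, cutoff, kmin = 1L, kmax = 1000L) {
  ks <- kmin:kmax
  w <- exp(-alpha * log(ks) - ks / cutoff)
  sample(ks, n, replace = TRUE, prob = w / sum(w))
}
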