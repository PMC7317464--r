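#' Host tolerance from a Bleaching Resistance Index value
#'
#' A species' BRI is the percentage of bleached tissue expected during a
#' heat-stress event, so it measures susceptibility. Tolerance is the
#' complement on the unit scale: `1 - bri/100`. Vectorized.
#'
#' @param bri BRI value(s) in \[0, 100\].
#' @return Tolerance value(s) in \[0, 1\].
#' @export
#' @examples
#' host_tolerance_from_bri(c(0, 37.5, 100))
host_tolerance_from_bri <- function(bri) {
  if (any(is.na(bri)) || any(bri < 0 | bri > 100)) {
    abort("BRI must lie in [0, 100]", class = "coralnet_domain_error")
  }
  1 - bri / 100
}

#' Symbiont tolerance from a thermal-tolerance rank score
#'
#' Rank-aggregated symbiont scores order ITS2 phylotypes from 0 to 100 but
#' are not magnitude-calibrated; the square-root transform compresses the
#' spread before rescaling to the unit interval: `sqrt(rank)/10`. Vectorized.
#'
#' @param rank Rank score(s) in \[0, 100\].
#' @return Tolerance value(s) in \[0, 1\].
#' @export
#' @examples
#' symbiont_tolerance_from_rank(c(0, 25, 100))
symbiont_tolerance_from_rank <- function(rank) {
  if (any(is.na(rank)) || any(rank < 0 | rank > 100)) {
    abort("rank score must lie in [0, 100]", class = "coralnet_domain_error")
  }
  sqrt(rank) / 10
}

#' Default symbiont thermal-tolerance class model
#'
#' Unlisted ITS2 types draw a rank score from one of three tolerance classes
#' (high / medium / low), mixed in genus-specific proportions, then
#' transformed with [symbiont_tolerance_from_rank()]. Class shapes default
#' to normals truncated to \[0, 100\] (high: mean 75, medium: 45, low: 15,
#' sd 10). Genus proportions reflect the broad physiological picture —
#' *Durusdinium* weighted toward the high-tolerance class, *Cladocopium*
#' toward low/medium — and are plain data, intended to be overridden when
#' empirical class frequencies are available.
#'
#' @return A list with tibbles `classes` (`class`, `mean`, `sd`) and
#'   `proportions` (`genus`, `high`, `medium`, `low`; row `"unknown"` is the
#'   pooled fallback).
#' @export
default_class_model <- function() {
  list(
    classes = tribble(
      ~class,   ~mean, ~sd,
      "high",      75,  10,
      "medium",    45,  10,
      "low",       15,  10
    ),
    proportions = tribble(
      ~genus,         ~high, ~medium, ~low,
      "Symbiodinium",  0.30,    0.40, 0.30,
      "Breviolum",     0.20,    0.50, 0.30,
      "Cladocopium",   0.10,    0.40, 0.50,
      "Durusdinium",   0.70,    0.20, 0.10,
      "unknown",       0.25,    0.40, 0.35
    )
  )
}

validate_class_model <- function(class_model) {
  stopifnot(is.list(class_model),
            all(c("classes", "proportions") %in% names(class_model)))
  if (nrow(class_model$classes) == 0) {
    abort("class model has no class distributions",
          class = "coralnet_configuration_error")
  }
  pr <- class_model$proportions
  sums <- rowSums(pr[, class_model$classes$class, drop = FALSE])
  if (any(abs(sums - 1) > 1e-8)) {
    abort("class mixing proportions must sum to 1 for every genus",
          class = "coralnet_configuration_error")
  }
  invisible(class_model)
}

# normal truncated to [lo, hi] via inverse-CDF; degenerate sd -> point mass
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd <= 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  pmin(hi, pmax(lo, qnorm(p, mean, sd)))
}

species_genus <- function(species) vapply(strsplit(species, " "), `[`, "", 1)

#' Impute a host tolerance from its closest listed relatives
#'
#' For a species absent from the BRI table, a BRI value is drawn from a
#' normal distribution whose mean and sd come from the closest listed
#' relative group — congeners (matched on the genus part of the binomial)
#' first, then confamilials, then all listed species — clamped to
#' \[0, 100\] and transformed with [host_tolerance_from_bri()].
#'
#' @param species Species binomial.
#' @param host_table Tibble with `species`, `bri_mean`, and optionally
#'   `bri_sd` and `family`.
#' @param family Family of `species`, used for the confamilial fallback.
#' @param n Number of independent draws.
#' @param global_fallback If `FALSE`, error when no congener or confamilial
#'   is listed instead of falling back to the global mean/sd.
#' @return List with `tolerance` (length-`n` numeric), `source`
#'   (`"imputed-relative"`), and the donor `mean`/`sd` on the BRI scale.
#' @export
impute_host_tolerance <- function(species, host_table, family = NULL, n = 1,
                                  global_fallback = TRUE) {
  donor <- host_donor_params(species, host_table, family, global_fallback)
  bri <- pmin(100, pmax(0, rnorm(n, donor$mean, donor$sd)))
  list(tolerance = host_tolerance_from_bri(bri), source = "imputed-relative",
       mean = donor$mean, sd = donor$sd)
}

host_donor_params <- function(species, host_table, family = NULL,
                              global_fallback = TRUE) {
  host_table <- as_tibble(host_table)
  if (nrow(host_table) == 0) {
    # no listed taxa at all: fall back to an uninformative mid-scale donor
    if (!global_fallback) {
      abort(paste0("no listed relative for species '", species,
                   "' and global fallback disabled"),
            class = "coralnet_imputation_error")
    }
    return(list(mean = 50, sd = 25))
  }
  if (!"bri_sd" %in% names(host_table)) host_table$bri_sd <- NA_real_
  genus <- species_genus(normalize_label(species))
  pool <- filter(host_table, species_genus(.data$species) == genus)
  if (nrow(pool) == 0 && !is.null(family) && "family" %in% names(host_table)) {
    pool <- filter(host_table, .data$family == !!family)
  }
  if (nrow(pool) == 0) {
    if (!global_fallback) {
      abort(paste0("no listed relative for species '", species,
                   "' and global fallback disabled"),
            class = "coralnet_imputation_error")
    }
    pool <- host_table
  }
  m <- mean(pool$bri_mean)
  s <- if (nrow(pool) == 1) {
    if (is.na(pool$bri_sd[1])) 0 else pool$bri_sd[1]
  } else {
    within_var <- mean(pool$bri_sd^2, na.rm = TRUE)
    if (is.nan(within_var)) within_var <- 0
    sqrt(within_var + stats::var(pool$bri_mean))
  }
  list(mean = m, sd = s)
}

#' Impute a symbiont tolerance from the class frequency model
#'
#' For an ITS2 type absent from the rank table: draw a tolerance class with
#' the genus' mixing proportions (the pooled `"unknown"` row when the genus
#' is not in the model), draw a rank score from that class's truncated
#' normal, and transform with [symbiont_tolerance_from_rank()]. Imputed
#' symbiont tolerances are redrawn independently for every simulation
#' replicate.
#'
#' @param genus Symbiont genus (or `"unknown"`).
#' @param class_model See [default_class_model()].
#' @param n Number of independent draws.
#' @return List with `tolerance`, `class` (drawn class per draw), `source`.
#' @export
impute_symbiont_tolerance <- function(genus, class_model = default_class_model(),
                                      n = 1) {
  validate_class_model(class_model)
  pr <- class_model$proportions
  row <- pr[pr$genus == genus, , drop = FALSE]
  if (nrow(row) == 0) row <- pr[pr$genus == "unknown", , drop = FALSE]
  if (nrow(row) == 0) {
    abort("class model lacks both the genus and an 'unknown' pooled row",
          class = "coralnet_configuration_error")
  }
  cls <- class_model$classes$class
  drawn <- sample(cls, n, replace = TRUE,
                  prob = as.numeric(row[1, cls]))
  rank <- vapply(drawn, function(cl) {
    p <- class_model$classes[class_model$classes$class == cl, ]
    rtruncnorm(1, p$mean, p$sd)
  }, 0, USE.NAMES = FALSE)
  list(tolerance = symbiont_tolerance_from_rank(rank), class = drawn,
       source = "imputed-class")
}

#' Attach a tolerance plan to a network
#'
#' Resolves every node against the tolerance source tables: listed species
#' and ITS2 types get fixed ("measured") tolerances via the two transforms;
#' unlisted hosts get a relative-based normal imputation recipe and unlisted
#' symbionts a class-model recipe. The plan records, per node, everything
#' [realize_tolerances()] needs to draw a replicate's tolerances, so that
#' measured values are replicate-invariant and imputed values are redrawn
#' per replicate.
#'
#' @param net A `coral_network`.
#' @param host_table Tibble `species`, `bri_mean`, optional `bri_sd`,
#'   `family`.
#' @param symbiont_table Tibble `its2_type`, optional `genus`, `rank_score`.
#' @param class_model Class frequency model for unlisted symbionts.
#' @param host_impute_once If `TRUE`, imputed host BRIs are drawn once here
#'   and frozen across replicates (the alternative reading of the
#'   per-replicate redraw convention); default redraws them per replicate
#'   like symbionts.
#' @return The network with plan columns on `hosts` and `symbionts`
#'   (`tol_source`, `tol_fixed`, donor parameters) and the class model
#'   attached as an attribute.
#' @export
tolerance_plan <- function(net, host_table, symbiont_table,
                           class_model = default_class_model(),
                           host_impute_once = FALSE) {
  stopifnot(inherits(net, "coral_network"))
  validate_class_model(class_model)
  host_table <- mutate(as_tibble(host_table), species = normalize_label(.data$species))
  symbiont_table <- mutate(as_tibble(symbiont_table),
                           its2_type = normalize_label(.data$its2_type))

  hosts <- net$hosts |>
    left_join(select(host_table, "species", "bri_mean"), by = "species") |>
    mutate(tol_source = if_else(is.na(.data$bri_mean), "imputed-relative", "measured"),
           tol_fixed = if_else(is.na(.data$bri_mean), NA_real_,
                               1 - .data$bri_mean / 100),
           donor_mean = NA_real_, donor_sd = NA_real_)
  todo <- which(hosts$tol_source == "imputed-relative")
  if (length(todo) > 0) {
    donors <- purrr::map(todo, function(i) {
      host_donor_params(hosts$species[i], host_table, hosts$family[i])
    })
    hosts$donor_mean[todo] <- purrr::map_dbl(donors, "mean")
    hosts$donor_sd[todo] <- purrr::map_dbl(donors, "sd")
    if (host_impute_once) {
      bri <- pmin(100, pmax(0, rnorm(length(todo), hosts$donor_mean[todo],
                                     hosts$donor_sd[todo])))
      hosts$tol_fixed[todo] <- 1 - bri / 100
      hosts$tol_source[todo] <- "imputed-relative-frozen"
    }
  }

  symbionts <- net$symbionts |>
    left_join(select(symbiont_table, "its2_type", "rank_score"),
              by = c(symbiont_id = "its2_type")) |>
    mutate(tol_source = if_else(is.na(.data$rank_score), "imputed-class", "measured"),
           tol_fixed = if_else(is.na(.data$rank_score), NA_real_,
                               sqrt(.data$rank_score) / 10))

  out <- new_coral_network(select(hosts, -"bri_mean"),
                           select(symbionts, -"rank_score"), net$edges)
  attr(out, "class_model") <- class_model
  out
}

#' Draw one replicate's node tolerances
#'
#' Fills the `tolerance` column on hosts and symbionts from the plan
#' attached by [tolerance_plan()]: measured (and frozen) values are copied,
#' imputed host BRIs are drawn from their donor normals (clamped to
#' \[0, 100\]), and imputed symbiont ranks are drawn from the class model.
#' Call once per simulation replicate under the replicate's RNG state.
#'
#' @param net A planned `coral_network`.
#' @return The network with `tolerance` columns populated (all in \[0, 1\]).
#' @export
realize_tolerances <- function(net) {
  stopifnot(inherits(net, "coral_network"))
  if (!"tol_source" %in% names(net$hosts)) {
    abort("network has no tolerance plan; call tolerance_plan() first",
          class = "coralnet_configuration_error")
  }
  class_model <- attr(net, "class_model")
  hosts <- net$hosts
  hosts$tolerance <- hosts$tol_fixed
  todo <- which(hosts$tol_source == "imputed-relative")
  if (length(todo) > 0) {
    bri <- pmin(100, pmax(0, rnorm(length(todo), hosts$donor_mean[todo],
                                   hosts$donor_sd[todo])))
    hosts$tolerance[todo] <- 1 - bri / 100
  }
  symbionts <- net$symbionts
  symbionts$tolerance <- symbionts$tol_fixed
  todo <- which(symbionts$tol_source == "imputed-class")
  if (length(todo) > 0) {
    pr <- class_model$proportions
    genus <- ifelse(symbionts$genus[todo] %in% pr$genus,
                    symbionts$genus[todo], "unknown")
    cls <- class_model$classes$class
    for (g in unique(genus)) {
      idx <- todo[genus == g]
      row <- pr[pr$genus == g, , drop = FALSE]
      drawn <- sample(cls, length(idx), replace = TRUE,
                      prob = as.numeric(row[1, cls]))
      for (cl in unique(drawn)) {
        p <- class_model$classes[class_model$classes$class == cl, ]
        j <- idx[drawn == cl]
        symbionts$tolerance[j] <- sqrt(rtruncnorm(length(j), p$mean, p$sd)) / 10
      }
    }
  }
  out <- new_coral_network(hosts, symbionts, net$edges)
  attr(out, "class_model") <- class_model
  out
}

#' Tidy node tolerances
#'
#' @param net A realized `coral_network`.
#' @return A tibble with `node_id`, `class`, `tolerance`, `source`.
#' @export
node_tolerances <- function(net) {
  bind_rows(
    tibble(node_id = net$hosts$host_id, class = "host",
           tolerance = net$hosts$tolerance %||% NA_real_,
           source = net$hosts$tol_source %||% NA_character_),
    tibble(node_id = net$symbionts$symbiont_id, class = "symbiont",
           tolerance = net$symbionts$tolerance %||% NA_real_,
           source = net$symbionts$tol_source %||% NA_character_)
  )
}
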