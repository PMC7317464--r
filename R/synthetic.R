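# Synthetic-data generator. Emulates the statistical structure the analysis
# assumes: a sparse bipartite host-symbiont network whose symbiont side is
# heavy-tailed (a few generalist hubs, many specialists), hosts partitioned
# into subregions carrying the packaged T_MMM climatology, host tolerances
# from a BRI-like distribution, and symbiont tolerances from a three-class
# (high/medium/low) mixture. A configurable fraction of taxa is left out of
# the tolerance tables to exercise the imputation paths.

coral_family_pool <- function() {
  tribble(
    ~family,            ~weight,
    "Acroporidae",         0.22,
    "Faviidae",            0.13,
    "Poritidae",           0.10,
    "Pocilloporidae",      0.09,
    "Agariciidae",         0.08,
    "Siderastreidae",      0.06,
    "Merulinidae",         0.06,
    "Fungiidae",           0.06,
    "Dendrophylliidae",    0.05,
    "Euphylliidae",        0.05,
    "Lobophylliidae",      0.04,
    "Oculinidae",          0.03,
    "Astrocoeniidae",      0.03
  )
}

# bring an integer degree sequence to an exact total by random unit moves
adjust_to_sum <- function(deg, target, lo = 1L, hi = Inf) {
  if (length(deg) * lo > target || length(deg) * min(hi, target) < target) {
    abort("infeasible degree sequence: target total out of range",
          class = "coralnet_generation_error")
  }
  while (sum(deg) > target) {
    idx <- which(deg > lo)
    i <- idx[sample.int(length(idx), 1)]
    deg[i] <- deg[i] - 1L
  }
  while (sum(deg) < target) {
    idx <- which(deg < hi)
    i <- idx[sample.int(length(idx), 1)]
    deg[i] <- deg[i] + 1L
  }
  deg
}

# bipartite degree-sequence wiring: a Havel-Hakimi-style construction
# (each host, in descending degree, connects to the symbionts with the most
# remaining stubs) realizes any bipartite-graphical sequence as a simple
# graph; the deterministic wiring is then randomized by degree-preserving
# double-edge swaps
wire_stubs <- function(host_degrees, sym_degrees, swaps_per_link = 10) {
  host_order <- order(-host_degrees, runif(length(host_degrees)))
  remaining <- as.numeric(sym_degrees)
  picks <- vector("list", length(host_degrees))
  for (h in host_order) {
    d <- host_degrees[h]
    if (sum(remaining > 0) < d) {
      abort("infeasible bipartite degree sequence: cannot wire a simple graph",
            class = "coralnet_generation_error")
    }
    # largest remaining first, random among ties
    chosen <- order(-remaining, runif(length(remaining)))[seq_len(d)]
    remaining[chosen] <- remaining[chosen] - 1
    picks[[h]] <- chosen
  }
  eh <- unlist(lapply(seq_along(host_degrees), function(h) rep(h, host_degrees[h])))
  es <- unlist(picks)
  # mix with double-edge swaps (reject swaps creating duplicate links)
  l <- length(eh)
  ns <- length(sym_degrees)
  key_env <- new.env(hash = TRUE, size = 2 * l)
  for (i in seq_len(l)) assign(as.character((eh[i] - 1) * ns + es[i]), TRUE, key_env)
  p1 <- sample.int(l, swaps_per_link * l, replace = TRUE)
  p2 <- sample.int(l, swaps_per_link * l, replace = TRUE)
  for (t in seq_along(p1)) {
    i <- p1[t]; j <- p2[t]
    if (i == j || eh[i] == eh[j] || es[i] == es[j]) next
    k1 <- as.character((eh[i] - 1) * ns + es[j])
    k2 <- as.character((eh[j] - 1) * ns + es[i])
    if (exists(k1, key_env, inherits = FALSE) ||
        exists(k2, key_env, inherits = FALSE)) next
    rm(list = c(as.character((eh[i] - 1) * ns + es[i]),
                as.character((eh[j] - 1) * ns + es[j])), envir = key_env)
    tmp <- es[i]; es[i] <- es[j]; es[j] <- tmp
    assign(k1, TRUE, key_env); assign(k2, TRUE, key_env)
  }
  tibble(host = eh, symbiont = es)
}

#' Generate a synthetic coral--symbiont data bundle
#'
#' Builds a full set of mutually consistent input tables — association
#' records, environment, host BRI table, symbiont rank table, taxonomy —
#' with the structure the pipeline assumes, plus the ground truth of every
#' drawn parameter. The `"global-like"` preset reproduces the marginals of
#' the global network: 685 host nodes over 362 species in the 14 packaged
#' subregions (host and link counts per subregion from the packaged table),
#' 250 symbiont nodes of which three are generalist *Cladocopium* hubs with
#' degree at least 140, and 1,697 links.
#'
#' @param preset `"global-like"` or `"single-subregion"`.
#' @param seed Seed for the generator; `NULL` uses the current RNG state.
#' @param unlisted_host_frac,unlisted_sym_frac Fraction of species / ITS2
#'   types withheld from the tolerance tables to force imputation.
#' @param ... Passed to [single_subregion_preset()] for that preset.
#' @return A `coral_bundle` list: `records`, `env`, `host_table`,
#'   `symbiont_table`, `taxonomy`, `truth`.
#' @export
synth_bundle <- function(preset = c("global-like", "single-subregion"),
                         seed = NULL, unlisted_host_frac = 0.25,
                         unlisted_sym_frac = 0.25, ...) {
  preset <- match.arg(preset)
  if (preset == "single-subregion") {
    return(single_subregion_preset(seed = seed,
                                   unlisted_host_frac = unlisted_host_frac,
                                   unlisted_sym_frac = unlisted_sym_frac, ...))
  }
  env <- subregion_environment(include_marginals = TRUE)
  with_substream(seed, generate_bundle(
    env = env, n_species = 362, n_symbionts = 250,
    n_hubs = 3, hub_min_degree = 140,
    sym_alpha = 1.4, sym_cutoff = 35,
    host_alpha = 1.6, host_cutoff = 20, host_max_degree = 25,
    unlisted_host_frac = unlisted_host_frac,
    unlisted_sym_frac = unlisted_sym_frac, seed = seed))
}

#' Generate a small single-subregion bundle
#'
#' One subregion at a chosen thermal baseline; every link threshold then
#' falls in `[t_mmm, t_mmm + t_delta]`, which bounds resistance by 1 and
#' makes the preset convenient for oracle tests.
#'
#' @param t_mmm Subregion baseline temperature, degrees C (default the
#'   Great Barrier Reef value, 28.68).
#' @param n_hosts,n_symbionts,n_links Network size.
#' @param subregion,region Labels for the synthetic location.
#' @param seed Generator seed.
#' @param unlisted_host_frac,unlisted_sym_frac Imputation fractions.
#' @return A `coral_bundle`.
#' @export
single_subregion_preset <- function(t_mmm = 28.68, n_hosts = 60,
                                    n_symbionts = 25, n_links = 150,
                                    subregion = "Synthetic Reef",
                                    region = "Synthetic Region",
                                    seed = NULL,
                                    unlisted_host_frac = 0.25,
                                    unlisted_sym_frac = 0.25) {
  env <- tibble(subregion = subregion, region = region, t_mmm_c = t_mmm,
                n_hosts = n_hosts, n_links = n_links)
  with_substream(seed, generate_bundle(
    env = env, n_species = n_hosts, n_symbionts = n_symbionts,
    n_hubs = 0, hub_min_degree = 0,
    sym_alpha = 1.4, sym_cutoff = 35,
    host_alpha = 1.6, host_cutoff = 20,
    host_max_degree = min(n_symbionts, 25),
    unlisted_host_frac = unlisted_host_frac,
    unlisted_sym_frac = unlisted_sym_frac, seed = seed))
}

generate_bundle <- function(env, n_species, n_symbionts, n_hubs,
                            hub_min_degree, sym_alpha, sym_cutoff,
                            host_alpha, host_cutoff, host_max_degree,
                            unlisted_host_frac, unlisted_sym_frac, seed) {
  n_host_nodes <- sum(env$n_hosts)
  n_links <- sum(env$n_links)
  if (max(env$n_hosts) > n_species) {
    abort("a subregion needs more distinct species than the species pool holds",
          class = "coralnet_generation_error")
  }

  # --- species pool with families ---
  fam <- coral_family_pool()
  species <- tibble(
    species = sprintf("Coral sp%03d", seq_len(n_species)),
    family = sample(fam$family, n_species, replace = TRUE, prob = fam$weight))

  # --- assign species to subregions: each species placed at least once,
  #     each subregion holds its published number of distinct species ---
  capacity <- setNames(env$n_hosts, env$subregion)
  placement <- vector("list", length(capacity))
  names(placement) <- names(capacity)
  for (sp in sample(species$species)) {
    open <- names(capacity)[capacity - lengths(placement) > 0]
    pick <- if (length(open) == 1) open else
      sample(open, 1, prob = (capacity - lengths(placement))[open])
    placement[[pick]] <- c(placement[[pick]], sp)
  }
  for (sr in names(placement)) {
    short <- capacity[[sr]] - length(placement[[sr]])
    if (short > 0) {
      pool <- setdiff(species$species, placement[[sr]])
      placement[[sr]] <- c(placement[[sr]], sample(pool, short))
    }
  }
  hosts <- purrr::imap_dfr(placement, function(sp, sr) {
    tibble(species = sp, subregion = sr)
  }) |>
    left_join(species, by = "species") |>
    left_join(select(env, "subregion", "region"), by = "subregion")

  # --- symbiont identities ---
  genus_prob <- c(Symbiodinium = 0.15, Breviolum = 0.12,
                  Cladocopium = 0.55, Durusdinium = 0.18)
  genus <- sample(names(genus_prob), n_symbionts, replace = TRUE,
                  prob = genus_prob)
  if (n_hubs > 0) genus[seq_len(n_hubs)] <- "Cladocopium"  # the observed hubs
  prefix <- c(Symbiodinium = "A", Breviolum = "B", Cladocopium = "C",
              Durusdinium = "D")[genus]
  its2 <- paste0(prefix, stats::ave(seq_len(n_symbionts), prefix,
                                    FUN = seq_along))

  # --- degrees and wiring: independently drawn host and symbiont degree
  #     sequences are not guaranteed to be jointly graphical, so redraw on
  #     an infeasible combination (bounded retries) ---
  wired <- NULL
  for (attempt in 1:50) {
    hosts_try <- hosts |>
      group_by(.data$subregion) |>
      group_modify(function(df, key) {
        target <- env$n_links[env$subregion == key$subregion]
        d <- rtrunc_power_law(nrow(df), host_alpha, host_cutoff,
                              kmax = host_max_degree)
        df$degree <- adjust_to_sum(as.integer(d), target, lo = 1L,
                                   hi = host_max_degree)
        df
      }) |>
      ungroup()
    hub_deg <- if (n_hubs > 0) hub_min_degree + sample.int(20, n_hubs) else integer()
    rest_n <- n_symbionts - n_hubs
    rest_target <- n_links - sum(hub_deg)
    rest_max <- if (n_hubs == 0) n_host_nodes else
      max(5L, min(hub_min_degree - 1L, n_host_nodes))
    rest_deg <- adjust_to_sum(
      as.integer(rtrunc_power_law(rest_n, sym_alpha, sym_cutoff,
                                  kmax = min(rest_max, 1000L))),
      rest_target, lo = 1L, hi = rest_max)
    symbionts_try <- tibble(symbiont_id = its2, genus = genus,
                            degree = c(hub_deg, rest_deg))
    wired <- tryCatch(wire_stubs(hosts_try$degree, symbionts_try$degree),
                      coralnet_generation_error = function(e) NULL)
    if (!is.null(wired)) {
      hosts <- hosts_try
      symbionts <- symbionts_try
      break
    }
  }
  if (is.null(wired)) {
    abort("infeasible degree sequence after bounded retries",
          class = "coralnet_generation_error")
  }
  records <- tibble(
    host_species = hosts$species[wired$host],
    host_family = hosts$family[wired$host],
    subregion = hosts$subregion[wired$host],
    region = hosts$region[wired$host],
    symbiont_type = symbionts$symbiont_id[wired$symbiont],
    symbiont_genus = symbionts$genus[wired$symbiont],
    in_situ = TRUE, scleractinian = TRUE) |>
    arrange(.data$host_species, .data$subregion, .data$symbiont_type)

  tol <- synth_tolerance_tables(species, select(symbionts, "symbiont_id", "genus"),
                                unlisted_host_frac, unlisted_sym_frac)

  structure(list(
    records = records,
    env = select(env, "subregion", "region", "t_mmm_c"),
    host_table = tol$host_table,
    symbiont_table = tol$symbiont_table,
    taxonomy = select(species, "species", "family"),
    truth = list(seed = seed, hosts = hosts, symbionts = symbionts,
                 host_truth = tol$host_truth, symbiont_truth = tol$symbiont_truth,
                 params = list(n_species = n_species, n_symbionts = n_symbionts,
                               n_links = n_links, n_hubs = n_hubs,
                               sym_alpha = sym_alpha, sym_cutoff = sym_cutoff,
                               unlisted_host_frac = unlisted_host_frac,
                               unlisted_sym_frac = unlisted_sym_frac))),
    class = "coral_bundle")
}

#' Generate tolerance-source tables for synthetic taxa
#'
#' Every species receives a true BRI (mean from a normal centred at 40 with
#' sd 20, truncated to \[0, 100\]; within-species sd uniform on \[5, 15\])
#' and every ITS2 type a true rank score from the three-class mixture with
#' the genus proportions of [default_class_model()]. The configured
#' unlisted fractions are then withheld from the published tables to force
#' imputation downstream; the full truth is returned alongside.
#'
#' @param species Tibble with `species` and `family`.
#' @param symbionts Tibble with `symbiont_id` and `genus`.
#' @param unlisted_host_frac,unlisted_sym_frac Fractions withheld.
#' @param class_model Class mixture used for the true symbiont ranks.
#' @return List: `host_table`, `symbiont_table` (the published subsets),
#'   `host_truth`, `symbiont_truth` (complete).
#' @export
synth_tolerance_tables <- function(species, symbionts,
                                   unlisted_host_frac = 0.25,
                                   unlisted_sym_frac = 0.25,
                                   class_model = default_class_model()) {
  host_truth <- species |>
    mutate(bri_mean = rtruncnorm(n(), 40, 20),
           bri_sd = runif(n(), 5, 15))
  pr <- class_model$proportions
  cls <- class_model$classes$class
  genus_known <- ifelse(symbionts$genus %in% pr$genus, symbionts$genus, "unknown")
  sym_class <- vapply(genus_known, function(g) {
    sample(cls, 1, prob = as.numeric(pr[pr$genus == g, cls]))
  }, "")
  rank <- vapply(sym_class, function(cl) {
    p <- class_model$classes[class_model$classes$class == cl, ]
    rtruncnorm(1, p$mean, p$sd)
  }, 0)
  symbiont_truth <- mutate(symbionts, class = unname(sym_class),
                           rank_score = unname(rank))

  n_unl_h <- round(unlisted_host_frac * nrow(host_truth))
  n_unl_s <- round(unlisted_sym_frac * nrow(symbiont_truth))
  unlisted_h <- if (n_unl_h > 0) sample(host_truth$species, n_unl_h) else character()
  unlisted_s <- if (n_unl_s > 0) sample(symbiont_truth$symbiont_id, n_unl_s) else character()

  list(
    host_table = host_truth |>
      filter(!.data$species %in% unlisted_h) |>
      select("species", "family", "bri_mean", "bri_sd"),
    symbiont_table = symbiont_truth |>
      filter(!.data$symbiont_id %in% unlisted_s) |>
      transmute(its2_type = .data$symbiont_id, genus = .data$genus,
                rank_score = .data$rank_score),
    host_truth = host_truth, symbiont_truth = symbiont_truth)
}

#' @export
print.coral_bundle <- function(x, ...) {
  cat("<coral_bundle> ", nrow(x$records), " association records, ",
      length(unique(x$records$host_species)), " species, ",
      length(unique(x$records$symbiont_type)), " ITS2 types, ",
      nrow(x$env), " subregion(s)\n", sep = "")
  invisible(x)
}

#' Build a planned network from a bundle
#'
#' Convenience composition: filter the bundle's records, build the
#' bipartite network against the bundle's environment, and attach the
#' tolerance plan from its source tables.
#'
#' @param bundle A `coral_bundle`.
#' @param ... Passed to [tolerance_plan()].
#' @return A planned `coral_network`.
#' @export
bundle_network <- function(bundle, ...) {
  records <- filter_records(bundle$records,
                            known_subregions = bundle$env$subregion)
  net <- build_network(records, env = bundle$env)
  tolerance_plan(net, bundle$host_table, bundle$symbiont_table, ...)
}
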