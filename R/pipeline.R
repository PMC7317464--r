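#' Run the full resistance-and-robustness pipeline
#'
#' End-to-end orchestration: filter the association records, build the
#' global bipartite network, attach the tolerance plan, enumerate the
#' spatial scopes (global, each region, each subregion), and, for every
#' scope with enough links, run the bleaching-resistance ensemble on the
#' natural network and each requested null, the R50 robustness ensemble for
#' each requested removal model, and the randomization-test comparison of
#' the resistance ensembles. Scopes with fewer than `min_links` links are
#' excluded from the simulations (they stay in the scope table, flagged).
#' One master seed drives documented per-stage substreams, so reruns with
#' the same configuration reproduce every number exactly.
#'
#' @param bundle A `coral_bundle` (synthetic or assembled from real
#'   tables); alternatively supply `records`, `env`, `host_table`,
#'   `symbiont_table` directly.
#' @param records,env,host_table,symbiont_table Input tables, used when
#'   `bundle` is `NULL`.
#' @param scopes Character vector of scope labels, or `"auto"` (global +
#'   all regions + all subregions present in the network).
#' @param replicates Simulations per ensemble.
#' @param t_delta Upper thermal limit, degrees C.
#' @param removal_models Removal models to run (susceptible_links runs all
#'   three modes).
#' @param nulls Null constructions to compare against the natural network.
#' @param n_perm,alpha Randomization-test settings.
#' @param min_links Minimum link count for a scope to be simulated
#'   (default 40).
#' @param seed Master seed.
#' @param out_dir Optional directory; results and a JSON manifest are
#'   written there.
#' @return A `coral_run` list: `network`, `scopes`, `resistance` (tibble:
#'   scope x network kind), `robustness` (tibble: scope x model),
#'   `comparisons` (per-scope `ensemble_comparison`), `family`,
#'   `manifest`.
#' @export
run_coral_pipeline <- function(bundle = NULL, records = NULL, env = NULL,
                               host_table = NULL, symbiont_table = NULL,
                               scopes = "auto", replicates = 100, t_delta = 3,
                               removal_models = c("random_links", "bleaching",
                                                  "susceptible_links",
                                                  "random_nodes",
                                                  "susceptible_nodes"),
                               nulls = c("shuffled_tolerance",
                                         "random_tolerance", "rbdc", "rbndc"),
                               n_perm = 999, alpha = 0.05, min_links = 40,
                               seed = 1, out_dir = NULL) {
  t0 <- Sys.time()
  if (!is.null(bundle)) {
    records <- bundle$records
    env <- bundle$env
    host_table <- bundle$host_table
    symbiont_table <- bundle$symbiont_table
  }
  env <- env %||% subregion_environment()
  records <- filter_records(records, known_subregions = env$subregion)
  net <- build_network(records, env = env)
  validate_network(net)
  plan <- tolerance_plan(net, host_table, symbiont_table)

  scope_tbl <- tibble(scope = "global", kind = "global") |>
    bind_rows(tibble(scope = unique(net$hosts$region), kind = "region"),
              tibble(scope = unique(net$hosts$subregion), kind = "subregion"))
  if (!identical(scopes, "auto")) {
    scope_tbl <- filter(scope_tbl, .data$scope %in% scopes)
  }
  scope_nets <- purrr::map(scope_tbl$scope, function(sc) {
    if (sc == "global") plan else subset_plan(plan, sc)
  })
  scope_tbl <- scope_tbl |>
    mutate(n_hosts = purrr::map_int(scope_nets, ~ nrow(.x$hosts)),
           n_links = purrr::map_int(scope_nets, ~ nrow(.x$edges)),
           simulated = .data$n_links >= min_links)

  run_scopes <- which(scope_tbl$simulated)
  resistance <- list(); robustness <- list(); comparisons <- list()
  for (i in run_scopes) {
    sc <- scope_tbl$scope[i]
    snet <- scope_nets[[i]]
    ens <- list(natural = resistance_ensemble(
      snet, replicates, t_delta, seed = substream_seed(seed, "scope", sc, "natural")))
    for (nl in nulls) {
      ens[[nl]] <- resistance_ensemble(
        snet, replicates, t_delta,
        seed = substream_seed(seed, "scope", sc, nl), null = nl)
    }
    resistance[[sc]] <- purrr::map_dfr(ens, glance) |>
      mutate(scope = sc, .before = 1)
    comparisons[[sc]] <- compare_ensembles(
      ens, alpha = alpha, n_perm = n_perm,
      seed = substream_seed(seed, "compare", sc))

    rb <- list()
    for (m in removal_models) {
      modes <- if (m == "susceptible_links") c("averaged", "host", "symbiont") else "averaged"
      for (md in modes) {
        lbl <- if (m == "susceptible_links") paste0(m, ":", md) else m
        rb[[lbl]] <- robustness_ensemble(
          snet, m, md, replicates, t_delta,
          seed = substream_seed(seed, "r50", sc, lbl))
      }
    }
    robustness[[sc]] <- purrr::imap_dfr(rb, function(e, nm) {
      mutate(glance(e), scope = sc, attack = nm, .before = 1)
    })
  }

  fam <- if ("family" %in% names(plan$hosts) &&
             !all(plan$hosts$family == "unknown")) {
    family_susceptibility(plan, replicates = replicates,
                          n_first = min(100, nrow(plan$hosts)),
                          t_delta = t_delta,
                          seed = substream_seed(seed, "family"))
  }

  resistance_tbl <- bind_rows(resistance)
  robustness_tbl <- bind_rows(robustness)
  manifest <- tibble(
    seed = seed, replicates = replicates, t_delta = t_delta,
    n_perm = n_perm, alpha = alpha, min_links = min_links,
    n_scopes_simulated = length(run_scopes),
    input_hash = rlang::hash(list(records, env, host_table, symbiont_table)),
    resistance_hash = rlang::hash(resistance_tbl),
    robustness_hash = rlang::hash(robustness_tbl),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- structure(list(network = plan, scopes = scope_tbl,
                        resistance = resistance_tbl,
                        robustness = robustness_tbl,
                        comparisons = comparisons, family = fam,
                        manifest = manifest),
                   class = "coral_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

# subset a planned network, keeping the plan columns and class model
subset_plan <- function(plan, scope) {
  out <- subset_network(plan, scope)
  attr(out, "class_model") <- attr(plan, "class_model")
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$scopes |> select(-dplyr::any_of("net")), file.path(out_dir, "scopes.csv"))
  readr::write_csv(run$resistance, file.path(out_dir, "resistance.csv"))
  readr::write_csv(run$robustness, file.path(out_dir, "robustness.csv"))
  if (!is.null(run$family)) {
    readr::write_csv(run$family, file.path(out_dir, "family_susceptibility.csv"))
  }
  jsonlite::write_json(as.list(run$manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run)
}

#' @export
print.coral_run <- function(x, ...) {
  cat("<coral_run> ", sum(x$scopes$simulated), " of ", nrow(x$scopes),
      " scopes simulated; seed ", x$manifest$seed, "\n", sep = "")
  cat("resistance (natural networks):\n")
  print(filter(x$resistance, .data$network == "natural") |>
          select("scope", "mean", "sd"))
  invisible(x)
}
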