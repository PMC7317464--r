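# Fixtures and independent oracles, all built in code.

toy_env <- function(subregions = "Reef A", t_mmm = 29, regions = "Region X") {
  tibble::tibble(subregion = subregions, region = regions,
                 t_mmm_c = rep_len(t_mmm, length(subregions)))
}

# records tibble from a host x symbiont edge list given as two vectors
toy_records <- function(hosts, symbionts, subregion = "Reef A",
                        region = "Region X", family = "Acroporidae") {
  tibble::tibble(host_species = hosts, host_family = family,
                 subregion = subregion, region = region,
                 symbiont_type = symbionts, symbiont_genus = "Cladocopium",
                 in_situ = TRUE, scleractinian = TRUE)
}

# build a fully measured, realized network with prescribed tolerances.
# host_tol / sym_tol are named vectors (species -> tau, its2 -> tau).
toy_realized <- function(records, env, host_tol, sym_tol) {
  net <- build_network(filter_records(records, known_subregions = env$subregion),
                       env = env)
  host_table <- tibble::tibble(species = names(host_tol),
                               bri_mean = (1 - unname(host_tol)) * 100,
                               bri_sd = 0)
  sym_table <- tibble::tibble(its2_type = names(sym_tol),
                              genus = "Cladocopium",
                              rank_score = (unname(sym_tol) * 10)^2)
  realize_tolerances(tolerance_plan(net, host_table, sym_table))
}

# random toy network with random measured tolerances, possibly several
# subregions; returns a realized network
random_toy_net <- function(n_hosts = 6, n_symbionts = 4, n_links = 10,
                           n_subregions = 2) {
  subs <- paste("Reef", seq_len(n_subregions))
  env <- toy_env(subs, t_mmm = 28 + runif(n_subregions, 0, 3))
  cells <- sample.int(n_hosts * n_symbionts, min(n_links, n_hosts * n_symbionts))
  hosts <- sprintf("Coral sp%02d", (cells - 1) %/% n_symbionts + 1)
  syms <- sprintf("C%d", (cells - 1) %% n_symbionts + 1)
  rec <- toy_records(hosts, syms,
                     subregion = sample(subs, length(hosts), replace = TRUE))
  rec <- dplyr::distinct(rec, host_species, subregion, symbiont_type,
                         .keep_all = TRUE)
  host_tol <- setNames(runif(n_hosts), sprintf("Coral sp%02d", seq_len(n_hosts)))
  sym_tol <- setNames(runif(n_symbionts), sprintf("C%d", seq_len(n_symbionts)))
  toy_realized(rec, env, host_tol, sym_tol)
}

# --- independent oracle: naive fine-grid temperature ramp ---------------
# computes per-link thresholds by hand from the node tables and sweeps a
# fixed grid; a host is bleached at T once every one of its links has
# W <= T (closed threshold).
naive_bleach_curve <- function(net, temps, t_delta = 3) {
  e <- merge(as.data.frame(net$edges),
             as.data.frame(net$hosts)[, c("host_id", "t_mmm_c", "tolerance")],
             by = "host_id")
  names(e)[names(e) == "tolerance"] <- "tau_h"
  e <- merge(e, as.data.frame(net$symbionts)[, c("symbiont_id", "tolerance")],
             by = "symbiont_id")
  names(e)[names(e) == "tolerance"] <- "tau_s"
  e$w <- e$t_mmm_c + t_delta * (e$tau_h + e$tau_s) / 2
  n_hosts <- nrow(net$hosts)
  vapply(temps, function(tt) {
    alive <- e[e$w > tt, ]
    sum(!(net$hosts$host_id %in% alive$host_id)) / n_hosts
  }, 0)
}

# --- independent oracle: r50 under link removal by direct simulation ----
# removes links one at a time from a plain edge data.frame and recounts
# non-isolated nodes from scratch after every removal.
brute_r50_link <- function(edges, n_nodes, order_idx) {
  l <- nrow(edges)
  for (k in seq_len(l)) {
    left <- edges[-order_idx[seq_len(k)], , drop = FALSE]
    remaining <- length(unique(left$host_id)) + length(unique(left$symbiont_id))
    if (remaining <= 0.5 * n_nodes) return(k / l)
  }
  stop("never reached 50%")
}

# exhaustive mean r50 over all link-removal permutations (tiny networks)
exhaustive_mean_r50 <- function(net) {
  l <- nrow(net$edges)
  n_nodes <- nrow(net$hosts) + nrow(net$symbionts)
  perms <- gtools_permutations(l)
  mean(apply(perms, 1, function(p) {
    brute_r50_link(as.data.frame(net$edges), n_nodes, p)
  }))
}

# all permutations of 1:n without extra packages
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(1:n, i)[sub], nrow(sub), n - 1))
  }))
}
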