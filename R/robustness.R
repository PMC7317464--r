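#' Removal order for an attack model
#'
#' Produces the ordered list of links or nodes removed by one of the five
#' attack models: `random_links` and `random_nodes` (uniform shuffles, the
#' baselines), `bleaching` (links ascending by their thermal threshold `W`),
#' `susceptible_links` (links ascending by tolerance — the holobiont average
#' of the two endpoint tolerances, or the host's or symbiont's alone,
#' depending on `mode`), and `susceptible_nodes` (hosts and symbionts pooled,
#' ascending by tolerance). Ties are broken by an independent uniform
#' shuffle, fresh per call.
#'
#' @param net A realized `coral_network`.
#' @param model One of `"random_links"`, `"bleaching"`,
#'   `"susceptible_links"`, `"random_nodes"`, `"susceptible_nodes"`.
#' @param mode For `susceptible_links` only: `"averaged"` (default),
#'   `"host"`, or `"symbiont"`.
#' @param t_delta Upper thermal limit used for `bleaching` thresholds.
#' @param node_class For node models: `"both"` (default, the pooled order),
#'   `"host"`, or `"symbiont"` to restrict the attack to one class.
#' @return A `removal_order` tibble: `entity` (`"link"` or `"node"`) plus
#'   `host_id`/`symbiont_id` for links or `node_id` for nodes, in removal
#'   order.
#' @export
removal_order <- function(net,
                          model = c("random_links", "bleaching",
                                    "susceptible_links", "random_nodes",
                                    "susceptible_nodes"),
                          mode = c("averaged", "host", "symbiont"),
                          t_delta = 3, node_class = c("both", "host", "symbiont")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  node_class <- match.arg(node_class)
  link_model <- model %in% c("random_links", "bleaching", "susceptible_links")
  if (link_model) {
    edges <- if (model == "random_links") {
      mutate(net$edges, key = runif(n()))
    } else {
      lw <- link_weights(net, t_delta)
      key <- switch(model,
        bleaching = lw$w_c,
        susceptible_links = switch(mode,
          averaged = (lw$tau_host + lw$tau_symbiont) / 2,
          host = lw$tau_host,
          symbiont = lw$tau_symbiont))
      mutate(net$edges, key = key)
    }
    out <- edges |>
      arrange(.data$key, runif(n())) |>
      transmute(entity = "link", .data$host_id, .data$symbiont_id)
  } else {
    tol <- node_tolerances(net)
    if (node_class != "both") tol <- filter(tol, .data$class == node_class)
    if (model == "susceptible_nodes" && anyNA(tol$tolerance)) {
      abort("node tolerances missing; call realize_tolerances() first",
            class = "coralnet_configuration_error")
    }
    key <- if (model == "random_nodes") runif(nrow(tol)) else tol$tolerance
    out <- tol |>
      mutate(key = key) |>
      arrange(.data$key, runif(n())) |>
      transmute(entity = "node", .data$node_id)
  }
  structure(out, class = c("removal_order", class(out)))
}

#' Trajectory of surviving nodes under sequential removal
#'
#' Removes the listed entities one at a time and records, after every
#' removal, the number of original nodes still "remaining": a node remains
#' while it keeps at least one link (secondary extinctions count as losses
#' for both attack classes), and a primarily removed node no longer remains
#' regardless of its links. The fraction-removed axis is the count of
#' primary removals over the length of the order; the fraction-remaining
#' axis is over the original node count.
#'
#' @param net A `coral_network`.
#' @param order A `removal_order` (links or nodes).
#' @return A `removal_trajectory` tibble with `n_removed`, `frac_removed`,
#'   `n_remaining`, `frac_remaining`, from step 0 to the full order.
#' @export
removal_trajectory <- function(net, order) {
  n_nodes <- nrow(net$hosts) + nrow(net$symbionts)
  l <- nrow(net$edges)
  hmap <- setNames(seq_len(nrow(net$hosts)), net$hosts$host_id)
  smap <- setNames(seq_len(nrow(net$symbionts)), net$symbionts$symbiont_id)
  eh <- hmap[net$edges$host_id]
  es <- smap[net$edges$symbiont_id]
  if (nrow(order) == 0) {
    out <- tibble(n_removed = 0L, frac_removed = 0, n_remaining = n_nodes,
                  frac_remaining = 1)
    return(structure(out, entity = NA_character_,
                     class = c("removal_trajectory", class(out))))
  }
  entity <- order$entity[1]
  k_total <- nrow(order)

  if (entity == "link") {
    key <- paste(order$host_id, order$symbiont_id, sep = "\r")
    pos <- match(paste(net$edges$host_id, net$edges$symbiont_id, sep = "\r"), key)
    if (anyNA(pos) || anyDuplicated(key) || k_total != l) {
      abort("link order must be a permutation of the network's links",
            class = "coralnet_integrity_error")
    }
    # a node exits when its last incident link is removed; nodes isolated
    # from the start never count as remaining
    exit <- c(tapply(pos, eh, max), tapply(pos, es, max))
    init_remaining <- length(exit)
    exited_by_k <- cumsum(tabulate(exit, nbins = k_total))
  } else {
    ids <- c(net$hosts$host_id, net$symbionts$symbiont_id)
    if (anyDuplicated(order$node_id) || !all(order$node_id %in% ids)) {
      abort("node order references unknown or duplicated nodes",
            class = "coralnet_integrity_error")
    }
    pos_node <- match(ids, order$node_id)
    pos_node[is.na(pos_node)] <- Inf  # outside the attacked class
    link_step <- pmin(pos_node[eh], pos_node[nrow(net$hosts) + es])
    # isolation step: when the node's last incident link is gone; a node
    # exits at its own removal or its isolation, whichever comes first
    iso <- rep(0, n_nodes)  # nodes with no links start isolated
    iso_h <- tapply(link_step, eh, max)
    iso_s <- tapply(link_step, es, max)
    iso[as.integer(names(iso_h))] <- iso_h
    iso[nrow(net$hosts) + as.integer(names(iso_s))] <- iso_s
    exit <- pmin(pos_node, iso)
    init_remaining <- sum(exit > 0)
    exited_by_k <- cumsum(tabulate(exit[is.finite(exit) & exit > 0],
                                   nbins = k_total))
  }

  remaining <- c(init_remaining, init_remaining - exited_by_k)
  out <- tibble(
    n_removed = 0:k_total,
    frac_removed = (0:k_total) / k_total,
    n_remaining = as.integer(remaining),
    frac_remaining = remaining / n_nodes)
  structure(out, entity = entity, n_nodes = n_nodes,
            class = c("removal_trajectory", class(out)))
}

#' R50 ecological robustness from a trajectory
#'
#' The smallest fraction of removed entities at which the number of
#' remaining nodes falls to half (or less) of the original node count.
#' Exact fraction `k / total`.
#'
#' @param trajectory A `removal_trajectory`.
#' @return The R50 fraction in (0, 1\].
#' @export
r50 <- function(trajectory) {
  hit <- which(trajectory$frac_remaining <= 0.5)
  if (length(hit) == 0) {
    abort("trajectory never reaches 50% of nodes remaining; R50 undefined",
          class = "coralnet_metric_error")
  }
  trajectory$frac_removed[hit[1]]
}

#' R50 over an ensemble of attack simulations
#'
#' Per replicate: redraw imputed tolerances from the plan, optionally apply
#' a null-network transform, draw the removal order (tie shuffles and
#' random baselines are replicate-specific), compute the trajectory and its
#' R50. Reproducible from `seed` via per-replicate substreams.
#'
#' @inheritParams removal_order
#' @inheritParams resistance_ensemble
#' @return An `r50_result` with replicate values, mean and sd.
#' @export
robustness_ensemble <- function(net, model, mode = "averaged", replicates = 100,
                                t_delta = 3, seed = NULL, null = NULL,
                                node_class = "both") {
  null_fun <- resolve_null(null)
  values <- rep(NA_real_, replicates)
  for (i in seq_len(replicates)) {
    sub <- if (is.null(seed)) NULL else substream_seed(seed, "robustness", model, mode, i)
    values[i] <- with_substream(sub, {
      real <- realize_tolerances(net)
      if (!is.null(null_fun)) real <- null_fun(real)
      ord <- removal_order(real, model, mode, t_delta, node_class)
      tryCatch(r50(removal_trajectory(real, ord)),
               coralnet_metric_error = function(e) NA_real_)
    })
  }
  n_failed <- sum(is.na(values))
  if (n_failed > 0) warn(paste0(n_failed, " replicate(s) with undefined R50 excluded"))
  ok <- values[!is.na(values)]
  structure(
    list(values = tibble(replicate = seq_len(replicates), r50 = values),
         mean = mean(ok), sd = if (length(ok) > 1) sd(ok) else 0,
         model = model, mode = if (model == "susceptible_links") mode else NA_character_,
         replicates = replicates, n_failed = n_failed, seed = seed),
    class = "r50_result")
}

#' @export
print.r50_result <- function(x, ...) {
  lbl <- if (!is.na(x$mode)) paste0(x$model, ":", x$mode) else x$model
  cat("<r50_result> ", lbl, ", ", x$replicates, " replicates\n  R50 = ",
      format(round(x$mean, 3), nsmall = 3), " ± ",
      format(round(x$sd, 3), nsmall = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.r50_result <- function(x, ...) x$values

#' @export
glance.r50_result <- function(x, ...) {
  tibble(model = x$model, mode = x$mode, mean = x$mean, sd = x$sd,
         replicates = x$replicates, n_failed = x$n_failed)
}

#' Coral families consistently among the first hosts to bleach
#'
#' Runs the bleaching model over replicates, records each replicate's first
#' `n_first` bleached host nodes (isolation-event order; ties within an
#' event are shuffled), intersects those sets across replicates, and counts
#' the host nodes that are *always* in the earliest-bleached set, by family
#' and subregion.
#'
#' @param net A planned `coral_network` with family labels on hosts.
#' @param replicates Number of simulations (at least 2 for a meaningful
#'   intersection).
#' @param n_first Size of the earliest-bleached set (default 100; networks
#'   with fewer hosts use all hosts, with a warning).
#' @param t_delta Upper thermal limit, degrees C.
#' @param seed Master seed.
#' @return A tibble with `family`, `subregion`, `n_hosts` (counts over the
#'   always-first set), with the host ids in attribute `host_ids`.
#' @export
family_susceptibility <- function(net, replicates = 100, n_first = 100,
                                  t_delta = 3, seed = NULL) {
  if (nrow(net$hosts) < n_first) {
    warn(paste0("network has ", nrow(net$hosts), " hosts (< ", n_first,
                "); using all hosts"))
    n_first <- nrow(net$hosts)
  }
  first_sets <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    sub <- if (is.null(seed)) NULL else substream_seed(seed, "family", i)
    first_sets[[i]] <- with_substream(sub, {
      real <- realize_tolerances(net)
      bt <- host_bleach_temperatures(real, t_delta)
      w <- ifelse(is.na(bt$w_max), -Inf, bt$w_max)  # initially isolated bleach first
      bt$host_id[order(w, runif(length(w)))][seq_len(n_first)]
    })
  }
  always <- Reduce(intersect, first_sets)
  counts <- net$hosts |>
    filter(.data$host_id %in% always) |>
    count(.data$family, .data$subregion, name = "n_hosts") |>
    arrange(desc(.data$n_hosts))
  structure(counts, host_ids = always)
}
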