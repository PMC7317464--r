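# Null-network constructions: physiological controls (tolerance shuffles)
# and structural controls (bipartite rewirings). All operate on a realized
# network and return a realized network, so they compose with the
# per-replicate tolerance redraw inside the ensembles.

#' Shuffled-tolerance null network
#'
#' Permutes the host tolerances among host nodes and the symbiont
#' tolerances among symbiont nodes; structure untouched. The tolerance
#' multisets are preserved exactly (sampling without replacement); set
#' `replace = TRUE` to resample from the empirical distributions with
#' replacement instead. Asks: do the *specific* tolerance-to-node
#' assignments matter, or only their distribution?
#'
#' @param net A realized `coral_network`.
#' @param replace Sample with replacement instead of permuting.
#' @return The null `coral_network`.
#' @export
null_shuffled_tolerance <- function(net, replace = FALSE) {
  check_realized(net)
  hosts <- net$hosts
  symbionts <- net$symbionts
  if (nrow(hosts) > 1 || replace) {
    hosts$tolerance <- sample(hosts$tolerance, nrow(hosts), replace = replace)
  }
  if (nrow(symbionts) > 1 || replace) {
    symbionts$tolerance <- sample(symbionts$tolerance, nrow(symbionts),
                                  replace = replace)
  }
  keep_attrs(new_coral_network(hosts, symbionts, net$edges), net)
}

#' Random-tolerance null network
#'
#' Replaces every node tolerance with an independent Uniform(0, 1) draw;
#' structure and environment untouched. Asks: does the tolerance
#' distribution found in nature affect resistance?
#'
#' @param net A realized `coral_network`.
#' @return The null `coral_network`.
#' @export
null_random_tolerance <- function(net) {
  hosts <- mutate(net$hosts, tolerance = runif(n()))
  symbionts <- mutate(net$symbionts, tolerance = runif(n()))
  keep_attrs(new_coral_network(hosts, symbionts, net$edges), net)
}

#' Degree-conserved random bipartite null network (RBDC)
#'
#' Rewires the links by bipartite double-edge swaps — `(h1-s1, h2-s2)`
#' becomes `(h1-s2, h2-s1)` whenever no duplicate link results — so every
#' node keeps its exact degree while the specific association pattern is
#' randomized. Tolerances are then shuffled (see
#' [null_shuffled_tolerance()]). Asks: do specific interaction patterns
#' affect resistance, beyond the degree distribution?
#'
#' @param net A realized `coral_network`.
#' @param n_swaps Number of attempted swaps; default 10 times the link
#'   count, enough to mix the wiring.
#' @return The null `coral_network`; if no swap is possible (the wiring is
#'   fully constrained, e.g. complete bipartite), the input structure is
#'   returned with a warning.
#' @export
null_rbdc <- function(net, n_swaps = 10 * nrow(net$edges)) {
  check_realized(net)
  l <- nrow(net$edges)
  if (l < 2) return(null_shuffled_tolerance(net))
  ns <- nrow(net$symbionts)
  h <- match(net$edges$host_id, net$hosts$host_id)
  s <- match(net$edges$symbiont_id, net$symbionts$symbiont_id)
  present <- new.env(hash = TRUE, size = 2 * l)
  for (i in seq_len(l)) assign(as.character((h[i] - 1) * ns + s[i]), TRUE, present)
  accepted <- 0L
  pick1 <- sample.int(l, n_swaps, replace = TRUE)
  pick2 <- sample.int(l, n_swaps, replace = TRUE)
  for (t in seq_len(n_swaps)) {
    i <- pick1[t]; j <- pick2[t]
    if (i == j || s[i] == s[j] || h[i] == h[j]) next
    k1 <- as.character((h[i] - 1) * ns + s[j])
    k2 <- as.character((h[j] - 1) * ns + s[i])
    if (exists(k1, present, inherits = FALSE) ||
        exists(k2, present, inherits = FALSE)) next
    rm(list = c(as.character((h[i] - 1) * ns + s[i]),
                as.character((h[j] - 1) * ns + s[j])), envir = present)
    tmp <- s[i]; s[i] <- s[j]; s[j] <- tmp
    assign(k1, TRUE, present); assign(k2, TRUE, present)
    accepted <- accepted + 1L
  }
  if (accepted == 0L) {
    warn("no degree-preserving swap possible; returning the input wiring")
    return(null_shuffled_tolerance(net))
  }
  edges <- tibble(host_id = net$hosts$host_id[h],
                  symbiont_id = net$symbionts$symbiont_id[s]) |>
    arrange(.data$host_id, .data$symbiont_id)
  out <- keep_attrs(new_coral_network(net$hosts, net$symbionts, edges), net)
  attr(out, "n_swaps_accepted") <- accepted
  null_shuffled_tolerance(out)
}

#' Non-degree-conserved random bipartite null network (RBNDC)
#'
#' Replaces the wiring with a uniformly random bipartite graph on the same
#' host nodes, symbiont nodes, and link count (links placed uniformly at
#' random without duplicates), then shuffles tolerances. Host nodes keep
#' their subregion and thermal baseline. Asks: does the heavy-tailed
#' network structure itself affect resistance?
#'
#' @param net A realized `coral_network`.
#' @return The null `coral_network`.
#' @export
null_rbndc <- function(net) {
  check_realized(net)
  nh <- nrow(net$hosts); ns <- nrow(net$symbionts); l <- nrow(net$edges)
  if (l > nh * ns) {
    abort("more links than host x symbiont pairs; no simple bipartite graph exists",
          class = "coralnet_configuration_error")
  }
  cells <- sample.int(nh * ns, l)
  edges <- tibble(host_id = net$hosts$host_id[(cells - 1) %/% ns + 1],
                  symbiont_id = net$symbionts$symbiont_id[(cells - 1) %% ns + 1]) |>
    arrange(.data$host_id, .data$symbiont_id)
  out <- keep_attrs(new_coral_network(net$hosts, net$symbionts, edges), net)
  null_shuffled_tolerance(out)
}

check_realized <- function(net) {
  ok <- "tolerance" %in% names(net$hosts) && !anyNA(net$hosts$tolerance) &&
    "tolerance" %in% names(net$symbionts) && !anyNA(net$symbionts$tolerance)
  if (!ok) {
    abort("null constructions need assigned tolerances; call realize_tolerances()",
          class = "coralnet_configuration_error")
  }
  invisible(net)
}

keep_attrs <- function(new, old) {
  attr(new, "class_model") <- attr(old, "class_model")
  new
}

# map a null name (or function) to a transform net -> net
resolve_null <- function(null) {
  if (is.null(null)) return(NULL)
  if (is.function(null)) return(null)
  switch(match.arg(null, c("shuffled_tolerance", "random_tolerance",
                           "rbdc", "rbndc")),
         shuffled_tolerance = null_shuffled_tolerance,
         random_tolerance = null_random_tolerance,
         rbdc = null_rbdc,
         rbndc = null_rbndc)
}
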