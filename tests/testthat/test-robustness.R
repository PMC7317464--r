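test_that("removal orders honour each attack model's sorting rule", {
  withr::with_seed(31, net <- random_toy_net(6, 4, 12, n_subregions = 1))
  l <- nrow(net$edges)
  # random: a permutation of all links
  ord <- removal_order(net, "random_links")
  expect_equal(nrow(ord), l)
  expect_equal(nrow(dplyr::distinct(ord, host_id, symbiont_id)), l)
  # bleaching: ascending thresholds
  ordb <- removal_order(net, "bleaching")
  lw <- link_weights(net)
  w <- lw$w_c[match(paste(ordb$host_id, ordb$symbiont_id),
                    paste(lw$host_id, lw$symbiont_id))]
  expect_true(all(diff(w) >= -1e-12))
  # susceptible links, host mode: ascending host tolerance, so each host's
  # links are consecutive (up to ties)
  ordh <- removal_order(net, "susceptible_links", mode = "host")
  tol <- net$hosts$tolerance[match(ordh$host_id, net$hosts$host_id)]
  expect_true(all(diff(tol) >= -1e-12))
  # susceptible nodes: pooled ascending tolerance
  ordn <- removal_order(net, "susceptible_nodes")
  nt <- node_tolerances(net)
  expect_true(all(diff(nt$tolerance[match(ordn$node_id, nt$node_id)]) >= -1e-12))
})

test_that("bleaching order equals averaged susceptible order under one T_MMM", {
  withr::with_seed(17, net <- random_toy_net(6, 4, 12, n_subregions = 1))
  # no ties in averaged tolerance with continuous draws: orders identical
  ord1 <- removal_order(net, "bleaching")
  ord2 <- removal_order(net, "susceptible_links", mode = "averaged")
  expect_equal(ord1$host_id, ord2$host_id)
  expect_equal(ord1$symbiont_id, ord2$symbiont_id)
})

test_that("trajectories match hand enumeration on stars", {
  hosts <- sprintf("Coral %02d", 1:10)
  net <- toy_realized(toy_records(hosts, rep("C1", 10)), toy_env(),
                      host_tol = setNames(runif(10), hosts), sym_tol = c(C1 = 0.5))
  # link removal: after k < 10 removals, 11 - k nodes remain; 0 at k = 10
  ord <- removal_order(net, "random_links")
  traj <- removal_trajectory(net, ord)
  expect_equal(traj$n_remaining, c(11, 11 - 1:9, 0))
  expect_equal(r50(traj), 0.6)  # remaining <= 5.5 first at k = 6
  # node removal of the hub: all leaves secondarily isolated at step 1
  ordn <- removal_order(net, "random_nodes")
  hub_first <- dplyr::bind_rows(ordn[ordn$node_id == "C1", ],
                                ordn[ordn$node_id != "C1", ])
  trajn <- removal_trajectory(net, hub_first)
  expect_equal(trajn$n_remaining[2], 0)
  # empty order: flat trajectory
  empty_ord <- ord[0, ]
  trem <- removal_trajectory(net, empty_ord)
  expect_equal(nrow(trem), 1)
  expect_equal(trem$frac_remaining, 1)
})

test_that("a perfect matching under link removal has R50 exactly one half", {
  n <- 8
  hosts <- sprintf("Coral %02d", 1:n)
  syms <- sprintf("C%d", 1:n)
  net <- toy_realized(toy_records(hosts, syms), toy_env(),
                      host_tol = setNames(runif(n), hosts),
                      sym_tol = setNames(runif(n), syms))
  for (i in 1:5) {
    traj <- removal_trajectory(net, removal_order(net, "random_links"))
    expect_equal(r50(traj), 0.5)  # every removal isolates exactly 2 of 2n nodes
  }
})

test_that("ensemble R50 matches the exhaustive permutation oracle", {
  withr::with_seed(23, net <- random_toy_net(4, 3, 6, n_subregions = 1))
  exact <- exhaustive_mean_r50(net)
  ens <- robustness_ensemble(net, "random_links", replicates = 400, seed = 12)
  # Monte-Carlo error at 400 replicates
  expect_lt(abs(ens$mean - exact), 3 * ens$sd / sqrt(400) + 0.02)
})

test_that("order integrity is enforced", {
  net <- random_toy_net(5, 3, 8)
  ord <- removal_order(net, "random_links")
  expect_error(removal_trajectory(net, ord[-1, ]),
               class = "coralnet_integrity_error")
  ordn <- removal_order(net, "random_nodes")
  ordn$node_id[1] <- "ghost"
  expect_error(removal_trajectory(net, ordn),
               class = "coralnet_integrity_error")
})

test_that("deterministic attacks have zero spread, seeded runs reproduce", {
  # a perfect matching: every host has one link, so the host-susceptibility
  # order has no ties and the attack is fully deterministic
  bm <- synth_bundle("single-subregion", seed = 3, n_hosts = 24, n_symbionts = 24,
                     n_links = 24, unlisted_host_frac = 0, unlisted_sym_frac = 0)
  r <- robustness_ensemble(bundle_network(bm), "susceptible_links",
                           mode = "host", replicates = 6, seed = 2)
  expect_equal(r$sd, 0)
  b <- synth_bundle("single-subregion", seed = 3, n_hosts = 30, n_symbionts = 15,
                    n_links = 70, unlisted_host_frac = 0, unlisted_sym_frac = 0)
  plan <- bundle_network(b)
  r1 <- robustness_ensemble(plan, "random_links", replicates = 8, seed = 5)
  r2 <- robustness_ensemble(plan, "random_links", replicates = 8, seed = 5)
  expect_identical(r1$values, r2$values)
})

test_that("family susceptibility intersects the earliest-bleached sets", {
  # family Alpha holds the lowest-threshold single-link hosts in every
  # replicate (measured tolerances only -> deterministic thresholds)
  hosts <- sprintf("Coral %02d", 1:12)
  fams <- rep(c("Alpha", "Beta"), each = 6)
  rec <- toy_records(hosts, rep(c("C1", "C2"), each = 6), family = fams)
  net <- toy_realized(rec, toy_env(),
                      host_tol = setNames(c(rep(0.1, 6), rep(0.9, 6)), hosts),
                      sym_tol = c(C1 = 0.1, C2 = 0.9))
  expect_warning(
    fam <- family_susceptibility(net, replicates = 3, n_first = 6, seed = 1),
    NA)
  expect_equal(fam$family, "Alpha")
  expect_equal(fam$n_hosts, 6)
  # single replicate: the intersection is that replicate's own first set
  fam1 <- family_susceptibility(net, replicates = 1, n_first = 6, seed = 1)
  expect_equal(sum(fam1$n_hosts), 6)
})

test_that("fewer hosts than the first-bleached window warns and uses all hosts", {
  net <- random_toy_net(5, 3, 8)
  expect_warning(family_susceptibility(net, replicates = 2, n_first = 100, seed = 1),
                 "using all hosts")
})
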