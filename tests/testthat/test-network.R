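test_that("record filtering deduplicates triples but keeps geographic duplicates", {
  rec <- toy_records(
    hosts = c("Coral a", "Coral a", "Coral a", "Coral b"),
    symbionts = c("C1", "C1", "C1", "C2"),
    subregion = c("Reef A", "Reef A", "Reef B", "Nowhere"))
  out <- filter_records(rec, known_subregions = c("Reef A", "Reef B"))
  # identical (species, subregion, symbiont) collapsed; Reef B copy kept;
  # unknown-subregion record dropped
  expect_equal(nrow(out), 2)
  expect_setequal(out$subregion, c("Reef A", "Reef B"))
  # idempotent
  expect_identical(filter_records(out, known_subregions = c("Reef A", "Reef B")), out)
})

test_that("filtering enforces the in-situ and scleractinian flags", {
  rec <- toy_records(c("Coral a", "Coral b", "Coral c"), c("C1", "C1", "C1"))
  rec$in_situ <- c(TRUE, FALSE, TRUE)
  rec$scleractinian <- c(TRUE, TRUE, FALSE)
  out <- filter_records(rec, known_subregions = "Reef A")
  expect_equal(out$host_species, "Coral a")
  # rules can be relaxed individually
  out2 <- filter_records(rec, require_in_situ = FALSE,
                         require_scleractinian = FALSE,
                         known_subregions = "Reef A")
  expect_equal(nrow(out2), 3)
})

test_that("missing required columns raise a schema error naming the column", {
  expect_error(filter_records(tibble::tibble(host_species = "x", subregion = "y",
                                             region = "z")),
               "symbiont_type", class = "coralnet_schema_error")
})

test_that("network construction follows the geographically-distinct host rule", {
  env <- toy_env(c("Reef A", "Reef B"))
  # one record -> 2 nodes, 1 link
  net1 <- build_network(toy_records("Coral x", "C1"), env = env)
  expect_equal(network_summary(net1)$n_nodes, 2)
  expect_equal(network_summary(net1)$n_links, 1)
  # species X in two subregions with one symbiont -> 3 nodes, 2 links
  net2 <- build_network(toy_records(c("Coral x", "Coral x"), c("C1", "C1"),
                                    subregion = c("Reef A", "Reef B")), env = env)
  s <- network_summary(net2)
  expect_equal(s$n_hosts, 2)
  expect_equal(s$n_symbionts, 1)
  expect_equal(s$n_links, 2)
  expect_equal(s$n_species, 1)
  # hosts carry their subregion's T_MMM
  expect_equal(net2$hosts$t_mmm_c, c(29, 29))
})

test_that("an unknown subregion is an environment-lookup error", {
  expect_error(build_network(toy_records("Coral x", "C1", subregion = "Atlantis"),
                             env = toy_env("Reef A")),
               "Atlantis", class = "coralnet_environment_error")
})

test_that("rebuilding a network from its exported edge list is the identity", {
  net <- random_toy_net(8, 5, 14, n_subregions = 2)
  env <- dplyr::distinct(net$hosts, subregion, region, t_mmm_c)
  net2 <- build_network(edges_table(net), env = env)
  expect_equal(net2$edges, net$edges)
  expect_equal(net2$hosts$host_id, net$hosts$host_id)
  expect_equal(net2$symbionts$symbiont_id, net$symbionts$symbiont_id)
})

test_that("node order is deterministic regardless of record order", {
  rec <- toy_records(c("Coral c", "Coral a", "Coral b"), c("C2", "C9", "C1"))
  net_a <- build_network(rec, env = toy_env())
  net_b <- build_network(rec[3:1, ], env = toy_env())
  expect_identical(net_a$hosts, net_b$hosts)
  expect_identical(net_a$edges, net_b$edges)
})

test_that("host and symbiont degrees both sum to the link count", {
  for (i in 1:5) {
    net <- random_toy_net(n_hosts = 5 + i, n_symbionts = 3 + i, n_links = 8 + 2 * i)
    deg <- degree_sequence(net)
    l <- nrow(net$edges)
    expect_equal(sum(deg$degree[deg$class == "host"]), l)
    expect_equal(sum(deg$degree[deg$class == "symbiont"]), l)
  }
})

test_that("subsetting by region equals the union of its subregions", {
  env <- toy_env(c("Reef A", "Reef B", "Reef C"),
                 regions = c("Region X", "Region X", "Region Y"))
  rec <- toy_records(sprintf("Coral %d", c(1, 2, 3, 1, 4)),
                     c("C1", "C1", "C2", "C2", "C3"),
                     subregion = c("Reef A", "Reef A", "Reef B", "Reef B", "Reef C"),
                     region = c("Region X", "Region X", "Region X", "Region X", "Region Y"))
  net <- build_network(rec, env = env)
  by_region <- subset_network(net, "Region X")
  merged_hosts <- sort(c(subset_network(net, "Reef A")$hosts$host_id,
                         subset_network(net, "Reef B")$hosts$host_id))
  expect_equal(by_region$hosts$host_id, merged_hosts)
  merged_edges <- dplyr::bind_rows(subset_network(net, "Reef A")$edges,
                                   subset_network(net, "Reef B")$edges) |>
    dplyr::arrange(host_id, symbiont_id)
  expect_equal(by_region$edges, merged_edges)
  # symbionts restricted to those with links in scope
  expect_setequal(subset_network(net, "Reef C")$symbionts$symbiont_id, "C3")
  # degenerate subset: no error, empty network
  empty <- subset_network(net, "Caribbean Sea")
  expect_equal(network_summary(empty)$n_nodes, 0)
  # unknown label errors
  expect_error(subset_network(net, "Middle Earth"), class = "coralnet_scope_error")
})

test_that("structural summary matches hand computations", {
  # star: 1 symbiont, 5 hosts
  star <- build_network(toy_records(sprintf("Coral %d", 1:5), rep("C1", 5)),
                        env = toy_env())
  s <- network_summary(star)
  expect_equal(s$n_nodes, 6)
  expect_equal(s$n_links, 5)
  expect_equal(s$mean_degree, 5 / 3)
  expect_equal(s$connectance_bipartite, 1)    # 5 / (5 x 1)
  expect_equal(s$connectance_printed, 5 / 36)
  # single link: both connectances well defined
  one <- build_network(toy_records("Coral 1", "C1"), env = toy_env())
  expect_equal(network_summary(one)$connectance_bipartite, 1)
})

test_that("validation rejects corrupted networks", {
  net <- random_toy_net()
  expect_silent(validate_network(net))
  bad <- net
  bad$edges$host_id[1] <- "not a node"
  expect_error(validate_network(bad), class = "coralnet_integrity_error")
  bad2 <- net
  bad2$edges <- dplyr::bind_rows(bad2$edges, bad2$edges[1, ])
  expect_error(validate_network(bad2), class = "coralnet_integrity_error")
})

test_that("round-trips through disk formats preserve the network", {
  net <- random_toy_net(6, 4, 9)
  csv <- tempfile(fileext = ".csv")
  gml <- tempfile(fileext = ".graphml")
  write_network(net, csv, gml)
  env <- dplyr::distinct(net$hosts, subregion, region, t_mmm_c)
  back <- build_network(read_associations(csv), env = env)
  expect_equal(back$edges, net$edges)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_true(igraph::is_bipartite(g))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
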