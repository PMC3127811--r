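test_that("network construction induces, dedups, and filters links", {
  rec <- tiny_records(c("A", "B", "C"), c("up", "down", "unchanged"))
  links <- dplyr::bind_rows(
    tiny_links("A", "B", confidence = 0.4),
    tiny_links("B", "A", confidence = 0.9, channel = "physical"),
    tiny_links("B", "C", confidence = 0.2)
  )
  net <- build_network(c("A", "B", "C"), links, rec)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  ab <- net$edges[net$edges$protein_a == "A" & net$edges$protein_b == "B", ]
  expect_equal(ab$confidence, 0.9)
  expect_equal(ab$channel, "physical")

  # score_min and non-reliable endpoints drop rows
  expect_message(net2 <- build_network(c("A", "B"), links, rec,
                                       score_min = 0.5), "Dropping 2")
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(glance(net2)$n_edges, 1L)
})

test_that("largest component extraction and its tie-break are correct", {
  rec <- tiny_records(c("A", "B", "C", "D"), rep("unchanged", 4))
  net <- suppressMessages(build_network(
    c("A", "B", "C", "D"), tiny_links(c("A", "B"), c("B", "C")), rec))
  lc <- largest_component(net)
  expect_setequal(lc$network$nodes$protein_id, c("A", "B", "C"))
  expect_equal(lc$excluded, "D")
  expect_equal(nrow(lc$network$nodes) + length(lc$excluded), 4L)

  # fully connected graph excludes nothing
  full <- suppressMessages(build_network(
    c("A", "B", "C"), tiny_links(c("A", "B", "A"), c("B", "C", "C")), rec[1:3, ]))
  expect_equal(largest_component(full)$excluded, character())

  # equal-size components: keep the one with the smallest member id
  two <- suppressMessages(build_network(
    c("A", "B", "C", "D"), tiny_links(c("C", "A"), c("D", "B")), rec))
  expect_setequal(largest_component(two)$network$nodes$protein_id, c("A", "B"))
})

test_that("link categories and the regulatory percentage are computed", {
  rec <- tiny_records(c("u1", "u2", "d1", "n1"),
                      c("up", "up", "down", "unchanged"))
  net <- suppressMessages(build_network(
    rec$protein_id,
    tiny_links(c("u1", "u1", "u1"), c("u2", "d1", "n1")), rec))
  out <- categorize_links(net)
  cats <- setNames(as.character(out$edges$category),
                   paste(out$edges$protein_a, out$edges$protein_b))
  expect_equal(unname(cats[c("u1 u2", "d1 u1", "n1 u1")]),
               c("intra", "inter", "other"))
  expect_equal(out$summary$n_total, 3L)
  expect_equal(out$summary$pct_intra_of_regulatory, 50)

  # degenerate: only unchanged nodes -> percentage reported absent
  nn <- tiny_records(c("x", "y"), c("unchanged", "unchanged"))
  net0 <- suppressMessages(build_network(c("x", "y"),
                                         tiny_links("x", "y"), nn))
  expect_true(is.na(categorize_links(net0)$summary$pct_intra_of_regulatory))
})

test_that("per-protein link fractions use regulatory edges as denominator", {
  rec <- tiny_records(c("u1", "u2", "u3", "d1", "n1"),
                      c("up", "up", "up", "down", "unchanged"))
  net <- suppressMessages(build_network(
    rec$protein_id,
    tiny_links(c("u1", "u1", "u1", "n1"), c("u2", "u3", "d1", "u2")), rec))
  fr <- link_fraction_samples(net)
  u1 <- fr[fr$protein_id == "u1", ]
  expect_equal(u1$frac_intra, 2 / 3)
  expect_equal(u1$frac_inter, 1 / 3)
  expect_equal(fr$frac_intra + fr$frac_inter, rep(1, nrow(fr)))
  # a node with only other-category edges is excluded
  only_other <- suppressMessages(build_network(
    c("u1", "n1"), tiny_links("u1", "n1"),
    tiny_records(c("u1", "n1"), c("up", "unchanged"))))
  expect_equal(nrow(link_fraction_samples(only_other)), 0L)
})

test_that("path samples bin pairs by class and match hand BFS", {
  rec <- tiny_records(c("uA", "nB", "uC"), c("up", "unchanged", "up"))
  net <- suppressMessages(build_network(
    rec$protein_id, tiny_links(c("uA", "nB"), c("nB", "uC")), rec))
  ps <- shortest_path_samples(net)
  expect_equal(ps$same_class, 2L)  # uA -(nB)- uC
  expect_equal(length(ps$opposite_class), 0L)

  tri <- tiny_records(c("a", "b", "c"), rep("up", 3))
  net3 <- suppressMessages(build_network(
    tri$protein_id, tiny_links(c("a", "b", "a"), c("b", "c", "c")), tri))
  expect_equal(shortest_path_samples(net3)$same_class, rep(1L, 3))

  no_pairs <- suppressMessages(build_network(
    c("x", "y"), tiny_links("x", "y"),
    tiny_records(c("x", "y"), c("unchanged", "unchanged"))))
  expect_error(shortest_path_samples(no_pairs), "regulated")
})

test_that("BFS distances equal the Floyd-Warshall oracle on random graphs", {
  set.seed(23)
  for (rep in 1:40) {
    net <- random_net(n_nodes = sample(4:10, 1), p_edge = runif(1, 0.2, 0.7))
    ids <- net$nodes$protein_id
    d_oracle <- fw_distances(ids, net$edges$protein_a, net$edges$protein_b)
    g <- igraph::graph_from_data_frame(
      net$edges[, 1:2], directed = FALSE, vertices = data.frame(name = ids))
    d_pkg <- igraph::distances(g)[ids, ids]
    expect_equal(unname(d_pkg), unname(d_oracle))
    # symmetry and triangle inequality on the finite part
    expect_equal(d_pkg, t(d_pkg))
    fin <- is.finite(d_pkg)
    for (k in seq_along(ids)) {
      lhs <- d_pkg
      rhs <- outer(d_pkg[, k], d_pkg[k, ], "+")
      expect_true(all(lhs[fin & is.finite(rhs)] <=
                        rhs[fin & is.finite(rhs)] + 1e-9))
    }

    # the sample multisets agree with the oracle's class binning
    reg <- setNames(as.character(net$nodes$regulation), ids)
    if (sum(reg != "unchanged") >= 2) {
      ps <- shortest_path_samples(net)
      same <- c(); opp <- c()
      regulated <- ids[reg != "unchanged"]
      for (i in seq_along(regulated)) for (j in seq_along(regulated)) {
        if (j <= i) next
        d <- d_oracle[regulated[i], regulated[j]]
        if (!is.finite(d)) next
        if (reg[regulated[i]] == reg[regulated[j]]) same <- c(same, d)
        else opp <- c(opp, d)
      }
      expect_equal(sort(ps$same_class), sort(as.integer(same)))
      expect_equal(sort(ps$opposite_class), sort(as.integer(opp)))
    }
  }
})

test_that("regulatory-subgraph path variant restricts to category edges", {
  rec <- tiny_records(c("u1", "u2", "n1"), c("up", "up", "unchanged"))
  # u1-u2 only via the unchanged node: connected in 'all', not in subgraph
  net <- suppressMessages(build_network(
    rec$protein_id, tiny_links(c("u1", "n1"), c("n1", "u2")), rec))
  expect_equal(shortest_path_samples(net, "all")$same_class, 2L)
  expect_equal(length(shortest_path_samples(net, "regulatory_subgraph")$same_class),
               0L)
})
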