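test_that("similarity matrix mirrors edges with the absence-is-zero rule", {
  rec <- tiny_records(c("A", "B", "C"), rep("up", 3))
  net <- suppressMessages(build_network(
    c("A", "B", "C"), tiny_links("A", "B", confidence = 0.8), rec))
  s <- similarity_from_network(net)
  expect_equal(s["A", "B"], 0.8)
  expect_equal(s["A", "C"], 0)
  expect_equal(diag(s), c(A = 1, B = 1, C = 1))

  set.seed(41)
  for (rep in 1:10) {
    net <- random_net()
    s <- similarity_from_network(net)
    expect_equal(s, t(s))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("UPGMA merges by best average similarity and stops at tau", {
  s <- matrix(c(1, .9, .1,
                .9, 1, .1,
                .1, .1, 1), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cs <- upgma_cluster(s, tau = 0.5, min_size = 2L)
  expect_equal(cs$clusters, list(M1 = c("A", "B")))
  expect_equal(cs$unassigned, "C")
  expect_equal(cs$merges$height, 0.9)

  # tau above every off-diagonal similarity: nothing merges
  none <- upgma_cluster(s * 0.5 + diag(3) * 0.5, tau = 1.0, min_size = 2L)
  expect_equal(length(none$clusters), 0L)
  expect_setequal(none$unassigned, c("A", "B", "C"))

  expect_error(upgma_cluster(s, tau = 0), "tau")
  expect_error(upgma_cluster(s, tau = 0.5, min_size = 1L), "min_size")
  expect_error(upgma_cluster(s + 0.01, tau = 0.5), "symmetric|\\[0,1\\]")
})

test_that("UPGMA agrees with the naive reference and with hclust", {
  set.seed(42)
  for (rep in 1:25) {
    s <- random_sim(6)
    tau <- runif(1, 0.2, 0.8)
    got <- upgma_cluster(s, tau = tau, min_size = 2L)
    ref <- naive_upgma(s, tau)
    got_groups <- c(got$clusters, as.list(got$unassigned))
    expect_equal(partition_key(got_groups), partition_key(ref$groups))
    expect_equal(got$merges$height, ref$heights)
    # merge heights are non-increasing (average-linkage monotonicity)
    expect_true(all(diff(got$merges$height) <= 1e-9))

    # independent route: average linkage on 1 - similarity, cut at 1 - tau
    hc <- stats::hclust(stats::as.dist(1 - s), method = "average")
    memb <- stats::cutree(hc, h = 1 - tau)
    hc_groups <- split(names(memb), memb)
    expect_equal(partition_key(got_groups), partition_key(hc_groups))
  }
})

test_that("hypergeometric tail matches enumeration and handles edge cases", {
  expect_equal(hypergeometric_tail(2, 4, 3, 10), hyper_tail_enum(2, 4, 3, 10))
  expect_equal(hypergeometric_tail(2, 4, 3, 10), 1 / 3)
  expect_equal(hypergeometric_tail(0, 4, 3, 10), 1)
  expect_equal(hypergeometric_tail(5, 5, 5, 5), 1)
  expect_error(hypergeometric_tail(4, 2, 3, 10), "Inconsistent")
  expect_error(hypergeometric_tail(2, 4, 11, 10), "Inconsistent")
})

test_that("term enrichment computes the documented tail probabilities", {
  cluster <- sprintf("c%02d", 1:5)
  background <- c(cluster, sprintf("b%02d", 1:95))
  ann <- dplyr::bind_rows(
    tibble::tibble(protein_id = c(cluster, sprintf("b%02d", 1:5)),
                   term_id = "T"),
    tibble::tibble(protein_id = background, term_id = "ALL")
  )
  res <- term_enrichment(cluster, ann, background)
  t_row <- res[res$term_id == "T", ]
  expect_equal(t_row$p_value, choose(10, 5) / choose(100, 5))
  # a term annotating everything is not enriched
  expect_equal(res$p_value[res$term_id == "ALL"], 1)
  expect_equal(res$term_id[1L], "T")  # representative = smallest p

  # cluster without annotated members -> empty result
  expect_equal(nrow(term_enrichment(c("zz1", "zz2"), ann, background)), 0L)
})

test_that("term enrichment is calibrated under random annotation", {
  set.seed(43)
  background <- sprintf("g%03d", 1:60)
  cluster <- background[1:12]
  hits <- 0L
  n_sim <- 3000L
  for (i in seq_len(n_sim)) {
    ann <- tibble::tibble(protein_id = background, term_id = "ALL")
    carriers <- sample(background, 15)
    ann <- dplyr::bind_rows(ann, tibble::tibble(protein_id = carriers,
                                                term_id = "T"))
    res <- term_enrichment(cluster, ann, background, min_annotated = 0L)
    p <- res$p_value[res$term_id == "T"]
    if (length(p) == 1L && p < 0.01) hits <- hits + 1L
  }
  # discrete test: type-I rate is bounded by alpha and not far below it
  expect_lt(hits / n_sim, 0.015)
})

test_that("regulation enrichment labels clusters and respects alpha", {
  ids <- c(sprintf("u%02d", 1:20), sprintf("d%02d", 1:20))
  rec <- tiny_records(ids, rep(c("up", "down"), each = 20))
  # all-up cluster of 8 against a half-up background
  res <- regulation_enrichment(sprintf("u%02d", 1:8), rec, ids)
  expect_equal(res$label, "up")
  expect_lt(res$p_value, 0.01)
  # mirroring the background composition: no label
  mix <- regulation_enrichment(c("u01", "u02", "d01", "d02"), rec, ids)
  expect_true(is.na(mix$label))
  # symmetric cluster in a symmetric background: equal p both ways, tie
  # broken toward the larger member count (here equal, so 'up')
  expect_message(
    tie <- regulation_enrichment(c("u01", "u02", "d01", "d02"),
                                 rec, ids, alpha = 1),
    "Equal enrichment"
  )
  expect_equal(tie$label, "up")
})

test_that("module assembly requires both enrichments and reports coverage", {
  up_ids <- sprintf("u%02d", 1:20)
  down_ids <- sprintf("d%02d", 1:20)
  unch <- sprintf("n%02d", 1:20)
  rec <- tiny_records(c(up_ids, down_ids, unch),
                      rep(c("up", "down", "unchanged"), each = 20))
  cs <- cluster_set(list(A = up_ids[1:10], B = c(down_ids[1:9], up_ids[11])),
                    unassigned = c(up_ids[12:20], down_ids[10:20], unch))
  ann <- dplyr::bind_rows(
    tibble::tibble(protein_id = c(up_ids, down_ids, unch), term_id = "ALL"),
    tibble::tibble(protein_id = up_ids[1:10], term_id = "TA"),
    tibble::tibble(protein_id = c(down_ids[1:9], up_ids[11]), term_id = "TB")
  )
  ms <- assemble_modules(cs, ann, rec)
  expect_equal(nrow(ms$modules), 2L)
  expect_equal(ms$modules$regulation_label[ms$modules$module_id == "A"], "up")
  b <- ms$modules[ms$modules$module_id == "B", ]
  expect_equal(b$regulation_label, "down")
  expect_equal(b$n_opposing, 1L)
  cov <- ms$coverage
  expect_equal(cov$pct[cov$class == "up"], 50)          # 10 of 20
  expect_equal(cov$pct[cov$class == "down"], 45)        # 9 of 20
  expect_equal(glance(ms)$n_modules, 2L)

  # clusters failing term enrichment yield no modules
  ms0 <- assemble_modules(cs, tibble::tibble(protein_id = c(up_ids, down_ids,
                                                            unch),
                                             term_id = "ALL"), rec)
  expect_equal(nrow(ms0$modules), 0L)
})
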