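test_that("the published over-connectivity table is reproduced at printed precision", {
  bench <- overconnectivity_benchmark()
  st <- with(bench, {
    E <- n * R / N
    sd <- sqrt(n * (R / N) * (1 - R / N) * (N - n) / (N - 1))
    list(E = E, z = (A - E) / sd, ratio = A / E,
         p = stats::phyper(A - 1, R, N - R, n, lower.tail = FALSE))
  })
  # printed values truncate in places: allow one unit in the last digit
  expect_true(all(abs(st$E - bench$E) <= 0.001 + 1e-9))
  expect_true(all(abs(st$ratio - bench$ratio) <= 0.1 + 1e-9))
  expect_true(all(abs(st$z - bench$z) <= 0.1 + 1e-9))
  expect_true(all(abs(st$p - bench$p) <= bench$p_tol + 1e-18))
})

test_that("connectivity statistics equal the enumeration oracle", {
  # toy: N=10, n=5, R=2, A=1 -> E=1, z=0, upper-tail p = 1 - C(8,5)/C(10,5)
  st <- degnet:::hypergeom_connectivity(1, 5, 2, 10)
  expect_equal(st$E, 1)
  expect_equal(st$z, 0)
  expect_equal(st$p, 1 - choose(8, 5) / choose(10, 5))
  expect_equal(st$p, enum_upper_tail(1, 2, 10, 5))

  set.seed(2)
  for (rep in 1:40) {
    N <- sample(10:500, 1); n <- sample.int(N, 1); R <- sample.int(N, 1)
    A <- sample.int(min(n, R), 1)
    st <- degnet:::hypergeom_connectivity(A, n, R, N)
    oracle <- if (st$z >= 0) enum_upper_tail(A, R, N, n)
              else enum_lower_tail(A, R, N, n)
    expect_equal(st$p, oracle, tolerance = 1e-12)
    expect_equal(st$E, n * R / N)
  }
})

test_that("connectivity_from_counts is vectorized and validates inputs", {
  # a vector A with scalar n, R, N must give element-wise results
  A <- 0:10
  v <- connectivity_from_counts(A, 30, 14, 500)
  expect_length(v$p, 11L)
  for (i in seq_along(A)) {
    s <- connectivity_from_counts(A[i], 30, 14, 500)
    expect_equal(v$p[i], s$p)
    expect_equal(v$z[i], s$z)
  }
  expect_error(connectivity_from_counts(5, 4, 10, 100), "counts")
  expect_error(connectivity_from_counts(2, 4, 1, 100), "counts")
})

test_that("p is monotone in A and z antisymmetric about E", {
  n <- 50; R <- 30; N <- 400
  p <- vapply(0:30, function(A)
    degnet:::hypergeom_connectivity(A, n, R, N)$p, numeric(1))
  up <- vapply(0:30, function(A)
    stats::phyper(A - 1, R, N - R, n, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(up) <= 1e-12))
  E <- n * R / N
  z1 <- degnet:::hypergeom_connectivity(E + 2, n, R, N)$z
  z2 <- degnet:::hypergeom_connectivity(E - 2, n, R, N)$z
  expect_equal(z1, -z2)
})

test_that("gene-to-object mapping collapses shared objects and reports unmapped", {
  nw <- make_network(cbind(c("MxA", "STAT1"), c("STAT1", "IRF9")),
                     gene_to_object = c(MX1 = "MxA", MX2 = "MxA",
                                        STAT1 = "STAT1"))
  objs <- suppressMessages(map_genes_to_objects(c("MX1", "MX2", "STAT1",
                                                  "NOPE"), nw))
  expect_setequal(as.character(objs), c("MxA", "STAT1"))
  expect_identical(attr(objs, "unmapped"), "NOPE")
  expect_length(suppressMessages(map_genes_to_objects(character(0), nw)), 0)
})

test_that("connectivity_stats counts distinct neighbors and excludes self", {
  # star: center C with leaves L1..L4; dataset = {C, L1, L2}
  nw <- make_network(cbind("C", paste0("L", 1:4)))
  st <- connectivity_stats("C", c("C", "L1", "L2"), nw)
  expect_identical(st$A, 2L)        # C itself never counts
  expect_identical(st$R, 4L)
  expect_identical(st$n, 3L)
  expect_identical(st$N, 5L)
  # isolated object flagged rather than given an infinite z
  nw2 <- make_network(cbind("A", "B"), objects = c("A", "B", "ISO"))
  st2 <- connectivity_stats("ISO", "A", nw2)
  expect_identical(st2$direction, "isolated")
  expect_true(is.na(st2$z))
})

test_that("over-connected set recovers planted hubs and respects alpha", {
  cfg <- small_sim_config(seed = 7)
  st <- simulate_study(cfg)
  rec <- collapse_probes(select_degs(test_differential(st$expression)),
                         st$annotation)
  objs <- suppressMessages(map_genes_to_objects(rec$gene_symbol,
                                                st$network))
  over <- overconnected_set(objs, st$network)
  expect_true(all(st$truth$hub_objects %in% over$object_id))
  # planted hubs carry the top z-scores
  top_z <- over$object_id[order(-over$z)][seq_along(st$truth$hub_objects)]
  expect_gte(length(intersect(top_z, st$truth$hub_objects)),
             length(st$truth$hub_objects) - 1)
  expect_identical(nrow(overconnected_set(objs, st$network, alpha = 0)), 0L)
  expect_true(all(over$direction == "over"))
  expect_true(!is.unsorted(over$p_value))
})

test_that("over-connectivity false-positive rate is calibrated under a null", {
  # random datasets on an unplanted network: empirical P(p < alpha) must
  # match the analytic rejection probability of the discrete test and
  # stay below alpha
  cfg <- small_sim_config(seed = 40, n_hub_plants = 0, network_nodes = 300)
  ex <- simulate_expression(cfg)
  nw <- simulate_network(cfg, ex$truth)$network
  adj <- degnet:::undirected_neighbors(nw)
  alpha <- 0.05
  set.seed(77)
  n_ds <- 40; n_rep <- 30
  # candidates within one dataset draw are correlated, so the tolerance
  # uses the empirical between-replicate standard error
  rates <- vapply(seq_len(n_rep), function(rep) {
    ds <- sample(nw$objects, n_ds)
    scored <- connectivity_table(ds, nw, alpha = alpha)
    scored <- scored[scored$direction != "isolated", ]
    mean(scored$p_value < alpha)
  }, numeric(1))
  # analytic expected rejection rate for the same candidates (one dataset
  # draw is exchangeable with any other)
  Rs <- lengths(adj)[lengths(adj) > 0]
  exp_rate <- mean(vapply(Rs, function(R) {
    A <- 0:min(n_ds, R)
    pr <- stats::dhyper(A, R, nw$N - R, n_ds)
    st <- degnet:::hypergeom_connectivity(A, n_ds, R, nw$N)
    sum(pr[st$p < alpha])
  }, numeric(1)))
  se_rep <- stats::sd(rates) / sqrt(n_rep)
  expect_lt(abs(mean(rates) - exp_rate), 5 * se_rep + 1e-3)
  expect_lt(mean(rates), alpha + 5 * se_rep + 1e-3)
})

test_that("over-connected pairings enumerate correctly", {
  # triangle of over-connected nodes: 3 pairs, each node in 2
  tri <- make_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  pr <- overconnected_pairs(c("a", "b", "c"), tri)
  expect_identical(nrow(pr$pairs), 3L)
  expect_true(all(pr$counts == 2))

  # planted 4-clique: top pairing count is 3
  cl <- t(combn(c("h1", "h2", "h3", "h4"), 2))
  nw <- make_network(rbind(cl, cbind("h1", "x")))
  pr2 <- overconnected_pairs(c("h1", "h2", "h3", "h4"), nw)
  expect_identical(unname(pr2$counts[1]), 3L)

  # isolated over-set: no pairs
  iso <- make_network(cbind("a", "b"), objects = c("a", "b", "u", "v"))
  pr3 <- overconnected_pairs(c("u", "v"), iso)
  expect_identical(nrow(pr3$pairs), 0L)
})

test_that("regulator ranking surfaces hidden TFs and signs deficits", {
  uni <- sprintf("g%02d", 1:60)
  degs <- uni[1:12]
  tfs <- list(perfect = degs,                    # targets exactly the DEGs
              same_R = c(degs[1:6], uni[40:45]),
              avoid = uni[30:55])                # no DEG targets, large R
  r <- regulator_enrichment(tfs, degs, uni)
  expect_identical(r$tf[1], "perfect")
  expect_lt(r$z[r$tf == "avoid"], 0)
  expect_identical(r$direction[r$tf == "avoid"], "under")
  expect_warning(regulator_enrichment(list(empty = character(0)), degs,
                                      uni), "skipped")

  # planted regulator among simulated decoys ranks top-3
  set.seed(5)
  decoys <- lapply(1:50, function(i) sample(uni, 10))
  names(decoys) <- sprintf("TF%02d", 1:50)
  decoys$planted <- c(degs[1:7], sample(setdiff(uni, degs), 3))
  rr <- regulator_enrichment(decoys, degs, uni)
  expect_lte(which(rr$tf == "planted"), 3)
})

test_that("topology summary matches hand counts and a brute-force CC oracle", {
  # star center in the dataset, leaves outside
  star <- make_network(cbind("C", paste0("L", 1:5)))
  ts <- topology_summary("C", star)
  d <- ts$degrees
  expect_identical(d$in_dataset + d$out_dataset, 0L)
  expect_identical(d$in_background + d$out_background, 5L)

  # triangle wholly inside the dataset: clustering coefficient 1
  tri <- make_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(topology_summary(c("a", "b", "c"), tri)$clustering_dataset, 1)

  # random graph: mean local CC equals direct enumeration
  set.seed(31)
  g <- igraph::sample_gnp(30, 0.2)
  igraph::V(g)$name <- sprintf("N%02d", 1:30)
  ed <- igraph::as_data_frame(g)
  nw <- make_network(cbind(ed$from, ed$to))
  cc_pkg <- topology_summary(character(0), nw)$clustering_background
  amat <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  cc_hand <- vapply(1:30, function(i) {
    nb <- which(amat[i, ] > 0)
    if (length(nb) < 2) return(NA_real_)
    links <- sum(amat[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
  expect_equal(cc_pkg, mean(cc_hand, na.rm = TRUE))
})
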