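test_that("order_genome masks duplicate probes and sorts by start", {
  ann <- make_ann(c("p1", "p2", "p3", "p4"),
                  c("gB", "gA", "gB", "gC"),
                  start = c(5000, 1000, 4000, 3000))
  ord <- order_genome(ann)
  expect_identical(ord$gene_symbol, c("gA", "gC", "gB"))
  expect_identical(nrow(ord), 3L)            # duplicate gB probe masked
  expect_identical(ord$index, 1:3)

  # gene annotated on two chromosomes: first locus kept, with a warning
  ann2 <- make_ann(c("p1", "p2"), c("gA", "gA"),
                   chromosome = c("chr1", "chr2"))
  expect_warning(ord2 <- order_genome(ann2), "multiple chromosomes")
  expect_identical(ord2$chromosome, "chr1")

  # unannotated probes disappear; an empty chromosome is absent
  ann3 <- make_ann(c("p1", "p2"), c("gA", NA))
  ann3$chromosome[2] <- NA; ann3$start[2] <- NA; ann3$end[2] <- NA
  expect_identical(nrow(order_genome(ann3)), 1L)
})

test_that("the adjacent-DEG toy gives the exact scan p-value 1/1140", {
  ord <- make_ordered(20)
  degs <- ord$gene_symbol[8:10]       # 3 adjacent DEGs among 20 genes
  hs <- scan_hotspots(ord, degs)
  expect_identical(nrow(hs), 1L)
  expect_equal(hs$p_value, 1 / choose(20, 3))
  expect_equal(hs$p_value, enum_upper_tail(3, 3, 20, 3))
  expect_identical(hs$m, 3L)
  expect_identical(hs$k, 3L)
  expect_identical(hs$start_bp, 8000L)
  expect_identical(hs$end_bp, 10100L)
  # no DEGs: empty result
  expect_identical(nrow(scan_hotspots(ord, character(0))), 0L)
})

test_that("scan windows are DEG-delimited and merged hot spots are maximal", {
  # two significant overlapping stretches merge into one hot spot whose p
  # is the minimum of its members
  ord <- make_ordered(60)
  degs <- ord$gene_symbol[c(10, 11, 12, 14, 50, 51, 52)]
  hs <- scan_hotspots(ord, degs)
  expect_identical(nrow(hs), 2L)
  expect_identical(hs$start_index, c(10L, 50L))
  expect_identical(hs$end_index, c(14L, 52L))
  expect_equal(hs$p_value[2], enum_upper_tail(3, 7, 60, 3))
  # merged p = min over merged member windows
  member_p <- c(enum_upper_tail(3, 7, 60, 3),   # 10-12
                enum_upper_tail(4, 7, 60, 5),   # 10-14
                enum_upper_tail(3, 7, 60, 4),   # 11-14 (m=4)
                enum_upper_tail(3, 7, 60, 3))   # 12-14
  expect_equal(hs$p_value[1], min(member_p))
})

test_that("merging is idempotent and order-independent", {
  win <- data.frame(chromosome = "chr1",
                    start_index = c(5L, 8L, 20L, 1L),
                    end_index = c(9L, 12L, 25L, 4L),
                    m = 1L, k = 1L,
                    p_value = c(0.01, 0.002, 0.03, 0.04))
  m1 <- degnet:::merge_windows(win)
  m2 <- degnet:::merge_windows(win[sample(4), ])
  m3 <- degnet:::merge_windows(m1)
  expect_identical(m1$start_index, c(1L, 20L))   # 1-4 adjacent to 5-12
  expect_identical(m1$end_index, c(12L, 25L))
  expect_equal(m1$p_value, c(0.002, 0.03))
  expect_equal(m1[c("start_index", "end_index", "p_value")],
               m2[c("start_index", "end_index", "p_value")])
  expect_equal(m1[c("start_index", "end_index", "p_value")],
               m3[c("start_index", "end_index", "p_value")])
})

test_that("the permutation null agrees with the analytic scan p", {
  ord <- make_ordered(20)
  degs <- ord$gene_symbol[8:10]
  hs <- scan_hotspots(ord, degs)
  p_perm <- hotspot_permutation_p(ord, degs, hs[1, ], B = 100000, seed = 2)
  p_an <- 1 / choose(20, 3)
  expect_lt(abs(p_perm - p_an), 4 * sqrt(p_an * (1 - p_an) / 1e5) + 2e-5)
  # determinism under a fixed seed
  expect_identical(p_perm,
                   hotspot_permutation_p(ord, degs, hs[1, ], B = 100000,
                                         seed = 2))
  # window covering the whole genome: empirical p = 1
  whole <- list(chromosome = "chr1", start_index = 1L, end_index = 20L)
  expect_equal(hotspot_permutation_p(ord, degs, whole, B = 200, seed = 1), 1)

  # random configurations: analytic vs permutation within Monte-Carlo error
  set.seed(6)
  for (rep in 1:8) {
    G <- sample(30:80, 1)
    ordr <- make_ordered(G)
    D <- sample(5:12, 1)
    degr <- sample(ordr$gene_symbol, D)
    hsr <- scan_hotspots(ordr, degr, alpha = 1, min_k = 2)
    if (nrow(hsr) == 0) next
    w <- hsr[1, ]
    pa <- enum_upper_tail(w$k, D, G, w$m)
    pp <- hotspot_permutation_p(ordr, degr, w, B = 4000,
                                seed = 10 + rep)
    expect_lt(abs(pp - pa), 4 * sqrt(pa * (1 - pa) / 4000) + 5e-4)
  }
})

test_that("DEG membership conserves every DEG across inside/outside", {
  st <- simulate_study(small_sim_config(seed = 19))
  rec <- collapse_probes(select_degs(test_differential(st$expression)),
                         st$annotation)
  ord <- order_genome(st$annotation)
  hs <- scan_hotspots(ord, rec$gene_symbol)
  mem <- hotspot_membership(hs, rec)
  expect_identical(mem$n_inside + mem$n_outside, nrow(rec))
  expect_length(intersect(mem$inside, mem$outside), 0)
  # disjoint hot spots have disjoint membership lists
  if (nrow(hs) >= 2)
    expect_length(intersect(mem$per_hotspot[[1]], mem$per_hotspot[[2]]), 0)
})

test_that("planted hot spots are recovered with high gene overlap", {
  cfg <- small_sim_config(seed = 13)
  st <- simulate_study(cfg)
  rec <- collapse_probes(select_degs(test_differential(st$expression)),
                         st$annotation)
  ord <- order_genome(st$annotation)
  hs <- scan_hotspots(ord, rec$gene_symbol)
  recovered <- 0
  for (iv in st$truth$hotspot_intervals) {
    truth_genes <- ord$gene_symbol[ord$chromosome == iv$chromosome &
                                     ord$index >= iv$start_index &
                                     ord$index <= iv$end_index]
    truth_degs <- intersect(truth_genes, names(st$truth$deg_genes))
    hit <- vapply(seq_len(nrow(hs)), function(i) {
      found <- strsplit(hs$genes[i], ",", fixed = TRUE)[[1]]
      length(intersect(found, truth_degs)) / length(truth_degs)
    }, numeric(1))
    if (length(hit) && max(hit) >= 0.8) recovered <- recovered + 1
  }
  expect_gte(recovered / length(st$truth$hotspot_intervals), 0.8)
})
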