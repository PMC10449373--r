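mock_assoc <- function() {
  data.frame(
    otu_a = c("a", "a", "b", "c", "d"),
    otu_b = c("b", "c", "c", "d", "e"),
    ls = c(0.6, 0.5, 0.4, 0.45, 0.3),
    ls_sign = c("+", "-", "+", "+", "-"),
    delay = c(0L, 0L, 1L, -1L, 0L),
    start_x = 1L, start_y = 1L, length = 5L,
    ls_p = 0.001, ls_q = 0.001,
    sscc = c(0.9, -0.8, 0.7, 0.75, -0.6),
    sscc_p = 0.001, sscc_q = 0.001,
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    edge_type = c("SSCC", "SSCC", "LS", "SSCC", NA),
    network = c("synchronous", "synchronous", "time_shifted",
                "time_shifted", "synchronous"),
    weight = c(0.9, -0.8, 0.4, 0.75, -0.6),
    n_interpolated = 0L, stringsAsFactors = FALSE)
}

test_that("network construction splits by delay and drops the insignificant", {
  assoc <- mock_assoc()
  sync <- build_network(assoc, "synchronous")
  shift <- build_network(assoc, "time_shifted")
  expect_equal(igraph::ecount(sync), 2)
  expect_equal(igraph::ecount(shift), 2)
  expect_setequal(igraph::V(sync)$name, c("a", "b", "c"))
  expect_setequal(igraph::V(shift)$name, c("b", "c", "d"))
  # a node may live in both networks; edge e (insignificant) in neither
  expect_true("c" %in% igraph::V(sync)$name &&
                "c" %in% igraph::V(shift)$name)
  expect_false("e" %in% c(igraph::V(sync)$name, igraph::V(shift)$name))
  expect_warning(empty <- build_network(assoc[assoc$otu_a == "zz", ],
                                        "synchronous"),
                 "no significant")
  expect_equal(igraph::vcount(empty), 0)
})

test_that("network properties follow the standard formulas", {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- letters[1:4]
  igraph::E(g)$weight <- 1
  igraph::E(g)$type <- "SSCC"
  p <- network_properties(g)
  expect_equal(p$density, 1)
  expect_equal(p$mean_degree, 3)
  expect_equal(p$n_negative, 0)
  # one edge on two nodes (isolated already dropped upstream)
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = "a", to = "b", weight = -0.5, type = "LS"),
    directed = FALSE)
  p2 <- network_properties(g2)
  expect_equal(p2$density, 1)
  expect_equal(p2$n_negative, 1)
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  p0 <- network_properties(empty)
  expect_equal(p0$density, 0)
  expect_false(p0$density_defined)
})

test_that("WI^3 reproduces hand-derived cases", {
  g1 <- igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B", weight = 0.5), directed = FALSE)
  ti <- topological_importance(g1)
  expect_equal(ti$wi, c(2 / 3, 2 / 3))
  star <- igraph::graph_from_data_frame(
    data.frame(from = "c", to = c("l1", "l2", "l3"), weight = 1),
    directed = FALSE)
  ts_ <- topological_importance(star)
  expect_equal(ts_$wi[ts_$otu_id == "c"], 2)
  expect_equal(ts_$wi[ts_$otu_id == "l1"], 4 / 9)
  # centre strictly dominates leaves for any star size >= 2
  for (k in c(2, 5, 8)) {
    st <- igraph::graph_from_data_frame(
      data.frame(from = "c", to = paste0("l", 1:k), weight = 0.3),
      directed = FALSE)
    tik <- topological_importance(st)
    expect_gt(tik$wi[tik$otu_id == "c"], max(tik$wi[tik$otu_id != "c"]))
  }
})

test_that("matrix-power WI agrees with walk enumeration on random graphs", {
  set.seed(31)
  for (i in 1:40) {
    V <- sample(3:8, 1)
    W <- matrix(0, V, V)
    idx <- which(upper.tri(W))
    on <- idx[runif(length(idx)) < 0.5]
    W[on] <- runif(length(on), 0.1, 1) * sample(c(-1, 1), length(on),
                                                replace = TRUE)
    W <- W + t(W)
    dimnames(W) <- list(paste0("n", 1:V), paste0("n", 1:V))
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    got <- topological_importance(g)
    A <- effect_matrix(W[got$otu_id, got$otu_id])
    want <- wi_walk_oracle(A)
    expect_equal(got$wi, want$wi, tolerance = 1e-12)
    expect_equal(unname(as.matrix(got[, c("sigma_1", "sigma_2", "sigma_3")])),
                 unname(want$sigma), tolerance = 1e-12)
    # conservation: one-step effects of all nodes sum to the number of
    # non-isolated nodes
    expect_equal(sum(got$sigma_1), sum(rowSums(abs(W)) > 0),
                 tolerance = 1e-12)
    # scale invariance
    g2 <- igraph::graph_from_adjacency_matrix(2 * W, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(topological_importance(g2)$wi, got$wi, tolerance = 1e-12)
  }
})

test_that("keystone selection applies the threshold and expansion branches", {
  wi7 <- setNames(rep(1.2, 7), paste0("o", 1:7))
  expect_setequal(call_keystones(wi7), names(wi7))
  wi5 <- setNames(c(1.4, 1.2, 1.1, 1, 1, 0.6), paste0("o", 1:6))
  expect_setequal(call_keystones(wi5), paste0("o", 1:5))
  none <- setNames(c(0.2, 0.9), c("a", "b"))
  expect_length(call_keystones(none), 0)
  # six above threshold: no expansion, exactly-1 stays out
  wi6 <- setNames(c(rep(1.2, 6), 1), paste0("o", 1:7))
  expect_setequal(call_keystones(wi6), paste0("o", 1:6))
  # monotone: raising one value never drops it
  raised <- wi5; raised["o6"] <- 1.5
  expect_true("o6" %in% call_keystones(raised))
  expect_true(all(call_keystones(wi5) %in% c(call_keystones(raised), "o6") |
                    call_keystones(wi5) %in% call_keystones(raised)))
})

test_that("keystone direction classes follow the signed incident sum", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("h", "h", "k", "k"),
               to = c("x", "y", "x", "y"),
               weight = c(0.5, 0.4, 0.5, -0.9)),
    directed = FALSE)
  expect_equal(keystone_sign(g, "h"), "positive")
  expect_equal(keystone_sign(g, "k"), "negative")
  bal <- igraph::graph_from_data_frame(
    data.frame(from = c("z", "z"), to = c("x", "y"),
               weight = c(0.5, -0.5)), directed = FALSE)
  expect_equal(keystone_sign(bal, "z"), "unspecified")
  expect_error(keystone_sign(g, "nope"), "not in network")
})

test_that("preferred season rules reproduce their defining cases", {
  seas <- c(rep("spring", 4), rep("summer", 6), rep("autumn", 4))
  # constant series: no season can exceed a zero SD strictly
  expect_equal(as.character(preferred_season(rep(0.3, 14), seas,
                                             "relabund")), "none")
  # spring-only block at 0.5: mean diff 0.3571 > sd 0.2259
  v <- c(rep(0.5, 4), rep(0, 10))
  expect_equal(as.character(preferred_season(v, seas, "relabund")),
               "spring")
  # independently recomputed bound
  expect_gt(mean(v[1:4]) - mean(v), sqrt(mean((v - mean(v))^2)))
  # z-score rule: two positive seasons -> unspecified
  v2 <- c(rep(1, 4), rep(1, 6), rep(-2, 4))
  expect_equal(as.character(preferred_season(v2, seas, "zscore")),
               "unspecified")
  v3 <- c(rep(2, 4), rep(-1, 6), rep(-1, 4))
  expect_equal(as.character(preferred_season(v3, seas, "zscore")),
               "spring")
  expect_equal(as.character(preferred_season(rep(1, 14), seas, "zscore")),
               "none")
})

test_that("keystone reports join WI, sign class, core label and seasons", {
  assoc <- mock_assoc()
  nets <- list(synchronous = build_network(assoc, "synchronous"),
               time_shifted = build_network(assoc, "time_shifted"))
  set.seed(41)
  m <- matrix(rpois(14 * 5, 50), 14, 5)
  md <- mk_meta(T_ = 14)
  dimnames(m) <- list(md$sample_id, c("a", "b", "c", "d", "e"))
  rep_ <- keystone_report(nets, otutab(m), md, core = c("a", "d"))
  expect_true(all(rep_$core[rep_$otu_id == "a"] == "core"))
  expect_true(all(rep_$core[rep_$otu_id %in% c("b", "c")] == "non-core"))
  expect_true(all(rep_$wi >= 1))
  expect_true(all(diff(rep_$wi[rep_$network == rep_$network[1]]) <= 0))
  empty <- list(synchronous = igraph::make_empty_graph(0, directed = FALSE))
  expect_equal(nrow(keystone_report(empty, otutab(m), md, core = "a")), 0)
})

test_that("networks export to GraphML and edge lists", {
  assoc <- mock_assoc()
  g <- build_network(assoc, "synchronous")
  gml <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  export_network(g, gml, tsv)
  expect_true(file.exists(gml))
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  el <- utils::read.delim(tsv)
  expect_equal(nrow(el), 2)
})
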