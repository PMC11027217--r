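make_stats <- function(n_users_i, n_users_j, n_co, severity = "major") {
  data.table(drug_a = sprintf("a%02d", seq_along(n_co)),
             drug_b = sprintf("b%02d", seq_along(n_co)),
             n_users_i = n_users_i, n_users_j = n_users_j,
             n_coadmin_users = n_co,
             gamma_ij = n_co / n_users_i, gamma_ji = n_co / n_users_j,
             tau_mean = 0.5, is_ddi = TRUE, severity = severity)
}

test_that("enrichment p-values match hypergeometric enumeration and fisher.test", {
  # |U| = 4, margins 1 and 1, one co-user: P(X >= 1) = 1/4
  st <- pair_significance(make_stats(1L, 1L, 1L), n_patients = 4L)
  expect_equal(st$p_value, 0.25)

  # degenerate margins: everyone takes both drugs -> only one table, p = 1
  st2 <- pair_significance(make_stats(10L, 10L, 10L), n_patients = 10L)
  expect_equal(st2$p_value, 1)

  # dual route: phyper-based p equals fisher.test(alternative = "greater")
  set.seed(8)
  for (k in 1:25) {
    N <- sample(20:200, 1)
    ki <- sample(1:N, 1); kj <- sample(1:N, 1)
    co_range <- max(0, ki + kj - N):min(ki, kj)
    co <- co_range[sample.int(length(co_range), 1)]
    if (co == 0) next
    st3 <- pair_significance(make_stats(ki, kj, co), n_patients = N)
    ft <- fisher.test(matrix(c(co, ki - co, kj - co, N - ki - kj + co), 2L),
                      alternative = "greater")
    expect_equal(st3$p_value, ft$p.value, tolerance = 1e-10)
  }

  # impossible co-user counts are a data-integrity error
  expect_error(pair_significance(make_stats(5L, 8L, 6L), n_patients = 20L),
               "integrity")
})

test_that("FDR filtering: edges pass the threshold and tightening never adds edges", {
  set.seed(15)
  n <- 40
  st <- make_stats(sample(50:150, n, TRUE), sample(50:150, n, TRUE),
                   sample(1:40, n, TRUE))
  st <- st[n_coadmin_users <= pmin(n_users_i, n_users_j)]
  sig <- pair_significance(st, n_patients = 400L)
  expect_true(all(sig[significant == TRUE, q_value] <= 0.05))
  e05 <- sig[q_value <= 0.05, paste(drug_a, drug_b)]
  e01 <- sig[q_value <= 0.01, paste(drug_a, drug_b)]
  expect_true(all(e01 %in% e05))
  # BH q-values never below raw p; bonferroni at least as large as q
  expect_true(all(sig$q_value >= sig$p_value - 1e-12))
  expect_true(all(sig$p_bonferroni >= sig$q_value - 1e-12))
})

net_fixture <- function() {
  # drug h interacts with x, y, z; co-user sets disjoint of sizes 2, 3, 5;
  # h has 20 users in total
  win <- dwin()
  users_h <- sprintf("u%02d", 1:20)
  co_x <- users_h[1:2]; co_y <- users_h[3:5]; co_z <- users_h[6:10]
  recs <- rbind(
    drec(users_h, "h", 0, 30),
    drec(co_x, "x", 10, 10), drec(co_y, "y", 10, 10), drec(co_z, "z", 10, 10),
    # extra sole users so margins are not degenerate
    drec(sprintf("vx%02d", 1:10), "x", 0, 10),
    drec(sprintf("vy%02d", 1:10), "y", 0, 10),
    drec(sprintf("vz%02d", 1:10), "z", 0, 10),
    # large background population so the observed co-usage is enriched far
    # beyond independence of the user sets
    drec(sprintf("w%05d", 1:5000), "filler", 0, 5))
  ddi <- ddi_ref(rep("h", 3), c("x", "y", "z"), c("major", "moderate", "minor"))
  pats <- pat(unique(recs$patient_id),
              gender = rep_len(c("W", "M"), length(unique(recs$patient_id))))
  list(recs = canonicalize_dispensations(recs, win), ddi = ddi, pats = pats,
       win = win)
}

test_that("network construction: node risk from the union of significant pairs", {
  fx <- net_fixture()
  ep <- detect_pair_episodes(fx$recs, fx$ddi, fx$win)
  st <- pair_population_stats(ep, fx$recs)
  sig <- pair_significance(st, data.table::uniqueN(fx$recs$patient_id))
  expect_true(all(sig$significant))  # strongly enriched by construction
  g <- build_network(sig, ep, fx$recs, fx$pats)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  # node h: 2 + 3 + 5 = 10 exposed of 20 users
  expect_equal(igraph::vertex_attr(g, "node_risk",
                                   igraph::V(g)[name == "h"]), 0.5)
  expect_true(all(igraph::edge_attr(g, "q_value") <= 0.05))
  rrd <- igraph::edge_attr(g, "rr_display")
  expect_true(all(rrd >= 1 & rrd <= 5))

  # node risk is invariant to patient relabeling and row order
  relab <- copy(fx$recs)[, patient_id := paste0("R_", patient_id)]
  pats2 <- copy(fx$pats)[, patient_id := paste0("R_", patient_id)]
  ep2 <- detect_pair_episodes(relab[sample(nrow(relab))], fx$ddi, fx$win)
  st2 <- pair_population_stats(ep2, relab)
  g2 <- build_network(pair_significance(st2, data.table::uniqueN(relab$patient_id)),
                      ep2, relab, pats2)
  ord <- order(igraph::V(g)$name); ord2 <- order(igraph::V(g2)$name)
  expect_equal(igraph::V(g)$node_risk[ord], igraph::V(g2)$node_risk[ord2])
})

test_that("network export: GraphML round trip and strength filter", {
  fx <- net_fixture()
  ep <- detect_pair_episodes(fx$recs, fx$ddi, fx$win)
  st <- pair_population_stats(ep, fx$recs)
  sig <- pair_significance(st, data.table::uniqueN(fx$recs$patient_id))
  g <- build_network(sig, ep, fx$recs, fx$pats)
  tmp <- withr::local_tempdir()

  p <- export_network(g, file.path(tmp, "net.graphml"))
  g2 <- import_network(p)
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_equal(sort(igraph::V(g2)$name), sort(igraph::V(g)$name))
  m <- match(igraph::V(g)$name, igraph::V(g2)$name)
  expect_equal(igraph::V(g2)$node_risk[m], igraph::V(g)$node_risk)
  expect_equal(sort(igraph::edge_attr(g2, "tau_mean")),
               sort(igraph::edge_attr(g, "tau_mean")))

  # strength filter drops weak edges only
  taus <- igraph::edge_attr(g, "tau_mean")
  thr <- sort(taus)[2]
  p2 <- export_network(g, file.path(tmp, "net2.graphml"), min_tau = thr)
  g3 <- import_network(p2)
  expect_equal(igraph::ecount(g3), sum(taus >= thr))

  # empty network still writes valid GraphML
  g0 <- build_network(pair_significance(make_stats(10L, 10L, 1L),
                                        n_patients = 1000L)[q_value > 2],
                      ep, fx$recs, fx$pats)
  p0 <- export_network(g0, file.path(tmp, "empty.graphml"))
  expect_equal(igraph::vcount(import_network(p0)), 0L)

  # edge list export
  pe <- export_network(g, file.path(tmp, "net.csv"), format = "edgelist")
  el <- data.table::fread(pe)
  expect_equal(nrow(el), igraph::ecount(g))
  expect_true(all(c("tau_mean", "q_value", "rr_women") %in% names(el)))
})
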