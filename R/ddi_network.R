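# The significance-filtered drug-interaction network: nodes are drugs with
# at least one significant interaction edge; an edge is an observed,
# known-interacting pair whose co-usage is enriched beyond independence of
# the two drugs' user sets (one-sided Fisher test, FDR-controlled).

#' Co-usage enrichment tests for observed interacting pairs
#'
#' For each observed known-DDI pair, tests whether the number of patients
#' co-administering the pair exceeds what independence of the two drugs'
#' user sets would give: a one-sided (enrichment) Fisher exact test on the
#' 2x2 of (administered drug i) x (administered drug j) over the
#' population, with the joint cell the concomitant co-users. Both
#' Benjamini-Hochberg q-values and Bonferroni-adjusted p-values across all
#' observed DDI pairs are reported; the significance flag uses FDR.
#'
#' @param stats Output of [pair_population_stats()].
#' @param n_patients Total number of patients in the population (with at
#'   least one administration).
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @return The DDI rows of `stats` with `p_value`, `q_value`,
#'   `p_bonferroni` and `significant` columns added.
#' @export
pair_significance <- function(stats, n_patients, fdr = 0.05) {
  st <- data.table::as.data.table(stats)[is_ddi == TRUE]
  if (nrow(st) == 0L) {
    return(st[, `:=`(p_value = numeric(), q_value = numeric(),
                     p_bonferroni = numeric(), significant = logical())])
  }
  abort_if(any(st$n_coadmin_users > pmin(st$n_users_i, st$n_users_j)),
           "data integrity error: co-users exceed a drug's user count")
  abort_if(any(st$n_users_i > n_patients) || any(st$n_users_j > n_patients),
           "data integrity error: drug user count exceeds population size")
  # P(X >= k) for k co-users under hypergeometric independence of user sets
  st[, p_value := phyper(n_coadmin_users - 1L, n_users_i,
                         n_patients - n_users_i, n_users_j,
                         lower.tail = FALSE)]
  st[, q_value := p.adjust(p_value, method = "BH")]
  st[, p_bonferroni := p.adjust(p_value, method = "bonferroni")]
  st[, significant := q_value <= fdr]
  st[]
}

#' Build the significance-filtered DDI network
#'
#' Nodes are drugs incident to at least one significant interaction edge,
#' sized by `node_risk`: the probability that a patient administering the
#' drug is exposed to a significant DDI involving it (distinct patients in
#' the union over the drug's significant pairs, divided by the drug's
#' users). Edges carry the strength of co-administration (`tau_mean`), the
#' per-pair gender relative risk for women (`rr_women`, the ratio of the
#' two genders' co-administration prevalences for the pair), a display
#' copy of the dominant-gender relative risk clipped to `[1, 5]`, severity
#' and the test results.
#'
#' @param sig Output of [pair_significance()].
#' @param episodes Output of [detect_pair_episodes()] (patient-level pairs,
#'   used for co-user sets).
#' @param records Canonical dispensation table (per-drug user counts).
#' @param patients Patient table (gender denominators).
#' @param fdr FDR threshold defining the edge set (default 0.05).
#' @return An `igraph` undirected graph with the attributes above.
#' @export
build_network <- function(sig, episodes, records, patients, fdr = 0.05) {
  sig <- data.table::as.data.table(sig)
  edges <- sig[q_value <= fdr]
  if (nrow(edges) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  pts <- data.table::as.data.table(patients)
  records <- data.table::as.data.table(records)
  active <- unique(records$patient_id)
  n_w <- pts[patient_id %chin% active & gender == "W", .N]
  n_m <- pts[patient_id %chin% active & gender == "M", .N]

  ep <- data.table::as.data.table(episodes)[
    edges[, .(drug_a, drug_b)], on = c("drug_a", "drug_b")]
  ep <- pts[, .(patient_id, gender)][ep, on = "patient_id"]

  gender_counts <- ep[, .(n_pair_w = data.table::uniqueN(patient_id[gender == "W"]),
                          n_pair_m = data.table::uniqueN(patient_id[gender == "M"])),
                      by = .(drug_a, drug_b)]
  edges <- gender_counts[edges, on = c("drug_a", "drug_b")]
  edges[, rr_women := (n_pair_w / n_w) / (n_pair_m / n_m)]
  edges[, rr_display := pmin(pmax(rr_women, 1 / rr_women), 5)]
  edges[is.na(rr_display), rr_display := 1]
  edges[, gender_dominant := data.table::fifelse(is.na(rr_women) | rr_women == 1,
                                                 "none",
                                                 data.table::fifelse(rr_women > 1, "W", "M"))]

  node_users <- records[, .(n_users = data.table::uniqueN(patient_id)), by = drug_id]
  exposed <- unique(rbind(ep[, .(drug_id = drug_a, patient_id)],
                          ep[, .(drug_id = drug_b, patient_id)]))
  node_exposed <- exposed[, .(n_exposed = .N), by = drug_id]
  nodes <- node_exposed[node_users, on = "drug_id", nomatch = NULL]
  nodes <- nodes[drug_id %chin% unique(c(edges$drug_a, edges$drug_b))]
  nodes[, node_risk := n_exposed / n_users]

  g <- igraph::graph_from_data_frame(
    edges[, .(from = drug_a, to = drug_b, tau_mean, severity,
              n_coadmin_users, rr_women, rr_display, gender_dominant,
              p_value, q_value, p_bonferroni, weight = tau_mean)],
    directed = FALSE,
    vertices = nodes[, .(name = drug_id, node_risk, n_users = n_users,
                         n_exposed = n_exposed)])
  g
}

#' Export a DDI network
#'
#' Writes GraphML (typed attributes, round-trip safe via
#' [import_network()]) or a flat delimited edge list. An optional
#' strength-of-interaction filter keeps only edges with
#' `tau_mean >= min_tau` (a display convention for dense networks).
#'
#' @param network An `igraph` graph from [build_network()].
#' @param path Output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @param min_tau Minimum strength of co-administration for an edge to be
#'   written (default 0 keeps all).
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "edgelist"),
                           min_tau = 0) {
  format <- match.arg(format)
  if (min_tau > 0 && igraph::ecount(network) > 0) {
    keep <- igraph::E(network)[igraph::edge_attr(network, "tau_mean") >= min_tau]
    network <- igraph::subgraph_from_edges(network, keep, delete.vertices = TRUE)
  }
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(network, what = "edges")
    data.table::fwrite(el, path)
  }
  invisible(path)
}

#' Re-import a GraphML network
#'
#' @param path GraphML file written by [export_network()].
#' @return An `igraph` graph with attributes preserved.
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
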