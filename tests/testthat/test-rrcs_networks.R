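test_that("single-atom pair scores follow the piecewise distance ramp", {
  two_at <- function(d) {
    toy_structure(rbind(c(0, 0, 0), c(d, 0, 0)),
                  generic = c("1x50", "2x50"))
  }
  # d <= d_min: full score
  expect_equal(compute_rrcs(two_at(3.00))$score, 1.0)
  # linear mid-range: (4.63 - 3.93) / 1.40 = 0.5
  expect_equal(compute_rrcs(two_at(3.93))$score, 0.5, tolerance = 1e-9)
  # boundary zero: edge absent
  expect_equal(nrow(compute_rrcs(two_at(4.63))), 0)
  expect_equal(nrow(compute_rrcs(two_at(6.0))), 0)
})

test_that("near-sequence pairs exclude backbone atoms", {
  # residues 1 and 2 (adjacent): CA atoms in contact but backbone-excluded
  adj <- toy_structure(rbind(c(0, 0, 0), c(3, 0, 0)), atom_name = "CA",
                       generic = c("1x50", "1x51"))
  expect_equal(nrow(compute_rrcs(adj)), 0)
  # same geometry via side-chain atoms scores normally
  adj_cb <- toy_structure(rbind(c(0, 0, 0), c(3, 0, 0)), atom_name = "CB",
                          generic = c("1x50", "1x51"))
  expect_equal(compute_rrcs(adj_cb)$score, 1.0)
  # far-in-sequence CA pairs are not excluded
  far <- structure_model(tibble::tibble(
    chain = "A", residue_index = c(1L, 10L), residue_name = "ALA",
    atom_name = "CA", element = "C",
    x = c(0, 3), y = 0, z = 0,
    generic_number = c("1x50", "3x50")
  ), structure_id = "far", state = "active")
  expect_equal(compute_rrcs(far)$score, 1.0)
})

test_that("RRCS equals the brute-force double loop on random structures", {
  for (seed in 1:4) {
    s <- random_structure(20, seed = seed)
    net <- compute_rrcs(s)
    oracle <- oracle_rrcs(s)
    got <- setNames(net$score, edge_keys(net))
    expect_setequal(names(got), names(oracle))
    for (k in names(oracle)) {
      expect_equal(got[[k]], oracle[[k]], tolerance = 1e-9)
    }
  }
})

test_that("RRCS is invariant to atom record order and non-negative", {
  s <- random_structure(12, seed = 9)
  net1 <- compute_rrcs(s)
  perm <- sample(nrow(s))
  s2 <- structure_model(tibble::as_tibble(s)[perm, ],
                        structure_id = "perm", state = "active")
  net2 <- compute_rrcs(s2)
  expect_equal(tidy(net1), tidy(net2))
  expect_true(all(net1$score >= 0))
})

test_that("delta networks subtract, filter at the 0.2 boundary, and pool", {
  mknet <- function(scores) {
    contact_network(tibble::tibble(
      source = paste0("1x", 40 + seq_along(scores)),
      target = paste0("2x", 40 + seq_along(scores)),
      score = scores
    ))
  }
  active <- mknet(c(1.0, 0.7, 0.5))
  inactive <- mknet(c(0.8, 0.2, 1.0))
  pool <- c(paste0("1x", 41:43), paste0("2x", 41:43))
  d <- delta_rrcs(active, inactive, pool)
  # deltas: 0.2 (dropped, |d| <= 0.2), 0.5 (kept), -0.5 (kept, negative)
  expect_equal(nrow(d), 2)
  expect_setequal(round(d$delta, 9), c(0.5, -0.5))
  # a pair absent from one side counts as zero there
  lone <- contact_network(tibble::tibble(source = "1x41", target = "2x41",
                                         score = 1.0))
  none <- contact_network(tibble::tibble(source = character(0),
                                         target = character(0),
                                         score = numeric(0)))
  d2 <- delta_rrcs(lone, none, pool = c("1x41", "2x41"))
  expect_equal(d2$delta, 1.0)
})

test_that("delta of a network with itself is empty, and the pool gates edges", {
  s <- random_structure(15, seed = 3)
  net <- compute_rrcs(s)
  pool <- unique(c(net$source, net$target))
  expect_equal(nrow(delta_rrcs(net, net, pool = pool)), 0)
  expect_error(delta_rrcs(net, net, pool = character(0)), "empty")

  a <- contact_network(tibble::tibble(source = "1x41", target = "2x41",
                                      score = 1.0))
  b <- contact_network(tibble::tibble(source = character(0),
                                      target = character(0),
                                      score = numeric(0)))
  expect_equal(nrow(delta_rrcs(a, b, pool = c("1x41"))), 0)  # both-endpoint rule
  expect_equal(nrow(delta_rrcs(a, b, pool = c("1x41"),
                               endpoints = "either")), 1)
})

test_that("planted structure-pair contact changes carry the right signs", {
  sp <- simulate_structure_pair(structure_pair_spec(
    12, planted_gain_pairs = list(c(2, 9)),
    planted_loss_pairs = list(c(3, 11)), seed = 4))
  na <- compute_rrcs(sp$active)
  ni <- compute_rrcs(sp$inactive)
  d <- delta_rrcs(na, ni, pool = unique(sp$active$generic_number))
  expect_equal(nrow(d), 2)
  gain_key <- paste(sp$truth$gain_edges[[1]], collapse = "|")
  loss_key <- paste(sp$truth$loss_edges[[1]], collapse = "|")
  expect_gt(d$delta[edge_keys(d) == gain_key], 0)
  expect_lt(d$delta[edge_keys(d) == loss_key], 0)
})

test_that("common networks apply the occurrence threshold exactly", {
  edge <- function() contact_network(tibble::tibble(
    source = "1x50", target = "7x50", delta = 1))
  blank <- function() contact_network(tibble::tibble(
    source = character(0), target = character(0), delta = numeric(0)))
  nets36 <- c(replicate(36, edge(), simplify = FALSE),
              replicate(5, blank(), simplify = FALSE))
  expect_equal(common_network(nets36, min_count = 36)$count, 36)
  nets35 <- c(replicate(35, edge(), simplify = FALSE),
              replicate(6, blank(), simplify = FALSE))
  expect_equal(nrow(common_network(nets35, min_count = 36)), 0)
  # min_count = 1 is the union of edges
  mixed <- list(edge(), blank(), contact_network(tibble::tibble(
    source = "2x50", target = "3x50", delta = -1)))
  expect_equal(nrow(common_network(mixed, min_count = 1)), 2)
  expect_warning(res <- common_network(list(edge()), min_count = 36),
                 "exceeds")
  expect_equal(nrow(res), 0)
})

test_that("pairing plans expand per-receptor Cartesian products", {
  plan <- pairing_plan(sets = tibble::tibble(
    receptor = c("ADRB2", "DRD2"),
    active = list(c("3SN6", "7DHI"), "6VMS"),
    inactive = list(c("2RH1", "6PS2"), c("6CM4", "6LUQ", "7DFP"))
  ))
  expect_equal(nrow(plan), 2 * 2 + 1 * 3)
  expect_true(all(plan$receptor[plan$active_id == "6VMS"] == "DRD2"))
  expect_error(pairing_plan(pairs = tibble::tibble(receptor = "X")),
               "missing column")
})

group_fixture <- function(seed = 1, group_delta = 1, jitter = 0.02,
                          n_group = 4, n_rest = 6,
                          outlier_receptor = NULL, outlier_delta = NULL) {
  set.seed(seed)
  mk <- function(delta) contact_network(tibble::tibble(
    source = "1x50", target = "7x50",
    delta = delta + rnorm(1, sd = jitter)), kind = "delta_rrcs")
  receptors <- c(paste0("G", seq_len(n_group)), paste0("R", seq_len(n_rest)))
  deltas <- c(rep(group_delta, n_group), rep(0, n_rest))
  if (!is.null(outlier_receptor)) {
    deltas[match(outlier_receptor, receptors)] <- outlier_delta
  }
  tibble::tibble(
    receptor = receptors,
    active_id = paste0(receptors, "_a"),
    inactive_id = paste0(receptors, "_i"),
    network = lapply(deltas, mk)
  )
}

test_that("group-specific edges are retained with the right sign", {
  pn <- group_fixture(seed = 2)
  net <- gprotein_specific_network(pn, group = paste0("G", 1:4),
                                   alpha = 0.01)
  expect_equal(nrow(net), 1)
  expect_equal(net$sign, 1)
  expect_lte(net$p_value, 0.01)
  expect_gt(net$delta_delta, 0.9)
})

test_that("excluding an outlier receptor can rescue an edge", {
  # one rest-group receptor shows the same gain as the group, washing out
  # significance until it is excluded
  pn <- group_fixture(seed = 5, jitter = 0.15,
                      outlier_receptor = "R1", outlier_delta = 1)
  with_out <- gprotein_specific_network(pn, group = paste0("G", 1:4),
                                        alpha = 0.01)
  without <- gprotein_specific_network(pn, group = paste0("G", 1:4),
                                       alpha = 0.01, exclude = "R1")
  expect_equal(nrow(with_out), 0)
  expect_equal(nrow(without), 1)
})

test_that("undersized groups warn and produce an empty network", {
  pn <- group_fixture()
  expect_warning(
    res <- gprotein_specific_network(pn, group = "G1", alpha = 0.01,
                                     exclude = paste0("G", 2:4)),
    "fewer than 2")
  expect_equal(nrow(res), 0)
})
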