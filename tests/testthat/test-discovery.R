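cfg02 <- search_config(cc_a = 0.2, cc_b = 0.2)

test_that("constrained score enforces clustering only from size 3", {
  tri <- net_from_triples("x", "y", 1, "y", "z", 1, "x", "z", 1)
  pathnet <- net_from_triples("x", "y", 1, "y", "z", 1)
  act <- activity_profile(c(x = 0.6, y = 0.6, z = 0.6))
  profs <- list(a = act, b = act)

  expect_equal(constrained_score(c("x", "y", "z"), list(a = tri, b = tri),
                                 profs, cfg02), 0.6)
  # species B induced graph is a path: average CC 0 -> violation
  expect_equal(constrained_score(c("x", "y", "z"), list(a = tri, b = pathnet),
                                 profs, cfg02), 0)
  # singletons and pairs are exempt
  expect_equal(constrained_score("x", list(a = tri, b = pathnet), profs,
                                 cfg02), 0.6)
  expect_error(constrained_score(c("x", "q"), list(a = tri, b = tri), profs,
                                 cfg02), "absent from species A")
})

test_that("growth from a clique seed excludes the low-activity pendant", {
  fx <- clique_fixture(pendant_activity = 0.05)
  # the pendant keeps the mean above the cutoff (0.65), so it is the
  # clustering constraint that stops growth: with it the average weighted CC
  # would drop from 0.9 to (3 * 0.9 + 0.45 + 0) / 5 = 0.63
  cfg65 <- search_config(cc_a = 0.65, cc_b = 0.65)
  sn <- grow_subnetwork("s", fx$nets, fx$profiles, cfg65)
  expect_setequal(sn$members, c("s", "m1", "m2", "m3"))
  expect_equal(sn$score, 0.8)
  expect_equal(sn$cc_a, 0.9)
  # trace starts at the seed and never dips below the cutoff
  expect_length(sn$trace, 4)
  expect_true(all(vapply(sn$trace, `[[`, 0, "score") >= cfg65$score_cutoff))
  expect_identical(sn$trace[[1]]$members, "s")
})

test_that("seeds that cannot sustain the cutoff return nothing", {
  fx <- clique_fixture()
  dead <- list(a = activity_profile(c(s = 0.2)),
               b = activity_profile(c(s = 0.2)))   # all neighbours zero
  expect_null(grow_subnetwork("s", fx$nets, dead, cfg02))

  zero <- list(a = activity_profile(c(s = 0)), b = activity_profile(c(s = 0)))
  expect_null(grow_subnetwork("s", fx$nets, zero, cfg02))
})

test_that("max_size caps growth", {
  fx <- clique_fixture()
  cfg <- search_config(cc_a = 0.2, cc_b = 0.2, max_size = 3)
  sn <- grow_subnetwork("s", fx$nets, fx$profiles, cfg)
  expect_length(sn$members, 3)
})

test_that("each greedy step picks the score-maximizing candidate", {
  set.seed(31)
  net <- random_graph(25, p = 0.25, seed = 31)
  act <- activity_profile(structure(
    round(stats::runif(25, -1, 1), 2), names = net$nodes))
  nets <- list(a = net, b = net)
  profs <- list(a = act, b = act)
  cfg <- search_config(cc_a = 0.05, cc_b = 0.05, score_cutoff = 0.1)

  grown <- 0
  for (seed_node in net$nodes) {
    sn <- grow_subnetwork(seed_node, nets, profs, cfg)
    if (is.null(sn) || length(sn$trace) < 2) next
    grown <- grown + 1
    nb <- functional_neighborhood(net, seed_node, cfg$path_threshold_a)
    pool <- sort(names(nb$confidence))
    for (step in seq_along(sn$trace)[-1]) {
      before <- sn$trace[[step - 1]]$members
      chosen_score <- sn$trace[[step]]$score
      # exhaustive evaluation of every candidate available at this step
      best <- -Inf
      for (g in setdiff(pool, before)) {
        cand <- union(before, c(nb$path[[g]][-1], g))
        s <- constrained_score(cand, nets, profs, cfg)
        if (s > best) best <- s
      }
      expect_equal(chosen_score, best, tolerance = 1e-12)
    }
  }
  expect_gt(grown, 0)
})

test_that("deduplication drops mostly-contained subnetworks and is idempotent", {
  A <- make_subnet("A", sprintf("c%02d", 1:10))
  B <- make_subnet("B", c(sprintf("c%02d", 1:7), "q1"))   # 7/8 shared
  C <- make_subnet("C", sprintf("z%02d", 1:5))
  kept <- deduplicate_subnetworks(list(A, B, C), 0.6)
  expect_setequal(vapply(kept, `[[`, "", "seed"), c("A", "C"))
  expect_identical(deduplicate_subnetworks(kept, 0.6), kept)

  # at exactly the threshold the smaller network is kept (strict >)
  D <- make_subnet("D", c(sprintf("c%02d", 1:6), sprintf("q%d", 1:4)))  # 6/10
  expect_length(deduplicate_subnetworks(list(A, D), 0.6), 2)
})

test_that("colour classification follows the 2x majority rule", {
  mk <- function(n_up, n_down) {
    ids <- sprintf("g%02d", seq_len(n_up + n_down))
    act <- activity_profile(structure(c(rep(0.5, n_up), rep(-0.5, n_down)),
                                      names = ids))
    classify_color(ids, list(a = act, b = act))
  }
  expect_equal(mk(5, 2), "green")
  expect_equal(mk(4, 2), "yellow")
  expect_equal(mk(1, 3), "red")
})

test_that("discovery separates disjoint planted modules and dedups seeds", {
  fx <- two_module_fixture()
  found <- discover_subnetworks(fx$nets$a, fx$profiles$a, fx$nets$b,
                                fx$profiles$b, cfg02)
  expect_length(found, 2)
  sets <- lapply(found, `[[`, "members")
  expect_true(any(vapply(sets, setequal, TRUE, fx$modules$m1)))
  expect_true(any(vapply(sets, setequal, TRUE, fx$modules$m2)))
  # module 1 is up in both species, module 2 down in both
  cols <- structure(vapply(found, `[[`, "", "color"),
                    names = vapply(sets, function(s)
                      if (setequal(s, fx$modules$m1)) "m1" else "m2", ""))
  expect_equal(cols[["m1"]], "green")
  expect_equal(cols[["m2"]], "red")
})

test_that("all-zero activities yield no subnetworks", {
  fx <- two_module_fixture()
  zero <- activity_profile(structure(numeric(length(fx$nets$a$nodes)),
                                     names = fx$nets$a$nodes))
  found <- discover_subnetworks(fx$nets$a, zero, fx$nets$b, zero, cfg02)
  expect_length(found, 0)
})

test_that("single-species mode recovers a planted module from one network", {
  fx <- two_module_fixture()
  cfg <- search_config(mode = "single_species", cc_a = 0.2)
  found <- discover_subnetworks(fx$nets$a, fx$profiles$a, config = cfg)
  sets <- lapply(found, `[[`, "members")
  expect_true(any(vapply(sets, setequal, TRUE, fx$modules$m1)))
  # m2 has negative single-species activity: mean below cutoff, not reported
  expect_false(any(vapply(sets, setequal, TRUE, fx$modules$m2)))
})

test_that("subnetwork counts are non-increasing in the score cutoff", {
  fx <- two_module_fixture()
  counts <- vapply(c(0.15, 0.4, 0.65, 0.75, 0.95), function(cut) {
    length(discover_subnetworks(fx$nets$a, fx$profiles$a, fx$nets$b,
                                fx$profiles$b,
                                search_config(score_cutoff = cut,
                                              cc_a = 0.2, cc_b = 0.2)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 2)
})

test_that("relative clustering thresholds add the network background", {
  fx <- clique_fixture()
  bg <- background_clustering_coefficient(fx$nets$a)
  cfg_rel <- search_config(cc_a = 0.2, cc_b = 0.2, cc_relative = TRUE)
  found <- discover_subnetworks(fx$nets$a, fx$profiles$a, fx$nets$b,
                                fx$profiles$b, cfg_rel)
  expect_equal(unname(attr(found, "cc_abs")), c(bg + 0.2, bg + 0.2))
})
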