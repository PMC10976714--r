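test_that("order_units sorts by last observation with stable ties", {
  X <- rbind(A = c(rep(1, 7), 3), B = c(rep(1, 7), 1),
             C = c(rep(1, 7), 2))
  p <- panel_series(X, value_scale = "log")
  expect_equal(order_units(p), c("A", "C", "B"))

  # tie on the last observation: alphabetical
  X2 <- rbind(B = c(rep(5, 7), 2), A = c(rep(1, 7), 2))
  p2 <- panel_series(X2, value_scale = "log")
  expect_equal(order_units(p2), c("A", "B"))

  # alternative rule: mean over the second half
  expect_equal(order_units(p2, rule = "mean_last_half"), c("B", "A"))
})

test_that("form_core finds the top club and handles hopeless panels", {
  # planted two-club panel, higher-loading club ordered first
  sim <- simulate_panel(dgp_spec(delta = rep(c(4, 1), each = 5),
                                 T_len = 40, theta = 0.05, a = 0.75,
                                 seed = 5))
  club_hi <- sim$partition$clubs[[1]]
  core <- form_core(sim$panel)
  expect_true(length(core) >= 2)
  expect_true(all(core %in% club_hi))

  # fully convergent panel: the core may extend to (nearly) all units and
  # the sieve then completes the single club
  sim2 <- simulate_panel(dgp_spec(delta = rep(1, 8), T_len = 40,
                                  theta = 0.02, a = 1, seed = 6))
  core2 <- form_core(sim2$panel)
  expect_gte(length(core2), 2)
  expect_setequal(sieve_members(sim2$panel, core2), sim2$panel$units)

  # mutually diverging units: no pair qualifies anywhere
  T_ <- 40
  X <- rbind(A = 0.5 + (1:T_) * 1.0, B = 0.5 + (1:T_) * 2.5,
             C = 0.5 + (1:T_) * 5.0)
  p_div <- panel_series(X, value_scale = "log")
  # brute-force oracle: every pair and the triple fail the test
  combos <- list(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "B", "C"))
  for (u in combos) {
    t_u <- logt_regression(subset_units(p_div, u))$t_gamma
    expect_lt(t_u, -1.65)
  }
  expect_length(form_core(p_div), 0)
})

test_that("sieve_members honors the criterion limits", {
  sim <- simulate_panel(three_club_spec(seed = 9))
  ordering <- order_units(sim$panel)
  core <- form_core(sim$panel, ordering)
  cands <- setdiff(ordering, core)

  # +Inf criterion admits nobody; -Inf admits everybody
  expect_identical(
    sieve_members(sim$panel, core, cands, c_star = Inf, critical = -Inf),
    core)
  expect_setequal(
    sieve_members(sim$panel, core, cands, c_star = -Inf, critical = Inf)[
      seq_along(core)], core)
  all_in <- sieve_members(sim$panel, core, cands, c_star = -Inf,
                          critical = -Inf)
  expect_setequal(all_in, sim$panel$units)

  # at the default criterion the sieve completes the top planted club
  club1 <- sim$partition$clubs[[1]]
  got <- sieve_members(sim$panel, core, cands)
  expect_setequal(got, club1)
})

test_that("club_cluster recovers planted structures", {
  # three planted clubs, no divergent units
  sim <- simulate_panel(three_club_spec(seed = 17))
  part <- club_cluster(sim$panel)
  expect_s3_class(part, "club_partition")
  expect_equal(part$stage, "initial")
  expect_length(part$clubs, 3)
  expect_length(part$divergent$members, 0)
  expect_true(partitions_equal(part, sim$partition))

  # single convergent process: one club with every unit
  sim1 <- simulate_panel(dgp_spec(delta = rep(2, 10), T_len = 60,
                                  theta = 0.05, a = 0.75, seed = 18))
  part1 <- club_cluster(sim1$panel)
  expect_length(part1$clubs, 1)
  expect_setequal(part1$clubs[[1]]$members, sim1$panel$units)

  # a planted drifting unit ends up divergent
  simd <- simulate_panel(dgp_spec(
    delta = c(rep(1, 5), rep(2, 5), DIV = 3), T_len = 60, theta = 0.03,
    a = 0.75, divergent = c(DIV = 4), seed = 19))
  partd <- club_cluster(simd$panel)
  expect_true("DIV" %in% partd$divergent$members)
})

test_that("every emitted club of size >= 2 passes the log-t test", {
  for (s in c(31, 32, 33)) {
    sim <- simulate_panel(three_club_spec(seed = s))
    part <- merge_clubs(sim$panel, club_cluster(sim$panel))
    for (cl in part$clubs) {
      if (length(cl$members) < 2) next
      t_check <- logt_regression(
        subset_units(sim$panel, cl$members))$t_gamma
      expect_gt(t_check, -1.65)
      expect_equal(cl$test$t_gamma, t_check, tolerance = 1e-12)
    }
  }
})

test_that("merge_clubs reunites split clubs and is idempotent", {
  # one true club artificially split into two adjacent fragments
  sim <- simulate_panel(dgp_spec(delta = rep(1, 12), T_len = 60,
                                 theta = 0.05, a = 0.75, seed = 41))
  ordering <- order_units(sim$panel)
  split2 <- club_partition(
    clubs = list(list(members = ordering[1:6]),
                 list(members = ordering[7:12])),
    divergent = list(members = character(0), test = NULL),
    units = sim$panel$units, stage = "initial")
  merged <- merge_clubs(sim$panel, split2)
  expect_length(merged$clubs, 1)
  expect_equal(merged$stage, "final")

  # chain merge: three fragments collapse transitively via restart
  split3 <- club_partition(
    clubs = list(list(members = ordering[1:4]),
                 list(members = ordering[5:8]),
                 list(members = ordering[9:12])),
    divergent = list(members = character(0), test = NULL),
    units = sim$panel$units, stage = "initial")
  merged3 <- merge_clubs(sim$panel, split3)
  expect_length(merged3$clubs, 1)

  # well-separated clubs do not merge; union fails by direct check
  sim2 <- simulate_panel(dgp_spec(delta = rep(c(4, 1), each = 5),
                                  T_len = 60, theta = 0.01, a = 0.75,
                                  seed = 42))
  part2 <- club_cluster(sim2$panel)
  expect_length(part2$clubs, 2)
  union_t <- logt_regression(sim2$panel)$t_gamma
  expect_lt(union_t, -1.65)
  final2 <- merge_clubs(sim2$panel, part2)
  expect_length(final2$clubs, 2)
  expect_identical(lapply(final2$clubs, `[[`, "members"),
                   lapply(part2$clubs, `[[`, "members"))

  # idempotence on a final partition
  again <- merge_clubs(sim2$panel, final2)
  expect_identical(lapply(again$clubs, `[[`, "members"),
                   lapply(final2$clubs, `[[`, "members"))
})

test_that("output is always a disjoint cover and divergent is preserved", {
  set.seed(55)
  for (i in 1:10) {
    N <- sample(6:14, 1)
    deltas <- sample(c(1, 2, 4), N, replace = TRUE)
    sim <- simulate_panel(dgp_spec(delta = deltas, T_len = 30,
                                   theta = 0.08, a = 0.5,
                                   seed = 200 + i))
    part <- club_cluster(sim$panel)
    final <- merge_clubs(sim$panel, part)
    for (pp in list(part, final)) {
      members <- c(unlist(lapply(pp$clubs, `[[`, "members")),
                   pp$divergent$members)
      expect_setequal(members, sim$panel$units)
      expect_equal(anyDuplicated(members), 0L)
    }
    expect_identical(final$divergent$members, part$divergent$members)
  }
})

test_that("clustering is invariant to unit relabeling/reordering", {
  sim <- simulate_panel(three_club_spec(seed = 77))
  p <- sim$panel
  part <- merge_clubs(p, club_cluster(p))

  set.seed(1)
  perm <- sample(length(p$units))
  p_perm <- panel_series(p$values[perm, , drop = FALSE],
                         value_scale = "log")
  part_perm <- merge_clubs(p_perm, club_cluster(p_perm))

  key <- function(pp) sort(vapply(pp$clubs, function(cl)
    paste(sort(cl$members), collapse = "|"), character(1)))
  expect_identical(key(part), key(part_perm))
  expect_setequal(part$divergent$members, part_perm$divergent$members)
})

test_that("club_report and JSON serialization mirror the partition", {
  sim <- simulate_panel(three_club_spec(seed = 91))
  part <- merge_clubs(sim$panel, club_cluster(sim$panel))
  rep_ <- club_report(part)
  expect_equal(nrow(rep_), length(part$clubs))
  expect_equal(rep_$size[1], length(part$clubs[[1]]$members))
  expect_true(all(rep_$t_stat[rep_$size >= 2] > -1.65))

  js <- jsonlite::fromJSON(partition_to_json(part),
                           simplifyVector = FALSE)
  expect_equal(js$stage, "final")
  expect_length(js$clubs, length(part$clubs))
})
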