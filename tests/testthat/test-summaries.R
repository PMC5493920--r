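# All expected numbers in this file are hand-enumerated on the six-node
# toy built in helper-oracles.R: two groups, three intensity categories,
# two steps, node 5 absent at step 2, node 3 switching group 1 -> 2.

test_that("connectivity tables match hand counts on the toy", {
  toy <- summary_toy()
  tab <- connectivity_summary(toy$net, toy$z)
  cell <- function(q, l, t) tab[tab$q == q & tab$l == l & tab$t == t, ]

  # step 1: groups {1,2,3} and {4,5,6}
  c11 <- cell(1, 1, 1)
  expect_equal(c11$n_possible, 3)
  expect_equal(c11$prop_absent, 0)
  expect_equal(unlist(c11[paste0("prop_cat_", 1:3)], use.names = FALSE),
               c(1, 1, 1) / 3)
  c22 <- cell(2, 2, 1)
  expect_equal(c22$n_possible, 3)
  expect_equal(c22$prop_absent, 1 / 3)
  expect_equal(unlist(c22[paste0("prop_cat_", 1:3)], use.names = FALSE),
               c(0.5, 0.5, 0))
  c12 <- cell(1, 2, 1)
  expect_equal(c12$n_possible, 9)
  expect_equal(c12$prop_absent, 7 / 9)
  expect_equal(unlist(c12[paste0("prop_cat_", 1:3)], use.names = FALSE),
               c(0.5, 0, 0.5))

  # step 2: groups {1,2} and {3,4,6}, node 5 absent
  c11 <- cell(1, 1, 2)
  expect_equal(c11$n_possible, 1)
  expect_equal(c11$prop_absent, 0)
  expect_equal(unlist(c11[paste0("prop_cat_", 1:3)], use.names = FALSE),
               c(0, 1, 0))
  c22 <- cell(2, 2, 2)
  expect_equal(c22$n_possible, 3)
  expect_equal(c22$prop_absent, 1 / 3)
  expect_equal(unlist(c22[paste0("prop_cat_", 1:3)], use.names = FALSE),
               c(0.5, 0.5, 0))
  c12 <- cell(1, 2, 2)
  expect_equal(c12$n_possible, 6)
  expect_equal(c12$prop_absent, 4 / 6)
  expect_equal(unlist(c12[paste0("prop_cat_", 1:3)], use.names = FALSE),
               c(0.5, 0, 0.5))

  # undirected symmetry
  for (t in 1:2) {
    expect_equal(unname(unlist(cell(2, 1, t)[-(1:2)])),
                 unname(unlist(cell(1, 2, t)[-(1:2)])))
  }

  # dyad counts sum to the number of observable dyads per step
  totals <- tapply(tab$n_possible[tab$q <= tab$l], tab$t[tab$q <= tab$l], sum)
  expect_equal(as.vector(totals), c(choose(6, 2), choose(5, 2)))
})

test_that("alluvial flows match hand counts and marginal invariants", {
  toy <- summary_toy()
  fl <- alluvial_flows(toy$z)
  get <- function(from, to) fl$count[fl$from == from & fl$to == to]
  expect_equal(get(1, 1), 2)   # nodes 1, 2
  expect_equal(get(1, 2), 1)   # node 3
  expect_equal(get(2, 2), 2)   # nodes 4, 6
  expect_equal(get(2, 0), 1)   # node 5 leaves
  expect_equal(sum(fl$count), 6)

  # row sums = group sizes at t, column sums = group sizes at t + 1
  rs <- tapply(fl$count, fl$from, sum)
  expect_equal(as.vector(rs[c("0", "1", "2")]), c(0, 3, 3))
  cs <- tapply(fl$count, fl$to, sum)
  expect_equal(as.vector(cs[c("0", "1", "2")]), c(1, 2, 3))

  # toy from a 3-node two-step trajectory
  z3 <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L))
  fl3 <- alluvial_flows(z3)
  expect_equal(fl3$count[fl3$from == 1 & fl3$to == 1], 1)
  expect_equal(fl3$count[fl3$from == 1 & fl3$to == 2], 1)
  expect_equal(fl3$count[fl3$from == 2 & fl3$to == 2], 1)

  # constant memberships: diagonal flows only
  zc <- matrix(rep(c(1L, 2L, 2L), 3), 3, 3)
  flc <- alluvial_flows(zc)
  expect_true(all(flc$count[flc$from != flc$to] == 0))
})

test_that("stability statistics match hand counts and are label-invariant", {
  toy <- summary_toy()
  st <- stability_stats(toy$z)
  expect_equal(st$fraction_never_switching, 5 / 6)
  n3 <- st$per_node[st$per_node$node == "n3", ]
  expect_equal(n3$modal_group, 1L)        # tie {1, 2} -> lowest group
  expect_equal(n3$occupancy, 0.5)
  expect_equal(n3$n_switches, 1L)
  n5 <- st$per_node[st$per_node$node == "n5", ]
  expect_true(n5$never_switched)          # single present step
  expect_equal(n5$occupancy_steps, 1L)

  expect_equal(stability_stats(matrix(1L, 4, 3))$fraction_never_switching, 1)
  z3 <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L))
  expect_equal(stability_stats(z3)$fraction_never_switching, 2 / 3)

  # relabelling invariance
  relab <- toy$z
  relab[toy$z == 1L] <- 2L
  relab[toy$z == 2L] <- 1L
  rownames(relab) <- rownames(toy$z)
  expect_equal(stability_stats(relab)$fraction_never_switching, 5 / 6)

  # identity chain in simulation: nobody ever switches
  p <- dynsbm_params(c(0.5, 0.5), diag(2), matrix(0.5, 2, 2), n_steps = 4)
  z <- simulate_memberships(p, matrix(1L, 30, 4), seed = 2)
  expect_equal(stability_stats(z)$fraction_never_switching, 1)
})

test_that("contingency tables apply the occupancy filter", {
  toy <- summary_toy()
  labels <- c(n1 = "A", n2 = "A", n3 = "A", n4 = "B", n5 = "B", n6 = "B")
  tab <- cross_tabulate(toy$z, labels, min_occupancy_steps = 2L)
  # nodes 3 and 5 drop (modal occupancy 1 step); the rest align perfectly
  expect_equal(as.integer(tab[cbind(c("1", "2"), c("A", "B"))]), c(2L, 2L))
  expect_equal(sum(tab), 4L)

  # filter beyond T empties the table
  expect_equal(sum(cross_tabulate(toy$z, labels, 3L)), 0L)
  # unlabelled nodes are ignored
  tab2 <- cross_tabulate(toy$z, labels[c("n1", "n4")], 1L)
  expect_equal(sum(tab2), 2L)
})

test_that("empty group-pair cells report NA proportions, not zeros", {
  z <- rbind(c(1L, 1L), c(1L, 1L), c(2L, 1L))
  v <- array(0L, c(3, 3, 2))
  v[1, 2, 1] <- v[2, 1, 1] <- 1L
  net <- dynamic_network(v, n_categories = 1L)
  tab <- connectivity_summary(net, z)
  c22_t2 <- tab[tab$q == 2 & tab$l == 2 & tab$t == 2, ]
  expect_equal(c22_t2$n_possible, 0)
  expect_true(is.na(c22_t2$prop_absent))
  expect_true(is.na(c22_t2$prop_cat_1))
})
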