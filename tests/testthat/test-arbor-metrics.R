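path_tree <- function() {
  # unbranched 4-node path along +x
  arbor_tree(data.frame(
    id = 1:4, type = 2, x = 0:3, y = 0, z = 0, radius = 0.5,
    parent = c(-1, 1, 2, 3)
  ))
}

test_that("branch orders: unbranched path is all shaft", {
  ord <- assign_branch_orders(path_tree())
  expect_equal(unname(ord$node_order), rep(0L, 4))
  expect_equal(nrow(ord$branches), 0)
})

test_that("branch orders: side branches and daughters get increasing orders", {
  # shaft 1-2-3-4 along x; two side branches at nodes 2 and 3; the branch
  # at node 2 bears a daughter
  nodes <- data.frame(
    id = 1:9, type = 2,
    x = c(0, 10, 20, 30, 10, 10, 13, 13, 25),
    y = c(0, 0, 0, 0, 5, 10, 12, 8, -4),
    z = 0, radius = 0.5,
    parent = c(-1, 1, 2, 3, 2, 5, 6, 6, 3)
  )
  # node 5-6 is the primary off node 2; at node 6 it continues to 7
  # (smaller turn) and sprouts daughter 8; node 9 is a primary off node 3
  tree <- arbor_tree(nodes)
  ord <- assign_branch_orders(tree)
  counts <- table(ord$branches$order)
  expect_equal(unname(counts[["1"]]), 2)
  expect_equal(unname(counts[["2"]]), 1)
  expect_equal(unname(ord$node_order[c("1", "2", "3", "4")]), rep(0L, 4))
})

test_that("branch orders recover the generator's ground truth exactly", {
  for (cfg in list(c(3, 2, 1), c(5, 4, 0), c(1, 0, 0), c(4, 8, 5))) {
    gen <- make_arbor(cfg[1], cfg[2], cfg[3], seed = sum(cfg) + 7)
    ord <- assign_branch_orders(gen$tree)
    counts <- table(factor(ord$branches$order, levels = 1:3))
    expect_equal(unname(as.integer(counts)), cfg)
  }
})

test_that("branch lengths sum segment lengths, excluding daughters", {
  # one branch of 3 collinear 1-um segments off a shaft
  nodes <- data.frame(
    id = 1:6, type = 2,
    x = c(0, 5, 10, 5, 5, 5),
    y = c(0, 0, 0, 1, 2, 3),
    z = 0, radius = 0.5,
    parent = c(-1, 1, 2, 2, 4, 5)
  )
  ord <- assign_branch_orders(arbor_tree(nodes))
  bl <- branch_lengths(ord)
  expect_equal(bl$total_length, 3)
  expect_equal(bl$per_branch$length_um, 3)

  bare <- assign_branch_orders(path_tree())
  expect_equal(branch_lengths(bare)$total_length, 0)

  gen <- make_arbor(4, 3, 2, mean_branch_len = 15, seed = 33)
  got <- branch_lengths(assign_branch_orders(gen$tree))$total_length
  expect_equal(got, gen$ground_truth$parameters$total_length,
               tolerance = 1e-6 / got)
})

test_that("ACI is the count-weighted mean branch order", {
  for (n in c(1, 3, 10)) {
    expect_equal(aci(setNames(n, "1")), 1.0)
  }
  expect_equal(aci(c("1" = 2, "2" = 2)), 1.5)
  expect_equal(aci(c("1" = 4, "2" = 3, "3" = 2)), 16 / 9)
  expect_warning(out <- aci(c("1" = 0)), "no branches")
  expect_true(is.na(out))
})

test_that("ACI is invariant to branch lengths and node relabeling", {
  gen <- make_arbor(3, 2, 1, seed = 41)
  a0 <- aci(assign_branch_orders(gen$tree))

  # scaling all coordinates changes lengths, not the ACI
  scaled <- gen$tree$nodes
  scaled[, c("x", "y", "z")] <- scaled[, c("x", "y", "z")] * 7.3
  expect_equal(aci(assign_branch_orders(arbor_tree(scaled))), a0)

  # permuting node ids leaves the ACI unchanged
  nd <- gen$tree$nodes
  set.seed(1)
  perm <- sample(nrow(nd) * 2, nrow(nd))   # new sparse ids
  map <- setNames(perm, nd$id)
  nd$id <- unname(map[as.character(nd$id)])
  nd$parent <- ifelse(nd$parent == -1, -1,
                      unname(map[as.character(nd$parent)]))
  nd <- nd[sample(nrow(nd)), ]
  expect_equal(aci(assign_branch_orders(arbor_tree(nd))), a0)
})

test_that("ACI obeys its ordering properties", {
  # adding one branch of order k+1 > ACI strictly increases the ACI
  counts <- c("1" = 4, "2" = 3)
  a <- aci(counts)
  expect_gt(aci(c("1" = 4, "2" = 3, "3" = 1)), a)
  # bounds: 1 <= ACI <= max order present
  set.seed(17)
  for (i in 1:20) {
    cnt <- setNames(rpois(3, 3) + c(1, 0, 0), 1:3)
    val <- aci(cnt)
    expect_gte(val, 1)
    expect_lte(val, max(as.numeric(names(cnt))[cnt > 0]))
  }
})

test_that("identical groups show no group effect", {
  set.seed(3)
  g <- do.call(rbind, lapply(1:6, function(i) {
    arbor_metrics(make_arbor(3 + i %% 2, 2, 1, seed = i)$tree)
  }))
  cmp <- arbor_group_compare(g, g)
  expect_equal(unname(cmp$anova_table["group"]), 1, tolerance = 1e-9)
  expect_equal(cmp$total_branches_p, 1, tolerance = 1e-9)
  expect_equal(cmp$total_length_p, 1, tolerance = 1e-9)
  expect_equal(cmp$aci_fisher_p, 1, tolerance = 1e-9)
})

test_that("a 56% branch-count reduction is detected (Monte Carlo)", {
  set.seed(55)
  lambda_ctrl <- c(8, 4, 2)
  hits <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    mk <- function(lams) {
      data.frame(
        n_order1 = rpois(25, lams[1]),
        n_order2 = rpois(25, lams[2]),
        n_order3 = rpois(25, lams[3])
      )
    }
    ctrl <- mk(lambda_ctrl)
    mo <- mk(lambda_ctrl * 0.44)
    ctrl$total_branches <- rowSums(ctrl); mo$total_branches <- rowSums(mo)
    ctrl$total_length <- ctrl$total_branches * 20
    mo$total_length <- mo$total_branches * 20
    ctrl$aci <- 1.5; mo$aci <- 1.5
    p <- suppressWarnings(
      arbor_group_compare(ctrl, mo)$anova_table["group"]
    )
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("single-order comparison reduces to the t-test identity F = t^2", {
  set.seed(77)
  ctrl <- data.frame(n_order1 = rpois(12, 6))
  trt <- data.frame(n_order1 = rpois(12, 4))
  ctrl$total_branches <- ctrl$n_order1; trt$total_branches <- trt$n_order1
  ctrl$total_length <- ctrl$n_order1 * 20; trt$total_length <- trt$n_order1 * 20
  ctrl$aci <- 1; trt$aci <- 1
  cmp <- suppressWarnings(arbor_group_compare(ctrl, trt))
  tt <- t.test(ctrl$n_order1, trt$n_order1, var.equal = TRUE)
  long <- data.frame(
    g = rep(c("a", "b"), each = 12),
    count = c(ctrl$n_order1, trt$n_order1)
  )
  Fval <- summary(aov(count ~ g, long))[[1]]$`F value`[1]
  expect_equal(Fval, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(unname(cmp$anova_table["group"]), tt$p.value, tolerance = 1e-9)
})
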