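# Internal: adjacency and coordinates keyed by node id.
tree_index <- function(tree) {
  nd <- tree$nodes
  idx <- stats::setNames(seq_len(nrow(nd)), nd$id)
  children <- split(nd$id[nd$parent != -1], nd$parent[nd$parent != -1])
  list(nodes = nd, idx = idx, children = children)
}

node_xyz <- function(ti, id) {
  r <- ti$nodes[ti$idx[as.character(id)], ]
  c(r$x, r$y, r$z)
}

seg_len <- function(ti, a, b) vnorm(node_xyz(ti, a) - node_xyz(ti, b))

# Longest root-to-leaf path (Euclidean length), returned as a node-id path.
longest_root_path <- function(ti, root) {
  best <- list(len = -1, path = integer(0))
  stack <- list(list(id = root, len = 0, path = root))
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    kids <- ti$children[[as.character(cur$id)]]
    if (is.null(kids) || !length(kids)) {
      if (cur$len > best$len) best <- list(len = cur$len, path = cur$path)
      next
    }
    for (k in kids) {
      stack[[length(stack) + 1L]] <- list(
        id = k, len = cur$len + seg_len(ti, cur$id, k),
        path = c(cur$path, k)
      )
    }
  }
  best$path
}

#' Assign branch orders to an arbor tree
#'
#' The axon shaft (order 0) is the root-to-terminal path; by default the
#' longest root-to-leaf path, overridable via `shaft_leaf` (the paper
#' traces the shaft manually). Every branch sprouting from the shaft is
#' primary (order 1); a branch sprouting from an order-k branch is order
#' k+1. At a bifurcation inside a branch, the continuation of the current
#' branch is the child most collinear with the incoming direction; the
#' other children start daughter branches.
#'
#' @param tree an [arbor_tree].
#' @param shaft_leaf optional node id of the shaft terminal.
#' @return object of class `arbor_orders`: list with `tree`, `shaft_path`
#'   (node ids), `branches` (data.frame `branch_id, order, attach_id,
#'   tip_id, length_um, n_nodes`) and `node_order` (named vector, order of
#'   each node; shaft nodes are 0).
#' @export
assign_branch_orders <- function(tree, shaft_leaf = NULL) {
  stopifnot(inherits(tree, "arbor_tree"))
  ti <- tree_index(tree)
  root <- tree$root
  if (is.null(shaft_leaf)) {
    shaft <- longest_root_path(ti, root)
  } else {
    # walk up from the designated leaf
    shaft <- shaft_leaf
    cur <- shaft_leaf
    while (cur != root) {
      cur <- ti$nodes$parent[ti$idx[as.character(cur)]]
      shaft <- c(cur, shaft)
    }
  }
  node_order <- stats::setNames(rep(NA_integer_, nrow(ti$nodes)),
                                ti$nodes$id)
  node_order[as.character(shaft)] <- 0L

  branches <- data.frame(
    branch_id = integer(0), order = integer(0), attach_id = integer(0),
    tip_id = integer(0), length_um = numeric(0), n_nodes = integer(0)
  )

  # queue of branches to trace: attach node, first node, order
  queue <- list()
  on_shaft <- function(id) id %in% shaft
  for (i in seq_along(shaft)) {
    kids <- ti$children[[as.character(shaft[i])]]
    nxt <- if (i < length(shaft)) shaft[i + 1L] else NA_integer_
    for (k in setdiff(kids, nxt)) {
      queue[[length(queue) + 1L]] <- list(
        attach = shaft[i], first = k, order = 1L
      )
    }
  }

  bid <- 0L
  while (length(queue)) {
    job <- queue[[1L]]
    queue[[1L]] <- NULL
    bid <- bid + 1L
    prev <- job$attach
    cur <- job$first
    len <- seg_len(ti, prev, cur)
    n_nodes <- 1L
    node_order[as.character(cur)] <- job$order
    repeat {
      kids <- ti$children[[as.character(cur)]]
      if (is.null(kids) || !length(kids)) break
      if (length(kids) == 1L) {
        cont <- kids
      } else {
        v_in <- normalize(node_xyz(ti, cur) - node_xyz(ti, prev))
        ang <- vapply(kids, function(k) {
          v_out <- normalize(node_xyz(ti, k) - node_xyz(ti, cur))
          acos(pmin(pmax(sum(v_in * v_out), -1), 1))
        }, numeric(1))
        cont <- kids[which.min(ang)]
        for (k in setdiff(kids, cont)) {
          queue[[length(queue) + 1L]] <- list(
            attach = cur, first = k, order = job$order + 1L
          )
        }
      }
      len <- len + seg_len(ti, cur, cont)
      prev <- cur
      cur <- cont
      n_nodes <- n_nodes + 1L
      node_order[as.character(cur)] <- job$order
    }
    branches[nrow(branches) + 1L, ] <- list(
      bid, job$order, job$attach, cur, len, n_nodes
    )
  }

  structure(
    list(tree = tree, shaft_path = shaft, branches = branches,
         node_order = node_order),
    class = "arbor_orders"
  )
}

#' Per-branch lengths and totals
#'
#' Branch length is the summed Euclidean segment length from the sprout
#' point on the parent branch to the branch terminal, excluding daughter
#' sub-branches. Totals are over branches of order >= 1.
#'
#' @param orders an `arbor_orders` object from [assign_branch_orders].
#' @return list with `per_branch` (data.frame), `total_length` and
#'   `mean_branch_length` (um).
#' @export
branch_lengths <- function(orders) {
  stopifnot(inherits(orders, "arbor_orders"))
  b <- orders$branches
  list(
    per_branch = b[, c("branch_id", "order", "length_um")],
    total_length = sum(b$length_um),
    mean_branch_length = if (nrow(b)) mean(b$length_um) else NA_real_
  )
}

#' Axon complexity index (ACI)
#'
#' The branch-count-weighted mean branch order,
#' `ACI = sum_k(k * N_k) / sum_k(N_k)` over orders k >= 1. It is 1 for an
#' arbor with only primary branches and grows as branching becomes more
#' nested; it is invariant to branch lengths. Undefined (NA, with a
#' warning) for an unbranched shaft. This count-weighted-mean-order
#' formulation is recorded in output metadata by the pipeline.
#'
#' @param x an `arbor_orders` object, or a named numeric vector / table of
#'   counts per order (names = order).
#' @return the ACI (>= 1), or `NA` for zero branches.
#' @export
aci <- function(x) {
  if (inherits(x, "arbor_orders")) {
    counts <- table(x$branches$order)
  } else if (!is.null(names(x))) {
    counts <- x
  } else {
    stop("aci() needs an arbor_orders object or named counts per order")
  }
  ks <- as.numeric(names(counts))
  ns <- as.numeric(counts)
  keep <- ks >= 1 & ns > 0
  ks <- ks[keep]; ns <- ns[keep]
  if (!length(ns) || sum(ns) == 0) {
    warning("ACI undefined: arbor has no branches")
    return(NA_real_)
  }
  sum(ks * ns) / sum(ns)
}

#' All arbor metrics for one tree
#'
#' @param tree an [arbor_tree].
#' @param max_order number of order columns to report (default 3).
#' @param ... passed to [assign_branch_orders].
#' @return one-row `data.frame` with counts per order, total branches,
#'   total and mean branch length, and ACI.
#' @export
arbor_metrics <- function(tree, max_order = 3, ...) {
  ord <- assign_branch_orders(tree, ...)
  bl <- branch_lengths(ord)
  counts <- table(factor(ord$branches$order, levels = seq_len(max_order)))
  out <- as.data.frame(as.list(stats::setNames(
    as.integer(counts), paste0("n_order", seq_len(max_order))
  )))
  out$total_branches <- nrow(ord$branches)
  out$total_length <- bl$total_length
  out$mean_branch_length <- bl$mean_branch_length
  out$aci <- if (out$total_branches > 0) aci(ord) else NA_real_
  out
}

#' Compare arbor metrics between two groups
#'
#' Branch counts are compared by a two-way ANOVA with factors group and
#' branch order (interaction included), total branch numbers and total
#' lengths by unpaired t-tests, and the ACI distribution by Fisher's exact
#' test after binning at a threshold (default: the median ACI of the
#' first, control, group).
#'
#' @param control,treated data.frames of per-axon metrics as returned by
#'   [arbor_metrics] (one row per axon).
#' @param aci_threshold optional ACI bin edge; default median of control.
#' @return list with `anova_table` (group, order, interaction p-values),
#'   `total_branches_p`, `total_length_p`, `aci_fisher_p`, and
#'   `aci_threshold`.
#' @export
arbor_group_compare <- function(control, treated, aci_threshold = NULL) {
  if (nrow(control) < 2 || nrow(treated) < 2) {
    stop("each group needs at least 2 axons")
  }
  order_cols <- grep("^n_order", names(control), value = TRUE)
  mk_long <- function(df, g) {
    do.call(rbind, lapply(order_cols, function(cl) {
      data.frame(
        group = g, order = sub("^n_order", "", cl),
        count = df[[cl]]
      )
    }))
  }
  long <- rbind(mk_long(control, "control"), mk_long(treated, "treated"))
  long$group <- factor(long$group)
  long$order <- factor(long$order)
  if (nlevels(long$order) >= 2) {
    fit <- stats::aov(count ~ group * order, data = long)
    an <- summary(fit)[[1]]
    pvals <- stats::setNames(
      an[["Pr(>F)"]][seq_len(3)],
      c("group", "order", "group_x_order")
    )
  } else {
    # single-order data: the two-way layout degenerates to one-way
    fit <- stats::aov(count ~ group, data = long)
    an <- summary(fit)[[1]]
    pvals <- c(group = an[["Pr(>F)"]][1], order = NA_real_,
               group_x_order = NA_real_)
  }

  tb_p <- stats::t.test(control$total_branches, treated$total_branches,
                        var.equal = TRUE)$p.value
  tl_p <- stats::t.test(control$total_length, treated$total_length,
                        var.equal = TRUE)$p.value

  if (is.null(aci_threshold)) {
    aci_threshold <- stats::median(control$aci, na.rm = TRUE)
  }
  bin <- function(a) factor(a >= aci_threshold, levels = c(FALSE, TRUE))
  tab <- rbind(table(bin(control$aci)), table(bin(treated$aci)))
  aci_p <- stats::fisher.test(tab)$p.value

  list(
    anova_table = pvals,
    total_branches_p = tb_p,
    total_length_p = tl_p,
    aci_fisher_p = aci_p,
    aci_threshold = aci_threshold
  )
}
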