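#' Arbor tree
#'
#' A rooted tree of 2-D/3-D points with parent links, in SWC column
#' convention (`id, type, x, y, z, radius, parent`; root parent = -1).
#'
#' @param nodes data.frame with columns `id, type, x, y, z, radius,
#'   parent`.
#' @return object of class `arbor_tree`.
#' @export
arbor_tree <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  miss <- setdiff(need, names(nodes))
  if (length(miss)) stop("nodes missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  roots <- nodes$id[nodes$parent == -1]
  if (length(roots) != 1) stop("tree must have exactly one root")
  if (!all(nodes$parent %in% c(-1, nodes$id))) {
    stop("parent links reference unknown node ids")
  }
  # reachability from root (also rejects cycles among non-root nodes)
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  reached <- rep(FALSE, nrow(nodes))
  reached[idx[as.character(roots)]] <- TRUE
  repeat {
    newly <- !reached & reached[idx[as.character(nodes$parent)]]
    newly[is.na(newly)] <- FALSE
    if (!any(newly)) break
    reached <- reached | newly
  }
  if (!all(reached)) stop("tree contains nodes unreachable from the root")
  structure(list(nodes = nodes, root = roots), class = "arbor_tree")
}

#' @export
print.arbor_tree <- function(x, ...) {
  cat(sprintf(
    "<arbor_tree> %d nodes, root id %d\n", nrow(x$nodes), x$root
  ))
  invisible(x)
}

#' Simulate a rooted axon arbor with known branch orders
#'
#' Builds an arbor whose shaft (order 0) runs straight along +x and whose
#' branch counts per order equal the requested counts exactly. Branch
#' lengths are drawn from an exponential distribution with the stated
#' mean. Daughter branches sprout from interior nodes of their parent at
#' a 70-degree angle (alternating sides) so that branch continuations are
#' unambiguous; the shaft length is set after the branch lengths are drawn
#' so that the shaft is guaranteed to be the longest root-to-leaf path.
#'
#' @param n_primary,n_secondary,n_tertiary branch counts per order.
#' @param mean_branch_len mean branch length (um), > 0.
#' @param seed integer RNG seed.
#' @return list with `tree` (an [arbor_tree]) and `ground_truth`
#'   (counts per order, per-branch and total lengths, and the implied
#'   axon complexity index, `NA` for a bare shaft).
#' @export
make_arbor <- function(n_primary, n_secondary = 0, n_tertiary = 0,
                       mean_branch_len = 20, seed = 1L) {
  if (n_primary < 0 || n_secondary < 0 || n_tertiary < 0) {
    stop("branch counts must be >= 0")
  }
  if (n_secondary > 0 && n_primary == 0) {
    stop("a secondary branch requires at least one primary")
  }
  if (n_tertiary > 0 && n_secondary == 0) {
    stop("a tertiary branch requires at least one secondary")
  }
  if (mean_branch_len <= 0) stop("mean_branch_len must be > 0")

  with_seed(seed, {
    counts <- c(n_primary, n_secondary, n_tertiary)
    n_branches <- sum(counts)
    lens <- if (n_branches > 0) {
      stats::rexp(n_branches, rate = 1 / mean_branch_len)
    } else {
      numeric(0)
    }
    orders <- rep(1:3, counts)

    # parent assignment: round-robin over branches of the previous order
    branch <- data.frame(
      bid = seq_len(n_branches), order = orders, length = lens,
      parent_bid = rep(NA_integer_, n_branches)
    )
    for (k in 2:3) {
      kids <- which(branch$order == k)
      if (!length(kids)) next
      parents <- which(branch$order == k - 1)
      branch$parent_bid[kids] <- parents[(seq_along(kids) - 1) %% length(parents) + 1]
    }

    nodes <- data.frame(
      id = integer(0), type = integer(0), x = numeric(0), y = numeric(0),
      z = numeric(0), radius = numeric(0), parent = integer(0)
    )
    next_id <- 0L
    add_node <- function(x, y, parent) {
      next_id <<- next_id + 1L
      nodes[nrow(nodes) + 1L, ] <<- list(next_id, 2L, x, y, 0, 0.5, parent)
      next_id
    }

    # shaft: straight along +x, long enough to dominate any branch chain
    shaft_len <- sum(lens) + 2 * mean_branch_len
    n_prim_slots <- max(n_primary, 1)
    root_id <- add_node(0, 0, -1L)
    shaft_attach <- integer(n_prim_slots)
    prev <- root_id
    for (i in seq_len(n_prim_slots)) {
      xx <- shaft_len * i / (n_prim_slots + 1)
      prev <- add_node(xx, 0, prev)
      shaft_attach[i] <- prev
    }
    add_node(shaft_len, 0, prev)  # shaft tip

    # grow branches order by order; record attach node, direction, and
    # interior nodes available for daughters
    branch$attach_node <- rep(NA_integer_, n_branches)
    branch$dir_deg <- rep(NA_real_, n_branches)
    branch_nodes <- vector("list", n_branches)
    daughters_of <- function(b) which(branch$parent_bid == b)

    grow_branch <- function(b, attach_id, parent_dir_deg, side) {
      L <- branch$length[b]
      dir_deg <- parent_dir_deg + side * 70
      nd <- daughters_of(b)
      n_seg <- length(nd) + 2L
      a <- nodes[nodes$id == attach_id, ]
      ux <- cos(deg2rad(dir_deg)); uy <- sin(deg2rad(dir_deg))
      prev <- attach_id
      interior <- integer(0)
      for (s in seq_len(n_seg)) {
        d <- L * s / n_seg
        prev <- add_node(a$x + d * ux, a$y + d * uy, prev)
        if (s < n_seg) interior <- c(interior, prev)
      }
      branch$attach_node[b] <<- attach_id
      branch$dir_deg[b] <<- dir_deg
      branch_nodes[[b]] <<- interior
      for (j in seq_along(nd)) {
        grow_branch(nd[j], interior[j], dir_deg, if (j %% 2) 1 else -1)
      }
    }

    prim <- which(branch$order == 1)
    for (i in seq_along(prim)) {
      grow_branch(prim[i], shaft_attach[i], 0, if (i %% 2) 1 else -1)
    }

    tree <- arbor_tree(nodes)
    counts_per_order <- stats::setNames(as.list(counts), paste0("order", 1:3))
    gt <- ground_truth("arbor", list(
      n_primary = n_primary, n_secondary = n_secondary,
      n_tertiary = n_tertiary,
      counts_per_order = counts_per_order,
      branch_lengths = lens,
      total_length = sum(lens),
      mean_branch_len_param = mean_branch_len,
      aci = if (n_branches > 0) sum(orders) / n_branches else NA_real_
    ), seed)
    list(tree = tree, ground_truth = gt)
  })
}
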