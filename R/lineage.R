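#' Population parameters for the tumor coalescent
#'
#' Bundles the parameters of the retrospective genealogy model. Time is
#' measured in coalescent units (population-size-scaled), so branch lengths
#' are later converted to expected event counts through a per-unit event
#' rate and no calendar-time calibration is needed.
#'
#' @param n tumor sample size (number of observed tumor cells), >= 1.
#' @param growth_rate exponential growth rate of the tumor population per
#'   coalescent time unit, >= 0. Backward in time the population size
#'   shrinks as `exp(-growth_rate * t)`, accelerating coalescence.
#' @param sweeps optional `data.frame` with columns `time` (> 0, coalescent
#'   units before the present) and `severity` (in (0, 1]): each selective
#'   sweep is modeled as an instantaneous bottleneck that multiplies the
#'   population size by `severity` at the sweep time, producing a burst of
#'   coalescences. A sweep older than the sample's TMRCA is silently inert.
#' @param n_normal number of normal diploid cells diluting the sample, >= 0.
#' @param n_pseudo_normal number of pseudo-normal (near-diploid, non-tumor)
#'   cells diluting the sample, >= 0.
#' @return an object of class `population_params`.
#' @export
population_params <- function(n, growth_rate = 0, sweeps = NULL,
                              n_normal = 0, n_pseudo_normal = 0) {
  check_that(is.numeric(n) && length(n) == 1L && n >= 1 && n == floor(n),
             "`n` must be a single integer >= 1")
  check_that(is.numeric(growth_rate) && length(growth_rate) == 1L &&
               growth_rate >= 0, "`growth_rate` must be a single number >= 0")
  if (!is.null(sweeps)) {
    check_that(is.data.frame(sweeps) &&
                 all(c("time", "severity") %in% names(sweeps)),
               "`sweeps` must be a data.frame with columns time, severity")
    check_that(all(sweeps$time > 0), "sweep times must be > 0")
    check_that(all(sweeps$severity > 0 & sweeps$severity <= 1),
               "sweep severities must be in (0, 1]")
    sweeps <- sweeps[order(sweeps$time), , drop = FALSE]
  }
  check_that(n_normal >= 0 && n_normal == floor(n_normal),
             "`n_normal` must be an integer >= 0")
  check_that(n_pseudo_normal >= 0 && n_pseudo_normal == floor(n_pseudo_normal),
             "`n_pseudo_normal` must be an integer >= 0")
  structure(list(n = as.integer(n), growth_rate = growth_rate,
                 sweeps = sweeps, n_normal = as.integer(n_normal),
                 n_pseudo_normal = as.integer(n_pseudo_normal)),
            class = "population_params")
}

new_lineage_tree <- function(nodes) {
  structure(list(nodes = nodes), class = "cell_lineage_tree")
}

#' @export
print.cell_lineage_tree <- function(x, ...) {
  nd <- x$nodes
  cat("cell lineage tree:", sum(nd$class == "tumor_leaf"), "tumor leaves,",
      sum(nd$class == "normal_leaf"), "normal,",
      sum(nd$class == "pseudo_normal_leaf"), "pseudo-normal;",
      nrow(nd), "nodes\n")
  invisible(x)
}

#' Simulate the tumor cell genealogy under the neutral coalescent
#'
#' Draws a binary timed genealogy of `params$n` sampled tumor cells. With
#' zero growth and no sweeps this is the standard Kingman coalescent: while
#' k lineages remain, pairwise mergers occur at rate k(k-1)/2 per coalescent
#' time unit. Exponential growth shrinks the population backward in time as
#' `exp(-growth_rate * t)`, and each sweep instantaneously multiplies the
#' population size by its severity, both of which accelerate coalescence.
#' Waiting times are drawn exactly by inverting the piecewise cumulative
#' coalescence hazard, so no time discretization is involved.
#'
#' The most recent common ancestor of the tumor sample is marked as the
#' tumor founder cell.
#'
#' @param params a [population_params()] object.
#' @return a `cell_lineage_tree`: a list with a `nodes` data.frame holding
#'   columns `id`, `parent` (NA at the root), `length` (branch length to
#'   the parent), `time` (node age, 0 at the leaves), `class` (one of
#'   `tumor_leaf`, `normal_leaf`, `pseudo_normal_leaf`, `ancestral`),
#'   `is_founder`, `subclone` (NA or subclone id).
#' @export
simulate_tumor_lineage <- function(params) {
  check_that(inherits(params, "population_params"),
             "`params` must be created with population_params()")
  n <- params$n
  alpha <- params$growth_rate
  sweeps <- params$sweeps
  n_sw <- if (is.null(sweeps)) 0L else nrow(sweeps)

  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  time <- numeric(n_nodes)
  active <- seq_len(n)
  next_id <- n + 1L
  t <- 0
  S <- 1       # cumulative bottleneck factor for sweeps already passed
  si <- 1L     # index of next unapplied sweep

  while (length(active) > 1L) {
    k <- length(active)
    rate0 <- k * (k - 1) / 2
    E <- stats::rexp(1)
    repeat {
      t_sw <- if (si <= n_sw) sweeps$time[si] else Inf
      if (alpha > 0) {
        # hazard over [t, t_sw): rate0 * exp(alpha*u) / S
        t_cand <- t + log1p(E * S * alpha * exp(-alpha * t) / rate0) / alpha
        if (t_cand <= t_sw) {
          t <- t_cand
          break
        }
        E <- E - rate0 / (S * alpha) * (exp(alpha * t_sw) - exp(alpha * t))
      } else {
        t_cand <- t + E * S / rate0
        if (t_cand <= t_sw) {
          t <- t_cand
          break
        }
        E <- E - rate0 * (t_sw - t) / S
      }
      t <- t_sw
      S <- S * sweeps$severity[si]
      si <- si + 1L
    }
    pair <- sample(length(active), 2L)
    a <- active[pair[1L]]
    b <- active[pair[2L]]
    parent[c(a, b)] <- next_id
    time[next_id] <- t
    active <- c(active[-pair], next_id)
    next_id <- next_id + 1L
  }

  cls <- c(rep("tumor_leaf", n), rep("ancestral", max(n_nodes - n, 0L)))
  root <- active[1L]
  len <- ifelse(is.na(parent), 0, time[parent] - time)
  nodes <- data.frame(id = seq_len(n_nodes), parent = parent,
                      length = len, time = time, class = cls,
                      is_founder = FALSE, subclone = NA_integer_,
                      stringsAsFactors = FALSE)
  nodes$is_founder[root] <- TRUE
  new_lineage_tree(nodes)
}

tree_root <- function(tree) tree$nodes$id[is.na(tree$nodes$parent)]

founder_id <- function(tree) tree$nodes$id[tree$nodes$is_founder]

children_map <- function(nodes) {
  split(nodes$id[!is.na(nodes$parent)], nodes$parent[!is.na(nodes$parent)])
}

# ids of all descendants of `id` (excluding id itself)
descendants_of <- function(nodes, id) {
  ch <- children_map(nodes)
  out <- integer(0)
  queue <- ch[[as.character(id)]]
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(ch[as.character(queue)], use.names = FALSE)
  }
  out
}

#' Attach outgroup normal and pseudo-normal cells
#'
#' Adds a stem of the given length above the tumor founder (the tumor MRCA)
#' and hangs `normal_count` normal and `pseudo_normal_count` pseudo-normal
#' leaves as outgroup branches from evenly spaced attachment points along
#' the stem. Normal leaves attach closest to the new root, pseudo-normal
#' leaves between the normals and the tumor founder; all leaves are
#' contemporaneous with the tumor sample (age 0). The tumor topology is
#' unchanged.
#'
#' @param tree a `cell_lineage_tree` with a marked tumor founder.
#' @param normal_count,pseudo_normal_count numbers of outgroup leaves (>= 0).
#' @param root_stem_length length of the stem added above the tumor MRCA,
#'   in coalescent units.
#' @return the augmented `cell_lineage_tree`.
#' @export
attach_outgroup_cells <- function(tree, normal_count, pseudo_normal_count,
                                  root_stem_length = 1) {
  check_that(normal_count >= 0 && pseudo_normal_count >= 0,
             "outgroup cell counts must be >= 0")
  check_that(root_stem_length >= 0, "`root_stem_length` must be >= 0")
  nodes <- tree$nodes
  fid <- founder_id(tree)
  check_that(length(fid) == 1L, "tree has no marked tumor founder")
  check_that(is.na(nodes$parent[nodes$id == fid]),
             "outgroup cells already attached")
  tmrca <- nodes$time[nodes$id == fid]
  m <- normal_count + pseudo_normal_count
  seg <- root_stem_length / (m + 1)
  next_id <- max(nodes$id) + 1L

  add_node <- function(df, id, parent, time, class) {
    rbind(df, data.frame(id = id, parent = parent, length = NA_real_,
                         time = time, class = class, is_founder = FALSE,
                         subclone = NA_integer_, stringsAsFactors = FALSE))
  }

  # chain of attachment nodes from the new root down to the founder
  new_root <- next_id
  nodes <- add_node(nodes, new_root, NA_integer_,
                    tmrca + root_stem_length, "ancestral")
  next_id <- next_id + 1L
  prev <- new_root
  if (m > 0) {
    classes <- c(rep("normal_leaf", normal_count),
                 rep("pseudo_normal_leaf", pseudo_normal_count))
    for (j in seq_len(m)) {
      att <- next_id
      att_time <- tmrca + root_stem_length - j * seg
      nodes <- add_node(nodes, att, prev, att_time, "ancestral")
      next_id <- next_id + 1L
      leaf <- next_id
      nodes <- add_node(nodes, leaf, att, 0, classes[j])
      next_id <- next_id + 1L
      prev <- att
    }
  }
  nodes$parent[nodes$id == fid] <- prev
  nodes$length <- ifelse(is.na(nodes$parent), 0,
                         nodes$time[match(nodes$parent, nodes$id)] - nodes$time)
  new_lineage_tree(nodes)
}

leaves_under <- function(nodes, id) {
  is_leaf <- !(nodes$id %in% nodes$parent[!is.na(nodes$parent)])
  dd <- descendants_of(nodes, id)
  dd[dd %in% nodes$id[is_leaf]]
}

#' Select subclone clades within the tumor lineage
#'
#' Marks `k` internal nodes of the tumor clade as subclone roots so that
#' their leaf sets are disjoint and each subtends at least `min_size` tumor
#' leaves. Selection is greedy-random: internal candidates are shuffled and
#' accepted while compatible, retried until a set of size `k` is found.
#' Feasibility is first verified exactly by dynamic programming over the
#' tumor clade, so an infeasible request fails immediately with the
#' achievable maximum.
#'
#' @param tree a `cell_lineage_tree`.
#' @param k number of subclones (>= 0).
#' @param min_size minimum number of tumor leaves per subclone (>= 1).
#' @return the tree with subclone ids 1..k set on the subclone root nodes
#'   and propagated to their descendant tumor leaves.
#' @export
select_subclones <- function(tree, k, min_size = 1) {
  check_that(k >= 0 && k == floor(k), "`k` must be an integer >= 0")
  check_that(min_size >= 1, "`min_size` must be >= 1")
  if (k == 0) return(tree)
  nodes <- tree$nodes
  fid <- founder_id(tree)
  tumor_nodes <- c(fid, descendants_of(nodes, fid))
  is_leaf <- !(nodes$id %in% nodes$parent[!is.na(nodes$parent)])
  ch <- children_map(nodes)

  n_leaves <- integer(max(nodes$id))
  # post-order leaf counts and DP for the max number of disjoint clades
  dp <- integer(max(nodes$id))
  post <- rev(bfs_order(nodes, fid))
  for (v in post) {
    if (is_leaf[nodes$id == v]) {
      n_leaves[v] <- 1L
      dp[v] <- 0L  # leaves are not candidate clades
    } else {
      kids <- ch[[as.character(v)]]
      n_leaves[v] <- sum(n_leaves[kids])
      child_sum <- sum(dp[kids])
      self_ok <- if (v == fid) 0L else as.integer(n_leaves[v] >= min_size)
      dp[v] <- max(self_ok, child_sum)
    }
  }
  max_k <- sum(dp[ch[[as.character(fid)]]])
  if (max_k < k) {
    stop(sprintf(
      "cannot select %d disjoint subclones of >= %d leaves; at most %d are possible",
      k, min_size, max_k), call. = FALSE)
  }

  candidates <- setdiff(tumor_nodes[!(tumor_nodes %in% nodes$id[is_leaf])], fid)
  candidates <- candidates[vapply(candidates,
                                  function(v) n_leaves[v] >= min_size,
                                  logical(1))]
  leafsets <- lapply(candidates, function(v) leaves_under(nodes, v))
  names(leafsets) <- as.character(candidates)

  for (attempt in seq_len(1000L)) {
    ordr <- sample(length(candidates))
    accepted <- integer(0)
    taken <- integer(0)
    for (i in ordr) {
      ls <- leafsets[[i]]
      if (!any(ls %in% taken)) {
        accepted <- c(accepted, candidates[i])
        taken <- c(taken, ls)
        if (length(accepted) == k) break
      }
    }
    if (length(accepted) == k) {
      for (j in seq_len(k)) {
        sc <- accepted[j]
        nodes$subclone[nodes$id == sc] <- j
        tl <- leafsets[[as.character(sc)]]
        nodes$subclone[nodes$id %in% tl & nodes$class == "tumor_leaf"] <- j
      }
      return(new_lineage_tree(nodes))
    }
  }
  stop("subclone selection did not converge despite feasibility; please report",
       call. = FALSE)
}

# breadth-first order of the subtree rooted at `root` (root first)
bfs_order <- function(nodes, root) {
  ch <- children_map(nodes)
  out <- integer(0)
  queue <- root
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    queue <- c(queue, ch[[as.character(v)]])
  }
  out
}

#' Leaf names and metadata
#'
#' Leaf names follow a fixed grammar: `tumor_0001` (with optional `_sc<k>`
#' suffix when the leaf belongs to subclone k), `normal_0001`,
#' `pseudonormal_0001`; numbering is by node id within each class.
#'
#' @param tree a `cell_lineage_tree`.
#' @return data.frame with columns `id`, `leaf`, `class`, `subclone`.
#' @export
leaf_metadata <- function(tree) {
  nodes <- tree$nodes
  is_leaf <- !(nodes$id %in% nodes$parent[!is.na(nodes$parent)])
  lf <- nodes[is_leaf, , drop = FALSE]
  lf <- lf[order(lf$id), , drop = FALSE]
  name <- character(nrow(lf))
  for (cl in unique(lf$class)) {
    sel <- lf$class == cl
    prefix <- switch(cl, tumor_leaf = "tumor", normal_leaf = "normal",
                     pseudo_normal_leaf = "pseudonormal", "node")
    name[sel] <- sprintf("%s_%04d", prefix, seq_len(sum(sel)))
  }
  sc <- !is.na(lf$subclone) & lf$class == "tumor_leaf"
  name[sc] <- sprintf("%s_sc%d", name[sc], lf$subclone[sc])
  data.frame(id = lf$id, leaf = name, class = lf$class,
             subclone = lf$subclone, stringsAsFactors = FALSE)
}

#' Serialize a cell lineage tree to newick
#'
#' @param tree a `cell_lineage_tree`.
#' @param file optional path; when given the newick string is written there.
#' @return the newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  nodes <- tree$nodes
  ch <- children_map(nodes)
  meta <- leaf_metadata(tree)
  lab <- stats::setNames(meta$leaf, meta$id)
  len <- stats::setNames(format_branch_length(nodes$length), nodes$id)

  build <- function(v) {
    kids <- ch[[as.character(v)]]
    if (is.null(kids)) {
      paste0(lab[[as.character(v)]], ":", len[[as.character(v)]])
    } else {
      inner <- paste(vapply(kids, build, character(1)), collapse = ",")
      if (is.na(nodes$parent[nodes$id == v])) {
        paste0("(", inner, ")")
      } else {
        paste0("(", inner, "):", len[[as.character(v)]])
      }
    }
  }
  root <- tree_root(tree)
  nwk <- if (length(ch[[as.character(root)]]) == 0L) {
    # degenerate single-leaf tree
    paste0(lab[[as.character(root)]], ":0.0")
  } else {
    build(root)
  }
  nwk <- paste0(nwk, ";")
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}

#' Time to the most recent common ancestor of the tumor sample
#' @param tree a `cell_lineage_tree`.
#' @return TMRCA in coalescent units.
#' @export
tumor_tmrca <- function(tree) {
  tree$nodes$time[tree$nodes$is_founder]
}

#' Total branch length of the tumor clade
#' @param tree a `cell_lineage_tree`.
#' @return sum of branch lengths below (and excluding the edge into) the
#'   tumor founder.
#' @export
tumor_total_length <- function(tree) {
  nodes <- tree$nodes
  dd <- descendants_of(nodes, founder_id(tree))
  sum(nodes$length[nodes$id %in% dd])
}
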