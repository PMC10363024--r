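# Independent brute-force oracles. These deliberately avoid the package's
# genome containers and apply functions: genomes are plain named lists of
# integer vectors spliced with base concatenation, and a per-region
# copy-number counter is maintained incrementally from each event's own
# footprint (2 + sum of gain copies - sum of loss copies per region), so a
# bookkeeping bug in the implementation cannot cancel out of the check.

naive_arm_range <- function(template, chrom, arm) {
  i <- match(chrom, template$chrom$name)
  switch(arm,
         p = c(0L, template$chrom$arm_region[i]),
         q = c(template$chrom$arm_region[i], template$chrom$n_regions[i]),
         whole = c(0L, template$chrom$n_regions[i]))
}

naive_apply <- function(state, template, ev) {
  g <- state$g       # g[[chrom]] = named list of integer region vectors
  cnt <- state$cnt   # cnt[[chrom]] = integer per-region total CN counter
  R <- setNames(template$chrom$n_regions, template$chrom$name)
  if (ev$scale == "wgd") {
    for (cn in names(g)) {
      for (lab in names(g[[cn]])) {
        i <- 1L
        repeat {
          nl <- sprintf("%s.wgd%d", lab, i)
          if (!nl %in% names(g[[cn]])) break
          i <- i + 1L
        }
        g[[cn]][[nl]] <- g[[cn]][[lab]]
      }
      cnt[[cn]] <- cnt[[cn]] * 2L
    }
  } else if (ev$scale == "focal") {
    a <- g[[ev$chrom]][[ev$allele]]
    s <- ev$start; L <- ev$length
    seg <- a[(s + 1L):(s + L)]
    foot <- tabulate(seg + 1L, nbins = R[[ev$chrom]])
    if (ev$type == "loss") {
      g[[ev$chrom]][[ev$allele]] <- c(head(a, s), tail(a, length(a) - s - L))
      cnt[[ev$chrom]] <- cnt[[ev$chrom]] - foot
    } else if (ev$type == "gain") {
      g[[ev$chrom]][[ev$allele]] <-
        c(head(a, s + L), rep(seg, ev$magnitude), tail(a, length(a) - s - L))
      cnt[[ev$chrom]] <- cnt[[ev$chrom]] + ev$magnitude * foot
    } else {  # cnloh: move copies to the homolog; total unchanged
      g[[ev$chrom]][[ev$allele]] <- c(head(a, s), tail(a, length(a) - s - L))
      h <- g[[ev$chrom]][[ev$allele2]]
      pos <- match(seg[1L], h)
      if (is.na(pos)) pos <- length(h)
      g[[ev$chrom]][[ev$allele2]] <- c(head(h, pos), seg,
                                       tail(h, length(h) - pos))
    }
  } else {  # arm / chromosome scale
    rng <- naive_arm_range(template, ev$chrom, ev$arm)
    a <- g[[ev$chrom]][[ev$allele]]
    hit <- a[a >= rng[1L] & a < rng[2L]]
    foot <- tabulate(hit + 1L, nbins = R[[ev$chrom]])
    if (ev$type == "loss") {
      if (ev$arm == "whole") {
        g[[ev$chrom]][[ev$allele]] <- NULL
      } else {
        g[[ev$chrom]][[ev$allele]] <- a[!(a >= rng[1L] & a < rng[2L])]
      }
      cnt[[ev$chrom]] <- cnt[[ev$chrom]] - foot
    } else {
      if (ev$arm == "whole") {
        g[[ev$chrom]][[ev$allele2]] <- a
      } else {
        idx <- which(a >= rng[1L] & a < rng[2L])
        last <- max(idx)
        g[[ev$chrom]][[ev$allele]] <- c(head(a, last), a[idx],
                                        tail(a, length(a) - last))
      }
      cnt[[ev$chrom]] <- cnt[[ev$chrom]] + foot
    }
  }
  list(g = g, cnt = cnt)
}

# Replay an event log over the tree with the naive machinery; returns per
# node both the counter-based and the sequence-tally-based region CN.
naive_replay <- function(tree, template, event_log) {
  nodes <- tree$nodes
  el <- as.data.frame(event_log)
  root <- nodes$id[is.na(nodes$parent)]
  fresh <- function() {
    g <- lapply(seq_len(nrow(template$chrom)), function(i) {
      r <- 0:(template$chrom$n_regions[i] - 1L)
      list(A = r, B = r)
    })
    names(g) <- template$chrom$name
    cnt <- lapply(template$chrom$n_regions, function(R) rep(2L, R))
    names(cnt) <- template$chrom$name
    list(g = g, cnt = cnt)
  }
  states <- list()
  states[[as.character(root)]] <- fresh()
  # process children in log/tree order (breadth-first by parent availability)
  todo <- nodes$id[!is.na(nodes$parent)]
  while (length(todo)) {
    ready <- todo[nodes$parent[match(todo, nodes$id)] %in%
                    as.integer(names(states))]
    for (child in ready) {
      st <- states[[as.character(nodes$parent[nodes$id == child])]]
      rows <- el[el$edge_child_id == child, , drop = FALSE]
      if (nrow(rows)) {
        rows <- rows[order(rows$order), , drop = FALSE]
        for (j in seq_len(nrow(rows))) {
          st <- naive_apply(st, template, as.list(rows[j, ]))
        }
      }
      states[[as.character(child)]] <- st
    }
    todo <- setdiff(todo, ready)
  }
  states
}

# sequence-derived total CN of a naive genome state
naive_seq_cn <- function(state, template) {
  stats::setNames(lapply(seq_len(nrow(template$chrom)), function(i) {
    cn <- template$chrom$name[i]
    R <- template$chrom$n_regions[i]
    tot <- integer(R)
    for (a in state$g[[cn]]) tot <- tot + tabulate(a + 1L, nbins = R)
    tot
  }), template$chrom$name)
}
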