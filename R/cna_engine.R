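#' Event-model parameters
#'
#' Parameters of the copy-number event model. Focal events arrive along
#' each tumor edge as a Poisson process in branch length; chromosome-scale
#' events are concentrated on the edge into the tumor founder (the burst of
#' genomic instability that creates the tumor lineage) and on the edges
#' into subclone ancestors.
#'
#' @param focal_rate focal CNA rate per coalescent time unit (lambda_f).
#' @param mean_length mean focal event length in regions.
#' @param min_length minimum focal event length in regions (>= 1). The
#'   length law is `min_length` plus a geometric draw whose mean matches
#'   `mean_length`, truncated so the event fits the allele.
#' @param p_gain probability a focal event is a gain (else a loss).
#' @param p_cnloh probability a focal event is reclassified as copy-neutral
#'   LOH (requires a homologous allele lineage carrying the locus; the
#'   event falls back to plain gain/loss otherwise).
#' @param p_mag geometric parameter of the amplification magnitude; gains
#'   add `1 + Geometric(p_mag)` copies.
#' @param founder_event_mean mean number of chromosomal events (Poisson) on
#'   the edge into the tumor founder.
#' @param subclone_event_mean each subclone-root edge receives
#'   `1 + Poisson(subclone_event_mean)` chromosomal events; the multiset of
#'   (chromosome, arm, type) is resampled until unique across subclones.
#' @param p_arm probability a chromosomal event is arm-level (else whole
#'   chromosome).
#' @param p_chrom_gain probability a chromosomal event is a gain.
#' @param wgd logical: apply a whole-genome duplication at the onset of the
#'   tumor lineage (first event on the founder edge).
#' @param pseudo_normal_event_mean mean number (Poisson) of focal events on
#'   each pseudo-normal cell's pendant edge.
#' @return an object of class `event_model_params`.
#' @export
event_model_params <- function(focal_rate = 3, mean_length = 1000,
                               min_length = 100, p_gain = 0.5,
                               p_cnloh = 0.1, p_mag = 0.5,
                               founder_event_mean = 5,
                               subclone_event_mean = 2, p_arm = 0.75,
                               p_chrom_gain = 0.5, wgd = FALSE,
                               pseudo_normal_event_mean = 3) {
  for (p in c(p_gain, p_cnloh, p_chrom_gain, p_arm)) {
    check_that(p >= 0 && p <= 1, "probabilities must be in [0, 1]")
  }
  check_that(p_mag > 0 && p_mag <= 1, "`p_mag` must be in (0, 1]")
  check_that(min_length >= 1, "`min_length` must be >= 1")
  check_that(mean_length >= min_length,
             "`mean_length` must be >= `min_length`")
  for (m in c(focal_rate, founder_event_mean, subclone_event_mean,
              pseudo_normal_event_mean)) {
    check_that(m >= 0, "rates/means must be >= 0")
  }
  structure(list(focal_rate = focal_rate, mean_length = mean_length,
                 min_length = min_length, p_gain = p_gain,
                 p_cnloh = p_cnloh, p_mag = p_mag,
                 founder_event_mean = founder_event_mean,
                 subclone_event_mean = subclone_event_mean, p_arm = p_arm,
                 p_chrom_gain = p_chrom_gain, wgd = isTRUE(wgd),
                 pseudo_normal_event_mean = pseudo_normal_event_mean),
            class = "event_model_params")
}

cna_event <- function(scale, type, chrom = NA_character_,
                      arm = NA_character_, allele = NA_character_,
                      allele2 = NA_character_, start = NA_integer_,
                      length = NA_integer_, magnitude = NA_integer_) {
  list(scale = scale, type = type, chrom = chrom, arm = arm,
       allele = allele, allele2 = allele2, start = start, length = length,
       magnitude = magnitude)
}

# smallest unused derived label base.kind<i> within a chromosome
new_allele_label <- function(base, kind, existing) {
  i <- 1L
  repeat {
    cand <- sprintf("%s.%s%d", base, kind, i)
    if (!cand %in% existing) return(cand)
    i <- i + 1L
  }
}

#' Draw a random focal copy-number event
#'
#' The target allele lineage is chosen with probability proportional to its
#' current region count (so the per-bp event rate is uniform across the
#' genome as it mutates), the start position uniformly among positions that
#' fit the minimum length, and the length as `min_length` plus a geometric
#' draw (mean-matched to `mean_length`), truncated at the allele end. Type
#' is gain with probability `p_gain` else loss, then reclassified as
#' copy-neutral LOH with probability `p_cnloh` when a homologous allele
#' lineage carries the whole locus. Gains get magnitude
#' `1 + Geometric(p_mag)`.
#'
#' @param genome a `cell_genome`.
#' @param params an `event_model_params` object.
#' @return a focal event record (list), or `NULL` with a warning when no
#'   allele lineage is long enough to host an event (e.g. fully deleted
#'   genome).
#' @export
draw_focal_event <- function(genome, params) {
  tab <- do.call(rbind, lapply(names(genome), function(cn) {
    lens <- vapply(genome[[cn]], length, integer(1))
    if (length(lens) == 0) return(NULL)
    data.frame(chrom = cn, allele = names(lens), len = as.integer(lens),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(tab)) {
    tab <- tab[tab$len >= params$min_length, , drop = FALSE]
  }
  if (is.null(tab) || nrow(tab) == 0) {
    warning("focal event skipped: no allele lineage can host it",
            call. = FALSE)
    return(NULL)
  }
  i <- sample.int(nrow(tab), 1L, prob = tab$len)
  cn <- tab$chrom[i]
  al <- tab$allele[i]
  alen <- tab$len[i]
  start <- sample.int(alen - params$min_length + 1L, 1L) - 1L
  p_len <- 1 / (params$mean_length - params$min_length + 1)
  len <- params$min_length + stats::rgeom(1L, p_len)
  len <- min(len, alen - start)
  type <- if (stats::runif(1) < params$p_gain) "gain" else "loss"
  magnitude <- if (type == "gain") 1L + stats::rgeom(1L, params$p_mag)
               else NA_integer_
  allele2 <- NA_character_
  if (stats::runif(1) < params$p_cnloh) {
    seg <- genome[[cn]][[al]][(start + 1L):(start + len)]
    others <- setdiff(names(genome[[cn]]), al)
    ok <- others[vapply(others, function(o) all(seg %in% genome[[cn]][[o]]),
                        logical(1))]
    if (length(ok)) {
      type <- "cnloh"
      magnitude <- NA_integer_
      allele2 <- if (length(ok) == 1L) ok else sample(ok, 1L)
    }
  }
  cna_event("focal", type, chrom = cn, allele = al, allele2 = allele2,
            start = as.integer(start), length = as.integer(len),
            magnitude = as.integer(magnitude))
}

#' Apply a focal event to a genome
#'
#' Deterministic given the event record. A loss deletes positions
#' `[start, start + length)` of the target allele's region sequence; a gain
#' of magnitude m inserts m tandem copies of the segment immediately after
#' it; copy-neutral LOH moves the segment's copies to the homologous allele
#' recorded in `allele2` (the target loses the segment, the homolog gains a
#' tandem duplicate of the same reference regions), so the per-region total
#' copy number is unchanged.
#'
#' @param genome a `cell_genome`.
#' @param event a focal event record from [draw_focal_event()].
#' @return the mutated `cell_genome`.
#' @export
apply_focal_event <- function(genome, event) {
  a <- genome[[event$chrom]][[event$allele]]
  check_that(!is.null(a), "event names an allele lineage absent from the genome")
  s <- event$start
  L <- event$length
  check_that(s >= 0 && L >= 1 && s + L <= length(a),
             "focal event out of bounds for its allele")
  idx <- (s + 1L):(s + L)
  seg <- a[idx]
  if (event$type == "loss") {
    genome[[event$chrom]][[event$allele]] <- a[-idx]
  } else if (event$type == "gain") {
    genome[[event$chrom]][[event$allele]] <-
      append(a, rep(seg, event$magnitude), after = s + L)
  } else if (event$type == "cnloh") {
    h <- genome[[event$chrom]][[event$allele2]]
    check_that(!is.null(h), "CNLOH event names a missing homolog")
    genome[[event$chrom]][[event$allele]] <- a[-idx]
    pos <- match(seg[1L], h)
    if (is.na(pos)) pos <- length(h)
    genome[[event$chrom]][[event$allele2]] <- append(h, seg, after = pos)
  } else {
    stop("unknown focal event type: ", event$type, call. = FALSE)
  }
  genome
}

# region index range [lo, hi) of an arm ("p", "q") or "whole"
arm_region_range <- function(template, chrom, arm) {
  i <- match(chrom, template$chrom$name)
  R <- template$chrom$n_regions[i]
  ar <- template$chrom$arm_region[i]
  switch(arm,
         p = c(0L, ar),
         q = c(ar, R),
         whole = c(0L, R),
         stop("unknown arm: ", arm, call. = FALSE))
}

# draw the (chrom, arm, type) part of a chromosomal event
draw_chrom_signature <- function(n, template, params) {
  if (n == 0) {
    return(data.frame(chrom = character(0), arm = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  chrom <- sample(template$chrom$name, n, replace = TRUE)
  is_arm <- stats::runif(n) < params$p_arm
  arm <- ifelse(is_arm, sample(c("p", "q"), n, replace = TRUE), "whole")
  type <- ifelse(stats::runif(n) < params$p_chrom_gain, "gain", "loss")
  data.frame(chrom = chrom, arm = arm, type = type, stringsAsFactors = FALSE)
}

# pick a carrier allele and build the full event record; NULL when no
# allele carries the arm (event is skipped)
draw_chrom_event <- function(genome, template, chrom, arm, type) {
  rng <- arm_region_range(template, chrom, arm)
  carriers <- names(genome[[chrom]])[vapply(genome[[chrom]], function(a) {
    any(a >= rng[1L] & a < rng[2L])
  }, logical(1))]
  if (length(carriers) == 0L) {
    warning(sprintf("%s %s %s skipped: no allele carries the target",
                    chrom, arm, type), call. = FALSE)
    return(NULL)
  }
  allele <- if (length(carriers) == 1L) carriers else sample(carriers, 1L)
  allele2 <- NA_character_
  if (type == "gain" && arm == "whole") {
    allele2 <- new_allele_label(allele, "dup", names(genome[[chrom]]))
  }
  cna_event(scale = if (arm == "whole") "chromosome" else "arm",
            type = type, chrom = chrom, arm = arm, allele = allele,
            allele2 = allele2, magnitude = 1L)
}

# deterministic application of a chromosomal event record
apply_chrom_event_record <- function(genome, template, event) {
  rng <- arm_region_range(template, event$chrom, event$arm)
  a <- genome[[event$chrom]][[event$allele]]
  check_that(!is.null(a), "event names an allele lineage absent from the genome")
  in_arm <- a >= rng[1L] & a < rng[2L]
  if (event$type == "loss") {
    if (event$arm == "whole") {
      genome[[event$chrom]][[event$allele]] <- NULL
    } else {
      genome[[event$chrom]][[event$allele]] <- a[!in_arm]
    }
  } else {
    if (event$arm == "whole") {
      newlab <- event$allele2
      if (is.na(newlab)) {
        newlab <- new_allele_label(event$allele, "dup",
                                   names(genome[[event$chrom]]))
      }
      genome[[event$chrom]][[newlab]] <- a
    } else {
      idx <- which(in_arm)
      genome[[event$chrom]][[event$allele]] <-
        append(a, a[idx], after = max(idx))
    }
  }
  genome
}

#' Apply a chromosome-scale event
#'
#' A loss removes every region of the chosen arm from one uniformly chosen
#' allele lineage carrying it (a whole-chromosome loss removes the entire
#' lineage). A whole-chromosome gain copies a carrier lineage into a new
#' allele lineage with a derived label (`<source>.dup<i>`) — newly created
#' chromosomes are treated as new alleles; an arm gain appends a tandem
#' duplicate of the arm's regions on the source lineage. When no allele
#' carries the target, the event is skipped with a warning.
#'
#' @param genome a `cell_genome`.
#' @param template the `genome_template` (for arm boundaries).
#' @param chrom chromosome name.
#' @param arm one of `"p"`, `"q"`, `"whole"`.
#' @param type `"gain"` or `"loss"`.
#' @return the mutated `cell_genome`.
#' @export
apply_chromosomal_event <- function(genome, template, chrom, arm, type) {
  check_that(chrom %in% template$chrom$name, "unknown chromosome")
  ev <- draw_chrom_event(genome, template, chrom, arm, type)
  if (is.null(ev)) return(genome)
  apply_chrom_event_record(genome, template, ev)
}

#' Apply a whole-genome duplication
#'
#' Every existing allele lineage is copied into a new lineage with a
#' derived label (`<source>.wgd<i>`), so the per-region total copy number
#' exactly doubles and duplicated chromosomes are tracked as new alleles.
#'
#' @param genome a `cell_genome`.
#' @return the duplicated `cell_genome`.
#' @export
apply_wgd <- function(genome) {
  for (cn in names(genome)) {
    labs <- names(genome[[cn]])
    for (l in labs) {
      nl <- new_allele_label(l, "wgd", names(genome[[cn]]))
      genome[[cn]][[nl]] <- genome[[cn]][[l]]
    }
  }
  genome
}

empty_event_log <- function() {
  data.table::data.table(edge_child_id = integer(0), order = integer(0),
                         scale = character(0), type = character(0),
                         chrom = character(0), arm = character(0),
                         allele = character(0), allele2 = character(0),
                         start = integer(0), length = integer(0),
                         magnitude = integer(0))
}

event_row <- function(child, ord, ev) {
  data.table::data.table(edge_child_id = as.integer(child),
                         order = as.integer(ord), scale = ev$scale,
                         type = ev$type, chrom = ev$chrom, arm = ev$arm,
                         allele = ev$allele, allele2 = ev$allele2,
                         start = ev$start, length = ev$length,
                         magnitude = ev$magnitude)
}

#' Evolve genomes along the cell lineage tree
#'
#' Top-down traversal from a healthy diploid root. Each edge inside the
#' tumor clade draws `Poisson(focal_rate * branch_length)` focal events,
#' applied in draw order (later events see the already-mutated allele
#' sequences). The edge into the tumor founder additionally receives, first
#' an optional WGD, then `Poisson(founder_event_mean)` chromosomal events;
#' each edge into a subclone root receives `1 + Poisson(subclone_event_mean)`
#' chromosomal events whose (chromosome, arm, type) multiset is resampled
#' until unique across subclones, so every subclone carries a distinctive
#' chromosomal signature. Normal leaves (and the outgroup stem) receive no
#' events ever; pseudo-normal leaves receive
#' `Poisson(pseudo_normal_event_mean)` focal events on their pendant edge
#' only.
#'
#' @param tree a `cell_lineage_tree`.
#' @param template a `genome_template`.
#' @param params an `event_model_params` object.
#' @return list with `genomes` (named list of `cell_genome`, one per node
#'   id) and `event_log` (a data.table recording every applied event with
#'   its edge, in application order).
#' @export
evolve_tree <- function(tree, template, params) {
  check_that(inherits(params, "event_model_params"), "invalid params")
  nodes <- tree$nodes
  root <- tree_root(tree)
  fid <- founder_id(tree)
  tumor_set <- c(fid, descendants_of(nodes, fid))
  ord <- bfs_order(nodes, root)

  genomes <- vector("list", length(ord))
  names(genomes) <- as.character(ord)
  genomes[[as.character(root)]] <- init_diploid_genome(template)

  log_rows <- list()
  subclone_sigs <- character(0)

  for (child in ord[-1L]) {
    key <- as.character(child)
    prow <- nodes[nodes$id == child, ]
    g <- genomes[[as.character(prow$parent)]]
    k <- 0L
    in_tumor <- child %in% tumor_set

    if (in_tumor) {
      if (child == fid && params$wgd) {
        g <- apply_wgd(g)
        k <- k + 1L
        log_rows[[length(log_rows) + 1L]] <-
          event_row(child, k, cna_event("wgd", "gain"))
      }
      n_chrom_events <- 0L
      if (child == fid) {
        n_chrom_events <- stats::rpois(1L, params$founder_event_mean)
        sig <- draw_chrom_signature(n_chrom_events, template, params)
      } else if (!is.na(prow$subclone) && prow$class == "ancestral") {
        # subclone root: unique chromosomal signature
        for (attempt in seq_len(100L)) {
          n_chrom_events <- 1L + stats::rpois(1L, params$subclone_event_mean)
          sig <- draw_chrom_signature(n_chrom_events, template, params)
          key_sig <- paste(sort(paste(sig$chrom, sig$arm, sig$type)),
                           collapse = ";")
          if (!key_sig %in% subclone_sigs) {
            subclone_sigs <- c(subclone_sigs, key_sig)
            break
          }
          if (attempt == 100L) {
            stop("could not draw a unique chromosomal signature for subclone ",
                 prow$subclone, call. = FALSE)
          }
        }
      }
      if (n_chrom_events > 0L) {
        for (j in seq_len(n_chrom_events)) {
          ev <- draw_chrom_event(g, template, sig$chrom[j], sig$arm[j],
                                 sig$type[j])
          if (is.null(ev)) next
          g <- apply_chrom_event_record(g, template, ev)
          k <- k + 1L
          log_rows[[length(log_rows) + 1L]] <- event_row(child, k, ev)
        }
      }
      n_focal <- stats::rpois(1L, params$focal_rate * prow$length)
      for (j in seq_len(n_focal)) {
        ev <- draw_focal_event(g, params)
        if (is.null(ev)) next
        g <- apply_focal_event(g, ev)
        k <- k + 1L
        log_rows[[length(log_rows) + 1L]] <- event_row(child, k, ev)
      }
    } else if (prow$class == "pseudo_normal_leaf") {
      n_focal <- stats::rpois(1L, params$pseudo_normal_event_mean)
      for (j in seq_len(n_focal)) {
        ev <- draw_focal_event(g, params)
        if (is.null(ev)) next
        g <- apply_focal_event(g, ev)
        k <- k + 1L
        log_rows[[length(log_rows) + 1L]] <- event_row(child, k, ev)
      }
    }
    # normal leaves and outgroup stem nodes: no events, genome inherited

    genomes[[key]] <- g
  }

  log <- if (length(log_rows)) data.table::rbindlist(log_rows)
         else empty_event_log()
  list(genomes = genomes, event_log = log)
}

#' Replay an event log from a fresh diploid root
#'
#' Deterministically re-applies every logged event along the tree, starting
#' from an initialized diploid genome at the root. Used to verify that the
#' event log fully determines every cell's genome.
#'
#' @param tree the `cell_lineage_tree` the log was generated on.
#' @param template the `genome_template`.
#' @param event_log the event-log data.table from [evolve_tree()].
#' @return named list of `cell_genome` objects, one per node id.
#' @export
replay_event_log <- function(tree, template, event_log) {
  nodes <- tree$nodes
  root <- tree_root(tree)
  ord <- bfs_order(nodes, root)
  genomes <- vector("list", length(ord))
  names(genomes) <- as.character(ord)
  genomes[[as.character(root)]] <- init_diploid_genome(template)
  el <- as.data.frame(event_log)
  for (child in ord[-1L]) {
    parent <- nodes$parent[nodes$id == child]
    g <- genomes[[as.character(parent)]]
    rows <- el[el$edge_child_id == child, , drop = FALSE]
    if (nrow(rows)) {
      rows <- rows[order(rows$order), , drop = FALSE]
      for (j in seq_len(nrow(rows))) {
        ev <- as.list(rows[j, ])
        g <- switch(ev$scale,
                    wgd = apply_wgd(g),
                    focal = apply_focal_event(g, ev),
                    arm = ,
                    chromosome = apply_chrom_event_record(g, template, ev))
      }
    }
    genomes[[as.character(child)]] <- g
  }
  genomes
}

#' Generate a pseudo-normal cell genome
#'
#' A pseudo-normal cell is a near-diploid cell outside the tumor lineage:
#' a fresh diploid genome subjected to `Poisson(pseudo_normal_event_mean)`
#' focal events (never chromosomal events or WGD).
#'
#' @param template a `genome_template`.
#' @param params an `event_model_params` object.
#' @return list with `genome` (a `cell_genome`) and `events` (list of the
#'   applied focal event records).
#' @export
make_pseudo_normal <- function(template, params) {
  g <- init_diploid_genome(template)
  n <- stats::rpois(1L, params$pseudo_normal_event_mean)
  evs <- list()
  for (j in seq_len(n)) {
    ev <- draw_focal_event(g, params)
    if (is.null(ev)) next
    g <- apply_focal_event(g, ev)
    evs[[length(evs) + 1L]] <- ev
  }
  list(genome = g, events = evs)
}

#' Write the event log to a TSV file
#' @param event_log event-log data.table from [evolve_tree()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_event_log <- function(event_log, path) {
  data.table::fwrite(event_log, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
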