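# In-code fixtures shared across test files.

# Toy genome template: n_chrom chromosomes of n_regions regions each.
toy_template <- function(n_chrom = 1, n_regions = 10, region_size = 10,
                         regions_per_bin = 1, arm_region = NULL) {
  if (is.null(arm_region)) arm_region <- max(1L, floor(n_regions / 2))
  arm <- data.frame(chrom = sprintf("chr%d", seq_len(n_chrom)),
                    length = n_regions * region_size,
                    centromere_start = arm_region * region_size,
                    stringsAsFactors = FALSE)
  build_template(NULL, arm, region_size = region_size,
                 bin_size = region_size * regions_per_bin)
}

# Hand-built focal event record.
focal_ev <- function(type, start, length, chrom = "chr1", allele = "A",
                     magnitude = NA, allele2 = NA) {
  list(scale = "focal", type = type, chrom = chrom, arm = NA_character_,
       allele = allele, allele2 = as.character(allele2),
       start = as.integer(start), length = as.integer(length),
       magnitude = as.integer(magnitude))
}

# Hand-built lineage trees (white-box fixtures matching the nodes schema).
make_tree <- function(nodes) {
  nodes$length <- ifelse(is.na(nodes$parent), 0,
                         nodes$time[match(nodes$parent, nodes$id)] - nodes$time)
  structure(list(nodes = nodes), class = "cell_lineage_tree")
}

two_leaf_tree <- function() {
  make_tree(data.frame(
    id = 1:3, parent = c(3L, 3L, NA), length = NA_real_, time = c(0, 0, 1),
    class = c("tumor_leaf", "tumor_leaf", "ancestral"),
    is_founder = c(FALSE, FALSE, TRUE), subclone = NA_integer_,
    stringsAsFactors = FALSE))
}

# Perfectly balanced tumor clade with n = 2^k leaves.
balanced_tree <- function(n) {
  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  tm <- numeric(n_nodes)
  cur <- seq_len(n)
  next_id <- n + 1L
  lev <- 1
  while (length(cur) > 1L) {
    nxt <- integer(0)
    for (i in seq(1L, length(cur), by = 2L)) {
      parent[cur[i]] <- next_id
      parent[cur[i + 1L]] <- next_id
      tm[next_id] <- lev
      nxt <- c(nxt, next_id)
      next_id <- next_id + 1L
    }
    cur <- nxt
    lev <- lev + 1
  }
  nodes <- data.frame(id = seq_len(n_nodes), parent = parent,
                      length = NA_real_, time = tm,
                      class = c(rep("tumor_leaf", n),
                                rep("ancestral", n_nodes - n)),
                      is_founder = FALSE, subclone = NA_integer_,
                      stringsAsFactors = FALSE)
  nodes$is_founder[n_nodes] <- TRUE
  make_tree(nodes)
}

# Divergence time (age of the MRCA) of two leaves, from the nodes table.
mrca_time <- function(tree, id_a, id_b) {
  nodes <- tree$nodes
  anc <- function(id) {
    out <- id
    while (!is.na(nodes$parent[nodes$id == id])) {
      id <- nodes$parent[nodes$id == id]
      out <- c(out, id)
    }
    out
  }
  common <- intersect(anc(id_a), anc(id_b))
  min(nodes$time[nodes$id %in% common])
}

# total CN per region from a cell_genome, one vector per chromosome
genome_region_cn <- function(genome, template) {
  stats::setNames(lapply(seq_len(nrow(template$chrom)), function(i) {
    cn <- template$chrom$name[i]
    R <- template$chrom$n_regions[i]
    tot <- integer(R)
    for (a in genome[[cn]]) tot <- tot + tabulate(a + 1L, nbins = R)
    tot
  }), template$chrom$name)
}
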