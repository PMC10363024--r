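#' Error-model parameters for noisy copy number profiles
#'
#' The error model mimics what a CNA caller produces from low-coverage
#' single-cell sequencing: segmentation breakpoints wander around true
#' copy-number boundaries, and read-count nonuniformity adds fluctuations
#' whose size grows with the underlying copy number state.
#'
#' @param p_boundary probability that each within-chromosome boundary
#'   between differing copy-number states is perturbed, in \[0, 1\].
#' @param p_shift geometric parameter of the boundary displacement length
#'   (support 1, 2, ... bins; mean `1/p_shift`), in (0, 1\].
#' @param jitter_sd jitter scale: standard deviation of the added Gaussian
#'   noise per unit copy (a bin at state c gets s.d. `jitter_sd * c`),
#'   >= 0.
#' @return an object of class `error_model_params`.
#' @export
error_model_params <- function(p_boundary = 0.5, p_shift = 0.5,
                               jitter_sd = 0.15) {
  check_that(p_boundary >= 0 && p_boundary <= 1,
             "`p_boundary` must be in [0, 1]")
  check_that(p_shift > 0 && p_shift <= 1, "`p_shift` must be in (0, 1]")
  check_that(jitter_sd >= 0, "`jitter_sd` must be >= 0")
  structure(list(p_boundary = p_boundary, p_shift = p_shift,
                 jitter_sd = jitter_sd), class = "error_model_params")
}

# bin table (chrom, start, end, chrom index, bins-per-chrom) for a template
template_bins <- function(template) {
  out <- lapply(seq_len(nrow(template$chrom)), function(i) {
    len <- template$chrom$length[i]
    nb <- ceiling(len / template$bin_size)
    start <- (seq_len(nb) - 1) * template$bin_size
    data.frame(chrom = template$chrom$name[i], start = start,
               end = pmin(start + template$bin_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# per-region total / A-derived / B-derived copy counts for one chromosome
region_counts <- function(alleles, R) {
  total <- integer(R)
  cn_a <- integer(R)
  cn_b <- integer(R)
  for (lab in names(alleles)) {
    t <- tabulate(alleles[[lab]] + 1L, nbins = R)
    total <- total + t
    if (startsWith(lab, "A")) cn_a <- cn_a + t else cn_b <- cn_b + t
  }
  list(total = total, cn_a = cn_a, cn_b = cn_b)
}

#' Ground-truth binned copy number profile of one genome
#'
#' Per reference region, the total copy number is the number of occurrences
#' of that region identifier across all allele lineages; the allele-specific
#' pair partitions the count by founding haplotype (A-derived vs B-derived
#' lineages). Each bin reports the length-weighted mean of its regions'
#' copy numbers (the last region of a chromosome may be short), rounded
#' half away from zero.
#'
#' @param genome a `cell_genome`.
#' @param template the `genome_template`.
#' @return data.frame with columns `chrom`, `start`, `end`, `cn_total`,
#'   `cn_a`, `cn_b` (one row per bin).
#' @export
compute_ground_truth_cnp <- function(genome, template) {
  rpb <- template$bin_size / template$region_size
  out <- lapply(seq_len(nrow(template$chrom)), function(i) {
    cn <- template$chrom$name[i]
    R <- template$chrom$n_regions[i]
    counts <- region_counts(genome[[cn]], R)
    w <- region_bp_lengths(template, i)
    bin_of <- (0:(R - 1L)) %/% rpb
    wsum <- rowsum(w, bin_of)
    bin_val <- function(v) {
      as.integer(round_half_away(rowsum(v * w, bin_of) / wsum))
    }
    nb <- length(unique(bin_of))
    start <- (0:(nb - 1L)) * template$bin_size
    data.frame(chrom = cn, start = start,
               end = pmin(start + template$bin_size, template$chrom$length[i]),
               cn_total = bin_val(counts$total), cn_a = bin_val(counts$cn_a),
               cn_b = bin_val(counts$cn_b), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble a multi-cell copy number profile object
#'
#' @param genomes named list of `cell_genome` objects (names become cell
#'   ids).
#' @param template the `genome_template`.
#' @return an object of class `copy_number_profile`: list with `bins`
#'   (data.frame chrom/start/end), and cells x bins integer matrices
#'   `total`, `cn_a`, `cn_b` (cell ids as row names).
#' @export
compute_profiles <- function(genomes, template) {
  bins <- template_bins(template)
  mats <- lapply(genomes, compute_ground_truth_cnp, template = template)
  total <- do.call(rbind, lapply(mats, function(m) m$cn_total))
  cn_a <- do.call(rbind, lapply(mats, function(m) m$cn_a))
  cn_b <- do.call(rbind, lapply(mats, function(m) m$cn_b))
  rownames(total) <- rownames(cn_a) <- rownames(cn_b) <- names(genomes)
  structure(list(bins = bins, total = total, cn_a = cn_a, cn_b = cn_b),
            class = "copy_number_profile")
}

#' @export
print.copy_number_profile <- function(x, ...) {
  cat("copy number profile:", nrow(x$total), "cell(s) x", nrow(x$bins),
      "bins on", length(unique(x$bins$chrom)), "chromosome(s)\n")
  invisible(x)
}

# displace one cell-chromosome's bins; v, a, b are integer vectors,
# boundaries and adopted values are taken from the original vector, but
# clipping is against the current state so every segment keeps >= 1 bin
# (no copy-number state can be erased from the chromosome).
perturb_boundaries_1 <- function(v, a, b, p_b, p_s) {
  orig <- v
  nb <- length(orig)
  bnd <- which(diff(orig) != 0)
  for (i in bnd) {
    if (stats::runif(1) >= p_b) next
    s <- stats::rgeom(1L, p_s) + 1L
    lv <- orig[i]; rv <- orig[i + 1L]
    if (stats::runif(1) < 0.5) {
      # boundary moves right: left segment value invades the right segment
      e <- i + 1L
      while (e < nb && v[e + 1L] == rv) e <- e + 1L
      hi <- min(i + s, e - 1L)
      if (hi >= i + 1L) {
        idx <- (i + 1L):hi
        v[idx] <- lv; a[idx] <- a[i]; b[idx] <- b[i]
      }
    } else {
      # boundary moves left: right segment value invades the left segment
      st <- i
      while (st > 1L && v[st - 1L] == lv) st <- st - 1L
      lo <- max(i - s + 1L, st + 1L)
      if (lo <= i) {
        idx <- lo:i
        v[idx] <- rv; a[idx] <- a[i + 1L]; b[idx] <- b[i + 1L]
      }
    }
  }
  list(v = v, a = a, b = b)
}

#' Add segment-boundary noise to a copy number profile
#'
#' For each within-chromosome boundary between adjacent bins of differing
#' total copy number, with probability `p_boundary` the boundary is
#' displaced by `Geometric(p_shift)` bins (support 1, 2, ...) in a
#' uniformly random direction; displaced bins adopt the state (total and
#' allele-specific) of the segment the boundary moved away from. Boundaries
#' are processed left to right against the original profile; displacement
#' is clipped so the invaded segment always retains at least one bin, hence
#' no copy-number state ever disappears from a chromosome.
#'
#' @param profile a `copy_number_profile`.
#' @param params an `error_model_params` object.
#' @return the perturbed `copy_number_profile`.
#' @export
add_boundary_noise <- function(profile, params) {
  if (params$p_boundary == 0) return(profile)
  chroms <- unique(profile$bins$chrom)
  idx_by_chrom <- lapply(chroms, function(cn) which(profile$bins$chrom == cn))
  for (cell in seq_len(nrow(profile$total))) {
    for (ci in seq_along(chroms)) {
      idx <- idx_by_chrom[[ci]]
      if (length(idx) < 2L) next
      r <- perturb_boundaries_1(profile$total[cell, idx],
                                profile$cn_a[cell, idx],
                                profile$cn_b[cell, idx],
                                params$p_boundary, params$p_shift)
      profile$total[cell, idx] <- r$v
      profile$cn_a[cell, idx] <- r$a
      profile$cn_b[cell, idx] <- r$b
    }
  }
  profile
}

#' Add state-proportional jitter to a copy number profile
#'
#' Each bin at total copy number c > 0 becomes
#' `max(0, round(c + Normal(0, (jitter_sd * c)^2)))` (rounding half away
#' from zero), independently per bin per cell; zero-copy bins stay zero.
#' The allele-specific split is rescaled proportionally to the jittered
#' total and re-rounded.
#'
#' @param profile a `copy_number_profile`.
#' @param params an `error_model_params` object.
#' @return the jittered `copy_number_profile`.
#' @export
add_jitter <- function(profile, params) {
  if (params$jitter_sd == 0) return(profile)
  v <- profile$total
  pos <- v > 0
  eps <- stats::rnorm(sum(pos), mean = 0, sd = params$jitter_sd * v[pos])
  nv <- v
  nv[pos] <- pmax(0, round_half_away(v[pos] + eps))
  a <- profile$cn_a
  na <- a
  na[pos] <- round_half_away(a[pos] * nv[pos] / v[pos])
  na <- pmin(na, nv)
  profile$total <- nv
  profile$cn_a <- na
  profile$cn_b <- nv - na
  mode(profile$total) <- "integer"
  mode(profile$cn_a) <- "integer"
  mode(profile$cn_b) <- "integer"
  profile
}

#' Write copy number profiles to TSV files
#'
#' Writes a long-format table (`<prefix>_long.tsv`: cell_id, chrom, start,
#' end, cn_total, cn_a, cn_b) and a wide bins x cells matrix
#' (`<prefix>_matrix.tsv`: chrom, start, end, one column per cell holding
#' the total copy number). Both round-trip losslessly through
#' [read_profiles()].
#'
#' @param profile a `copy_number_profile`.
#' @param dir output directory.
#' @param prefix file-name prefix (e.g. `"truth"` or `"noisy"`).
#' @return character vector of the written paths, invisibly.
#' @export
write_profiles <- function(profile, dir, prefix = "truth") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells <- rownames(profile$total)
  nb <- nrow(profile$bins)
  long <- data.table::data.table(
    cell_id = rep(cells, each = nb),
    chrom = rep(profile$bins$chrom, length(cells)),
    start = rep(profile$bins$start, length(cells)),
    end = rep(profile$bins$end, length(cells)),
    cn_total = as.integer(t(profile$total)),
    cn_a = as.integer(t(profile$cn_a)),
    cn_b = as.integer(t(profile$cn_b)))
  long_path <- file.path(dir, paste0(prefix, "_long.tsv"))
  data.table::fwrite(long, long_path, sep = "\t", quote = FALSE)
  wide <- data.table::data.table(profile$bins)
  for (cl in cells) wide[[cl]] <- as.integer(profile$total[cl, ])
  wide_path <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  data.table::fwrite(wide, wide_path, sep = "\t", quote = FALSE)
  invisible(c(long_path, wide_path))
}

#' Read a long-format profile TSV back into a profile object
#' @param path path to a `*_long.tsv` file written by [write_profiles()].
#' @return a `copy_number_profile`.
#' @export
read_profiles <- function(path) {
  long <- data.table::fread(path, sep = "\t")
  cells <- unique(long$cell_id)
  first <- long[long$cell_id == cells[1L], ]
  bins <- data.frame(chrom = first$chrom, start = first$start,
                     end = first$end, stringsAsFactors = FALSE)
  nb <- nrow(bins)
  shape <- function(col) {
    m <- matrix(as.integer(long[[col]]), nrow = length(cells), ncol = nb,
                byrow = TRUE)
    rownames(m) <- cells
    m
  }
  structure(list(bins = bins, total = shape("cn_total"),
                 cn_a = shape("cn_a"), cn_b = shape("cn_b")),
            class = "copy_number_profile")
}

#' Write per-cell copy-number segments (BED-like)
#'
#' Merges runs of adjacent equal-total-CN bins per cell and chromosome into
#' segments and writes them as a TSV (cell_id, chrom, start, end, cn).
#'
#' @param profile a `copy_number_profile`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_segments <- function(profile, path) {
  rows <- list()
  for (cell in rownames(profile$total)) {
    for (cn in unique(profile$bins$chrom)) {
      idx <- which(profile$bins$chrom == cn)
      v <- profile$total[cell, idx]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        cell_id = cell, chrom = cn,
        start = profile$bins$start[idx][starts],
        end = profile$bins$end[idx][ends], cn = r$values)
    }
  }
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}
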