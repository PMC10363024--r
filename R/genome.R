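#' Build the discretized genome template
#'
#' The template defines the coordinate system shared by every simulated
#' cell: each chromosome is cut into uniform `region_size`-bp regions (the
#' unit of the event model) and into `bin_size`-bp bins (the unit of copy
#' number reporting). All coordinates are 0-based, half-open; region `i`
#' covers `[i * region_size, min((i + 1) * region_size, length))`, so the
#' last region of a chromosome may be shorter than the rest.
#'
#' Chromosome lengths come from the reference FASTA when one is given (for
#' read generation) or from the arm table alone (profile-only mode needs no
#' sequence at all). The arm table is a minimal cytoband digest: a TSV with
#' columns `chrom`, `length`, `centromere_start` (0-based bp coordinate of
#' the first q-arm base). Use [read_ucsc_cytoband()] to derive one from a
#' UCSC `cytoBand.txt` file.
#'
#' @param reference path to a FASTA file (optionally gzipped), a
#'   [Biostrings::DNAStringSet], or `NULL` for profile-only mode.
#' @param arm_table path to the arm-table TSV or an equivalent data.frame.
#' @param region_size region size in bp (event-model resolution).
#' @param bin_size bin size in bp; must be a positive integer multiple of
#'   `region_size`.
#' @return an object of class `genome_template` with elements `chrom` (a
#'   data.frame: `name`, `length`, `arm_boundary`, `n_regions`,
#'   `arm_region`), `region_size`, `bin_size`.
#' @export
build_template <- function(reference = NULL, arm_table = NULL,
                           region_size = 1000, bin_size = 1e6) {
  check_that(region_size >= 1 && region_size == floor(region_size),
             "`region_size` must be a positive integer")
  check_that(bin_size >= 1 && bin_size %% region_size == 0,
             sprintf("`bin_size` (%s) must be a positive integer multiple of `region_size` (%s)",
                     format(bin_size), format(region_size)))
  check_that(!is.null(arm_table), "an arm table is required")
  arms <- if (is.data.frame(arm_table)) {
    arm_table
  } else {
    utils::read.table(arm_table, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  check_that(all(c("chrom", "length", "centromere_start") %in% names(arms)),
             "arm table needs columns chrom, length, centromere_start")

  if (!is.null(reference)) {
    seqs <- if (inherits(reference, "DNAStringSet")) reference
            else Biostrings::readDNAStringSet(reference)
    chrom_names <- sub("\\s.*$", "", names(seqs))
    missing <- setdiff(chrom_names, arms$chrom)
    if (length(missing)) {
      stop("chromosome(s) in FASTA missing from arm table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    lens <- as.numeric(Biostrings::width(seqs))
    ord <- chrom_names
  } else {
    ord <- arms$chrom
    lens <- as.numeric(arms$length[match(ord, arms$chrom)])
  }
  bound <- as.numeric(arms$centromere_start[match(ord, arms$chrom)])
  check_that(all(lens > 0), "chromosome lengths must be > 0")
  check_that(all(bound > 0 & bound < lens),
             "arm boundaries must lie strictly inside their chromosome")

  chrom <- data.frame(
    name = ord, length = lens, arm_boundary = bound,
    n_regions = as.integer(ceiling(lens / region_size)),
    arm_region = as.integer(floor(bound / region_size)),
    stringsAsFactors = FALSE)
  structure(list(chrom = chrom, region_size = region_size,
                 bin_size = bin_size),
            class = "genome_template")
}

#' @export
print.genome_template <- function(x, ...) {
  cat("genome template:", nrow(x$chrom), "chromosome(s),",
      "region", x$region_size, "bp, bin", x$bin_size, "bp\n")
  invisible(x)
}

#' Convert a UCSC cytoBand file to the arm-table format
#'
#' Reads the 5-column UCSC `cytoBand.txt` schema (chrom, start, end, band,
#' stain) and reduces it to the minimal digest used by [build_template()]:
#' chromosome length is the maximum band end and the centromere start is
#' the start of the first `acen` band.
#'
#' @param path path to a cytoBand.txt(.gz) file.
#' @return data.frame with columns `chrom`, `length`, `centromere_start`.
#' @export
read_ucsc_cytoband <- function(path) {
  cb <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "band",
                                        "stain"),
                          stringsAsFactors = FALSE)
  chroms <- unique(cb$chrom)
  out <- lapply(chroms, function(cn) {
    sub <- cb[cb$chrom == cn, , drop = FALSE]
    acen <- sub[sub$stain == "acen", , drop = FALSE]
    if (nrow(acen) == 0) return(NULL)
    data.frame(chrom = cn, length = max(sub$end),
               centromere_start = min(acen$start),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Generate a synthetic reference genome and arm table
#'
#' Writes a FASTA of i.i.d. bases with the requested expected GC fraction
#' plus a matching arm table whose centromere sits at
#' `round(arm_fraction * length)`. Deterministic under `seed`: the same
#' seed produces byte-identical files. Used so no genome download is ever
#' needed to run or test the simulator.
#'
#' @param n_chromosomes number of chromosomes (>= 1), named chr1, chr2, ...
#' @param chrom_length length of each chromosome in bp.
#' @param arm_fraction fraction of the chromosome on the p arm, in (0, 1).
#' @param gc expected GC content, in \[0, 1\].
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return list with elements `fasta` and `arm_table` (file paths).
#' @export
generate_synthetic_reference <- function(n_chromosomes = 2,
                                         chrom_length = 1e6,
                                         arm_fraction = 0.4, gc = 0.41,
                                         seed = 1, dir = tempdir()) {
  check_that(n_chromosomes >= 1, "`n_chromosomes` must be >= 1")
  check_that(arm_fraction > 0 && arm_fraction < 1,
             "`arm_fraction` must be in (0, 1)")
  check_that(gc >= 0 && gc <= 1, "`gc` must be in [0, 1]")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chromosomes), function(i) {
    paste(sample(names(probs), chrom_length, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- sprintf("chr%d", seq_len(n_chromosomes))
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(dna, fasta)
  arms <- data.frame(chrom = names(dna), length = chrom_length,
                     centromere_start = round(arm_fraction * chrom_length),
                     stringsAsFactors = FALSE)
  arm_path <- file.path(dir, "arms.tsv")
  utils::write.table(arms, arm_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, arm_table = arm_path)
}

#' Initialize a healthy diploid genome
#'
#' Every chromosome starts with exactly two allele lineages, labeled `A`
#' and `B`, each carrying the reference regions `0..R-1` in order. Allele
#' lineages created later by duplications or WGD get derived labels (e.g.
#' `A.dup1`, `B.wgd1`); the leading letter records the founding haplotype.
#'
#' @param template a `genome_template`.
#' @return an object of class `cell_genome`: a named list (one element per
#'   chromosome) of named lists of integer vectors (0-based reference
#'   region indices per allele lineage).
#' @export
init_diploid_genome <- function(template) {
  check_that(inherits(template, "genome_template"), "invalid template")
  g <- lapply(seq_len(nrow(template$chrom)), function(i) {
    r <- 0:(template$chrom$n_regions[i] - 1L)
    list(A = as.integer(r), B = as.integer(r))
  })
  names(g) <- template$chrom$name
  structure(g, class = "cell_genome")
}

#' @export
print.cell_genome <- function(x, ...) {
  for (cn in names(x)) {
    lens <- vapply(x[[cn]], length, integer(1))
    cat(cn, ": ", paste(sprintf("%s(%d)", names(lens), lens),
                        collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

# bp length of each region of chromosome i of the template
region_bp_lengths <- function(template, i) {
  R <- template$chrom$n_regions[i]
  len <- rep(template$region_size, R)
  last <- template$chrom$length[i] - (R - 1) * template$region_size
  len[R] <- last
  len
}
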