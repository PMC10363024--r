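#' Coverage and sequencing model parameters
#'
#' Parameters of the read generator. Reads are drawn per fixed-size window
#' per genome copy, so the expected depth at a locus of copy number c is
#' `(c / 2) * coverage` by construction. The per-window rate multipliers
#' follow a stationary lognormal AR(1) process giving a smooth coverage
#' landscape with one dispersion knob (`coverage_sd`) and one smoothness
#' knob (`autocorrelation`).
#'
#' @param coverage mean sequencing depth C across a diploid genome (x).
#' @param window_size window size in bp for read-count generation.
#' @param read_length read length L in bp.
#' @param insert_mean,insert_sd fragment (insert) size mean and s.d. in bp;
#'   `read_length <= insert_mean` is required.
#' @param error_rate per-base substitution error probability, in \[0, 1\].
#' @param coverage_sd s.d. of the log-scale coverage fluctuation (sigma_c).
#' @param autocorrelation lag-1 autocorrelation rho of the log-coverage
#'   process, in \[0, 1).
#' @return an object of class `coverage_model`.
#' @export
coverage_model <- function(coverage = 0.1, window_size = 1e6,
                           read_length = 100, insert_mean = 350,
                           insert_sd = 50, error_rate = 0.002,
                           coverage_sd = 0.3, autocorrelation = 0.5) {
  check_that(coverage >= 0, "`coverage` must be >= 0")
  check_that(read_length >= 1 && read_length <= insert_mean,
             "`read_length` must be in [1, insert_mean]")
  check_that(error_rate >= 0 && error_rate <= 1,
             "`error_rate` must be in [0, 1]")
  check_that(coverage_sd >= 0, "`coverage_sd` must be >= 0")
  check_that(autocorrelation >= 0 && autocorrelation < 1,
             "`autocorrelation` must be in [0, 1)")
  check_that(window_size >= read_length,
             "`window_size` must be >= `read_length`")
  structure(list(coverage = coverage, window_size = window_size,
                 read_length = read_length, insert_mean = insert_mean,
                 insert_sd = insert_sd, error_rate = error_rate,
                 coverage_sd = coverage_sd,
                 autocorrelation = autocorrelation),
            class = "coverage_model")
}

#' Build a haplotype pair from a reference genome
#'
#' Haplotype 1 is the reference itself; haplotype 2 carries
#' `Binomial(length, snp_rate)` substitutions per chromosome at uniformly
#' chosen sites, each to a uniformly chosen different base. The SNP truth
#' table records every site. Assigning the two founding alleles to separate
#' haplotypes is what makes the simulated reads haplotype-aware.
#'
#' @param reference FASTA path or a [Biostrings::DNAStringSet].
#' @param snp_rate per-bp heterozygous SNP rate theta, in \[0, 0.1\].
#' @return an object of class `haplotype_pair`: list with `hap1`, `hap2`
#'   (DNAStringSet) and `snps` (data.frame chrom, pos (1-based), hap1,
#'   hap2).
#' @export
make_haplotypes <- function(reference, snp_rate = 0.001) {
  check_that(snp_rate >= 0 && snp_rate <= 0.1,
             "`snp_rate` must be in [0, 0.1]")
  hap1 <- if (inherits(reference, "DNAStringSet")) reference
          else Biostrings::readDNAStringSet(reference)
  names(hap1) <- sub("\\s.*$", "", names(hap1))
  hap2 <- hap1
  bases <- c("A", "C", "G", "T")
  snps <- list()
  for (i in seq_along(hap1)) {
    len <- Biostrings::width(hap1)[i]
    n_snp <- stats::rbinom(1L, len, snp_rate)
    if (n_snp == 0L) next
    pos <- sort(sample.int(len, n_snp))
    ref_b <- strsplit(as.character(Biostrings::subseq(
      hap1[[i]], 1L, len))[1], "")[[1]][pos]
    alt_b <- vapply(ref_b, function(b) sample(setdiff(bases, b), 1L),
                    character(1), USE.NAMES = FALSE)
    hap2[[i]] <- Biostrings::replaceLetterAt(
      hap2[[i]], at = pos, letter = paste(alt_b, collapse = ""))
    snps[[length(snps) + 1L]] <- data.frame(
      chrom = names(hap1)[i], pos = pos, hap1 = ref_b, hap2 = alt_b,
      stringsAsFactors = FALSE)
  }
  snps <- if (length(snps)) do.call(rbind, snps)
          else data.frame(chrom = character(0), pos = integer(0),
                          hap1 = character(0), hap2 = character(0),
                          stringsAsFactors = FALSE)
  structure(list(hap1 = hap1, hap2 = hap2, snps = snps),
            class = "haplotype_pair")
}

#' Write the SNP truth table
#' @param haplotypes a `haplotype_pair`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_snp_table <- function(haplotypes, path) {
  data.table::fwrite(haplotypes$snps, path, sep = "\t", quote = FALSE)
  invisible(path)
}

founding_haplotype <- function(label) {
  if (startsWith(label, "A")) 1L else 2L
}

#' Reconstruct full DNA sequences of a mutated genome
#'
#' Substitutes each region of every allele lineage with its corresponding
#' reference segment, taken from haplotype 1 for A-derived lineages and
#' haplotype 2 for B-derived lineages (lineages created by duplication or
#' WGD inherit their source's haplotype through the leading letter of the
#' label).
#'
#' @param genome a `cell_genome`.
#' @param haplotypes a `haplotype_pair`.
#' @param template the `genome_template`.
#' @return nested list: `sequences[[chrom]][[allele]]` is a character
#'   string of the allele lineage's reconstructed sequence.
#' @export
reconstruct_sequence <- function(genome, haplotypes, template) {
  out <- list()
  for (i in seq_len(nrow(template$chrom))) {
    cn <- template$chrom$name[i]
    clen <- template$chrom$length[i]
    rs <- template$region_size
    hap_str <- c(as.character(haplotypes$hap1[[cn]]),
                 as.character(haplotypes$hap2[[cn]]))
    out[[cn]] <- list()
    for (lab in names(genome[[cn]])) {
      regions <- genome[[cn]][[lab]]
      if (length(regions) == 0L) {
        out[[cn]][[lab]] <- ""
        next
      }
      hs <- hap_str[founding_haplotype(lab)]
      starts <- regions * rs + 1
      ends <- pmin((regions + 1) * rs, clen)
      out[[cn]][[lab]] <- paste(substring(hs, starts, ends), collapse = "")
    }
  }
  out
}

#' Simulate smooth per-window coverage rate multipliers
#'
#' Log-multipliers follow a stationary AR(1) process:
#' `x_1 ~ N(0, sigma^2)`, `x_t = rho x_{t-1} + N(0, sigma^2 (1 - rho^2))`;
#' the multiplier is `exp(x - sigma^2 / 2)` so its mean is exactly 1.
#'
#' @param n_windows number of windows (>= 1).
#' @param model a `coverage_model`.
#' @return numeric vector of positive rate multipliers with mean 1.
#' @export
simulate_window_rates <- function(n_windows, model) {
  check_that(n_windows >= 1, "`n_windows` must be >= 1")
  sigma <- model$coverage_sd
  if (sigma == 0) return(rep(1, n_windows))
  rho <- model$autocorrelation
  x1 <- stats::rnorm(1L, 0, sigma)
  if (n_windows == 1L) return(exp(x1 - sigma^2 / 2))
  innov <- stats::rnorm(n_windows - 1L, 0, sigma * sqrt(1 - rho^2))
  x <- c(x1, stats::filter(innov, rho, method = "recursive", init = x1))
  exp(x - sigma^2 / 2)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substitute each base with prob e to a uniformly different base
add_base_errors <- function(reads, e) {
  if (e == 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads)
  k <- stats::rbinom(length(reads), L, e)
  hit <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(L[i], k[i])
    chars <- strsplit(reads[i], "")[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Generate haplotype-aware paired-end reads for one cell
#'
#' Each allele lineage's reconstructed sequence is partitioned into
#' non-overlapping windows of `window_size` bp. For a window of length w
#' with rate multiplier r the number of read pairs drawn from that copy is
#' `Poisson((C / 2) * w * r / (2 L))`, so the expected depth at a
#' copy-number-c locus is `(c / 2) * C * r`. Fragment starts are uniform in
#' the window; fragment lengths are `Normal(insert_mean, insert_sd)`
#' clipped to at least the read length (and to the sequence end). Mate 1 is
#' the fragment's 5' `read_length` bp, mate 2 the reverse complement of its
#' 3' end; each base is substituted with probability `error_rate` to a
#' uniformly different base and qualities are constant Phred-30. Read names
#' encode cell, chromosome, allele lineage, window, pair index and true
#' haplotype.
#'
#' @param sequences reconstructed sequences from [reconstruct_sequence()].
#' @param model a `coverage_model`.
#' @param cell_id cell identifier used in file names and read names.
#' @param dir output directory.
#' @return list with `r1`, `r2` (gzipped FASTQ paths) and `n_pairs`.
#' @export
generate_reads <- function(sequences, model, cell_id, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  L <- model$read_length
  W <- model$window_size
  qual <- strrep("?", L)  # Phred-30
  lines1 <- list()
  lines2 <- list()
  n_pairs <- 0L
  clip_warned <- FALSE

  for (cn in names(sequences)) {
    for (lab in names(sequences[[cn]])) {
      s <- sequences[[cn]][[lab]]
      slen <- nchar(s)
      if (slen < L) next
      hap <- founding_haplotype(lab)
      w_starts <- seq(1L, slen, by = W)
      rates <- simulate_window_rates(length(w_starts), model)
      for (wi in seq_along(w_starts)) {
        ws <- w_starts[wi]
        wlen <- min(W, slen - ws + 1L)
        mu <- (model$coverage / 2) * wlen * rates[wi] / (2 * L)
        np <- stats::rpois(1L, mu)
        if (np == 0L) next
        if (!clip_warned && wlen < model$insert_mean) {
          warning("window shorter than the mean insert size; fragments clipped",
                  call. = FALSE)
          clip_warned <- TRUE
        }
        fs <- ws - 1L + sample.int(wlen, np, replace = TRUE)
        flen <- pmax(L, round_half_away(stats::rnorm(np, model$insert_mean,
                                                     model$insert_sd)))
        fe <- pmin(fs + flen - 1, slen)
        fs <- pmax(1, pmin(fs, fe - L + 1))
        m1 <- add_base_errors(substring(s, fs, fs + L - 1L),
                              model$error_rate)
        m2 <- add_base_errors(revcomp_chr(substring(s, fe - L + 1L, fe)),
                              model$error_rate)
        ids <- sprintf("%s:%s:%s:w%d:p%d:h%d", cell_id, cn, lab, wi,
                       n_pairs + seq_len(np), hap)
        lines1[[length(lines1) + 1L]] <-
          as.vector(rbind(paste0("@", ids, "/1"), m1, "+", qual))
        lines2[[length(lines2) + 1L]] <-
          as.vector(rbind(paste0("@", ids, "/2"), m2, "+", qual))
        n_pairs <- n_pairs + np
      }
    }
  }
  r1 <- file.path(dir, paste0(cell_id, "_R1.fastq.gz"))
  r2 <- file.path(dir, paste0(cell_id, "_R2.fastq.gz"))
  for (fp in list(list(r1, lines1), list(r2, lines2))) {
    con <- gzfile(fp[[1L]], "wb")
    out <- unlist(fp[[2L]], use.names = FALSE)
    writeLines(if (is.null(out)) character(0) else out, con)
    close(con)
  }
  list(r1 = r1, r2 = r2, n_pairs = n_pairs)
}
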