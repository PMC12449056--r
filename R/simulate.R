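#' Configuration for the hierarchical pseudo-sequence simulator
#'
#' The simulator emulates the structure of genotype pseudo-sequences built
#' from a joint variant call over many samples: every sample carries one
#' symbol per shared variant locus, loci are grouped into chromosomes, and
#' genetic divergence is hierarchical (species differ much more than
#' cultivars within a species, which differ more than samples within a
#' cultivar).  Defaults describe a small five-species collection with 19
#' chromosomes of 2,000 loci each, three cultivars per species and three
#' samples per cultivar.
#'
#' @param seed Integer seed; the simulation is fully determined by it.
#' @param n_chromosomes Number of chromosomes (default 19).
#' @param loci_per_chromosome Loci per chromosome when `chromosome_lengths`
#'   is not given.
#' @param n_species Number of species classes.
#' @param cultivars_per_species Cultivar classes within each species.
#' @param samples_per_cultivar Samples drawn from each cultivar.
#' @param species_divergence Fraction of loci substituted from the root
#'   sequence in each species founder.
#' @param cultivar_divergence Additional fraction substituted per cultivar
#'   within its species.
#' @param sample_noise Additional fraction substituted per sample within its
#'   cultivar.
#' @param ambiguity_rate Fraction of loci replaced by `"N"` per sample
#'   (missing/ambiguous genotype calls).
#' @param chromosome_lengths Optional integer vector of per-chromosome locus
#'   counts, overriding `loci_per_chromosome` (mimics unequal chromosome
#'   sizes at small scale).
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_collection()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes = 3, loci_per_chromosome = 100)
sim_config <- function(seed,
                       n_chromosomes = 19L,
                       loci_per_chromosome = 2000L,
                       n_species = 5L,
                       cultivars_per_species = 3L,
                       samples_per_cultivar = 3L,
                       species_divergence = 0.05,
                       cultivar_divergence = 0.005,
                       sample_noise = 0.001,
                       ambiguity_rate = 0,
                       chromosome_lengths = NULL) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  assert_fraction(species_divergence, "species_divergence")
  assert_fraction(cultivar_divergence, "cultivar_divergence")
  assert_fraction(sample_noise, "sample_noise")
  assert_fraction(ambiguity_rate, "ambiguity_rate")
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- rep(as.integer(loci_per_chromosome),
                              as.integer(n_chromosomes))
  } else {
    chromosome_lengths <- as.integer(chromosome_lengths)
    n_chromosomes <- length(chromosome_lengths)
  }
  if (any(chromosome_lengths < 1L) || sum(chromosome_lengths) < 1L) {
    stop("invalid config: every chromosome needs at least one locus",
         call. = FALSE)
  }
  for (nm in c("n_species", "cultivars_per_species", "samples_per_cultivar")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 1L) stop(sprintf("'%s' must be >= 1", nm),
                                       call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_lengths = chromosome_lengths,
    n_species = as.integer(n_species),
    cultivars_per_species = as.integer(cultivars_per_species),
    samples_per_cultivar = as.integer(samples_per_cultivar),
    species_divergence = species_divergence,
    cultivar_divergence = cultivar_divergence,
    sample_noise = sample_noise,
    ambiguity_rate = ambiguity_rate
  ), class = "sim_config")
}

# Substitute the bases at 'idx' by a uniform choice among the 3 other bases.
substitute_bases <- function(chars, idx) {
  if (!length(idx)) return(chars)
  bases <- c("A", "C", "G", "T")
  cur <- match(chars[idx], bases)
  step <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- bases[((cur - 1L + step) %% 4L) + 1L]
  chars
}

split_by_chromosome <- function(chars, chr_len, chr_names) {
  ends <- cumsum(chr_len)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- vapply(seq_along(chr_len), function(i) {
    paste0(chars[starts[i]:ends[i]], collapse = "")
  }, character(1L))
  names(out) <- chr_names
  out
}

#' Simulate a labelled pseudo-sequence collection
#'
#' Draws a root sequence uniformly over `{A,C,G,T}`, derives one founder per
#' species by substituting `round(species_divergence * L)` loci (sampled
#' without replacement, each replaced by a uniform choice among the three
#' other bases), derives each cultivar from its species founder with
#' `round(cultivar_divergence * L)` further substitutions, and each sample
#' from its cultivar with `round(sample_noise * L)` substitutions plus
#' `round(ambiguity_rate * L)` loci overwritten with `"N"`.  Every mutated
#' locus index is recorded so tests can reason about exact divergence.
#'
#' @param config A [sim_config()].
#' @return An object of class `cgr_sim` with elements
#'   \describe{
#'     \item{config}{the input configuration}
#'     \item{chromosomes}{named integer vector of chromosome lengths}
#'     \item{root}{named character vector, root sequence per chromosome}
#'     \item{sequences}{list `sample_id -> named chromosome string vector`}
#'     \item{manifest}{data.frame with `sample_id`, `species`, `cultivar`}
#'     \item{truth}{recorded mutated locus indices per species, cultivar and
#'       sample (genome-wide 1-based coordinates), and per-sample `"N"` loci}
#'   }
#' @export
#' @examples
#' sim <- simulate_collection(sim_config(seed = 1, n_chromosomes = 2,
#'                                       loci_per_chromosome = 50,
#'                                       n_species = 2))
#' sim$manifest
simulate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chr_len <- config$chromosome_lengths
  L <- sum(chr_len)
  chr_names <- sprintf("chr%02d", seq_along(chr_len))
  n_mut <- function(rate) as.integer(round(rate * L))

  withr::with_seed(config$seed, {
    root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

    sequences <- list()
    manifest <- list()
    truth <- list(species = list(), cultivar = list(), sample = list())

    for (s in seq_len(config$n_species)) {
      sp_label <- sprintf("species_%02d", s)
      sp_idx <- sort(sample.int(L, n_mut(config$species_divergence)))
      sp_chars <- substitute_bases(root, sp_idx)
      truth$species[[sp_label]] <- sp_idx

      for (cv in seq_len(config$cultivars_per_species)) {
        cv_label <- sprintf("sp%02d_cv%02d", s, cv)
        cv_idx <- sort(sample.int(L, n_mut(config$cultivar_divergence)))
        cv_chars <- substitute_bases(sp_chars, cv_idx)
        truth$cultivar[[cv_label]] <- cv_idx

        for (r in seq_len(config$samples_per_cultivar)) {
          sid <- sprintf("sp%02d_cv%02d_s%02d", s, cv, r)
          noise_idx <- sort(sample.int(L, n_mut(config$sample_noise)))
          chars <- substitute_bases(cv_chars, noise_idx)
          amb_idx <- sort(sample.int(L, n_mut(config$ambiguity_rate)))
          chars[amb_idx] <- "N"
          truth$sample[[sid]] <- list(substituted = noise_idx,
                                      ambiguous = amb_idx)
          sequences[[sid]] <- split_by_chromosome(chars, chr_len, chr_names)
          manifest[[sid]] <- data.frame(sample_id = sid,
                                        species = sp_label,
                                        cultivar = cv_label,
                                        stringsAsFactors = FALSE)
        }
      }
    }
  })

  structure(list(
    config = config,
    chromosomes = stats::setNames(chr_len, chr_names),
    root = split_by_chromosome(root, chr_len, chr_names),
    sequences = sequences,
    manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
    truth = truth
  ), class = "cgr_sim")
}

#' @export
print.cgr_sim <- function(x, ...) {
  cat(sprintf(paste0("cgr_sim: %d samples (%d species x %d cultivars x %d",
                     " reps), %d chromosomes, %d loci\n"),
              nrow(x$manifest), x$config$n_species,
              x$config$cultivars_per_species, x$config$samples_per_cultivar,
              x$config$n_chromosomes, sum(x$chromosomes)))
  invisible(x)
}

#' Write simulated pseudo-sequences as FASTA
#'
#' One record per sample-chromosome with header `sampleID|chrN`, and/or one
#' concatenated record per sample with header `sampleID|genome`.  Records are
#' wrapped at 80 columns.
#'
#' @param sim A `cgr_sim` object.
#' @param dir Output directory (created if absent).
#' @param per_chromosome Write `<sample>.fa` files with per-chromosome
#'   records.
#' @param genome Also write `<sample>.genome.fa` with the concatenated
#'   sequence.
#' @return Invisibly, the paths written.
#' @export
write_sim_fasta <- function(sim, dir, per_chromosome = TRUE, genome = FALSE) {
  stopifnot(inherits(sim, "cgr_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sid in names(sim$sequences)) {
    seqs <- sim$sequences[[sid]]
    if (per_chromosome) {
      x <- Biostrings::DNAStringSet(seqs)
      names(x) <- paste0(sid, "|", names(seqs))
      p <- file.path(dir, paste0(sid, ".fa"))
      Biostrings::writeXStringSet(x, p, width = 80L)
      paths <- c(paths, p)
    }
    if (genome) {
      g <- Biostrings::DNAStringSet(concat_genome(seqs))
      names(g) <- paste0(sid, "|genome")
      p <- file.path(dir, paste0(sid, ".genome.fa"))
      Biostrings::writeXStringSet(g, p, width = 80L)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Write the simulation manifest as CSV
#'
#' @param sim A `cgr_sim` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sim_manifest <- function(sim, path) {
  stopifnot(inherits(sim, "cgr_sim"))
  utils::write.csv(sim$manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Emit a toy multi-sample variant table from a simulation
#'
#' Produces minimal VCF-style text with the simulation root as the reference:
#' one row per locus at which any sample deviates from the root, identical
#' locus list across samples (the joint-call convention where per-sample
#' variant filtering is disabled), and a per-sample `GT` column.  Genotypes
#' are homozygous (`0/0` for reference, `j/j` for the j-th alternate) because
#' the simulator draws haploid-style symbols; `"N"` becomes a missing call
#' `./.`.
#'
#' @param sim A `cgr_sim` object.
#' @param path Optional file to write; when `NULL` the lines are returned
#'   only.
#' @return Invisibly (or visibly when `path` is `NULL`), the character vector
#'   of VCF lines.
#' @export
emit_toy_variant_table <- function(sim, path = NULL) {
  stopifnot(inherits(sim, "cgr_sim"))
  samples <- names(sim$sequences)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cgrtyper_simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(sim$chromosomes),
            sim$chromosomes),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- character(0)
  for (chr in names(sim$chromosomes)) {
    ref <- strsplit(sim$root[[chr]], "", fixed = TRUE)[[1]]
    mat <- vapply(samples,
                  function(sid) strsplit(sim$sequences[[sid]][[chr]], "",
                                         fixed = TRUE)[[1]],
                  character(length(ref)))
    if (length(ref) == 1L) mat <- matrix(mat, nrow = 1L,
                                         dimnames = list(NULL, samples))
    rows <- which(rowSums(mat != ref) > 0)
    for (i in rows) {
      obs <- mat[i, ]
      alts <- sort(setdiff(unique(obs), c(ref[i], "N")))
      gt <- ifelse(obs == "N", "./.",
                   ifelse(obs == ref[i], "0/0",
                          paste0(match(obs, alts), "/", match(obs, alts))))
      body <- c(body, paste(c(chr, i, ".", ref[i],
                              if (length(alts)) paste(alts, collapse = ",")
                              else ".",
                              ".", ".", ".", "GT", gt), collapse = "\t"))
    }
  }
  lines <- c(header, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
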