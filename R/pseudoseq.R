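# Genotype -> pseudo-DNA encoding.
#
# Each shared variant locus contributes exactly one symbol per sample, so
# sequences are position-aligned ("orthologous") across samples: homozygous
# calls map to the allele base, heterozygous SNPs to the IUPAC two-base
# ambiguity code, and indel alleles or missing calls to 'N' (one symbol per
# locus keeps all samples the same length).

IUPAC_PAIR <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Encode one diploid genotype as a single pseudo-sequence symbol
#'
#' Homozygous reference gives the reference base; a homozygous SNP alternate
#' gives that base; a heterozygous SNP gives the IUPAC ambiguity code of the
#' two bases (e.g. A/G -> `R`); any allele that is not exactly one base
#' (an indel) and any missing genotype give `"N"`.
#'
#' @param ref Reference allele (single string).
#' @param alts Character vector of alternate alleles (may be empty).
#' @param gt Genotype string(s) such as `"0/0"`, `"0/1"`, `"1|2"`, `"./."`.
#' @return Character vector of single symbols, one per genotype.
#' @export
#' @examples
#' genotype_to_base("A", "G", c("0/0", "0/1", "1/1", "./."))
genotype_to_base <- function(ref, alts, gt) {
  alleles <- c(ref, alts)
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) == 1L) p <- c(p, p)
    if (any(p == ".") || any(is.na(p))) return("N")
    i <- suppressWarnings(as.integer(p)) + 1L
    if (any(is.na(i)) || any(i < 1L) || any(i > length(alleles))) {
      stop("malformed genotype record: allele index out of range",
           call. = FALSE)
    }
    encode_allele_pair(alleles[i[1L]], alleles[i[2L]])
  }, character(1L))
}

encode_allele_pair <- function(a, b) {
  if (is.na(a) || is.na(b) || nchar(a) != 1L || nchar(b) != 1L) return("N")
  if (a == "N" || b == "N") return("N")
  if (a == b) return(a)
  IUPAC_PAIR[[paste0(min(a, b), max(a, b))]] %||% "N"
}

read_variant_table <- function(x) {
  if (inherits(x, "vcfR")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(vcfR::read.vcfR(x, verbose = FALSE))
  }
  stop("expected a vcfR object or a path to a VCF file", call. = FALSE)
}

#' Convert a multi-sample variant table into pseudo-DNA sequences
#'
#' Reads a (minimal, text) VCF — all samples must share one locus list, the
#' output of a joint call without per-sample variant filtering — and emits,
#' per sample and per chromosome, the string of encoded genotype symbols in
#' locus order.  All samples yield identical sequence lengths per chromosome.
#'
#' @param vcf Path to a VCF file, or a `vcfR::vcfR` object.
#' @param samples Optional subset of sample names to encode.
#' @return An object of class `pseudoseq_set`: list with `samples`,
#'   `chromosomes` (in input order) and `seqs`, a list
#'   `sample_id -> named chromosome string vector`.
#' @export
variants_to_pseudoseqs <- function(vcf, samples = NULL) {
  v <- read_variant_table(vcf)
  fix <- v@fix
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  # positions must be strictly increasing within each chromosome block
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      stop(sprintf("ordering error: positions not strictly increasing on %s",
                   ch), call. = FALSE)
    }
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) {
    stop("schema error: no per-sample GT fields found", call. = FALSE)
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing)) {
      stop(sprintf("schema error: samples absent from table: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    gt <- gt[, samples, drop = FALSE]
  }
  n_loci <- nrow(fix)
  n_samp <- ncol(gt)

  alt_split <- strsplit(ifelse(is.na(fix[, "ALT"]) | fix[, "ALT"] == ".",
                               "", fix[, "ALT"]), ",", fixed = TRUE)
  alleles <- mapply(function(r, a) c(r, a), fix[, "REF"], alt_split,
                    SIMPLIFY = FALSE, USE.NAMES = FALSE)
  n_alleles <- lengths(alleles)
  max_a <- max(n_alleles)
  allele_mat <- matrix(NA_character_, n_loci, max_a)
  for (j in seq_len(max_a)) {
    has <- n_alleles >= j
    allele_mat[has, j] <- vapply(alleles[has], `[[`, character(1L), j)
  }

  g <- gt
  g[is.na(g)] <- "./."
  first <- sub("^([^/|]*).*$", "\\1", g)
  second <- sub("^[^/|]*[/|]?", "", g)
  second[second == ""] <- first[second == ""]
  a_idx <- suppressWarnings(matrix(as.integer(first), n_loci, n_samp))
  b_idx <- suppressWarnings(matrix(as.integer(second), n_loci, n_samp))
  loc <- as.vector(row(a_idx))
  bad <- (!is.na(a_idx) & (a_idx < 0L | a_idx + 1L > n_alleles[loc])) |
    (!is.na(b_idx) & (b_idx < 0L | b_idx + 1L > n_alleles[loc]))
  if (any(bad)) {
    stop("malformed genotype record: allele index out of range",
         call. = FALSE)
  }
  a_chr <- allele_mat[cbind(loc, as.vector(a_idx) + 1L)]
  b_chr <- allele_mat[cbind(loc, as.vector(b_idx) + 1L)]

  sym <- rep("N", n_loci * n_samp)
  ok <- !is.na(a_chr) & !is.na(b_chr) &
    nchar(a_chr) == 1L & nchar(b_chr) == 1L &
    a_chr != "N" & b_chr != "N"
  hom <- ok & a_chr == b_chr
  sym[hom] <- a_chr[hom]
  het <- ok & a_chr != b_chr
  if (any(het)) {
    key <- paste0(pmin(a_chr[het], b_chr[het]), pmax(a_chr[het], b_chr[het]))
    code <- IUPAC_PAIR[key]
    code[is.na(code)] <- "N"
    sym[het] <- code
  }
  sym <- matrix(sym, n_loci, n_samp, dimnames = list(NULL, colnames(gt)))

  chroms <- unique(chrom)
  seqs <- lapply(colnames(sym), function(sid) {
    out <- vapply(chroms, function(ch) {
      paste0(sym[chrom == ch, sid], collapse = "")
    }, character(1L))
    names(out) <- chroms
    out
  })
  names(seqs) <- colnames(sym)
  structure(list(samples = colnames(sym), chromosomes = chroms, seqs = seqs),
            class = "pseudoseq_set")
}

#' @export
print.pseudoseq_set <- function(x, ...) {
  cat(sprintf("pseudoseq_set: %d samples, %d chromosomes, %d loci\n",
              length(x$samples), length(x$chromosomes),
              sum(nchar(x$seqs[[1L]]))))
  invisible(x)
}

#' Concatenate one sample's chromosome sequences into a genome sequence
#'
#' Chromosomes are concatenated in natural sort order of their identifiers
#' (`chr2` before `chr10`), so the result does not depend on input order.
#'
#' @param chr_seqs Named character vector, chromosome id -> sequence string.
#' @param expected Optional character vector of chromosome ids that must all
#'   be present (a missing one raises a completeness error).
#' @return Single genome sequence string.
#' @export
#' @examples
#' concat_genome(c(chr2 = "ACGT", chr10 = "TT", chr1 = "GG"))
concat_genome <- function(chr_seqs, expected = NULL) {
  stopifnot(is.character(chr_seqs), !is.null(names(chr_seqs)))
  if (!is.null(expected)) {
    missing <- setdiff(expected, names(chr_seqs))
    if (length(missing)) {
      stop(sprintf("completeness error: missing chromosome(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  paste0(chr_seqs[natural_order(names(chr_seqs))], collapse = "")
}

#' Write a pseudo-sequence set as FASTA
#'
#' @param pset A `pseudoseq_set`.
#' @param dir Output directory.
#' @param genome Write concatenated `sampleID|genome` records instead of
#'   per-chromosome records.
#' @return Invisibly, the paths written.
#' @export
write_pseudoseq_fasta <- function(pset, dir, genome = FALSE) {
  stopifnot(inherits(pset, "pseudoseq_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sid in pset$samples) {
    if (genome) {
      x <- Biostrings::DNAStringSet(concat_genome(pset$seqs[[sid]]))
      names(x) <- paste0(sid, "|genome")
      p <- file.path(dir, paste0(sid, ".genome.fa"))
    } else {
      x <- Biostrings::DNAStringSet(pset$seqs[[sid]])
      names(x) <- paste0(sid, "|", names(pset$seqs[[sid]]))
      p <- file.path(dir, paste0(sid, ".fa"))
    }
    Biostrings::writeXStringSet(x, p, width = 80L)
    paths <- c(paths, p)
  }
  invisible(paths)
}
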