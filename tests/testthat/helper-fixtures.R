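# Shared fixture builders: everything is generated in code at test time.

tiny_sim <- function(seed = 11, n_chromosomes = 3, loci = 200,
                     n_species = 2, cultivars = 2, reps = 3,
                     species_div = 0.1, cultivar_div = 0.02,
                     noise = 0.005, ambiguity = 0) {
  simulate_collection(sim_config(
    seed = seed, n_chromosomes = n_chromosomes,
    loci_per_chromosome = loci, n_species = n_species,
    cultivars_per_species = cultivars, samples_per_cultivar = reps,
    species_divergence = species_div, cultivar_divergence = cultivar_div,
    sample_noise = noise, ambiguity_rate = ambiguity))
}

species_manifest <- function(sim) {
  data.frame(sample_id = sim$manifest$sample_id,
             class = sim$manifest$species, stringsAsFactors = FALSE)
}

cultivar_manifest <- function(sim) {
  data.frame(sample_id = sim$manifest$sample_id,
             class = sim$manifest$cultivar, stringsAsFactors = FALSE)
}

random_acgt <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent slow CGR oracle: literal loop over the midpoint rule.
cgr_trajectory_loop <- function(seq) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  cx <- c(A = 0, C = 0, G = 1, T = 1)
  cy <- c(A = 0, C = 1, G = 1, T = 0)
  p <- c(0.5, 0.5)
  out <- matrix(NA_real_, length(b), 2)
  for (i in seq_along(b)) {
    tgt <- if (b[i] %in% names(cx)) c(cx[[b[i]]], cy[[b[i]]]) else c(0.5, 0.5)
    p <- (p + tgt) / 2
    out[i, ] <- p
  }
  out
}

pixel_of <- function(x, y, R) {
  c(row = min(floor((1 - y) * R), R - 1), col = min(floor(x * R), R - 1))
}
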