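# Small in-memory image sets built from a strongly separated simulation.
sep_setup <- function(seed = 31, n_chromosomes = 4) {
  sim <- tiny_sim(seed = seed, n_chromosomes = n_chromosomes, loci = 400,
                  n_species = 3, cultivars = 1, reps = 4,
                  species_div = 0.1, cultivar_div = 0, noise = 0.002)
  iset <- suppressWarnings(build_image_set(sim$sequences, resolution = 16,
                                           normalize = "linear"))
  man <- split_samples(species_manifest(sim), seed = seed)
  list(sim = sim, iset = iset, man = man)
}

test_that("late-integration majority vote handles unanimity and majority", {
  s <- sep_setup()
  bank <- fit_model_bank(s$iset$units, s$man)
  test_ids <- s$man$sample_id[s$man$split == "test"]
  rec <- predict_late_integration(bank, s$iset$units, test_ids)
  votes <- attr(rec, "votes")
  expect_identical(dim(votes), c(length(test_ids), length(bank)))
  # tallies always conserve the number of voting models
  for (tal in attr(rec, "tallies")) {
    expect_identical(sum(tal), as.integer(length(bank)))
  }
  # strongly separated data: votes are unanimous, final = the voted class
  unanimous <- apply(votes, 1, function(v) length(unique(v)) == 1)
  expect_identical(rec$predicted[unanimous], unname(votes[unanimous, 1]))
})

test_that("vote tie-breaking uses score mass then lexicographic label", {
  # constructed two-model tie: one vote each for "a" and "b"
  fake_model <- function(cls, centre) {
    structure(list(classes = c("a", "b"),
                   centroids = rbind(a = centre$a, b = centre$b), p = 2),
              class = "centroid_classifier")
  }
  x <- matrix(c(0, 0), 1, dimnames = list("s1", NULL))
  m_a <- fake_model(centre = list(a = c(0, 0), b = c(5, 5)))   # votes a
  m_b <- fake_model(centre = list(a = c(9, 9), b = c(1, 1)))   # votes b
  bank <- structure(list(u1 = m_a, u2 = m_b), class = "model_bank")
  imgs <- list(u1 = x, u2 = x)
  rec <- predict_late_integration(bank, imgs, "s1")
  # summed score mass: a gets -(0 + dist to (9,9)); b gets -(dist(5,5)+dist(1,1))
  # |(9,9)| ~ 12.73 vs 7.07+1.41 ~ 8.49, so b wins the tie-break
  expect_identical(rec$predicted, "b")
  expect_true(rec$tie_broken)
  # equalize the scores: lexicographic fallback picks "a"
  m_c <- fake_model(centre = list(a = c(5, 5), b = c(0, 0)))   # votes b
  m_d <- fake_model(centre = list(a = c(0, 0), b = c(5, 5)))   # votes a
  bank2 <- structure(list(u1 = m_c, u2 = m_d), class = "model_bank")
  rec2 <- predict_late_integration(bank2, imgs, "s1")
  expect_identical(rec2$predicted, "a")
  expect_true(rec2$tie_broken)
})

test_that("a single-model bank reduces to that model's prediction", {
  s <- sep_setup(n_chromosomes = 1)
  bank <- fit_model_bank(s$iset$units, s$man)
  test_ids <- s$man$sample_id[s$man$split == "test"]
  rec <- predict_late_integration(bank, s$iset$units, test_ids)
  direct <- predict(bank[[1]], s$iset$units[[1]][test_ids, , drop = FALSE])
  expect_identical(rec$predicted, unname(direct))
  expect_false(any(rec$tie_broken))
})

test_that("chromosome-wise mean is the arithmetic mean over chromosomes", {
  s <- sep_setup()
  cw <- run_chromosome_wise(s$iset$units, s$man)
  expect_equal(cw$mean_ba, mean(cw$per_chromosome), tolerance = 1e-12)
  expect_length(cw$per_chromosome, length(s$iset$units))
  # permuting chromosome order leaves the mean unchanged
  cw2 <- run_chromosome_wise(rev(s$iset$units), s$man)
  expect_equal(cw2$mean_ba, cw$mean_ba, tolerance = 1e-12)
})

test_that("early integration pools all chromosome images for training", {
  s <- sep_setup()
  ei <- run_early_integration(s$iset$units, s$man)
  n_test <- sum(s$man$split == "test")
  expect_identical(nrow(ei$predictions), n_test * length(s$iset$units))
  # per-image and per-sample evaluation agree when every chromosome of a
  # sample is classified identically
  by_sample <- split(ei$predictions$predicted, ei$predictions$sample_id)
  if (all(vapply(by_sample, function(v) length(unique(v)) == 1,
                 logical(1)))) {
    ei_s <- run_early_integration(s$iset$units, s$man, per_sample = TRUE)
    expect_equal(ei_s$ba, ei$ba, tolerance = 1e-12)
  }
})

test_that("whole-genome strategy scores one image per sample", {
  s <- sep_setup()
  wg <- run_whole_genome(s$iset$genome, s$man)
  expect_identical(nrow(wg$predictions), sum(s$man$split == "test"))
  expect_identical(nrow(s$iset$genome), nrow(s$man))
})

test_that("genome CGR counts differ from summed chromosome counts only at
           boundary transitions", {
  sim <- tiny_sim(seed = 55, n_chromosomes = 5, loci = 300, ambiguity = 0)
  seqs <- sim$sequences[[1]]
  k <- 3; R <- 2^k
  chr_sum <- Reduce(`+`, lapply(seqs, function(s) unclass(cgr_matrix(s, R))))
  genome <- unclass(cgr_matrix(concat_genome(seqs), R))
  expect_identical(sum(genome), sum(chr_sum))
  # each of the k first points after a boundary may move one count
  max_moved <- 2 * k * (length(seqs) - 1)
  expect_lte(sum(abs(genome - chr_sum)), max_moved)
})

test_that("all four strategies beat chance on separated species", {
  s <- sep_setup(seed = 77)
  chance <- 1 / 3
  expect_gt(run_chromosome_wise(s$iset$units, s$man)$mean_ba, chance)
  expect_gt(run_early_integration(s$iset$units, s$man)$ba, chance)
  expect_gt(run_late_integration(s$iset$units, s$man)$ba, chance)
  expect_gt(run_whole_genome(s$iset$genome, s$man)$ba, chance)
})
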