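test_that("identity similarity is symbol-equality over aligned positions", {
  expect_equal(identity_similarity("AAAA", "AAAA"), 1)
  expect_equal(identity_similarity("AAAA", "AAAT"), 0.75)
  expect_equal(identity_similarity("NN", "NN"), 1)
  expect_equal(identity_similarity("AN", "AA"), 0.5)
  expect_error(identity_similarity("AA", "AAA"), "alignment-contract")
  withr::local_seed(71)
  for (rep in 1:20) {
    a <- random_acgt(50); b <- random_acgt(50)
    expect_equal(identity_similarity(a, b), identity_similarity(b, a))
    expect_identical(identity_similarity(a, b) == 1, a == b)
  }
})

test_that("identity k-NN predicts exact matches and breaks ties stably", {
  train <- c(t1 = "AAAA", t2 = "CCCC", t3 = "GGGG")
  labels <- c("x", "y", "z")
  expect_identical(unname(knn_classify(c(q = "CCCC"), train, labels)), "y")
  # k = train size with balanced labels: all tie, lexicographic label wins
  expect_identical(
    unname(knn_classify(c(q = "TTTT"), train, labels, k = 3)), "x")
  # similarity tie between two equally near neighbours: train order decides
  train2 <- c(t1 = "AATT", t2 = "TTAA")
  expect_identical(
    unname(knn_classify(c(q = "AAAA"), train2, c("p", "q"), k = 1)), "p")
  expect_error(knn_classify(c(q = "A"), character(0), character(0)),
               "empty training set")
})

test_that("k-mer profiles enumerate distinct ACGT-only windows", {
  expect_setequal(kmer_profile("ACGTACGT", k = 4),
                  c("ACGT", "CGTA", "GTAC", "TACG"))
  expect_identical(sort(kmer_profile("AAAA", k = 2)), "AA")
  # windows containing a non-ACGT symbol are skipped, not expanded
  expect_setequal(kmer_profile("ACGNACG", k = 3), c("ACG"))
  expect_identical(kmer_profile("ACG", k = 4), character(0))
  expect_identical(kmer_profile("NNNN", k = 2), character(0))
  expect_error(kmer_profile("ACGT", k = 0), "must be >= 1")
})

test_that("Jaccard similarity is bounded, symmetric, 1 iff equal sets", {
  p <- kmer_profile("ACGTACGT", 4)
  q <- kmer_profile("TTTTTTTT", 4)
  expect_equal(kmer_similarity(p, p), 1)
  expect_equal(kmer_similarity(p, q), 0)
  expect_warning(z <- kmer_similarity(character(0), character(0)), "empty")
  expect_equal(z, 0)
  withr::local_seed(72)
  for (rep in 1:20) {
    a <- kmer_profile(random_acgt(60), 5)
    b <- kmer_profile(random_acgt(60), 5)
    s <- kmer_similarity(a, b)
    expect_true(s >= 0 && s <= 1)
    expect_equal(s, kmer_similarity(b, a))
  }
})

test_that("baseline classifiers recover well-separated species", {
  sim <- tiny_sim(seed = 73, n_chromosomes = 3, loci = 600, n_species = 3,
                  species_div = 0.08, cultivar_div = 0.005, noise = 0.001)
  g <- vapply(sim$sequences, concat_genome, character(1))
  man <- split_samples(species_manifest(sim), seed = 73)
  tr <- man[man$split == "train", ]
  te <- man[man$split == "test", ]
  knn <- knn_classify(g[te$sample_id], g[tr$sample_id], tr$class, k = 1)
  expect_equal(balanced_accuracy_score(te$class, knn), 1)
  kmer <- kmer_nn_classify(g[te$sample_id], g[tr$sample_id], tr$class,
                           k = 21)
  expect_equal(balanced_accuracy_score(te$class, kmer), 1)
})

test_that("kernel SVM separates classes and honours the kernel contract", {
  # two tight clusters on a line; linear kernel built by hand
  withr::local_seed(74)
  x_tr <- c(rnorm(6, 0, 0.1), rnorm(6, 4, 0.1))
  y_tr <- rep(c("lo", "hi"), each = 6)
  x_te <- c(x_tr[1], rnorm(3, 0, 0.1), rnorm(3, 4, 0.1))
  K_tr <- outer(x_tr, x_tr) + 1
  K_te <- outer(x_te, x_tr) + 1
  pred <- kernel_svm_classify(K_tr, y_tr, K_te, C_reg = 2)
  # a duplicated training point keeps its label; clusters are recovered
  expect_identical(unname(pred),
                   c("lo", "lo", "lo", "lo", "hi", "hi", "hi"))
  # training-set prediction is perfect on this separable toy
  self <- kernel_svm_classify(K_tr, y_tr, K_tr, C_reg = 2)
  expect_identical(unname(self), y_tr)
  expect_error(kernel_svm_classify(matrix(c(1, 0, 0.5, 1), 2),
                                   c("a", "b"), matrix(1, 1, 2)),
               "not symmetric")
})

test_that("a C sweep yields one prediction set per cost value", {
  sim <- tiny_sim(seed = 75, n_chromosomes = 2, loci = 300, n_species = 2,
                  species_div = 0.1)
  g <- vapply(sim$sequences, concat_genome, character(1))
  man <- split_samples(species_manifest(sim), seed = 75)
  tr <- man[man$split == "train", ]
  te <- man[man$split == "test", ]
  K_tr <- kmer_kernel(g[tr$sample_id], k = 11)
  K_te <- kmer_kernel(g[te$sample_id], g[tr$sample_id], k = 11)
  sweep <- lapply(c(0.5, 2, 10), function(C) {
    kernel_svm_classify(K_tr, tr$class, K_te, C_reg = C)
  })
  expect_length(sweep, 3)
  for (p in sweep) expect_length(p, nrow(te))
})
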