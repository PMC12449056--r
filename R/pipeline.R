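# End-to-end orchestration: simulate -> pseudo-sequences -> CGR images ->
# dataset policy -> train the four integration strategies (and optional
# similarity baselines) across repeated runs -> results table.

#' Assemble and validate a pipeline configuration
#'
#' @param sim A [sim_config()] describing the input collection (a mandatory
#'   seed lives here).
#' @param label Classification target: `"species"` or `"cultivar"`.
#' @param resolution CGR image side length.
#' @param normalize CGR normalization method.
#' @param min_samples,cap_per_class Dataset policy, see [filter_and_cap()].
#' @param class_proportion Fraction of largest classes kept, see
#'   [top_proportion()].
#' @param split_fractions Named train/val/test fractions.
#' @param methods Integration strategies to run; any of
#'   `"chromosome_wise"`, `"early_integration"`, `"late_integration"`,
#'   `"whole_genome"`.
#' @param classifier Registered classifier name.
#' @param n_runs Repetitions per method (each run re-splits with its own
#'   seed).
#' @param seed Base seed for the repeated runs.
#' @param baselines Also run the identity-kNN, k-mer-NN and kernel-SVM
#'   baselines on the concatenated genome sequences.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim,
                            label = c("species", "cultivar"),
                            resolution = 64L,
                            normalize = "robust",
                            min_samples = 3L,
                            cap_per_class = 60L,
                            class_proportion = 1,
                            split_fractions = c(train = 0.6, val = 0.2,
                                                test = 0.2),
                            methods = c("chromosome_wise",
                                        "early_integration",
                                        "late_integration",
                                        "whole_genome"),
                            classifier = "reference",
                            n_runs = 1L,
                            seed = NULL,
                            baselines = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  label <- match.arg(label)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(seed)) {
    stop("validation error: 'seed' is mandatory", call. = FALSE)
  }
  structure(list(sim = sim, label = label,
                 resolution = as.integer(resolution), normalize = normalize,
                 min_samples = as.integer(min_samples),
                 cap_per_class = as.integer(cap_per_class),
                 class_proportion = class_proportion,
                 split_fractions = split_fractions, methods = methods,
                 classifier = classifier, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), baselines = isTRUE(baselines)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim`
#' key holds the [sim_config()] arguments.  Entries in `overrides` replace
#' file values (command-line flags win over the file).
#'
#' @param path YAML file path.
#' @param overrides Named list of overriding values.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  if (is.null(raw$sim)) stop("config lacks a 'sim' section", call. = FALSE)
  sim <- do.call(sim_config, raw$sim)
  raw$sim <- NULL
  if (!is.null(raw$split_fractions)) {
    raw$split_fractions <- unlist(raw$split_fractions)
  }
  do.call(pipeline_config, c(list(sim = sim), raw))
}

#' Run the full pipeline
#'
#' Simulates the collection, renders CGR images, applies the dataset
#' policy, trains every configured integration strategy for `n_runs`
#' seeded repetitions, optionally runs the sequence-similarity baselines,
#' and writes `manifest.csv`, `results.csv` and `runlog.txt` under
#' `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @param save_fasta Also write the simulated FASTA files.
#' @param save_images Also export the test-split genome CGR images as PNG.
#' @return Invisibly, the results data.frame (one row per method and run,
#'   columns `method`, `run`, `seed`, `resolution`, `normalization`,
#'   `proportion`, `balanced_accuracy`).
#' @export
run_pipeline <- function(config, out_dir, save_fasta = FALSE,
                         save_images = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "runlog.txt")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logf("stage %-12s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  cat(sprintf("cgrtyper %s | R %s.%s\n",
              as.character(utils::packageVersion("cgrtyper")),
              R.version$major, R.version$minor),
      file = log_path)
  cat(yaml::as.yaml(list(
    label = config$label, resolution = config$resolution,
    normalize = config$normalize, min_samples = config$min_samples,
    cap_per_class = config$cap_per_class,
    class_proportion = config$class_proportion,
    methods = config$methods, classifier = config$classifier,
    n_runs = config$n_runs, seed = config$seed,
    sim = unclass(config$sim))),
    file = log_path, append = TRUE)

  sim <- stage("simulate", simulate_collection(config$sim))
  if (save_fasta) {
    stage("fasta", write_sim_fasta(sim, file.path(out_dir, "fasta"),
                                   genome = TRUE))
  }
  manifest <- data.frame(sample_id = sim$manifest$sample_id,
                         class = sim$manifest[[config$label]],
                         stringsAsFactors = FALSE)
  utils::write.csv(sim$manifest,
                   file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)

  iset <- stage("cgr", suppressWarnings(
    build_image_set(sim$sequences, resolution = config$resolution,
                    normalize = config$normalize,
                    genome = "whole_genome" %in% config$methods ||
                      config$baselines || save_images)))

  flt <- stage("policy", filter_and_cap(manifest,
                                        min_samples = config$min_samples,
                                        cap_per_class = config$cap_per_class,
                                        seed = config$seed))
  base_manifest <- top_proportion(flt$manifest, config$class_proportion)

  one_run <- function(run_seed) {
    man <- split_samples(base_manifest, config$split_fractions,
                         seed = run_seed)
    out <- list()
    for (m in config$methods) {
      ba <- switch(m,
        chromosome_wise = run_chromosome_wise(iset$units, man,
                                              config$classifier,
                                              seed = run_seed)$mean_ba,
        early_integration = run_early_integration(iset$units, man,
                                                  config$classifier,
                                                  seed = run_seed)$ba,
        late_integration = run_late_integration(iset$units, man,
                                                config$classifier,
                                                seed = run_seed)$ba,
        whole_genome = run_whole_genome(iset$genome, man,
                                        config$classifier,
                                        seed = run_seed)$ba)
      out[[m]] <- ba
    }
    if (config$baselines) {
      genome_seqs <- vapply(sim$sequences, concat_genome, character(1L))
      tr <- man[man$split == "train", ]
      te <- man[man$split == "test", ]
      train_seqs <- genome_seqs[tr$sample_id]
      test_seqs <- genome_seqs[te$sample_id]
      out$knn_identity <- balanced_accuracy_score(
        te$class, knn_classify(test_seqs, train_seqs, tr$class, k = 1L),
        classes = sort(unique(man$class)))
      out$kmer_nn <- balanced_accuracy_score(
        te$class, kmer_nn_classify(test_seqs, train_seqs, tr$class,
                                   k = 21L),
        classes = sort(unique(man$class)))
      K_train <- kmer_kernel(train_seqs, k = 21L)
      K_test <- kmer_kernel(test_seqs, train_seqs, k = 21L)
      out$kernel_svm <- balanced_accuracy_score(
        te$class, kernel_svm_classify(K_train, tr$class, K_test, C_reg = 2),
        classes = sort(unique(man$class)))
    }
    out
  }

  seeds <- config$seed + seq_len(config$n_runs) - 1L
  rows <- list()
  for (i in seq_along(seeds)) {
    res <- stage(sprintf("run %d/%d", i, config$n_runs), one_run(seeds[i]))
    for (m in names(res)) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, run = i, seed = seeds[i],
        resolution = config$resolution, normalization = config$normalize,
        proportion = config$class_proportion,
        balanced_accuracy = res[[m]], stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)

  if (save_images && !is.null(iset$genome)) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (sid in rownames(iset$genome)) {
      write_cgr_png(matrix(iset$genome[sid, ], nrow = config$resolution),
                    file.path(img_dir, paste0(sid, ".genome.png")))
    }
  }
  logf("wrote %d result rows", nrow(results))
  invisible(results)
}
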