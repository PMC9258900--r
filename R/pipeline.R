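#' Declarative configuration for the end-to-end pipeline
#'
#' Bundles the data source (an aligned FASTA file or a synthetic planted
#' model), the original-model choice and hyperparameters, the list of
#' extractions to run, and the evaluation options, together with one global
#' seed from which all stage seeds are derived.
#'
#' @param msa path to an aligned FASTA file, or \code{NULL} to use a
#'   synthetic source
#' @param synthetic list describing the synthetic source:
#'   \code{N}, \code{q}, \code{n_sequences}, and optionally
#'   \code{coupling_scale}, \code{field_scale}, \code{n_triplets},
#'   \code{strength} (three-body planting, default none)
#' @param original list with \code{type} (\code{"ardca"} or \code{"vae"})
#'   plus hyperparameters forwarded to \code{\link{train_ardca}} /
#'   \code{\link{train_vae}}
#' @param extractions list of extraction specs, each a list with
#'   \code{distribution} (\code{"M"}/\code{"U"}), \code{family}
#'   (\code{"pairwise"}/\code{"independent"}), optional \code{route}
#'   (\code{"sgd"}, default, or \code{"closed_form"} for the uniform
#'   conditional-average estimators) and any \code{\link{extraction_config}}
#'   overrides; an empty list evaluates the original model only
#' @param mutational \code{NULL}, a list \code{(n_single_mutants,
#'   noise_sd)} for a synthetic fitness table, or a list \code{(path)}
#'   naming a mutational CSV (requires \code{msa})
#' @param test_fraction,distant_fraction split options
#' @param similarity_threshold reweighting threshold
#' @param seed global integer seed
#' @param out_dir optional directory for stage artifacts (models, report
#'   tables, seed log)
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(msa = NULL, synthetic = NULL, original,
                            extractions = list(), mutational = NULL,
                            test_fraction = 0.1, distant_fraction = 0.1,
                            similarity_threshold = 0.8, seed = 1L,
                            out_dir = NULL) {
  if (is.null(msa) && is.null(synthetic))
    stop("either an MSA path or a synthetic source is required")
  if (!is.null(msa) && !file.exists(msa)) stop("MSA path does not exist: ", msa)
  structure(list(msa = msa, synthetic = synthetic, original = original,
                 extractions = extractions, mutational = mutational,
                 test_fraction = test_fraction,
                 distant_fraction = distant_fraction,
                 similarity_threshold = similarity_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full train-and-distill pipeline
#'
#' Stages: load or generate the alignment, remove duplicates, split 9:1
#' into train and test, reweight the training sequences, train the original
#' model, run every requested extraction, and evaluate with the stratified
#' energy report (plus mutational-effect Spearman when a mutational dataset
#' is configured).  All stage seeds derive deterministically from the
#' global seed, so rerunning a config reproduces the report.
#'
#' @param config a \code{\link{pipeline_config}}
#' @return the \code{evaluation_report}, with attributes \code{"original"},
#'   \code{"extracted"} (named model list), \code{"split"},
#'   \code{"mutdata"} and \code{"seeds"}
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(source = config$seed, split = config$seed + 1L,
                mutational = config$seed + 2L, original = config$seed + 3L,
                extraction_base = config$seed + 10L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  src <- stage("load_data", {
    if (!is.null(config$msa)) {
      list(aln = read_fasta_alignment(config$msa), truth = NULL)
    } else {
      sp <- config$synthetic
      truth <- if ((sp$n_triplets %||% 0) > 0) {
        planted_threebody_model(sp$N, sp$q, sp$n_triplets,
                                sp$strength %||% 1, seed = seeds$source,
                                coupling_scale = sp$coupling_scale %||% 0.5,
                                field_scale = sp$field_scale %||% 0.5)
      } else {
        random_pairwise_model(sp$N, sp$q,
                              coupling_scale = sp$coupling_scale %||% 0.5,
                              field_scale = sp$field_scale %||% 0.5,
                              seed = seeds$source)
      }
      S <- sample_model(truth, sp$n_sequences, seed = seeds$source + 1L)
      list(aln = encoded_alignment(S, alphabet = alphabet_of(truth)),
           truth = truth)
    }
  })
  aln <- src$aln
  truth <- src$truth

  aln <- stage("deduplicate", deduplicate(aln))
  split <- stage("split", split_train_test(aln, config$test_fraction,
                                           seed = seeds$split,
                                           config$distant_fraction))
  train <- stage("reweight",
                 reweight_alignment(split$train, config$similarity_threshold))

  original <- stage("train_original", {
    oc <- config$original
    args <- oc[setdiff(names(oc), "type")]
    if (oc$type == "ardca") {
      do.call(train_ardca, c(list(aln = train), args))
    } else if (oc$type == "vae") {
      do.call(train_vae, c(list(aln = train),
                           utils::modifyList(list(seed = seeds$original),
                                             args)))
    } else stop("unknown original model type '", oc$type, "'")
  })

  mutdata <- stage("mutational_data", {
    mc <- config$mutational
    if (is.null(mc)) NULL
    else if (!is.null(mc$path)) {
      read_mutational_csv(mc$path, wildtype = train$seqs[1, ],
                          alphabet = train$alphabet)
    } else {
      fitness_model <- truth %||% original
      synthetic_mutational_dataset(fitness_model,
                                   wildtype = train$seqs[1, ],
                                   n_single_mutants = mc$n_single_mutants,
                                   noise_sd = mc$noise_sd %||% 0,
                                   seed = seeds$mutational)
    }
  })

  extracted <- list()
  for (k in seq_along(config$extractions)) {
    ex <- config$extractions[[k]]
    nm <- ex$name %||%
      paste0(if ((ex$family %||% "pairwise") == "pairwise") "PW" else "IND",
             "/", ex$distribution)
    extracted[[nm]] <- stage(paste0("extract_", nm), {
      route <- ex$route %||% "sgd"
      if (route == "closed_form") {
        extract_uniform_closed_form(original, n_samples = ex$n_samples,
                                    seed = seeds$extraction_base + k,
                                    family = ex$family %||% "pairwise",
                                    K_target = ex$K_target %||% 5000)
      } else {
        opts <- ex[setdiff(names(ex), c("name", "route"))]
        cfg <- do.call(extraction_config,
                       utils::modifyList(list(seed = seeds$extraction_base + k),
                                         opts))
        extract_sgd(original, cfg)
      }
    })
  }

  report <- stage("evaluate", {
    if (is_estimated_energy(original))
      stratified_energy_report(original, extracted, split, mutdata,
                               K = config$original$K_eval %||% 1000,
                               seed = seeds$original + 1L)
    else
      stratified_energy_report(original, extracted, split, mutdata)
  })

  attr(report, "original") <- original
  attr(report, "extracted") <- extracted
  attr(report, "split") <- split
  attr(report, "mutdata") <- mutdata
  attr(report, "seeds") <- seeds

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_model(original, file.path(config$out_dir, "original.rds"))
    for (nm in names(extracted))
      write_model(extracted[[nm]],
                  file.path(config$out_dir,
                            paste0(gsub("/", "_", nm), ".rds")))
    utils::write.table(report$nrmse,
                       file.path(config$out_dir, "nrmse.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(report$spearman))
      utils::write.table(report$spearman,
                         file.path(config$out_dir, "spearman.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(seeds, file.path(config$out_dir, "seeds.json"),
                         auto_unbox = TRUE)
  }
  report
}

#' Enumerate a VAE hyperparameter grid
#'
#' Cartesian product of hidden-layer widths, latent dimensions, weight
#' decay strengths and datasets, in deterministic order (the first list
#' varies fastest).  The reference grid of 6 hidden widths, 6 latent
#' dimensions and 5 weight decays gives 180 configurations per dataset.
#'
#' @param hidden_list,latent_list,wd_list hyperparameter value lists
#' @param dataset_list dataset labels (default a single unnamed dataset)
#' @return data.frame with one row per configuration
#' @export
enumerate_vae_grid <- function(hidden_list = c(40, 80, 100, 120, 140, 160),
                               latent_list = c(5, 10, 20, 40, 80, 120),
                               wd_list = c(0.1, 0.05, 0.01, 0.005, 0.001),
                               dataset_list = "dataset1") {
  if (!length(hidden_list) || !length(latent_list) || !length(wd_list) ||
      !length(dataset_list)) stop("grid lists must be non-empty")
  expand.grid(hidden = hidden_list, latent = latent_list,
              weight_decay = wd_list, dataset = dataset_list,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}
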