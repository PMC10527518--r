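# Synthetic cohort generator. Emulates the statistical structure the
# signature-development pipeline assumes: redundant feature blocks,
# scanner-dependent batch effects, class-informative features, class
# imbalance, and realistic CT acquisition metadata.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the package is built around: an
#' 85-patient small-renal-mass cohort (37 clear cell + 7 chromophobe +
#' 7 papillary RCC malignant; 25 oncocytoma + 7 lipid-poor AML + 2 leiomyoma
#' benign), 107 radiomic features containing 14 redundant triplets
#' (pairwise |r| > 0.99), 24 scanner-batch-affected features (2-sd additive
#' per-scanner shifts), and 5 class-informative features at a standardized
#' mean difference of 1.5. Acquisition metadata covers three Siemens scanner
#' models with nested convolution-kernel subsets (B31s, B40s, B20f, B30f,
#' Br32f), pixel spacing 0.61-0.98 mm, slice thickness 1.5-2.5 mm and tube
#' voltage 100-130 kVp.
#'
#' @param n_per_histotype Named integer vector, patients per histotype.
#' @param malignant_histotypes Histotypes labelled malignant (`label = 1`).
#' @param n_features Total number of radiomic features.
#' @param n_informative Number of class-informative features.
#' @param effect_size Standardized mean shift of informative features in the
#'   malignant class.
#' @param n_redundant_blocks,block_size Number and size of redundant feature
#'   blocks (one anchor plus `block_size - 1` near-copies each).
#' @param redundancy_noise_sd Noise sd added to block members; at the
#'   default 0.05 pairwise member correlations are ~1/(1 + sd^2) > 0.99.
#' @param n_batch_affected Number of features with scanner batch effects.
#' @param batch_shift Spacing (in sd units) of the additive per-scanner
#'   shifts, centred across scanners.
#' @param scanner_models Character vector of scanner labels.
#' @param kernels Named list mapping each scanner to its convolution-kernel
#'   subset (kernels are nested within scanner, as in clinical archives).
#' @param pixel_spacing_range,slice_thickness_range,tube_voltage_range
#'   Uniform sampling ranges for the continuous acquisition metadata
#'   (mm, mm, kVp).
#' @param seed Default seed used by [generate_cohort()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_per_histotype = c(clear_cell = 37, chromophobe = 7,
                                                 papillary = 7, oncocytoma = 25,
                                                 lipid_poor_aml = 7, leiomyoma = 2),
                             malignant_histotypes = c("clear_cell", "chromophobe",
                                                      "papillary"),
                             n_features = 107,
                             n_informative = 5,
                             effect_size = 1.5,
                             n_redundant_blocks = 14,
                             block_size = 3,
                             redundancy_noise_sd = 0.05,
                             n_batch_affected = 24,
                             batch_shift = 2,
                             scanner_models = c("SOMATOM_Emotion_6",
                                                "SOMATOM_Sensation_64",
                                                "SOMATOM_Definition_Flash"),
                             kernels = list(SOMATOM_Emotion_6 = c("B31s", "B40s"),
                                            SOMATOM_Sensation_64 = c("B20f", "B30f"),
                                            SOMATOM_Definition_Flash = "Br32f"),
                             pixel_spacing_range = c(0.61, 0.98),
                             slice_thickness_range = c(1.5, 2.5),
                             tube_voltage_range = c(100, 130),
                             seed = 20230914L) {
  abort_if(is.null(names(n_per_histotype)) || any(n_per_histotype < 0),
           "n_per_histotype must be a named vector of non-negative counts")
  abort_if(!all(malignant_histotypes %in% names(n_per_histotype)),
           "malignant_histotypes must name entries of n_per_histotype")
  abort_if(n_redundant_blocks > 0 && block_size < 2,
           "block_size must be >= 2")
  reserved <- n_informative + n_batch_affected + n_redundant_blocks * block_size
  abort_if(reserved > n_features,
           paste0("feature roles (", reserved, ") exceed n_features (",
                  n_features, ")"))
  abort_if(!setequal(names(kernels), scanner_models),
           "kernels must be a named list keyed by scanner_models")
  for (rng in list(pixel_spacing_range, slice_thickness_range, tube_voltage_range)) {
    abort_if(length(rng) != 2 || rng[1] >= rng[2], "ranges must be ordered pairs")
  }
  structure(list(
    n_per_histotype = n_per_histotype,
    malignant_histotypes = malignant_histotypes,
    n_features = as.integer(n_features),
    n_informative = as.integer(n_informative),
    effect_size = effect_size,
    n_redundant_blocks = as.integer(n_redundant_blocks),
    block_size = as.integer(block_size),
    redundancy_noise_sd = redundancy_noise_sd,
    n_batch_affected = as.integer(n_batch_affected),
    batch_shift = batch_shift,
    scanner_models = scanner_models,
    kernels = kernels,
    pixel_spacing_range = pixel_spacing_range,
    slice_thickness_range = slice_thickness_range,
    tube_voltage_range = tube_voltage_range,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Generate a synthetic radiomic cohort
#'
#' Draws features as standard normal noise, then plants the configured
#' structure: informative features are shifted by `effect_size` in the
#' malignant class; batch-affected features receive additive per-scanner
#' shifts spaced `batch_shift` sd apart; redundant block members equal their
#' block anchor plus `N(0, redundancy_noise_sd^2)` noise. Scanners are
#' assigned uniformly, kernels uniformly within each scanner's subset, and
#' continuous metadata uniformly in range, independent of the class label.
#' The per-feature ground-truth roles are attached and retrievable with
#' [ground_truth()].
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`); the same seed gives
#'   an identical cohort.
#' @return A cohort tibble with attributes `roles` and `generator_config`.
#' @export
generate_cohort <- function(config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(seed, {
    histotype <- rep(names(config$n_per_histotype), config$n_per_histotype)
    n <- length(histotype)
    abort_if(n < 4, "cohort too small to be useful")
    label <- as.integer(histotype %in% config$malignant_histotypes)
    patient_id <- sprintf("P%03d", seq_len(n))

    scanner <- sample(config$scanner_models, n, replace = TRUE)
    kernel <- vapply(scanner, function(s) {
      ks <- config$kernels[[s]]
      if (length(ks) == 1) ks else sample(ks, 1)
    }, character(1), USE.NAMES = FALSE)
    pixel_spacing <- runif(n, config$pixel_spacing_range[1], config$pixel_spacing_range[2])
    thickness <- runif(n, config$slice_thickness_range[1], config$slice_thickness_range[2])
    kvp <- runif(n, config$tube_voltage_range[1], config$tube_voltage_range[2])

    p <- config$n_features
    fnames <- sprintf("rf%03d", seq_len(p))
    roles <- rep("noise", p)
    i <- 0
    idx_informative <- seq_len(config$n_informative) + i
    i <- i + config$n_informative
    idx_batch <- seq_len(config$n_batch_affected) + i
    i <- i + config$n_batch_affected
    block_idx <- list()
    for (b in seq_len(config$n_redundant_blocks)) {
      block_idx[[b]] <- seq_len(config$block_size) + i
      i <- i + config$block_size
    }
    roles[idx_informative] <- "informative"
    roles[idx_batch] <- "batch_affected"
    for (b in block_idx) {
      roles[b[1]] <- "redundant_anchor"
      roles[b[-1]] <- "redundant_member"
    }

    X <- matrix(rnorm(n * p), nrow = n, ncol = p, dimnames = list(NULL, fnames))
    if (config$n_informative > 0) {
      X[, idx_informative] <- X[, idx_informative] + config$effect_size * label
    }
    if (config$n_batch_affected > 0) {
      k <- length(config$scanner_models)
      shifts <- config$batch_shift * (match(scanner, config$scanner_models) - (k + 1) / 2)
      X[, idx_batch] <- X[, idx_batch] + shifts
    }
    for (b in block_idx) {
      anchor <- X[, b[1]]
      for (m in b[-1]) {
        X[, m] <- anchor + rnorm(n, 0, config$redundancy_noise_sd)
      }
    }

    cohort <- tibble::tibble(
      patient_id = patient_id,
      label = label,
      histotype = histotype,
      scanner_model = scanner,
      convolution_kernel = kernel,
      pixel_spacing_mm = pixel_spacing,
      slice_thickness_mm = thickness,
      tube_voltage_kvp = kvp
    )
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(X))
    cohort <- as_cohort(cohort)
    attr(cohort, "roles") <- tibble::tibble(feature = fnames, role = roles)
    attr(cohort, "generator_config") <- config
    cohort
  })
}

#' Ground-truth feature roles of a generated cohort
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @return A tibble with columns `feature` and `role`, where role is one of
#'   `noise`, `informative`, `batch_affected`, `redundant_anchor`,
#'   `redundant_member`.
#' @export
ground_truth <- function(cohort) {
  roles <- attr(cohort, "roles")
  abort_if(is.null(roles),
           "cohort carries no ground-truth roles; was it produced by generate_cohort()?")
  roles
}
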