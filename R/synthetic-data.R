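#' Configuration for the synthetic descriptor-data generator
#'
#' The generator emulates the statistical structure of a curated pesticide
#' QSAR dataset: a ~79:21 toxic:nontoxic imbalance, a handful of
#' informative descriptors (some with interaction- or threshold-shaped
#' effects that only tree models exploit) hidden among many noise,
#' correlated and constant columns, and NOEC endpoints expressed both as
#' real values and as the interval dialects the curation rules handle.
#'
#' Defaults mirror the scale of the real dataset capped for desk use:
#' 449 compounds, 300 descriptors (rather than the original 2199),
#' 355/449 toxic fraction, 8 informative of which 2 nonlinear.
#'
#' @param n_compounds Number of compounds.
#' @param n_descriptors Total descriptors.
#' @param n_informative Descriptors carrying class signal.
#' @param n_nonlinear Subset of the informative descriptors whose effect is
#'   interaction (XOR-pair) or threshold shaped.
#' @param toxic_fraction Expected toxic proportion, in (0, 1).
#' @param correlated_block_size Redundant descriptors driven by one latent
#'   factor (emulating descriptor-family redundancy).
#' @param n_constant Zero-variance descriptors.
#' @param noise_sd Standard deviation of the noise descriptors.
#' @param interval_fraction Share of NOEC records emitted as intervals.
#' @param effect_size Class mean shift of linear informative descriptors,
#'   in within-class standard deviations.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = 449,
                             n_descriptors = 300,
                             n_informative = 8,
                             n_nonlinear = 2,
                             toxic_fraction = 355 / 449,
                             correlated_block_size = 10,
                             n_constant = 5,
                             noise_sd = 1,
                             interval_fraction = 0.15,
                             effect_size = 1.0,
                             seed = 1) {
  cfg <- list(n_compounds = n_compounds, n_descriptors = n_descriptors,
              n_informative = n_informative, n_nonlinear = n_nonlinear,
              toxic_fraction = toxic_fraction,
              correlated_block_size = correlated_block_size,
              n_constant = n_constant, noise_sd = noise_sd,
              interval_fraction = interval_fraction,
              effect_size = effect_size, seed = seed)
  if (!(toxic_fraction > 0 && toxic_fraction < 1))
    abort_config("synthetic_config: toxic_fraction must be in (0,1)")
  if (n_nonlinear > n_informative)
    abort_config("synthetic_config: n_nonlinear exceeds n_informative")
  if (n_informative + n_constant > n_descriptors)
    abort_config(
      "synthetic_config: n_informative + n_constant exceeds n_descriptors")
  if (n_informative + n_constant + correlated_block_size > n_descriptors)
    abort_config(
      "synthetic_config: informative + constant + correlated block exceed n_descriptors")
  if (noise_sd <= 0)
    abort_config("synthetic_config: noise_sd must be positive")
  if (interval_fraction < 0 || interval_fraction > 1)
    abort_config("synthetic_config: interval_fraction must be in [0,1]")
  structure(cfg, class = "synthetic_config")
}

# NOEC text dialect for one compound given its generating class.
# A small fixed share of interval records uses the breakpoint-straddling
# dialects so every curation rule (including the discard rules) fires.
synth_noec_text <- function(toxic, interval_fraction) {
  if (stats::runif(1) >= interval_fraction) {
    # reals: lognormal around class-conditional medians straddling 100 mg/kg
    if (toxic) {
      v <- stats::qlnorm(stats::runif(1) * stats::plnorm(100, log(10), 1),
                         log(10), 1)
    } else {
      p0 <- stats::plnorm(100, log(1000), 1)
      v <- stats::qlnorm(p0 + stats::runif(1) * (1 - p0), log(1000), 1)
    }
    return(trimws(formatC(v, format = "fg", digits = 4)))
  }
  if (stats::runif(1) < 0.10) {
    # uninformative interval dialects -> curation discards the record
    return(sample(c(">10-100", "<100-inf"), 1))
  }
  if (toxic) sample(c(">0-10", "<100"), 1) else ">100"
}

#' Generate a synthetic QSAR dataset
#'
#' Produces a labelled descriptor matrix, NOEC records consistent with the
#' labels under the curation rules, and the list of planted informative
#' descriptor names (the ground truth that descriptor-selection benchmarks
#' are scored against).
#'
#' Descriptor layout: linear informative columns are class-conditional
#' Gaussians shifted by `effect_size` standard deviations; nonlinear
#' informative columns are an XOR-coupled pair (individually weak, jointly
#' predictive) and/or threshold-shaped columns; a correlated block shares
#' one latent factor; the rest are constants and pure noise.
#'
#' @param config A `synthetic_config`.
#' @return A `synthetic_dataset` list with elements `descriptor_matrix`
#'   (labelled with the generating class), `noec_records`, `noec_text`,
#'   `truth` (informative descriptor names) and `config`.
#' @examples
#' ds <- generate_dataset(synthetic_config(n_compounds = 60,
#'                                         n_descriptors = 20,
#'                                         n_informative = 3,
#'                                         n_nonlinear = 1,
#'                                         correlated_block_size = 3,
#'                                         n_constant = 2, seed = 7))
#' ds$truth
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  with_seed(config$seed, {
    n <- config$n_compounds
    z <- stats::rbinom(n, 1, config$toxic_fraction) # 1 = toxic
    n_lin <- config$n_informative - config$n_nonlinear
    cols <- list()
    # linear signal: class-conditional mean shift
    for (i in seq_len(n_lin)) {
      cols[[sprintf("sig_lin_%02d", i)]] <-
        stats::rnorm(n, mean = config$effect_size * z, sd = 1)
    }
    # nonlinear signal
    nl_left <- config$n_nonlinear
    if (nl_left >= 2) {
      # XOR pair: a hidden switch flips which tail of the pair marks a
      # toxic compound, so each column alone is only weakly informative
      s <- stats::rbinom(n, 1, 0.5)
      sgn1 <- 2 * s - 1
      sgn2 <- sgn1 * (2 * z - 1)
      a <- 0.6 * config$effect_size
      cols[["sig_xor_01"]] <- stats::rnorm(n, 0.9 * sgn1 + a * z, 1)
      cols[["sig_xor_02"]] <- stats::rnorm(n, 0.9 * sgn2 + a * z, 1)
      nl_left <- nl_left - 2
    }
    for (i in seq_len(nl_left)) {
      # threshold effect: toxic compounds concentrate above a cut point
      p_hi <- ifelse(z == 1, 0.70, 0.20)
      hi <- stats::rbinom(n, 1, p_hi)
      cols[[sprintf("sig_thr_%02d", i)]] <-
        ifelse(hi == 1, stats::rnorm(n, 1.4, 0.6), stats::rnorm(n, -0.4, 1))
    }
    # correlated block: scaled copies of one class-independent latent factor
    latent <- stats::rnorm(n)
    for (i in seq_len(config$correlated_block_size)) {
      cols[[sprintf("corr_%02d", i)]] <-
        0.8 * latent + stats::rnorm(n, 0, 0.6 * config$noise_sd)
    }
    for (i in seq_len(config$n_constant)) {
      cols[[sprintf("const_%02d", i)]] <- rep(i, n)
    }
    n_noise <- config$n_descriptors - length(cols)
    for (i in seq_len(n_noise)) {
      cols[[sprintf("noise_%03d", i)]] <- stats::rnorm(n, 0, config$noise_sd)
    }
    x <- do.call(cbind, cols)
    ids <- sprintf("cmpd_%04d", seq_len(n))
    labels <- ifelse(z == 1, "toxic", "nontoxic")
    noec_text <- vapply(seq_len(n), function(i)
      synth_noec_text(z[i] == 1, config$interval_fraction), character(1))
    noec_records <- lapply(seq_len(n), function(i)
      parse_noec(noec_text[i], ids[i]))
    truth <- grep("^sig_", colnames(x), value = TRUE)
    structure(list(
      descriptor_matrix = descriptor_matrix(x, labels = labels,
                                            compound_id = ids),
      noec_records = noec_records,
      noec_text = noec_text,
      truth = truth,
      config = config), class = "synthetic_dataset")
  })
}

#' Write a synthetic dataset to plain-text files
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly. Writes `descriptors.csv`
#'   (compound id, descriptors, label), `noec.csv` (compound id, NOEC text,
#'   generating label) and `config.json`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_descriptor_csv(dataset$descriptor_matrix,
                       file.path(dir, "descriptors.csv"))
  utils::write.csv(
    data.frame(compound_id = dataset$descriptor_matrix$compound_id,
               noec = dataset$noec_text,
               label = as.character(dataset$descriptor_matrix$labels)),
    file.path(dir, "noec.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Univariate AUC of a descriptor for the toxic class
#'
#' Rank-based (Mann-Whitney) area under the ROC curve of a single
#' descriptor against the binary labels; 0.5 means no signal.
#'
#' @param values Numeric descriptor values.
#' @param labels `toxic`/`nontoxic` labels.
#' @return AUC in `[0, 1]`, folded to `>= 0.5` (direction-free).
#' @export
univariate_auc <- function(values, labels) {
  y <- as.character(labels) == "toxic"
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0)
    abort_config("univariate_auc: both classes required")
  r <- rank(values)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(auc, 1 - auc)
}
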