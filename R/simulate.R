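#' Simulation configuration for a 4-plex labelling study
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate a 5-replicate iTRAQ 4-plex cell-exposure study: four
#' drug conditions rotated over the four reporter channels with a
#' different tag/condition association per experiment, a null (unregulated)
#' ratio population Gaussian around 1.02 with SD 0.10, multiplicative
#' log-normal reporter noise, occasional missing (zero) reporter channels,
#' decoy identifications annotated REVERSED or Fragment, and a fraction of
#' identification scores at or below the retention cutoff of 30.
#'
#' @param n_proteins number of simulated proteins.
#' @param n_experiments number of independent replicate experiments
#'   (default 5).
#' @param conditions character vector of exactly 4 condition names; the
#'   4-plex design admits no other multiplicity.
#' @param reference_condition the denominator condition for all ratios
#'   (default: first of `conditions`, the vehicle control).
#' @param fraction_regulated proportion of proteins given a deliberate
#'   effect at a +/- sigma-tier midpoint.
#' @param null_mean,null_sd parameters of the Gaussian null ratio
#'   distribution (defaults 1.02, 0.10).
#' @param noise_sd_log SD of the per-channel log-normal reporter noise
#'   (natural-log scale, default 0.05).
#' @param missing_rate probability any one reporter channel reads 0.
#' @param decoy_rate probability a PSM is annotated REVERSED or Fragment.
#' @param low_score_rate probability an identification score falls at or
#'   below `score_cutoff`.
#' @param score_cutoff retention cutoff the score distribution is anchored
#'   to (default 30).
#' @param score_shape,score_scale shape/scale of the shifted gamma the
#'   scores are drawn from.
#' @param peptide_geom_prob success probability of the truncated geometric
#'   (minimum 1) for peptides per protein.
#' @param base_intensity_range reporter base intensity range; drawn
#'   log-uniform (default `c(1e3, 1e6)`).
#' @param seed integer seed from which all randomness in the generator
#'   flows.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 500L,
                       n_experiments = 5L,
                       conditions = c("vehicle", "CsA", "Tac", "CAI"),
                       reference_condition = conditions[1],
                       fraction_regulated = 0.2,
                       null_mean = 1.02,
                       null_sd = 0.10,
                       noise_sd_log = 0.05,
                       missing_rate = 0.05,
                       decoy_rate = 0.05,
                       low_score_rate = 0.10,
                       score_cutoff = 30,
                       score_shape = 4,
                       score_scale = 10,
                       peptide_geom_prob = 0.35,
                       base_intensity_range = c(1e3, 1e6),
                       seed = 1L) {
  if (length(conditions) != 4L)
    stop("a 4-plex design requires exactly 4 conditions, got ",
         length(conditions))
  if (anyDuplicated(conditions)) stop("condition names must be distinct")
  if (!reference_condition %in% conditions)
    stop("reference_condition must be one of the conditions")
  props <- c(fraction_regulated = fraction_regulated,
             missing_rate = missing_rate, decoy_rate = decoy_rate,
             low_score_rate = low_score_rate)
  bad <- props < 0 | props > 1
  if (any(bad)) stop("proportions out of [0,1]: ",
                     paste(names(props)[bad], collapse = ", "))
  stopifnot(n_proteins >= 1, n_experiments >= 1, null_sd > 0,
            noise_sd_log >= 0, score_shape > 0, score_scale > 0,
            peptide_geom_prob > 0, peptide_geom_prob <= 1,
            length(base_intensity_range) == 2L,
            all(base_intensity_range > 0))
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_experiments = as.integer(n_experiments),
    conditions = conditions,
    reference_condition = reference_condition,
    fraction_regulated = fraction_regulated,
    null_mean = null_mean, null_sd = null_sd,
    noise_sd_log = noise_sd_log,
    missing_rate = missing_rate, decoy_rate = decoy_rate,
    low_score_rate = low_score_rate, score_cutoff = score_cutoff,
    score_shape = score_shape, score_scale = score_scale,
    peptide_geom_prob = peptide_geom_prob,
    base_intensity_range = base_intensity_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_proteins, "proteins,", x$n_experiments,
      "experiments,\n  conditions", paste(x$conditions, collapse = "/"),
      "(reference", paste0(x$reference_condition, "),"),
      "\n  regulated fraction", x$fraction_regulated,
      "| null N(", x$null_mean, ",", x$null_sd, ")",
      "| reporter noise sdlog", x$noise_sd_log,
      "\n  missing", x$missing_rate, "| decoy", x$decoy_rate,
      "| low-score", x$low_score_rate, "| seed", x$seed, "\n")
  invisible(x)
}

# deterministic per-experiment sub-seed, kept inside 32-bit range
.exp_seed <- function(seed, experiment_index, offset = 0L) {
  (as.integer(seed) + 7919L * as.integer(experiment_index) +
     104729L * as.integer(offset)) %% .Machine$integer.max
}

#' Tag/condition rotation for one replicate experiment
#'
#' Assigns the four conditions to the four reporter channels (114-117) so
#' that every replicate uses a different tag/condition association and
#' label-specific biases cannot align with any one condition. Experiments
#' 1-4 use cyclic Latin-square shifts of `experiment_index - 1`; a pure
#' cyclic shift repeats after 4 experiments, so experiments 5-8 apply the
#' same shifts to the reversed condition order, giving 8 pairwise
#' distinct bijections before the scheme recycles.
#'
#' @param experiment_index replicate index, 1-based.
#' @param conditions character vector of exactly 4 condition names.
#' @return Named character vector mapping channels `"114".."117"` to
#'   conditions; a bijection.
#' @examples
#' make_tag_rotation(2, c("A", "B", "C", "D"))
#' @export
make_tag_rotation <- function(experiment_index, conditions) {
  if (length(conditions) != 4L)
    stop("a 4-plex rotation requires exactly 4 conditions")
  experiment_index <- as.integer(experiment_index)
  if (is.na(experiment_index) || experiment_index < 1L)
    stop("experiment_index must be a positive integer")
  if ((((experiment_index - 1L) %/% 4L) %% 2L) == 1L)
    conditions <- rev(conditions)
  idx <- ((seq_len(4L) - 1L - (experiment_index - 1L)) %% 4L) + 1L
  stats::setNames(conditions[idx], c("114", "115", "116", "117"))
}

#' Ground truth for a synthetic study
#'
#' Draws one true fold per protein, applied to every non-reference
#' condition. A `fraction_regulated` subset receives a deliberate effect
#' at a sigma-tier band midpoint (`null_mean + s * (k + 0.5) * null_sd`,
#' k in 1..3, both signs, cycled evenly); the rest draw their fold from
#' the Gaussian null `N(null_mean, null_sd)`. The tier label is obtained
#' by classifying the true fold with the generating thresholds, so a null
#' protein that happens to land beyond +/- sigma is labelled truthfully.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `"itraq_truth"`: list with `proteins`
#'   (protein_id, fold, tier, regulated, n_peptides, protein_class) and
#'   `peptides` (protein_id, peptide).
#' @export
simulate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  protein_id <- sprintf("SYN%04d", seq_len(n))
  n_reg <- round(cfg$fraction_regulated * n)
  regulated <- rep(FALSE, n)
  if (n_reg > 0) regulated[sample.int(n, n_reg)] <- TRUE
  fold <- stats::rnorm(n, cfg$null_mean, cfg$null_sd)
  # keep folds strictly positive (essentially never triggers at sd 0.10)
  while (any(fold <= 0)) {
    bad <- fold <= 0
    fold[bad] <- stats::rnorm(sum(bad), cfg$null_mean, cfg$null_sd)
  }
  if (n_reg > 0) {
    k <- rep_len(c(1, 2, 3), n_reg)
    sgn <- rep_len(c(1, -1), n_reg)
    sgn <- sgn[sample.int(n_reg)]
    fold[regulated] <- cfg$null_mean + sgn * (k + 0.5) * cfg$null_sd
  }
  th <- tier_thresholds(cfg$null_mean, sd = cfg$null_sd)
  tier <- classify_tiers(fold, th)
  n_peptides <- 1L + stats::rgeom(n, cfg$peptide_geom_prob)
  peptides <- data.frame(
    protein_id = rep(protein_id, n_peptides),
    peptide = random_peptides(sum(n_peptides)),
    stringsAsFactors = FALSE
  )
  protein_class <- sample(names(.synthetic_class_sizes()), n, replace = TRUE,
                          prob = .synthetic_class_sizes() /
                            sum(.synthetic_class_sizes()))
  structure(list(
    proteins = data.frame(protein_id = protein_id, fold = fold,
                          tier = tier, regulated = regulated,
                          n_peptides = n_peptides,
                          protein_class = protein_class,
                          stringsAsFactors = FALSE),
    peptides = peptides,
    thresholds = th
  ), class = "itraq_truth")
}

# synthetic protein-class reference sizes used for over-representation
# exercises; invented, roughly log-spread like a real class annotation
.synthetic_class_sizes <- function() {
  c(SC01 = 40, SC02 = 90, SC03 = 220, SC04 = 450, SC05 = 900,
    SC06 = 1800, SC07 = 3500, SC08 = 13000)
}

# tryptic-looking random peptide sequences ending in K/R, unique
random_peptides <- function(n, min_len = 7L, max_len = 16L) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    len <- sample(min_len:max_len, need, replace = TRUE)
    body <- vapply(len, function(l)
      paste(sample(aa, l - 1L, replace = TRUE), collapse = ""), "")
    out <- unique(c(out, paste0(body, sample(c("K", "R"), need,
                                             replace = TRUE))))
  }
  out[seq_len(n)]
}

#' Simulate the PSM table of one replicate experiment
#'
#' Every peptide of every protein yields one peptide-spectrum match. The
#' reporter intensity of channel c is
#' `base * fold(condition(c)) * exp(N(0, noise_sd_log))` with the
#' reference condition at fold 1 and `base` drawn log-uniform over
#' `base_intensity_range`. Channels drop to 0 with probability
#' `missing_rate`; PSMs carry a REVERSED or Fragment annotation with
#' probability `decoy_rate`; identification scores come from a gamma
#' shifted so that `P(score <= score_cutoff) = low_score_rate`.
#'
#' @param truth an `"itraq_truth"` object.
#' @param cfg the [sim_config()] used to build `truth`.
#' @param experiment_index replicate index in `1..n_experiments`.
#' @return A data frame of PSM records: `spectrum_id`, `experiment`,
#'   `peptide`, `accession`, `flags`, `score`, `I114`..`I117`, with the
#'   tag rotation attached as attribute `"rotation"`.
#' @export
simulate_experiment <- function(truth, cfg, experiment_index) {
  stopifnot(inherits(truth, "itraq_truth"), inherits(cfg, "sim_config"))
  experiment_index <- as.integer(experiment_index)
  if (experiment_index < 1L || experiment_index > cfg$n_experiments)
    stop("experiment_index out of 1..", cfg$n_experiments)
  set.seed(.exp_seed(cfg$seed, experiment_index))
  rotation <- make_tag_rotation(experiment_index, cfg$conditions)
  pep <- truth$peptides
  prot <- truth$proteins
  fold <- prot$fold[match(pep$protein_id, prot$protein_id)]
  m <- nrow(pep)
  lr <- log(cfg$base_intensity_range)
  base <- exp(stats::runif(m, lr[1], lr[2]))
  intens <- matrix(0, nrow = m, ncol = 4,
                   dimnames = list(NULL, paste0("I", names(rotation))))
  for (j in seq_len(4L)) {
    f <- if (rotation[j] == cfg$reference_condition) rep(1, m) else fold
    noise <- if (cfg$noise_sd_log > 0)
      exp(stats::rnorm(m, 0, cfg$noise_sd_log)) else rep(1, m)
    intens[, j] <- base * f * noise
  }
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(m * 4) < cfg$missing_rate, nrow = m)
    intens[drop] <- 0
  }
  flags <- rep("", m)
  if (cfg$decoy_rate > 0) {
    is_decoy <- stats::runif(m) < cfg$decoy_rate
    kind <- sample(c("REVERSED", "Fragment"), m, replace = TRUE)
    flags[is_decoy] <- kind[is_decoy]
  }
  shift <- cfg$score_cutoff -
    stats::qgamma(cfg$low_score_rate, cfg$score_shape, scale = cfg$score_scale)
  score <- shift + stats::rgamma(m, cfg$score_shape, scale = cfg$score_scale)
  out <- data.frame(
    spectrum_id = sprintf("exp%d.%05d", experiment_index, seq_len(m)),
    experiment = paste0("exp", experiment_index),
    peptide = pep$peptide,
    accession = pep$protein_id,
    flags = flags,
    score = score,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(intens))
  attr(out, "rotation") <- rotation
  out
}

#' Simulate a full multi-replicate study
#'
#' @param cfg a [sim_config()].
#' @return An object of class `"itraq_sim"`: list with `truth`, `psms`
#'   (one PSM data frame per experiment), `rotations`, and `cfg`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- simulate_ground_truth(cfg)
  psms <- lapply(seq_len(cfg$n_experiments), function(i)
    simulate_experiment(truth, cfg, i))
  names(psms) <- paste0("exp", seq_len(cfg$n_experiments))
  structure(list(truth = truth, psms = psms,
                 rotations = lapply(seq_len(cfg$n_experiments),
                                    make_tag_rotation,
                                    conditions = cfg$conditions),
                 cfg = cfg),
            class = "itraq_sim")
}

#' @export
print.itraq_sim <- function(x, ...) {
  cat("Synthetic 4-plex study:", x$cfg$n_proteins, "proteins,",
      x$cfg$n_experiments, "experiments,",
      sum(vapply(x$psms, nrow, 0L)), "PSMs\n")
  print(table(tier = x$truth$proteins$tier))
  invisible(x)
}

#' Write/read a tab-delimited PSM table
#'
#' @param psms PSM data frame from [simulate_experiment()].
#' @param path file path.
#' @return `path` (writer) or the PSM data frame (reader).
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(flags = "character"))
}

#' Write the ground-truth table as TSV
#'
#' @param truth an `"itraq_truth"` object.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth$proteins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
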