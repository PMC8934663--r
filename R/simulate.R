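#' Configure a synthetic guide-set simulation
#'
#' The generator emulates the statistical structure the feature model
#' assumes: protospacers drawn uniformly and independently over
#' \{A,C,G,T\}^20 with a uniform PAM N followed by the fixed GG, and a latent
#' per-guide efficiency built as `baseline` plus the sum of planted additive
#' (position, nucleotide) effects plus Gaussian between-guide noise.
#' Replicates add within-guide Gaussian noise and are clamped to \[0, 100\]
#' by default. Defaults mirror a typical single-condition study of this
#' kind: 51 guides, 4 replicate embryo pools each, a baseline near 57%
#' efficiency, between-guide residual SD 15 points, replicate SD 5 points.
#'
#' @param n_guides number of guides (>= 4).
#' @param n_replicates replicates per guide (>= 1).
#' @param baseline grand-mean efficiency, percent.
#' @param effects planted effect table: a data frame with columns
#'   `position` (1-21; the fixed GG at 22-23 never carries effects),
#'   `nucleotide` and `effect` (additive percent points). See
#'   [planted_effects()]. `NULL` for a null simulation.
#' @param noise_sd between-guide residual SD, percent points (>= 0).
#' @param replicate_sd within-guide replicate SD, percent points (>= 0).
#' @param clip clamp replicate values to \[0, 100\]?
#' @return a list of class `"kp_sim_config"`.
#' @export
kp_sim_config <- function(n_guides = 51, n_replicates = 4, baseline = 57,
                          effects = NULL, noise_sd = 15, replicate_sd = 5,
                          clip = TRUE) {
  n_guides <- as.integer(n_guides)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_guides) || n_guides < 4L) stop("n_guides must be >= 4")
  if (is.na(n_replicates) || n_replicates < 1L) {
    stop("n_replicates must be >= 1")
  }
  if (!is.finite(baseline)) stop("baseline must be finite")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.finite(replicate_sd) || replicate_sd < 0) {
    stop("replicate_sd must be >= 0")
  }
  if (is.null(effects)) {
    effects <- data.frame(position = integer(), nucleotide = character(),
                          effect = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(effects),
            all(c("position", "nucleotide", "effect") %in% names(effects)))
  effects$position <- as.integer(effects$position)
  effects$nucleotide <- toupper(effects$nucleotide)
  if (any(effects$position < 1L | effects$position > 21L)) {
    stop("planted effects are restricted to positions 1-21 ",
         "(22-23 are the fixed PAM GG)")
  }
  if (any(!effects$nucleotide %in% NUCLEOTIDES)) {
    stop("effect nucleotides must be A/C/G/T")
  }
  if (anyDuplicated(effects[, c("position", "nucleotide")])) {
    stop("duplicate (position, nucleotide) effects")
  }
  structure(list(n_guides = n_guides, n_replicates = n_replicates,
                 baseline = baseline, effects = effects,
                 noise_sd = noise_sd, replicate_sd = replicate_sd,
                 clip = clip),
            class = "kp_sim_config")
}

#' Build a planted-effect table
#'
#' @param position,nucleotide,effect parallel vectors: target position
#'   (1-21), nucleotide, and additive effect in percent points (positive =
#'   favored).
#' @return data frame usable as the `effects` argument of
#'   [kp_sim_config()].
#' @examples
#' planted_effects(c(5, 20), c("T", "C"), c(20, -15))
#' @export
planted_effects <- function(position, nucleotide, effect) {
  data.frame(position = as.integer(position),
             nucleotide = toupper(as.character(nucleotide)),
             effect = as.numeric(effect), stringsAsFactors = FALSE)
}

#' Simulate a guide set with known ground truth
#'
#' Sampling is deterministic given `seed`: an independent substream is
#' derived for each guide, so guide `i` of a run is reproducible regardless
#' of vectorisation details.
#'
#' @param config a [kp_sim_config()].
#' @param seed integer seed governing all sampling.
#' @param condition_label label stored on the generated set.
#' @return list of class `"kp_sim"` with elements `guides` (a [guide_set()])
#'   and `truth`: the echoed config, per-guide latent efficiencies (before
#'   replicate noise and clamping), the planted effects as a 4 x 23 matrix
#'   (`effect_matrix`), and the seed.
#' @examples
#' sim <- simulate_guides(kp_sim_config(n_guides = 10, noise_sd = 0,
#'                                      replicate_sd = 0), seed = 42)
#' all(sim$guides$mean_efficiency == 57)
#' @export
simulate_guides <- function(config, seed, condition_label = "synthetic") {
  stopifnot(inherits(config, "kp_sim_config"))
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  n <- config$n_guides

  set.seed(seed)
  guide_seeds <- sample.int(.Machine$integer.max, n)

  eff_mat <- matrix(0, 4, N_POSITIONS,
                    dimnames = list(NUCLEOTIDES, as.character(1:N_POSITIONS)))
  if (nrow(config$effects)) {
    eff_mat[cbind(match(config$effects$nucleotide, NUCLEOTIDES),
                  config$effects$position)] <- config$effects$effect
  }

  proto <- character(n)
  pam <- character(n)
  latent <- numeric(n)
  reps <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(guide_seeds[i])
    nts <- sample(NUCLEOTIDES, 21, replace = TRUE)  # positions 1-20 + PAM N
    proto[i] <- paste(nts[1:20], collapse = "")
    pam[i] <- paste0(nts[21], "GG")
    target_idx <- cbind(match(c(nts, "G", "G"), NUCLEOTIDES), 1:N_POSITIONS)
    latent[i] <- config$baseline + sum(eff_mat[target_idx]) +
      stats::rnorm(1, 0, config$noise_sd)
    r <- latent[i] + stats::rnorm(config$n_replicates, 0, config$replicate_sd)
    if (config$clip) r <- pmin(pmax(r, 0), 100)
    reps[[i]] <- r
  }

  guides <- guide_set(
    name = sprintf("synth_%03d", seq_len(n)),
    protospacer = proto, pam = pam, replicates = reps,
    strand = sample(c("sense", "antisense"), n, replace = TRUE),
    condition_label = condition_label, weight_source = "other"
  )
  structure(list(
    guides = guides,
    truth = list(config = config, latent = latent,
                 effect_matrix = eff_mat, seed = seed)
  ), class = "kp_sim")
}

#' Assess recovery of planted effects by a fitted feature model
#'
#' @param truth the `truth` element of a [simulate_guides()] result (or the
#'   whole `"kp_sim"` object).
#' @param fit a `"crisprkp"` model (or a `kp_features` table) built from the
#'   generated guides.
#' @param k rank cutoff for precision; defaults to the number of planted
#'   effects.
#' @return list with `planted` (one row per planted effect: its rank among
#'   informative cells by p-value, recovered direction, and sign agreement),
#'   `precision_at_k` (fraction of the top `k` cells that are planted;
#'   `NA` for a null run), and `all_signs_agree`.
#' @export
recovery_assessment <- function(truth, fit, k = NULL) {
  if (inherits(truth, "kp_sim")) truth <- truth$truth
  features <- if (inherits(fit, "crisprkp")) fit$features else fit
  stopifnot(is.data.frame(features))
  effects <- truth$config$effects
  n_planted <- nrow(effects)
  if (is.null(k)) k <- max(n_planted, 1L)

  ranked <- top_features(features, k = 92)
  key <- function(p, nt) paste0(p, "-", nt)
  planted_keys <- key(effects$position, effects$nucleotide)
  ranked_keys <- key(ranked$position, ranked$nucleotide)

  if (n_planted == 0L) {
    return(list(planted = data.frame(), precision_at_k = NA_real_,
                all_signs_agree = NA, null_run = TRUE))
  }
  rank_of <- match(planted_keys, ranked_keys)
  idx <- match(planted_keys,
               key(features$position, features$nucleotide))
  recovered_dir <- features$direction[idx]
  expected_dir <- ifelse(effects$effect > 0, "favored", "disfavored")
  planted <- data.frame(
    position = effects$position, nucleotide = effects$nucleotide,
    effect = effects$effect, rank = rank_of,
    direction = recovered_dir,
    sign_agrees = !is.na(recovered_dir) & recovered_dir == expected_dir,
    stringsAsFactors = FALSE
  )
  top_k <- utils::head(ranked_keys, k)
  list(planted = planted,
       precision_at_k = length(intersect(top_k, planted_keys)) / k,
       all_signs_agree = all(planted$sign_agrees),
       null_run = FALSE)
}
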