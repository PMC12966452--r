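# Synthetic two-group cohort generator.
#
# The generator emulates the structure of an online task battery administered
# to autistic and non-autistic adults: 54 task-derived measures in 8
# correlated task blocks, plus age, gender, an AQ-28 total score and an
# abbreviated intelligence score (ICAR, proportion correct).  Group signal
# enters through per-feature standardized mean differences (Cohen's d) and,
# optionally, through "joint signals": feature pairs whose marginal group
# difference is zero but whose joint distribution differs between groups.

#' Default task-block schema
#'
#' Eight task blocks covering multisensory perception (`mcg`), emotion
#' recognition (`kdf`, `rme`, `psd`) and executive function (`gng`, `agc`,
#' `cbd`, `tmt`), with per-block feature counts summing to 54.
#'
#' @return Named integer vector mapping task code to feature count.
#' @export
default_task_blocks <- function() {
  c(mcg = 10L, kdf = 7L, rme = 7L, psd = 7L,
    gng = 6L, agc = 6L, cbd = 6L, tmt = 5L)
}

#' Feature names implied by a task-block schema
#'
#' Features are named `<task>_<index>` with a zero-padded two-digit index,
#' e.g. `rme_03`.
#'
#' @param task_blocks named integer vector of per-block feature counts.
#' @return Character vector of feature names, block by block.
#' @export
feature_names_from_blocks <- function(task_blocks) {
  stopifnot(length(task_blocks) > 0, !is.null(names(task_blocks)))
  unlist(lapply(names(task_blocks), function(b) {
    sprintf("%s_%02d", b, seq_len(task_blocks[[b]]))
  }), use.names = FALSE)
}

#' Illustrative per-feature effect-size profile
#'
#' A documented guess profile of standardized group mean differences
#' (Cohen's d; positive = autistic group higher).  It is not derived from
#' any published per-feature estimates: it encodes the qualitative pattern
#' that response-time measures on emotion-recognition tasks and several
#' executive-function measures separate the groups moderately, while most
#' measures (including all multisensory ones) show no marginal difference.
#'
#' @param task_blocks task-block schema (see [default_task_blocks()]).
#' @return Named numeric vector over all features; unlisted features are 0.
#' @export
default_effect_profile <- function(task_blocks = default_task_blocks()) {
  feats <- feature_names_from_blocks(task_blocks)
  d <- stats::setNames(numeric(length(feats)), feats)
  pick <- function(nm, val) {
    nm <- intersect(nm, feats)
    d[nm] <<- val[seq_along(nm)]
  }
  pick(c("kdf_01", "kdf_02"), c(0.50, 0.35))
  pick(c("rme_01", "rme_02", "rme_06"), c(0.55, 0.35, 0.30))
  pick(c("psd_01", "psd_02"), c(0.45, 0.30))
  pick(c("gng_01", "tmt_01", "tmt_02", "cbd_01", "agc_01"),
       c(0.30, 0.30, 0.25, 0.25, 0.20))
  d
}

#' Construct a joint-signal specification
#'
#' A joint signal couples two features so that the autistic group differs
#' from the non-autistic group only in the joint distribution of the pair:
#' autistic records falling in the quadrant where both features lie above
#' their group means are shifted outward by `shift` standard deviations on
#' both features, and records in the opposite quadrant (both below) are
#' shifted outward by the same amount in the negative direction.  The two
#' quadrant shifts mirror each other, so group means (and hence marginal
#' Cohen's d) are preserved exactly in expectation.
#'
#' @param features character vector of exactly two feature names.
#' @param shift outward quadrant shift in within-group standard deviations.
#' @return An object of class `joint_signal`.
#' @export
joint_signal <- function(features, shift = 1.0) {
  stopifnot(is.character(features), length(features) == 2,
            features[1] != features[2], is.numeric(shift), shift >= 0)
  structure(list(features = features, shift = shift), class = "joint_signal")
}

#' Default joint-signal specification
#'
#' One planted pair of executive-function features (`gng_03`, `cbd_04`) with
#' a 1 SD quadrant shift; both carry zero marginal effect in
#' [default_effect_profile()], so all their group signal lives in the pair.
#'
#' @return List of [joint_signal()] objects.
#' @export
default_joint_signals <- function() {
  list(joint_signal(c("gng_03", "cbd_04"), shift = 1.0))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the marginal structure of the registry cohort the
#' analysis is designed for: 286 autistic and 266 non-autistic adults, the
#' autistic group older (44.2 (13.6) vs 32.2 (12.0) years), with a higher
#' share of women (71.0% vs 48.9%), a much higher AQ-28 total
#' (83.4 (10.7) vs 60.1 (11.6)) and near-identical ICAR scores
#' (0.54 (0.20) vs 0.53 (0.17)).
#'
#' @param n_autistic,n_nonautistic group sizes (positive integers).
#' @param task_blocks named integer vector: features per task block.
#' @param effect_sizes named numeric vector of per-feature standardized mean
#'   differences (autistic minus non-autistic, in SD units).  Names must be
#'   a subset of the schema's feature names; omitted features get 0.
#' @param within_block_corr equicorrelation within each task block, in
#'   `[0, 1)`.  Either a single value or a named vector per block.
#' @param joint_signal_specs list of [joint_signal()] objects.
#' @param age_params,aq_params,icar_params lists with `autistic` and
#'   `nonautistic` elements, each `c(mean =, sd =)`.  Age in years, AQ on
#'   the AQ-28 total scale (truncated to its possible range 28..112), ICAR
#'   as proportion correct (truncated to `[0, 1]`).
#' @param gender_women_share named vector of the proportion of women per
#'   group, in `[0, 1]`.
#' @param lognormal_features character vector of features given a log-normal
#'   marginal (the generated Gaussian value is exponentiated), for
#'   response-time-like skew.
#' @param missing_rate proportion of records missing one entire task block
#'   (emulating attrition from one experiment); the number of incomplete
#'   records is exactly `round(missing_rate * n)`.
#' @param seed integer seed; generation is fully reproducible given the
#'   configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_autistic = 286L,
                             n_nonautistic = 266L,
                             task_blocks = default_task_blocks(),
                             effect_sizes = default_effect_profile(task_blocks),
                             within_block_corr = 0.3,
                             joint_signal_specs = default_joint_signals(),
                             age_params = list(
                               autistic = c(mean = 44.2, sd = 13.6),
                               nonautistic = c(mean = 32.2, sd = 12.0)),
                             gender_women_share = c(autistic = 0.710,
                                                    nonautistic = 0.489),
                             aq_params = list(
                               autistic = c(mean = 83.4, sd = 10.7),
                               nonautistic = c(mean = 60.1, sd = 11.6)),
                             icar_params = list(
                               autistic = c(mean = 0.54, sd = 0.20),
                               nonautistic = c(mean = 0.53, sd = 0.17)),
                             lognormal_features = character(),
                             missing_rate = 0,
                             seed = 1974L) {
  if (!is.numeric(n_autistic) || !is.numeric(n_nonautistic) ||
      n_autistic < 1 || n_nonautistic < 1) {
    stop("group sizes must be positive integers", call. = FALSE)
  }
  stopifnot(is.numeric(task_blocks), all(task_blocks >= 1),
            !is.null(names(task_blocks)))
  feats <- feature_names_from_blocks(task_blocks)

  d <- stats::setNames(numeric(length(feats)), feats)
  if (length(effect_sizes)) {
    bad <- setdiff(names(effect_sizes), feats)
    if (length(bad)) {
      stop("effect_sizes name features absent from the schema: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    d[names(effect_sizes)] <- effect_sizes
  }

  rho <- within_block_corr
  if (length(rho) == 1L) {
    rho <- stats::setNames(rep(rho, length(task_blocks)), names(task_blocks))
  }
  if (!all(names(task_blocks) %in% names(rho))) {
    stop("within_block_corr must cover every task block", call. = FALSE)
  }
  rho <- rho[names(task_blocks)]
  bad_rho <- names(rho)[rho < 0 | rho >= 1]
  if (length(bad_rho)) {
    stop("within_block_corr outside [0, 1) gives a non-positive-definite ",
         "covariance for block(s): ", paste(bad_rho, collapse = ", "),
         call. = FALSE)
  }

  for (js in joint_signal_specs) {
    stopifnot(inherits(js, "joint_signal"))
    missing_feats <- setdiff(js$features, feats)
    if (length(missing_feats)) {
      stop("joint signal names unknown feature(s): ",
           paste(missing_feats, collapse = ", "), call. = FALSE)
    }
  }

  check_ms <- function(p, what, sd_floor = 0) {
    stopifnot(all(c("autistic", "nonautistic") %in% names(p)))
    for (g in c("autistic", "nonautistic")) {
      if (!all(c("mean", "sd") %in% names(p[[g]])) || p[[g]][["sd"]] <= sd_floor)
        stop(what, " needs mean and positive sd for group ", g, call. = FALSE)
    }
  }
  check_ms(age_params, "age_params")
  check_ms(aq_params, "aq_params")
  check_ms(icar_params, "icar_params")
  stopifnot(all(gender_women_share >= 0 & gender_women_share <= 1),
            all(c("autistic", "nonautistic") %in% names(gender_women_share)),
            missing_rate >= 0, missing_rate <= 1)
  stopifnot(all(lognormal_features %in% feats))

  structure(list(
    n_autistic = as.integer(n_autistic),
    n_nonautistic = as.integer(n_nonautistic),
    task_blocks = task_blocks,
    feature_names = feats,
    effect_sizes = d,
    within_block_corr = rho,
    joint_signal_specs = joint_signal_specs,
    age_params = age_params,
    gender_women_share = gender_women_share,
    aq_params = aq_params,
    icar_params = icar_params,
    lognormal_features = lognormal_features,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Truncated-normal draws by rejection; truncation bounds are far enough from
# the configured means that acceptance rates stay high.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lower & x <= upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

# Draw one group's centered task-feature matrix: block-wise equicorrelated
# Gaussians, unit marginal variance.
draw_task_features <- function(n, task_blocks, rho) {
  mats <- lapply(names(task_blocks), function(b) {
    k <- task_blocks[[b]]
    z <- matrix(stats::rnorm(n * k), n, k)
    if (k > 1L && rho[[b]] > 0) {
      sigma <- matrix(rho[[b]], k, k)
      diag(sigma) <- 1
      z <- z %*% chol(sigma)
    }
    z
  })
  x <- do.call(cbind, mats)
  colnames(x) <- feature_names_from_blocks(task_blocks)
  x
}

#' Generate a synthetic participant cohort
#'
#' Draws `n_autistic + n_nonautistic` participant records with the structure
#' described in [synthetic_config()].  Task features are multivariate normal
#' within blocks with unit SD; the autistic group's means are shifted by the
#' configured effect sizes.  Joint signals then displace autistic records
#' outward in the two same-sign quadrants of the pair (relative to group
#' means), leaving marginal means unchanged.  With `missing_rate > 0`,
#' exactly `round(missing_rate * n)` records have one randomly chosen task
#' block set entirely missing.
#'
#' @param config a [synthetic_config()] object.
#' @return A `data.frame` of class `cohort`: columns `participant_id`,
#'   `group` (factor, `autistic`/`nonautistic`), `age`, `gender` (factor,
#'   `w`/`m`), `aq_total`, `icar`, then one column per task feature.  The
#'   task-block schema travels in the `"task_blocks"` attribute.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  feats <- config$feature_names
  groups <- c(autistic = config$n_autistic, nonautistic = config$n_nonautistic)

  one_group <- function(gname, n) {
    x <- draw_task_features(n, config$task_blocks, config$within_block_corr)
    for (js in config$joint_signal_specs) {
      if (gname == "autistic" && js$shift > 0) {
        f1 <- x[, js$features[1]]
        f2 <- x[, js$features[2]]
        hi <- f1 > 0 & f2 > 0
        lo <- f1 < 0 & f2 < 0
        x[hi, js$features] <- x[hi, js$features] + js$shift
        x[lo, js$features] <- x[lo, js$features] - js$shift
      }
    }
    if (gname == "autistic") {
      x <- sweep(x, 2L, config$effect_sizes, "+")
    }
    if (length(config$lognormal_features)) {
      x[, config$lognormal_features] <- exp(x[, config$lognormal_features])
    }
    ap <- config$age_params[[gname]]
    qp <- config$aq_params[[gname]]
    ip <- config$icar_params[[gname]]
    data.frame(
      group = gname,
      age = stats::rnorm(n, ap[["mean"]], ap[["sd"]]),
      gender = ifelse(
        stats::runif(n) < config$gender_women_share[[gname]], "w", "m"),
      aq_total = round(rtruncnorm(n, qp[["mean"]], qp[["sd"]], 28, 112)),
      icar = rtruncnorm(n, ip[["mean"]], ip[["sd"]], 0, 1),
      x,
      stringsAsFactors = FALSE
    )
  }

  records <- do.call(rbind, lapply(names(groups), function(g) {
    one_group(g, groups[[g]])
  }))
  n <- nrow(records)
  records <- data.frame(
    participant_id = sprintf("S%04d", seq_len(n)),
    records,
    stringsAsFactors = FALSE
  )
  records$group <- factor(records$group, levels = c("autistic", "nonautistic"))
  records$gender <- factor(records$gender, levels = c("w", "m"))

  n_missing <- round(config$missing_rate * n)
  if (n_missing > 0) {
    rows <- sample.int(n, n_missing)
    blocks <- sample(names(config$task_blocks), n_missing, replace = TRUE)
    for (i in seq_along(rows)) {
      bfeats <- grep(paste0("^", blocks[i], "_"), feats, value = TRUE)
      records[rows[i], bfeats] <- NA_real_
    }
  }

  structure(records, task_blocks = config$task_blocks,
            class = c("cohort", "data.frame"))
}

#' Task-feature column names of a cohort
#'
#' @param records a cohort data frame (see [generate_cohort()]).
#' @return Character vector of task-feature column names, schema order.
#' @export
cohort_feature_names <- function(records) {
  blocks <- attr(records, "task_blocks")
  if (is.null(blocks)) {
    demo <- c("participant_id", "group", "age", "gender", "aq_total", "icar")
    return(setdiff(names(records), demo))
  }
  feature_names_from_blocks(blocks)
}
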